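#' Read an XYZ file
#'
#' Standard XYZ: atom-count line, comment line, then `element x y z` in
#' Angstrom.  Multiple frames may be concatenated.
#'
#' @param file Path to an XYZ file.
#' @param params `qspcfw_params` supplying masses.
#' @return A single `wc_configuration`, or a list of them for multi-frame
#'   files.
#' @export
read_xyz <- function(file, params = qspcfw_params()) {
  lines <- readLines(file)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ at line ", i, ": expected atom count")
    if (i + 1 + n > length(lines)) stop("malformed XYZ at line ", i, ": truncated frame")
    block <- lines[(i + 2):(i + 1 + n)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(vapply(toks, length, integer(1)) < 4)
    if (length(bad)) stop("malformed XYZ at line ", i + 1 + bad[1], ": need element x y z")
    el <- vapply(toks, `[[`, character(1), 1)
    co <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(!is.finite(co))) stop("malformed XYZ at line ", i + 2, ": non-numeric coordinate")
    frames[[length(frames) + 1]] <- configuration(co, el, params = params)
    i <- i + 2 + n
  }
  if (!length(frames)) stop("no frames found in ", file)
  if (length(frames) == 1) frames[[1]] else frames
}

#' Write configurations to an XYZ file
#'
#' @param conf A `wc_configuration` or a list of them (multi-frame
#'   trajectory).
#' @param file Output path.
#' @param comment Comment line(s), recycled across frames.
#' @export
write_xyz <- function(conf, file, comment = "") {
  if (inherits(conf, "wc_configuration")) conf <- list(conf)
  comment <- rep_len(comment, length(conf))
  out <- character(0)
  for (k in seq_along(conf)) {
    cf <- conf[[k]]
    out <- c(out, as.character(nrow(cf$coords)), comment[k],
             sprintf("%-2s %18.10f %18.10f %18.10f",
                     cf$elements, cf$coords[, 1], cf$coords[, 2], cf$coords[, 3]))
  }
  writeLines(out, file)
  invisible(file)
}
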