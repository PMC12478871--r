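#' Read and validate a declarative run configuration
#'
#' YAML configuration for the end-to-end pipeline.  Recognized keys:
#' `cluster` (number of waters), `scale` (factor applied to the default
#' walker count), `params_file`, `scheme`, `basis`, `n_dmc_c` (concatenated
#' repetitions), `seed`, `output_dir`, and a `dmc` block accepting any
#' [dmc_config()] argument.  Defaults encode the production protocol
#' (tau = 50000, dtau = 1, tau_eq = 30000, 20 snapshots, tau_dw = 1000,
#' n_dw = 3; walker counts 5000/10000/50000/100000 for n = 1/2/3/>=4), so a
#' bare `cluster: 2` reproduces the full dimer protocol and `scale` shrinks
#' it proportionally.
#'
#' @param file YAML file path.
#' @return Object of class `run_config`.
#' @export
read_run_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  known <- c("cluster", "scale", "params_file", "scheme", "basis",
             "n_dmc_c", "seed", "output_dir", "dmc")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$cluster)) stop("missing configuration key: cluster")
  n <- as.integer(cfg$cluster)
  scale <- if (is.null(cfg$scale)) 1 else as.numeric(cfg$scale)
  default_nw <- c(5000, 10000, 50000, 100000)[min(n, 4)]
  dmc_args <- if (is.null(cfg$dmc)) list() else cfg$dmc
  bad2 <- setdiff(names(dmc_args), names(formals(dmc_config)))
  if (length(bad2)) stop("unknown dmc key(s): ", paste(bad2, collapse = ", "))
  if (is.null(dmc_args$n_walkers)) dmc_args$n_walkers <- max(2, round(default_nw * scale))
  if (!is.null(cfg$seed) && is.null(dmc_args$seed)) dmc_args$seed <- cfg$seed
  structure(list(cluster = n,
                 params_file = cfg$params_file,
                 scheme = if (is.null(cfg$scheme)) "chem_informed" else cfg$scheme,
                 basis = if (is.null(cfg$basis)) "n2" else cfg$basis,
                 n_dmc_c = if (is.null(cfg$n_dmc_c)) 1L else as.integer(cfg$n_dmc_c),
                 seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
                 output_dir = if (is.null(cfg$output_dir)) "dmcvib_out" else cfg$output_dir,
                 dmc = do.call(dmc_config, dmc_args)),
            class = "run_config")
}

#' Run the full pipeline: isomer search, DMC, GSPA, spectrum
#'
#' Executes the chain landscape search -> DMC repetitions -> descendant
#' weighting -> GSPA analysis -> spectrum, writing plain-text artifacts
#' (XYZ catalog, TSV mode table and spectrum, YAML summary stamped with the
#' seed and a configuration hash) plus RDS snapshot containers into the
#' output directory.
#'
#' @param cfg `run_config` (or path to a YAML file).
#' @param quiet Suppress progress messages.
#' @return `gspa_result`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  params <- if (is.null(cfg$params_file)) qspcfw_params() else qspcfw_params(cfg$params_file)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  say("isomer search (n = ", cfg$cluster, ")")
  cat_ <- isomer_search(cfg$cluster, params, seed = cfg$seed)
  write_xyz(cat_$minima, file.path(cfg$output_dir, "catalog.xyz"),
            comment = sprintf("minimum %d  E = %.6f kcal/mol",
                              seq_along(cat_$minima) - 1, cat_$energies))
  gm <- cat_$minima[[1]]
  runs <- vector("list", cfg$n_dmc_c)
  for (r in seq_len(cfg$n_dmc_c)) {
    rcfg <- cfg$dmc
    rcfg$seed <- cfg$seed + 1000L * (r - 1L)
    say("DMC repetition ", r, "/", cfg$n_dmc_c, " (seed ", rcfg$seed, ")")
    runs[[r]] <- run_dmc(water_system(gm, params, guided = rcfg$guided), rcfg)
  }
  save_snapshots(runs, file.path(cfg$output_dir, "snapshots.rds"))
  say("GSPA analysis (", cfg$scheme, ", ", cfg$basis, ")")
  res <- gspa_modes(runs, reference = gm, scheme = cfg$scheme, level = cfg$basis)
  utils::write.table(res$modes, file.path(cfg$output_dir, "modes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sp <- vibrational_spectrum(res)
  utils::write.table(sp$curve, file.path(cfg$output_dir, "spectrum.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- list(seed = cfg$seed, cluster = cfg$cluster, scheme = cfg$scheme,
               basis = cfg$basis, n_dmc_c = cfg$n_dmc_c,
               config_hash = .config_hash(cfg),
               zpe_kcal = mean(vapply(runs, zpe, numeric(1), units = "kcal")),
               acceptance = mean(vapply(runs, function(r)
                 if (is.na(r$acceptance)) 1 else r$acceptance, numeric(1))),
               cif_intra = res$cif$cif_intra)
  yaml::write_yaml(summ, file.path(cfg$output_dir, "summary.yml"))
  invisible(res)
}

.config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg))), collapse = "\n")
  # small rolling hash; provenance stamp, not cryptographic
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Persist DMC runs (snapshot container)
#'
#' Serializes runs -- walker coordinates, weights, descendant weights,
#' V_ref traces and full configuration metadata including the seed -- to an
#' RDS container.
#'
#' @param runs `dmc_run` or list of runs.
#' @param file Output path.
#' @export
save_snapshots <- function(runs, file) {
  saveRDS(runs, file)
  invisible(file)
}

#' @rdname save_snapshots
#' @return `load_snapshots` returns the stored run list.
#' @export
load_snapshots <- function(file) readRDS(file)
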