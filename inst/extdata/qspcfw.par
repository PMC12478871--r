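# q-SPC/Fw flexible point-charge water model.
#
# Intramolecular potential per monomer (harmonic, V = (k/2) x^2 convention):
#   V = (k_oh/2)(l1 - l_eq)^2 + (k_oh/2)(l2 - l_eq)^2 + (k_a/2)(theta - theta_eq)^2
# Intermolecular: O-O Lennard-Jones plus Coulomb over all atom pairs in
# different monomers.  No intramolecular nonbonded terms.
#
# The force constants are the flexible-SPC intramolecular pair; with the
# (k/2) convention they give an OH local-mode stretch harmonic of 3630 cm^-1
# (nu = sqrt(k_oh/mu_OH)/2 pi c) and an HOH local-mode bend harmonic of
# 1389 cm^-1 (mu_A = l_eq^2/2 / (1/m_H + (1-cos theta_eq)/m_O)).
# Masses are standard atomic weights.
k_oh      1059.162     # kcal mol^-1 A^-2
l_eq      1.0          # A
k_a       75.90        # kcal mol^-1 rad^-2
theta_eq  112.0        # degrees
q_o       -0.84        # e
q_h       0.42         # e
epsilon   0.1554253    # kcal mol^-1 (O-O Lennard-Jones well depth)
sigma     3.165492     # A (O-O Lennard-Jones radius)
m_h       1.008        # amu
m_o       15.999       # amu
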