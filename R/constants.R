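# Unit system of the dynamics layer: Angstrom, femtosecond, amu, kcal/mol, Kelvin.
# The quantum solver works internally in Hartree atomic units.

# Boltzmann constant, kcal mol^-1 K^-1
.kB <- 0.0019872041

# 1 kcal/mol expressed in the internal energy unit amu A^2 fs^-2
# (uses N_A * 1 amu = 1 g/mol)
.KCAL_TO_INT <- 4.184e-4

# speed of light, cm / fs
.C_CM_FS <- 2.99792458e-5

# atomic-unit conversions
.HARTREE_KCAL <- 627.509474
.HARTREE_CM <- 219474.6313632
.BOHR_ANG <- 0.529177210903
.AMU_ME <- 1822.888486
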