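# Embedded physical constants and element data shared across modules.

.AVOGADRO <- 6.02214076e23
.MEC2_MEV <- 0.51099895    # electron rest energy, MeV
.K_BETHE  <- 0.307075      # 4 pi N_A r_e^2 m_e c^2, MeV cm^2 / mol
.M_PROTON <- 938.27208816  # proton rest energy, MeV
.M_ALPHA  <- 3727.3794066  # alpha rest energy, MeV

# Element data: standard atomic weights and mean excitation energies (ICRU-37
# style I-values). Compositions quote principal isotopes (1H, 16O, ...); the
# difference between isotopic and standard masses is < 0.1% and irrelevant at
# the fidelity of the embedded physics.
.ELEMENTS <- data.frame(
  symbol = c("H", "B", "C", "N", "O", "P", "Ar"),
  Z      = c(1,   5,   6,   7,   8,   15,  18),
  A      = c(1.008, 10.811, 12.011, 14.007, 15.999, 30.974, 39.948),
  I_eV   = c(19.2, 76.0, 78.0, 82.0, 95.0, 173.0, 188.0),
  stringsAsFactors = FALSE
)
rownames(.ELEMENTS) <- .ELEMENTS$symbol

# natural boron isotopic atom fractions
.B10_ATOM_FRACTION <- 0.199
.B11_ATOM_FRACTION <- 0.801

# nuclide masses in amu, for two-body reaction kinematics
.NUCLIDE_MASS <- c(
  p = 1.007825, n = 1.008665, alpha = 4.002602,
  B9 = 9.013329, B10 = 10.012937, B11 = 11.009305,
  C11 = 11.011433, C12 = 12.0, N13 = 13.005739,
  N14 = 14.003074, O16 = 15.994915, P31 = 30.973762, Ar40 = 39.962383
)

# nuclides tracked in inventories (module contract)
.INVENTORY_NUCLIDES <- c("H1", "B10", "B11", "C12", "N14", "O16", "P31", "Ar40")

# map element symbol -> inventory nuclide (boron handled separately)
.ELEMENT_NUCLIDE <- c(H = "H1", C = "C12", N = "N14", O = "O16",
                      P = "P31", Ar = "Ar40")

# package-level cache (range-energy tables etc.)
.pbft_cache <- new.env(parent = emptyenv())
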