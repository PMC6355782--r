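#' Physical constants and unit conversions
#'
#' All coordinates and box lengths are in nm (GRO convention), energies in
#' kJ/mol, masses in amu, times in ns. `kB` is the Boltzmann constant in
#' kJ/(mol K), so `kB * 298` is the thermal energy at 298 K
#' (about 2.5 kJ/mol).
#'
#' @format `kB` is a single number, 0.0083145 kJ/(mol K).
#' @export
kB <- 0.0083145

# 1 kJ/(mol nm^2) expressed in mN/m (used for area compressibility output)
MN_PER_M_PER_KJ_MOL_NM2 <- 1.6606

# 1 nm^2/ns expressed in cm^2/s (diffusion coefficient conversion)
CM2_S_PER_NM2_NS <- 1e-5

#' Thermal energy kB*T
#'
#' @param temperature Absolute temperature in K.
#' @return Thermal energy in kJ/mol.
#' @examples
#' thermal_energy(298) # about 2.5 kJ/mol
#' @export
thermal_energy <- function(temperature) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  kB * temperature
}

# recognised bead group labels
GROUP_LEVELS <- c("lipid_head", "lipid_glycerol", "lipid_tail", "double_bond",
                  "fullerene", "water", "other")

LIPID_GROUPS <- c("lipid_head", "lipid_glycerol", "lipid_tail", "double_bond")
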