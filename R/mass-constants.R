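# Residue-level mass bookkeeping. Monoisotopic values are the standard
# most-abundant-isotope residue masses; average values follow the ExPASy
# reference table. Both are residue (dehydrated) masses: a free peptide adds
# one water.

.RESIDUE_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.RESIDUE_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.WATER_MONO <- 18.010565
.WATER_AVG <- 18.0153
.PROTON <- 1.007276

#' Mass constants used throughout the package
#'
#' Returns the residue and small-molecule masses that every mass computation
#' in the package draws from: standard monoisotopic and average (ExPASy)
#' residue masses for the 20 proteinogenic amino acids, the mass of water
#' (lost per dehydration event, gained once per free peptide), the proton
#' mass used for charge-state m/z arithmetic, and the deltas of the two
#' modifications the verification workflow uses (cysteine
#' carbamidomethylation from iodoacetamide alkylation, methionine oxidation).
#'
#' The same table ships as a plain-text resource at
#' `system.file("extdata", "residue_masses.tsv", package = "lanthominer")`
#' so that other implementations can diff it.
#'
#' @return A list with elements `residues` (a tibble with columns `residue`,
#'   `mono`, `avg` in Da), `water` (named vector `mono`, `avg`), `proton`
#'   (Da), and `mods` (named vector of modification deltas:
#'   `carbamidomethyl`, `oxidation`, `dehydration`).
#' @examples
#' mass_constants()$water
#' @export
mass_constants <- function() {
  list(
    residues = tibble(
      residue = names(.RESIDUE_MONO),
      mono = unname(.RESIDUE_MONO),
      avg = unname(.RESIDUE_AVG)
    ),
    water = c(mono = .WATER_MONO, avg = .WATER_AVG),
    proton = .PROTON,
    mods = c(
      carbamidomethyl = 57.02146,
      oxidation = 15.994915,
      dehydration = -.WATER_MONO
    )
  )
}

.residue_table <- function(mass_type = c("mono", "avg")) {
  mass_type <- match.arg(mass_type)
  if (mass_type == "mono") .RESIDUE_MONO else .RESIDUE_AVG
}

.water <- function(mass_type = c("mono", "avg")) {
  mass_type <- match.arg(mass_type)
  if (mass_type == "mono") .WATER_MONO else .WATER_AVG
}
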