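## Monoisotopic mass bookkeeping shared by every module.

## Charge carrier is the proton, not the hydrogen atom.
PROTON_MASS <- 1.007276466
WATER_MASS <- 18.0105646863
## Averaged neutral spacing between adjacent peptide isotope peaks.
ISOTOPE_SPACING <- 1.00235

## Monoisotopic residue masses for the 20 canonical amino acids.
RESIDUE_MASS <- c(
  G = 57.02146372376, A = 71.03711378471, S = 87.03202840427,
  P = 97.05276384885, V = 99.06841391299, T = 101.04767846841,
  C = 103.00918478471, L = 113.08406397713, I = 113.08406397713,
  N = 114.04292744114, D = 115.02694302383, Q = 128.05857750528,
  K = 128.09496301399, E = 129.04259308797, M = 131.04048491299,
  H = 137.05891185845, F = 147.06841391299, R = 156.10111102359,
  Y = 163.06332853255, W = 186.07931294986
)

#' Monoisotopic neutral mass of a peptide
#'
#' Computes the neutral monoisotopic mass as the sum of residue masses plus
#' one water, plus the delta masses of any modifications. Modification
#' positions are not needed for the mass itself, so `mods` may be given
#' either as a numeric vector of delta masses or as a two-column
#' `data.frame` with columns `position` and `delta_mass`.
#'
#' @param sequence Peptide sequence (canonical one-letter residues).
#' @param mods Modification delta masses in Da (numeric vector), or a
#'   `data.frame` with a `delta_mass` column. Default: none.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptideNeutralMass("G")           # 75.03203
#' peptideNeutralMass("PEPTIDE")
#' @export
peptideNeutralMass <- function(sequence, mods = numeric(0)) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("'sequence' must be a single non-empty string")
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  m <- RESIDUE_MASS[res]
  if (anyNA(m))
    stop("unknown residue(s): ", paste(unique(res[is.na(m)]), collapse = ", "))
  deltas <- if (is.data.frame(mods)) mods$delta_mass else as.numeric(mods)
  sum(m) + WATER_MASS + sum(deltas)
}

## Cumulative prefix residue masses (length L), including positional mod
## deltas. Internal helper for fragment generation.
prefixMasses <- function(sequence, mod_pos = integer(0), mod_delta = numeric(0)) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  m <- RESIDUE_MASS[res]
  if (anyNA(m))
    stop("unknown residue(s): ", paste(unique(res[is.na(m)]), collapse = ", "))
  if (length(mod_pos)) {
    ## 0-based positions onto 1-based vector
    m[mod_pos + 1L] <- m[mod_pos + 1L] + mod_delta
  }
  cumsum(m)
}

## m/z of an ion given its neutral mass and positive charge.
massToMz <- function(neutral_mass, charge) {
  (neutral_mass + charge * PROTON_MASS) / charge
}

## Inverse: neutral mass from m/z at a given charge.
mzToMass <- function(mz, charge) {
  mz * charge - charge * PROTON_MASS
}
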