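## fragment_index: theoretical b/y fragment generation, the binned
## fragment index, and full-isolation-window candidate retrieval.

#' Theoretical b/y fragments of a peptide
#'
#' All b and y ions with ordinals 1..L-1 at fragment charges
#' 1..`max_frag_charge`; modification deltas are folded into the prefix
#' and suffix masses.
#'
#' @param sequence Peptide sequence.
#' @param mods Modification string (`"pos:delta;..."`, 0-based) or a
#'   list as from [parseMods()].
#' @param max_frag_charge Maximum fragment charge (default 1).
#' @return data.frame with columns series (`"b"`/`"y"`), ordinal,
#'   charge, mz.
#' @examples
#' generateFragments("GK")  # b1 = 58.02874, y1 = 147.11280
#' @export
generateFragments <- function(sequence, mods = "", max_frag_charge = 1L) {
  if (is.character(mods)) mods <- parseMods(mods)
  L <- nchar(sequence)
  if (L < 2L) stop("peptide must have at least 2 residues")
  pref <- prefixMasses(sequence, mods$pos, mods$delta)
  total <- pref[L]
  ord <- seq_len(L - 1L)
  b_neutral <- pref[ord]                       # prefix fragments
  y_neutral <- total - pref[L - ord] + WATER_MASS  # suffix + water
  out <- vector("list", max_frag_charge)
  for (z in seq_len(max_frag_charge)) {
    out[[z]] <- data.frame(
      series = rep(c("b", "y"), each = L - 1L),
      ordinal = c(ord, ord),
      charge = z,
      mz = c((b_neutral + z * PROTON_MASS) / z,
             (y_neutral + z * PROTON_MASS) / z))
  }
  do.call(rbind, out)
}

#' Build the binned fragment index over a peptide database
#'
#' Every b/y fragment of every peptide is assigned to the m/z bin
#' `floor(mz / bin_width)`; within each bin entries are ordered by the
#' parent peptide's neutral mass. Fragments outside `mz_range` are not
#' indexed.
#'
#' @param db A [PeptideDb-class] (or its peptide data.frame).
#' @param bin_width Bin width in Th (default 0.02, suited to
#'   high-resolution MS2).
#' @param max_frag_charge Maximum fragment charge to index.
#' @param mz_range Fragment m/z range retained in the index.
#' @return A [FragmentIndex-class].
#' @export
buildFragmentIndex <- function(db, bin_width = 0.02, max_frag_charge = 1L,
                               mz_range = c(100, 2000)) {
  pep <- if (is(db, "PeptideDb")) peptides(db) else db
  n <- nrow(pep)
  if (!n) stop("empty peptide table")
  frag <- vector("list", n)
  for (i in seq_len(n)) {
    f <- generateFragments(pep$sequence[i], pep$mods[i], max_frag_charge)
    keep <- f$mz >= mz_range[1] & f$mz <= mz_range[2]
    if (!any(keep)) { frag[[i]] <- NULL; next }
    f <- f[keep, , drop = FALSE]
    f$pep <- i
    frag[[i]] <- f
  }
  frag <- do.call(rbind, frag)
  bin <- floor(frag$mz / bin_width)
  pm <- pep$neutral_mass
  o <- order(bin, pm[frag$pep], frag$mz)
  frag <- frag[o, ]; bin <- bin[o]
  bin_ids <- unique(bin)                       # already sorted
  bin_offsets <- c(0L, cumsum(tabulate(match(bin, bin_ids))))
  new("FragmentIndex",
      bin_width = bin_width,
      frag_mz = frag$mz,
      frag_pep = as.integer(frag$pep),
      frag_series = ifelse(frag$series == "b", 1L, 2L),
      frag_ordinal = as.integer(frag$ordinal),
      frag_charge = as.integer(frag$charge),
      bin_ids = as.numeric(bin_ids),
      bin_offsets = as.integer(bin_offsets),
      pep_mass = pm,
      mass_order = order(pm),
      mass_sorted = sort(pm),
      mz_range = as.numeric(mz_range))
}

## Fragment entries whose m/z lies within [lo, hi], as integer indices
## into the index's fragment vectors.
indexEntriesInMzRange <- function(index, lo, hi) {
  b0 <- floor(lo / index@bin_width)
  b1 <- floor(hi / index@bin_width)
  pos <- findInterval(c(b0, b1), index@bin_ids)
  from <- if (pos[1] >= 1L && index@bin_ids[pos[1]] == b0) pos[1] else pos[1] + 1L
  to <- pos[2]
  if (from > to) return(integer(0))
  e <- (index@bin_offsets[from] + 1L):index@bin_offsets[to + 1L]
  e[index@frag_mz[e] >= lo & index@frag_mz[e] <= hi]
}

#' Candidate peptides inside an isolation window
#'
#' Retrieves every (peptide, assumed charge, isotope error) whose
#' precursor m/z, `(M + e * 1.00235 + z * 1.007276466) / z`, falls
#' inside `iso_center +/- iso_width/2`, by binary search over the
#' mass-sorted peptide list. Isotope errors are applied as negative
#' monoisotopic shifts: a peptide isolated on its M+e isotope peak is
#' still a candidate. One row per (peptide, charge) is returned, keeping
#' the smallest qualifying isotope error.
#'
#' @param index A [FragmentIndex-class] (carries the mass-sorted
#'   peptides), or a numeric vector of neutral masses sorted ascending.
#' @param iso_center,iso_width Isolation window center and full width
#'   (Th).
#' @param charges Assumed precursor charges to consider.
#' @param isotope_errors Isotope-error set (default 0:2).
#' @return data.frame with columns pep (peptide index), charge,
#'   isotope_error, ordered by (pep, charge).
#' @export
candidatesInWindow <- function(index, iso_center, iso_width,
                               charges = 2:4, isotope_errors = 0:2) {
  if (is(index, "FragmentIndex")) {
    sorted <- index@mass_sorted
    perm <- index@mass_order
  } else {
    sorted <- index
    perm <- seq_along(index)
  }
  lo_mz <- iso_center - iso_width / 2
  hi_mz <- iso_center + iso_width / 2
  pep <- integer(0); chg <- integer(0); err <- integer(0)
  for (z in charges) {
    for (e in isotope_errors) {
      m_lo <- mzToMass(lo_mz, z) - e * ISOTOPE_SPACING
      m_hi <- mzToMass(hi_mz, z) - e * ISOTOPE_SPACING
      r <- findInterval(c(m_lo, m_hi), sorted)
      ## masses strictly above m_lo up to m_hi; handle ties on the
      ## boundary by widening to >= via a tiny left-closed correction
      from <- r[1] + 1L
      if (from > 1L && sorted[from - 1L] == m_lo) from <- from - 1L
      if (from <= r[2]) {
        idx <- perm[from:r[2]]
        pep <- c(pep, idx)
        chg <- c(chg, rep.int(as.integer(z), length(idx)))
        err <- c(err, rep.int(as.integer(e), length(idx)))
      }
    }
  }
  if (!length(pep))
    return(data.frame(pep = integer(0), charge = integer(0),
                      isotope_error = integer(0)))
  o <- order(pep, chg, err)
  pep <- pep[o]; chg <- chg[o]; err <- err[o]
  keep <- !duplicated(paste(pep, chg))
  data.frame(pep = pep[keep], charge = chg[keep],
             isotope_error = err[keep])
}
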