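## search_engine: hyperscore PSM scoring of every candidate peptide in
## the isolation window, via the binned fragment index.

#' Match theoretical fragments to spectrum peaks
#'
#' Each theoretical fragment matches at most one peak: the nearest peak
#' within tolerance (ties resolve to the lower-m/z peak). A peak may be
#' matched by several fragments of the same candidate but is counted
#' once in the matched-peak set.
#'
#' @param peaks Two-column peak matrix (mz, intensity), m/z-sorted.
#' @param frag_mz Theoretical fragment m/z values.
#' @param tol Tolerance value.
#' @param tol_unit `"ppm"` or `"Th"`.
#' @return Integer vector parallel to `frag_mz`: the matched peak row
#'   index, or NA.
#' @export
matchFragments <- function(peaks, frag_mz, tol = 20, tol_unit = "ppm") {
  np <- nrow(peaks)
  nf <- length(frag_mz)
  if (!np || !nf) return(rep(NA_integer_, nf))
  pmz <- peaks[, 1L]
  idx <- findInterval(frag_mz, pmz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, np)
  d_lo <- abs(pmz[lo] - frag_mz)
  d_hi <- abs(pmz[hi] - frag_mz)
  pick <- ifelse(d_lo <= d_hi, lo, hi)
  d <- abs(pmz[pick] - frag_mz)
  tolv <- if (tol_unit == "ppm") frag_mz * tol * 1e-6 else rep(tol, nf)
  ifelse(d <= tolv, pick, NA_integer_)
}

#' Hyperscore
#'
#' X!Tandem-lineage similarity score:
#' `log10(Nb! * Ny! * max(sum Ib, 1) * max(sum Iy, 1))`, with the
#' factorial counts capped (default 64) and evaluated through the
#' log-gamma function. Returns 0 when no fragment of either series
#' matched.
#'
#' @param sum_b,sum_y Matched intensity sums for the b and y series.
#' @param n_b,n_y Matched fragment counts per series.
#' @param cap Factorial-argument cap.
#' @return Non-negative score.
#' @examples
#' hyperscore(100, 10, 2, 1)  # log10(2 * 1 * 100 * 10) = 3.30103
#' @export
hyperscore <- function(sum_b, sum_y, n_b, n_y, cap = 64L) {
  n_b <- pmin(n_b, cap)
  n_y <- pmin(n_y, cap)
  s <- (lgamma(n_b + 1) + lgamma(n_y + 1)) / log(10) +
    log10(pmax(sum_b, 1)) + log10(pmax(sum_y, 1))
  ifelse(n_b + n_y == 0L, 0, s)
}

## Vectorized index-driven scoring of one spectrum against a candidate
## peptide set. Walks spectrum peaks -> occupied bins -> fragment
## entries, keeps entries of candidate peptides within tolerance,
## resolves each fragment to its nearest peak, and aggregates matched
## counts and intensity sums per peptide and ion series. Identical in
## result to naive per-candidate matching with matchFragments().
scoreCandidatesIndexed <- function(index, peaks, cand_pep, tol = 20,
                                   tol_unit = "ppm") {
  ucand <- sort(unique(cand_pep))
  nc <- length(ucand)
  out <- data.frame(pep = ucand, n_b = 0L, n_y = 0L, sum_b = 0,
                    sum_y = 0)
  np <- nrow(peaks)
  if (!np || !nc) return(out)
  pmz <- peaks[, 1L]; pint <- peaks[, 2L]
  ## gather band around each peak, slightly widened; the exact
  ## tolerance test below is relative to the fragment m/z, matching
  ## matchFragments()
  tolv <- if (tol_unit == "ppm") pmz * tol * 1e-6 * 1.001 else
    rep(tol, np)
  lo <- pmz - tolv; hi <- pmz + tolv
  bw <- index@bin_width
  b0 <- floor(lo / bw); b1 <- floor(hi / bw)
  nbins <- as.integer(b1 - b0 + 1)
  peak_rep <- rep.int(seq_len(np), nbins)
  bins <- b0[peak_rep] + (sequence(nbins) - 1)
  pos <- findInterval(bins, index@bin_ids)
  ok <- pos >= 1L
  ok[ok] <- index@bin_ids[pos[ok]] == bins[ok]
  if (!any(ok)) return(out)
  pos <- pos[ok]; peak_rep <- peak_rep[ok]
  from <- index@bin_offsets[pos] + 1L
  cnt <- index@bin_offsets[pos + 1L] - index@bin_offsets[pos]
  entry <- sequence(cnt, from = from)
  pk <- rep.int(peak_rep, cnt)
  if (!length(entry)) return(out)
  candmask <- logical(length(index@pep_mass))
  candmask[ucand] <- TRUE
  fmz <- index@frag_mz[entry]
  ftol <- if (tol_unit == "ppm") fmz * tol * 1e-6 else tol
  keep <- candmask[index@frag_pep[entry]] &
    abs(fmz - pmz[pk]) <= ftol
  entry <- entry[keep]; pk <- pk[keep]
  if (!length(entry)) return(out)
  ## nearest peak per fragment entry; tie -> lower m/z peak
  d <- abs(index@frag_mz[entry] - pmz[pk])
  o <- order(entry, d, pmz[pk])
  entry <- entry[o]; pk <- pk[o]
  first <- !duplicated(entry)
  entry <- entry[first]; pk <- pk[first]
  local <- match(index@frag_pep[entry], ucand)
  g <- (local - 1L) * 2L + index@frag_series[entry]
  counts <- tabulate(g, nbins = 2L * nc)
  sums <- numeric(2L * nc)
  agg <- rowsum(pint[pk], g)
  sums[as.integer(rownames(agg))] <- agg[, 1L]
  out$n_b <- counts[seq(1L, 2L * nc, by = 2L)]
  out$n_y <- counts[seq(2L, 2L * nc, by = 2L)]
  out$sum_b <- sums[seq(1L, 2L * nc, by = 2L)]
  out$sum_y <- sums[seq(2L, 2L * nc, by = 2L)]
  out
}

## Matched peak ids (unique, sorted) of one candidate against a peak
## set, by naive fragment matching. Used for the top-k PSMs only.
matchedPeakIds <- function(peaks, sequence, mods, tol, tol_unit,
                           max_frag_charge = 1L,
                           mz_range = c(100, 2000)) {
  f <- generateFragments(sequence, mods, max_frag_charge)
  f <- f[f$mz >= mz_range[1] & f$mz <= mz_range[2], , drop = FALSE]
  m <- matchFragments(peaks, f$mz, tol, tol_unit)
  sort(unique(m[!is.na(m)]))
}

## Deterministic PSM ordering: hyperscore desc, matched peaks desc,
## |theo precursor mz - window center| asc, peptide sequence, charge.
orderPsms <- function(score, n_matched, center_dist, sequence, charge) {
  order(-score, -n_matched, center_dist, sequence, charge)
}

#' Search one MS2 spectrum against the full isolation window
#'
#' Scores every (peptide, assumed charge, isotope error) candidate
#' retrieved by [candidatesInWindow()] with the hyperscore, discards
#' PSMs with fewer than `min_matched` matched fragments, and returns
#' the `top_k` PSMs. Ties break by more matched peaks, then smaller
#' distance of the theoretical precursor m/z to the window center,
#' then peptide sequence.
#'
#' @param peaks Preprocessed peak matrix of the spectrum.
#' @param index A [FragmentIndex-class] built over `db`.
#' @param db A [PeptideDb-class].
#' @param iso_center,iso_width Isolation window (Th).
#' @param params Search parameters, see [searchParamsDefault()].
#' @return data.frame of PSMs with columns pep, sequence, mods, origin,
#'   assumed_charge, isotope_error, hyperscore, n_matched_b,
#'   n_matched_y, theo_precursor_mz, rank, and a list-column
#'   matched_peaks.
#' @export
searchSpectrum <- function(peaks, index, db, iso_center, iso_width,
                           params = searchParamsDefault()) {
  cand <- candidatesInWindow(index, iso_center, iso_width,
                             charges = params$charges,
                             isotope_errors = params$isotope_errors)
  scorePsmCandidates(peaks, index, db, cand, iso_center, params)
}

## Shared scoring/ranking core for the full-window and narrow-window
## search modes.
scorePsmCandidates <- function(peaks, index, db, cand, iso_center,
                               params) {
  empty <- data.frame(
    pep = integer(0), sequence = character(0), mods = character(0),
    origin = character(0), assumed_charge = integer(0),
    isotope_error = integer(0), hyperscore = numeric(0),
    n_matched_b = integer(0), n_matched_y = integer(0),
    theo_precursor_mz = numeric(0), rank = integer(0))
  empty$matched_peaks <- list()
  if (!nrow(cand) || !nrow(peaks)) return(empty)
  sc <- scoreCandidatesIndexed(index, peaks, cand$pep,
                               tol = params$fragment_tol,
                               tol_unit = params$fragment_tol_unit)
  sc <- sc[match(cand$pep, sc$pep), ]
  n_matched <- sc$n_b + sc$n_y
  keep <- n_matched >= params$min_matched
  if (!any(keep)) return(empty)
  cand <- cand[keep, , drop = FALSE]
  sc <- sc[keep, , drop = FALSE]
  n_matched <- n_matched[keep]
  pep <- peptides(db)
  score <- hyperscore(sc$sum_b, sc$sum_y, sc$n_b, sc$n_y,
                      cap = params$hyperscore_cap)
  theo_mz <- massToMz(pep$neutral_mass[cand$pep], cand$charge)
  o <- orderPsms(score, n_matched, abs(theo_mz - iso_center),
                 pep$sequence[cand$pep], cand$charge)
  o <- o[seq_len(min(length(o), params$top_k))]
  out <- data.frame(
    pep = cand$pep[o],
    sequence = pep$sequence[cand$pep[o]],
    mods = pep$mods[cand$pep[o]],
    origin = pep$origin[cand$pep[o]],
    assumed_charge = cand$charge[o],
    isotope_error = cand$isotope_error[o],
    hyperscore = score[o],
    n_matched_b = sc$n_b[o],
    n_matched_y = sc$n_y[o],
    theo_precursor_mz = theo_mz[o],
    rank = seq_along(o),
    stringsAsFactors = FALSE)
  out$matched_peaks <- lapply(seq_len(nrow(out)), function(i) {
    matchedPeakIds(peaks, out$sequence[i], out$mods[i],
                   params$fragment_tol, params$fragment_tol_unit,
                   max_frag_charge = params$max_frag_charge,
                   mz_range = index@mz_range)
  })
  out
}

## Narrow-tolerance candidate retrieval for the conventional
## single-identification baseline: peptides whose theoretical precursor
## m/z at the reported charge(s) lies within precursor_tol (ppm) of the
## reported precursor m/z, allowing the configured isotope errors.
candidatesNarrow <- function(index, precursor_mz, charges,
                             precursor_tol = 20, isotope_errors = 0:2) {
  sorted <- index@mass_sorted
  perm <- index@mass_order
  tol <- precursor_mz * precursor_tol * 1e-6
  pep <- integer(0); chg <- integer(0); err <- integer(0)
  for (z in charges) {
    for (e in isotope_errors) {
      m_lo <- mzToMass(precursor_mz - tol, z) - e * ISOTOPE_SPACING
      m_hi <- mzToMass(precursor_mz + tol, z) - e * ISOTOPE_SPACING
      r <- findInterval(c(m_lo, m_hi), sorted)
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

#' Default search parameters
#'
#' @param fragment_tol,fragment_tol_unit Fragment match tolerance
#'   (default 20 ppm).
#' @param precursor_tol Precursor tolerance in ppm (narrow/baseline
#'   mode and XIC trace extraction; default 10).
#' @param charges Assumed precursor charges (default 2:4; the
#'   instrument-reported charge is considered but never restricts the
#'   set).
#' @param isotope_errors Allowed isotope errors (default 0:2).
#' @param top_k PSMs per spectrum entering refinement (default 5).
#' @param min_matched Minimum matched fragments for a PSM to survive;
#'   also the greedy-rescore termination floor (default 4).
#' @param max_frag_charge Fragment charge cap (default 1).
#' @param hyperscore_cap Factorial cap in the hyperscore (default 64).
#' @param top_n_peaks,min_intensity_frac MS2 preprocessing, see
#'   [preprocessMs2()].
#' @return Named list of parameters.
#' @export
searchParamsDefault <- function(fragment_tol = 20,
                                fragment_tol_unit = "ppm",
                                precursor_tol = 10,
                                charges = 2:4,
                                isotope_errors = 0:2,
                                top_k = 5L,
                                min_matched = 4L,
                                max_frag_charge = 1L,
                                hyperscore_cap = 64L,
                                top_n_peaks = 150L,
                                min_intensity_frac = 0.01) {
  list(fragment_tol = fragment_tol, fragment_tol_unit = fragment_tol_unit,
       precursor_tol = precursor_tol, charges = charges,
       isotope_errors = isotope_errors, top_k = as.integer(top_k),
       min_matched = as.integer(min_matched),
       max_frag_charge = as.integer(max_frag_charge),
       hyperscore_cap = as.integer(hyperscore_cap),
       top_n_peaks = as.integer(top_n_peaks),
       min_intensity_frac = min_intensity_frac)
}

#' Search every MS2 spectrum of a run
#'
#' Applies [preprocessMs2()] and [searchSpectrum()] (or the
#' narrow-window baseline retrieval when `mode = "dda_single"`) to each
#' MS2 scan. Output is deterministic and independent of scan processing
#' order. Per-spectrum failures are logged and skipped, never abort the
#' run.
#'
#' @param run An [MsRun-class].
#' @param index A [FragmentIndex-class] built over `db`.
#' @param db A [PeptideDb-class].
#' @param params See [searchParamsDefault()].
#' @param mode `"dda_plus"` (full isolation window) or `"dda_single"`
#'   (reported precursor +/- `precursor_tol` ppm, rank-1 only).
#' @return A [PsmSet-class]; the PSM table gains scan columns scan_id,
#'   rt, iso_center, iso_width.
#' @export
searchRun <- function(run, index, db, params = searchParamsDefault(),
                      mode = c("dda_plus", "dda_single")) {
  mode <- match.arg(mode)
  ms2 <- ms2Scans(run)
  res <- vector("list", nrow(ms2))
  for (i in seq_len(nrow(ms2))) {
    peaks <- preprocessMs2(ms2Peaks(run)[[i]],
                           top_n = params$top_n_peaks,
                           min_intensity_frac = params$min_intensity_frac)
    psms <- tryCatch({
      if (mode == "dda_plus") {
        searchSpectrum(peaks, index, db, ms2$iso_center[i],
                       ms2$iso_width[i], params)
      } else {
        pmz <- ms2$precursor_mz[i]
        if (is.na(pmz)) pmz <- ms2$iso_center[i]
        zs <- if (!is.na(ms2$precursor_charge[i]))
          ms2$precursor_charge[i] else params$charges
        cand <- candidatesNarrow(index, pmz, zs,
                                 precursor_tol = params$precursor_tol,
                                 isotope_errors = params$isotope_errors)
        p1 <- scorePsmCandidates(peaks, index, db, cand,
                                 ms2$iso_center[i], params)
        p1[p1$rank == 1L, , drop = FALSE]
      }
    }, error = function(e) {
      message("scan ", ms2$scan_id[i], " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(psms) || !nrow(psms)) next
    psms$scan_id <- ms2$scan_id[i]
    psms$scan_index <- i
    psms$rt <- ms2$rt[i]
    psms$iso_center <- ms2$iso_center[i]
    psms$iso_width <- ms2$iso_width[i]
    res[[i]] <- psms
  }
  res <- res[!vapply(res, is.null, logical(1))]
  tab <- if (length(res)) do.call(rbind, res) else
    data.frame(scan_id = integer(0))
  new("PsmSet", psms = tab, run_id = runId(run),
      params = c(params, list(mode = mode)))
}
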