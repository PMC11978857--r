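## chimera_rescore: greedy shared-fragment removal and hyperscore
## re-computation across the per-spectrum PSM list.

## Current match state of a set of PSM fragment lists against the
## remaining (not yet claimed) peaks. frag_list is a list of data.frames
## (mz, series) per PSM.
rescoreState <- function(peaks, remaining, frag_list, tol, tol_unit,
                         cap = 64L) {
  origidx <- which(remaining)
  sub <- peaks[remaining, , drop = FALSE]
  n <- length(frag_list)
  score <- numeric(n); n_matched <- integer(n)
  nb <- integer(n); ny <- integer(n)
  matched <- vector("list", n)
  for (i in seq_len(n)) {
    f <- frag_list[[i]]
    m <- matchFragments(sub, f$mz, tol, tol_unit)
    hit <- !is.na(m)
    isb <- f$series[hit] == "b"
    nb[i] <- sum(isb); ny[i] <- sum(!isb)
    sb <- sum(sub[m[hit][isb], 2L])
    sy <- sum(sub[m[hit][!isb], 2L])
    score[i] <- hyperscore(sb, sy, nb[i], ny[i], cap = cap)
    n_matched[i] <- nb[i] + ny[i]
    matched[[i]] <- origidx[unique(m[hit])]
  }
  list(score = score, n_matched = n_matched, n_b = nb, n_y = ny,
       matched = matched)
}

#' Greedy shared-fragment rescoring of one spectrum's PSM list
#'
#' Iteratively: emit the current top-scoring PSM with its current
#' score, remove the peaks it matched from the spectrum, recompute
#' every remaining PSM's match and hyperscore against the reduced peak
#' set, drop PSMs left with fewer than `min_matched` matched fragments,
#' re-rank, and repeat until no PSM can still be matched (or
#' `max_chimeras` PSMs have been emitted). The first emitted PSM is
#' always the global top scorer on the full spectrum, with its original
#' score.
#'
#' @param peaks Preprocessed peak matrix of the spectrum.
#' @param psms data.frame of PSMs for this spectrum (columns sequence,
#'   mods, assumed_charge, theo_precursor_mz, hyperscore, ...).
#' @param params Search parameters ([searchParamsDefault()]); supplies
#'   the tolerance, `min_matched` and the fragment charge cap.
#' @param max_chimeras Maximum emissions per spectrum (default 5).
#' @param iso_center Window center used in tie-breaking (defaults to
#'   the PSM table's `iso_center` if present, else 0).
#' @param mz_range Fragment m/z range (must match the search index).
#' @return The emitted PSMs with columns `rescored_hyperscore`,
#'   `emission_rank`, `n_matched_rescored` added, in emission order.
#' @export
greedyRescore <- function(peaks, psms, params = searchParamsDefault(),
                          max_chimeras = 5L, iso_center = NULL,
                          mz_range = c(100, 2000)) {
  if (is.null(iso_center))
    iso_center <- if ("iso_center" %in% names(psms) && nrow(psms))
      psms$iso_center[1L] else 0
  out0 <- psms[0, , drop = FALSE]
  out0$rescored_hyperscore <- numeric(0)
  out0$emission_rank <- integer(0)
  out0$n_matched_rescored <- integer(0)
  if (!nrow(psms) || !nrow(peaks)) return(out0)

  frag_list <- lapply(seq_len(nrow(psms)), function(i) {
    f <- generateFragments(psms$sequence[i], psms$mods[i],
                           params$max_frag_charge)
    f[f$mz >= mz_range[1] & f$mz <= mz_range[2], c("mz", "series")]
  })
  remaining <- rep(TRUE, nrow(peaks))
  live <- seq_len(nrow(psms))
  st <- rescoreState(peaks, remaining, frag_list, params$fragment_tol,
                     params$fragment_tol_unit, params$hyperscore_cap)
  emitted <- list()
  while (length(live) && length(emitted) < max_chimeras) {
    o <- orderPsms(st$score, st$n_matched,
                   abs(psms$theo_precursor_mz[live] - iso_center),
                   psms$sequence[live], psms$assumed_charge[live])
    top <- o[1L]
    em <- psms[live[top], , drop = FALSE]
    em$rescored_hyperscore <- st$score[top]
    em$emission_rank <- length(emitted) + 1L
    em$n_matched_rescored <- st$n_matched[top]
    emitted[[length(emitted) + 1L]] <- em
    remaining[st$matched[[top]]] <- FALSE
    live <- live[-top]
    if (!length(live)) break
    st <- rescoreState(peaks, remaining, frag_list[live],
                       params$fragment_tol, params$fragment_tol_unit,
                       params$hyperscore_cap)
    keep <- st$n_matched >= params$min_matched
    live <- live[keep]
    st <- lapply(st, function(x) if (is.list(x)) x[keep] else x[keep])
  }
  out <- do.call(rbind, emitted)
  rownames(out) <- NULL
  out
}

#' Greedy rescoring across a whole run
#'
#' Applies [greedyRescore()] to the (XIC-filtered) PSM list of each
#' spectrum. Spectra are processed independently; output order follows
#' the scan order.
#'
#' @param psmset A [PsmSet-class] (after [filterByXic()] in the
#'   standard pipeline).
#' @param run The searched [MsRun-class].
#' @param max_chimeras Maximum emissions per spectrum.
#' @param mz_range Fragment m/z range used by the search index.
#' @return A [PsmSet-class] whose table contains only emitted PSMs.
#' @export
rescoreRun <- function(psmset, run, max_chimeras = 5L,
                       mz_range = c(100, 2000)) {
  tab <- psmTable(psmset)
  params <- psmset@params
  if (!nrow(tab))
    return(new("PsmSet", psms = tab, run_id = psmset@run_id,
               params = c(params, list(max_chimeras = max_chimeras))))
  pieces <- split(seq_len(nrow(tab)), tab$scan_index)
  res <- vector("list", length(pieces))
  for (j in seq_along(pieces)) {
    rows <- pieces[[j]]
    i <- tab$scan_index[rows[1L]]
    peaks <- preprocessMs2(ms2Peaks(run)[[i]],
                           top_n = params$top_n_peaks,
                           min_intensity_frac = params$min_intensity_frac)
    res[[j]] <- greedyRescore(peaks, tab[rows, , drop = FALSE], params,
                              max_chimeras = max_chimeras,
                              mz_range = mz_range)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$scan_index, out$emission_rank), , drop = FALSE]
  rownames(out) <- NULL
  new("PsmSet", psms = out, run_id = psmset@run_id,
      params = c(params, list(max_chimeras = max_chimeras)))
}

#' Assemble the final result table
#'
#' One row per emitted PSM with the identification, scores and
#' precursor-evidence metrics; list-columns are dropped.
#'
#' @param psmset A rescored [PsmSet-class] (see [rescoreRun()]).
#' @return data.frame ordered by (scan_id, emission_rank).
#' @export
assembleResults <- function(psmset) {
  tab <- psmTable(psmset)
  cols <- c("scan_id", "rt", "iso_center", "iso_width",
            "emission_rank", "sequence", "mods", "assumed_charge",
            "isotope_error", "theo_precursor_mz",
            "observed_precursor_mz", "hyperscore",
            "rescored_hyperscore", "n_matched_b", "n_matched_y",
            "n_isotopes_detected", "n_consecutive_scans", "xic_kl",
            "xic_quality", "origin")
  if (!nrow(tab)) {
    out <- as.data.frame(stats::setNames(rep(list(logical(0)),
                                             length(cols)), cols))
    return(out)
  }
  if (!"emission_rank" %in% names(tab)) tab$emission_rank <- tab$rank
  keep <- intersect(cols, names(tab))
  out <- tab[order(tab$scan_id, tab$emission_rank), keep, drop = FALSE]
  rownames(out) <- NULL
  out
}
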