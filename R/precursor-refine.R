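## precursor_refine: targeted extraction of precursor isotope XICs for
## each surviving PSM, envelope quality scoring with the
## Kullback-Leibler divergence, and filtering of PSMs without credible
## precursor evidence.

## Averagine unit composition per 111.1254 Da of peptide mass.
AVERAGINE_UNIT <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773,
                    S = 0.0417)
AVERAGINE_UNIT_MASS <- 111.1254

## Natural isotope abundances by nominal mass offset.
ELEMENT_ISOTOPES <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

## p convolved with itself n times (distribution of the sum of n iid
## atoms), truncated to maxlen isotope slots; exponentiation by
## squaring.
convPow <- function(p, n, maxlen) {
  conv <- function(a, b) {
    out <- numeric(min(length(a) + length(b) - 1L, maxlen))
    for (i in seq_along(a)) {
      jmax <- min(length(b), maxlen - i + 1L)
      if (jmax < 1L) break
      idx <- i:(i + jmax - 1L)
      out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
    }
    out
  }
  result <- 1
  base <- p[seq_len(min(length(p), maxlen))]
  while (n > 0L) {
    if (n %% 2L == 1L) result <- conv(result, base)
    base <- conv(base, base)
    n <- n %/% 2L
  }
  result
}

#' Theoretical isotope envelope from the averagine model
#'
#' Scales the averagine unit composition to the given neutral mass
#' (rounding element counts to integers), convolves the elemental
#' isotope distributions, truncates to `n_isotopes` and renormalizes.
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param n_isotopes Number of isotope slots returned (>= 2).
#' @return Numeric vector of isotope abundances summing to 1.
#' @export
averagineEnvelope <- function(mass, n_isotopes = 5L) {
  stopifnot(mass > 0, n_isotopes >= 2L)
  counts <- pmax(round(mass / AVERAGINE_UNIT_MASS * AVERAGINE_UNIT), 0)
  maxlen <- as.integer(n_isotopes)
  dist <- 1
  for (el in names(AVERAGINE_UNIT)) {
    if (counts[[el]] < 1) next
    eld <- convPow(ELEMENT_ISOTOPES[[el]], as.integer(counts[[el]]),
                   maxlen)
    dist <- convPow2(dist, eld, maxlen)
  }
  dist <- c(dist, numeric(maxlen))[seq_len(maxlen)]
  dist / sum(dist)
}

## plain truncated convolution of two distributions
convPow2 <- function(a, b, maxlen) {
  out <- numeric(min(length(a) + length(b) - 1L, maxlen))
  for (i in seq_along(a)) {
    jmax <- min(length(b), maxlen - i + 1L)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

## Number of isotope traces to request: as many as needed to cover 95%
## of the envelope, capped at 5 and floored at 2.
requestedIsotopes <- function(mass, cap = 5L, coverage = 0.95) {
  env <- averagineEnvelope(mass, n_isotopes = cap + 3L)
  k <- which(cumsum(env) >= coverage)[1L]
  max(2L, min(cap, if (is.na(k)) cap else k))
}

#' Kullback-Leibler divergence of an observed isotope pattern
#'
#' Observed intensities are normalized to a distribution P; the
#' theoretical envelope is truncated to the same length and
#' renormalized to Q. Returns `sum(p * ln(p / q))` in nats with the
#' convention `0 * ln 0 = 0`.
#'
#' @param observed Non-negative per-isotope intensity sums (length
#'   >= 2, at least one positive).
#' @param envelope Theoretical envelope probabilities (from
#'   [averagineEnvelope()]), length >= length(observed).
#' @return KL divergence in nats (>= 0 when both are distributions).
#' @export
klDivergence <- function(observed, envelope) {
  if (length(observed) < 2L) stop("need at least 2 isotope slots")
  s <- sum(observed)
  if (s <= 0) stop("all-zero observed isotope pattern")
  p <- observed / s
  q <- envelope[seq_along(observed)]
  q <- q / sum(q)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Targeted extraction of precursor isotope XICs for one PSM
#'
#' For isotope k, the expected trace m/z is
#' `theo_mz + k * 1.00235 / charge`. In each MS1 scan within
#' `rt_halfwidth` of the MS2 retention time, the most intense peak
#' within `mz_tol` ppm of the expected m/z is appended to trace k.
#' Traces are then trimmed to the contiguous block of scans around the
#' MS2's parent scan in which the monoisotopic (k = 0) trace is
#' detected.
#'
#' @param run An [MsRun-class].
#' @param theo_mz Theoretical precursor m/z of the PSM.
#' @param charge Assumed precursor charge.
#' @param rt MS2 retention time (seconds).
#' @param n_isotopes Number of isotope traces to extract.
#' @param rt_halfwidth Extraction half-window in seconds (default 30).
#' @param mz_tol Trace m/z tolerance in ppm (default 10).
#' @return list with fields `iso_sums`, `n_isotopes_detected`,
#'   `n_consecutive_scans`, `observed_mz`, `apex_rt`, `kl` (NA when
#'   fewer than 2 isotopes detected), and the per-scan intensity matrix
#'   `traces` over the trimmed region.
#' @export
extractXic <- function(run, theo_mz, charge, rt, n_isotopes = 3L,
                       rt_halfwidth = 30, mz_tol = 10) {
  ms1 <- ms1Scans(run)
  win <- which(ms1$rt >= rt - rt_halfwidth & ms1$rt <= rt + rt_halfwidth)
  none <- list(iso_sums = numeric(n_isotopes), n_isotopes_detected = 0L,
               n_consecutive_scans = 0L, observed_mz = NA_real_,
               apex_rt = NA_real_, kl = NA_real_,
               traces = matrix(0, 0L, n_isotopes))
  if (!length(win)) return(none)
  mz_iso <- theo_mz + (seq_len(n_isotopes) - 1L) * ISOTOPE_SPACING / charge
  tolv <- mz_iso * mz_tol * 1e-6
  ns <- length(win)
  inten <- matrix(0, ns, n_isotopes)
  mzobs0 <- rep(NA_real_, ns)
  pklist <- ms1Peaks(run)
  for (s in seq_len(ns)) {
    m <- pklist[[win[s]]]
    if (!nrow(m)) next
    pmz <- m[, 1L]
    lo <- findInterval(mz_iso - tolv, pmz)
    hi <- findInterval(mz_iso + tolv, pmz)
    for (k in seq_len(n_isotopes)) {
      if (hi[k] <= lo[k]) next
      rows <- (lo[k] + 1L):hi[k]
      best <- rows[which.max(m[rows, 2L])]
      inten[s, k] <- m[best, 2L]
      if (k == 1L) mzobs0[s] <- m[best, 1L]
    }
  }
  det0 <- inten[, 1L] > 0
  if (!any(det0)) return(none)
  ## contiguous detected blocks of the monoisotopic trace
  r <- rle(det0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blocks <- which(r$values)
  ## anchor: window-local position of the MS2's parent MS1 scan
  anchor <- findInterval(rt, ms1$rt[win])
  anchor <- min(max(anchor, 1L), ns)
  dist <- vapply(blocks, function(b) {
    if (anchor >= starts[b] && anchor <= ends[b]) 0L
    else min(abs(anchor - starts[b]), abs(anchor - ends[b]))
  }, integer(1))
  b <- blocks[which.min(dist)]
  region <- starts[b]:ends[b]
  tr <- inten[region, , drop = FALSE]
  iso_sums <- colSums(tr)
  n_det <- sum(iso_sums > 0)
  w0 <- tr[, 1L]
  observed_mz <- sum(mzobs0[region] * w0, na.rm = TRUE) / sum(w0)
  apex_rt <- ms1$rt[win[region[which.max(w0)]]]
  kl <- if (n_det >= 2L) {
    env <- averagineEnvelope(mzToMass(theo_mz, charge),
                             n_isotopes = n_isotopes)
    klDivergence(iso_sums, env)
  } else NA_real_
  list(iso_sums = iso_sums, n_isotopes_detected = as.integer(n_det),
       n_consecutive_scans = length(region), observed_mz = observed_mz,
       apex_rt = apex_rt, kl = kl, traces = tr)
}

#' Extract precursor XICs for every PSM of a run
#'
#' Adds the refinement columns `n_isotopes_detected`,
#' `n_consecutive_scans`, `xic_kl`, `observed_precursor_mz`, `apex_rt`
#' and `xic_quality` to the PSM table. The number of isotope traces per
#' PSM follows the averagine envelope (enough isotopes to cover 95% of
#' the envelope, between 2 and 5).
#'
#' @param psmset A [PsmSet-class] from [searchRun()].
#' @param run The searched [MsRun-class].
#' @param rt_halfwidth,mz_tol See [extractXic()].
#' @param thresholds See [xicThresholds()].
#' @return The [PsmSet-class] with refinement columns filled.
#' @export
refinePsms <- function(psmset, run, rt_halfwidth = 30, mz_tol = 10,
                       thresholds = xicThresholds()) {
  tab <- psmTable(psmset)
  n <- nrow(tab)
  tab$n_isotopes_detected <- integer(n)
  tab$n_consecutive_scans <- integer(n)
  tab$xic_kl <- rep(NA_real_, n)
  tab$observed_precursor_mz <- rep(NA_real_, n)
  tab$apex_rt <- rep(NA_real_, n)
  if (n) {
    mass <- mzToMass(tab$theo_precursor_mz, tab$assumed_charge)
    niso <- vapply(mass, requestedIsotopes, integer(1))
    for (i in seq_len(n)) {
      x <- extractXic(run, tab$theo_precursor_mz[i],
                      tab$assumed_charge[i], tab$rt[i],
                      n_isotopes = niso[i],
                      rt_halfwidth = rt_halfwidth, mz_tol = mz_tol)
      tab$n_isotopes_detected[i] <- x$n_isotopes_detected
      tab$n_consecutive_scans[i] <- x$n_consecutive_scans
      tab$xic_kl[i] <- x$kl
      tab$observed_precursor_mz[i] <- x$observed_mz
      tab$apex_rt[i] <- x$apex_rt
    }
  }
  tab$xic_quality <- ifelse(xicPass(tab, thresholds), "pass", "fail")
  new("PsmSet", psms = tab, run_id = psmset@run_id,
      params = c(psmset@params,
                 list(rt_halfwidth = rt_halfwidth, xic_mz_tol = mz_tol,
                      xic_thresholds = thresholds)))
}

#' XIC quality thresholds
#'
#' Deliberately permissive defaults: the refinement is meant to keep
#' low-quality but real precursor signals while discarding PSMs with no
#' credible precursor evidence at all.
#'
#' @param min_isotopes Minimum detected isotope traces (default 2).
#' @param min_scans Minimum consecutive MS1 detections of the
#'   monoisotopic trace (default 2).
#' @param kl_max Maximum KL divergence versus the averagine envelope,
#'   in nats (default 0.5).
#' @export
xicThresholds <- function(min_isotopes = 2L, min_scans = 2L,
                          kl_max = 0.5) {
  list(min_isotopes = as.integer(min_isotopes),
       min_scans = as.integer(min_scans), kl_max = kl_max)
}

xicPass <- function(tab, thresholds) {
  if (!nrow(tab)) return(logical(0))
  tab$n_isotopes_detected >= thresholds$min_isotopes &
    tab$n_consecutive_scans >= thresholds$min_scans &
    (!is.na(tab$xic_kl) & tab$xic_kl <= thresholds$kl_max)
}

#' Filter PSMs by precursor-XIC quality
#'
#' Keeps PSMs whose refinement columns meet the thresholds; survivors
#' carry their `observed_precursor_mz`. With all thresholds disabled
#' (`min_isotopes = 0, min_scans = 0, kl_max = Inf`) every PSM passes.
#'
#' @param psmset A refined [PsmSet-class] (see [refinePsms()]).
#' @param thresholds See [xicThresholds()].
#' @return The [PsmSet-class] restricted to surviving PSMs.
#' @export
filterByXic <- function(psmset, thresholds = xicThresholds()) {
  tab <- psmTable(psmset)
  if (!nrow(tab)) return(psmset)
  disabled <- thresholds$min_isotopes <= 0L &&
    thresholds$min_scans <= 0L && !is.finite(thresholds$kl_max)
  keep <- if (disabled) rep(TRUE, nrow(tab)) else
    xicPass(tab, thresholds)
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("PsmSet", psms = out, run_id = psmset@run_id,
      params = psmset@params)
}
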