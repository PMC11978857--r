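## spectra_io: read/write centroided LC-MS runs (mzML through mzR, plus
## a plain-TSV bundle used by the synthetic generator), MS2 peak
## preprocessing. All m/z in Th, retention times in seconds.

peakMatrix <- function(mz, intensity) {
  o <- order(mz)
  cbind(mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o])
}

emptyPeaks <- function() cbind(mz = numeric(0), intensity = numeric(0))

#' Construct an MsRun
#'
#' Assembles an in-memory run from MS1/MS2 scan tables and parallel
#' peak lists. Scans are ordered by retention time and each MS2 scan is
#' linked to the latest MS1 scan with `rt <= MS2 rt`.
#'
#' @param run_id Run identifier.
#' @param ms1 data.frame with columns `scan_id`, `rt` (seconds).
#' @param ms1_peaks list of two-column matrices (mz, intensity).
#' @param ms2 data.frame with columns `scan_id`, `rt`, `iso_center`,
#'   `iso_width`, and optionally `precursor_mz`, `precursor_charge`.
#' @param ms2_peaks list of peak matrices parallel to `ms2`.
#' @param metadata Optional list.
#' @return An [MsRun-class] object.
#' @export
msRun <- function(run_id, ms1, ms1_peaks, ms2, ms2_peaks,
                  metadata = list()) {
  o1 <- order(ms1$rt)
  ms1 <- ms1[o1, , drop = FALSE]; rownames(ms1) <- NULL
  ms1_peaks <- ms1_peaks[o1]
  o2 <- order(ms2$rt)
  ms2 <- ms2[o2, , drop = FALSE]; rownames(ms2) <- NULL
  ms2_peaks <- ms2_peaks[o2]
  if (!"precursor_mz" %in% names(ms2))
    ms2$precursor_mz <- rep(NA_real_, nrow(ms2))
  if (!"precursor_charge" %in% names(ms2))
    ms2$precursor_charge <- rep(NA_integer_, nrow(ms2))
  parent <- findInterval(ms2$rt, ms1$rt)
  ms2$parent_ms1 <- ifelse(parent >= 1L, parent, NA_integer_)
  if (nrow(ms2) && anyNA(ms2$parent_ms1))
    warning("MS2 scan(s) without a preceding MS1 scan")
  ## reported precursor must sit inside the (slightly widened) window
  bad <- with(ms2, !is.na(precursor_mz) &
                (precursor_mz < iso_center - iso_width / 2 - 0.1 |
                 precursor_mz > iso_center + iso_width / 2 + 0.1))
  if (any(bad))
    stop("reported precursor m/z outside isolation window for scan(s): ",
         paste(utils::head(ms2$scan_id[bad], 5), collapse = ", "))
  new("MsRun", run_id = as.character(run_id), ms1 = ms1,
      ms1_peaks = ms1_peaks, ms2 = ms2, ms2_peaks = ms2_peaks,
      metadata = metadata)
}

#' Read an mzML file
#'
#' Reads a centroided mzML run through \pkg{mzR}. Isolation windows are
#' taken from the standard CV terms (target m/z with lower/upper
#' offsets); scans lacking offsets fall back to `default_iso_width`.
#' Profile-mode spectra are rejected.
#'
#' @param path mzML file (indexed or plain).
#' @param default_iso_width Fallback isolation width in Th.
#' @return An [MsRun-class].
#' @export
readMzML <- function(path, default_iso_width = 2.0) {
  if (!file.exists(path)) stop("no such file: ", path)
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hdr <- mzR::header(ms)
  if (nrow(hdr) == 0L) stop("no spectra in ", path)
  if (any(hdr$centroided %in% FALSE))
    stop("profile-mode spectra found; centroid the data before reading")
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  rt <- hdr$retentionTime          # mzR reports seconds
  is1 <- hdr$msLevel == 1L
  is2 <- hdr$msLevel == 2L
  mkPeaks <- function(idx) lapply(pk[idx], function(m) {
    if (is.null(m) || nrow(m) == 0L) return(emptyPeaks())
    peakMatrix(m[, 1L], m[, 2L])
  })
  ms1 <- data.frame(scan_id = hdr$acquisitionNum[is1], rt = rt[is1])
  center <- hdr$isolationWindowTargetMZ[is2]
  lo <- hdr$isolationWindowLowerOffset[is2]
  hi <- hdr$isolationWindowUpperOffset[is2]
  pmz <- hdr$precursorMZ[is2]
  width <- ifelse(!is.na(lo) & !is.na(hi) & (lo + hi) > 0, lo + hi,
                  default_iso_width)
  center <- ifelse(is.na(center) | center <= 0, pmz, center)
  if (anyNA(center))
    stop("MS2 scan(s) with no isolation target and no precursor m/z")
  chg <- hdr$precursorCharge[is2]
  ms2 <- data.frame(
    scan_id = hdr$acquisitionNum[is2], rt = rt[is2],
    iso_center = center, iso_width = width,
    precursor_mz = ifelse(is.na(pmz) | pmz <= 0, NA_real_, pmz),
    precursor_charge = ifelse(is.na(chg) | chg <= 0, NA_integer_,
                              as.integer(chg)))
  msRun(sub("\\.mzML$", "", basename(path), ignore.case = TRUE),
        ms1, mkPeaks(which(is1)), ms2, mkPeaks(which(is2)))
}

#' Write an MsRun to mzML
#'
#' @param run An [MsRun-class].
#' @param path Output mzML path.
#' @export
writeMzML <- function(run, path) {
  ms1 <- ms1Scans(run); ms2 <- ms2Scans(run)
  n1 <- nrow(ms1); n2 <- nrow(ms2)
  scans <- rbind(
    data.frame(scan_id = ms1$scan_id, rt = ms1$rt, level = 1L,
               iso_center = NA_real_, iso_width = NA_real_,
               precursor_mz = NA_real_, precursor_charge = NA_integer_,
               idx = seq_len(n1), stringsAsFactors = FALSE),
    data.frame(scan_id = ms2$scan_id, rt = ms2$rt, level = 2L,
               iso_center = ms2$iso_center, iso_width = ms2$iso_width,
               precursor_mz = ms2$precursor_mz,
               precursor_charge = ms2$precursor_charge,
               idx = seq_len(n2), stringsAsFactors = FALSE))
  scans <- scans[order(scans$rt, scans$level), ]
  pk <- vector("list", nrow(scans))
  for (i in seq_len(nrow(scans))) {
    pk[[i]] <- if (scans$level[i] == 1L) ms1Peaks(run)[[scans$idx[i]]]
               else ms2Peaks(run)[[scans$idx[i]]]
  }
  npk <- vapply(pk, nrow, integer(1))
  bp <- function(m, col) if (nrow(m)) m[which.max(m[, 2L]), col] else 0
  n <- nrow(scans)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = scans$scan_id,
    msLevel = scans$level, polarity = 1L, peaksCount = npk,
    totIonCurrent = vapply(pk, function(m) sum(m[, 2L]), numeric(1)),
    retentionTime = scans$rt,
    basePeakMZ = vapply(pk, bp, numeric(1), col = 1L),
    basePeakIntensity = vapply(pk, bp, numeric(1), col = 2L),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(pk, function(m) if (nrow(m)) min(m[, 1L]) else 0,
                   numeric(1)),
    highMZ = vapply(pk, function(m) if (nrow(m)) max(m[, 1L]) else 0,
                    numeric(1)),
    precursorScanNum = 0L,
    precursorMZ = ifelse(is.na(scans$precursor_mz), 0,
                         scans$precursor_mz),
    precursorCharge = ifelse(is.na(scans$precursor_charge), 0L,
                             scans$precursor_charge),
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", scans$scan_id),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(is.na(scans$iso_center), NA_real_,
                                     scans$iso_center),
    isolationWindowLowerOffset = ifelse(is.na(scans$iso_width), NA_real_,
                                        scans$iso_width / 2),
    isolationWindowUpperOffset = ifelse(is.na(scans$iso_width), NA_real_,
                                        scans$iso_width / 2),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  mzR::writeMSData(object = pk, file = path, header = hdr,
                   outformat = "mzml")
  invisible(path)
}

#' Write the native TSV run bundle
#'
#' Two plain TSV files per run: `<prefix>_scans.tsv` (scan metadata for
#' both MS levels) and `<prefix>_peaks.tsv` (one row per centroid).
#'
#' @param run An [MsRun-class].
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
writeRunBundle <- function(run, prefix) {
  ms1 <- ms1Scans(run); ms2 <- ms2Scans(run)
  scans <- rbind(
    data.frame(scan_id = ms1$scan_id, ms_level = 1L, rt = ms1$rt,
               iso_center = NA_real_, iso_width = NA_real_,
               precursor_mz = NA_real_, precursor_charge = NA_integer_),
    data.frame(scan_id = ms2$scan_id, ms_level = 2L, rt = ms2$rt,
               iso_center = ms2$iso_center, iso_width = ms2$iso_width,
               precursor_mz = ms2$precursor_mz,
               precursor_charge = ms2$precursor_charge))
  allpk <- c(ms1Peaks(run), ms2Peaks(run))
  ids <- rep(scans$scan_id, vapply(allpk, nrow, integer(1)))
  pkdf <- data.frame(scan_id = ids,
                     mz = unlist(lapply(allpk, function(m) m[, 1L])),
                     intensity = unlist(lapply(allpk, function(m) m[, 2L])))
  fs <- paste0(prefix, "_scans.tsv")
  fp <- paste0(prefix, "_peaks.tsv")
  utils::write.table(scans, fs, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(pkdf, fp, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(scans = fs, peaks = fp))
}

#' Read a native TSV run bundle
#'
#' @param prefix Path prefix used by [writeRunBundle()].
#' @param run_id Run identifier (default: basename of the prefix).
#' @return An [MsRun-class].
#' @export
readRunBundle <- function(prefix, run_id = basename(prefix)) {
  fs <- paste0(prefix, "_scans.tsv")
  fp <- paste0(prefix, "_peaks.tsv")
  if (!file.exists(fs) || !file.exists(fp))
    stop("run bundle not found at prefix ", prefix)
  scans <- utils::read.delim(fs)
  pkdf <- utils::read.delim(fp)
  pksplit <- split(seq_len(nrow(pkdf)), factor(pkdf$scan_id,
                                               levels = scans$scan_id))
  mk <- function(i) {
    rows <- pksplit[[as.character(scans$scan_id[i])]]
    if (is.null(rows) || !length(rows)) return(emptyPeaks())
    peakMatrix(pkdf$mz[rows], pkdf$intensity[rows])
  }
  is1 <- scans$ms_level == 1L
  is2 <- scans$ms_level == 2L
  msRun(run_id,
        data.frame(scan_id = scans$scan_id[is1], rt = scans$rt[is1]),
        lapply(which(is1), mk),
        data.frame(scan_id = scans$scan_id[is2], rt = scans$rt[is2],
                   iso_center = scans$iso_center[is2],
                   iso_width = scans$iso_width[is2],
                   precursor_mz = scans$precursor_mz[is2],
                   precursor_charge = scans$precursor_charge[is2]),
        lapply(which(is2), mk))
}

#' Preprocess an MS2 peak list before scoring
#'
#' Retains the `top_n` most intense peaks that also exceed
#' `min_intensity_frac` of the base-peak intensity, restores ascending
#' m/z order, and optionally square-root transforms intensities. Ties
#' in intensity at the cutoff keep the lower-m/z peak.
#'
#' @param peaks Two-column peak matrix (mz, intensity).
#' @param top_n Number of peaks to keep (default 150).
#' @param min_intensity_frac Relative intensity floor (default 0.01).
#' @param sqrt_transform Square-root transform intensities.
#' @return Filtered peak matrix.
#' @export
preprocessMs2 <- function(peaks, top_n = 150L, min_intensity_frac = 0.01,
                          sqrt_transform = FALSE) {
  stopifnot(top_n >= 1L)
  if (nrow(peaks) == 0L) return(peaks)
  keep <- peaks[, 2L] >= min_intensity_frac * max(peaks[, 2L])
  peaks <- peaks[keep, , drop = FALSE]
  if (nrow(peaks) > top_n) {
    ## stable order: intensity desc, then mz asc, so equal-intensity
    ## peaks at the cutoff resolve toward lower m/z
    o <- order(-peaks[, 2L], peaks[, 1L])
    peaks <- peaks[sort(o[seq_len(top_n)]), , drop = FALSE]
  }
  if (sqrt_transform) peaks[, 2L] <- sqrt(peaks[, 2L])
  peaks
}
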