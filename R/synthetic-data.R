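## synthetic_data: ground-truthed synthetic proteomes and LC-MS runs
## with controlled chimera multiplicity, precursor detectability and
## noise, covering conventional DDA and wide-window geometries.

## Approximate human proteome residue frequencies.
RESIDUE_FREQ <- c(
  A = 0.083, R = 0.057, N = 0.040, D = 0.054, C = 0.014, E = 0.068,
  Q = 0.047, G = 0.071, H = 0.022, I = 0.060, L = 0.097, K = 0.058,
  M = 0.024, F = 0.039, P = 0.047, S = 0.083, T = 0.053, W = 0.011,
  Y = 0.029, V = 0.060
)

#' Simulation configuration
#'
#' Defaults describe a small but structurally realistic single-shot
#' LC-MS run: tryptic peptides with Gaussian elution (10-30 s FWHM)
#' and log-normal abundance, MS1 scans on a fixed cycle carrying
#' averagine isotope envelopes plus exponential noise, and DDA top-1
#' precursor selection with dynamic exclusion. `iso_width` switches
#' between conventional DDA (0.7-2 Th) and wide-window (1.6-48 Th)
#' geometries.
#'
#' @param n_proteins Number of synthetic proteins.
#' @param protein_length_range Protein length bounds (residues).
#' @param digest A [digestSpec()] (peptides are simulated unmodified).
#' @param gradient_length Gradient length in seconds.
#' @param ms1_cycle MS1 cycle time in seconds.
#' @param ms2_per_cycle MS2 scans triggered after each MS1.
#' @param iso_width Isolation window width in Th.
#' @param chimera_rate Expected number of co-isolated peptides per MS2;
#'   controls how many digest peptides are put on the gradient.
#' @param frac_precursor_missing Fraction of eluting peptides given no
#'   MS1 signal at all (they still co-fragment).
#' @param noise_peaks_per_ms2,noise_peaks_per_ms1 Noise centroids per
#'   scan.
#' @param fragment_ppm_jitter,ms1_ppm_jitter Mass-error SD in ppm.
#' @param intensity_cv Multiplicative intensity noise (log-normal CV).
#' @param elution_fwhm_range Elution peak FWHM bounds in seconds.
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance model.
#' @param ms1_noise_mean,ms2_noise_mean Mean noise-peak intensity.
#' @param dynamic_exclusion Dynamic exclusion time in seconds.
#' @param prob_charge2 Probability a peptide carries charge 2 (else 3).
#' @param seed Master seed; everything is deterministic given it.
#' @return list of class `SimConfig`.
#' @export
simConfig <- function(n_proteins = 40L,
                      protein_length_range = c(200L, 400L),
                      digest = digestSpec(max_missed_cleavages = 0L),
                      gradient_length = 300,
                      ms1_cycle = 1.5,
                      ms2_per_cycle = 1L,
                      iso_width = 2.0,
                      chimera_rate = 1.5,
                      frac_precursor_missing = 0.2,
                      noise_peaks_per_ms2 = 50L,
                      noise_peaks_per_ms1 = 100L,
                      fragment_ppm_jitter = 5,
                      ms1_ppm_jitter = 3,
                      intensity_cv = 0.2,
                      elution_fwhm_range = c(10, 30),
                      abundance_meanlog = log(5e4),
                      abundance_sdlog = 1,
                      ms1_noise_mean = 300,
                      ms2_noise_mean = 200,
                      dynamic_exclusion = 20,
                      prob_charge2 = 0.7,
                      seed = 1L) {
  stopifnot(iso_width > 0, frac_precursor_missing >= 0,
            frac_precursor_missing <= 1, chimera_rate >= 0)
  structure(as.list(environment()), class = "SimConfig")
}

#' Simulate a synthetic proteome
#'
#' Random proteins drawn from a fixed residue-frequency model (with a
#' guaranteed C-terminal K/R so every protein digests cleanly), written
#' as a protein table plus the true digest peptide set.
#'
#' @param config A [simConfig()].
#' @param seed Seed (default `config$seed`).
#' @return list with `proteins` (data.frame) and `peptides` (the
#'   digest truth table with sequence, neutral_mass).
#' @export
simulateProteome <- function(config = simConfig(), seed = config$seed) {
  proteins <- withSeed(seed, {
    lens <- sample(config$protein_length_range[1]:
                     config$protein_length_range[2],
                   config$n_proteins, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      s <- sample(names(RESIDUE_FREQ), L, replace = TRUE,
                  prob = RESIDUE_FREQ)
      s[L] <- sample(c("K", "R"), 1L)
      paste(s, collapse = "")
    }, character(1))
    data.frame(accession = sprintf("SYN%04d", seq_along(seqs)),
               description = "synthetic protein",
               sequence = seqs, origin = "target",
               stringsAsFactors = FALSE)
  })
  pep <- do.call(rbind, lapply(proteins$sequence, digestProtein,
                               spec = config$digest))
  pep <- pep[!duplicated(pep$sequence), , drop = FALSE]
  pep$neutral_mass <- vapply(pep$sequence, peptideNeutralMass, numeric(1),
                             USE.NAMES = FALSE)
  rownames(pep) <- NULL
  list(proteins = proteins, peptides = pep)
}

#' Simulate an LC-MS run with ground truth
#'
#' Digest peptides are put on a Gaussian elution gradient with
#' log-normal abundances; MS1 scans carry averagine isotope envelopes
#' for every present precursor plus noise; MS2 scans are triggered
#' DDA-style on the most abundant unexcluded precursor, and every
#' peptide whose precursor m/z falls inside the isolation window while
#' eluting contributes jittered b/y fragment peaks — including the
#' configured fraction of peptides with no MS1 signal.
#'
#' @param config A [simConfig()].
#' @param proteome Result of [simulateProteome()] (generated if NULL).
#' @param seed Seed (default `config$seed + 1`, so the proteome and
#'   the run draw independent streams from the master seed).
#' @return list with `run` ([MsRun-class]), `truth` (one row per
#'   planted (scan, peptide)), and `peptide_truth` (per-peptide elution
#'   and abundance parameters).
#' @export
simulateRun <- function(config = simConfig(), proteome = NULL,
                        seed = config$seed + 1L) {
  if (is.null(proteome)) proteome <- simulateProteome(config)
  pep <- proteome$peptides
  withSeed(seed, {
    ## --- assign peptide ion properties -------------------------------
    z <- ifelse(stats::runif(nrow(pep)) < config$prob_charge2, 2L, 3L)
    mz <- massToMz(pep$neutral_mass, z)
    ## how many peptides elute: calibrated so the expected number of
    ## co-isolated peptides per MS2 matches chimera_rate
    span <- diff(stats::quantile(mz, c(0.05, 0.95)))
    mean_dur <- 2 * mean(config$elution_fwhm_range)
    n_target <- round(config$chimera_rate * (span / config$iso_width) *
                        config$gradient_length / mean_dur)
    n_use <- max(10L, min(nrow(pep), n_target))
    sel <- sort(sample(nrow(pep), n_use))
    pt <- data.frame(
      sequence = pep$sequence[sel],
      neutral_mass = pep$neutral_mass[sel],
      charge = z[sel], mz = mz[sel],
      apex_rt = stats::runif(n_use, 0.05, 0.95) * config$gradient_length,
      fwhm = stats::runif(n_use, config$elution_fwhm_range[1],
                          config$elution_fwhm_range[2]),
      abundance = stats::rlnorm(n_use, config$abundance_meanlog,
                                config$abundance_sdlog),
      precursor_present = stats::runif(n_use) >=
        config$frac_precursor_missing,
      stringsAsFactors = FALSE)
    pt$sigma <- pt$fwhm / 2.3548
    env4 <- t(vapply(pt$neutral_mass,
                     function(m) averagineEnvelope(m, 4L), numeric(4)))
    pt$snr <- pt$abundance * env4[, 1L] / config$ms1_noise_mean
    ## per-peptide fixed relative fragment pattern
    frag_tmpl <- lapply(pt$sequence, function(s) generateFragments(s))
    frag_rel <- lapply(frag_tmpl, function(f)
      stats::runif(nrow(f), 0.2, 1.0))

    elut <- function(i, t)
      pt$abundance[i] * exp(-(t - pt$apex_rt[i])^2 / (2 * pt$sigma[i]^2))
    floor_int <- 2 * config$ms1_noise_mean  # detectability floor

    jitter_mz <- function(mzv, ppm)
      mzv * (1 + stats::rnorm(length(mzv), 0, ppm) * 1e-6)
    jitter_int <- function(x, cv)
      x * stats::rlnorm(length(x), -0.5 * log(1 + cv^2),
                        sqrt(log(1 + cv^2)))

    times <- seq(0, config$gradient_length, by = config$ms1_cycle)
    mz_lo <- max(150, min(mz) - 50); mz_hi <- max(mz) + 50
    scan_id <- 0L
    ms1_meta <- vector("list", length(times))
    ms1_pk <- vector("list", length(times))
    ms2_meta <- list(); ms2_pk <- list(); truth_rows <- list()
    last_selected <- rep(-Inf, n_use)

    for (ci in seq_along(times)) {
      t <- times[ci]
      ## ---------- MS1 scan ------------------------------------------
      scan_id <- scan_id + 1L
      cur <- elut(seq_len(n_use), t)
      vis <- which(pt$precursor_present & cur > floor_int)
      mzv <- numeric(0); inv <- numeric(0)
      if (length(vis)) {
        mzv <- unlist(lapply(vis, function(i)
          jitter_mz(pt$mz[i] + (0:3) * ISOTOPE_SPACING / pt$charge[i],
                    config$ms1_ppm_jitter)))
        inv <- unlist(lapply(vis, function(i)
          jitter_int(cur[i] * env4[i, ], config$intensity_cv)))
      }
      if (config$noise_peaks_per_ms1 > 0L) {
        mzv <- c(mzv, stats::runif(config$noise_peaks_per_ms1, mz_lo,
                                   mz_hi))
        inv <- c(inv, stats::rexp(config$noise_peaks_per_ms1,
                                  1 / config$ms1_noise_mean))
      }
      ms1_meta[[ci]] <- data.frame(scan_id = scan_id, rt = t)
      ms1_pk[[ci]] <- peakMatrix(mzv, inv)

      ## ---------- MS2 selection (DDA logic) -------------------------
      sel_vis <- vis[t - last_selected[vis] > config$dynamic_exclusion]
      if (!length(sel_vis)) next
      ord <- sel_vis[order(-cur[sel_vis])]
      picks <- utils::head(ord, config$ms2_per_cycle)
      for (j in seq_along(picks)) {
        p <- picks[j]
        last_selected[p] <- t
        scan_id <- scan_id + 1L
        rt2 <- t + config$ms1_cycle * j / (config$ms2_per_cycle + 1L)
        center <- jitter_mz(pt$mz[p], config$ms1_ppm_jitter)
        cur2 <- elut(seq_len(n_use), rt2)
        contrib <- which(abs(pt$mz - center) <= config$iso_width / 2 &
                           cur2 > floor_int)
        fmz <- numeric(0); fint <- numeric(0)
        for (i in contrib) {
          ci2 <- cur2[i]
          fmz <- c(fmz, jitter_mz(frag_tmpl[[i]]$mz,
                                  config$fragment_ppm_jitter))
          fint <- c(fint, jitter_int(frag_rel[[i]] * ci2,
                                     config$intensity_cv))
        }
        if (config$noise_peaks_per_ms2 > 0L) {
          fmz <- c(fmz, stats::runif(config$noise_peaks_per_ms2, 150,
                                     1600))
          fint <- c(fint, stats::rexp(config$noise_peaks_per_ms2,
                                      1 / config$ms2_noise_mean))
        }
        ms2_meta[[length(ms2_meta) + 1L]] <- data.frame(
          scan_id = scan_id, rt = rt2, iso_center = center,
          iso_width = config$iso_width, precursor_mz = center,
          precursor_charge = pt$charge[p])
        ms2_pk[[length(ms2_pk) + 1L]] <- peakMatrix(fmz, fint)
        if (length(contrib))
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            scan_id = scan_id, sequence = pt$sequence[contrib],
            charge = pt$charge[contrib], mz = pt$mz[contrib],
            precursor_present = pt$precursor_present[contrib],
            selected = contrib == p,
            elut_intensity = cur2[contrib],
            snr = pt$snr[contrib],
            stringsAsFactors = FALSE)
      }
    }
    run <- msRun("synthetic", do.call(rbind, ms1_meta), ms1_pk,
                 do.call(rbind, ms2_meta), ms2_pk,
                 metadata = list(config = config))
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(scan_id = integer(0), sequence = character(0),
                 charge = integer(0), mz = numeric(0),
                 precursor_present = logical(0), selected = logical(0),
                 elut_intensity = numeric(0), snr = numeric(0))
    rownames(truth) <- NULL
    list(run = run, truth = truth, peptide_truth = pt,
         proteome = proteome)
  })
}

#' Write / read the ground-truth table
#'
#' One row per (MS2 scan, planted peptide); the columns are the join
#' keys and metrics needed to score any pipeline output against the
#' truth: scan_id, sequence, charge, mz, precursor_present, selected,
#' elut_intensity, snr.
#'
#' @param truth Truth data.frame from [simulateRun()].
#' @param path TSV path.
#' @export
writeTruth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
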