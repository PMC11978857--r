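## Shared fixtures: all built in code, no stored data.

## Sorted two-column peak matrix.
mkPeaks <- function(mz, intensity) {
  o <- order(mz)
  cbind(mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o])
}

## A PeptideDb directly from peptide sequences (bypasses digestion);
## origins default to target.
mkDb <- function(sequences, origins = "target", mods = "") {
  origins <- rep_len(origins, length(sequences))
  mods <- rep_len(mods, length(sequences))
  mass <- mapply(function(s, m) peptideNeutralMass(s, parseMods(m)$delta),
                 sequences, mods, USE.NAMES = FALSE)
  pepdf <- data.frame(sequence = sequences, mods = mods,
                      neutral_mass = mass, missed_cleavages = 0L,
                      origin = origins,
                      parents = paste0("P", seq_along(sequences)),
                      stringsAsFactors = FALSE)
  protdf <- data.frame(accession = paste0("P", seq_along(sequences)),
                       description = "", sequence = sequences,
                       origin = origins, stringsAsFactors = FALSE)
  new("PeptideDb", proteins = protdf, peptides = pepdf, digest = list())
}

## Synthetic MS2 peak list holding the exact b/y ions of the given
## peptides (charge-1 fragments), each series scaled by `intensity`.
spectrumFromPeptides <- function(sequences, intensity = 1000,
                                 noise_mz = numeric(0),
                                 noise_intensity = numeric(0)) {
  intensity <- rep_len(intensity, length(sequences))
  mz <- numeric(0); int <- numeric(0)
  for (i in seq_along(sequences)) {
    f <- generateFragments(sequences[i])
    mz <- c(mz, f$mz)
    int <- c(int, rep(intensity[i], nrow(f)))
  }
  mz <- c(mz, noise_mz); int <- c(int, noise_intensity)
  ## centroid semantics: coinciding fragment m/z (shared ions) merge
  ## into a single peak with summed intensity
  agg <- rowsum(int, sprintf("%.9f", mz))
  mzu <- as.numeric(rownames(agg))
  mkPeaks(mzu, agg[, 1])
}

## Brute-force oracle for full-window candidate retrieval: exhaustive
## O(N * |z| * |e|) scan with the same keep-smallest-isotope-error
## deduplication per (peptide, charge).
oracleCandidates <- function(masses, center, width, charges,
                             isotope_errors) {
  rows <- list()
  for (i in seq_along(masses)) {
    for (z in charges) {
      for (e in sort(isotope_errors)) {
        pmz <- (masses[i] + e * 1.00235 + z * 1.007276466) / z
        if (pmz >= center - width / 2 && pmz <= center + width / 2) {
          rows[[length(rows) + 1L]] <- data.frame(
            pep = i, charge = as.integer(z), isotope_error = as.integer(e))
          break  # smallest qualifying isotope error per (pep, z)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(pep = integer(0), charge = integer(0),
                      isotope_error = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$pep, out$charge), , drop = FALSE]
}

## Naive per-candidate hyperscore, independent of the fragment index.
oracleScore <- function(peaks, sequence, mods, tol = 20,
                        tol_unit = "ppm", mz_range = c(100, 2000)) {
  f <- generateFragments(sequence, mods)
  f <- f[f$mz >= mz_range[1] & f$mz <= mz_range[2], , drop = FALSE]
  m <- matchFragments(peaks, f$mz, tol, tol_unit)
  hit <- !is.na(m)
  isb <- f$series == "b"
  sb <- sum(peaks[m[hit & isb], 2])
  sy <- sum(peaks[m[hit & !isb], 2])
  hyperscore(sb, sy, sum(hit & isb), sum(hit & !isb))
}

## Small deterministic synthetic WWA benchmark configuration used by
## the end-to-end tests: wide 12 Th windows, ~200 MS2 scans, 2-4
## co-isolated peptides per spectrum.
wwaBenchConfig <- function(seed) {
  simConfig(iso_width = 12, chimera_rate = 3, seed = seed)
}

## Run both pipeline modes on one seeded replicate; returns accepted
## peptide tables plus the planted truth.
runBenchReplicate <- function(seed, entrapment = FALSE,
                              mode = c("both", "dda_plus")) {
  mode <- match.arg(mode)
  cfg <- wwaBenchConfig(seed)
  sim <- simulateRun(cfg)
  db <- buildPeptideDb(sim$proteome$proteins, spec = cfg$digest,
                       mods = list(), entrapment = entrapment,
                       entrapment_seed = seed + 1000L)
  planted <- unique(sim$truth$sequence)
  plus <- runPipeline(db, sim$run, cofragConfig(mode = "dda_plus"))
  single <- if (mode == "both")
    runPipeline(db, sim$run, cofragConfig(mode = "dda_single")) else NULL
  list(sim = sim, db = db, planted = planted, plus = plus,
       single = single)
}
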