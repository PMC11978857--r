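test_that("fragment-peak matching picks the nearest in-tolerance peak only", {
  pk <- mkPeaks(c(500.004, 500.012), c(10, 20))
  ## 10 ppm of 500 = 0.005: only 500.004 is in reach
  m <- matchFragments(pk, 500.000, tol = 10, tol_unit = "ppm")
  expect_equal(m, 1L)
  expect_true(is.na(matchFragments(pk, 400.0, tol = 10)))
  ## empty peak list
  expect_true(all(is.na(matchFragments(mkPeaks(numeric(0), numeric(0)),
                                       c(500, 600)))))
  ## tie in distance resolves to the lower-m/z peak
  pk2 <- mkPeaks(c(499.999, 500.001), c(1, 2))
  expect_equal(matchFragments(pk2, 500.000, tol = 10), 1L)
})

test_that("hyperscore arithmetic, no-match zero and homogeneity", {
  expect_equal(hyperscore(100, 10, 2, 1), log10(2 * 1 * 100 * 10),
               tolerance = 1e-12)
  expect_equal(hyperscore(0, 0, 0, 0), 0)
  expect_equal(hyperscore(5, 0, 3, 0), log10(6 * 5 * 1), tolerance = 1e-12)
  ## doubling all intensities adds exactly 2 log10(2)
  s1 <- hyperscore(100, 40, 4, 3)
  s2 <- hyperscore(200, 80, 4, 3)
  expect_equal(s2 - s1, 2 * log10(2), tolerance = 1e-12)
  ## factorial cap: counts above the cap contribute like the cap
  expect_equal(hyperscore(10, 10, 80, 80, cap = 64L),
               hyperscore(10, 10, 64, 64, cap = 64L))
  ## vectorized
  expect_equal(hyperscore(c(100, 0), c(10, 0), c(2, 0), c(1, 0)),
               c(log10(2000), 0))
})

test_that("indexed spectrum search equals the naive per-candidate oracle", {
  set.seed(202)
  aas <- names(CoFrag:::RESIDUE_MASS)
  seqs <- unique(replicate(120, paste(
    c(sample(aas, sample(6:12, 1), replace = TRUE),
      sample(c("K", "R"), 1)), collapse = "")))
  db <- mkDb(seqs)
  idx <- buildFragmentIndex(db)
  params <- searchParamsDefault(min_matched = 1L, top_k = 10L)
  for (rep in 1:25) {
    ## chimeric spectrum from 2-3 random peptides plus noise
    pick <- sample(seqs, sample(2:3, 1))
    pk <- spectrumFromPeptides(pick, intensity = runif(length(pick),
                                                       100, 1000),
                               noise_mz = runif(20, 150, 1500),
                               noise_intensity = runif(20, 1, 50))
    center <- runif(1, 350, 900)
    out <- searchSpectrum(pk, idx, db, center, 24, params)
    for (i in seq_len(nrow(out))) {
      expect_equal(out$hyperscore[i],
                   oracleScore(pk, out$sequence[i], out$mods[i]),
                   tolerance = 1e-12)
    }
    ## rank-1 score equals brute-force maximum over all candidates
    cand <- candidatesInWindow(idx, center, 24,
                               charges = params$charges,
                               isotope_errors = params$isotope_errors)
    if (nrow(cand) && nrow(out)) {
      naive <- vapply(unique(cand$pep), function(p)
        oracleScore(pk, peptides(db)$sequence[p], ""), numeric(1))
      expect_equal(out$hyperscore[1], max(naive), tolerance = 1e-12)
    }
  }
})

test_that("planted peptide is rank 1 and co-planted peptides reach top-K", {
  db <- mkDb(c("PEPTIDEKR", "LLLGGGAAK", "TTTVVVNNK"))
  idx <- buildFragmentIndex(db)
  m <- peptides(db)$neutral_mass
  ## window covering peptides 1 and 2 at charge 2
  center <- mean((m[1:2] + 2 * 1.007276466) / 2)
  width <- abs(diff((m[1:2] + 2 * 1.007276466) / 2)) + 1
  pk <- spectrumFromPeptides(c("PEPTIDEKR", "LLLGGGAAK"),
                             intensity = c(1000, 100))
  out <- searchSpectrum(pk, idx, db, center, width,
                        searchParamsDefault(min_matched = 4L))
  expect_equal(out$sequence[1], "PEPTIDEKR")
  expect_true("LLLGGGAAK" %in% out$sequence)
  expect_false("TTTVVVNNK" %in% out$sequence)
  ## empty candidate set -> empty PSM list
  out2 <- searchSpectrum(pk, idx, db, 5000, 0.5, searchParamsDefault())
  expect_equal(nrow(out2), 0L)
})

test_that("run-level search is deterministic and robust to empty runs", {
  cfg <- simConfig(n_proteins = 8L, gradient_length = 60, iso_width = 4,
                   seed = 9)
  sim <- simulateRun(cfg)
  db <- buildPeptideDb(sim$proteome$proteins, spec = cfg$digest,
                       mods = list())
  idx <- buildFragmentIndex(db)
  r1 <- searchRun(sim$run, idx, db)
  r2 <- searchRun(sim$run, idx, db)
  expect_identical(psmTable(r1)[, setdiff(names(psmTable(r1)),
                                          "matched_peaks")],
                   psmTable(r2)[, setdiff(names(psmTable(r2)),
                                          "matched_peaks")])
  ## zero-MS2 run
  empty <- msRun("e", data.frame(scan_id = 1L, rt = 0),
                 list(mkPeaks(500, 1)),
                 data.frame(scan_id = integer(0), rt = numeric(0),
                            iso_center = numeric(0),
                            iso_width = numeric(0)), list())
  r0 <- searchRun(empty, idx, db)
  expect_equal(nrow(psmTable(r0)), 0L)
})
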