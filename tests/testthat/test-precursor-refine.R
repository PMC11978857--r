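test_that("averagine envelope normalizes, grows with mass, matches convolution oracle", {
  for (m in c(600, 1500, 3000)) {
    env <- averagineEnvelope(m, 5L)
    expect_equal(sum(env), 1, tolerance = 1e-12)
    expect_true(all(env >= 0))
  }
  ## M+1 / M ratio strictly increases with mass (more carbons)
  masses <- seq(500, 5000, by = 500)
  ratio <- vapply(masses, function(m) {
    e <- averagineEnvelope(m, 3L); e[2] / e[1]
  }, numeric(1))
  expect_true(all(diff(ratio) > 0))

  ## independent oracle at 1500 Da: direct multinomial convolution over
  ## the scaled composition, written without the package's helpers
  unit <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
  iso <- list(C = c(0.9893, 0.0107), H = c(0.999885, 0.000115),
              N = c(0.99636, 0.00364), O = c(0.99757, 0.00038, 0.00205),
              S = c(0.9499, 0.0075, 0.0425, 0, 0.0001))
  counts <- round(1500 / 111.1254 * unit)
  dist <- 1
  for (el in names(unit)) {
    for (k in seq_len(counts[[el]])) {
      p <- iso[[el]]
      new <- numeric(length(dist) + length(p) - 1)
      for (i in seq_along(dist))
        new[i:(i + length(p) - 1)] <- new[i:(i + length(p) - 1)] +
          dist[i] * p
      dist <- new[1:min(length(new), 8)]
    }
  }
  oracle <- (dist / sum(dist[1:5]))[1:5]
  oracle <- oracle / sum(oracle)
  expect_equal(averagineEnvelope(1500, 5L), oracle, tolerance = 1e-3)
})

test_that("KL divergence identity, hand-computed case, non-negativity", {
  env <- c(0.5, 0.3, 0.2)
  expect_equal(klDivergence(c(5, 3, 2), env), 0, tolerance = 1e-12)
  expect_equal(klDivergence(c(0.5, 0.5), c(0.9, 0.1)),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-12)
  expect_equal(klDivergence(c(0.5, 0.5), c(0.9, 0.1)), 0.5108,
               tolerance = 1e-4)
  set.seed(5)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    p <- rexp(n); q <- rexp(n) + 1e-6
    expect_gte(klDivergence(p, q / sum(q)), -1e-12)
  }
  expect_error(klDivergence(c(0, 0), c(0.5, 0.5)), "all-zero")
  expect_error(klDivergence(1, 1), "at least 2")
})

test_that("targeted XIC extraction recovers a planted Gaussian elution", {
  ## hand-built run: one precursor at 500.25 (z=2), Gaussian over MS1
  theo_mz <- 500.25
  mass <- (theo_mz - 1.007276466) * 2
  env <- averagineEnvelope(mass, 3L)
  rts <- seq(0, 60, by = 2)
  apex <- 30; sigma <- 6; ab <- 1e5
  ms1_pk <- lapply(rts, function(t) {
    inten <- ab * exp(-(t - apex)^2 / (2 * sigma^2))
    if (inten < 100) return(mkPeaks(numeric(0), numeric(0)))
    mkPeaks(theo_mz + (0:2) * 1.00235 / 2, inten * env)
  })
  run <- msRun("x", data.frame(scan_id = seq_along(rts), rt = rts),
               ms1_pk,
               data.frame(scan_id = 100L, rt = 29, iso_center = 500.25,
                          iso_width = 2), list(mkPeaks(200, 1)))
  x <- extractXic(run, theo_mz, 2L, rt = 29, n_isotopes = 3L)
  expect_equal(x$apex_rt, apex, tolerance = 2)       # within one cycle
  expect_equal(x$observed_mz, theo_mz, tolerance = 500.25 * 10e-6)
  expect_equal(x$n_isotopes_detected, 3L)
  expect_gte(x$n_consecutive_scans, 5L)
  ## observed pattern equals the planted envelope -> tiny KL
  expect_lt(x$kl, 1e-6)
  ## absent precursor: zero detections
  x0 <- extractXic(run, 800.77, 2L, rt = 29, n_isotopes = 3L)
  expect_equal(x0$n_isotopes_detected, 0L)
  expect_equal(x0$n_consecutive_scans, 0L)
})

test_that("co-isolated precursors track their own m/z traces", {
  rts <- seq(0, 40, by = 2)
  mzA <- 500.25; mzB <- 503.40
  ms1_pk <- lapply(rts, function(t) {
    mkPeaks(c(mzA + (0:1) * 1.00235 / 2, mzB + (0:1) * 1.00235 / 2),
            c(1000, 600, 400, 240))
  })
  run <- msRun("x", data.frame(scan_id = seq_along(rts), rt = rts),
               ms1_pk,
               data.frame(scan_id = 99L, rt = 20, iso_center = 501.8,
                          iso_width = 8), list(mkPeaks(200, 1)))
  xa <- extractXic(run, mzA, 2L, rt = 20, n_isotopes = 2L)
  xb <- extractXic(run, mzB, 2L, rt = 20, n_isotopes = 2L)
  expect_equal(xa$observed_mz, mzA, tolerance = 1e-4)
  expect_equal(xb$observed_mz, mzB, tolerance = 1e-4)
  expect_equal(xa$iso_sums[1] / xa$iso_sums[2], 1000 / 600,
               tolerance = 1e-9)
})

test_that("XIC filter keeps strong precursors, drops absent ones, disables cleanly", {
  cfg <- simConfig(n_proteins = 10L, gradient_length = 80, iso_width = 4,
                   frac_precursor_missing = 0.3, seed = 21)
  sim <- simulateRun(cfg)
  db <- buildPeptideDb(sim$proteome$proteins, spec = cfg$digest,
                       mods = list())
  idx <- buildFragmentIndex(db)
  psm <- searchRun(sim$run, idx, db)
  ref <- refinePsms(psm, sim$run)
  tab <- psmTable(ref)
  ## join PSMs to the planted truth
  key <- paste(tab$scan_id, tab$sequence, tab$assumed_charge)
  tkey <- paste(sim$truth$scan_id, sim$truth$sequence, sim$truth$charge)
  j <- match(key, tkey)
  present <- sim$truth$precursor_present[j]
  snr <- sim$truth$snr[j]
  planted <- !is.na(j)
  pass <- tab$xic_quality == "pass"
  strong <- planted & present & snr >= 5
  if (any(strong)) expect_gte(mean(pass[strong]), 0.9)
  absent <- planted & !present
  if (any(absent)) expect_true(!any(pass[absent]))
  ## disabling thresholds passes everything (monotonicity)
  off <- filterByXic(ref, xicThresholds(0L, 0L, Inf))
  expect_equal(nrow(psmTable(off)), nrow(tab))
  on <- filterByXic(ref)
  expect_lte(nrow(psmTable(on)), nrow(psmTable(off)))
  expect_true(all(!is.na(psmTable(on)$observed_precursor_mz)))
})
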