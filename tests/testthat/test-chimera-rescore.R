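test_that("disjoint-fragment PSMs are both emitted with unchanged scores", {
  db_seqs <- c("PEPTIDEKR", "LLLGGGAAK")
  pk <- spectrumFromPeptides(db_seqs, intensity = c(1000, 100))
  psms <- data.frame(sequence = db_seqs, mods = "",
                     assumed_charge = 2L,
                     theo_precursor_mz = c(500, 510),
                     hyperscore = 0, stringsAsFactors = FALSE)
  out <- greedyRescore(pk, psms, searchParamsDefault(), iso_center = 505)
  expect_equal(nrow(out), 2L)
  expect_equal(out$sequence[1], "PEPTIDEKR")
  ## disjoint fragments: rescored equals full-spectrum score for both
  expect_equal(out$rescored_hyperscore[1],
               oracleScore(pk, "PEPTIDEKR", ""), tolerance = 1e-12)
  expect_equal(out$rescored_hyperscore[2],
               oracleScore(pk, "LLLGGGAAK", ""), tolerance = 1e-12)
  expect_equal(out$emission_rank, 1:2)
})

test_that("a PSM matching only a subset of the winner's peaks is suppressed", {
  ## B's y ions are a subset of A's peaks: after A is emitted and its
  ## peaks removed, B drops below min_matched
  pk <- spectrumFromPeptides("PEPTIDEKR", intensity = 1000)
  psms <- data.frame(
    sequence = c("PEPTIDEKR", "TIDEKR"), mods = "",
    assumed_charge = 2L, theo_precursor_mz = c(500, 380),
    hyperscore = 0, stringsAsFactors = FALSE)
  out <- greedyRescore(pk, psms, searchParamsDefault(min_matched = 4L),
                       iso_center = 450)
  expect_equal(out$sequence, "PEPTIDEKR")
  expect_equal(nrow(out), 1L)
})

test_that("single-candidate rescoring is the identity", {
  pk <- spectrumFromPeptides("PEPTIDEKR")
  psms <- data.frame(sequence = "PEPTIDEKR", mods = "",
                     assumed_charge = 2L, theo_precursor_mz = 500,
                     hyperscore = 0, stringsAsFactors = FALSE)
  out <- greedyRescore(pk, psms, searchParamsDefault())
  expect_equal(nrow(out), 1L)
  expect_equal(out$rescored_hyperscore,
               oracleScore(pk, "PEPTIDEKR", ""), tolerance = 1e-12)
  ## empty list -> empty output
  out0 <- greedyRescore(pk, psms[0, ], searchParamsDefault())
  expect_equal(nrow(out0), 0L)
})

test_that("greedy loop matches an independently coded reference on random instances", {
  set.seed(303)
  aas <- names(CoFrag:::RESIDUE_MASS)
  for (rep in 1:40) {
    seqs <- unique(replicate(4, paste(
      c(sample(aas, sample(6:10, 1), replace = TRUE),
        sample(c("K", "R"), 1)), collapse = "")))
    planted <- sample(seqs, sample(2:length(seqs), 1))
    pk <- spectrumFromPeptides(planted,
                               intensity = runif(length(planted), 50, 2000),
                               noise_mz = runif(15, 150, 1500),
                               noise_intensity = runif(15, 1, 40))
    psms <- data.frame(sequence = seqs, mods = "", assumed_charge = 2L,
                       theo_precursor_mz = 500, hyperscore = 0,
                       stringsAsFactors = FALSE)
    got <- greedyRescore(pk, psms, searchParamsDefault(), iso_center = 500)
    want <- referenceGreedy(pk, psms)
    expect_equal(got$sequence, psms$sequence[want$idx])
    expect_equal(got$rescored_hyperscore, want$score, tolerance = 1e-10)
  }
})

test_that("peak claims are conserved: no peak contributes to two emissions", {
  set.seed(9)
  seqs <- c("PEPTIDEKR", "PEPTIDEK", "LLLGGGAAK")
  pk <- spectrumFromPeptides(seqs[1:2], intensity = c(900, 500))
  psms <- data.frame(sequence = seqs, mods = "", assumed_charge = 2L,
                     theo_precursor_mz = 500, hyperscore = 0,
                     stringsAsFactors = FALSE)
  out <- greedyRescore(pk, psms, searchParamsDefault(min_matched = 1L),
                       iso_center = 500)
  ## first emission is the global top scorer on the full spectrum
  full <- vapply(seqs, function(s) oracleScore(pk, s, ""), numeric(1))
  expect_equal(out$rescored_hyperscore[1], max(full), tolerance = 1e-12)
  ## later emissions never reuse earlier claims: their rescored score
  ## never exceeds their full-spectrum score
  for (i in seq_len(nrow(out)))
    expect_lte(out$rescored_hyperscore[i],
               full[out$sequence[i]] + 1e-9)
})

test_that("result assembly conserves rows and ordering", {
  cfg <- simConfig(n_proteins = 8L, gradient_length = 60, iso_width = 8,
                   seed = 13)
  sim <- simulateRun(cfg)
  db <- buildPeptideDb(sim$proteome$proteins, spec = cfg$digest,
                       mods = list())
  idx <- buildFragmentIndex(db)
  psm <- filterByXic(refinePsms(searchRun(sim$run, idx, db), sim$run))
  res <- rescoreRun(psm, sim$run)
  tab <- assembleResults(res)
  expect_equal(nrow(tab), nrow(psmTable(res)))
  expect_false(is.unsorted(tab$scan_id))
  per_scan <- split(tab$emission_rank, tab$scan_id)
  for (er in per_scan) expect_equal(er, seq_along(er))
  expect_true(all(c("rescored_hyperscore", "origin", "xic_kl")
                  %in% names(tab)))
})

test_that("three-plex chimeras with low fragment overlap emit all three peptides", {
  set.seed(71)
  aas <- names(CoFrag:::RESIDUE_MASS)
  ok <- logical(0)
  for (rep in 1:30) {
    seqs <- unique(replicate(3, paste(
      c(sample(aas, sample(8:12, 1), replace = TRUE),
        sample(c("K", "R"), 1)), collapse = "")))
    if (length(seqs) < 3) next
    ## skip draws whose pairwise fragment overlap exceeds 30%
    fr <- lapply(seqs, function(s) round(generateFragments(s)$mz, 3))
    over <- max(vapply(1:2, function(i) max(vapply((i + 1):3, function(j)
      mean(fr[[i]] %in% fr[[j]]), numeric(1))), numeric(1)))
    if (over > 0.3) next
    pk <- spectrumFromPeptides(seqs, intensity = runif(3, 200, 2000),
                               noise_mz = runif(30, 150, 1500),
                               noise_intensity = runif(30, 1, 60))
    psms <- data.frame(sequence = seqs, mods = "", assumed_charge = 2L,
                       theo_precursor_mz = 500, hyperscore = 0,
                       stringsAsFactors = FALSE)
    out <- greedyRescore(pk, psms, searchParamsDefault(), iso_center = 500)
    ok <- c(ok, all(seqs %in% out$sequence))
  }
  expect_gte(length(ok), 25L)
  expect_gte(mean(ok), 0.9)
})
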