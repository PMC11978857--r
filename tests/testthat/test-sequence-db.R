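test_that("peptide neutral mass matches residue-table arithmetic", {
  ## independent oracle: published residue masses + water
  expect_equal(peptideNeutralMass("G"), 57.02146 + 18.0105646863,
               tolerance = 1e-5)
  oracle <- c(P = 97.05276, E = 129.04259, T = 101.04768, I = 113.08406,
              D = 115.02694)
  expect_equal(peptideNeutralMass("PEPTIDE"),
               oracle["P"] + 2 * oracle["E"] + 2 * oracle["P"] +
                 oracle["T"] + oracle["I"] + oracle["D"] + 18.0105646863 -
                 oracle["P"],  # PEPTIDE = P,E,P,T,I,D,E
               tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(peptideNeutralMass("AK", mods = 15.9949),
               71.03711 + 128.09496 + 18.01056 + 15.9949,
               tolerance = 1e-4)
  expect_error(peptideNeutralMass(""), "non-empty")
  expect_error(peptideNeutralMass("AXZ"), "unknown residue")
})

test_that("FASTA round-trip, accession parsing and error contracts", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">P1 first protein", "PEPTIDEK", ">P2", "acdefghikr"), f)
  p <- readProteinFasta(f)
  expect_equal(p$accession, c("P1", "P2"))
  expect_equal(p$description[1], "first protein")
  expect_equal(p$sequence[2], "ACDEFGHIKR")  # upper-cased
  ## duplicate accession rejected by name
  writeLines(c(">P1 a", "AAA", ">P1 b", "CCC"), f)
  expect_error(readProteinFasta(f), "P1")
  ## round-trip
  f2 <- tempfile(fileext = ".fasta")
  writeProteinFasta(p, f2)
  expect_equal(readProteinFasta(f2)$sequence, p$sequence)
})

test_that("tryptic digestion honours cleavage rule, exceptions and missed cleavages", {
  spec0 <- digestSpec(max_missed_cleavages = 0L, length_range = c(1, 50),
                      mass_range = c(1, 1e5), clip_nterm_met = FALSE)
  expect_setequal(digestProtein("AAAKGGGR", spec0)$sequence,
                  c("AAAK", "GGGR"))
  spec1 <- digestSpec(max_missed_cleavages = 1L, length_range = c(1, 50),
                      mass_range = c(1, 1e5), clip_nterm_met = FALSE)
  expect_setequal(digestProtein("AAAKGGGR", spec1)$sequence,
                  c("AAAK", "GGGR", "AAAKGGGR"))
  ## proline blocks cleavage
  expect_setequal(digestProtein("AAKPGG", spec0)$sequence, "AAKPGG")
  ## missed-cleavage superset property across random proteins
  set.seed(11)
  for (rep in 1:5) {
    sq <- paste(sample(names(CoFrag:::RESIDUE_MASS), 80, replace = TRUE),
                collapse = "")
    d1 <- digestProtein(sq, spec0)$sequence
    d2 <- digestProtein(sq, spec1)$sequence
    expect_true(all(d1 %in% d2))
  }
  ## AspN cuts N-terminally of D
  specN <- digestSpec(enzyme = enzymeRule("aspn"),
                      max_missed_cleavages = 0L, length_range = c(1, 50),
                      mass_range = c(1, 1e5), clip_nterm_met = FALSE)
  expect_setequal(digestProtein("AAADGGG", specN)$sequence,
                  c("AAA", "DGGG"))
})

test_that("peptides containing non-canonical residues are excluded", {
  spec0 <- digestSpec(max_missed_cleavages = 0L, length_range = c(1, 50),
                      mass_range = c(1, 1e5), clip_nterm_met = FALSE)
  out <- digestProtein("AAXKGGGR", spec0)
  expect_setequal(out$sequence, "GGGR")
})

test_that("decoy generation reverses sequences and preserves cardinality", {
  p <- data.frame(accession = c("P1", "P2"), description = "",
                  sequence = c("PEPTIDEK", "AAACCC"), origin = "target")
  d <- generateDecoys(p)
  expect_equal(nrow(d), 2L)
  expect_equal(d$sequence[1], "KEDITPEP")
  expect_equal(d$accession, c("rev_P1", "rev_P2"))
  expect_true(all(d$origin == "decoy"))
  ## palindrome flagged
  pal <- data.frame(accession = "P3", description = "",
                    sequence = "ABCBA", origin = "target")
  expect_message(generateDecoys(pal), "palindromic")
})

test_that("entrapment shuffle fixes cleavage sites and preserves composition", {
  p <- data.frame(accession = c("P1", "P2"), description = "",
                  sequence = c("ABCKDEFR", "KKKK"), origin = "target")
  e <- generateEntrapment(p, seed = 42)
  s <- strsplit(e$sequence[1], "")[[1]]
  expect_equal(s[4], "K")
  expect_equal(s[8], "R")
  expect_setequal(s[1:3], c("A", "B", "C"))
  expect_setequal(s[5:7], c("D", "E", "F"))
  expect_equal(e$sequence[2], "KKKK")     # all positions fixed
  ## composition preserved and reproducible for random proteins
  set.seed(3)
  seqs <- replicate(10, paste(sample(names(CoFrag:::RESIDUE_MASS), 60,
                                     replace = TRUE), collapse = ""))
  p2 <- data.frame(accession = paste0("Q", 1:10), description = "",
                   sequence = seqs, origin = "target")
  e1 <- generateEntrapment(p2, seed = 7)
  e2 <- generateEntrapment(p2, seed = 7)
  expect_identical(e1$sequence, e2$sequence)
  for (i in 1:10) {
    expect_equal(sort(strsplit(e1$sequence[i], "")[[1]]),
                 sort(strsplit(seqs[i], "")[[1]]))
    ## proline-blocked K/R are not cleavage sites, hence free to move;
    ## true cleavage sites stay put
    sites <- CoFrag:::cleavageSites(seqs[i], enzymeRule("trypsin"))
    expect_equal(strsplit(e1$sequence[i], "")[[1]][sites],
                 strsplit(seqs[i], "")[[1]][sites])
  }
})

test_that("variable-modification enumeration respects per-rule and global caps", {
  ox <- modificationRule("ox", 15.9949, "M", max_per_peptide = 2L)
  out <- enumerateModifiedPeptides("MAMK", list(ox))
  expect_equal(nrow(out), 4L)  # none, M1, M3, both
  expect_equal(sum(out$mods == ""), 1L)
  expect_equal(max(out$neutral_mass) - min(out$neutral_mass),
               2 * 15.9949, tolerance = 1e-6)
  ## global cap 1 -> 3 forms
  out1 <- enumerateModifiedPeptides("MAMK", list(ox), max_variable = 1L)
  expect_equal(nrow(out1), 3L)
  ## fixed carbamidomethyl applied to every form
  cam <- modificationRule("cam", 57.02146, "C", kind = "fixed")
  outc <- enumerateModifiedPeptides("ACK", list(cam))
  expect_equal(nrow(outc), 1L)
  expect_equal(outc$neutral_mass,
               peptideNeutralMass("ACK") + 57.02146, tolerance = 1e-6)
  ## protein N-term rule only fires on protein N-terminal peptides
  ac <- modificationRule("ac", 42.010565, "protein-N", max_per_peptide = 1L)
  expect_equal(nrow(enumerateModifiedPeptides("AAK", list(ac),
                                              is_protein_nterm = FALSE)), 1L)
  expect_equal(nrow(enumerateModifiedPeptides("AAK", list(ac),
                                              is_protein_nterm = TRUE)), 2L)
  ## combinatorial cap skips the peptide with a warning
  many <- modificationRule("x", 1.0, "A", max_per_peptide = 10L)
  expect_warning(
    out_skip <- enumerateModifiedPeptides(strrep("A", 12),
                                          list(many), max_variable = 12L,
                                          max_forms = 16L),
    "skipped")
  expect_equal(nrow(out_skip), 0L)
})

test_that("database assembly: target-wins origin, stored masses recompute", {
  prot <- data.frame(accession = "P1", description = "",
                     sequence = "MAAAKPEPTIDEKLLLLR", origin = "target")
  db <- buildPeptideDb(prot, spec = digestSpec(length_range = c(5, 50),
                                               mass_range = c(400, 6000)),
                       mods = standardMods(), entrapment = TRUE,
                       entrapment_seed = 5)
  pep <- peptides(db)
  expect_true(all(pep$origin %in% c("target", "decoy", "entrapment")))
  ## every stored mass recomputes within 1e-6 Da
  recomputed <- mapply(function(s, m) peptideNeutralMass(s, parseMods(m)$delta),
                       pep$sequence, pep$mods)
  expect_equal(unname(recomputed), pep$neutral_mass, tolerance = 1e-9)
  ## decoy+entrapment protein counts equal target count each
  tab <- table(proteins(db)$origin)
  expect_equal(unname(tab["entrapment"]), unname(tab["target"]))
  expect_equal(unname(tab["decoy"]),
               unname(tab["target"] + tab["entrapment"]))
  ## a sequence present in target and decoy is labelled target
  pal <- data.frame(accession = "S1", description = "",
                    sequence = "AAAKDDDKAAAK", origin = "target")
  db2 <- buildPeptideDb(pal, spec = digestSpec(length_range = c(4, 50),
                                               mass_range = c(100, 6000),
                                               max_missed_cleavages = 0L),
                        mods = list())
  p2 <- peptides(db2)
  expect_equal(p2$origin[p2$sequence == "AAAK"], "target")
})
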