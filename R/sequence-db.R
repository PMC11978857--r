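## sequence_db: FASTA ingestion, in-silico digestion, decoy and
## entrapment database generation, variable-modification enumeration.

CANONICAL_RESIDUES <- names(RESIDUE_MASS)

#' Digestion settings
#'
#' @param enzyme Named cleavage rule as returned by [enzymeRule()].
#' @param max_missed_cleavages Maximum retained internal cleavage sites.
#' @param length_range Peptide length bounds (residues), inclusive.
#' @param mass_range Neutral mass bounds (Da), inclusive.
#' @param clip_nterm_met Also emit protein N-terminal peptides with the
#'   initiator methionine removed.
#' @return A list of class `DigestSpec`.
#' @export
digestSpec <- function(enzyme = enzymeRule("trypsin"),
                       max_missed_cleavages = 1L,
                       length_range = c(7L, 50L),
                       mass_range = c(500, 5000),
                       clip_nterm_met = TRUE) {
  stopifnot(length(length_range) == 2L, length_range[1] <= length_range[2],
            length(mass_range) == 2L, mass_range[1] <= mass_range[2],
            max_missed_cleavages >= 0L)
  structure(list(enzyme = enzyme,
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 length_range = as.integer(length_range),
                 mass_range = as.numeric(mass_range),
                 clip_nterm_met = isTRUE(clip_nterm_met)),
            class = "DigestSpec")
}

#' Enzymatic cleavage rules
#'
#' @param name One of the built-in enzymes (`"trypsin"`, `"aspn"`,
#'   `"gluc"`), or `"custom"` with the remaining arguments supplied.
#' @param cut Residues after (C side) or before (N side) which the
#'   enzyme cuts.
#' @param side `"C"` or `"N"`.
#' @param exception Residues blocking cleavage on the far side of the
#'   cut (classically proline for trypsin).
#' @return A list describing the rule.
#' @export
enzymeRule <- function(name = "trypsin", cut = NULL, side = NULL,
                       exception = NULL) {
  builtin <- list(
    trypsin = list(cut = "KR", side = "C", exception = "P"),
    aspn    = list(cut = "D",  side = "N", exception = ""),
    gluc    = list(cut = "E",  side = "C", exception = "P")
  )
  if (name %in% names(builtin)) {
    r <- builtin[[name]]
    if (!is.null(cut)) r$cut <- cut
    if (!is.null(side)) r$side <- side
    if (!is.null(exception)) r$exception <- exception
  } else {
    if (is.null(cut) || is.null(side))
      stop("custom enzyme needs 'cut' and 'side'")
    r <- list(cut = cut, side = side,
              exception = if (is.null(exception)) "" else exception)
  }
  c(list(name = name), r)
}

## 0-based cut points: cleavage occurs between position i and i+1
## (1-based residues i, i+1) for each returned i in 1..L-1.
cleavageSites <- function(sequence, enzyme) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(res)
  if (L < 2L) return(integer(0))
  cutset <- strsplit(enzyme$cut, "", fixed = TRUE)[[1L]]
  excset <- strsplit(enzyme$exception, "", fixed = TRUE)[[1L]]
  if (identical(enzyme$side, "C")) {
    i <- which(res[-L] %in% cutset)
    if (length(excset)) i <- i[!(res[i + 1L] %in% excset)]
  } else {
    i <- which(res[-1L] %in% cutset)
    if (length(excset)) i <- i[!(res[i] %in% excset)]
  }
  i
}

#' Read a protein FASTA file
#'
#' The header token before the first whitespace becomes the accession;
#' the remainder becomes the description. Sequences are upper-cased.
#'
#' @param path FASTA file.
#' @param origin Origin label assigned to every record (default
#'   `"target"`).
#' @return data.frame with columns accession, description, sequence,
#'   origin.
#' @export
readProteinFasta <- function(path, origin = "target") {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aa)
  acc <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  dup <- acc[duplicated(acc)]
  if (length(dup))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(aa))
  if (any(!nzchar(seqs))) stop("empty sequence record in FASTA")
  data.frame(accession = acc, description = desc, sequence = unname(seqs),
             origin = origin, stringsAsFactors = FALSE)
}

#' Write proteins to FASTA
#'
#' @param proteins data.frame as returned by [readProteinFasta()].
#' @param path Output path.
#' @export
writeProteinFasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- ifelse(nzchar(proteins$description),
                      paste(proteins$accession, proteins$description),
                      proteins$accession)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Digest one protein in silico
#'
#' Enumerates all peptides obeying the cleavage rule with up to
#' `spec$max_missed_cleavages` missed cleavages, filtered by the length
#' and mass ranges. Peptides containing non-canonical residues (e.g. X)
#' are dropped. When `spec$clip_nterm_met` is set and the protein starts
#' with methionine, N-terminal peptides with the initiator Met removed
#' are also emitted.
#'
#' @param sequence Protein sequence string.
#' @param spec A [digestSpec()].
#' @return data.frame with columns sequence, missed_cleavages,
#'   is_protein_nterm.
#' @export
digestProtein <- function(sequence, spec = digestSpec()) {
  out <- digestCore(sequence, spec, nterm_offset = 0L)
  if (spec$clip_nterm_met && startsWith(sequence, "M") &&
      nchar(sequence) > 1L) {
    clipped <- digestCore(substr(sequence, 2L, nchar(sequence)), spec,
                          nterm_offset = 0L)
    clipped <- clipped[clipped$start == 1L, , drop = FALSE]
    out <- rbind(out, clipped)
  }
  out <- out[!duplicated(paste(out$sequence, out$missed_cleavages)), ]
  out$is_protein_nterm <- out$start == 1L
  out$start <- NULL
  rownames(out) <- NULL
  out
}

digestCore <- function(sequence, spec, nterm_offset = 0L) {
  L <- nchar(sequence)
  sites <- cleavageSites(sequence, spec$enzyme)
  bounds <- c(0L, sites, L)              # peptide i spans bounds[i]+1 .. bounds[i+1]
  n <- length(bounds) - 1L
  seqs <- character(0); mc <- integer(0); start <- integer(0)
  for (i in seq_len(n)) {
    for (m in 0:spec$max_missed_cleavages) {
      j <- i + m
      if (j > n) break
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      len <- e - s + 1L
      if (len < spec$length_range[1] || len > spec$length_range[2]) next
      seqs <- c(seqs, substr(sequence, s, e))
      mc <- c(mc, m)
      start <- c(start, s)
    }
  }
  keep <- !grepl(paste0("[^", paste(CANONICAL_RESIDUES, collapse = ""), "]"),
                 seqs)
  seqs <- seqs[keep]; mc <- mc[keep]; start <- start[keep]
  if (length(seqs)) {
    mass <- vapply(seqs, peptideNeutralMass, numeric(1), USE.NAMES = FALSE)
    keep <- mass >= spec$mass_range[1] & mass <= spec$mass_range[2]
    seqs <- seqs[keep]; mc <- mc[keep]; start <- start[keep]
  }
  data.frame(sequence = seqs, missed_cleavages = mc, start = start,
             stringsAsFactors = FALSE)
}

#' Generate reversed decoy proteins
#'
#' One decoy per target, full sequence reversed, accession prefixed.
#'
#' @param proteins Target (or target+entrapment) protein data.frame.
#' @param prefix Accession prefix (default `"rev_"`).
#' @export
generateDecoys <- function(proteins, prefix = "rev_") {
  revseq <- vapply(strsplit(proteins$sequence, "", fixed = TRUE),
                   function(x) paste(rev(x), collapse = ""), character(1))
  pal <- revseq == proteins$sequence
  if (any(pal))
    message(sum(pal), " palindromic sequence(s): decoy identical to target (",
            paste(utils::head(proteins$accession[pal], 5), collapse = ", "),
            ")")
  data.frame(accession = paste0(prefix, proteins$accession),
             description = proteins$description,
             sequence = revseq, origin = "decoy",
             stringsAsFactors = FALSE)
}

#' Generate shuffled entrapment proteins
#'
#' Each target protein is shuffled to yield one entrapment protein with
#' identical length and amino-acid composition. Residues at enzymatic
#' cleavage positions (for trypsin: K/R not followed by P) stay fixed so
#' that the digested entrapment peptides keep the same terminal
#' structure and count statistics as the targets; all other residues
#' are permuted uniformly at random within each stretch between fixed
#' positions.
#'
#' @param proteins Target protein data.frame.
#' @param seed Integer seed; output is reproducible given the seed.
#' @param enzyme Active cleavage rule (defines the fixed positions).
#' @param prefix Accession prefix (default `"ent_"`).
#' @export
generateEntrapment <- function(proteins, seed,
                               enzyme = enzymeRule("trypsin"),
                               prefix = "ent_") {
  shuffled <- withSeed(seed, {
    vapply(proteins$sequence, function(sq) {
      res <- strsplit(sq, "", fixed = TRUE)[[1L]]
      fixed <- cleavageSites(sq, enzyme)      # 1-based fixed residue positions
      free <- setdiff(seq_along(res), fixed)
      if (length(free) > 1L) {
        ## independent shuffle per stretch between fixed positions
        stretch <- findInterval(free, fixed + 0.5)
        for (g in split(free, stretch)) {
          if (length(g) > 1L) res[g] <- res[sample(g)]
        }
      }
      paste(res, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  data.frame(accession = paste0(prefix, proteins$accession),
             description = proteins$description,
             sequence = shuffled, origin = "entrapment",
             stringsAsFactors = FALSE)
}

## Evaluate expr under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Modification rule
#'
#' @param name Rule name.
#' @param delta_mass Monoisotopic delta in Da.
#' @param site Residue letter, or one of `"protein-N"`, `"peptide-N"`,
#'   `"peptide-C"`.
#' @param kind `"fixed"` or `"variable"`.
#' @param max_per_peptide Cap on occurrences of this rule per peptide
#'   (variable rules).
#' @export
modificationRule <- function(name, delta_mass, site, kind = "variable",
                             max_per_peptide = 3L) {
  stopifnot(kind %in% c("fixed", "variable"))
  structure(list(name = name, delta_mass = delta_mass, site = site,
                 kind = kind, max_per_peptide = as.integer(max_per_peptide)),
            class = "ModificationRule")
}

#' Standard modification rules
#'
#' Carbamidomethylation of cysteine (fixed), oxidation of methionine and
#' acetylation of the protein N-terminus (variable).
#' @export
standardMods <- function() {
  list(
    modificationRule("carbamidomethyl", 57.02146, "C", kind = "fixed"),
    modificationRule("oxidation", 15.9949, "M", max_per_peptide = 2L),
    modificationRule("acetyl_protein_nterm", 42.010565, "protein-N",
                     max_per_peptide = 1L)
  )
}

modsToString <- function(pos, delta) {
  if (!length(pos)) return("")
  o <- order(pos)
  paste(sprintf("%d:%.9g", pos[o], delta[o]), collapse = ";")
}

#' Parse a modification string
#'
#' Inverse of the internal `position:delta` encoding used in peptide
#' tables (0-based positions, semicolon-separated).
#' @param s Modification string (possibly `""`).
#' @return list with integer `pos` and numeric `delta`.
#' @export
parseMods <- function(s) {
  if (is.na(s) || !nzchar(s)) return(list(pos = integer(0), delta = numeric(0)))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  list(pos = vapply(parts, function(p) as.integer(p[1]), integer(1)),
       delta = vapply(parts, function(p) as.numeric(p[2]), numeric(1)))
}

#' Enumerate modified forms of a peptide
#'
#' Applies all fixed rules, then enumerates every combination of
#' variable modifications up to the per-rule caps and the global cap.
#' Terminal-site rules map onto position 0 (N) or L-1 (C) and may
#' coexist with a residue-site modification at the same position; two
#' residue-site modifications never stack.
#'
#' @param sequence Peptide sequence.
#' @param rules List of [modificationRule()]s.
#' @param is_protein_nterm Is this peptide the protein N-terminus
#'   (controls `"protein-N"` rules)?
#' @param max_variable Global cap on variable mods per peptide.
#' @param max_forms Combinatorial cap; if exceeded the peptide is
#'   skipped with a warning and an empty result returned.
#' @return data.frame with columns mods (encoded string) and
#'   neutral_mass; first row is always the form with fixed mods only.
#' @export
enumerateModifiedPeptides <- function(sequence, rules = standardMods(),
                                      is_protein_nterm = FALSE,
                                      max_variable = 3L,
                                      max_forms = 512L) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(res)
  base_mass <- peptideNeutralMass(sequence)

  sitePositions <- function(rule) {
    if (rule$site == "protein-N") {
      if (is_protein_nterm) 0L else integer(0)
    } else if (rule$site == "peptide-N") 0L
    else if (rule$site == "peptide-C") L - 1L
    else which(res == rule$site) - 1L
  }
  terminal <- function(rule) rule$site %in% c("protein-N", "peptide-N",
                                              "peptide-C")

  fixed_pos <- integer(0); fixed_delta <- numeric(0)
  for (r in rules) {
    if (r$kind != "fixed") next
    p <- sitePositions(r)
    fixed_pos <- c(fixed_pos, p)
    fixed_delta <- c(fixed_delta, rep(r$delta_mass, length(p)))
  }

  var_rules <- Filter(function(r) r$kind == "variable", rules)
  ## states: list of (pos, delta, res_pos_used, term_pos_used)
  states <- list(list(pos = integer(0), delta = numeric(0),
                      respos = integer(0), termpos = integer(0)))
  overflow <- FALSE
  for (r in var_rules) {
    sites <- sitePositions(r)
    if (!length(sites)) next
    is_term <- terminal(r)
    new_states <- list()
    for (st in states) {
      avail <- if (is_term) setdiff(sites, st$termpos)
               else setdiff(sites, st$respos)
      kmax <- min(length(avail), r$max_per_peptide,
                  max_variable - length(st$pos))
      new_states[[length(new_states) + 1L]] <- st
      if (kmax >= 1L) {
        for (k in seq_len(kmax)) {
          combs <- utils::combn(avail, k, simplify = FALSE)
          for (cm in combs) {
            st2 <- st
            st2$pos <- c(st2$pos, cm)
            st2$delta <- c(st2$delta, rep(r$delta_mass, length(cm)))
            if (is_term) st2$termpos <- c(st2$termpos, cm)
            else st2$respos <- c(st2$respos, cm)
            new_states[[length(new_states) + 1L]] <- st2
            if (length(new_states) > max_forms) { overflow <- TRUE; break }
          }
          if (overflow) break
        }
      }
      if (overflow) break
    }
    if (overflow) break
    states <- new_states
  }
  if (overflow) {
    warning("modification enumeration for '", sequence,
            "' exceeds max_forms = ", max_forms, "; peptide skipped")
    return(data.frame(mods = character(0), neutral_mass = numeric(0)))
  }
  mods <- vapply(states, function(st) {
    modsToString(c(fixed_pos, st$pos), c(fixed_delta, st$delta))
  }, character(1))
  mass <- vapply(states, function(st) {
    base_mass + sum(fixed_delta) + sum(st$delta)
  }, numeric(1))
  data.frame(mods = mods, neutral_mass = mass, stringsAsFactors = FALSE)
}

#' Build a searchable peptide database
#'
#' Digests target proteins (plus generated decoys and, optionally,
#' shuffled entrapment proteins), enumerates modified forms, and
#' assembles the unique peptide table. A peptide form appearing in
#' several origins is assigned by priority target > entrapment > decoy
#' (the standard target-wins convention).
#'
#' @param target_proteins data.frame of target proteins.
#' @param spec A [digestSpec()].
#' @param mods List of [modificationRule()]s (use `list()` for none).
#' @param decoys Generate reversed decoys (of targets and any
#'   entrapment proteins).
#' @param entrapment Also generate one shuffled entrapment protein per
#'   target.
#' @param entrapment_seed Seed for the entrapment shuffle.
#' @param max_variable Global variable-modification cap per peptide.
#' @return A [PeptideDb-class] object.
#' @export
buildPeptideDb <- function(target_proteins, spec = digestSpec(),
                           mods = standardMods(), decoys = TRUE,
                           entrapment = FALSE, entrapment_seed = 1L,
                           max_variable = 3L) {
  prot <- target_proteins
  prot$origin <- "target"
  if (entrapment)
    prot <- rbind(prot, generateEntrapment(target_proteins, entrapment_seed,
                                           enzyme = spec$enzyme))
  if (decoys) prot <- rbind(prot, generateDecoys(prot))

  chunks <- vector("list", nrow(prot))
  for (i in seq_len(nrow(prot))) {
    pep <- digestProtein(prot$sequence[i], spec)
    if (!nrow(pep)) { chunks[[i]] <- NULL; next }
    if (!length(mods)) {
      ## fast path: unmodified search space
      ch <- data.frame(
        mods = "", neutral_mass = vapply(pep$sequence,
                                         peptideNeutralMass, numeric(1),
                                         USE.NAMES = FALSE),
        sequence = pep$sequence,
        missed_cleavages = pep$missed_cleavages,
        stringsAsFactors = FALSE)
      ch <- ch[ch$neutral_mass >= spec$mass_range[1] &
               ch$neutral_mass <= spec$mass_range[2], , drop = FALSE]
      if (nrow(ch)) {
        ch$origin <- prot$origin[i]
        ch$parents <- prot$accession[i]
        chunks[[i]] <- ch
      }
      next
    }
    forms <- vector("list", nrow(pep))
    for (j in seq_len(nrow(pep))) {
      f <- enumerateModifiedPeptides(pep$sequence[j], mods,
                                     is_protein_nterm = pep$is_protein_nterm[j],
                                     max_variable = max_variable)
      if (!nrow(f)) { forms[[j]] <- NULL; next }
      f <- f[f$neutral_mass >= spec$mass_range[1] &
             f$neutral_mass <= spec$mass_range[2], , drop = FALSE]
      if (!nrow(f)) { forms[[j]] <- NULL; next }
      f$sequence <- pep$sequence[j]
      f$missed_cleavages <- pep$missed_cleavages[j]
      forms[[j]] <- f
    }
    ch <- do.call(rbind, forms)
    if (is.null(ch) || !nrow(ch)) { chunks[[i]] <- NULL; next }
    ch$origin <- prot$origin[i]
    ch$parents <- prot$accession[i]
    chunks[[i]] <- ch
  }
  tab <- do.call(rbind, chunks)
  if (is.null(tab) || !nrow(tab))
    stop("digestion produced no peptides within the configured ranges")

  ## target-wins deduplication by (sequence, mods)
  prio <- c(target = 1L, entrapment = 2L, decoy = 3L)
  key <- paste(tab$sequence, tab$mods, sep = "|")
  o <- order(key, prio[tab$origin])
  tab <- tab[o, ]
  key <- key[o]
  first <- !duplicated(key)
  parents <- vapply(split(tab$parents, match(key, key[first])),
                    function(x) paste(unique(x), collapse = ";"),
                    character(1))
  out <- tab[first, c("sequence", "mods", "neutral_mass",
                      "missed_cleavages", "origin", "parents")]
  out$parents <- unname(parents)
  out$missed_cleavages <- as.integer(
    vapply(split(tab$missed_cleavages, match(key, key[first])), min,
           numeric(1)))
  rownames(out) <- NULL
  new("PeptideDb", proteins = prot, peptides = out,
      digest = list(spec = spec, mods = mods, max_variable = max_variable,
                    decoys = decoys, entrapment = entrapment))
}

#' Export the combined database as FASTA
#'
#' @param db A [PeptideDb-class].
#' @param path Output FASTA path.
#' @export
exportDatabaseFasta <- function(db, path) {
  writeProteinFasta(proteins(db), path)
}
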