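## workflow_cli: end-to-end orchestration (digest -> index -> search ->
## XIC refine -> greedy rescore -> FDR) and result serialization. The
## thin command-line wrapper in inst/cli/cofrag.R calls straight into
## these functions.

#' Pipeline configuration
#'
#' Bundles the per-stage settings. `mode = "dda_plus"` is the full
#' isolation-window search with precursor refinement and greedy
#' rescoring; `mode = "dda_single"` is the conventional baseline:
#' candidates within a narrow ppm tolerance of the reported precursor,
#' one identification per spectrum, no refinement.
#'
#' @param search See [searchParamsDefault()].
#' @param xic See [xicThresholds()].
#' @param rt_halfwidth XIC extraction half-window, seconds.
#' @param xic_mz_tol XIC trace tolerance, ppm.
#' @param max_chimeras Maximum emitted PSMs per spectrum.
#' @param fdr_alpha q-value threshold for the reported tables.
#' @param bin_width Fragment index bin width, Th.
#' @param index_mz_range Indexed fragment m/z range, Th.
#' @param default_iso_width Fallback isolation width for files without
#'   window metadata, Th.
#' @param collapse_mods Count peptides by stripped sequence in the
#'   peptide-level rollup (both rollups are reported in the counts).
#' @param mode `"dda_plus"` or `"dda_single"`.
#' @return list of class `CoFragConfig`.
#' @export
cofragConfig <- function(search = searchParamsDefault(),
                         xic = xicThresholds(),
                         rt_halfwidth = 30,
                         xic_mz_tol = 10,
                         max_chimeras = 5L,
                         fdr_alpha = 0.01,
                         bin_width = 0.02,
                         index_mz_range = c(100, 2000),
                         default_iso_width = 2.0,
                         collapse_mods = FALSE,
                         mode = c("dda_plus", "dda_single")) {
  mode <- match.arg(mode)
  structure(as.list(environment()), class = "CoFragConfig")
}

#' Run the full identification pipeline
#'
#' @param db A [PeptideDb-class], or a target-protein data.frame (then
#'   a database with reversed decoys is built with default digestion
#'   and no modifications), or a FASTA path.
#' @param run An [MsRun-class], an mzML path, or a TSV bundle prefix.
#' @param config A [cofragConfig()].
#' @param output_dir Optional; when given, `psm.tsv`, `peptide.tsv`,
#'   `fdp_report.json` (when entrapment sequences are present) and
#'   `run.log` are written there.
#' @return list with `psms` (emitted PSMs with q-values), `peptides`
#'   (peptide-level table with q-values), `accepted_peptides` (the
#'   q <= alpha subset), `fdp` (entrapment FDP report or NULL), and
#'   `counts` (per-stage tallies).
#' @export
runPipeline <- function(db, run, config = cofragConfig(),
                        output_dir = NULL) {
  if (is.character(db)) db <- readProteinFasta(db)
  if (is.data.frame(db))
    db <- buildPeptideDb(db, mods = list())
  if (is.character(run)) {
    run <- if (grepl("\\.mzML$", run, ignore.case = TRUE))
      readMzML(run, default_iso_width = config$default_iso_width)
    else readRunBundle(run)
  }
  counts <- list(n_ms2 = nrow(ms2Scans(run)),
                 n_peptides_db = nrow(peptides(db)))

  index <- buildFragmentIndex(db, bin_width = config$bin_width,
                              max_frag_charge = config$search$max_frag_charge,
                              mz_range = config$index_mz_range)
  psm <- searchRun(run, index, db, params = config$search,
                   mode = config$mode)
  counts$n_psms_search <- nrow(psmTable(psm))

  if (config$mode == "dda_plus") {
    psm <- refinePsms(psm, run, rt_halfwidth = config$rt_halfwidth,
                      mz_tol = config$xic_mz_tol,
                      thresholds = config$xic)
    psm <- filterByXic(psm, config$xic)
    counts$n_psms_xic <- nrow(psmTable(psm))
    psm <- rescoreRun(psm, run, max_chimeras = config$max_chimeras,
                      mz_range = config$index_mz_range)
  } else {
    tab <- psmTable(psm)
    if (nrow(tab)) {
      tab$rescored_hyperscore <- tab$hyperscore
      tab$emission_rank <- 1L
      tab$n_isotopes_detected <- NA_integer_
      tab$n_consecutive_scans <- NA_integer_
      tab$xic_kl <- NA_real_
      tab$observed_precursor_mz <- NA_real_
      tab$xic_quality <- "not_evaluated"
    }
    psm <- new("PsmSet", psms = tab, run_id = psm@run_id,
               params = psm@params)
    counts$n_psms_xic <- nrow(tab)
  }
  counts$n_psms_emitted <- nrow(psmTable(psm))

  results <- assembleResults(psm)
  if (nrow(results)) {
    results$q_value <- computeQvalues(results$rescored_hyperscore,
                                      results$origin)
  } else results$q_value <- numeric(0)

  peptab <- rollupPeptides(psmTable(psm),
                           collapse_mods = config$collapse_mods)
  peptab$q_value <- computeQvalues(peptab$score, peptab$label)
  flt <- filterAtFdr(peptab, alpha = config$fdr_alpha)
  accepted <- flt$accepted
  counts$n_peptides_accepted <- nrow(accepted)
  counts$n_decoy_peptides_passing <- flt$n_decoys_passing
  ## stripped-sequence rollup reported alongside
  pep_str <- rollupPeptides(psmTable(psm), collapse_mods = TRUE)
  pep_str$q_value <- computeQvalues(pep_str$score, pep_str$label)
  counts$n_stripped_sequences_accepted <-
    sum(pep_str$q_value <= config$fdr_alpha & pep_str$label != "decoy")

  fdp <- NULL
  if (any(proteins(db)$origin == "entrapment") && nrow(accepted)) {
    r <- sum(proteins(db)$origin == "entrapment") /
      sum(proteins(db)$origin == "target")
    fdp <- entrapmentFdp(accepted$label, r = r)
  }

  out <- list(psms = results, peptides = peptab,
              accepted_peptides = accepted, fdp = fdp, counts = counts,
              config = config)
  if (!is.null(output_dir)) writePipelineOutputs(out, output_dir)
  out
}

writePipelineOutputs <- function(out, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  writePsmTable(out$psms, file.path(output_dir, "psm.tsv"))
  writePeptideTable(out$accepted_peptides,
                    file.path(output_dir, "peptide.tsv"))
  if (!is.null(out$fdp)) {
    json <- sprintf(paste0(
      '{"n_target": %d, "n_entrapment": %d, "r": %.6g, ',
      '"fdp_lower": %.6g, "fdp_upper": %.6g}'),
      out$fdp$n_target, out$fdp$n_entrapment, out$fdp$r,
      out$fdp$fdp_lower, out$fdp$fdp_upper)
    writeLines(json, file.path(output_dir, "fdp_report.json"))
  }
  log <- c(
    sprintf("CoFrag pipeline (%s mode)", out$config$mode),
    sprintf("R %s; CoFrag %s", getRversion(),
            as.character(utils::packageVersion("CoFrag"))),
    "config:",
    paste0("  ", names(unlist(out$config)), " = ", unlist(out$config)),
    "counts:",
    paste0("  ", names(out$counts), " = ", unlist(out$counts)))
  writeLines(log, file.path(output_dir, "run.log"))
  invisible(output_dir)
}

formatNum <- function(x) {
  ifelse(is.na(x), "", formatC(signif(x, 6), format = "g", digits = 6))
}

#' Write the PSM result table
#'
#' Fixed column order, floats at 6 significant digits, one header
#' line, rows sorted by (scan, emission rank).
#'
#' @param psms Result data.frame from [assembleResults()] /
#'   [runPipeline()].
#' @param path Output TSV.
#' @export
writePsmTable <- function(psms, path) {
  num <- vapply(psms, is.numeric, logical(1)) &
    !names(psms) %in% c("scan_id", "emission_rank", "assumed_charge",
                        "isotope_error", "n_matched_b", "n_matched_y",
                        "n_isotopes_detected", "n_consecutive_scans")
  out <- psms
  for (j in which(num)) out[[j]] <- formatNum(psms[[j]])
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write the accepted-peptide table
#'
#' @param peptides Peptide data.frame (one row per accepted key).
#' @param path Output TSV.
#' @export
writePeptideTable <- function(peptides, path) {
  out <- peptides
  for (j in which(vapply(out, is.numeric, logical(1))))
    out[[j]] <- formatNum(peptides[[j]])
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
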