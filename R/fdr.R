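## fdr_control: target-decoy q-values at PSM and peptide level, and
## entrapment-based false-discovery-proportion bounds.

#' Target-decoy q-values
#'
#' Records are sorted by score descending;
#' `FDR(s) = #decoys(score >= s) / max(1, #targets(score >= s))` and
#' q-values are the running minimum from the bottom of the list.
#' Entrapment records count as targets here (they are part of the
#' "target" database in the entrapment paradigm). Tied scores share a
#' q-value. With zero targets all q are 1.
#'
#' @param score Numeric scores (larger is better).
#' @param label `"target"`, `"decoy"` or `"entrapment"`.
#' @return Numeric q-values parallel to the input.
#' @export
computeQvalues <- function(score, label) {
  stopifnot(length(score) == length(label),
            all(label %in% c("target", "decoy", "entrapment")))
  n <- length(score)
  if (!n) return(numeric(0))
  is_decoy <- label == "decoy"
  if (sum(!is_decoy) == 0L) return(rep(1, n))
  o <- order(score, decreasing = TRUE)
  d <- cumsum(is_decoy[o])
  t <- cumsum(!is_decoy[o])
  fdr <- d / pmax(t, 1L)
  q <- rev(cummin(rev(fdr)))
  ## ties share the q of the worst-ranked member
  s <- score[o]
  last_of_tie <- c(s[-n] != s[-1L], TRUE)
  q <- rev(cummin(rev(ifelse(last_of_tie, q, 1))))
  out <- numeric(n)
  out[o] <- q
  out
}

#' Filter records at an FDR threshold
#'
#' @param records data.frame with columns `score`, `label` (and
#'   anything else); a `q_value` column is added if absent.
#' @param alpha q-value threshold (default 0.01).
#' @return list with `accepted` (target and entrapment records with
#'   `q_value <= alpha`), `n_decoys_passing`, and the full annotated
#'   table.
#' @export
filterAtFdr <- function(records, alpha = 0.01) {
  if (!"q_value" %in% names(records))
    records$q_value <- computeQvalues(records$score, records$label)
  pass <- records$q_value <= alpha
  accepted <- records[pass & records$label != "decoy", , drop = FALSE]
  rownames(accepted) <- NULL
  list(accepted = accepted,
       n_decoys_passing = sum(pass & records$label == "decoy"),
       records = records)
}

#' Roll PSMs up to peptides
#'
#' Best (highest) score per peptide key. With `collapse_mods` the key
#' is the stripped sequence; otherwise sequence plus modification
#' string.
#'
#' @param psms data.frame with columns `sequence`, `mods`, `score` (or
#'   `rescored_hyperscore`), `origin`.
#' @param collapse_mods Collapse modified forms onto the bare sequence.
#' @return data.frame with one row per peptide key, columns key,
#'   sequence, mods, score, label.
#' @export
rollupPeptides <- function(psms, collapse_mods = FALSE) {
  if (!nrow(psms))
    return(data.frame(key = character(0), sequence = character(0),
                      mods = character(0), score = numeric(0),
                      label = character(0)))
  score <- if ("score" %in% names(psms)) psms$score else
    psms$rescored_hyperscore
  key <- if (collapse_mods) psms$sequence else
    paste(psms$sequence, psms$mods, sep = "|")
  o <- order(key, -score)
  first <- !duplicated(key[o])
  idx <- o[first]
  data.frame(key = key[idx], sequence = psms$sequence[idx],
             mods = psms$mods[idx], score = score[idx],
             label = psms$origin[idx], stringsAsFactors = FALSE)
}

#' Entrapment false-discovery-proportion bounds
#'
#' Given the accepted set from a search against a combined
#' target+entrapment database, with `r` the ratio of entrapment to
#' target database size:
#' `fdp_lower = N_entrap / (N_target + N_entrap)` and
#' `fdp_upper = (N_entrap + N_entrap / r) / (N_target + N_entrap)`
#' (the combined method; with one shuffled entrapment per target,
#' r = 1 and the upper bound is exactly twice the lower bound).
#'
#' @param labels Labels of the accepted records (`"target"` /
#'   `"entrapment"`), or a data.frame with a `label` column.
#' @param r Entrapment-to-target database size ratio (default 1).
#' @return list with n_target, n_entrapment, r, fdp_lower, fdp_upper.
#' @export
entrapmentFdp <- function(labels, r = 1) {
  stopifnot(r > 0)
  if (is.data.frame(labels)) labels <- labels$label
  n_t <- sum(labels == "target")
  n_e <- sum(labels == "entrapment")
  tot <- n_t + n_e
  if (tot == 0L) {
    warning("empty accepted set; FDP reported as 0")
    return(list(n_target = 0L, n_entrapment = 0L, r = r,
                fdp_lower = 0, fdp_upper = 0))
  }
  lower <- n_e / tot
  upper <- min(1, (n_e + n_e / r) / tot)
  list(n_target = n_t, n_entrapment = n_e, r = r,
       fdp_lower = lower, fdp_upper = upper)
}
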