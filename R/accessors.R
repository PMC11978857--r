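#' @rdname PeptideDb-class
#' @export
setMethod("peptides", "PeptideDb", function(x) x@peptides)

#' @rdname PeptideDb-class
#' @export
setMethod("proteins", "PeptideDb", function(x) x@proteins)

#' @rdname MsRun-class
#' @export
setMethod("ms1Scans", "MsRun", function(x) x@ms1)

#' @rdname MsRun-class
#' @export
setMethod("ms2Scans", "MsRun", function(x) x@ms2)

#' @rdname MsRun-class
#' @export
setMethod("ms1Peaks", "MsRun", function(x) x@ms1_peaks)

#' @rdname MsRun-class
#' @export
setMethod("ms2Peaks", "MsRun", function(x) x@ms2_peaks)

#' @rdname MsRun-class
#' @export
setMethod("runId", "MsRun", function(x) x@run_id)

#' @rdname PsmSet-class
#' @export
setMethod("psmTable", "PsmSet", function(x) x@psms)

#' @rdname PsmSet-class
#' @export
setMethod("searchParams", "PsmSet", function(x) x@params)

#' @rdname FragmentIndex-class
#' @export
setMethod("binWidth", "FragmentIndex", function(x) x@bin_width)

setMethod("show", "PeptideDb", function(object) {
  p <- object@proteins
  tab <- table(factor(p$origin, levels = c("target", "decoy", "entrapment")))
  cat("PeptideDb with", nrow(p), "proteins (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n")
  cat("  ", nrow(object@peptides), "peptide entries after digestion",
      "and modification enumeration\n")
})

setMethod("show", "FragmentIndex", function(object) {
  cat("FragmentIndex:", length(object@frag_mz), "fragments over",
      length(object@pep_mass), "peptides\n")
  cat("  bin width", object@bin_width, "Th;",
      length(object@bin_ids), "occupied bins; fragment m/z range [",
      paste(signif(object@mz_range, 6), collapse = ", "), "]\n")
})

setMethod("show", "MsRun", function(object) {
  cat("MsRun '", object@run_id, "': ", nrow(object@ms1), " MS1 / ",
      nrow(object@ms2), " MS2 scans\n", sep = "")
  if (nrow(object@ms2)) {
    w <- unique(stats::na.omit(object@ms2$iso_width))
    cat("  isolation width(s):", paste(signif(sort(w), 4), collapse = ", "),
        "Th; rt span",
        signif(diff(range(c(object@ms1$rt, object@ms2$rt))), 4), "s\n")
  }
})

setMethod("show", "PsmSet", function(object) {
  cat("PsmSet for run '", object@run_id, "': ", nrow(object@psms),
      " PSMs over ", length(unique(object@psms$scan_id)),
      " spectra\n", sep = "")
  if ("emission_rank" %in% names(object@psms) &&
      any(!is.na(object@psms$emission_rank)))
    cat("  rescored:", sum(!is.na(object@psms$emission_rank)),
        "emitted PSMs\n")
})
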