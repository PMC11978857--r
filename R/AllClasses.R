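#' @import methods
NULL

#' Peptide database
#'
#' Container for a searchable peptide database: the source proteins
#' (targets plus any decoy / entrapment sequences), and the fully
#' enumerated peptide table after in-silico digestion and modification
#' enumeration.
#'
#' The peptide table has one row per (sequence, modification set) and
#' columns `sequence`, `mods` (semicolon-joined `position:delta` pairs,
#' 0-based positions), `neutral_mass` (monoisotopic Da),
#' `missed_cleavages`, `origin` (`target`, `decoy` or `entrapment`) and
#' `parents` (semicolon-joined protein accessions).
#'
#' @slot proteins data.frame with columns accession, description,
#'   sequence, origin.
#' @slot peptides data.frame as described above.
#' @slot digest list recording the digestion and modification settings
#'   used to build the table.
#' @aliases PeptideDb
#' @exportClass PeptideDb
setClass("PeptideDb", representation(
  proteins = "data.frame",
  peptides = "data.frame",
  digest = "list"
))

setValidity("PeptideDb", function(object) {
  msg <- character(0)
  p <- object@proteins
  need <- c("accession", "description", "sequence", "origin")
  if (!all(need %in% names(p)))
    msg <- c(msg, "proteins must have columns accession/description/sequence/origin")
  else {
    if (anyDuplicated(p$accession))
      msg <- c(msg, "duplicate protein accessions")
    if (!all(p$origin %in% c("target", "decoy", "entrapment")))
      msg <- c(msg, "protein origin must be target/decoy/entrapment")
  }
  pep <- object@peptides
  neededp <- c("sequence", "mods", "neutral_mass", "missed_cleavages",
               "origin", "parents")
  if (!all(neededp %in% names(pep)))
    msg <- c(msg, "peptides table is missing required columns")
  if (length(msg)) msg else TRUE
})

#' Binned theoretical-fragment index
#'
#' All b/y fragments of every peptide in a [PeptideDb], assigned to m/z
#' bins of fixed width and, within each bin, ordered by the parent
#' peptide's neutral mass so that precursor-window restrictions map to
#' contiguous slices. Also carries the peptide neutral masses sorted
#' ascending for binary-search candidate retrieval.
#'
#' @slot bin_width Fragment bin width in Th.
#' @slot frag_mz,frag_pep,frag_series,frag_ordinal,frag_charge Parallel
#'   vectors describing each indexed fragment, ordered by (bin, parent
#'   neutral mass). `frag_series` is 1 for b ions, 2 for y ions.
#' @slot bin_ids Sorted distinct bin ordinals present in the index.
#' @slot bin_offsets CSR-style offsets: fragments of bin `i` occupy
#'   positions `(bin_offsets[i]+1):bin_offsets[i+1]`.
#' @slot pep_mass Neutral mass per database peptide (database order).
#' @slot mass_order Permutation sorting peptides by neutral mass.
#' @slot mass_sorted `pep_mass[mass_order]`.
#' @slot mz_range Indexed fragment m/z range (Th).
#' @aliases FragmentIndex
#' @exportClass FragmentIndex
setClass("FragmentIndex", representation(
  bin_width = "numeric",
  frag_mz = "numeric",
  frag_pep = "integer",
  frag_series = "integer",
  frag_ordinal = "integer",
  frag_charge = "integer",
  bin_ids = "numeric",
  bin_offsets = "integer",
  pep_mass = "numeric",
  mass_order = "integer",
  mass_sorted = "numeric",
  mz_range = "numeric"
))

setValidity("FragmentIndex", function(object) {
  n <- length(object@frag_mz)
  if (length(object@frag_pep) != n || length(object@frag_series) != n ||
      length(object@frag_ordinal) != n || length(object@frag_charge) != n)
    return("fragment vectors must have equal length")
  if (length(object@bin_offsets) != length(object@bin_ids) + 1L)
    return("bin_offsets must have one more element than bin_ids")
  if (object@bin_width <= 0) return("bin_width must be positive")
  if (is.unsorted(object@mass_sorted)) return("mass_sorted must be ascending")
  TRUE
})

#' In-memory LC-MS run
#'
#' Centroided MS1 and MS2 scans of one run. Scan metadata live in two
#' data.frames; centroid peak lists are parallel lists of two-column
#' matrices (`mz`, `intensity`), each sorted ascending by m/z. Retention
#' times are in seconds, m/z in Th.
#'
#' MS2 scan columns: `scan_id`, `rt`, `parent_ms1` (row index into the
#' MS1 table, NA when no earlier MS1 exists), `iso_center`, `iso_width`,
#' `precursor_mz` and `precursor_charge` (instrument-reported; NA when
#' absent).
#'
#' @slot run_id Run identifier.
#' @slot ms1 data.frame (`scan_id`, `rt`), ordered by rt.
#' @slot ms1_peaks list of peak matrices parallel to `ms1`.
#' @slot ms2 data.frame as described above, ordered by rt.
#' @slot ms2_peaks list of peak matrices parallel to `ms2`.
#' @slot metadata Free-form list.
#' @aliases MsRun
#' @exportClass MsRun
setClass("MsRun", representation(
  run_id = "character",
  ms1 = "data.frame",
  ms1_peaks = "list",
  ms2 = "data.frame",
  ms2_peaks = "list",
  metadata = "list"
))

setValidity("MsRun", function(object) {
  msg <- character(0)
  if (nrow(object@ms1) != length(object@ms1_peaks))
    msg <- c(msg, "ms1 table and ms1_peaks length differ")
  if (nrow(object@ms2) != length(object@ms2_peaks))
    msg <- c(msg, "ms2 table and ms2_peaks length differ")
  if (nrow(object@ms1) && is.unsorted(object@ms1$rt))
    msg <- c(msg, "ms1 scans must be rt-ordered")
  if (nrow(object@ms2)) {
    if (is.unsorted(object@ms2$rt))
      msg <- c(msg, "ms2 scans must be rt-ordered")
    if (any(object@ms2$iso_width <= 0, na.rm = TRUE))
      msg <- c(msg, "iso_width must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Peptide-spectrum match set
#'
#' PSM table produced by [searchRun()] and downstream refinement steps.
#' One row per candidate peptide-spectrum pairing; refinement and
#' rescoring columns are filled as the pipeline progresses.
#'
#' @slot psms data.frame of PSMs.
#' @slot run_id Identifier of the searched run.
#' @slot params Search/refinement parameters used.
#' @aliases PsmSet
#' @exportClass PsmSet
setClass("PsmSet", representation(
  psms = "data.frame",
  run_id = "character",
  params = "list"
))
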