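#' Build an RNA-seq-augmented custom proteome library
#'
#' Concatenates the reference proteome with one entry per splicing-derived
#' junction peptide, for use as the search database of an MS run. Reference
#' entries are passed through unchanged and come first; peptide entries get
#' machine-parsable headers `AS|<id>|<flags>`. Duplicate peptide sequences
#' are still emitted under distinct ids (search engines deduplicate);
#' peptides that occur verbatim inside a reference protein are flagged
#' `substring-of-reference`.
#'
#' @param peptides data.table with columns event_id (or id) and sequence.
#' @param reference an `AAStringSet` or path to a protein FASTA.
#' @param out optional path; when given the library is written there.
#' @return `AAStringSet` of the combined library (reference first), with a
#'   data.table of peptide flags in attribute "peptide_flags".
#' @export
build_custom_proteome <- function(peptides, reference, out = NULL) {
  if (is.character(reference)) reference <- Biostrings::readAAStringSet(reference)
  peptides <- as.data.table(peptides)
  id_col <- if ("event_id" %in% names(peptides)) "event_id" else "id"
  if (nrow(peptides) == 0) {
    warning("empty peptide set; emitting reference proteome unchanged")
    lib <- reference
    flags <- data.table(id = character(), substring_of_reference = logical())
  } else {
    ids <- make.unique(as.character(peptides[[id_col]]), sep = "_dup")
    is_sub <- vapply(peptides$sequence, function(s) {
      any(Biostrings::vcountPattern(s, reference) > 0)
    }, TRUE)
    hdr <- sprintf("AS|%s|%s", ids,
                   ifelse(is_sub, "substring-of-reference", "-"))
    aspep <- Biostrings::AAStringSet(peptides$sequence)
    names(aspep) <- hdr
    lib <- c(reference, aspep)
    flags <- data.table(id = ids, substring_of_reference = is_sub)
  }
  attr(lib, "peptide_flags") <- flags
  if (!is.null(out)) Biostrings::writeXStringSet(lib, out)
  lib
}

#' Read a peptide-spectrum-match (PSM) table
#'
#' Consumes any tab-delimited PSM table with peptide and q-value columns;
#' `col_map` adapts dialects (e.g. MSGF+ TSV exports).
#'
#' @param path path to the PSM table.
#' @param col_map named character vector mapping canonical names
#'   (`peptide`, `q_value`, optionally `spectrum_id`, `protein`) to the
#'   file's column names.
#' @return data.table with canonical columns; peptides uppercased.
#' @export
read_psm_table <- function(path, col_map = c(peptide = "peptide",
                                             q_value = "q_value")) {
  tab <- data.table::fread(path, sep = "\t")
  missing <- setdiff(unname(col_map), names(tab))
  if (length(missing)) stop("PSM table missing column(s): ",
                            paste(missing, collapse = ", "))
  out <- data.table(peptide = toupper(as.character(tab[[col_map["peptide"]]])),
                    q_value = as.numeric(tab[[col_map["q_value"]]]))
  if ("spectrum_id" %in% names(col_map)) {
    out[, spectrum_id := tab[[col_map["spectrum_id"]]]]
  }
  if (any(out$q_value < 0 | out$q_value > 1, na.rm = TRUE)) {
    stop("q_value outside [0,1]")
  }
  out
}

#' Cross-reference predicted epitopes with MS-detected peptides
#'
#' MS-validated epitopes are epitopes that are both predicted and detected
#' in the immunopeptidomics data at or below the q-value cutoff. Because MS
#' cannot distinguish isoleucine from leucine, an optional I/L-equivalence
#' mode collapses I and L before intersecting (off by default, preserving
#' exactness).
#'
#' @param predicted character vector of predicted epitope peptides (or a
#'   data.table with a `peptide` column).
#' @param psms PSM data.table (peptide, q_value).
#' @param q_max FDR cutoff (default 0.05).
#' @param il_equivalence collapse I/L before matching.
#' @return list: `validated` (predicted peptide strings detected),
#'   `counts` (n_psms, n_unique_peptides, n_predicted, n_validated).
#' @export
crossref_ms_peptides <- function(predicted, psms, q_max = 0.05,
                                 il_equivalence = FALSE) {
  if (is.data.frame(predicted)) predicted <- predicted$peptide
  predicted <- unique(toupper(predicted))
  keep <- psms[!is.na(q_value) & q_value <= q_max]
  det <- unique(keep$peptide)
  key <- function(x) if (il_equivalence) chartr("I", "L", x) else x
  validated <- predicted[key(predicted) %in% key(det)]
  list(validated = validated,
       counts = list(n_psms = nrow(keep),
                     n_unique_peptides = length(det),
                     n_predicted = length(predicted),
                     n_validated = length(validated)))
}

#' Bin epitope detection rates by expression and binding affinity
#'
#' Approximates transcript-level expression as gene FPKM times PSI (for
#' inclusion-isoform epitopes) or times 1-PSI (skipping), bins epitopes on
#' an expression x affinity grid, and tallies the fraction of predicted
#' epitopes that were MS-detected per cell. Default bin edges follow the
#' thresholds that matter in practice: 1/10/100 FPKM and 50/250/500 nM.
#'
#' @param epitopes data.table with peptide, fpkm, psi, isoform,
#'   median_ic50.
#' @param validated character vector of MS-validated peptide strings.
#' @param expr_edges,aff_edges ascending bin edges (right-open; first edge
#'   inclusive, Inf-terminated).
#' @return list: `grid` (expr_bin x aff_bin with predicted, detected,
#'   fraction — NA fraction for empty cells), `n_excluded` (epitopes
#'   lacking expression).
#' @export
bin_detection_rates <- function(epitopes, validated,
                                expr_edges = c(0, 1, 10, 100, Inf),
                                aff_edges = c(0, 50, 250, 500, Inf)) {
  x <- as.data.table(epitopes)
  x[, expression := fpkm * ifelse(isoform == "inclusion", psi, 1 - psi)]
  excl <- sum(is.na(x$expression) | is.na(x$median_ic50))
  x <- x[!is.na(expression) & !is.na(median_ic50)]
  x[, expr_bin := cut(expression, expr_edges, right = FALSE,
                      include.lowest = TRUE)]
  x[, aff_bin := cut(median_ic50, aff_edges, right = FALSE,
                     include.lowest = TRUE)]
  x[, detected := peptide %in% validated]
  grid <- x[data.table::CJ(expr_bin = levels(x$expr_bin),
                           aff_bin = levels(x$aff_bin)),
            on = c("expr_bin", "aff_bin"),
            .(predicted = sum(!is.na(peptide)), detected = sum(detected, na.rm = TRUE)),
            by = .EACHI]
  grid[, expr_bin := factor(expr_bin, levels = levels(x$expr_bin))]
  grid[, aff_bin := factor(aff_bin, levels = levels(x$aff_bin))]
  data.table::setorder(grid, expr_bin, aff_bin)
  grid[, fraction := ifelse(predicted > 0, detected / predicted, NA_real_)]
  list(grid = grid[], n_excluded = excl)
}

utils::globalVariables(c("expression", "psi", "spectrum_id", "fraction"))
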