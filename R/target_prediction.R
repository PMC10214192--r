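#' Enumerate junction-spanning HLA-I epitope windows
#'
#' All substrings of the requested lengths that contain the
#' junction-position residue of a junction peptide, deduplicated.
#' Typical HLA class I ligands are 8-11 residues; the default asks for
#' 9- and 10-mers.
#'
#' @param sequence junction peptide (amino-acid string).
#' @param junction_position residue index whose codon spans or abuts the
#'   junction.
#' @param lengths integer vector of window lengths.
#' @return data.table with columns peptide, start, length (0 rows when the
#'   peptide is shorter than every requested length).
#' @export
enumerate_junction_epitopes <- function(sequence, junction_position,
                                        lengths = c(9L, 10L)) {
  n <- nchar(sequence)
  out <- list()
  for (L in sort(unique(as.integer(lengths)))) {
    if (n < L) next
    from <- max(1L, junction_position - L + 1L)
    to <- min(junction_position, n - L + 1L)
    if (from > to) next
    starts <- from:to
    out[[length(out) + 1L]] <- data.table(
      peptide = substring(sequence, starts, starts + L - 1L),
      start = starts, length = L)
  }
  if (!length(out)) {
    return(data.table(peptide = character(), start = integer(), length = integer()))
  }
  res <- data.table::rbindlist(out)
  res[!duplicated(peptide)]
}

#' Deterministic mock HLA binding-affinity predictor
#'
#' Stands in for external HLA-I binding predictors (which are network
#' services and out of scope): for each (peptide, allele) it returns three
#' pseudo-tool IC50 values in nanomolar, log-uniformly spread over
#' `[1, 50000]` nM, derived from a cryptographic hash of the inputs so the
#' values are reproducible across platforms but carry no biology. Supported
#' alleles follow HLA class I nomenclature (`HLA-A/B/C*..`).
#'
#' @param n_tools number of pseudo prediction tools.
#' @return an `AffinityPredictor`: list(name, supports(allele),
#'   predict(peptide, allele) -> numeric IC50 vector).
#' @export
mock_affinity_predictor <- function(n_tools = 3L) {
  pred_one <- function(peptide, allele, tool) {
    h <- digest::digest(paste(peptide, allele, tool, sep = "|"), algo = "sha1")
    u <- strtoi(substr(h, 1, 6), 16L) / 16^6
    10^(u * log10(50000))
  }
  structure(list(
    name = "mock",
    supports = function(allele) grepl("^HLA-[ABC]\\*[0-9]+:[0-9]+$", allele),
    predict = function(peptide, allele) {
      vapply(seq_len(n_tools), function(t) pred_one(peptide, allele, t), 0)
    }), class = "AffinityPredictor")
}

#' Score epitope candidates and call TCR targets by median IC50
#'
#' Each (peptide, allele) pair is scored by the predictor plugin, which may
#' return several IC50 values (one per underlying tool); these are
#' summarized as a median, and a positive TCR-target call requires
#' median IC50 strictly below `ic50_threshold` (default 500 nM). An
#' unsupported allele marks the candidate unscored rather than dropping it.
#'
#' @param candidates data.table with at least columns event_id, peptide.
#' @param alleles character vector of HLA allele names.
#' @param predictor an `AffinityPredictor` (default: the mock).
#' @param ic50_threshold positive-call threshold, nM.
#' @return data.table: event_id, peptide, allele, ic50_values
#'   (";"-joined), median_ic50, positive, scored.
#' @export
score_epitopes <- function(candidates, alleles,
                           predictor = mock_affinity_predictor(),
                           ic50_threshold = 500) {
  if (!length(alleles)) stop("alleles must be non-empty")
  candidates <- as.data.table(candidates)
  grid <- data.table::CJ(i = seq_len(nrow(candidates)), allele = alleles,
                         sorted = FALSE)
  res <- candidates[grid$i, .(event_id, peptide)]
  res[, allele := grid$allele]
  supported <- vapply(res$allele, predictor$supports, TRUE)
  vals <- vector("list", nrow(res))
  med <- rep(NA_real_, nrow(res))
  for (i in which(supported)) {
    v <- predictor$predict(res$peptide[i], res$allele[i])
    vals[[i]] <- v
    med[i] <- median(v)
  }
  res[, ic50_values := vapply(vals, function(v)
    if (is.null(v)) NA_character_ else paste(sprintf("%.6g", v), collapse = ";"), "")]
  res[, median_ic50 := med]
  res[, scored := supported]
  res[, positive := scored & median_ic50 < ic50_threshold]
  res[]
}

#' Read an extracellular-domain annotation table
#'
#' @param path TSV with columns protein_id, start, end (1-based inclusive
#'   residue intervals) and optionally a feature label column.
#' @return data.table of normalized (sorted, merged) intervals per protein.
#' @export
read_extracellular_annotation <- function(path) {
  ann <- data.table::fread(path, sep = "\t")
  if (!all(c("protein_id", "start", "end") %in% names(ann))) {
    stop("extracellular annotation needs columns protein_id, start, end")
  }
  ann <- ann[order(protein_id, start)]
  ann[, .(protein_id, start = as.integer(start), end = as.integer(end))]
}

#' Map junction peptides to extracellular domains (CAR-T candidacy)
#'
#' A peptide is a CAR-T candidate iff its residue interval on the annotated
#' protein intersects an annotated extracellular interval. Peptides that
#' cannot be mapped to a protein (no frame, frameshift, novel junction)
#' are "unmapped"; proteins without topology annotation give "no
#' annotation".
#'
#' @param peptides data.table from [translate_event_peptides()] (needs
#'   protein_id, residue_start, residue_end).
#' @param annotation data.table protein_id/start/end (see
#'   [read_extracellular_annotation()]).
#' @return input with cart_candidate, cart_overlap, cart_reason columns.
#' @export
map_extracellular <- function(peptides, annotation) {
  out <- data.table::copy(peptides)
  ov <- integer(nrow(out)); cand <- logical(nrow(out))
  reason <- rep(NA_character_, nrow(out))
  for (i in seq_len(nrow(out))) {
    pid <- out$protein_id[i]
    if (is.na(pid) || is.na(out$residue_start[i])) {
      reason[i] <- "unmapped"; next
    }
    ints <- annotation[protein_id == pid]
    if (!nrow(ints)) { reason[i] <- "no annotation"; next }
    o <- pmin(ints$end, out$residue_end[i]) - pmax(ints$start, out$residue_start[i]) + 1L
    ov[i] <- max(0L, max(o))
    cand[i] <- ov[i] > 0L
    if (!cand[i]) reason[i] <- "outside extracellular region"
  }
  out[, cart_candidate := cand]
  out[, cart_overlap := ov]
  out[, cart_reason := reason]
  out[]
}

#' Shortlist epitopes for experimental validation
#'
#' Applies the validation-selection filters to positive epitopes:
#' restriction to a given HLA allele, fold-change of the tumor-enriched
#' isoform at or above `fc_min`, and mean gene expression at or above
#' `fpkm_min` FPKM. The shortlist is deduplicated to unique peptide
#' strings (one row per peptide, all contributing events listed);
#' tumor-specific events are flagged for priority.
#'
#' @param scored output of [score_epitopes()].
#' @param records screen records (fc, tumor_specific per event).
#' @param expression data.table event_id (or gene_id) to mean FPKM; column
#'   `fpkm`.
#' @param allele_restrict HLA allele the shortlist is restricted to.
#' @param fc_min,fpkm_min inclusive thresholds.
#' @return list with `shortlist` (unique peptides) and `excluded`
#'   (event-level exclusion reasons).
#' @export
prioritize_candidates <- function(scored, records, expression,
                                  allele_restrict = "HLA-A*02:01",
                                  fc_min = 2, fpkm_min = 20) {
  x <- scored[positive %in% TRUE & allele == allele_restrict]
  idx <- match(x$event_id, records$event_id)
  x[, fc := records$fc[idx]]
  x[, tumor_specific := records$tumor_specific[idx]]
  key_col <- if ("event_id" %in% names(expression)) "event_id" else "gene_id"
  x[, fpkm := expression$fpkm[match(x$event_id, expression[[key_col]])]]
  excluded <- x[is.na(fpkm), .(event_id = unique(event_id),
                               reason = "missing expression")]
  x <- x[!is.na(fpkm) & fc >= fc_min & fpkm >= fpkm_min]
  shortlist <- x[, .(event_ids = paste(unique(event_id), collapse = ","),
                     allele = allele_restrict,
                     median_ic50 = min(median_ic50),
                     fc = max(fc), fpkm = max(fpkm),
                     priority_tumor_specific = any(tumor_specific %in% TRUE)),
                 by = peptide]
  list(shortlist = shortlist[], excluded = excluded)
}

utils::globalVariables(c("fpkm", "ic50_values", "scored", "cart_candidate",
                         "cart_overlap", "cart_reason", "min_p_bh"))
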