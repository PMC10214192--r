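#' Run the full target-discovery pipeline
#'
#' Orchestrates the stages panel -> screen -> translate -> predict ->
#' proteo over one panel and tumor cohort, producing the stepwise funnel
#' (events quantified, tested, tumor-associated, tumor-specific,
#' translatable, epitope candidates, positive epitopes, shortlist) and all
#' intermediate tables. Stages whose inputs are not supplied (e.g. no
#' alleles, no genome) are skipped with an explicit notice; every drop is
#' tallied by reason so the funnel arithmetic is auditable.
#'
#' @param panel a `ReferencePanel`.
#' @param tumor_group tumor cohort group id.
#' @param config a [screen_config()].
#' @param genome `DNAStringSet`/FASTA path (enables translation).
#' @param models `gene_models` (enables translation).
#' @param alleles HLA allele names (enables epitope prediction).
#' @param predictor an `AffinityPredictor`.
#' @param expression data.table event_id/gene_id + fpkm (enables the
#'   shortlist stage).
#' @param extracellular annotation table (enables CAR-T mapping).
#' @param psms PSM table (enables MS cross-referencing).
#' @param epitope_lengths window lengths for epitope enumeration.
#' @param out_dir optional directory; when given, all tables are written
#'   as TSVs plus a run-metadata JSON.
#' @param seed recorded in the metadata (the pipeline itself is
#'   deterministic given its inputs).
#' @return list of class `target_report`: funnel counts, per-stage tables,
#'   notices, and run metadata (config hash).
#' @export
run_pipeline <- function(panel, tumor_group, config = screen_config(),
                         genome = NULL, models = NULL, alleles = NULL,
                         predictor = mock_affinity_predictor(),
                         expression = NULL, extracellular = NULL,
                         psms = NULL, epitope_lengths = c(9L, 10L),
                         out_dir = NULL, seed = NA_integer_) {
  notices <- character(0)
  scr <- screen_events(panel, tumor_group, config)
  rec <- scr$records
  funnel <- list(events_quantified = nrow(rec),
                 events_tested = sum(rec$tested),
                 tumor_associated = sum(rec$tumor_associated),
                 tumor_specific = sum(rec$tumor_specific %in% TRUE),
                 cpm_pass = sum(rec$cpm_pass %in% TRUE))

  peptides <- NULL; dropped <- NULL
  if (!is.null(genome) && !is.null(models)) {
    tr <- translate_event_peptides(panel$events, rec[tumor_associated == TRUE],
                                   genome, models)
    peptides <- tr$peptides; dropped <- tr$dropped
    funnel$translatable <- nrow(peptides)
  } else {
    notices <- c(notices, "translation skipped: no genome/annotation provided")
  }

  scored <- NULL; epitopes <- NULL
  if (!is.null(peptides) && nrow(peptides) && length(alleles)) {
    cand <- peptides[, enumerate_junction_epitopes(
      sequence, junction_position, epitope_lengths), by = event_id]
    cand <- cand[!duplicated(paste(event_id, peptide))]
    scored <- score_epitopes(cand, alleles, predictor)
    # candidates are counted per (window, allele), the unit of scoring
    funnel$epitope_candidates <- nrow(scored)
    epitopes <- scored[positive %in% TRUE]
    funnel$positive_epitopes <- nrow(epitopes)
  } else if (is.null(alleles) || !length(alleles)) {
    notices <- c(notices, "prediction skipped: no HLA alleles provided")
  }

  cart <- NULL
  if (!is.null(peptides) && !is.null(extracellular)) {
    cart <- map_extracellular(peptides, as.data.table(extracellular))
    funnel$cart_candidates <- sum(cart$cart_candidate)
  }

  shortlist <- NULL
  if (!is.null(scored) && !is.null(expression)) {
    pr <- prioritize_candidates(scored, rec, as.data.table(expression),
                                allele_restrict = alleles[1])
    shortlist <- pr$shortlist
    funnel$shortlist <- nrow(shortlist)
  } else if (!is.null(scored)) {
    notices <- c(notices, "shortlist skipped: no expression table provided")
  }

  ms <- NULL
  if (!is.null(epitopes) && !is.null(psms)) {
    ms <- crossref_ms_peptides(unique(epitopes$peptide), as.data.table(psms))
    funnel$ms_validated <- ms$counts$n_validated
  }

  meta <- list(config_hash = config_hash(unclass(config)), seed = seed,
               package_version = as.character(utils::packageVersion("splicescreen")),
               tumor_group = tumor_group)
  report <- structure(list(funnel = funnel, records = rec,
                           junction_calls = scr$junction_calls,
                           junction_specificity = scr$junction_specificity,
                           peptides = peptides, dropped = dropped,
                           epitopes = scored, shortlist = shortlist,
                           cart = cart, ms = ms,
                           microexons = microexon_tally(panel$events, rec),
                           notices = notices, meta = meta,
                           screen = scr),
                      class = "target_report")
  if (!is.null(out_dir)) export_report(report, out_dir)
  report
}

#' @export
print.target_report <- function(x, ...) {
  cat("target_report (config ", substr(x$meta$config_hash, 1, 8), ")\n", sep = "")
  for (nm in names(x$funnel)) {
    cat(sprintf("  %-20s %d\n", nm, x$funnel[[nm]]))
  }
  if (length(x$notices)) cat("  notices: ", paste(x$notices, collapse = "; "), "\n")
  invisible(x)
}

export_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) if (!is.null(x) && is.data.frame(x)) {
    data.table::fwrite(x, file.path(dir, f), sep = "\t")
  }
  wr(report$records, "screen_records.tsv")
  wr(report$peptides, "junction_peptides.tsv")
  wr(report$dropped, "dropped_events.tsv")
  wr(report$epitopes, "epitopes.tsv")
  wr(report$shortlist, "shortlist.tsv")
  wr(report$cart, "cart_candidates.tsv")
  wr(report$microexons, "microexon_tally.tsv")
  jsonlite::write_json(c(report$meta, list(funnel = report$funnel,
                                           notices = report$notices)),
                       file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Export per-event visualization data
#'
#' For each selected event, writes (or returns) the data behind the
#' standard paired violin/bar display: per-sample PSI by group (violin)
#' and the fraction of samples expressing each junction of the
#' tumor-enriched isoform by group (bar). Inclusion-enriched skipped-exon
#' events yield two junction rows (upstream and downstream inclusion
#' junction), skipping-enriched events one (the skipping junction).
#' All-masked groups are emitted as NA rows, not dropped.
#'
#' @param panel a `ReferencePanel`.
#' @param screen a `screen_result` from [screen_events()].
#' @param event_ids events to export.
#' @param dir optional output directory (one pair of TSVs per event).
#' @param config a [screen_config()] (expressing thresholds for the bars).
#' @return named list per event: list(violin = data.table, bars =
#'   data.table).
#' @export
export_visual_data <- function(panel, screen, event_ids, dir = NULL,
                               config = screen_config()) {
  unknown <- setdiff(event_ids, panel$events$event_id)
  if (length(unknown)) {
    stop("unknown event id(s): ", paste(unknown, collapse = ", "),
         "; valid keys are panel event ids")
  }
  out <- list()
  for (eid in event_ids) {
    rec <- screen$records[event_id == eid]
    violin <- data.table(sample_id = colnames(screen$psi_masked),
                         group_id = panel$groups$group_id,
                         role = panel$groups$role,
                         psi = screen$psi_masked[eid, ])
    iso <- rec$enriched_isoform
    ev <- panel$events[event_id == eid]
    jks <- if (identical(iso, "inclusion")) ev$inclusion_junctions[[1]]
           else if (identical(iso, "skipping")) ev$skipping_junctions[[1]]
           else unlist(c(ev$inclusion_junctions, ev$skipping_junctions))
    bars <- data.table::rbindlist(lapply(unique(panel$groups$group_id), function(g) {
      cols <- sample_ids_of(panel, g)
      thr <- if (panel$groups[group_id == g, role][1] == "normal_reference")
        config$specificity_count_normal else config$specificity_count_tumor
      data.table(junction = jks, group_id = g,
                 fraction_expressing =
                   rowMeans(panel$sjc[jks, cols, drop = FALSE] >= thr))
    }))
    out[[eid]] <- list(violin = violin, bars = bars)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      safe <- gsub("[^A-Za-z0-9._-]", "_", eid)
      data.table::fwrite(violin, file.path(dir, paste0(safe, ".psi.tsv")), sep = "\t")
      data.table::fwrite(bars, file.path(dir, paste0(safe, ".sj.tsv")), sep = "\t")
    }
  }
  out
}

#' Write junction peptides as FASTA
#'
#' Headers are structured `event_id|isoform|flags` so downstream tools can
#' recover provenance.
#'
#' @param peptides data.table from [translate_event_peptides()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
peptides_to_fasta <- function(peptides, path) {
  x <- Biostrings::AAStringSet(peptides$sequence)
  names(x) <- sprintf("%s|%s|%s", peptides$event_id, peptides$isoform,
                      ifelse(nchar(peptides$flags) == 0, "-", peptides$flags))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
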