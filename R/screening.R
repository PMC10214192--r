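#' Screening configuration
#'
#' Collects every tunable threshold of the in-silico screens. The defaults
#' are the published ones: two-sided t test p < 0.01 with |dPSI| > 0.05 for
#' the tumor-association screen; degree-of-association threshold 8 (of an
#' 11-tissue normal panel); read-count thresholds 5 (tumor) / 2 (normal)
#' with one-sided Fisher p < 1e-6 and degree 8 for the tumor-specificity
#' screen; one-sided t p < 0.01 for the CPM screen; at least 3 non-missing
#' tumor PSI values per tested event.
#'
#' @param psi_p_threshold two-sided t test p threshold for the PSI screen.
#' @param delta_psi_threshold minimum |dPSI| (strict greater-than).
#' @param equal_variance pooled-variance t instead of Welch.
#' @param association_degree_min degree of tumor association required.
#' @param cpm_p_threshold one-sided t p threshold for the CPM screen.
#' @param specificity_count_tumor read count at-or-above which a tumor
#'   sample counts as expressing a junction.
#' @param specificity_count_normal same for normal tissue samples.
#' @param specificity_p_threshold one-sided Fisher exact p threshold.
#' @param specificity_degree_min number of significant normal tissues
#'   required for a junction to be tumor-specific.
#' @param min_tumor_nonmissing minimum non-missing tumor PSI values.
#' @param fc_denominator_floor floor for the normal-proportion denominator
#'   of the fold-change (flagged when applied).
#' @param recurrence_groups tumor_reference group ids for the recurrence
#'   screen (NULL = all groups with that role).
#' @return a list of class `ScreenConfig`.
#' @export
screen_config <- function(psi_p_threshold = 0.01,
                          delta_psi_threshold = 0.05,
                          equal_variance = FALSE,
                          association_degree_min = 8,
                          cpm_p_threshold = 0.01,
                          specificity_count_tumor = 5,
                          specificity_count_normal = 2,
                          specificity_p_threshold = 1e-6,
                          specificity_degree_min = 8,
                          min_tumor_nonmissing = 3,
                          fc_denominator_floor = 0.01,
                          recurrence_groups = NULL) {
  cfg <- list(psi_p_threshold = psi_p_threshold,
              delta_psi_threshold = delta_psi_threshold,
              equal_variance = isTRUE(equal_variance),
              association_degree_min = association_degree_min,
              cpm_p_threshold = cpm_p_threshold,
              specificity_count_tumor = specificity_count_tumor,
              specificity_count_normal = specificity_count_normal,
              specificity_p_threshold = specificity_p_threshold,
              specificity_degree_min = specificity_degree_min,
              min_tumor_nonmissing = min_tumor_nonmissing,
              fc_denominator_floor = fc_denominator_floor,
              recurrence_groups = recurrence_groups)
  stopifnot(all(vapply(cfg[c("psi_p_threshold", "delta_psi_threshold",
                             "cpm_p_threshold", "specificity_p_threshold",
                             "fc_denominator_floor")], function(x)
    is.numeric(x) && x > 0, TRUE)))
  class(cfg) <- "ScreenConfig"
  cfg
}

# Per-normal-group p-value and dPSI matrices for one query group.
association_matrices <- function(psi, panel, query_group, config,
                                 normal_groups) {
  qs <- row_group_stats(psi, sample_ids_of(panel, query_group))
  p <- d <- matrix(NA_real_, nrow(psi), length(normal_groups),
                   dimnames = list(rownames(psi), normal_groups))
  for (g in normal_groups) {
    ns <- row_group_stats(psi, sample_ids_of(panel, g))
    p[, g] <- t_test_summary(qs$mean, qs$var, qs$n, ns$mean, ns$var, ns$n,
                             equal_variance = config$equal_variance)
    d[, g] <- qs$mean - ns$mean
  }
  list(p = p, delta = d, query_n = qs$n, query_mean = qs$mean)
}

#' PSI-based tumor-association screen
#'
#' For every event, compares tumor PSI against each normal tissue type with
#' a two-sided two-sample t test (Welch by default). A comparison is
#' significant iff p < `psi_p_threshold` and |dPSI| > `delta_psi_threshold`.
#' The degree of tumor association is the number of normal tissue types
#' with a significant comparison in the consistent direction; any
#' significant comparison in the opposite direction disqualifies the event.
#' An event is tumor-associated iff it is testable (at least
#' `min_tumor_nonmissing` non-missing tumor values), its significant
#' comparisons share one direction, and the degree reaches
#' `association_degree_min`. Untestable comparisons (e.g. a fully masked
#' normal tissue) count as non-significant, never as disqualifying.
#'
#' @param panel a `ReferencePanel` containing the tumor group.
#' @param tumor_group group id of the tumor cohort.
#' @param config a [screen_config()].
#' @param psi optional masked PSI matrix (defaults to
#'   [mask_low_coverage()] on the panel).
#' @return list with `records` (one row per event: per-group significance
#'   summarized as degree/direction), `p` and `delta` (event x normal-group
#'   matrices).
#' @export
tumor_association_screen <- function(panel, tumor_group, config = screen_config(),
                                     psi = NULL) {
  if (is.null(psi)) psi <- mask_low_coverage(panel)
  normals <- groups_of_role(panel, "normal_reference")
  if (!length(normals)) stop("panel has no normal_reference groups")
  am <- association_matrices(psi, panel, tumor_group, config, normals)
  sig <- !is.na(am$p) & am$p < config$psi_p_threshold &
         abs(am$delta) > config$delta_psi_threshold
  n_up <- rowSums(sig & am$delta > 0)
  n_down <- rowSums(sig & am$delta < 0)
  tested <- am$query_n >= config$min_tumor_nonmissing
  direction <- ifelse(n_up > 0 & n_down > 0, "mixed",
               ifelse(n_up > 0, "higher",
               ifelse(n_down > 0, "lower", "none")))
  degree <- pmax(n_up, n_down)
  records <- data.table(
    event_id = rownames(psi),
    tested = tested,
    n_sig_higher = n_up,
    n_sig_lower = n_down,
    degree_of_association = as.integer(degree),
    direction = direction,
    tumor_associated = tested & direction %in% c("higher", "lower") &
      degree >= config$association_degree_min,
    tumor_mean_psi = am$query_mean
  )
  list(records = records, p = am$p, delta = am$delta)
}

#' Tumor-enriched isoform and its fold-change
#'
#' For tumor-associated events, the tumor-enriched isoform is the isoform
#' more abundant in tumor than in the normal panel: inclusion when the
#' consistent significant direction is "higher", skipping when "lower".
#' Its proportion is the mean PSI (inclusion) or 1 - mean PSI (skipping);
#' the fold-change is the tumor proportion over the average of the
#' normal-tissue group mean proportions, each tissue type weighted equally
#' regardless of sample count. A denominator below
#' `fc_denominator_floor` is floored and flagged.
#'
#' @param assoc result of [tumor_association_screen()].
#' @param panel a `ReferencePanel`.
#' @param tumor_group tumor group id.
#' @param config a [screen_config()].
#' @param psi masked PSI matrix (same one used for the screen).
#' @return `assoc$records` with columns enriched_isoform, fc, fc_floored
#'   added (NA for non-associated events).
#' @export
determine_enriched_isoform_and_fc <- function(assoc, panel, tumor_group,
                                              config = screen_config(),
                                              psi = NULL) {
  if (is.null(psi)) psi <- mask_low_coverage(panel)
  rec <- assoc$records
  normals <- colnames(assoc$p)
  gmeans <- vapply(normals, function(g) {
    rowMeans(psi[, sample_ids_of(panel, g), drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(psi)))
  gmeans <- matrix(gmeans, nrow = nrow(psi),
                   dimnames = list(rownames(psi), normals))
  gmeans[is.nan(gmeans)] <- NA_real_
  iso <- ifelse(rec$direction == "higher", "inclusion",
         ifelse(rec$direction == "lower", "skipping", NA_character_))
  iso[!rec$tumor_associated] <- NA_character_
  tumor_prop <- ifelse(iso == "inclusion", rec$tumor_mean_psi,
                       1 - rec$tumor_mean_psi)
  norm_prop <- ifelse(rep(iso, ncol(gmeans)) == "inclusion", gmeans, 1 - gmeans)
  dim(norm_prop) <- dim(gmeans)
  denom <- rowMeans(norm_prop, na.rm = TRUE)
  denom[is.nan(denom)] <- NA_real_
  floored <- !is.na(denom) & denom < config$fc_denominator_floor
  denom2 <- pmax(denom, config$fc_denominator_floor)
  rec[, enriched_isoform := iso]
  rec[, fc := ifelse(is.na(iso), NA_real_, tumor_prop / denom2)]
  rec[, fc_floored := ifelse(is.na(iso), NA, floored)]
  rec
}

# Junction keys of an event's tumor-enriched isoform.
enriched_junctions <- function(events, records) {
  idx <- match(records$event_id, events$event_id)
  mapply(function(i, iso) {
    if (is.na(iso)) character(0)
    else if (iso == "inclusion") events$inclusion_junctions[[i]]
    else events$skipping_junctions[[i]]
  }, idx, records$enriched_isoform, SIMPLIFY = FALSE)
}

#' Secondary tumor-association screen on junction CPM
#'
#' Junction counts are normalized to counts per million
#' (`count * 1e6 / total_mapped_reads`). For each junction, a one-sided t
#' test (tumor CPM greater) against each normal tissue type is called
#' significant at `cpm_p_threshold`; the junction's CPM degree of
#' association is the number of significant tissues and the junction passes
#' iff that degree reaches `association_degree_min`. An event passes iff
#' all junctions of its tumor-enriched isoform pass.
#'
#' @param panel a `ReferencePanel`.
#' @param tumor_group tumor group id.
#' @param records screen records with `enriched_isoform` (from
#'   [determine_enriched_isoform_and_fc()]).
#' @param config a [screen_config()].
#' @return list with `junctions` (per-junction degree and pass flag) and
#'   `records` (input with cpm_pass column added).
#' @export
sj_cpm_screen <- function(panel, tumor_group, records, config = screen_config()) {
  totals <- panel$groups$total_mapped_reads
  if (anyNA(totals)) {
    stop("missing total_mapped_reads for sample(s): ",
         paste(panel$groups$sample_id[is.na(totals)], collapse = ", "))
  }
  cpm <- sweep(panel$sjc, 2, 1e6 / totals, `*`)
  normals <- groups_of_role(panel, "normal_reference")
  ts <- row_group_stats(cpm, sample_ids_of(panel, tumor_group))
  nsig <- rep(0L, nrow(cpm))
  for (g in normals) {
    ns <- row_group_stats(cpm, sample_ids_of(panel, g))
    p <- t_test_summary(ts$mean, ts$var, ts$n, ns$mean, ns$var, ns$n,
                        equal_variance = config$equal_variance,
                        alternative = "greater")
    nsig <- nsig + as.integer(!is.na(p) & p < config$cpm_p_threshold)
  }
  jt <- data.table(junction = rownames(cpm), cpm_degree = nsig,
                   cpm_junction_pass = nsig >= config$association_degree_min)
  ej <- enriched_junctions(panel$events, records)
  pass <- vapply(ej, function(ks) {
    if (!length(ks)) return(NA)
    all(jt$cpm_junction_pass[match(ks, jt$junction)])
  }, NA)
  records[, cpm_pass := pass]
  list(junctions = jt, records = records)
}

#' Junction presence/absence tumor-specificity screen
#'
#' For each junction and sample group, the fraction of samples expressing
#' the junction at or above the role-specific read-count threshold is
#' computed; a one-sided Fisher exact test then asks whether the junction
#' is expressed in a significantly higher percentage of tumor samples than
#' of samples of each normal tissue type. A junction is tumor-specific iff
#' the number of normal tissues with p < `specificity_p_threshold` reaches
#' `specificity_degree_min`; a tumor-associated event is tumor-specific iff
#' every junction of its tumor-enriched isoform is tumor-specific.
#'
#' @param panel a `ReferencePanel`.
#' @param tumor_group tumor group id.
#' @param records screen records with tumor_associated and
#'   enriched_isoform columns.
#' @param config a [screen_config()].
#' @return list with `junctions` (long table: junction x normal group with
#'   expressing fractions and p), `junction_calls` (per-junction specific
#'   flag and degree) and `records` (with tumor_specific column added).
#' @export
tumor_specificity_screen <- function(panel, tumor_group, records,
                                     config = screen_config()) {
  normals <- groups_of_role(panel, "normal_reference")
  tcols <- sample_ids_of(panel, tumor_group)
  texp <- rowSums(panel$sjc[, tcols, drop = FALSE] >= config$specificity_count_tumor)
  nt <- length(tcols)
  long <- vector("list", length(normals))
  nsig <- rep(0L, nrow(panel$sjc))
  for (i in seq_along(normals)) {
    ncols <- sample_ids_of(panel, normals[i])
    nexp <- rowSums(panel$sjc[, ncols, drop = FALSE] >= config$specificity_count_normal)
    p <- fisher_onesided(texp, nt, nexp, length(ncols))
    nsig <- nsig + as.integer(!is.na(p) & p < config$specificity_p_threshold)
    long[[i]] <- data.table(junction = rownames(panel$sjc),
                            group_id = normals[i],
                            tumor_pct = texp / nt,
                            normal_pct = nexp / length(ncols),
                            p = p)
  }
  long <- data.table::rbindlist(long)
  calls <- data.table(junction = rownames(panel$sjc),
                      specificity_degree = nsig,
                      specific = nsig >= config$specificity_degree_min)
  ej <- enriched_junctions(panel$events, records)
  all_spec <- vapply(ej, function(ks) {
    if (!length(ks)) return(NA)
    all(calls$specific[match(ks, calls$junction)])
  }, NA)
  records[, tumor_specific := tumor_associated & !is.na(all_spec) & all_spec]
  list(junctions = long, junction_calls = calls, records = records)
}

#' Tumor-recurrence screen
#'
#' Asks whether an event's tumor association replicates in independent
#' cohorts of a similar tumor type (panel groups with role
#' `tumor_reference`). The rule used here — the event must be
#' tumor-associated against the same normal panel, at the same thresholds
#' and in the same direction, in every configured reference cohort — is a
#' documented stand-in; the original procedure is not public.
#'
#' @param panel a `ReferencePanel`.
#' @param records screen records for the query cohort (with direction).
#' @param config a [screen_config()]; `recurrence_groups` selects cohorts
#'   (default: all tumor_reference groups).
#' @param psi masked PSI matrix.
#' @return `records` with a logical `recurrent` column (NA when no
#'   reference cohorts are configured).
#' @export
tumor_recurrence_screen <- function(panel, records, config = screen_config(),
                                    psi = NULL) {
  if (is.null(psi)) psi <- mask_low_coverage(panel)
  cohorts <- config$recurrence_groups
  if (is.null(cohorts)) cohorts <- groups_of_role(panel, "tumor_reference")
  if (!length(cohorts)) {
    warning("no tumor_reference cohorts configured; recurrence screen skipped")
    records[, recurrent := NA]
    return(records)
  }
  agree <- matrix(FALSE, nrow(records), length(cohorts))
  for (i in seq_along(cohorts)) {
    res <- tumor_association_screen(panel, cohorts[i], config, psi = psi)
    agree[, i] <- res$records$tumor_associated &
      res$records$direction == records$direction
  }
  records[, recurrent := records$tumor_associated & rowSums(agree) == length(cohorts)]
  records
}

#' Run all in-silico screens
#'
#' Orchestrates masking, the PSI tumor-association screen, enriched-isoform
#' and fold-change computation, the CPM secondary screen, the
#' tumor-specificity screen, and (when reference cohorts exist) the
#' tumor-recurrence screen. Also emits an informational BH-adjusted minimum
#' p per event; no multiple-testing correction enters any call.
#'
#' @param panel a `ReferencePanel`.
#' @param tumor_group tumor group id (role `tumor_query`).
#' @param config a [screen_config()].
#' @return list of class `screen_result`: records (full per-event table),
#'   junction tables, masked PSI, and the per-group p / dPSI matrices.
#' @export
screen_events <- function(panel, tumor_group, config = screen_config()) {
  psi <- mask_low_coverage(panel)
  assoc <- tumor_association_screen(panel, tumor_group, config, psi = psi)
  rec <- determine_enriched_isoform_and_fc(assoc, panel, tumor_group, config,
                                           psi = psi)
  spec <- tumor_specificity_screen(panel, tumor_group, rec, config)
  cpmr <- sj_cpm_screen(panel, tumor_group, spec$records, config)
  rec <- cpmr$records
  if (length(groups_of_role(panel, "tumor_reference")) ||
      length(config$recurrence_groups)) {
    rec <- tumor_recurrence_screen(panel, rec, config, psi = psi)
  } else {
    rec[, recurrent := NA]
  }
  minp <- suppressWarnings(matrixStats::rowMins(assoc$p, na.rm = TRUE))
  minp[!is.finite(minp)] <- NA_real_
  rec[, min_p_bh := stats::p.adjust(minp, method = "BH")]
  structure(list(records = rec,
                 junction_specificity = spec$junctions,
                 junction_calls = spec$junction_calls,
                 junction_cpm = cpmr$junctions,
                 psi_masked = psi, p = assoc$p, delta = assoc$delta,
                 config = unclass(config)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  r <- x$records
  cat("screen_result: ", nrow(r), " events; ",
      sum(r$tested), " tested; ",
      sum(r$tumor_associated), " tumor-associated; ",
      sum(r$tumor_specific), " tumor-specific; ",
      sum(r$cpm_pass %in% TRUE), " CPM-pass\n", sep = "")
  invisible(x)
}
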