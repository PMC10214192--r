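test_that("closed-form t statistics match stats::t.test on fixed vectors", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(8 + i %% 5, mean = 0.3, sd = 0.2)
    y <- rnorm(6 + i %% 7, mean = 0.25, sd = 0.1)
    p_welch <- t_test_summary(mean(x), var(x), length(x),
                              mean(y), var(y), length(y))
    expect_equal(p_welch, t.test(x, y)$p.value, tolerance = 1e-10)
    p_pool <- t_test_summary(mean(x), var(x), length(x),
                             mean(y), var(y), length(y), equal_variance = TRUE)
    expect_equal(p_pool, t.test(x, y, var.equal = TRUE)$p.value,
                 tolerance = 1e-10)
    p_gt <- t_test_summary(mean(x), var(x), length(x),
                           mean(y), var(y), length(y),
                           alternative = "greater")
    expect_equal(p_gt, t.test(x, y, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})

test_that("degenerate t inputs follow the documented limit behaviour", {
  # both groups constant: p = 1 when equal, 0 when different
  expect_equal(t_test_summary(0.5, 0, 5, 0.5, 0, 5), 1)
  expect_equal(t_test_summary(0.6, 0, 5, 0.5, 0, 5), 0)
  expect_equal(t_test_summary(0.4, 0, 5, 0.5, 0, 5,
                              alternative = "greater"), 1)
  # under-sized groups are untestable
  expect_true(is.na(t_test_summary(0.5, NA, 1, 0.5, 0.01, 5)))
})

test_that("welch test is calibrated under a simulated null", {
  set.seed(2024)
  n_rep <- 10000
  x <- matrix(rnorm(n_rep * 23), n_rep)
  y <- matrix(rnorm(n_rep * 20), n_rep)
  p <- t_test_summary(rowMeans(x), matrixStats::rowVars(x), 23,
                      rowMeans(y), matrixStats::rowVars(y), 20)
  rate <- mean(p < 0.01)
  ci <- 0.01 + c(-1, 1) * qnorm(0.995) * sqrt(0.01 * 0.99 / n_rep)
  expect_gt(rate, ci[1])
  expect_lt(rate, ci[2])
})

test_that("one-sided Fisher p agrees with fisher.test and the brute-force oracle", {
  cases <- list(c(10, 10, 0, 50), c(5, 10, 3, 20), c(0, 10, 0, 50),
                c(7, 12, 7, 12), c(1, 3, 2, 4))
  for (cc in cases) {
    p <- fisher_onesided(cc[1], cc[2], cc[3], cc[4])
    tab <- matrix(c(cc[1], cc[2] - cc[1], cc[3], cc[4] - cc[3]), 2)
    expect_equal(p, fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-12)
    expect_equal(p, fisher_bruteforce(cc[1], cc[2], cc[3], cc[4]),
                 tolerance = 1e-12)
  }
  # all tumor expressing vs none of the normals: p = 1 / choose(60, 10)
  expect_equal(fisher_onesided(10, 10, 0, 50), 1 / choose(60, 10))
  # no expression anywhere: p = 1
  expect_equal(fisher_onesided(0, 10, 0, 50), 1)
})

test_that("tumor-association screen applies the direction-consistency rule", {
  cfg <- screen_config(association_degree_min = 8)
  # 9 groups higher + 2 untestable (all-masked) -> degree 9, associated
  set.seed(1)
  tumor <- plogis(qlogis(0.6) + rnorm(12, 0, 0.1))
  normals <- replicate(11, plogis(qlogis(0.2) + rnorm(10, 0, 0.1)),
                       simplify = FALSE)
  panel <- panel_from_psi(tumor, normals)
  # mask two normal groups by zeroing their counts
  for (g in c("normal10", "normal11")) {
    panel$sjc[, panel$groups[group_id == g, sample_id]] <- 0L
  }
  res <- tumor_association_screen(panel, "tumor", cfg)
  expect_equal(res$records$degree_of_association, 9L)
  expect_true(res$records$tumor_associated)
  expect_equal(res$records$direction, "higher")

  # one significant opposite-direction group disqualifies the event
  normals_mixed <- c(replicate(9, plogis(qlogis(0.2) + rnorm(10, 0, 0.1)),
                               simplify = FALSE),
                     list(plogis(qlogis(0.95) + rnorm(10, 0, 0.1))))
  panel2 <- panel_from_psi(tumor, normals_mixed)
  res2 <- tumor_association_screen(panel2, "tumor", cfg)
  expect_equal(res2$records$direction, "mixed")
  expect_false(res2$records$tumor_associated)

  # identical distributions: not significant
  set.seed(2)
  same <- replicate(11, rnorm(10, 0.5, 0.05), simplify = FALSE)
  panel3 <- panel_from_psi(rnorm(12, 0.5, 0.05), same)
  res3 <- tumor_association_screen(panel3, "tumor", cfg)
  expect_false(res3$records$tumor_associated)
  expect_equal(res3$records$degree_of_association, 0L)

  # fewer than min_tumor_nonmissing tumor values: untested
  panel4 <- panel_from_psi(tumor, normals)
  panel4$psi[1, panel4$groups[group_id == "tumor", sample_id][-(1:2)]] <- NA
  res4 <- tumor_association_screen(panel4, "tumor", cfg,
                                   psi = panel4$psi)
  expect_false(res4$records$tested)
  expect_false(res4$records$tumor_associated)
})

test_that("enriched isoform and fold-change follow the worked examples", {
  cfg <- screen_config(association_degree_min = 2,
                       delta_psi_threshold = 0.05)
  # tumor mean 0.8, normal group means 0.2 and 0.4 -> inclusion, FC 2.667
  panel <- panel_from_psi(rep(0.8, 6), list(rep(0.2, 6), rep(0.4, 6)))
  assoc <- tumor_association_screen(panel, "tumor", cfg)
  rec <- determine_enriched_isoform_and_fc(assoc, panel, "tumor", cfg)
  expect_equal(rec$enriched_isoform, "inclusion")
  expect_equal(rec$fc, 0.8 / 0.3, tolerance = 1e-12)
  expect_false(rec$fc_floored)
  # tumor 0.1 vs normals 0.9, 0.9 -> skipping, FC 0.9/0.1 = 9
  panel2 <- panel_from_psi(rep(0.1, 6), list(rep(0.9, 6), rep(0.9, 6)))
  assoc2 <- tumor_association_screen(panel2, "tumor", cfg)
  rec2 <- determine_enriched_isoform_and_fc(assoc2, panel2, "tumor", cfg)
  expect_equal(rec2$enriched_isoform, "skipping")
  expect_equal(rec2$fc, 9, tolerance = 1e-12)
  # all-zero normal proportions -> denominator floored at 0.01, flagged
  panel3 <- panel_from_psi(rep(0.5, 6), list(rep(0, 6), rep(0, 6)))
  assoc3 <- tumor_association_screen(panel3, "tumor", cfg)
  rec3 <- determine_enriched_isoform_and_fc(assoc3, panel3, "tumor", cfg)
  expect_equal(rec3$fc, 0.5 / 0.01, tolerance = 1e-12)
  expect_true(rec3$fc_floored)
})

test_that("CPM values and scale-invariance behave as documented", {
  sim <- small_panel()
  panel <- sim$panel
  # CPM arithmetic: count 50 at R = 25e6 -> 2.0
  expect_equal(50 * 1e6 / 25e6, 2)
  scr <- screen_events(panel, "tumor")
  rec1 <- scr$records
  # doubling every total halves CPM but leaves every t test (and so every
  # pass flag) unchanged
  panel2 <- panel
  panel2$groups <- data.table::copy(panel$groups)
  panel2$groups[, total_mapped_reads := total_mapped_reads * 2]
  scr2 <- screen_events(panel2, "tumor")
  expect_identical(scr2$records$cpm_pass, rec1$cpm_pass)
  # missing totals -> error naming the sample
  panel3 <- panel
  panel3$groups <- data.table::copy(panel$groups)
  panel3$groups[1, total_mapped_reads := NA]
  expect_error(sj_cpm_screen(panel3, "tumor", data.table::copy(rec1)),
               panel$groups$sample_id[1])
})

test_that("event-level specificity requires every enriched-isoform junction", {
  sim <- small_panel()
  panel <- sim$panel
  scr <- screen_events(panel, "tumor")
  truth <- sim$truth
  spec_ids <- truth[class == "specific", event_id]
  rec <- scr$records
  expect_true(all(rec[event_id %in% spec_ids, tumor_specific]))
  # knock one inclusion junction back into the normals: event loses its call
  ev <- panel$events[event_id == spec_ids[1]]
  j1 <- ev$inclusion_junctions[[1]][1]
  panel$sjc[j1, panel$groups[role == "normal_reference", sample_id]] <- 50L
  scr2 <- screen_events(panel, "tumor")
  expect_false(scr2$records[event_id == spec_ids[1], tumor_specific])
  jc <- scr2$junction_calls
  expect_false(jc[junction == j1, specific])
  expect_true(jc[junction == ev$inclusion_junctions[[1]][2], specific])
})

test_that("tumor-specific events are a subset of tumor-associated events", {
  sim <- small_panel()
  rec <- screen_events(sim$panel, "tumor")$records
  expect_true(all(rec[tumor_specific == TRUE, tumor_associated]))
})

test_that("recurrence screen follows the replication rule", {
  sim <- small_panel(n_tumor_reference_groups = 2L)
  scr <- screen_events(sim$panel, "tumor")
  rec <- scr$records
  truth <- sim$truth
  # planted events replicate in both auxiliary cohorts
  expect_true(all(rec[event_id %in% truth[class != "null", event_id], recurrent]))
  expect_false(any(rec[event_id %in% truth[class == "null", event_id],
                       recurrent] %in% TRUE))
  # one disagreeing cohort breaks recurrence
  panel2 <- sim$panel
  ref1 <- panel2$groups[group_id == "tumorref01", sample_id]
  eid <- truth[class == "specific", event_id][1]
  panel2$psi[eid, ref1] <- 0.02
  rec2 <- screen_events(panel2, "tumor")$records
  expect_false(rec2[event_id == eid, recurrent])
  # no auxiliary cohorts: NA flags with a warning
  sim0 <- small_panel()
  assoc <- tumor_association_screen(sim0$panel, "tumor")
  expect_warning(
    r0 <- tumor_recurrence_screen(sim0$panel, assoc$records),
    "skipped")
  expect_true(all(is.na(r0$recurrent)))
})

test_that("tightening thresholds never increases passing events", {
  sim <- small_panel()
  base <- screen_events(sim$panel, "tumor", screen_config())
  n_assoc <- sum(base$records$tumor_associated)
  n_spec <- sum(base$records$tumor_specific)
  tighter <- list(
    screen_config(psi_p_threshold = 0.001),
    screen_config(delta_psi_threshold = 0.2),
    screen_config(association_degree_min = 10),
    screen_config(specificity_p_threshold = 1e-9),
    screen_config(specificity_count_tumor = 20))
  for (cfg in tighter) {
    r <- screen_events(sim$panel, "tumor", cfg)$records
    expect_lte(sum(r$tumor_associated), n_assoc)
    expect_lte(sum(r$tumor_specific), n_spec)
  }
})
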