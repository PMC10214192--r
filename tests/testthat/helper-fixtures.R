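library(data.table)

# Toy genome is deterministic and cheap; build once per test run.
TOY <- generate_toy_genome()

# Small synthetic world used by several unit tests (the full-size defaults
# are exercised in test-acceptance.R).
# Group sizes stay at the default shape (the one-sided Fisher test cannot
# reach p < 1e-6 with much smaller groups); only the event count shrinks.
small_spec <- function(...) {
  synthetic_spec(n_events = 40L, n_planted_specific = 4L, seed = 11L, ...)
}

small_panel <- function(...) {
  spec <- small_spec(...)
  plant_tumor_events(generate_reference_panel(spec), spec)
}

# Build a ReferencePanel directly from explicit per-group PSI vectors for
# one event; junction counts are set high enough to escape masking.
panel_from_psi <- function(tumor_psi, normal_psi_list, sjc_tumor = NULL,
                           sjc_normals = NULL, depth = 50L) {
  ev <- splicescreen:::synthetic_event_table(1L, 30L)
  samples <- c(sprintf("T%02d", seq_along(tumor_psi)),
               unlist(lapply(seq_along(normal_psi_list), function(i)
                 sprintf("N%d_%02d", i, seq_along(normal_psi_list[[i]])))))
  groups <- data.table(
    sample_id = samples,
    group_id = c(rep("tumor", length(tumor_psi)),
                 unlist(lapply(seq_along(normal_psi_list), function(i)
                   rep(paste0("normal", i), length(normal_psi_list[[i]]))))),
    role = c(rep("tumor_query", length(tumor_psi)),
             rep("normal_reference", length(unlist(normal_psi_list)))),
    total_mapped_reads = 25e6)
  psi <- matrix(c(tumor_psi, unlist(normal_psi_list)), nrow = 1,
                dimnames = list(ev$event_id, samples))
  jk <- c(ev$inclusion_junctions[[1]], ev$skipping_junctions[[1]])
  sjc <- matrix(depth, length(jk), length(samples),
                dimnames = list(jk, samples))
  if (!is.null(sjc_tumor)) sjc[, seq_along(tumor_psi)] <- sjc_tumor
  if (!is.null(sjc_normals)) sjc[, -seq_along(tumor_psi)] <- sjc_normals
  storage.mode(sjc) <- "integer"
  build_reference_panel(ev, psi, sjc, groups)
}

# Independent brute-force one-sided Fisher oracle: explicit sum of
# hypergeometric terms via log-binomial coefficients.
fisher_bruteforce <- function(k_tumor, n_tumor, k_normal, n_normal) {
  N <- n_tumor + n_normal
  k <- k_tumor + k_normal
  j <- seq(k_tumor, min(n_tumor, k))
  sum(exp(lchoose(k, j) + lchoose(N - k, n_tumor - j) - lchoose(N, n_tumor)))
}

# Write an inline rMATS-style SE table and return its path.
write_se_fixture <- function(lines) {
  header <- paste("ID", "GeneID", "geneSymbol", "chr", "strand",
                  "exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
                  "downstreamES", "downstreamEE", "IJC_SAMPLE_1",
                  "SJC_SAMPLE_1", "IncFormLen", "SkipFormLen", "IncLevel1",
                  sep = "\t")
  path <- tempfile(fileext = ".txt")
  writeLines(c(header, lines), path)
  path
}

se_row <- function(id = 1, gene = "G1", sym = "Sym1", chr = "chr9", strand = "+",
                   es = 1200, ee = 1230, us = 1000, ue = 1100,
                   ds = 1400, de = 1500, ijc = "12,8", sjc = "4,20",
                   lvl = "NA,NA") {
  paste(id, gene, sym, chr, strand, es, ee, us, ue, ds, de, ijc, sjc,
        98, 49, lvl, sep = "\t")
}

# Panel over the toy genome's events with a planted inclusion signal in
# tumor, enabling end-to-end pipeline runs with real translation.
toy_panel <- function(n_tumor = 12L, n_per_group = 10L, n_groups = 11L,
                      seed = 5L) {
  set.seed(seed)
  ev <- TOY$events
  n_ev <- nrow(ev)
  groups <- c("tumor", sprintf("normal%02d", seq_len(n_groups)))
  samples <- unlist(lapply(groups, function(g)
    sprintf("%s_s%02d", g, seq_len(if (g == "tumor") n_tumor else n_per_group))))
  manifest <- data.table(
    sample_id = samples,
    group_id = sub("_s[0-9]+$", "", samples),
    role = ifelse(grepl("^tumor", samples), "tumor_query", "normal_reference"),
    total_mapped_reads = 25e6)
  is_tumor <- manifest$role == "tumor_query"
  psi <- matrix(NA_real_, n_ev, length(samples),
                dimnames = list(ev$event_id, samples))
  psi[, is_tumor] <- plogis(qlogis(0.6) + rnorm(n_ev * sum(is_tumor), 0, 0.3))
  psi[, !is_tumor] <- plogis(qlogis(0.05) + rnorm(n_ev * sum(!is_tumor), 0, 0.3))
  jk <- unique(unlist(c(ev$inclusion_junctions, ev$skipping_junctions)))
  sjc <- matrix(0L, length(jk), length(samples), dimnames = list(jk, samples))
  for (i in seq_len(n_ev)) {
    inc <- ev$inclusion_junctions[[i]]; skp <- ev$skipping_junctions[[i]]
    d <- 60L
    for (k in inc) sjc[k, ] <- as.integer(rbinom(length(samples), d, psi[i, ]))
    sjc[skp[1], ] <- as.integer(rbinom(length(samples), d, 1 - psi[i, ]))
    # junction-level tumor specificity: inclusion junctions absent in normals
    for (k in inc) sjc[k, !is_tumor] <- pmin(sjc[k, !is_tumor], 1L)
    for (k in inc) sjc[k, is_tumor] <- pmax(sjc[k, is_tumor], 5L)
  }
  build_reference_panel(ev, psi, sjc, manifest)
}
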