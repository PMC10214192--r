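test_that("rMATS SE reader parses rows, recomputes PSI, derives junctions", {
  path <- write_se_fixture(se_row(ijc = "12,8", sjc = "4,20", lvl = "NA,NA"))
  rd <- read_rmats_events(path, "SE", sample_ids = c("s1", "s2"))
  expect_equal(nrow(rd$events), 1L)
  # junction-count-normalized PSI: (12/2)/((12/2)+4) = 0.6; (8/2)/((8/2)+20)
  expect_equal(unname(rd$psi[1, ]), c((12/2)/((12/2)+4), (8/2)/((8/2)+20)))
  ev <- rd$events
  expect_equal(ev$inclusion_junctions[[1]],
               c("chr9:1101-1200:+", "chr9:1231-1400:+"))
  expect_equal(ev$skipping_junctions[[1]], "chr9:1101-1400:+")
  expect_equal(ev$alt_len, 30L)
  # stated inclusion levels are parsed, not recomputed
  path2 <- write_se_fixture(se_row(lvl = "0.5,0.25"))
  expect_equal(unname(read_rmats_events(path2, "SE")$psi[1, ]), c(0.5, 0.25))
})

test_that("rMATS reader handles malformed/degenerate input", {
  # missing column named in the error
  path <- tempfile()
  writeLines(c("GeneID\tchr\tstrand", "g\tchr1\t+"), path)
  expect_error(read_rmats_events(path, "SE"), "geneSymbol")
  # empty file with valid header -> empty event list
  empty <- write_se_fixture(character(0))
  rd <- read_rmats_events(empty, "SE")
  expect_equal(nrow(rd$events), 0L)
  # duplicate coordinate tuple: first kept, warning
  dup <- write_se_fixture(c(se_row(ijc = "10,10", sjc = "10,10"),
                            se_row(id = 2, ijc = "1,1", sjc = "1,1")))
  expect_warning(rd <- read_rmats_events(dup, "SE"), "duplicate")
  expect_equal(nrow(rd$events), 1L)
  expect_equal(unname(rd$sjc["chr9:1101-1400:+", ]), c(10L, 10L))
  # coordinate inconsistency (alt exon outside flanks) -> row rejected
  bad <- write_se_fixture(se_row(es = 900, ee = 950))
  expect_message(rd <- read_rmats_events(bad, "SE"), "rejected")
  expect_equal(nrow(rd$events), 0L)
})

test_that("rMATS A5SS and RI dialects derive the documented junctions", {
  header <- paste("ID", "GeneID", "geneSymbol", "chr", "strand",
                  "longExonStart_0base", "longExonEnd", "shortES", "shortEE",
                  "flankingES", "flankingEE", "IJC_SAMPLE_1", "SJC_SAMPLE_1",
                  "IncFormLen", "SkipFormLen", "IncLevel1", sep = "\t")
  path <- tempfile()
  writeLines(c(header, paste(1, "g", "s", "chr2", "+", 100, 220, 100, 200,
                             400, 500, "6", "2", 98, 49, "NA", sep = "\t")), path)
  rd <- read_rmats_events(path, "A5SS")
  ev <- rd$events
  expect_equal(ev$inclusion_junctions[[1]], "chr2:221-400:+")
  expect_equal(ev$skipping_junctions[[1]], "chr2:201-400:+")
  # single inclusion junction: PSI = 6/(6+2)
  expect_equal(unname(rd$psi[1, 1]), 0.75)

  header_ri <- sub("longExonStart_0base\tlongExonEnd\tshortES\tshortEE\tflankingES\tflankingEE",
                   "riExonStart_0base\triExonEnd\tupstreamES\tupstreamEE\tdownstreamES\tdownstreamEE",
                   header)
  path_ri <- tempfile()
  writeLines(c(header_ri, paste(1, "g", "s", "chr2", "-", 100, 500, 100, 200,
                                400, 500, "8", "2", 98, 49, "NA", sep = "\t")), path_ri)
  rd_ri <- read_rmats_events(path_ri, "RI")
  ev <- rd_ri$events
  expect_equal(ev$skipping_junctions[[1]], "chr2:201-400:-")
  expect_equal(ev$inclusion_junctions[[1]], c("chr2:201-201:-", "chr2:400-400:-"))
})

test_that("STAR junction reader maps fields and assembles matrices", {
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(c("chr1\t100\t200\t1\t1\t1\t57\t3\t40",
               "chr1\t300\t400\t2\t2\t1\t12\t0\t38"), f1)
  writeLines("chr1\t100\t200\t1\t1\t1\t9\t0\t40", f2)
  m <- read_star_junctions(c(a = f1, b = f2))
  expect_equal(m["chr1:100-200:+", ], c(a = 57L, b = 9L))
  expect_equal(m["chr1:300-400:-", ], c(a = 12L, b = 0L))
  # undefined strand: stored once under '.', with a warning
  f3 <- tempfile()
  writeLines("chr1\t500\t600\t0\t0\t0\t4\t0\t20", f3)
  expect_warning(m3 <- read_star_junctions(c(c = f3)), "undefined strand")
  expect_equal(rownames(m3), "chr1:500-600:.")
  # non-integer count -> format error with line number
  f4 <- tempfile()
  writeLines(c("chr1\t100\t200\t1\t1\t1\t57\t3\t40",
               "chr1\t300\t400\t1\t1\t1\txx\t0\t38"), f4)
  expect_error(read_star_junctions(f4), "line 2")
})

test_that("reference panel construction validates the manifest", {
  sim <- small_panel()
  panel <- sim$panel
  ev <- panel$events
  # round-trip identity: query by key returns the input vectors
  eid <- ev$event_id[5]
  expect_equal(panel_events(panel, eid)$event_id, eid)
  expect_equal(panel_events(panel, ev$gene_id[5])$event_id, eid)
  expect_equal(panel_events(panel, ev$gene_symbol[5])$event_id, eid)
  expect_equal(panel_events(panel, sprintf("chr1:%d", ev$c2s[5]))$event_id, eid)
  # sample in manifest absent from inputs
  bad <- rbind(panel$groups, data.table(sample_id = "ghost", group_id = "g",
                                        role = "normal_reference",
                                        total_mapped_reads = 1e7))
  expect_error(build_reference_panel(ev, panel$psi, panel$sjc, bad), "ghost")
  # overlapping membership
  dup <- rbind(panel$groups, panel$groups[1])
  expect_error(build_reference_panel(ev, panel$psi, panel$sjc, dup),
               "overlapping")
  expect_error(build_reference_panel(ev, panel$psi, panel$sjc,
                                     panel$groups[0]), "empty")
})

test_that("panel persists and loads bit-exactly, deterministically", {
  sim <- small_panel()
  d1 <- tempfile(); save_panel(sim$panel, d1)
  p2 <- load_panel(d1)
  expect_identical(p2$psi, sim$panel$psi)
  expect_identical(p2$sjc, sim$panel$sjc)
  expect_equal(as.data.frame(p2$groups), as.data.frame(sim$panel$groups))
  expect_equal(p2$events$inclusion_junctions, sim$panel$events$inclusion_junctions)
  # same seed -> byte-identical on-disk panel
  sim2 <- small_panel()
  d2 <- tempfile(); save_panel(sim2$panel, d2)
  for (f in c("events.tsv", "psi.tsv", "sjc.tsv", "panel.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("low-coverage masking follows the strict group-mean rule", {
  # one event, tumor group of 2 samples with junction sums 9 and 10:
  # depth per junction chosen so inc1+inc2+skip sums to the target
  panel <- panel_from_psi(c(0.5, 0.5), list(c(0.5, 0.5)), depth = 50L)
  jk <- rownames(panel$sjc)
  panel$sjc[, 1] <- c(3L, 3L, 3L)   # sum 9
  panel$sjc[, 2] <- c(4L, 3L, 3L)   # sum 10
  panel$sjc[, 3:4] <- 4L            # normal group sums 12, not masked
  psi <- mask_low_coverage(panel, 10)
  expect_true(all(is.na(psi[1, 1:2])))   # mean 9.5 < 10 masks the group
  expect_false(anyNA(psi[1, 3:4]))
  # sums 10 and 10 -> mean 10: strict "<" leaves them unmasked
  panel$sjc[, 1] <- c(4L, 3L, 3L)
  expect_false(anyNA(mask_low_coverage(panel, 10)[1, 1:2]))
  # all-zero counts -> missing
  panel$sjc[] <- 0L
  expect_true(all(is.na(mask_low_coverage(panel, 10))))
})

test_that("masking is idempotent and monotone in the threshold", {
  sim <- small_panel()
  panel <- sim$panel
  m10 <- mask_low_coverage(panel, 10)
  # idempotence: re-masking the panel changes nothing (counts unchanged)
  expect_identical(mask_low_coverage(panel, 10), m10)
  # monotone: raising the threshold never unmasks
  for (thr in c(20, 60, 150)) {
    m <- mask_low_coverage(panel, thr)
    expect_true(all(is.na(m[is.na(m10)])))
  }
  # per-sample granularity masks at least as much per masked cell rule
  ms <- mask_low_coverage(panel, 150, granularity = "sample")
  expect_true(is.matrix(ms))
})

test_that("PSI recomputed from written counts matches stated levels within 0.01", {
  sim <- small_panel()
  path <- tempfile()
  tumor_ids <- sim$panel$groups[group_id == "tumor", sample_id]
  write_rmats_table(sim$panel, tumor_ids, path)
  tab <- data.table::fread(path)
  I <- do.call(rbind, lapply(strsplit(tab$IJC_SAMPLE_1, ","), as.numeric))
  S <- do.call(rbind, lapply(strsplit(tab$SJC_SAMPLE_1, ","), as.numeric))
  L <- do.call(rbind, lapply(strsplit(tab$IncLevel1, ","), as.numeric))
  expect_lt(max(abs((I / 2) / (I / 2 + S) - L), na.rm = TRUE), 0.01)
})
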