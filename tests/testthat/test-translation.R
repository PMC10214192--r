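toy_translate <- function(sym, iso, models = TOY$models,
                          genome = TOY$genome) {
  ev <- as.list(TOY$events[gene_symbol == sym][1, ])
  an <- splicescreen:::isoform_frame_anchor(ev, iso)
  fr <- splicescreen:::resolve_frame_at(an$chrom, an$pos, an$strand, models)
  translate_junction_peptide(ev, iso, fr, genome)
}

test_that("reading-frame resolution returns the annotated phase", {
  # PH0: upstream exon of 36 nt ends on a complete codon
  ev <- as.list(TOY$events[TOY$events$gene_symbol == "PH0"][1, ])
  fr <- resolve_reading_frame(ev$inclusion_junctions[[1]][1], TOY$models)
  expect_equal(fr$phase, 0L)
  # PH1 (37 nt): one base into a codon; PH2 (38 nt): two
  ev1 <- as.list(TOY$events[TOY$events$gene_symbol == "PH1"][1, ])
  expect_equal(resolve_reading_frame(ev1$inclusion_junctions[[1]][1],
                                     TOY$models)$phase, 1L)
  ev2 <- as.list(TOY$events[TOY$events$gene_symbol == "PH2"][1, ])
  expect_equal(resolve_reading_frame(ev2$inclusion_junctions[[1]][1],
                                     TOY$models)$phase, 2L)
  # non-coding gene: no frame
  evnc <- as.list(TOY$events[TOY$events$gene_symbol == "NC"][1, ])
  expect_null(resolve_reading_frame(evnc$inclusion_junctions[[1]][1],
                                    TOY$models))
})

test_that("frame ties break deterministically (longest CDS, then id)", {
  tx <- TOY$models$transcripts$tPH0
  short <- tx
  short$transcript_id <- "aaa_short"
  short$cds <- tx$cds[1:2, , drop = FALSE]
  short$cds_len <- sum(short$cds[, 2] - short$cds[, 1] + 1L)
  twin <- tx; twin$transcript_id <- "aaa_twin"   # same CDS length, earlier id
  models2 <- structure(list(transcripts = c(
    TOY$models$transcripts, list(aaa_short = short, aaa_twin = twin))),
    class = "gene_models")
  ev <- as.list(TOY$events[TOY$events$gene_symbol == "PH0"][1, ])
  fr <- resolve_reading_frame(ev$inclusion_junctions[[1]][1], models2)
  expect_equal(fr$transcript_id, "aaa_twin")
})

test_that("every toy junction peptide equals the naive-oracle answer key", {
  for (i in seq_len(nrow(TOY$expected))) {
    exp_row <- TOY$expected[i]
    pep <- toy_translate(exp_row$gene_symbol, exp_row$isoform)
    expect_false(is_dropped(pep), info = exp_row$gene_symbol)
    expect_identical(pep$sequence, exp_row$sequence,
                     info = paste(exp_row$gene_symbol, exp_row$isoform))
    expect_equal(pep$junction_position, exp_row$junction_position)
    expect_identical(paste(pep$flags, collapse = ";"), exp_row$flags)
    expect_lte(nchar(pep$sequence), 21L)
    expect_false(grepl("\\*", pep$sequence))
  }
})

test_that("frames read back from the GTF give identical peptides", {
  dir <- tempfile()
  paths <- write_toy_genome(TOY, dir)
  models_gtf <- read_gene_models(paths$gtf)
  genome_fa <- Biostrings::readDNAStringSet(paths$genome)
  names(genome_fa) <- sub(" .*", "", names(genome_fa))
  for (sym in c("PH1", "MINUS", "RI", "STOP")) {
    for (iso in c("inclusion", "skipping")) {
      a <- toy_translate(sym, iso)
      b <- toy_translate(sym, iso, models = models_gtf, genome = genome_fa)
      expect_identical(b$sequence, a$sequence, info = sym)
    }
  }
})

test_that("minus-strand gene mirrors its forward twin's peptides", {
  for (iso in c("inclusion", "skipping")) {
    expect_identical(toy_translate("MINUS", iso)$sequence,
                     toy_translate("MICRO", iso)$sequence)
  }
})

test_that("a 12-nt microexon contributes exactly 4 residues", {
  pep <- toy_translate("MICRO", "inclusion")
  skip <- toy_translate("MICRO", "skipping")
  jp <- pep$junction_position
  # residues after the junction up to where the skipping peptide resumes
  micro_res <- substr(pep$sequence, jp + 1, jp + 4)
  expect_equal(nchar(micro_res), 4L)
  # removing the 4 microexon residues reproduces the skipping continuation
  expect_identical(substr(pep$sequence, jp + 5, jp + 8),
                   substr(skip$sequence, jp + 1, jp + 4))
})

test_that("ambiguous bases truncate the window with a flag", {
  genome2 <- TOY$genome
  ev <- as.list(TOY$events[TOY$events$gene_symbol == "PH0"][1, ])
  seq <- genome2[["chrPH0"]]
  # drop an N a few bases into the alternative exon
  mut <- Biostrings::replaceLetterAt(seq, ev$c2s + 6L, "N")
  genome2[["chrPH0"]] <- mut
  an <- splicescreen:::isoform_frame_anchor(ev, "inclusion")
  fr <- splicescreen:::resolve_frame_at(an$chrom, an$pos, an$strand, TOY$models)
  pep <- translate_junction_peptide(ev, "inclusion", fr, genome2)
  expect_true("ambiguous" %in% pep$flags)
  expect_lt(nchar(pep$sequence), 20L)
  expect_gte(nchar(pep$sequence), pep$junction_position)
})

test_that("isoform peptide comparison keeps only distinct sequences", {
  a <- list(sequence = "AAAAKLMNPQ"); b <- list(sequence = "AAAAKLM")
  expect_true(diff_isoform_peptides(a, b)$keep)
  expect_false(diff_isoform_peptides(a, list(sequence = "AAAAKLMNPQ"))$keep)
  res <- diff_isoform_peptides(a, NULL)
  expect_true(res$keep)
  expect_equal(res$flag, "no-normal-peptide")
  expect_false(diff_isoform_peptides(NULL, b)$keep)
})

test_that("translate_event_peptides filters and tallies drop reasons", {
  ev <- TOY$events
  records <- data.table(event_id = ev$event_id,
                        enriched_isoform = "inclusion")
  out <- translate_event_peptides(ev, records, TOY$genome, TOY$models)
  # non-coding gene dropped with a reason; all others translate
  expect_true(ev[gene_symbol == "NC", event_id] %in% out$dropped$event_id)
  expect_equal(nrow(out$peptides) + nrow(out$dropped), nrow(ev))
  expect_true(all(out$peptides$junction_position >= 1))
  # every kept sequence is in the answer key
  key <- TOY$expected[isoform == "inclusion"]
  expect_identical(out$peptides$sequence,
                   key$sequence[match(out$peptides$event_id, key$event_id)])
})

test_that("microexon classification applies the 30-nt inclusive cutoff", {
  ev <- data.table(event_type = c("SE", "SE", "SE", "RI"),
                   alt_len = c(30L, 31L, 12L, NA))
  cls <- classify_microexon(ev, c("inclusion", "inclusion", "inclusion", NA))
  expect_equal(cls, c("inclusion_microexon", "none", "inclusion_microexon",
                      "none"))
  expect_equal(classify_microexon(ev, c(NA, NA, "skipping", NA)),
               c("microexon_unassigned", "none", "skipping_microexon", "none"))
})
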