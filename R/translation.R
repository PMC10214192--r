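#' Read gene models from a GTF file
#'
#' Imports a GTF (via rtracklayer) and assembles per-transcript gene models:
#' ordered exon intervals, CDS intervals, and the protein id linking a
#' coding transcript to its annotated protein product. Only the features
#' needed for reading-frame resolution are kept.
#'
#' @param gtf_path path to a GTF with exon and CDS features; CDS rows may
#'   carry a `protein_id` attribute.
#' @return object of class `gene_models`: list of transcripts, each with
#'   transcript_id, gene_id, chrom, strand, exons and cds (2-column
#'   matrices, genomic order), protein_id and cds_len.
#' @export
read_gene_models <- function(gtf_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  df <- as.data.table(as.data.frame(gr))
  df <- df[type %in% c("exon", "CDS")]
  txs <- split(df, df$transcript_id)
  models <- lapply(txs, function(t) {
    ex <- t[type == "exon"][order(start)]
    cd <- t[type == "CDS"][order(start)]
    pid <- if ("protein_id" %in% names(t)) {
      p <- unique(stats::na.omit(t$protein_id)); if (length(p)) p[1] else NA_character_
    } else NA_character_
    list(transcript_id = t$transcript_id[1],
         gene_id = if ("gene_id" %in% names(t)) t$gene_id[1] else NA_character_,
         chrom = as.character(t$seqnames[1]),
         strand = as.character(t$strand[1]),
         exons = cbind(start = ex$start, end = ex$end),
         cds = cbind(start = cd$start, end = cd$end),
         protein_id = pid,
         cds_len = if (nrow(cd)) sum(cd$end - cd$start + 1L) else 0L)
  })
  names(models) <- vapply(models, `[[`, "", "transcript_id")
  structure(list(transcripts = models), class = "gene_models")
}

utils::globalVariables(c("type", "start", "transcript_id"))

# Coding position (1-based within the CDS, transcript orientation) of a
# genomic base, for one transcript. NA if outside the CDS.
cds_position <- function(tx, pos) {
  cds <- tx$cds
  if (!nrow(cds)) return(NA_integer_)
  ord <- if (tx$strand == "+") order(cds[, 1]) else order(-cds[, 1])
  cds <- cds[ord, , drop = FALSE]
  acc <- 0L
  for (i in seq_len(nrow(cds))) {
    s <- cds[i, 1]; e <- cds[i, 2]
    if (pos >= s && pos <= e) {
      off <- if (tx$strand == "+") pos - s + 1L else e - pos + 1L
      return(acc + off)
    }
    acc <- acc + (e - s + 1L)
  }
  NA_integer_
}

#' Resolve the reading frame at a splice junction
#'
#' Identifies a coding transcript whose CDS contains the exonic base
#' immediately upstream (in transcript orientation) of the junction, and
#' returns the phase of translation at the junction: the number of
#' nucleotides by which the upstream exon overhangs its last complete
#' codon (0, 1 or 2). Ties between qualifying transcripts are broken
#' deterministically: longest CDS, then lexicographic transcript id.
#'
#' @param junction a junction key from [sj_key()], or a list with chrom,
#'   start, end, strand.
#' @param models a `gene_models` object.
#' @return a `FrameAssignment` list (transcript_id, protein_id, phase,
#'   cds_pos of the upstream flank base, the containing CDS interval), or
#'   NULL when no annotated frame covers the upstream flank.
#' @export
resolve_reading_frame <- function(junction, models) {
  if (is.character(junction)) junction <- as.list(sj_parse(junction)[1])
  pos <- if (junction$strand == "+") junction$start - 1L else junction$end + 1L
  resolve_frame_at(junction$chrom, pos, junction$strand, models)
}

resolve_frame_at <- function(chrom, pos, strand, models) {
  cand <- Filter(function(tx) {
    tx$chrom == chrom && tx$strand == strand && nrow(tx$cds) > 0 &&
      any(tx$cds[, 1] <= pos & tx$cds[, 2] >= pos)
  }, models$transcripts)
  if (!length(cand)) return(NULL)
  lens <- vapply(cand, `[[`, 0L, "cds_len")
  ids <- vapply(cand, `[[`, "", "transcript_id")
  tx <- cand[[order(-lens, ids)[1]]]
  p <- cds_position(tx, pos)
  ci <- tx$cds[tx$cds[, 1] <= pos & tx$cds[, 2] >= pos, , drop = FALSE][1, ]
  list(transcript_id = tx$transcript_id, protein_id = tx$protein_id,
       phase = as.integer(p %% 3L), cds_pos = p,
       cds_interval = ci, strand = strand, chrom = chrom)
}

# Genomic intervals (transcript order) of the exonic path of one isoform.
event_isoform_segments <- function(ev, isoform) {
  c1 <- c(ev$c1s, ev$c1e); c2 <- c(ev$c2s, ev$c2e); c3 <- c(ev$c3s, ev$c3e)
  segs <- switch(ev$event_type,
    SE = if (isoform == "inclusion") list(c1, c2, c3) else list(c1, c3),
    A5SS = ,
    A3SS = {
      # short exon (c2) shares a boundary with the long exon; the flank is
      # whichever outer exon does not contain it
      long_is_c1 <- c2[1] >= c1[1] && c2[2] <= c1[2]
      lng <- if (long_is_c1) c1 else c3
      fla <- if (long_is_c1) c3 else c1
      if (isoform == "inclusion") list(lng, fla) else list(c2, fla)
    },
    RI = if (isoform == "inclusion") list(c(c1[1], c3[2])) else list(c1, c3))
  segs <- segs[order(vapply(segs, `[`, 0L, 1))]
  if (ev$strand == "-") segs <- rev(segs)
  segs
}

# The junction (or exon-intron boundary, for retained introns) at which the
# isoform's peptide is centered, as (flank_pos, chrom, strand): flank_pos is
# the last exonic base upstream of the junction in transcript orientation.
isoform_frame_anchor <- function(ev, isoform) {
  plus <- ev$strand == "+"
  pos <- switch(ev$event_type,
    SE = if (plus) ev$c1e else ev$c3s,
    A5SS = ,
    A3SS = {
      long_is_c1 <- ev$c2s >= ev$c1s && ev$c2e <= ev$c1e
      lng <- if (long_is_c1) c(ev$c1s, ev$c1e) else c(ev$c3s, ev$c3e)
      sht <- c(ev$c2s, ev$c2e)
      use <- if (isoform == "inclusion") lng else sht
      # flank side: if the flank exon is genomic-right, junction leaves the
      # right end of the used exon (upstream on +); mirrored otherwise
      flank_right <- if (long_is_c1) TRUE else FALSE
      if (flank_right) { if (plus) use[2] else { if (long_is_c1) ev$c3s else ev$c1s } }
      else { if (plus) { if (long_is_c1) ev$c3e else ev$c1e } else use[1] }
    },
    RI = if (plus) ev$c1e else ev$c3s)
  list(chrom = ev$chrom, pos = as.integer(pos), strand = ev$strand)
}

seg_sequence <- function(genome, chrom, s, e, strand) {
  x <- Biostrings::subseq(genome[[chrom]], s, e)
  if (strand == "-") x <- Biostrings::reverseComplement(x)
  as.character(x)
}

#' Translate the junction-spanning peptide of an event isoform
#'
#' Builds the nucleotide window around the isoform's splice junction —
#' up to `flank_codons` complete codons of upstream exonic sequence plus
#' the split codon dictated by the reading-frame phase, then up to
#' `flank_codons` codons downstream following the isoform's splice path
#' (for skipped-exon inclusion the downstream sequence starts in the
#' alternative exon and crosses into the downstream constitutive exon when
#' the alternative exon is shorter than the window, as with microexons; for
#' retained introns the peptide reads through the exon-intron boundary) —
#' and translates it on the coding strand with the standard nuclear codon
#' table. Translation stops at the first stop codon (flag `stop_codon`);
#' short flanks shrink the window (flag `exon_boundary`); ambiguous bases
#' truncate the window at the first N (flag `ambiguous`). Frameshifts
#' downstream of a non-multiple-of-3 skipped exon are tolerated within the
#' window: translation proceeds in the upstream frame.
#'
#' @param ev one event row (list or single-row data.frame) from the
#'   canonical event table.
#' @param isoform "inclusion" or "skipping".
#' @param frame a `FrameAssignment` from [resolve_reading_frame()] /
#'   [resolve_frame_at()] for this isoform's junction.
#' @param genome a `DNAStringSet` (or path to a FASTA, read on the fly).
#' @param flank_codons codons per side (default 10, for 21-aa peptides).
#' @return a `JunctionPeptide` list (event_id, isoform, sequence,
#'   junction_position, flags, transcript/protein mapping, residue
#'   interval), or a `dropped_peptide` marker carrying the drop reason when
#'   no junction-spanning peptide exists (test with [is_dropped()]).
#' @export
translate_junction_peptide <- function(ev, isoform, frame, genome,
                                       flank_codons = 10L) {
  if (is.data.frame(ev)) ev <- as.list(ev[1, ])
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  drop <- function(reason) structure(list(reason = reason), class = "dropped_peptide")
  if (is.null(frame)) return(drop("no annotated frame"))
  segs <- event_isoform_segments(ev, isoform)
  anchor <- isoform_frame_anchor(ev, isoform)
  plus <- ev$strand == "+"

  # upstream segment: the path exon containing the anchor, clipped to the
  # CDS interval of the frame's transcript (drops any 5' UTR part)
  up_i <- which(vapply(segs, function(s) anchor$pos >= s[1] && anchor$pos <= s[2],
                       TRUE))[1]
  if (is.na(up_i)) return(drop("anchor outside isoform path"))
  up <- segs[[up_i]]
  ci <- frame$cds_interval
  if (plus) {
    u_s <- max(up[1], ci["start"]); u_e <- anchor$pos
  } else {
    u_s <- anchor$pos; u_e <- min(up[2], ci["end"])
  }
  if (u_s > u_e) return(drop("no coding sequence upstream of junction"))
  up_seq <- seg_sequence(genome, ev$chrom, u_s, u_e, ev$strand)
  phase <- frame$phase
  avail <- nchar(up_seq)
  if (avail < phase + 3L) return(drop("upstream flank shorter than one codon"))
  k_up <- min(flank_codons, (avail - phase) %/% 3L)
  up_take <- phase + 3L * k_up
  flags <- character(0)
  if (k_up < flank_codons) flags <- c(flags, "exon_boundary")
  nt_up <- substr(up_seq, avail - up_take + 1L, avail)

  # downstream: the remaining path segments in transcript order
  need <- (3L - phase) %% 3L + 3L * flank_codons
  down_segs <- segs[-seq_len(up_i)]
  if (!plus) {
    # transcript-downstream of the anchor within the same genomic segment
    # (retained introns): handled by splitting the merged segment
    if (up_i <= length(segs) && anchor$pos > segs[[up_i]][1] &&
        ev$event_type == "RI" && isoform == "inclusion") {
      down_segs <- c(list(c(segs[[up_i]][1], anchor$pos - 1L)), down_segs)
    }
  } else if (ev$event_type == "RI" && isoform == "inclusion" &&
             anchor$pos < segs[[up_i]][2]) {
    down_segs <- c(list(c(anchor$pos + 1L, segs[[up_i]][2])), down_segs)
  }
  nt_down <- ""
  for (s in down_segs) {
    if (nchar(nt_down) >= need) break
    nt_down <- paste0(nt_down, seg_sequence(genome, ev$chrom, s[1], s[2], ev$strand))
  }
  if (nchar(nt_down) < need) flags <- c(flags, "exon_boundary")
  nt_down <- substr(nt_down, 1L, min(need, nchar(nt_down)))

  nt <- paste0(nt_up, nt_down)
  amb <- regexpr("[^ACGTacgt]", nt)
  if (amb > 0) {
    flags <- c(flags, "ambiguous")
    nt <- substr(nt, 1L, amb - 1L)
  }
  nt <- substr(nt, 1L, (nchar(nt) %/% 3L) * 3L)
  if (nchar(nt) < 3L) return(drop("window too short"))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) {
    flags <- c(flags, "stop_codon")
    aa <- substr(aa, 1L, stop_at - 1L)
  }
  junction_position <- if (phase > 0) k_up + 1L else k_up
  if (junction_position < 1L) return(drop("no upstream residue"))
  if (nchar(aa) < junction_position ||
      (phase == 0L && nchar(aa) == junction_position)) {
    return(drop("stop before junction"))
  }
  flags <- unique(flags)
  res_start <- if (!is.na(frame$cds_pos)) (frame$cds_pos - up_take) %/% 3L + 1L
               else NA_integer_
  list(event_id = ev$event_id, isoform = isoform, sequence = aa,
       junction_position = junction_position, flags = flags,
       transcript_id = frame$transcript_id, protein_id = frame$protein_id,
       residue_start = res_start,
       residue_end = if (!is.na(res_start)) res_start + nchar(aa) - 1L else NA_integer_)
}

#' Compare tumor- and normal-enriched isoform peptides
#'
#' The peptide of the tumor-enriched isoform is only a credible target if
#' it differs from the peptide of the normal-enriched isoform; identical
#' sequences are dropped. An untranslatable normal-enriched peptide keeps
#' the tumor peptide, flagged.
#'
#' @param tumor_pep,normal_pep `JunctionPeptide` lists (or a dropped
#'   marker / NULL when untranslatable).
#' @return list(keep = logical, reason/flag).
#' @export
diff_isoform_peptides <- function(tumor_pep, normal_pep) {
  if (is.null(tumor_pep) || is_dropped(tumor_pep)) {
    return(list(keep = FALSE, reason = "no tumor peptide"))
  }
  if (is.null(normal_pep) || is_dropped(normal_pep)) {
    return(list(keep = TRUE, flag = "no-normal-peptide"))
  }
  if (identical(tumor_pep$sequence, normal_pep$sequence)) {
    list(keep = FALSE, reason = "identical to normal-enriched peptide")
  } else list(keep = TRUE, flag = NA_character_)
}

#' Translate peptides for a set of screened events
#'
#' For each tumor-associated event, translates the junction peptide of the
#' tumor-enriched isoform and of the opposite (normal-enriched) isoform,
#' applies the distinct-peptide filter, and tallies drop reasons.
#'
#' @param events canonical event table.
#' @param records screen records with enriched_isoform (only rows with a
#'   non-NA isoform are translated).
#' @param genome `DNAStringSet` or FASTA path.
#' @param models `gene_models`.
#' @param flank_codons window half-size in codons.
#' @return list with `peptides` (data.table of kept tumor-isoform peptides)
#'   and `dropped` (data.table event_id, reason).
#' @export
translate_event_peptides <- function(events, records, genome, models,
                                     flank_codons = 10L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  events <- as.data.table(events)
  records <- as.data.table(records)
  todo <- records[!is.na(enriched_isoform)]
  peps <- list(); dropped <- list()
  for (i in seq_len(nrow(todo))) {
    eid <- todo$event_id[i]
    ev <- as.list(events[event_id == eid][1, ])
    iso <- todo$enriched_isoform[i]
    other <- if (iso == "inclusion") "skipping" else "inclusion"
    fr_t <- with(isoform_frame_anchor(ev, iso),
                 resolve_frame_at(chrom, pos, strand, models))
    pep_t <- translate_junction_peptide(ev, iso, fr_t, genome, flank_codons)
    if (is_dropped(pep_t)) {
      dropped[[length(dropped) + 1L]] <-
        data.table(event_id = eid, reason = pep_t$reason)
      next
    }
    fr_n <- with(isoform_frame_anchor(ev, other),
                 resolve_frame_at(chrom, pos, strand, models))
    pep_n <- translate_junction_peptide(ev, other, fr_n, genome, flank_codons)
    cmp <- diff_isoform_peptides(pep_t, pep_n)
    if (!cmp$keep) {
      dropped[[length(dropped) + 1L]] <- data.table(event_id = eid, reason = cmp$reason)
      next
    }
    flags <- pep_t$flags
    if (!is.null(cmp$flag) && !is.na(cmp$flag)) flags <- c(flags, cmp$flag)
    peps[[length(peps) + 1L]] <- data.table(
      event_id = eid, isoform = iso, sequence = pep_t$sequence,
      junction_position = pep_t$junction_position,
      flags = paste(flags, collapse = ";"),
      transcript_id = pep_t$transcript_id, protein_id = pep_t$protein_id,
      residue_start = pep_t$residue_start, residue_end = pep_t$residue_end)
  }
  list(peptides = if (length(peps)) data.table::rbindlist(peps) else
         data.table(event_id = character(), isoform = character(),
                    sequence = character(), junction_position = integer(),
                    flags = character(), transcript_id = character(),
                    protein_id = character(), residue_start = integer(),
                    residue_end = integer()),
       dropped = if (length(dropped)) data.table::rbindlist(dropped) else
         data.table(event_id = character(), reason = character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Test whether a translation result is a dropped-peptide marker
#' @param x result of [translate_junction_peptide()].
#' @return logical scalar.
#' @export
is_dropped <- function(x) inherits(x, "dropped_peptide")

#' Classify microexon events
#'
#' A microexon is an alternative exon of at most 30 nucleotides. For
#' skipped-exon events the classification is paired with the enriched
#' isoform; other event types are "none".
#'
#' @param events canonical event table.
#' @param enriched_isoform optional per-event isoform ("inclusion" /
#'   "skipping" / NA) aligned with `events` rows.
#' @param max_nt microexon length cutoff (default 30, inclusive).
#' @return character vector: "inclusion_microexon", "skipping_microexon",
#'   "microexon_unassigned" or "none".
#' @export
classify_microexon <- function(events, enriched_isoform = NULL, max_nt = 30L) {
  is_micro <- events$event_type == "SE" & !is.na(events$alt_len) &
    events$alt_len <= max_nt
  if (is.null(enriched_isoform)) enriched_isoform <- rep(NA_character_, nrow(events))
  ifelse(!is_micro, "none",
  ifelse(is.na(enriched_isoform), "microexon_unassigned",
         paste0(enriched_isoform, "_microexon")))
}

#' Microexon enrichment tally
#'
#' Tallies, among tumor-associated and tumor-specific skipped-exon events
#' split by enriched isoform (inclusion vs skipping), how many involve a
#' microexon, with the percentage per bin.
#'
#' @param events canonical event table.
#' @param records screen records with tumor_associated, tumor_specific and
#'   enriched_isoform columns.
#' @param max_nt microexon cutoff in nucleotides.
#' @return data.table with bin, n_events, n_microexon, pct_microexon.
#' @export
microexon_tally <- function(events, records, max_nt = 30L) {
  idx <- match(records$event_id, events$event_id)
  micro <- events$event_type[idx] == "SE" & !is.na(events$alt_len[idx]) &
    events$alt_len[idx] <= max_nt
  se <- events$event_type[idx] == "SE"
  bins <- list(
    specific_inclusion = records$tumor_specific %in% TRUE &
      records$enriched_isoform %in% "inclusion",
    associated_inclusion = records$tumor_associated %in% TRUE &
      records$enriched_isoform %in% "inclusion",
    specific_skipping = records$tumor_specific %in% TRUE &
      records$enriched_isoform %in% "skipping",
    associated_skipping = records$tumor_associated %in% TRUE &
      records$enriched_isoform %in% "skipping")
  data.table::rbindlist(lapply(names(bins), function(b) {
    sel <- bins[[b]] & se
    data.table(bin = b, n_events = sum(sel), n_microexon = sum(micro & sel),
               pct_microexon = 100 * sum(micro & sel) / max(1L, sum(sel)))
  }))
}
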