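#' Specification of a synthetic splicing panel
#'
#' Describes the stated world the generator emulates: a multi-tissue
#' normal reference panel plus a tumor cohort with planted
#' tumor-associated and tumor-specific skipped-exon events. Defaults match
#' the shape of the published screen: 11 normal tissue types, a 23-sample
#' tumor cohort, degree thresholds of 8, and a planted effect of
#' dPSI = 0.3. PSI noise lives on the logit scale (respecting `[0,1]`);
#' junction depth is negative binomial and inclusion/skipping counts are
#' binomial splits of depth at the sample's PSI, so the ratio (PSI) and
#' count (SJC) representations of each event carry the same signal.
#'
#' @param n_normal_groups number of normal tissue types.
#' @param samples_per_group samples per normal tissue type.
#' @param n_tumor_samples tumor cohort size.
#' @param n_events total skipped-exon events.
#' @param n_planted_associated planted tumor-associated (but not
#'   junction-specific) events.
#' @param n_planted_specific planted tumor-specific events (junctions
#'   absent from normal tissues).
#' @param n_tumor_reference_groups auxiliary tumor cohorts for the
#'   recurrence screen.
#' @param delta_psi_effect planted PSI shift in tumor.
#' @param psi_noise_sd per-sample noise SD on the logit-PSI scale.
#' @param nb_mean,nb_size junction depth negative binomial parameters.
#' @param total_reads_range range of per-sample total mapped reads.
#' @param seed RNG seed; same seed, same outputs.
#' @return list of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_normal_groups = 11L, samples_per_group = 20L,
                           n_tumor_samples = 23L, n_events = 500L,
                           n_planted_associated = 0L, n_planted_specific = 20L,
                           n_tumor_reference_groups = 0L,
                           delta_psi_effect = 0.3, psi_noise_sd = 0.4,
                           nb_mean = 100, nb_size = 10,
                           total_reads_range = c(2e7, 6e7), seed = 7L) {
  spec <- as.list(environment())
  if (spec$n_planted_associated + spec$n_planted_specific > spec$n_events) {
    stop("planted events exceed n_events")
  }
  stopifnot(spec$n_normal_groups >= 1, spec$samples_per_group >= 2,
            spec$n_tumor_samples >= 2, spec$delta_psi_effect > 0,
            spec$psi_noise_sd > 0, spec$nb_mean > 0, spec$nb_size > 0,
            all(spec$total_reads_range > 0))
  class(spec) <- "SyntheticSpec"
  spec
}

synthetic_event_table <- function(n_events, alt_lens) {
  base <- 10000L * seq_len(n_events)
  ev <- data.table(
    event_type = "SE",
    gene_id = sprintf("GENE%04d", seq_len(n_events)),
    gene_symbol = sprintf("Sym%04d", seq_len(n_events)),
    chrom = "chr1", strand = "+",
    c1s = base + 1L, c1e = base + 100L,
    c2s = base + 201L, c2e = base + 200L + alt_lens,
    c3s = base + 401L, c3e = base + 500L,
    alt_len = alt_lens)
  ev[, inclusion_junctions := Map(function(c1e, c2s, c2e, c3s) c(
        sj_key("chr1", c1e + 1L, c2s - 1L, "+"),
        sj_key("chr1", c2e + 1L, c3s - 1L, "+")),
      c1e, c2s, c2e, c3s)]
  ev[, skipping_junctions := Map(function(c1e, c3s)
        sj_key("chr1", c1e + 1L, c3s - 1L, "+"), c1e, c3s)]
  ev[, event_id := sprintf("SE:chr1:+:%d-%d:%d-%d:%d-%d",
                           c1s, c1e, c2s, c2e, c3s, c3e)]
  data.table::setcolorder(ev, "event_id")
  ev
}

# One group's PSI and junction counts for given per-event target PSI.
simulate_group <- function(psi_target, n_samples, spec, clamp_normal_absent = NULL) {
  n_ev <- length(psi_target)
  noise <- matrix(rnorm(n_ev * n_samples, 0, spec$psi_noise_sd), n_ev)
  psi <- plogis(qlogis(pmin(pmax(psi_target, 1e-4), 1 - 1e-4)) + noise)
  depth <- matrix(rnbinom(n_ev * n_samples, mu = spec$nb_mean,
                          size = spec$nb_size) + 1L, n_ev)
  inc1 <- matrix(rbinom(n_ev * n_samples, depth, psi), n_ev)
  inc2 <- matrix(rbinom(n_ev * n_samples, depth, psi), n_ev)
  skp <- matrix(rbinom(n_ev * n_samples, depth, 1 - psi), n_ev)
  if (!is.null(clamp_normal_absent)) {
    # construction guarantee: specific events are below the normal-tissue
    # expressing threshold (count < 2) in every normal sample
    inc1[clamp_normal_absent, ] <- pmin(inc1[clamp_normal_absent, ], 1L)
    inc2[clamp_normal_absent, ] <- pmin(inc2[clamp_normal_absent, ], 1L)
  }
  list(psi = psi, inc1 = inc1, inc2 = inc2, skp = skp)
}

assemble_counts <- function(events, sims, sample_ids) {
  jk <- cbind(vapply(events$inclusion_junctions, `[`, "", 1),
              vapply(events$inclusion_junctions, `[`, "", 2),
              vapply(events$skipping_junctions, `[`, "", 1))
  inc1 <- do.call(cbind, lapply(sims, `[[`, "inc1"))
  inc2 <- do.call(cbind, lapply(sims, `[[`, "inc2"))
  skp <- do.call(cbind, lapply(sims, `[[`, "skp"))
  sjc <- rbind(inc1, inc2, skp)
  rownames(sjc) <- c(jk[, 1], jk[, 2], jk[, 3])
  colnames(sjc) <- sample_ids
  storage.mode(sjc) <- "integer"
  sjc
}

#' Generate a synthetic normal-tissue reference panel
#'
#' Null events share their PSI distribution across all normal tissue types
#' (logit-normal noise around a per-event baseline); planted tumor-specific
#' events have near-zero inclusion in every normal tissue with inclusion
#' junction counts clamped below the normal expressing threshold. The
#' planted signal itself only appears when the tumor cohort is added with
#' [plant_tumor_events()].
#'
#' @param spec a [synthetic_spec()].
#' @return list: `panel` (`ReferencePanel` of the normal groups), `truth`
#'   (event class and baseline PSI per event).
#' @export
generate_reference_panel <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  n <- spec$n_events
  cls <- rep("null", n)
  if (spec$n_planted_specific > 0) cls[seq_len(spec$n_planted_specific)] <- "specific"
  if (spec$n_planted_associated > 0) {
    cls[spec$n_planted_specific + seq_len(spec$n_planted_associated)] <- "associated"
  }
  psi0 <- runif(n, 0.1, 0.9)
  psi0[cls == "associated"] <- runif(sum(cls == "associated"), 0.15, 0.55)
  psi0[cls == "specific"] <- 0.02
  alt_lens <- sample(9:99, n, replace = TRUE)
  events <- synthetic_event_table(n, alt_lens)

  groups <- sprintf("normal%02d", seq_len(spec$n_normal_groups))
  sims <- list(); ids <- character(0); manifest <- list()
  for (g in groups) {
    sims[[g]] <- simulate_group(psi0, spec$samples_per_group, spec,
                                clamp_normal_absent = which(cls == "specific"))
    sid <- sprintf("%s_s%02d", g, seq_len(spec$samples_per_group))
    ids <- c(ids, sid)
    manifest[[g]] <- data.table(sample_id = sid, group_id = g,
                                role = "normal_reference",
                                total_mapped_reads = round(runif(
                                  spec$samples_per_group,
                                  spec$total_reads_range[1],
                                  spec$total_reads_range[2])))
  }
  psi <- do.call(cbind, lapply(sims, `[[`, "psi"))
  dimnames(psi) <- list(events$event_id, ids)
  sjc <- assemble_counts(events, sims, ids)
  panel <- build_reference_panel(events, psi, sjc,
                                 data.table::rbindlist(manifest))
  truth <- data.table(event_id = events$event_id, class = cls, psi0 = psi0,
                      delta = ifelse(cls == "null", 0, spec$delta_psi_effect))
  stopifnot(all(panel$sjc[unlist(lapply(which(cls == "specific"), function(i)
    events$inclusion_junctions[[i]])), ] < 2))
  list(panel = panel, truth = truth)
}

#' Add a tumor cohort (and optional auxiliary cohorts) with planted events
#'
#' Tumor PSI for planted events is the baseline shifted by
#' `delta_psi_effect` (clipped to `[0,1]`; baselines are drawn so clipping
#' never collapses the effect below 0.05 — asserted, not tuned). Planted
#' tumor-specific events additionally have inclusion junction counts
#' forced to at least 5 in at least 80% of tumor samples. When
#' `n_tumor_reference_groups > 0`, auxiliary cohorts with the same planted
#' signal are appended with role `tumor_reference` for the recurrence
#' screen.
#'
#' @param sim result of [generate_reference_panel()].
#' @param spec the same [synthetic_spec()].
#' @param tumor_group group id of the query cohort.
#' @return list: `panel` (extended `ReferencePanel`), `truth`.
#' @export
plant_tumor_events <- function(sim, spec, tumor_group = "tumor") {
  set.seed(spec$seed + 1L)
  panel <- sim$panel; truth <- sim$truth
  planted <- truth$class != "null"
  psi_t <- ifelse(planted, pmin(truth$psi0 + spec$delta_psi_effect, 1), truth$psi0)
  if (any(planted & (psi_t - truth$psi0) < 0.05)) {
    stop("clipping collapsed a planted effect below 0.05; re-draw baselines")
  }
  cohorts <- c(setNames(list(c("tumor_query", spec$n_tumor_samples)), tumor_group))
  if (spec$n_tumor_reference_groups > 0) {
    for (i in seq_len(spec$n_tumor_reference_groups)) {
      cohorts[[sprintf("tumorref%02d", i)]] <- c("tumor_reference",
                                                 spec$n_tumor_samples)
    }
  }
  events <- panel$events
  psi <- panel$psi; sjc <- panel$sjc; manifest <- panel$groups
  for (g in names(cohorts)) {
    ns <- as.integer(cohorts[[g]][2])
    s <- simulate_group(psi_t, ns, spec)
    if (any(truth$class == "specific")) {
      keep_hi <- seq_len(ceiling(0.8 * ns))
      idx <- which(truth$class == "specific")
      s$inc1[idx, keep_hi] <- pmax(s$inc1[idx, keep_hi], 5L)
      s$inc2[idx, keep_hi] <- pmax(s$inc2[idx, keep_hi], 5L)
    }
    sid <- sprintf("%s_s%02d", g, seq_len(ns))
    psi2 <- s$psi; dimnames(psi2) <- list(events$event_id, sid)
    psi <- cbind(psi, psi2)
    sjc2 <- assemble_counts(events, list(s), sid)
    sjc <- cbind(sjc, sjc2[rownames(sjc), , drop = FALSE])
    manifest <- rbind(manifest, data.table(
      sample_id = sid, group_id = g, role = cohorts[[g]][1],
      total_mapped_reads = round(runif(ns, spec$total_reads_range[1],
                                       spec$total_reads_range[2]))))
  }
  list(panel = build_reference_panel(events, psi, sjc, manifest),
       truth = truth)
}

# ---- toy genome ------------------------------------------------------------

codon_of <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

cod <- function(aa) paste(codon_of[strsplit(aa, "")[[1]]], collapse = "")

toy_intron <- function(n = 60L) paste0("GT", strrep("CT", (n - 4L) / 2L), "AG")

# Naive translation oracle: standard-code codon table lookup over a spliced
# mRNA, independent of the genomic-window translation path.
naive_codon_table <- function() {
  b <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- as.vector(t(outer(b, b, paste0)))
  codons <- unlist(lapply(b, function(x) paste0(x, as.vector(t(outer(b, b, paste0))))))
  setNames(aas, codons)
}

naive_translate <- function(nt) {
  tab <- naive_codon_table()
  n <- nchar(nt) %/% 3L
  aa <- character(n)
  for (i in seq_len(n)) {
    a <- tab[[substr(nt, 3 * i - 2, 3 * i)]]
    if (a == "*") return(list(protein = paste(aa[seq_len(i - 1)], collapse = ""),
                              stopped = TRUE))
    aa[i] <- a
  }
  list(protein = paste(aa, collapse = ""), stopped = FALSE)
}

# Expected junction peptide of one isoform, from the full spliced mRNA.
naive_junction_peptide <- function(up_nt, down_nt, flank_codons = 10L) {
  tr <- naive_translate(paste0(up_nt, down_nt))
  prot <- tr$protein
  L_up <- nchar(up_nt)
  phase <- L_up %% 3L
  u_full <- (L_up - phase) %/% 3L
  k_up <- min(flank_codons, u_full)
  ws <- u_full - k_up + 1L
  jp <- if (phase > 0) k_up + 1L else k_up
  we_nominal <- (if (phase > 0) u_full + 1L else u_full) + flank_codons
  we <- min(we_nominal, nchar(prot))
  flags <- character(0)
  if (tr$stopped && nchar(prot) < we_nominal) flags <- c(flags, "stop_codon")
  list(sequence = substr(prot, ws, we), junction_position = jp, flags = flags)
}

#' Generate a deterministic toy genome with known junction peptides
#'
#' Builds a small genome (one chromosome per gene) whose genes exercise
#' the translation corner cases: codon-aligned and phase-1/2 junctions, a
#' 12-nt microexon, a frameshifting skip, a minus-strand mirror gene, a
#' retained intron with read-through translation, a premature stop, a
#' surface protein with an extracellular annotation, and a non-coding
#' gene. The expected peptide of every translatable isoform is computed by
#' an independent naive codon-table oracle over the spliced mRNA and
#' returned as an answer key.
#'
#' @param seed seed for the intergenic padding sequence.
#' @return list: `genome` (DNAStringSet), `models` (`gene_models`),
#'   `events` (canonical event table), `expected` (answer key:
#'   event_id, isoform, sequence, junction_position, flags),
#'   `extracellular` (annotation table), `gtf` (data.table of GTF fields).
#' @export
generate_toy_genome <- function(seed = 1L) {
  set.seed(seed)
  pad <- function(n = 100L) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                  collapse = "")
  genes <- list(
    PH0   = list(strand = "+", type = "SE",
                 pieces = c(cod("MAVLKTEDRISG"), toy_intron(), cod("NPQWY"),
                            toy_intron(), cod("FHCESTVKLMAR"))),
    PH1   = list(strand = "+", type = "SE",
                 pieces = c(paste0(cod("MAVLKTEDRISG"), "G"), toy_intron(),
                            paste0("CT", cod("NPQW")), toy_intron(),
                            cod("FHCESTVKLMAR"))),
    PH2   = list(strand = "+", type = "SE",
                 pieces = c(paste0(cod("MAVLKTEDRISG"), "GC"), toy_intron(),
                            paste0("T", cod("NPQW")), toy_intron(),
                            cod("FHCESTVKLMAR"))),
    MICRO = list(strand = "+", type = "SE",
                 pieces = c(cod("MKTLLEDVRSGQ"), toy_intron(), cod("WYHF"),
                            toy_intron(), cod("ESTVKLMARNPG"))),
    FS    = list(strand = "+", type = "SE",
                 pieces = c(cod("MAVLKTEDRISG"), toy_intron(),
                            paste0(cod("NPQW"), "G"), toy_intron(),
                            strrep("GCA", 14))),
    MINUS = list(strand = "-", type = "SE",
                 pieces = c(cod("MKTLLEDVRSGQ"), toy_intron(), cod("WYHF"),
                            toy_intron(), cod("ESTVKLMARNPG"))),
    RI    = list(strand = "+", type = "RI",
                 pieces = c(cod("MAVLKTEDRISG"), "GTAGCAGCTGCAGCTGCAGCAAAG",
                            cod("FHCESTVKLMAR"))),
    STOP  = list(strand = "+", type = "SE",
                 pieces = c(cod("MKTLLEDVRSGQ"), toy_intron(),
                            paste0(cod("NPQWY"), "TAA", cod("HH")),
                            toy_intron(), cod("ESTVKLMARNPG"))),
    SURF  = list(strand = "+", type = "SE",
                 pieces = c(cod("MSTEDLKVAGRQ"), toy_intron(), cod("NWCDY"),
                            toy_intron(), cod("FHKESTVALMPR"))),
    NC    = list(strand = "+", type = "SE", noncoding = TRUE,
                 pieces = c(cod("MAVLKTEDRISG"), toy_intron(), cod("NPQWY"),
                            toy_intron(), cod("FHCESTVKLMAR")))
  )

  chrom_seqs <- character(0)
  gtf <- list(); events <- list(); expected <- list(); models <- list()
  for (nm in names(genes)) {
    g <- genes[[nm]]
    chrom <- paste0("chr", nm)
    full <- paste(g$pieces, collapse = "")
    lens <- nchar(g$pieces)
    off_end <- cumsum(lens); off_start <- off_end - lens + 1L
    padL <- pad(); padR <- pad()
    if (g$strand == "+") {
      chrom_seqs[chrom] <- paste0(padL, full, padR)
      coords <- cbind(start = 100L + off_start, end = 100L + off_end)
    } else {
      chrom_seqs[chrom] <- paste0(padL, revcomp_chr(full), padR)
      coords <- cbind(start = 100L + nchar(full) - off_end + 1L,
                      end = 100L + nchar(full) - off_start + 1L)
    }
    exonic <- if (g$type == "RI") c(1L, 3L) else c(1L, 3L, 5L)
    ex <- coords[exonic, , drop = FALSE]
    coding <- !isTRUE(g$noncoding)
    tx_id <- paste0("t", nm); gene_id <- paste0("g", nm)
    prot_id <- if (coding) paste0("P_", nm) else NA_character_
    # annotated transcript = inclusion isoform for SE, spliced for RI
    ann_ex <- ex
    models[[tx_id]] <- list(
      transcript_id = tx_id, gene_id = gene_id, chrom = chrom,
      strand = g$strand,
      exons = ann_ex[order(ann_ex[, 1]), , drop = FALSE],
      cds = if (coding) ann_ex[order(ann_ex[, 1]), , drop = FALSE]
            else ann_ex[0, , drop = FALSE],
      protein_id = prot_id,
      cds_len = if (coding) sum(ann_ex[, 2] - ann_ex[, 1] + 1L) else 0L)
    cum <- c(0L, cumsum(lens[exonic])[-length(exonic)])
    frames <- (3L - (cum %% 3L)) %% 3L
    rows <- data.table(
      chrom = chrom, source = "toy",
      feature = c("exon", if (coding) "CDS")[c(rep(1, nrow(ann_ex)),
                                               if (coding) rep(2, nrow(ann_ex)))],
      start = c(ann_ex[, 1], if (coding) ann_ex[, 1]),
      end = c(ann_ex[, 2], if (coding) ann_ex[, 2]),
      score = ".", strand = g$strand,
      frame = c(rep(".", nrow(ann_ex)), if (coding) as.character(frames)),
      attrs = sprintf('gene_id "%s"; transcript_id "%s";%s', gene_id, tx_id,
                      if (coding) sprintf(' protein_id "%s";', prot_id) else ""))
    gtf[[nm]] <- rows

    # event table row (canonical genomic-order segments)
    if (g$type == "SE") {
      segs3 <- coords[exonic, , drop = FALSE]
      segs3 <- segs3[order(segs3[, 1]), , drop = FALSE]
      evr <- data.table(event_type = "SE", gene_id = gene_id, gene_symbol = nm,
                        chrom = chrom, strand = g$strand,
                        c1s = segs3[1, 1], c1e = segs3[1, 2],
                        c2s = segs3[2, 1], c2e = segs3[2, 2],
                        c3s = segs3[3, 1], c3e = segs3[3, 2],
                        alt_len = segs3[2, 2] - segs3[2, 1] + 1L)
      evr[, inclusion_junctions := list(list(c(
        sj_key(chrom, c1e + 1L, c2s - 1L, g$strand),
        sj_key(chrom, c2e + 1L, c3s - 1L, g$strand))))]
      evr[, skipping_junctions := list(list(
        sj_key(chrom, c1e + 1L, c3s - 1L, g$strand)))]
    } else { # RI
      segs3 <- coords[c(1L, 2L, 3L), , drop = FALSE]
      segs3 <- segs3[order(segs3[, 1]), , drop = FALSE]
      evr <- data.table(event_type = "RI", gene_id = gene_id, gene_symbol = nm,
                        chrom = chrom, strand = g$strand,
                        c1s = segs3[1, 1], c1e = segs3[1, 2],
                        c2s = segs3[2, 1], c2e = segs3[2, 2],
                        c3s = segs3[3, 1], c3e = segs3[3, 2],
                        alt_len = NA_integer_)
      evr[, inclusion_junctions := list(list(c(
        sj_key(chrom, c2s, c2s, g$strand),
        sj_key(chrom, c2e, c2e, g$strand))))]
      evr[, skipping_junctions := list(list(
        sj_key(chrom, c2s, c2e, g$strand)))]
    }
    evr[, event_id := sprintf("%s:%s:%s:%d-%d:%d-%d:%d-%d", event_type, chrom,
                              strand, c1s, c1e, c2s, c2e, c3s, c3e)]
    data.table::setcolorder(evr, "event_id")
    events[[nm]] <- evr

    if (coding) {
      e1 <- g$pieces[1]
      if (g$type == "SE") {
        alt <- g$pieces[3]; e3 <- g$pieces[5]
        for (iso in c("inclusion", "skipping")) {
          down <- if (iso == "inclusion") paste0(alt, e3) else e3
          np <- naive_junction_peptide(e1, down)
          expected[[paste(nm, iso)]] <- data.table(
            event_id = evr$event_id, gene_symbol = nm, isoform = iso,
            sequence = np$sequence, junction_position = np$junction_position,
            flags = paste(np$flags, collapse = ";"))
        }
      } else {
        intr <- g$pieces[2]; e2 <- g$pieces[3]
        for (iso in c("inclusion", "skipping")) {
          down <- if (iso == "inclusion") paste0(intr, e2) else e2
          np <- naive_junction_peptide(e1, down)
          expected[[paste(nm, iso)]] <- data.table(
            event_id = evr$event_id, gene_symbol = nm, isoform = iso,
            sequence = np$sequence, junction_position = np$junction_position,
            flags = paste(np$flags, collapse = ";"))
        }
      }
    }
  }
  genome <- Biostrings::DNAStringSet(chrom_seqs)
  list(genome = genome,
       models = structure(list(transcripts = models), class = "gene_models"),
       events = data.table::rbindlist(events),
       expected = data.table::rbindlist(expected),
       extracellular = data.table(protein_id = "P_SURF", start = 5L, end = 20L,
                                  feature = "Extracellular"),
       gtf = data.table::rbindlist(gtf))
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Write toy-genome artifacts to disk
#'
#' Emits genome FASTA, GTF, extracellular annotation TSV and the expected
#' peptide answer key in the exact dialects the readers consume.
#'
#' @param toy result of [generate_toy_genome()].
#' @param dir output directory.
#' @return named list of file paths.
#' @export
write_toy_genome <- function(toy, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(genome = file.path(dir, "genome.fa"),
                gtf = file.path(dir, "annotation.gtf"),
                extracellular = file.path(dir, "extracellular.tsv"),
                expected = file.path(dir, "expected_peptides.tsv"))
  Biostrings::writeXStringSet(toy$genome, paths$genome)
  writeLines(with(toy$gtf, sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                                   chrom, source, feature, start, end, score,
                                   strand, frame, attrs)), paths$gtf)
  data.table::fwrite(toy$extracellular, paths$extracellular, sep = "\t")
  data.table::fwrite(toy$expected, paths$expected, sep = "\t")
  paths
}

#' Write a panel's events as an rMATS-style SE table
#'
#' Serializes skipped-exon events and the counts of a set of samples in the
#' rMATS JC dialect, with the inclusion level recomputed from the written
#' counts (as rMATS itself reports it).
#'
#' @param panel a `ReferencePanel`.
#' @param sample_ids samples to include (columns of the table).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rmats_table <- function(panel, sample_ids, path) {
  ev <- panel$events[event_type == "SE"]
  jk1 <- vapply(ev$inclusion_junctions, `[`, "", 1)
  jk2 <- vapply(ev$inclusion_junctions, `[`, "", 2)
  jks <- vapply(ev$skipping_junctions, `[`, "", 1)
  ijc <- panel$sjc[jk1, sample_ids, drop = FALSE] +
         panel$sjc[jk2, sample_ids, drop = FALSE]
  sjc <- panel$sjc[jks, sample_ids, drop = FALSE]
  inorm <- ijc / 2
  lvl <- round(inorm / (inorm + sjc), 3)
  fmt_row <- function(m) apply(m, 1, paste, collapse = ",")
  out <- data.table(
    ID = seq_len(nrow(ev)), GeneID = ev$gene_id, geneSymbol = ev$gene_symbol,
    chr = ev$chrom, strand = ev$strand,
    exonStart_0base = ev$c2s - 1L, exonEnd = ev$c2e,
    upstreamES = ev$c1s - 1L, upstreamEE = ev$c1e,
    downstreamES = ev$c3s - 1L, downstreamEE = ev$c3e,
    IJC_SAMPLE_1 = fmt_row(ijc), SJC_SAMPLE_1 = fmt_row(sjc),
    IncFormLen = 98L, SkipFormLen = 49L,
    IncLevel1 = fmt_row(lvl))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write one sample's junction counts as a STAR-style SJ.out.tab file
#'
#' @param panel a `ReferencePanel`.
#' @param sample_id sample whose counts to write.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_star_junctions <- function(panel, sample_id, path) {
  jj <- sj_parse(rownames(panel$sjc))
  code <- match(jj$strand, c(".", "+", "-")) - 1L
  lines <- sprintf("%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%d",
                   jj$chrom, jj$start, jj$end, code, 1L, 1L,
                   panel$sjc[, sample_id], 0L, 30L)
  writeLines(lines, path)
  invisible(path)
}

utils::globalVariables(c("c1e", "c2s", "c2e", "c3s", "c1s", "c3e",
                         "event_type", "attrs", "feature", "frame",
                         "score", "source"))
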