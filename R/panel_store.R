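#' Read an rMATS-style event table
#'
#' Parses a tab-delimited alternative-splicing event table in the rMATS
#' "JC" dialect (one row per event; comma-separated per-sample inclusion and
#' skipping junction counts; comma-separated per-sample inclusion levels)
#' into an event table, a PSI matrix, and a per-junction count matrix.
#'
#' Junction coordinates are derived from the exon coordinates: rMATS exon
#' starts are 0-based and ends 1-based; internally every junction is the
#' intron as 1-based inclusive first/last intronic base. Flanking exons are
#' canonicalized by genomic position (left/right), not transcript
#' orientation. Rows whose coordinates are inconsistent (e.g. alternative
#' exon outside its flanks) are rejected with a message; duplicated
#' coordinate tuples keep the first row with a warning.
#'
#' When the inclusion-level field is NA, PSI is recomputed from counts with
#' junction-count normalization: `(I/n_inc) / (I/n_inc + S)` where `n_inc`
#' is the number of inclusion junctions (2 for SE and RI, 1 for A5SS/A3SS).
#' Per-junction counts from event tables are the average per-junction
#' inclusion support `round(I/n_inc)`; STAR junction files, when provided to
#' [build_reference_panel()], take precedence.
#'
#' @param path path to the event table.
#' @param event_type one of "SE", "A5SS", "A3SS", "RI".
#' @param sample_ids optional sample names for the count/PSI columns.
#' @return list with `events` (data.table), `psi` (event x sample matrix),
#'   `sjc` (junction x sample integer matrix).
#' @export
read_rmats_events <- function(path, event_type = c("SE", "A5SS", "A3SS", "RI"),
                              sample_ids = NULL) {
  event_type <- match.arg(event_type)
  # dec = "." guards against decimal-comma auto-detection on the
  # comma-separated per-sample count fields
  tab <- data.table::fread(path, sep = "\t", header = TRUE, dec = ".")
  coord_cols <- switch(event_type,
    SE = c("exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"),
    A5SS = ,
    A3SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
             "flankingES", "flankingEE"),
    RI = c("riExonStart_0base", "riExonEnd", "upstreamES", "upstreamEE",
           "downstreamES", "downstreamEE"))
  required <- c("GeneID", "geneSymbol", "chr", "strand", coord_cols,
                "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IncLevel1")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("malformed event table ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0) {
    return(list(events = empty_event_table(), psi = matrix(numeric(), 0, 0),
                sjc = matrix(integer(), 0, 0)))
  }

  parse_counts <- function(x) lapply(strsplit(as.character(x), ","), function(v) {
    v[v %in% c("NA", "")] <- NA
    as.numeric(v)
  })
  ijc <- parse_counts(tab$IJC_SAMPLE_1)
  sjc_cnt <- parse_counts(tab$SJC_SAMPLE_1)
  lvl <- parse_counts(tab$IncLevel1)
  ns <- unique(c(lengths(ijc), lengths(sjc_cnt), lengths(lvl)))
  if (length(ns) != 1) stop("inconsistent per-sample field lengths in ", path)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(ns))
  if (length(sample_ids) != ns) stop("sample_ids length != number of samples in table")

  ev <- build_events_from_rmats(tab, event_type)
  keep <- ev$keep
  if (length(keep) < nrow(tab)) {
    message(nrow(tab) - length(keep), " row(s) rejected in ", basename(path),
            ": ", paste(unique(ev$reasons), collapse = "; "))
  }
  events <- ev$events
  ijc <- ijc[keep]; sjc_cnt <- sjc_cnt[keep]; lvl <- lvl[keep]

  dup <- duplicated(events$event_id)
  if (any(dup)) {
    warning(sum(dup), " duplicate event row(s) in ", basename(path),
            "; keeping first occurrence")
    events <- events[!dup]
    ijc <- ijc[!dup]; sjc_cnt <- sjc_cnt[!dup]; lvl <- lvl[!dup]
  }

  n_inc <- lengths(events$inclusion_junctions)
  psi <- matrix(NA_real_, nrow(events), ns,
                dimnames = list(events$event_id, sample_ids))
  for (i in seq_len(nrow(events))) {
    v <- lvl[[i]]
    inorm <- ijc[[i]] / n_inc[i]
    recomputed <- inorm / (inorm + sjc_cnt[[i]])
    recomputed[!is.finite(recomputed)] <- NA_real_
    v[is.na(v)] <- recomputed[is.na(v)]
    psi[i, ] <- v
  }

  jkeys <- unique(unlist(c(events$inclusion_junctions, events$skipping_junctions)))
  sjm <- matrix(0L, length(jkeys), ns, dimnames = list(jkeys, sample_ids))
  seen <- logical(length(jkeys)); names(seen) <- jkeys
  for (i in seq_len(nrow(events))) {
    for (k in events$inclusion_junctions[[i]]) {
      if (!seen[k]) {
        sjm[k, ] <- as.integer(round(ifelse(is.na(ijc[[i]]), 0, ijc[[i]]) / n_inc[i]))
        seen[k] <- TRUE
      }
    }
    k <- events$skipping_junctions[[i]][1]
    if (!is.na(k) && !seen[k]) {
      sjm[k, ] <- as.integer(ifelse(is.na(sjc_cnt[[i]]), 0, sjc_cnt[[i]]))
      seen[k] <- TRUE
    }
  }
  list(events = events, psi = psi, sjc = sjm)
}

empty_event_table <- function() {
  data.table(event_id = character(), event_type = character(),
             gene_id = character(), gene_symbol = character(),
             chrom = character(), strand = character(),
             c1s = integer(), c1e = integer(), c2s = integer(),
             c2e = integer(), c3s = integer(), c3e = integer(),
             alt_len = integer(),
             inclusion_junctions = list(), skipping_junctions = list())
}

# Convert rMATS coordinate columns into the canonical event table.
# All internal exon coordinates are 1-based inclusive; c1/c2/c3 are the
# genomic-left flank, middle segment (alt exon / short-vs-long extension
# carrier / retained intron) and genomic-right flank.
build_events_from_rmats <- function(tab, event_type) {
  n <- nrow(tab)
  reasons <- character(0)
  rows <- vector("list", n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    chrom <- as.character(tab$chr[i]); strand <- as.character(tab$strand[i])
    if (!strand %in% c("+", "-")) { reasons <- c(reasons, "bad strand"); next }
    r <- switch(event_type,
      SE = {
        alt <- c(tab$exonStart_0base[i] + 1L, tab$exonEnd[i])
        e1 <- c(tab$upstreamES[i] + 1L, tab$upstreamEE[i])
        e2 <- c(tab$downstreamES[i] + 1L, tab$downstreamEE[i])
        fl <- if (e1[1] <= e2[1]) list(l = e1, r = e2) else list(l = e2, r = e1)
        if (!(fl$l[2] < alt[1] - 1L && alt[2] < fl$r[1] - 1L)) {
          reasons <- c(reasons, "alternative exon outside flanks"); NULL
        } else list(
          c1 = fl$l, c2 = alt, c3 = fl$r,
          inc = c(sj_key(chrom, fl$l[2] + 1L, alt[1] - 1L, strand),
                  sj_key(chrom, alt[2] + 1L, fl$r[1] - 1L, strand)),
          skp = sj_key(chrom, fl$l[2] + 1L, fl$r[1] - 1L, strand),
          alt_len = alt[2] - alt[1] + 1L)
      },
      A5SS = ,
      A3SS = {
        lng <- c(tab$longExonStart_0base[i] + 1L, tab$longExonEnd[i])
        sht <- c(tab$shortES[i] + 1L, tab$shortEE[i])
        fla <- c(tab$flankingES[i] + 1L, tab$flankingEE[i])
        if (fla[1] > lng[2]) {            # flanking exon to the right
          if (!(sht[1] == lng[1] && sht[2] < lng[2])) {
            reasons <- c(reasons, "short exon inconsistent with long exon"); NULL
          } else list(
            c1 = lng, c2 = sht, c3 = fla,
            inc = sj_key(chrom, lng[2] + 1L, fla[1] - 1L, strand),
            skp = sj_key(chrom, sht[2] + 1L, fla[1] - 1L, strand),
            alt_len = NA_integer_)
        } else if (fla[2] < lng[1]) {     # flanking exon to the left
          if (!(sht[2] == lng[2] && sht[1] > lng[1])) {
            reasons <- c(reasons, "short exon inconsistent with long exon"); NULL
          } else list(
            c1 = fla, c2 = sht, c3 = lng,
            inc = sj_key(chrom, fla[2] + 1L, lng[1] - 1L, strand),
            skp = sj_key(chrom, fla[2] + 1L, sht[1] - 1L, strand),
            alt_len = NA_integer_)
        } else { reasons <- c(reasons, "flanking exon overlaps long exon"); NULL }
      },
      RI = {
        e1 <- c(tab$upstreamES[i] + 1L, tab$upstreamEE[i])
        e2 <- c(tab$downstreamES[i] + 1L, tab$downstreamEE[i])
        if (e1[1] > e2[1]) { tmp <- e1; e1 <- e2; e2 <- tmp }
        if (!(e1[2] < e2[1] - 1L)) { reasons <- c(reasons, "no intron between RI flanks"); NULL }
        else list(
          c1 = e1, c2 = c(e1[2] + 1L, e2[1] - 1L), c3 = e2,
          # retained isoform: two exon-intron boundary pseudo-junctions
          inc = c(sj_key(chrom, e1[2] + 1L, e1[2] + 1L, strand),
                  sj_key(chrom, e2[1] - 1L, e2[1] - 1L, strand)),
          skp = sj_key(chrom, e1[2] + 1L, e2[1] - 1L, strand),
          alt_len = NA_integer_)
      })
    if (is.null(r)) next
    keep[i] <- TRUE
    rows[[i]] <- r
  }
  idx <- which(keep)
  if (!length(idx)) return(list(events = empty_event_table(), keep = idx, reasons = reasons))
  rows <- rows[idx]
  events <- data.table(
    event_type = event_type,
    gene_id = as.character(tab$GeneID[idx]),
    gene_symbol = as.character(tab$geneSymbol[idx]),
    chrom = as.character(tab$chr[idx]),
    strand = as.character(tab$strand[idx]),
    c1s = vapply(rows, function(r) r$c1[1], 1L),
    c1e = vapply(rows, function(r) r$c1[2], 1L),
    c2s = vapply(rows, function(r) r$c2[1], 1L),
    c2e = vapply(rows, function(r) r$c2[2], 1L),
    c3s = vapply(rows, function(r) r$c3[1], 1L),
    c3e = vapply(rows, function(r) r$c3[2], 1L),
    alt_len = vapply(rows, function(r) r$alt_len, 1L),
    inclusion_junctions = lapply(rows, function(r) r$inc),
    skipping_junctions = lapply(rows, function(r) list(r$skp)[[1]])
  )
  events[, event_id := sprintf("%s:%s:%s:%d-%d:%d-%d:%d-%d", event_type, chrom,
                               strand, c1s, c1e, c2s, c2e, c3s, c3e)]
  data.table::setcolorder(events, "event_id")
  list(events = events, keep = idx, reasons = reasons)
}

#' Read STAR-style splice-junction count files
#'
#' Parses one or more files in the STAR `SJ.out.tab` dialect (chrom,
#' 1-based intron start, 1-based intron end, strand code, motif, annotated,
#' unique reads, multimapping reads, overhang) into a junction x sample
#' matrix of unique-read counts. Strand code 0 (undetermined) is stored
#' under the both-strand key "." with a warning.
#'
#' @param paths character vector of file paths; names become sample ids
#'   (defaults to file base names).
#' @return integer matrix, rows keyed by [sj_key()], one column per sample.
#' @export
read_star_junctions <- function(paths) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  }
  frags <- lapply(seq_along(paths), function(i) {
    tab <- data.table::fread(paths[i], sep = "\t", header = FALSE)
    if (ncol(tab) < 7) stop("malformed STAR junction file ", paths[i])
    cnt <- suppressWarnings(as.integer(as.character(tab[[7]])))
    if (anyNA(cnt)) {
      stop("non-integer unique-read count in ", paths[i], " at line ",
           which(is.na(cnt))[1])
    }
    code <- tab[[4]]
    if (any(code == 0)) {
      warning(sum(code == 0), " junction(s) with undefined strand in ",
              basename(paths[i]), "; stored under both-strand key '.'")
    }
    strand <- c(".", "+", "-")[code + 1L]
    dt <- data.table(sj = sj_key(as.character(tab[[1]]), tab[[2]], tab[[3]], strand),
                     count = cnt)
    dt[!duplicated(sj)]
  })
  jkeys <- unique(unlist(lapply(frags, `[[`, "sj")))
  out <- matrix(0L, length(jkeys), length(paths),
                dimnames = list(jkeys, names(paths)))
  for (i in seq_along(frags)) out[frags[[i]]$sj, i] <- frags[[i]]$count
  out
}

#' Assemble an indexed multi-group reference panel
#'
#' Combines an event table, a PSI matrix and junction count matrices with a
#' group manifest into a `ReferencePanel`: the in-memory stand-in for a
#' reference database of splicing profiles across tumor and normal tissue
#' sample groups.
#'
#' @param events canonical event table (from [read_rmats_events()] or the
#'   synthetic generator).
#' @param psi event x sample PSI matrix, values in `[0,1]` or NA.
#' @param sjc junction x sample integer count matrix.
#' @param manifest data.frame with columns sample_id, group_id, role
#'   (`tumor_query`, `normal_reference` or `tumor_reference`) and
#'   total_mapped_reads.
#' @param star_sjc optional junction x sample matrix from
#'   [read_star_junctions()]; where present its counts override `sjc`.
#' @return object of class `ReferencePanel`.
#' @export
build_reference_panel <- function(events, psi, sjc, manifest, star_sjc = NULL) {
  manifest <- as.data.table(manifest)
  need <- c("sample_id", "group_id", "role", "total_mapped_reads")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(manifest$sample_id)) {
    stop("overlapping group membership for sample(s): ",
         paste(unique(manifest$sample_id[duplicated(manifest$sample_id)]),
               collapse = ", "))
  }
  if (nrow(manifest) == 0) stop("empty manifest")
  if (any(manifest[, .N, by = group_id]$N == 0)) stop("group with 0 samples")
  if (any(!is.finite(manifest$total_mapped_reads)) ||
      any(manifest$total_mapped_reads <= 0)) {
    stop("total_mapped_reads must be positive for every sample")
  }
  bad_role <- setdiff(unique(manifest$role),
                      c("tumor_query", "normal_reference", "tumor_reference"))
  if (length(bad_role)) stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  absent <- setdiff(manifest$sample_id, colnames(psi))
  if (length(absent)) {
    stop("manifest sample(s) absent from inputs: ", paste(absent, collapse = ", "))
  }
  psi <- psi[events$event_id, manifest$sample_id, drop = FALSE]

  if (!is.null(star_sjc)) {
    common <- intersect(rownames(star_sjc), rownames(sjc))
    shared_s <- intersect(colnames(star_sjc), colnames(sjc))
    if (length(common) && length(shared_s)) {
      sjc[common, shared_s] <- star_sjc[common, shared_s]
    }
    extra <- setdiff(rownames(star_sjc), rownames(sjc))
    if (length(extra)) {
      add <- matrix(0L, length(extra), ncol(sjc),
                    dimnames = list(extra, colnames(sjc)))
      add[, intersect(colnames(star_sjc), colnames(sjc))] <-
        star_sjc[extra, intersect(colnames(star_sjc), colnames(sjc)), drop = FALSE]
      sjc <- rbind(sjc, add)
    }
  }
  # every junction referenced by an event exists in sjc (possibly all-zero)
  jneed <- unique(unlist(c(events$inclusion_junctions, events$skipping_junctions)))
  miss <- setdiff(jneed, rownames(sjc))
  if (length(miss)) {
    sjc <- rbind(sjc, matrix(0L, length(miss), ncol(sjc),
                             dimnames = list(miss, colnames(sjc))))
  }
  sjc <- sjc[, manifest$sample_id, drop = FALSE]
  storage.mode(sjc) <- "integer"

  structure(list(events = events, psi = psi, sjc = sjc,
                 groups = manifest, version = "1"),
            class = "ReferencePanel")
}

#' @export
print.ReferencePanel <- function(x, ...) {
  cat("ReferencePanel (v", x$version, "): ", nrow(x$events), " events, ",
      nrow(x$sjc), " junctions, ", nrow(x$groups), " samples in ",
      length(unique(x$groups$group_id)), " groups\n", sep = "")
  print(x$groups[, .(n = .N, role = role[1]), by = group_id])
  invisible(x)
}

#' Look up panel events by key
#'
#' Events are indexed by event id, gene id, gene symbol and genomic
#' coordinates; a query against any key returns the matching event rows.
#'
#' @param panel a `ReferencePanel`.
#' @param key character: an event id, gene id, gene symbol, or a genomic
#'   position "chrom:pos" (matches events whose span covers the position).
#' @return data.table of matching event rows (possibly empty).
#' @export
panel_events <- function(panel, key) {
  ev <- panel$events
  hit <- ev$event_id == key | ev$gene_id == key | ev$gene_symbol == key
  if (!any(hit) && grepl("^[^:]+:[0-9]+$", key)) {
    parts <- strsplit(key, ":")[[1]]
    pos <- as.integer(parts[2])
    hit <- ev$chrom == parts[1] & ev$c1s <= pos & ev$c3e >= pos
  }
  ev[hit]
}

sample_ids_of <- function(panel, group) {
  panel$groups[group_id == group, sample_id]
}

groups_of_role <- function(panel, r) {
  unique(panel$groups[role == r, group_id])
}

#' Persist a reference panel to a versioned on-disk layout
#'
#' Writes a columnar text layout (events table, PSI matrix with 17
#' significant digits for exact double round-trip, integer junction counts)
#' plus a JSON sidecar carrying the format version, the group manifest and
#' the row/column orders. [load_panel()] reproduces all values bit-exactly.
#'
#' @param panel a `ReferencePanel`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- data.table::copy(panel$events)
  ev[, inclusion_junctions := vapply(inclusion_junctions, paste, "", collapse = ",")]
  ev[, skipping_junctions := vapply(skipping_junctions, paste, "", collapse = ",")]
  data.table::fwrite(ev, file.path(dir, "events.tsv"), sep = "\t")
  psi_chr <- format_full(panel$psi)
  data.table::fwrite(data.table(event_id = rownames(panel$psi), psi_chr),
                     file.path(dir, "psi.tsv"), sep = "\t")
  data.table::fwrite(data.table(junction = rownames(panel$sjc), panel$sjc),
                     file.path(dir, "sjc.tsv"), sep = "\t")
  jsonlite::write_json(
    list(format_version = panel$version,
         groups = panel$groups,
         event_order = rownames(panel$psi),
         junction_order = rownames(panel$sjc),
         sample_order = colnames(panel$psi)),
    file.path(dir, "panel.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

format_full <- function(m) {
  out <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  out[is.na(m)] <- "NA"
  as.data.table(out)
}

#' Load a persisted reference panel
#'
#' @param dir directory written by [save_panel()].
#' @return a `ReferencePanel` identical to the one saved.
#' @export
load_panel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "panel.json"), simplifyVector = TRUE)
  if (!identical(meta$format_version, "1")) {
    stop("unsupported panel format version: ", meta$format_version)
  }
  ev <- data.table::fread(file.path(dir, "events.tsv"), sep = "\t")
  ev[, inclusion_junctions := strsplit(inclusion_junctions, ",")]
  ev[, skipping_junctions := strsplit(skipping_junctions, ",")]
  psi_t <- data.table::fread(file.path(dir, "psi.tsv"), sep = "\t",
                             colClasses = "character")
  psi <- as.matrix(psi_t[, -1])
  psi <- matrix(as.numeric(psi), nrow(psi),
                dimnames = list(psi_t$event_id, colnames(psi)))
  sj_t <- data.table::fread(file.path(dir, "sjc.tsv"), sep = "\t")
  sjc <- as.matrix(sj_t[, -1]); rownames(sjc) <- sj_t$junction
  storage.mode(sjc) <- "integer"
  groups <- as.data.table(meta$groups)
  ev <- ev[match(meta$event_order, ev$event_id)]
  structure(list(events = ev,
                 psi = psi[meta$event_order, meta$sample_order, drop = FALSE],
                 sjc = sjc[meta$junction_order, meta$sample_order, drop = FALSE],
                 groups = groups, version = meta$format_version),
            class = "ReferencePanel")
}

#' Mask low-coverage PSI estimates
#'
#' PSI estimates for events with low splice-junction coverage are unreliable
#' and are masked as missing. An event's coverage in a sample is the sum of
#' read counts over all of its junctions; with the default per-group
#' granularity, all samples of a group are masked for an event whenever the
#' group mean of that sum is below `min_avg_total` (strict less-than).
#' Counts themselves are not modified, and masking is idempotent and
#' monotone in the threshold.
#'
#' @param panel a `ReferencePanel`.
#' @param min_avg_total coverage threshold (default 10 reads).
#' @param granularity "group" (default) or "sample".
#' @return PSI matrix with masked entries set to NA.
#' @export
mask_low_coverage <- function(panel, min_avg_total = 10,
                              granularity = c("group", "sample")) {
  granularity <- match.arg(granularity)
  ev <- panel$events
  sums <- matrix(0, nrow(ev), ncol(panel$sjc),
                 dimnames = dimnames(panel$psi))
  for (i in seq_len(nrow(ev))) {
    ks <- c(ev$inclusion_junctions[[i]], ev$skipping_junctions[[i]])
    sums[i, ] <- colSums(panel$sjc[ks, , drop = FALSE])
  }
  psi <- panel$psi
  if (granularity == "sample") {
    psi[sums < min_avg_total] <- NA_real_
  } else {
    for (g in unique(panel$groups$group_id)) {
      cols <- sample_ids_of(panel, g)
      masked <- rowMeans(sums[, cols, drop = FALSE]) < min_avg_total
      psi[masked, cols] <- NA_real_
    }
  }
  psi
}
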