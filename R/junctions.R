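#' Splice-junction keys
#'
#' A splice junction is the intron excised between two exons, identified by
#' chromosome, first and last intronic base (1-based, inclusive) and strand.
#' Junctions are carried throughout the package as canonical string keys so
#' that matrix joins are exact.
#'
#' @param chrom chromosome name.
#' @param start first intronic base, 1-based inclusive.
#' @param end last intronic base, 1-based inclusive.
#' @param strand "+", "-" or "." (undetermined).
#' @return character vector of keys of the form `chrom:start-end:strand`.
#' @export
sj_key <- function(chrom, start, end, strand) {
  stopifnot(all(start <= end))
  stopifnot(all(strand %in% c("+", "-", ".")))
  sprintf("%s:%d-%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

#' Parse splice-junction keys back into coordinates
#'
#' @param keys character vector produced by [sj_key()].
#' @return data.table with columns chrom, start, end, strand.
#' @export
sj_parse <- function(keys) {
  m <- regmatches(keys, regexec("^(.+):([0-9]+)-([0-9]+):([+.-])$", keys))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) stop("malformed junction key: ", keys[which(bad)[1]])
  data.table(
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    strand = vapply(m, `[`, "", 5L)
  )
}

# Validate an event table: junction sets disjoint between isoforms, all
# junctions on the event's chrom/strand, SE alt exon strictly inside the
# skipping junction. Returns indices of valid rows; attribute "reasons"
# explains rejections.
validate_events <- function(events) {
  n <- nrow(events)
  ok <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    inc <- events$inclusion_junctions[[i]]
    skp <- events$skipping_junctions[[i]]
    if (length(intersect(inc, skp)) > 0) {
      ok[i] <- FALSE; reason[i] <- "isoform junction sets overlap"; next
    }
    jj <- sj_parse(c(inc, skp))
    if (any(jj$chrom != events$chrom[i]) || any(jj$strand != events$strand[i])) {
      ok[i] <- FALSE; reason[i] <- "junction chrom/strand mismatch"; next
    }
    if (any(jj$start > jj$end)) {
      ok[i] <- FALSE; reason[i] <- "inverted junction coordinates"; next
    }
    if (events$event_type[i] == "SE") {
      sk <- sj_parse(skp)
      if (!(events$c2s[i] > sk$start && events$c2e[i] < sk$end)) {
        ok[i] <- FALSE; reason[i] <- "alternative exon not inside skipping junction"
      }
    }
  }
  structure(which(ok), reasons = reason[!ok])
}
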