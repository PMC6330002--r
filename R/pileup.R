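#' Build a pileup over a reference window
#'
#' Converts a set of overlapping reads into per-locus pileup columns.
#' Deletions contribute a fifth base type `"*"` at every deleted locus,
#' carrying a quality equal to the floor of the mean of the flanking base
#' qualities of the same read; soft-clipped bases contribute to no column;
#' insertions never create columns but are recorded per read for the rewrite
#' stage.  Reads flagged unmapped/secondary/supplementary/duplicate/QC-fail
#' are excluded.  Coordinates are 0-based half-open throughout (the SAM
#' `pos` column is converted on entry).
#'
#' @param reads record table (see [read_alignments()]); must be
#'   coordinate-sorted or a hard error naming the offending read is raised.
#' @param span optional `c(start, end)` 0-based half-open window; defaults to
#'   the full span of the reads.
#' @param read_id identifiers attached to each read's entries (defaults to
#'   the row number); used by whole-read retention.
#' @param mapq_unavailable substitute for MAPQ 255 ("unavailable"); the
#'   substituted value feeds the caller and the low-MAPQ heuristic.
#' @return an object of class `"pileup"`: per-entry vectors sorted by
#'   column (`base` codes 0..5 for A,C,G,T,*,N; `qual`; `mapq`; `read`;
#'   `qpos`; `strand`), `offsets` (cumulative entries per locus), soft-clip
#'   and indel side tables, and a per-read summary with footprints.
#' @export
build_pileup <- function(reads, span = NULL, read_id = NULL,
                         mapq_unavailable = 30L) {
  stopifnot(is.data.frame(reads))
  if (is.null(read_id)) read_id <- seq_len(nrow(reads))
  use <- bitwAnd(reads$flag, QC_EXCLUDE_FLAGS) == 0L
  reads <- reads[use, , drop = FALSE]
  read_id <- read_id[use]
  if (nrow(reads) > 1L && is.unsorted(reads$pos)) {
    bad <- which(diff(reads$pos) < 0)[1] + 1L
    stop("reads not coordinate-sorted: read '", reads$qname[bad],
         "' (", bad, ") starts before its predecessor")
  }
  pos0 <- reads$pos - 1L
  cs <- cigar_stats(reads$cigar)
  end0 <- pos0 + cs[, "ref_len"]
  if (is.null(span)) {
    span <- if (nrow(reads)) c(min(pos0), max(end0)) else c(0L, 0L)
  }
  span <- as.integer(span)
  mq <- as.integer(reads$mapq)
  mq[mq == 255L] <- as.integer(mapq_unavailable)
  strand <- as.integer(bitwAnd(reads$flag, 16L) != 0L)
  raw <- cpp_build_pileup(pos0, reads$cigar, reads$seq, reads$qual,
                          mq, strand, span[1], span[2])
  structure(list(
    span = span,
    offsets = raw$offsets,
    base = raw$base, qual = raw$qual, mapq = raw$mapq,
    read = raw$read, qpos = raw$qpos, strand = raw$strand,
    clips = data.frame(read_id = read_id[raw$clip_read],
                       pos = raw$clip_pos,
                       side = c("left", "right")[raw$clip_side + 1L],
                       len = raw$clip_len),
    indels = data.frame(read_id = read_id[raw$indel_read],
                        start = raw$indel_start, end = raw$indel_end,
                        type = c("ins", "del")[raw$indel_type + 1L],
                        len = raw$indel_len),
    reads = data.frame(read_id = read_id,
                       start = pos0, end = end0,
                       foot_start = pos0 - cs[, "left_clip"],
                       foot_end = end0 + cs[, "right_clip"],
                       mapq = mq),
    n_reads = nrow(reads)
  ), class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("pileup: span [%d,%d), %d reads, %d entries over %d loci\n",
              x$span[1], x$span[2], x$n_reads, length(x$base),
              sum(diff(x$offsets) > 0)))
  invisible(x)
}

#' Extract individual pileup columns
#'
#' Mainly for inspection and testing; the pipeline works on the packed
#' vectors directly.
#'
#' @param pu a [build_pileup()] object.
#' @param pos 0-based positions; defaults to every covered locus.
#' @return named list of data.frames (`base`, `qual`, `mapq`, `read_id`,
#'   `qpos`, `strand`), one per requested position.
#' @export
pileup_columns <- function(pu, pos = NULL) {
  all_pos <- pu$span[1]:(pu$span[2] - 1L)
  if (is.null(pos)) pos <- all_pos[diff(pu$offsets) > 0]
  out <- lapply(pos, function(p) {
    i <- p - pu$span[1] + 1L
    if (i < 1L || i >= length(pu$offsets)) stop("position ", p, " outside span")
    idx <- if (pu$offsets[i] < pu$offsets[i + 1L])
      (pu$offsets[i] + 1L):pu$offsets[i + 1L] else integer()
    data.frame(base = QC_BASES[pu$base[idx] + 1L],
               qual = pu$qual[idx], mapq = pu$mapq[idx],
               read_id = pu$reads$read_id[pu$read[idx]],
               qpos = pu$qpos[idx], strand = pu$strand[idx])
  })
  names(out) <- pos
  out
}

#' Soft-clip placements of a single read
#'
#' A left clip maps to the read's leftmost aligned reference coordinate, a
#' right clip to one past the last aligned reference base.
#'
#' @param read one-row record table or list with `pos` (1-based SAM) and
#'   `cigar`.
#' @return data.frame with 0-based `pos`, `side` (`"left"`/`"right"`) and
#'   `len`; zero rows when the read has no soft clips.
#' @export
softclip_positions <- function(read) {
  cg <- as.character(read$cigar)
  stopifnot(length(cg) == 1L)
  ops <- parse_cigar(cg)
  pos0 <- as.integer(read$pos) - 1L
  out <- data.frame(pos = integer(), side = character(), len = integer())
  seen_ref <- FALSE
  r <- pos0
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X", "D", "N")) { r <- r + len; seen_ref <- TRUE }
    else if (op == "S") {
      out <- rbind(out, data.frame(pos = if (seen_ref) r else pos0,
                                   side = if (seen_ref) "right" else "left",
                                   len = len))
    }
  }
  out
}

parse_cigar <- function(cg) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
  if (m[1] == -1L) stop("malformed CIGAR: ", cg)
  toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
  if (sum(nchar(toks)) != nchar(cg)) stop("malformed CIGAR: ", cg)
  data.frame(op = substring(toks, nchar(toks)),
             len = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}
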