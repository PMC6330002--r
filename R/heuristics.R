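#' Heuristic thresholds for quality retention
#'
#' Knobs for the six detectors that decide where qualities must be kept
#' verbatim because any caller might be confidently wrong there.
#'
#' @param clip_min_count minimum soft clips sharing a coordinate.
#' @param clip_min_fraction minimum fraction of reads spanning that
#'   coordinate (footprints, clips included) that clip there.
#' @param depth_max loci deeper than this are flagged (collapsed repeat /
#'   contamination).
#' @param mapq_low reads mapped below this get whole-read retention; also
#'   the per-entry bar for the locus-level low-MAPQ fraction.
#' @param low_mapq_fraction locus flagged when at least this fraction of its
#'   entries are low-MAPQ.
#' @param keep_colocated_high_mapq also retain whole high-MAPQ reads that
#'   overlap a flagged low-MAPQ interval.
#' @param max_alleles more well-supported alleles than this flags the locus
#'   (diploid: 2).
#' @param str_unit_max,str_min_copies short-tandem-repeat definition: unit
#'   length up to `str_unit_max` repeated at least `str_min_copies` times.
#' @param pad bases of sequence context added around every flagged locus.
#' @export
heuristic_params <- function(clip_min_count = 3L, clip_min_fraction = 0.3,
                             depth_max = 100L, mapq_low = 10L,
                             low_mapq_fraction = 0.25,
                             keep_colocated_high_mapq = TRUE,
                             max_alleles = 2L, str_unit_max = 4L,
                             str_min_copies = 3L, pad = 10L) {
  stopifnot(clip_min_count >= 0, depth_max >= 0, mapq_low >= 0,
            max_alleles >= 0, str_unit_max >= 1, str_min_copies >= 2, pad >= 0,
            clip_min_fraction >= 0, clip_min_fraction <= 1,
            low_mapq_fraction >= 0, low_mapq_fraction <= 1)
  structure(list(clip_min_count = as.integer(clip_min_count),
                 clip_min_fraction = clip_min_fraction,
                 depth_max = as.integer(depth_max),
                 mapq_low = as.integer(mapq_low),
                 low_mapq_fraction = low_mapq_fraction,
                 keep_colocated_high_mapq = isTRUE(keep_colocated_high_mapq),
                 max_alleles = as.integer(max_alleles),
                 str_unit_max = as.integer(str_unit_max),
                 str_min_copies = as.integer(str_min_copies),
                 pad = as.integer(pad)),
            class = "heuristic_params")
}

qc_intervals <- function(start = integer(), end = integer(), tag = character(0)) {
  keep <- end > start
  data.frame(start = as.integer(start[keep]), end = as.integer(end[keep]),
             tag = rep_len(tag, sum(keep)))
}

# positions (0-based, sorted, unique) -> padded merged intervals
positions_to_intervals <- function(pos, pad, tag) {
  if (length(pos) == 0L) return(qc_intervals())
  pos <- sort(unique(as.integer(pos)))
  brk <- c(0L, which(diff(pos) > 1L), length(pos))
  st <- pos[brk[-length(brk)] + 1L]
  en <- pos[brk[-1]] + 1L
  merge_intervals(qc_intervals(st - pad, en + pad, tag))
}

merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  ir <- IRanges::IRanges(iv$start + 1L, iv$end)   # 1-based inclusive
  red <- IRanges::reduce(ir, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  tags <- vapply(revmap, function(i)
    paste(sort(unique(unlist(strsplit(iv$tag[i], ",", fixed = TRUE)))),
          collapse = ","), character(1))
  qc_intervals(IRanges::start(red) - 1L, IRanges::end(red), tags)
}

#' Concordant soft clipping
#'
#' Coordinates where at least `clip_min_count` reads soft-clip and the
#' clippers make up at least `clip_min_fraction` of the reads whose
#' footprint (alignment plus clipped tails) spans the site are flagged: many
#' reads clipping at one site usually means a large insertion absent from
#' the reference, or contamination.  Each hit becomes
#' `[site - pad, site + pad)`.
#'
#' @param pu a [build_pileup()] object (its clip table and read footprints
#'   are used).
#' @param params [heuristic_params()].
#' @return interval data.frame (`start`, `end`, `tag = "softclip"`).
#' @export
detect_softclip_concordance <- function(pu, params = heuristic_params()) {
  cl <- pu$clips
  if (nrow(cl) == 0L) return(qc_intervals())
  tab <- table(cl$pos)
  sites <- as.integer(names(tab))
  cnt <- as.integer(tab)
  fs <- pmax(pu$reads$foot_start, pu$span[1])
  fe <- pmin(pu$reads$foot_end, pu$span[2])
  ns <- pu$span[2] - pu$span[1]
  ok <- fe > fs
  cov <- cumsum(tabulate(fs[ok] - pu$span[1] + 1L, ns + 1L) -
                tabulate(fe[ok] - pu$span[1] + 1L, ns + 1L))
  inside <- sites >= pu$span[1] & sites < pu$span[2]
  span_n <- ifelse(inside, cov[sites - pu$span[1] + 1L], 0L)
  hit <- cnt >= params$clip_min_count & span_n > 0L &
         cnt >= params$clip_min_fraction * span_n
  merge_intervals(qc_intervals(sites[hit] - params$pad,
                               sites[hit] + params$pad, "softclip"))
}

#' Excessive depth
#'
#' Loci deeper than `depth_max` (possible contamination or collapsed repeat,
#' where calls often look deceptively good) become padded, merged intervals.
#'
#' @param calls a [call_consensus()] table (its `depth` column is used).
#' @param params [heuristic_params()].
#' @export
detect_excess_depth <- function(calls, params = heuristic_params()) {
  positions_to_intervals(calls$pos[calls$depth > params$depth_max],
                         params$pad, "depth")
}

#' Low mapping quality
#'
#' Any read with `mapq < mapq_low` gets whole-read retention.  Loci where at
#' least `low_mapq_fraction` of entries are low-MAPQ become intervals; with
#' `keep_colocated_high_mapq`, high-MAPQ reads overlapping those intervals
#' are whole-retained as well (their placement may be right where the
#' reference is poor).
#'
#' @param pu a [build_pileup()] object.
#' @param calls matching [call_consensus()] table, called with
#'   `mapq_low = params$mapq_low` so the low-MAPQ tallies are present.
#' @param params [heuristic_params()].
#' @return `list(intervals, whole_read_ids)`.
#' @export
detect_low_mapq <- function(pu, calls, params = heuristic_params()) {
  rd <- pu$reads
  whole <- rd$read_id[rd$mapq < params$mapq_low]
  nlow <- attr(calls, "n_lowmapq")
  frac_hit <- calls$depth > 0L & nlow >= params$low_mapq_fraction * calls$depth &
              nlow > 0L
  iv <- positions_to_intervals(calls$pos[frac_hit], params$pad, "mapq")
  if (params$keep_colocated_high_mapq && nrow(iv) > 0L) {
    for (i in seq_len(nrow(iv))) {
      ov <- rd$start < iv$end[i] & rd$end > iv$start[i] & rd$mapq >= params$mapq_low
      whole <- c(whole, rd$read_id[ov])
    }
  }
  list(intervals = iv, whole_read_ids = unique(whole))
}

#' Unexpected number of alleles
#'
#' A single diploid sample has at most two alleles per locus; more implies
#' misalignment, duplication or contamination.  An allele counts only when
#' supported by at least 2 reads and at least 10% of the column depth, so
#' scattered sequencing errors do not trigger the detector.
#'
#' @param calls a [call_consensus()] table (its base-count attribute is
#'   used; `N` never counts as an allele).
#' @param params [heuristic_params()].
#' @export
detect_excess_alleles <- function(calls, params = heuristic_params()) {
  cnt <- attr(calls, "counts")
  if (is.null(cnt) || ncol(cnt) == 0L) return(qc_intervals())
  dp <- calls$depth
  sup <- cnt[1:5, , drop = FALSE]
  good <- sup >= 2L & sweep(sup, 2L, 0.1 * dp, ">=")
  nall <- colSums(good)
  positions_to_intervals(calls$pos[nall > params$max_alleles],
                         params$pad, "alleles")
}

#' Low-quality consensus calls
#'
#' Covered loci where the pessimistic confidence fails the caller's bar —
#' typically a single unclear base — become padded intervals.  With
#' `conf_threshold = Inf` this covers every covered locus (the degenerate
#' full-retention mode).
#'
#' @param calls a [call_consensus()] table.
#' @param cparams [caller_params()] (supplies `conf_threshold`).
#' @param params [heuristic_params()] (supplies `pad`).
#' @export
detect_low_conf_calls <- function(calls, cparams = caller_params(),
                                  params = heuristic_params()) {
  low <- calls$depth > 0L & !is_confident(calls$phred_conf, cparams)
  positions_to_intervals(calls$pos[low], params$pad, "lowconf")
}

#' Short tandem repeats near the consensus
#'
#' Alignments are unreliable in and around short tandem repeats, especially
#' with indels, so bases land in the wrong pileup column.  The scan runs on
#' the computed consensus string (first allele per locus; no reference is
#' available): maximal tracts whose repeat unit is at most `str_unit_max`
#' long and repeats at least `str_min_copies` times (exact copies) are
#' flagged.  Tracts are extended to cover any overlapping read's indel span,
#' then padded.
#'
#' @param calls a [call_consensus()] table.
#' @param pu the matching [build_pileup()] object (for indel spans); may be
#'   `NULL` to skip the indel extension.
#' @param params [heuristic_params()].
#' @export
detect_str <- function(calls, pu = NULL, params = heuristic_params()) {
  s <- calls$g1
  s[s == "*"] <- "N"        # deleted consensus base: breaks any tract
  code <- match(s, QC_BASES) - 1L
  n <- length(code)
  iv <- qc_intervals()
  if (n >= 2L) {
    st <- en <- integer()
    for (u in seq_len(min(params$str_unit_max, n - 1L))) {
      eq <- code[seq_len(n - u)] == code[seq_len(n - u) + u] &
            code[seq_len(n - u)] != 5L
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hit <- r$values & (r$lengths + u) >= u * params$str_min_copies
      if (any(hit)) {
        st <- c(st, calls$pos[starts[hit]])
        en <- c(en, calls$pos[starts[hit]] + r$lengths[hit] + u)
      }
    }
    if (length(st)) {
      iv <- qc_intervals(st, en, "str")
      if (!is.null(pu) && nrow(pu$indels) > 0L) {
        ind <- pu$indels
        ind$end2 <- pmax(ind$end, ind$start + 1L)
        for (i in seq_len(nrow(iv))) {
          ov <- ind$start < iv$end[i] & ind$end2 > iv$start[i]
          if (any(ov)) {
            iv$start[i] <- min(iv$start[i], ind$start[ov])
            iv$end[i] <- max(iv$end[i], ind$end2[ov])
          }
        }
      }
      iv <- merge_intervals(qc_intervals(iv$start - params$pad,
                                         iv$end + params$pad, "str"))
    }
  }
  iv
}

#' Assemble the retention mask
#'
#' Unions any number of detector outputs: intervals are merged (overlapping
#' or adjacent) with their reason tags combined, whole-read id sets are
#' unioned.  Idempotent and order-independent.
#'
#' @param ... interval data.frames (as returned by the detectors) and/or
#'   lists with `intervals`/`whole_read_ids` elements (as returned by
#'   [detect_low_mapq()]).
#' @return object of class `"retention_mask"`: `intervals` (disjoint,
#'   sorted, each with at least one reason tag) and `whole_read_ids`.
#' @export
assemble_mask <- function(...) {
  parts <- list(...)
  ivs <- list()
  whole <- c()
  for (p in parts) {
    if (is.null(p)) next
    if (inherits(p, "retention_mask")) {
      ivs <- c(ivs, list(p$intervals)); whole <- c(whole, p$whole_read_ids)
    } else if (is.data.frame(p)) {
      ivs <- c(ivs, list(p))
    } else if (is.list(p)) {
      if (!is.null(p$intervals)) ivs <- c(ivs, list(p$intervals))
      if (!is.null(p$whole_read_ids)) whole <- c(whole, p$whole_read_ids)
    } else stop("cannot interpret detector output of class ", class(p)[1])
  }
  iv <- if (length(ivs)) do.call(rbind, ivs) else qc_intervals()
  structure(list(intervals = merge_intervals(iv),
                 whole_read_ids = unique(whole)),
            class = "retention_mask")
}

#' @export
print.retention_mask <- function(x, ...) {
  cat(sprintf("retention mask: %d interval(s) covering %d bp, %d whole read(s)\n",
              nrow(x$intervals), sum(x$intervals$end - x$intervals$start),
              length(x$whole_read_ids)))
  if (nrow(x$intervals)) {
    tags <- sort(table(unlist(strsplit(x$intervals$tag, ","))), decreasing = TRUE)
    cat("  reasons:", paste(names(tags), tags, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

# paint mask intervals onto a logical vector over [span[1], span[2])
mask_to_vector <- function(mask, span) {
  ns <- span[2] - span[1]
  v <- logical(ns)
  iv <- mask$intervals
  if (!is.null(iv) && nrow(iv)) {
    st <- pmax(iv$start, span[1]) - span[1] + 1L
    en <- pmin(iv$end, span[2]) - span[1]
    for (i in seq_along(st)) if (st[i] <= en[i]) v[st[i]:en[i]] <- TRUE
  }
  v
}
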