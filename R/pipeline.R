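#' Preset parameter bundles
#'
#' Level 1 is conservative: every detector on, loose thresholds (more is
#' retained), disagreeing bases kept verbatim, no P-block.  Level 9 is
#' aggressive: tight thresholds, disagreeing bases quantized.  In between,
#' `conf_threshold` falls 75..35, `mapq_low` 25..5, `depth_max` 400..100,
#' and `disagree_mode` steps keep (1-3) / low (4-6) / quantize (7-9).
#' Level 0 is the degenerate lossless bundle: nothing is ever confident and
#' disagreeing bases are kept, so output qualities are byte-identical to
#' input.  `tuned = TRUE` is the hand-tuned aggressive bundle (level 9,
#' P-block 8, `conf_threshold = 60`, `mapq_low = 30`, `depth_max = 100`).
#'
#' @param level integer 0..9.
#' @param pblock_p P-block parameter (applied to kept stretches).
#' @param tuned use the tuned bundle (overrides `level`/`pblock_p`).
#' @return `list(policy, cparams, hparams)` ready for [compress_records()].
#' @export
qc_preset <- function(level = 1L, pblock_p = 0L, tuned = FALSE) {
  if (tuned) {
    p <- qc_preset(9L, pblock_p = 8L)
    p$cparams$conf_threshold <- 60
    p$hparams$mapq_low <- 30L
    p$hparams$depth_max <- 100L
    return(p)
  }
  level <- as.integer(level)
  stopifnot(level >= 0L, level <= 9L)
  if (level == 0L) {
    return(list(policy = quality_policy(disagree_mode = "keep", pblock_p = 0L,
                                        preset_level = 0L),
                cparams = caller_params(conf_threshold = Inf),
                hparams = heuristic_params()))
  }
  mode <- c("keep", "keep", "keep", "low", "low", "low",
            "quantize", "quantize", "quantize")[level]
  list(policy = quality_policy(disagree_mode = mode,
                               pblock_p = as.integer(pblock_p),
                               preset_level = level),
       cparams = caller_params(conf_threshold = 75 - 5 * level),
       hparams = heuristic_params(
         mapq_low = as.integer(round(25 - 2.5 * (level - 1))),
         depth_max = as.integer(round(400 - 37.5 * (level - 1)))))
}

QC_DETECTORS <- c("softclip", "depth", "mapq", "alleles", "lowconf", "str")

plan_windows <- function(lo, hi, window_size, overlap) {
  if (!is.finite(window_size) || window_size >= hi - lo)
    return(data.frame(ws = lo, we = hi, cs = lo, ce = hi))
  stopifnot(window_size > 2 * overlap)
  ws <- seq.int(lo, hi - 1L, by = window_size)
  we <- pmin(ws + window_size, hi)
  data.frame(ws = ws, we = we,
             cs = pmax(ws - overlap, lo), ce = pmin(we + overlap, hi))
}

#' Plan the streaming windows of a sorted input
#'
#' Exposes the window decomposition used by [compress_records()]: each
#' window owns the reads that *start* inside it (they are rewritten and
#' emitted exactly once) but its detectors see `overlap` extra bases of
#' context on both sides, so signals straddling a boundary are not missed.
#'
#' @param input path to a SAM/BAM file, or a record table.
#' @param window_size window width in bases (must exceed `2 * overlap`);
#'   `Inf` gives one monolithic window per reference.
#' @param overlap context carried on each side.
#' @return list of windows: `rname`, `span`, `context`, `read_idx` (rows
#'   emitted by this window), `context_idx` (rows visible to its detectors).
#' @export
stream_windows <- function(input, window_size = 10000L, overlap = 1000L) {
  records <- if (is.character(input)) read_alignments(input) else input
  check_sorted(records)
  use <- bitwAnd(records$flag, QC_EXCLUDE_FLAGS) == 0L
  out <- list()
  for (rn in unique(records$rname[use])) {
    sel <- which(use & records$rname == rn)
    pos0 <- records$pos[sel] - 1L
    end0 <- pos0 + cigar_stats(records$cigar[sel])[, "ref_len"]
    wp <- plan_windows(min(pos0), max(end0), window_size, overlap)
    for (i in seq_len(nrow(wp))) {
      own <- pos0 >= wp$ws[i] & pos0 < wp$we[i]
      ctx <- pos0 < wp$ce[i] & end0 > wp$cs[i]
      out[[length(out) + 1L]] <- list(
        rname = rn, span = c(wp$ws[i], wp$we[i]),
        context = c(wp$cs[i], wp$ce[i]),
        read_idx = sel[own], context_idx = sel[ctx])
    }
  }
  out
}

#' Compress the quality values of a record table
#'
#' The full pipeline, window by window: pileup, pessimistic diploid
#' consensus, retention heuristics, quality rewrite.  Reads excluded from
#' analysis (unmapped, secondary, supplementary, duplicate, QC-fail) pass
#' through untouched.  Windowed and monolithic runs produce identical
#' output whenever `overlap` comfortably exceeds read length plus padding
#' (the default 1000 vs typical short reads).
#'
#' @param records coordinate-sorted record table (hard error otherwise).
#' @param preset a [qc_preset()] bundle; the default is level 1.  Individual
#'   pieces can be overridden with `policy`/`cparams`/`hparams`.
#' @param policy,cparams,hparams explicit overrides of the preset pieces.
#' @param window_size,overlap streaming geometry (see [stream_windows()]).
#' @param detectors subset of `r toString(QC_DETECTORS)` to run; the
#'   low-confidence detector is part of the method's contract and is
#'   included by default.
#' @param verbose log per-window retention counts by reason tag to stderr.
#' @return list of class `"qualcrunch_result"`: `records` (qualities
#'   rewritten), `mask` (merged retention mask, absolute coordinates),
#'   `window_log` (per-window retained-interval counts by tag) and the
#'   parameter bundle used.
#' @export
compress_records <- function(records, preset = qc_preset(1L),
                             policy = preset$policy, cparams = preset$cparams,
                             hparams = preset$hparams,
                             window_size = 10000L, overlap = 1000L,
                             detectors = QC_DETECTORS, verbose = FALSE) {
  stopifnot(is.data.frame(records))
  detectors <- match.arg(detectors, QC_DETECTORS, several.ok = TRUE)
  check_sorted(records)
  out_qual <- records$qual
  windows <- stream_windows(records, window_size, overlap)
  all_iv <- list()
  all_whole <- c()
  log <- list()
  for (w in windows) {
    ctx <- records[w$context_idx, , drop = FALSE]
    pu <- build_pileup(ctx, span = w$context, read_id = w$context_idx,
                       mapq_unavailable = cparams$mapq_floor)
    calls <- call_consensus(pu, cparams, mapq_low = hparams$mapq_low)
    parts <- list()
    if ("softclip" %in% detectors)
      parts$softclip <- detect_softclip_concordance(pu, hparams)
    if ("depth" %in% detectors)
      parts$depth <- detect_excess_depth(calls, hparams)
    if ("mapq" %in% detectors)
      parts$mapq <- detect_low_mapq(pu, calls, hparams)
    if ("alleles" %in% detectors)
      parts$alleles <- detect_excess_alleles(calls, hparams)
    if ("lowconf" %in% detectors)
      parts$lowconf <- detect_low_conf_calls(calls, cparams, hparams)
    if ("str" %in% detectors)
      parts$str <- detect_str(calls, pu, hparams)
    mask <- do.call(assemble_mask, unname(parts))
    own <- match(w$read_idx, w$context_idx)
    if (length(own)) {
      out_qual[w$read_idx] <- rewrite_core(ctx[own, , drop = FALSE],
                                           w$read_idx, calls, mask,
                                           policy, cparams)
    }
    iv <- mask$intervals
    iv <- iv[iv$start < w$span[2] & iv$end > w$span[1], , drop = FALSE]
    all_iv[[length(all_iv) + 1L]] <- iv
    all_whole <- c(all_whole, mask$whole_read_ids)
    tag_n <- table(factor(unlist(strsplit(iv$tag, ",")), levels = QC_DETECTORS))
    log[[length(log) + 1L]] <- data.frame(rname = w$rname,
                                          start = w$span[1], end = w$span[2],
                                          as.list(tag_n))
    if (verbose)
      message(sprintf("[%s:%d-%d] retained intervals by reason: %s",
                      w$rname, w$span[1], w$span[2],
                      paste(names(tag_n), as.integer(tag_n),
                            sep = "=", collapse = " ")))
  }
  records$qual <- out_qual
  structure(list(records = records,
                 mask = assemble_mask(do.call(rbind, c(all_iv, list(qc_intervals()))),
                                      list(whole_read_ids = unique(all_whole))),
                 window_log = if (length(log)) do.call(rbind, log) else NULL,
                 policy = policy, cparams = cparams, hparams = hparams),
            class = "qualcrunch_result")
}

#' @export
print.qualcrunch_result <- function(x, ...) {
  cat(sprintf("qualcrunch result: %d records\n", nrow(x$records)))
  print(x$mask)
  invisible(x)
}

#' Compress the quality values of a SAM/BAM file
#'
#' File-level wrapper around [compress_records()]: reads the input, rewrites
#' qualities, writes the output with an appended `@PG` header line.  The
#' recorded command line includes policy options but not the window
#' geometry, which never affects output.
#'
#' @inheritParams compress_records
#' @param input,output file paths (`.sam`, or `.bam` via samtools).
#' @param drop_names,drop_aux passed to [write_alignments()].
#' @return the [compress_records()] result, invisibly, with a
#'   `compression` element comparing input and output quality streams.
#' @export
compress_file <- function(input, output, preset = qc_preset(1L),
                          policy = preset$policy, cparams = preset$cparams,
                          hparams = preset$hparams,
                          window_size = 10000L, overlap = 1000L,
                          detectors = QC_DETECTORS,
                          drop_names = FALSE, drop_aux = character(),
                          verbose = FALSE) {
  records <- read_alignments(input)
  res <- compress_records(records, policy = policy, cparams = cparams,
                          hparams = hparams, window_size = window_size,
                          overlap = overlap, detectors = detectors,
                          verbose = verbose)
  cl <- sprintf("qualcrunch -l%s -p%d -Q%s -u%d -D%d --disagree-mode %s",
                if (is.null(policy$preset_level)) "?" else policy$preset_level,
                policy$pblock_p, format(cparams$conf_threshold),
                hparams$mapq_low, hparams$depth_max, policy$disagree_mode)
  write_alignments(res$records, output, drop_names = drop_names,
                   drop_aux = drop_aux, header = attr(records, "header"),
                   cl = cl)
  res$compression <- compression_summary(records$qual, res$records$qual)
  invisible(res)
}
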