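#' Default 8-level quantizer
#'
#' Illumina-style binning of the Phred range \[0,93\]:
#' \{0-1, 2-9, 10-19, 20-24, 25-29, 30-34, 35-39, 40+\} with representatives
#' \{0, 6, 15, 22, 27, 33, 37, 40\}.
#'
#' @return data.frame with `lo`, `hi` (inclusive) and representative `q`.
#' @export
default_quant_bins <- function() {
  data.frame(lo = c(0L, 2L, 10L, 20L, 25L, 30L, 35L, 40L),
             hi = c(1L, 9L, 19L, 24L, 29L, 34L, 39L, 93L),
             q  = c(0L, 6L, 15L, 22L, 27L, 33L, 37L, 40L))
}

quant_lookup <- function(bins) {
  stopifnot(all(c("lo", "hi", "q") %in% names(bins)))
  lut <- rep(NA_integer_, 94L)
  for (i in seq_len(nrow(bins))) {
    idx <- (bins$lo[i]:bins$hi[i]) + 1L
    if (any(idx < 1L | idx > 94L)) stop("quantizer bin outside [0,93]")
    if (any(!is.na(lut[idx]))) stop("quantizer bins overlap")
    lut[idx] <- as.integer(bins$q[i])
  }
  if (anyNA(lut)) stop("quantizer bins do not partition [0,93]")
  lut
}

#' Quantize quality values
#'
#' Maps each value to its bin representative; idempotent when the
#' representatives lie inside their own bins (as in the default scheme).
#'
#' @param quals integer Phred values in \[0,93\] (values outside are a hard
#'   error).
#' @param bins bin table as in [default_quant_bins()]; must partition
#'   \[0,93\].
#' @export
quantize <- function(quals, bins = default_quant_bins()) {
  lut <- quant_lookup(bins)
  q <- as.integer(quals)
  if (length(q) && (min(q) < 0L || max(q) > 93L))
    stop("quality value outside [0,93]")
  lut[q + 1L]
}

#' P-block horizontal smoothing
#'
#' Greedy left-to-right blocking: the current block is extended while the
#' spread (max - min) of its *original* values stays within `2p`; on close
#' every position in the block takes `floor((max + min) / 2)`.  Hence every
#' output value is within `p` of its input and `p = 0` is the identity.
#' Applied by the rewriter only to stretches of kept (verbatim) qualities.
#'
#' @param quals integer Phred values.
#' @param p maximum tolerated deviation (>= 0).
#' @return smoothed integer vector; 1-based block start indices in
#'   `attr(, "block_starts")`.
#' @export
pblock_smooth <- function(quals, p) {
  stopifnot(p >= 0)
  r <- cpp_pblock(as.integer(quals), as.integer(p))
  structure(r$values, block_starts = r$starts)
}

#' Quality rewrite policy
#'
#' @param qual_high constant substituted for bases agreeing with a confident
#'   consensus call.
#' @param disagree_mode what happens to bases that disagree with a confident
#'   call (and to soft-clipped/inserted bases, which have no column):
#'   `"low"` (constant `qual_low`), `"quantize"` (bin lookup) or `"keep"`.
#' @param qual_low the constant for `disagree_mode = "low"`.
#' @param quant_bins quantizer table (see [default_quant_bins()]).
#' @param pblock_p P-block parameter for kept stretches; 0 disables.
#' @param preset_level informational preset level (1..9) this policy came
#'   from, if any.
#' @export
quality_policy <- function(qual_high = 40L, disagree_mode = c("low", "quantize", "keep"),
                           qual_low = 10L, quant_bins = default_quant_bins(),
                           pblock_p = 0L, preset_level = NULL) {
  disagree_mode <- match.arg(disagree_mode)
  stopifnot(qual_high >= 0, qual_high <= 93, qual_low >= 0, qual_low <= 93,
            pblock_p >= 0)
  quant_lookup(quant_bins)  # validates the partition
  structure(list(qual_high = as.integer(qual_high),
                 disagree_mode = disagree_mode,
                 qual_low = as.integer(qual_low),
                 quant_bins = quant_bins,
                 pblock_p = as.integer(pblock_p),
                 preset_level = preset_level),
            class = "quality_policy")
}

# shared driver: rewrite quality strings for a subset of reads against
# span-aligned call/mask vectors (all 0-based, span = attr(calls, "span"))
rewrite_core <- function(reads, read_id, calls, mask, policy, cparams) {
  span <- attr(calls, "span")
  conf <- is_confident(calls$phred_conf, cparams)
  g1 <- match(calls$g1, QC_BASES) - 1L
  g2 <- match(calls$g2, QC_BASES) - 1L
  maskv <- mask_to_vector(mask, span)
  whole <- read_id %in% mask$whole_read_ids
  mode <- match(policy$disagree_mode, c("low", "quantize", "keep")) - 1L
  cpp_rewrite_reads(reads$pos - 1L, reads$cigar, reads$seq, reads$qual,
                    whole, span[1], maskv, conf, g1, g2,
                    policy$qual_high, mode, policy$qual_low,
                    quant_lookup(policy$quant_bins), policy$pblock_p)
}

#' Rewrite one read's quality string
#'
#' Applies the quality budget to a single read: whole-retained reads come
#' back verbatim; bases inside a mask interval are kept (then P-block
#' smoothed if enabled); aligned bases agreeing with a confident call take
#' `qual_high`; everything else (disagreeing, unconfident-and-unmasked,
#' soft-clipped, inserted) follows `disagree_mode`.  Soft-clip bases are
#' projected through the alignment (left clips before `pos`, right clips
#' past the aligned end) when testing mask membership.  All non-quality
#' fields are returned untouched.  A confident call missing for a covered
#' locus is a hard error: it means the calls do not cover the read's span.
#'
#' @param read one-row record table (needs `pos`, `cigar`, `seq`, `qual`).
#' @param mask a [assemble_mask()] retention mask.
#' @param calls a [call_consensus()] table covering the read's aligned span.
#' @param policy a [quality_policy()].
#' @param params [caller_params()] supplying the confidence bar.
#' @param read_id id used to test whole-read retention.
#' @return the read with its `qual` replaced.
#' @export
rewrite_read <- function(read, mask, calls, policy = quality_policy(),
                         params = caller_params(), read_id = 1L) {
  stopifnot(nrow(read) == 1L)
  read$qual <- rewrite_core(read, read_id, calls, mask, policy, params)
  read
}
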