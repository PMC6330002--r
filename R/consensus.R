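#' Caller parameters
#'
#' @param max_phred_cap ceiling on per-base evidence: the effective quality
#'   of an entry is `min(qual, mapq, max_phred_cap)`.
#' @param mapq_floor value substituted for MAPQ 255 ("unavailable") when the
#'   pipeline builds pileups.
#' @param conf_threshold Phred bar for a "confident" call (inclusive); may be
#'   `Inf`, in which case nothing is confident and every covered locus ends
#'   up retained.
#' @return a list of class `"caller_params"`.
#' @export
caller_params <- function(max_phred_cap = 40L, mapq_floor = 30L,
                          conf_threshold = 30) {
  stopifnot(max_phred_cap >= 0, mapq_floor >= 0, conf_threshold >= 0)
  structure(list(max_phred_cap = as.integer(max_phred_cap),
                 mapq_floor = as.integer(mapq_floor),
                 conf_threshold = conf_threshold),
            class = "caller_params")
}

#' Call the diploid consensus over every locus of a pileup
#'
#' For each column the most likely of the 15 unordered genotypes over
#' \{A,C,G,T,*\} is found by exact log-space enumeration under a flat prior
#' (no reference, hence no reference bias).  Per entry with base `b` and
#' effective error `e = 10^(-min(qual, mapq, cap)/10)`:
#' homozygous `g`: `P(b) = 1-e` if `b == g`, else `e/4`; heterozygous
#' \{g1,g2\}: `P(b) = (1-e)/2 + e/8` if `b` is an allele, else `e/4`.
#' `raw_conf` is the Phred-scaled posterior of the winner, capped at 99;
#' `phred_conf` is the deliberately pessimistic adjustment
#' `max(0, raw_conf - sum of min(qual, mapq) over mismatching entries)`.
#' `N` bases carry no information: they are skipped by the likelihood and
#' the penalty but still count toward depth.  Ties prefer homozygotes, then
#' alleles in A<C<G<T<* order, so the caller is deterministic.
#'
#' @param pu a [build_pileup()] object.
#' @param params [caller_params()].
#' @param mapq_low entries with `mapq` below this count into the per-locus
#'   low-MAPQ tally reported in the attributes (used by [detect_low_mapq()]).
#' @return data.frame of class `"consensus_calls"`, one row per locus in the
#'   pileup span: `pos` (0-based), `g1`, `g2` (characters, `"N"` for
#'   no-call), `raw_conf`, `phred_conf`, `depth`, `n_alleles`; base count
#'   matrix and low-MAPQ counts in attributes.
#' @export
call_consensus <- function(pu, params = caller_params(), mapq_low = 0L) {
  stopifnot(inherits(pu, "pileup"))
  cc <- cpp_call_columns(pu$offsets, pu$base, pu$qual, pu$mapq,
                         params$max_phred_cap, as.integer(mapq_low))
  ns <- length(pu$offsets) - 1L
  pos <- if (ns > 0L) pu$span[1] + 0:(ns - 1L) else integer()
  out <- data.frame(pos = pos,
                    g1 = QC_BASES[cc$g1 + 1L], g2 = QC_BASES[cc$g2 + 1L],
                    raw_conf = cc$raw_conf,
                    phred_conf = pmax(0, cc$raw_conf - cc$penalty),
                    depth = cc$depth, n_alleles = cc$n_alleles)
  attr(out, "counts") <- cc$counts       # 6 x ns matrix, rows A,C,G,T,*,N
  attr(out, "n_lowmapq") <- cc$n_lowmapq
  attr(out, "penalty") <- cc$penalty
  attr(out, "span") <- pu$span
  class(out) <- c("consensus_calls", "data.frame")
  out
}

as_column <- function(col) {
  # accept data.frame(base, qual, mapq) with base as character symbols
  stopifnot(all(c("base", "qual", "mapq") %in% names(col)))
  list(base = qc_base_code(as.character(col$base)),
       qual = as.integer(col$qual), mapq = as.integer(col$mapq))
}

#' Genotype a single pileup column
#'
#' Single-column interface to the same engine as [call_consensus()].  An
#' empty column yields the `("N","N")` no-call sentinel with confidence 0.
#' The returned `phred_conf` equals `raw_conf`; apply [pessimistic_adjust()]
#' to discount mismatching evidence.
#'
#' @param col data.frame with columns `base` (symbols among A,C,G,T,*,N),
#'   `qual`, `mapq`.
#' @param params [caller_params()].
#' @param pos optional 0-based coordinate carried through.
#' @return list of class `"genotype_call"`: `pos`, `genotype` (length-2
#'   character), `phred_conf`, `raw_conf`, `allele_count`, `depth`.
#' @export
genotype_call <- function(col, params = caller_params(), pos = NA_integer_) {
  cl <- as_column(col)
  n <- length(cl$base)
  cc <- cpp_call_columns(c(0L, n), cl$base, cl$qual, cl$mapq,
                         params$max_phred_cap, 0L)
  structure(list(pos = pos,
                 genotype = QC_BASES[c(cc$g1, cc$g2) + 1L],
                 phred_conf = cc$raw_conf,
                 raw_conf = cc$raw_conf,
                 allele_count = cc$n_alleles,
                 depth = cc$depth),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("genotype (%s/%s)  conf %.1f (raw %.1f)  depth %d, %d allele(s)\n",
              x$genotype[1], x$genotype[2], x$phred_conf, x$raw_conf,
              x$depth, x$allele_count))
  invisible(x)
}

#' Pessimistic confidence adjustment
#'
#' Reduces the call confidence by `min(qual, mapq)` summed over entries
#' whose base is not an allele of the called genotype (`N` entries excluded:
#' they carry no evidence either way), floored at 0.  Idempotent: the
#' adjustment always starts from `raw_conf`.
#'
#' @param call a [genotype_call()].
#' @param col the column the call was made on.
#' @return the call with `phred_conf` reduced.
#' @export
pessimistic_adjust <- function(call, col) {
  stopifnot(inherits(call, "genotype_call"))
  cl <- as_column(col)
  mm <- !(QC_BASES[cl$base + 1L] %in% call$genotype) & cl$base != 5L
  pen <- sum(pmin(cl$qual, cl$mapq)[mm])
  call$phred_conf <- max(0, call$raw_conf - pen)
  call
}

#' Is a call confident?
#'
#' `TRUE` iff `phred_conf >= conf_threshold` (boundary inclusive).  Also
#' accepts a bare numeric vector of confidences.
#'
#' @param call a [genotype_call()], [call_consensus()] table, or numeric.
#' @param params [caller_params()].
#' @export
is_confident <- function(call, params = caller_params()) {
  conf <- if (inherits(call, "genotype_call")) call$phred_conf
          else if (is.data.frame(call)) call$phred_conf
          else as.numeric(call)
  conf >= params$conf_threshold
}
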