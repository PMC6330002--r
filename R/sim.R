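#' Simulate coordinate-sorted alignments with known truth
#'
#' Fixture generator for the whole pipeline: a random reference window, a
#' diploid pair of haplotypes carrying SNPs and short indels at configurable
#' density, uniformly placed reads with Phred-calibrated base errors, and
#' optional planted anomalies (a large novel insertion producing concordant
#' soft clips, a collapsed repeat producing doubled depth, a low-MAPQ tract,
#' a short tandem repeat).  Everything is reproducible from `seed` and
#' reported in a truth table.
#'
#' Base qualities are drawn from `clamp(round(Normal(mean, sd)), range)`
#' (default Normal(37,3) clamped to \[2,41\], mimicking modern Illumina; use
#' a larger `qual_sd`/range for legacy many-level data).  Errors are always
#' injected per base with probability `10^(-q/10)`.  When `err_rate` is
#' given, the Normal mean is re-calibrated by root finding so that the
#' expected per-base error of the discretised distribution equals
#' `err_rate`, keeping the realised mismatch rate binomially consistent
#' with the target; `err_rate = 0` disables errors.
#'
#' @param ref_len reference window length (bp).
#' @param depth target mean coverage; the read count is
#'   `round(depth * ref_len / read_len)`.
#' @param read_len read length (query bases).
#' @param err_rate target mean base-error rate in `[0, 1)`, or `NULL` to use
#'   `qual_mean` as-is.
#' @param var_density per-bp probability of a germline variant (90% SNP,
#'   5% short insertion, 5% short deletion).
#' @param het_fraction fraction of variants that are heterozygous (placed on
#'   haplotype 2 only).
#' @param anomalies list with optional elements `insertion =
#'   list(pos, len)`, `collapsed_repeat = list(start, end)`,
#'   `low_mapq = list(start, end, frac = 0.5, mapq = 0)`,
#'   `str = list(pos, unit, copies)`; positions 0-based.
#' @param seed RNG seed (the simulation is a pure function of seed+params).
#' @param qual_mean,qual_sd,qual_range quality distribution knobs.
#' @param base_mapq MAPQ assigned outside the low-MAPQ anomaly.
#' @param str_free scrub the random reference of any tandem repeat with unit
#'   <= 4 and >= 3 exact copies (for clean-control fixtures).
#' @param rname reference name used in the records.
#' @return list with `records` (coordinate-sorted table, SAM header in its
#'   attribute) and `truth` (`reference`, `variants`, `anomalies`,
#'   `qual_mean_used`, `seed`).
#' @export
simulate_alignments <- function(ref_len = 20000L, depth = 30, read_len = 100L,
                                err_rate = NULL, var_density = 0.001,
                                het_fraction = 0.5, anomalies = list(),
                                seed = 1L, qual_mean = 37, qual_sd = 3,
                                qual_range = c(2L, 41L), base_mapq = 60L,
                                str_free = FALSE, rname = "ref") {
  ref_len <- as.integer(ref_len); read_len <- as.integer(read_len)
  if (read_len > ref_len) stop("read_len exceeds ref_len")
  if (depth <= 0) stop("depth must be positive")
  if (!is.null(err_rate) && (err_rate < 0 || err_rate >= 1))
    stop("err_rate must be in [0,1)")
  set.seed(seed)

  refv <- sample(c("A", "C", "G", "T"), ref_len, replace = TRUE)
  if (str_free) refv <- scrub_str(refv)
  if (!is.null(anomalies$str)) {
    a <- anomalies$str
    tract <- strsplit(strrep(a$unit, a$copies), "")[[1]]
    refv[(a$pos + 1L):(a$pos + length(tract))] <- tract
    anomalies$str$span <- c(a$pos, a$pos + length(tract))
  }

  # --- germline variants ----------------------------------------------------
  vpos <- which(runif(ref_len) < var_density)               # 1-based
  vpos <- vpos[vpos > 10L & vpos < ref_len - 10L]
  if (length(vpos) > 1L) vpos <- vpos[c(TRUE, diff(vpos) > 10L)]
  # keep variants clear of planted features
  avoid <- function(p, span, margin) p <= span[1] - margin | p > span[2] + margin
  if (!is.null(anomalies$str)) vpos <- vpos[avoid(vpos, anomalies$str$span + 1L, 10L)]
  if (!is.null(anomalies$insertion))
    vpos <- vpos[abs(vpos - anomalies$insertion$pos) > read_len]
  nv <- length(vpos)
  vtype <- if (nv) sample(c("SNP", "ins", "del"), nv, replace = TRUE,
                          prob = c(0.9, 0.05, 0.05)) else character()
  vhet <- if (nv) runif(nv) < het_fraction else logical()
  vlen <- ifelse(vtype == "SNP", 1L, sample(1:4, max(nv, 1L), replace = TRUE)[seq_len(nv)])
  # deletions must not run past the window or into the next variant
  if (nv) {
    room <- c(diff(vpos), ref_len - 5L - vpos[nv])
    vlen <- pmin(vlen, pmax(1L, room - 6L))
  }
  valt <- character(nv); vref <- character(nv)
  hap1v <- refv; hap2v <- refv
  for (i in seq_len(nv)) {
    p <- vpos[i]
    if (vtype[i] == "SNP") {
      vref[i] <- refv[p]
      valt[i] <- sample(setdiff(c("A", "C", "G", "T"), refv[p]), 1L)
      hap2v[p] <- valt[i]
      if (!vhet[i]) hap1v[p] <- valt[i]
    } else if (vtype[i] == "ins") {
      vref[i] <- ""
      valt[i] <- paste(sample(c("A", "C", "G", "T"), vlen[i], replace = TRUE),
                       collapse = "")
    } else {
      vref[i] <- paste(refv[p:(p + vlen[i] - 1L)], collapse = "")
      valt[i] <- ""
    }
  }
  variants <- data.frame(pos0 = vpos - 1L, type = vtype, len = vlen,
                         ref = vref, alt = valt,
                         zygosity = ifelse(vhet, "het", "hom"))
  indels <- variants[variants$type != "SNP", , drop = FALSE]
  hap_str <- c(paste(hap1v, collapse = ""), paste(hap2v, collapse = ""))
  ind_by_hap <- list(indels[indels$zygosity == "hom", , drop = FALSE], indels)

  # --- read placement -------------------------------------------------------
  n_reads <- as.integer(round(depth * ref_len / read_len))
  start1 <- sample.int(ref_len - read_len + 1L, n_reads, replace = TRUE)
  if (!is.null(anomalies$collapsed_repeat)) {
    cr <- anomalies$collapsed_repeat
    n_extra <- as.integer(round(depth * (cr$end - cr$start) / read_len))
    lo <- max(1L, cr$start - read_len + 2L)
    hi <- min(cr$end, ref_len - read_len + 1L)
    start1 <- c(start1, sample(lo:hi, n_extra, replace = TRUE))
    n_reads <- n_reads + n_extra
  }
  hap <- sample(1:2, n_reads, replace = TRUE)
  rev <- runif(n_reads) < 0.5

  # reads overlapping an indel on their haplotype need a CIGAR walk;
  # everything else is a plain substring with an all-M CIGAR
  margin <- 8L
  complex <- logical(n_reads)
  for (h in 1:2) {
    ih <- ind_by_hap[[h]]
    if (nrow(ih) == 0L) next
    for (j in seq_len(nrow(ih))) {
      p <- ih$pos0[j] + 1L
      complex <- complex | (hap == h & start1 <= p + margin &
                            start1 + read_len + margin > p)
    }
  }
  seqs <- character(n_reads)
  cigars <- character(n_reads)
  pos_out <- start1
  for (h in 1:2) {
    sel <- !complex & hap == h
    seqs[sel] <- substring(hap_str[h], start1[sel], start1[sel] + read_len - 1L)
  }
  cigars[!complex] <- sprintf("%dM", read_len)
  for (i in which(complex)) {
    r <- sim_read_walk(hap_str[hap[i]], ind_by_hap[[hap[i]]], start1[i],
                       read_len, ref_len)
    seqs[i] <- r$seq; cigars[i] <- r$cigar; pos_out[i] <- r$pos
  }

  # --- large novel insertion -> concordant soft clips -----------------------
  if (!is.null(anomalies$insertion)) {
    a <- anomalies$insertion
    donor <- paste(sample(c("A", "C", "G", "T"),
                          max(a$len, read_len) + read_len, replace = TRUE),
                   collapse = "")
    bp <- a$pos                                   # 0-based breakpoint
    cross <- !complex & (pos_out - 1L) < bp & (pos_out - 1L + read_len) > bp
    for (i in which(cross)) {
      k <- bp - (pos_out[i] - 1L)                 # aligned bases left of bp
      if (k >= read_len %/% 2L) {                 # clip on the right
        seqs[i] <- paste0(substr(seqs[i], 1L, k), substr(donor, 1L, read_len - k))
        cigars[i] <- sprintf("%dM%dS", k, read_len - k)
      } else {                                    # clip on the left
        c_len <- read_len - (read_len - k)        # == k
        c_len <- k
        seqs[i] <- paste0(substr(donor, nchar(donor) - c_len + 1L, nchar(donor)),
                          substring(hap_str[hap[i]], bp + 1L, bp + read_len - c_len))
        cigars[i] <- sprintf("%dS%dM", c_len, read_len - c_len)
        pos_out[i] <- bp + 1L
      }
    }
    anomalies$insertion$breakpoint <- bp
  }

  # --- qualities and sequencing errors --------------------------------------
  lens <- nchar(seqs)
  totB <- sum(lens)
  mu <- qual_mean
  if (!is.null(err_rate) && err_rate > 0)
    mu <- calibrate_qual_mean(err_rate, qual_sd, qual_range)
  qall <- pmin(pmax(as.integer(round(rnorm(totB, mu, qual_sd))),
                    qual_range[1]), qual_range[2])
  if (is.null(err_rate) || err_rate > 0) {
    err <- runif(totB) < 10^(-qall / 10)
    if (any(err)) {
      ridx <- rep.int(seq_len(n_reads), lens)
      off <- sequence(lens)
      ei <- which(err)
      for (i in ei) {
        old <- substr(seqs[ridx[i]], off[i], off[i])
        substr(seqs[ridx[i]], off[i], off[i]) <-
          sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      }
    }
  }
  bigq <- rawToChar(as.raw(qall + 33L))
  ends <- cumsum(lens)
  quals <- substring(bigq, ends - lens + 1L, ends)

  mapq <- rep(as.integer(base_mapq), n_reads)
  if (!is.null(anomalies$low_mapq)) {
    a <- anomalies$low_mapq
    frac <- if (is.null(a$frac)) 0.5 else a$frac
    mval <- if (is.null(a$mapq)) 0L else as.integer(a$mapq)
    ov <- (pos_out - 1L) < a$end & (pos_out - 1L + read_len) > a$start
    hitlow <- ov & runif(n_reads) < frac
    mapq[hitlow] <- mval
    anomalies$low_mapq$n_reads <- sum(hitlow)
  }

  ord <- order(pos_out)
  rec <- data.table::data.table(
    qname = sprintf("sim%06d", seq_len(n_reads)),
    flag = ifelse(rev[ord], 16L, 0L),
    rname = rname, pos = pos_out[ord], mapq = mapq[ord],
    cigar = cigars[ord], rnext = "*", pnext = "0", tlen = "0",
    seq = seqs[ord], qual = quals[ord], aux = "")
  attr(rec, "header") <- c("@HD\tVN:1.6\tSO:coordinate",
                           sprintf("@SQ\tSN:%s\tLN:%d", rname, ref_len))
  list(records = rec,
       truth = list(reference = paste(refv, collapse = ""),
                    variants = variants, anomalies = anomalies,
                    qual_mean_used = mu, seed = seed,
                    n_reads = n_reads, read_len = read_len))
}

# choose the Normal mean whose discretised/clamped quality distribution has
# expected phred->prob error equal to the target
calibrate_qual_mean <- function(target, sd, range) {
  q <- range[1]:range[2]
  f <- function(mu) {
    lo <- q - 0.5; hi <- q + 0.5
    lo[1] <- -Inf; hi[length(q)] <- Inf
    p <- pnorm(hi, mu, sd) - pnorm(lo, mu, sd)
    sum(p * 10^(-q / 10)) - target
  }
  if (f(range[1]) < 0 || f(range[2]) > 0)
    stop("err_rate ", target, " not achievable with quality range [",
         range[1], ",", range[2], "]")
  uniroot(f, c(range[1], range[2]), tol = 1e-8)$root
}

# remove every tandem repeat with unit <= 4 and >= 3 exact copies by
# re-drawing the offending bases (regex back-references; independent of the
# package's own STR detector)
scrub_str <- function(refv, max_iter = 100L) {
  pats <- sprintf("([ACGT]{%d})\\1{2,}", 1:4)
  for (it in seq_len(max_iter)) {
    s <- paste(refv, collapse = "")
    hit <- FALSE
    for (pat in pats) {
      m <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      hit <- TRUE
      for (j in seq_along(m)) {
        idx <- m[j]:(m[j] + attr(m, "match.length")[j] - 1L)
        refv[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
      }
    }
    if (!hit) return(refv)
  }
  stop("could not scrub reference of short tandem repeats")
}

# CIGAR walk for a read overlapping indel variants on its haplotype.
# hap_str carries the SNPs; indels are applied on the fly at their reference
# coordinates (insertion before pos0+1, deletion covering pos0..pos0+len-1).
sim_read_walk <- function(hap_str, indels, start1, read_len, ref_len) {
  ind <- indels[order(indels$pos0), , drop = FALSE]
  r <- start1                       # 1-based reference cursor
  # never start inside a deletion
  for (j in seq_len(nrow(ind))) {
    if (ind$type[j] == "del" && r > ind$pos0[j] + 1L &&
        r <= ind$pos0[j] + ind$len[j]) r <- ind$pos0[j] + ind$len[j] + 1L
  }
  pos <- r
  sq <- character(0)
  ops <- character(0); opl <- integer(0)
  push <- function(op, len) {
    if (len <= 0L) return()
    if (length(ops) && ops[length(ops)] == op)
      opl[length(opl)] <<- opl[length(opl)] + len
    else { ops[length(ops) + 1L] <<- op; opl[length(opl) + 1L] <<- len }
  }
  q <- 0L
  while (q < read_len && r <= ref_len) {
    nxt <- ind$pos0[ind$pos0 + 1L >= r]
    nxt_p <- if (length(nxt)) min(nxt) + 1L else ref_len + 1L
    seg <- min(nxt_p - r, read_len - q, ref_len - r + 1L)
    if (seg > 0L) {
      sq <- c(sq, substring(hap_str, r, r + seg - 1L))
      push("M", seg)
      r <- r + seg; q <- q + seg
    }
    if (q >= read_len || r > ref_len) break
    j <- which(ind$pos0 + 1L == r)[1]
    if (is.na(j)) next
    if (ind$type[j] == "ins") {
      if (q > 0L) {
        k <- min(nchar(ind$alt[j]), read_len - q)
        sq <- c(sq, substring(ind$alt[j], 1L, k))
        push("I", k)
        q <- q + k
      }
      # the inserted copy is consumed; continue with the reference base at r
      sq <- c(sq, substring(hap_str, r, r))
      push("M", 1L)
      r <- r + 1L; q <- q + 1L
    } else {
      if (q > 0L) push("D", ind$len[j])
      r <- r + ind$len[j]
      if (q == 0L) pos <- r
    }
  }
  list(seq = paste(sq, collapse = ""),
       cigar = paste0(opl, ops, collapse = ""),
       pos = pos)
}
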