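# independent oracles, deliberately written with different algorithms /
# code paths than the package internals they check

# brute-force 15-genotype enumeration with the same emission model
# (hom: 1-e vs e/4; het: (1-e)/2 + e/8 vs e/4), flat prior, rule-based
# tie-break (prefer homozygous, then lexicographic A<C<G<T<*)
oracle_genotype <- function(base, qual, mapq, cap = 40) {
  B <- c("A", "C", "G", "T", "*")
  inf <- base != "N"
  if (!any(inf)) return(list(genotype = c("N", "N"), raw_conf = 0))
  b <- base[inf]
  qe <- pmin(qual[inf], mapq[inf], cap)
  qe[qe < 0] <- 0
  e <- 10^(-qe / 10)
  gset <- list(); k <- 0L
  for (i in 1:5) for (j in i:5) { k <- k + 1L; gset[[k]] <- c(i, j) }
  ll <- vapply(gset, function(g) {
    if (g[1] == g[2]) p <- ifelse(b == B[g[1]], 1 - e, e / 4)
    else p <- ifelse(b == B[g[1]] | b == B[g[2]], (1 - e) / 2 + e / 8, e / 4)
    sum(log(p))
  }, numeric(1))
  best_ll <- max(ll)
  ties <- which(ll == best_ll)
  hom <- vapply(gset[ties], function(g) g[1] == g[2], logical(1))
  ord <- order(!hom,
               vapply(gset[ties], `[`, integer(1), 1L),
               vapply(gset[ties], `[`, integer(1), 2L))
  best <- ties[ord[1]]
  s_others <- sum(exp(ll[-best] - best_ll))
  raw <- if (s_others <= 0) 99 else -10 * log10(s_others / (1 + s_others))
  names(ll) <- vapply(gset, function(g) paste(B[g], collapse = ""), character(1))
  list(genotype = B[gset[[best]]], raw_conf = min(raw, 99), ll = ll)
}

# oracle log-likelihood of an arbitrary genotype (unordered character pair)
oracle_ll_of <- function(or, genotype) {
  g <- sort(factor(genotype, levels = c("A", "C", "G", "T", "*")))
  or$ll[[paste(as.character(g), collapse = "")]]
}

oracle_penalty <- function(base, qual, mapq, genotype) {
  mm <- !(base %in% genotype) & base != "N"
  sum(pmin(qual, mapq)[mm])
}

# reference greedy P-block
oracle_pblock <- function(x, p) {
  n <- length(x)
  out <- integer(n); starts <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i; mn <- x[i]; mx <- x[i]
    while (j < n && max(mx, x[j + 1L]) - min(mn, x[j + 1L]) <= 2L * p) {
      j <- j + 1L
      mn <- min(mn, x[j]); mx <- max(mx, x[j])
    }
    out[i:j] <- (mn + mx) %/% 2L
    starts <- c(starts, i)
    i <- j + 1L
  }
  list(values = out, starts = starts)
}

# paint-and-scan interval union over [lo, hi)
oracle_paint <- function(intervals, lo, hi) {
  v <- logical(hi - lo)
  for (i in seq_len(nrow(intervals))) {
    a <- max(intervals$start[i], lo); b <- min(intervals$end[i], hi)
    if (b > a) v[(a - lo + 1L):(b - lo)] <- TRUE
  }
  v
}

# quadratic tandem-repeat scan: paint every position inside a maximal
# periodic stretch with unit <= umax and >= minc exact copies
oracle_str_paint <- function(s, umax, minc) {
  n <- length(s)
  keep <- logical(n)
  for (i in seq_len(n)) {
    for (u in seq_len(min(umax, n - i))) {
      if (s[i] == "N") break
      m <- 0L
      while (i + m + u <= n && s[i + m] != "N" && s[i + m] == s[i + m + u]) m <- m + 1L
      if ((m + u) %/% u >= minc) keep[i:(i + m + u - 1L)] <- TRUE
    }
  }
  keep
}

# per-base re-derivation of the rewrite rules, walking the CIGAR in R
oracle_rewrite <- function(read, read_id, calls, mask, policy, cparams) {
  if (read_id %in% mask$whole_read_ids) return(read$qual)
  span <- attr(calls, "span")
  maskv <- oracle_paint(mask$intervals, span[1], span[2])
  conf <- calls$phred_conf >= cparams$conf_threshold
  q <- phred_ints(read$qual)
  s <- strsplit(read$seq, "")[[1]]
  keep <- logical(length(q))
  toks <- regmatches(read$cigar, gregexpr("\\d+[MIDNSHP=X]", read$cigar))[[1]]
  lens <- as.integer(sub(".$", "", toks))
  ops <- sub("^\\d+", "", toks)
  bins <- policy$quant_bins
  quant1 <- function(v) bins$q[bins$lo <= v & v <= bins$hi]
  apply_mode <- function(at) {
    if (policy$disagree_mode == "low") q[at] <<- policy$qual_low
    else if (policy$disagree_mode == "quantize") q[at] <<- vapply(q[at], quant1, integer(1))
    else keep[at] <<- TRUE
  }
  r <- read$pos - 1L; qi <- 0L; seen_ref <- FALSE
  for (t in seq_along(ops)) {
    op <- ops[t]; len <- lens[t]
    if (op %in% c("M", "=", "X")) {
      for (k in 0:(len - 1L)) {
        idx <- r + k - span[1] + 1L
        at <- qi + k + 1L
        if (maskv[idx]) keep[at] <- TRUE
        else if (conf[idx] && s[at] %in% c(calls$g1[idx], calls$g2[idx]))
          q[at] <- policy$qual_high
        else apply_mode(at)
      }
      r <- r + len; qi <- qi + len; seen_ref <- TRUE
    } else if (op %in% c("D", "N")) {
      r <- r + len; seen_ref <- TRUE
    } else if (op %in% c("I", "S")) {
      for (k in 0:(len - 1L)) {
        proj <- if (op == "I") r
                else if (seen_ref) r + k
                else (read$pos - 1L) - len + k
        idx <- proj - span[1] + 1L
        at <- qi + k + 1L
        if (idx >= 1L && idx <= length(maskv) && maskv[idx]) keep[at] <- TRUE
        else apply_mode(at)
      }
      qi <- qi + len
    }
  }
  if (policy$pblock_p > 0L) {
    rl <- rle(keep)
    en <- cumsum(rl$lengths); st <- en - rl$lengths + 1L
    for (t in which(rl$values))
      q[st[t]:en[t]] <- oracle_pblock(q[st[t]:en[t]], policy$pblock_p)$values
  }
  phred_string(q)
}
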