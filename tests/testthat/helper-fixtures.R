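# in-code fixtures: no files, everything is built programmatically

# a one-or-more-row record table from parallel vectors
make_reads <- function(pos, cigar, seq, qual, mapq = 60L, flag = 0L,
                       qname = NULL, rname = "ref") {
  n <- length(pos)
  if (is.numeric(qual[[1]])) qual <- vapply(qual, phred_string, character(1))
  data.frame(qname = if (is.null(qname)) sprintf("r%03d", seq_len(n)) else qname,
             flag = rep_len(as.integer(flag), n), rname = rname,
             pos = as.integer(pos), mapq = rep_len(as.integer(mapq), n),
             cigar = cigar, rnext = "*", pnext = "0", tlen = "0",
             seq = seq, qual = unlist(qual), aux = "",
             stringsAsFactors = FALSE)
}

phred_string <- function(q) rawToChar(as.raw(as.integer(q) + 33L))
phred_ints <- function(s) utf8ToInt(s) - 33L

# single pileup column as the data.frame the consensus ops accept
make_column <- function(base, qual, mapq = 60L) {
  data.frame(base = base, qual = as.integer(qual),
             mapq = rep_len(as.integer(mapq), length(base)))
}

random_column <- function(max_depth = 8L, bases = c("A","C","G","T","*","N")) {
  n <- sample(0:max_depth, 1L)
  make_column(sample(bases, n, replace = TRUE,
                     prob = c(0.35, 0.25, 0.15, 0.1, 0.1, 0.05)),
              sample(2:41, n, replace = TRUE),
              sample(c(0L, 10L, 20L, 40L, 60L), n, replace = TRUE))
}

# a consensus-calls shaped table whose first allele spells a given sequence
# (for driving the STR detector directly)
calls_from_seq <- function(s, start = 0L) {
  ch <- strsplit(s, "")[[1]]
  out <- data.frame(pos = start + seq_along(ch) - 1L, g1 = ch, g2 = ch,
                    raw_conf = 99, phred_conf = 99,
                    depth = 10L, n_alleles = 1L)
  attr(out, "span") <- c(start, start + length(ch))
  class(out) <- c("consensus_calls", "data.frame")
  out
}
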