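#' Quality-stream statistics
#'
#' Summaries of a set of quality strings treated as one concatenated symbol
#' stream: distinct symbol count, order-0 Shannon entropy (bits/symbol) and
#' gzip-compressed size (a cheap proxy for what a real codec would achieve).
#'
#' @param qual character vector of Phred+33 quality strings (or a record
#'   table, whose `qual` column is used).
#' @return list with `n_symbols`, `distinct_symbols`, `entropy_bits`,
#'   `gzip_bytes`.
#' @export
quality_stats <- function(qual) {
  if (is.data.frame(qual)) qual <- qual$qual
  stream <- paste(qual, collapse = "")
  n <- nchar(stream)
  if (n == 0L)
    return(list(n_symbols = 0L, distinct_symbols = 0L,
                entropy_bits = 0, gzip_bytes = 0L))
  codes <- utf8ToInt(stream)
  tab <- tabulate(codes + 1L, 256L)
  p <- tab[tab > 0] / n
  list(n_symbols = n,
       distinct_symbols = sum(tab > 0),
       entropy_bits = -sum(p * log2(p)),
       gzip_bytes = length(memCompress(charToRaw(stream), type = "gzip")))
}

#' Compare quality streams before and after compression
#'
#' @param qual_in,qual_out quality strings (or record tables).
#' @return data.frame with one row per stream plus the gzip fold-reduction
#'   in `attr(, "gzip_fold")`.
#' @export
compression_summary <- function(qual_in, qual_out) {
  a <- quality_stats(qual_in)
  b <- quality_stats(qual_out)
  out <- data.frame(stream = c("input", "output"),
                    n_symbols = c(a$n_symbols, b$n_symbols),
                    distinct_symbols = c(a$distinct_symbols, b$distinct_symbols),
                    entropy_bits = c(a$entropy_bits, b$entropy_bits),
                    gzip_bytes = c(a$gzip_bytes, b$gzip_bytes))
  attr(out, "gzip_fold") <- a$gzip_bytes / max(1L, b$gzip_bytes)
  out
}
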