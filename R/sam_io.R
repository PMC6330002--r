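#' Read a coordinate-sorted SAM or BAM file
#'
#' SAM text is parsed directly; `.bam`/`.cram` input is converted through
#' `samtools view` (samtools must be on the PATH).  The first eleven fields
#' are split out; everything after the eleventh tab (the auxiliary tags) is
#' kept as one opaque string so that records can be re-emitted byte-identical.
#'
#' @param path input file (`.sam`, `.bam` or `.cram`).
#' @return a `data.table` with columns `qname`, `flag`, `rname`, `pos`
#'   (1-based, as in SAM), `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`,
#'   `qual`, `aux`; header lines are in `attr(, "header")`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.(bam|cram)$", path, ignore.case = TRUE)) {
    if (Sys.which("samtools") == "")
      stop("BAM/CRAM input needs samtools on the PATH")
    lines <- system2("samtools", c("view", "-h", shQuote(path)), stdout = TRUE)
    if (!is.null(attr(lines, "status")))
      stop("samtools failed reading ", path)
  } else {
    lines <- readLines(path)
  }
  is_hdr <- startsWith(lines, "@")
  header <- lines[is_hdr]
  body <- lines[!is_hdr]
  rec <- parse_sam_lines(body)
  attr(rec, "header") <- header
  rec
}

parse_sam_lines <- function(lines) {
  n <- length(lines)
  if (n == 0L) {
    rec <- data.table::data.table(
      qname = character(), flag = integer(), rname = character(),
      pos = integer(), mapq = integer(), cigar = character(),
      rnext = character(), pnext = character(), tlen = character(),
      seq = character(), qual = character(), aux = character())
    return(rec)
  }
  # split off the opaque aux remainder after the 11th tab
  m <- regexpr("^([^\t]*\t){11}", lines, perl = TRUE)
  ml <- attr(m, "match.length")
  has_aux <- m > 0L
  # records with fewer than 11 fields are truncated/malformed
  ntab <- nchar(lines) - nchar(gsub("\t", "", lines, fixed = TRUE))
  bad <- !has_aux & ntab != 10L
  if (any(bad))
    stop("truncated or malformed SAM record at body line ", which(bad)[1],
         " (", ntab[which(bad)[1]] + 1L, " fields)")
  head11 <- ifelse(has_aux, substring(lines, 1L, ml - 1L), lines)
  aux <- ifelse(has_aux, substring(lines, ml + 1L), "")
  f <- data.table::tstrsplit(head11, "\t", fixed = TRUE)
  data.table::data.table(
    qname = f[[1]], flag = as.integer(f[[2]]), rname = f[[3]],
    pos = as.integer(f[[4]]), mapq = as.integer(f[[5]]), cigar = f[[6]],
    rnext = f[[7]], pnext = f[[8]], tlen = f[[9]],
    seq = f[[10]], qual = f[[11]], aux = aux)
}

#' Write alignment records as SAM or BAM
#'
#' Records are emitted in their stored order.  With `drop_names` every
#' distinct read name is replaced by a minimal deterministic name
#' (`r1`, `r2`, ... in order of first appearance), so both mates of a pair
#' keep a shared name.  `drop_aux` removes the listed two-letter tags from
#' the auxiliary field; everything else is written byte-identical.  A `@PG`
#' line recording the tool and (policy-level) command line is appended to
#' the header.
#'
#' @param records a record table as returned by [read_alignments()] or
#'   [simulate_alignments()].
#' @param path output file; a `.bam` suffix triggers conversion via samtools.
#' @param drop_names replace read identifiers with a minimal scheme.
#' @param drop_aux character vector of aux tag names (e.g. `c("OQ","BI")`).
#' @param header header lines; defaults to `attr(records, "header")`.
#' @param cl command line recorded in the `@PG` line; `NULL` suppresses the
#'   `@PG` line entirely.
#' @return the output path, invisibly.
#' @export
write_alignments <- function(records, path, drop_names = FALSE,
                             drop_aux = character(), header = NULL,
                             cl = "qualcrunch") {
  if (is.null(header)) header <- attr(records, "header")
  if (is.null(header)) header <- "@HD\tVN:1.6\tSO:coordinate"
  qname <- records$qname
  if (drop_names && length(qname))
    qname <- paste0("r", match(qname, unique(qname)))
  aux <- records$aux
  if (is.null(aux)) aux <- rep("", nrow(records))
  if (length(drop_aux) && length(aux)) {
    for (tag in drop_aux) {
      pat <- paste0("(^|\t)", tag, ":[^\t]*")
      hit <- grepl(pat, aux)
      if (any(hit)) {
        parts <- strsplit(aux[hit], "\t", fixed = TRUE)
        aux[hit] <- vapply(parts, function(p)
          paste(p[substr(p, 1L, 2L) != tag], collapse = "\t"), character(1))
      }
    }
  }
  if (!is.null(cl)) {
    pg <- sprintf("@PG\tID:qualcrunch\tPN:qualcrunch\tVN:%s\tCL:%s",
                  as.character(utils::packageVersion("qualcrunch")), cl)
    header <- c(header, pg)
  }
  body <- if (nrow(records)) {
    line <- paste(qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar, records$rnext, records$pnext,
                  records$tlen, records$seq, records$qual, sep = "\t")
    ifelse(aux == "", line, paste(line, aux, sep = "\t"))
  } else character()
  out_lines <- c(header, body)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (Sys.which("samtools") == "")
      stop("BAM output needs samtools on the PATH")
    tmp <- tempfile(fileext = ".sam")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(out_lines, tmp)
    st <- system2("samtools", c("view", "-b", "-o", shQuote(path), shQuote(tmp)))
    if (st != 0L) stop("samtools failed writing ", path)
  } else {
    writeLines(out_lines, path)
  }
  invisible(path)
}

# reference span / clip summary for a vector of CIGARs
cigar_stats <- function(cigar) cpp_cigar_stats(as.character(cigar))

# error unless pos is non-decreasing within each contiguous rname block and
# no rname appears in two separate blocks
check_sorted <- function(records) {
  if (nrow(records) < 2L) return(invisible(TRUE))
  rn <- records$rname
  blocks <- rle(rn)$values
  if (anyDuplicated(blocks))
    stop("input not coordinate-sorted: reference ", blocks[duplicated(blocks)][1],
         " occurs in non-contiguous blocks")
  bad <- which(diff(records$pos) < 0 & rn[-1] == rn[-length(rn)])
  if (length(bad))
    stop("input not coordinate-sorted: read '", records$qname[bad[1] + 1L],
         "' (record ", bad[1] + 1L, ") starts before its predecessor")
  invisible(TRUE)
}
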