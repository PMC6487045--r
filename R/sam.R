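#' SAM flag bits
#'
#' Named constants for the SAM FLAG field, plus small predicates used across
#' the package. Flags are plain integers; test bits with [sam_flag_isset()].
#'
#' @format A named integer vector.
#' @export
SAM_FLAGS <- c(
  paired        = 1L,
  proper_pair   = 2L,
  unmapped      = 4L,
  mate_unmapped = 8L,
  reverse       = 16L,
  mate_reverse  = 32L,
  first_in_pair = 64L,
  second_in_pair = 128L,
  secondary     = 256L,
  qcfail        = 512L,
  duplicate     = 1024L,
  supplementary = 2048L
)

#' @param flag integer FLAG value(s).
#' @param name one of `names(SAM_FLAGS)`.
#' @return logical vector.
#' @rdname SAM_FLAGS
#' @export
sam_flag_isset <- function(flag, name) {
  bit <- SAM_FLAGS[[name]]
  bitwAnd(as.integer(flag), bit) != 0L
}

#' Read-pair segment of a record (0 = unpaired, 1 = first mate, 2 = second)
#' @param flag integer FLAG value(s).
#' @return integer vector in {0, 1, 2}.
#' @export
read_segment <- function(flag) {
  ifelse(sam_flag_isset(flag, "first_in_pair"), 1L,
         ifelse(sam_flag_isset(flag, "second_in_pair"), 2L, 0L))
}

.sam_record_cols <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
                      "rnext", "pnext", "tlen", "seq", "qual", "tags")

#' Read a SAM file
#'
#' Parses the plain-text SAM format: `@`-prefixed header lines are kept
#' verbatim; each record line must have at least the 11 mandatory
#' tab-separated fields. FLAG, POS and MAPQ are parsed as integers;
#' everything else, including any optional tags, is kept as the original
#' text so that [write_sam()] reproduces the input byte for byte.
#'
#' Positions are stored 1-based as in the file; coordinate arithmetic
#' elsewhere in the package converts to 0-based half-open internally.
#' Records whose SEQ is present but whose query-consuming CIGAR length does
#' not equal `nchar(SEQ)` trigger a warning naming the read (the record is
#' still returned).
#'
#' @param path path to a SAM file.
#' @return An object of class `"sam"`: a list with `header` (character
#'   vector of header lines) and `records` (data frame with columns
#'   `qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq, qual,
#'   tags`).
#' @seealso [write_sam()]
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  # header must be a prefix of the file, but be permissive: any @ line is header
  header <- lines[is_hdr]
  body <- lines[!is_hdr]
  body <- body[nzchar(body)]
  lineno <- which(!is_hdr & nzchar(lines))
  recs <- .parse_sam_lines(body, lineno)
  structure(list(header = header, records = recs), class = "sam")
}

.parse_sam_lines <- function(body, lineno = seq_along(body)) {
  n <- length(body)
  if (n == 0L) {
    recs <- as.data.frame(setNames(
      c(list(character(0), integer(0), character(0), integer(0), integer(0)),
        rep(list(character(0)), 2), list(integer(0)), list(character(0)),
        rep(list(character(0)), 3)),
      c("qname", "flag", "rname", "pos", "mapq", "cigar", "rnext", "pnext",
        "tlen", "seq", "qual")), stringsAsFactors = FALSE)
    recs$tags <- character(0)
    return(recs)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1]
    stop("SAM line ", lineno[bad], ": expected >= 11 tab-separated fields, got ",
         nf[bad])
  }
  field <- function(i) vapply(parts, `[[`, "", i)
  int_field <- function(i, what) {
    txt <- field(i)
    val <- suppressWarnings(as.integer(txt))
    if (anyNA(val)) {
      bad <- which(is.na(val))[1]
      stop("SAM line ", lineno[bad], ": non-integer ", what, " '", txt[bad], "'")
    }
    val
  }
  tags <- vapply(parts, function(p) {
    if (length(p) > 11L) paste(p[-(1:11)], collapse = "\t") else ""
  }, "")
  recs <- data.frame(
    qname = field(1), flag = int_field(2, "FLAG"), rname = field(3),
    pos = int_field(4, "POS"), mapq = int_field(5, "MAPQ"), cigar = field(6),
    rnext = field(7), pnext = field(8), tlen = field(9),
    seq = field(10), qual = field(11), tags = tags,
    stringsAsFactors = FALSE
  )
  # SEQ/CIGAR consistency: query-consuming CIGAR length must equal len(SEQ)
  chk <- recs$seq != "*" & recs$cigar != "*"
  if (any(chk)) {
    qlen <- vapply(recs$cigar[chk], function(cg) query_span(parse_cigar(cg)), 1L)
    bad <- which(qlen != nchar(recs$seq[chk]))
    if (length(bad)) {
      warning("CIGAR/SEQ length mismatch for read(s): ",
              paste(utils::head(recs$qname[chk][bad], 5), collapse = ", "))
    }
  }
  recs
}

#' Write a SAM file
#'
#' Inverse of [read_sam()]: emits the stored header lines verbatim followed
#' by one tab-separated line per record (optional tags re-appended).
#' `write_sam(read_sam(p))` reproduces `p` byte for byte on well-formed
#' input.
#'
#' @param sam an object of class `"sam"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, path) {
  stopifnot(inherits(sam, "sam"))
  writeLines(c(sam$header, format_sam_records(sam$records)), path)
  invisible(path)
}

#' @rdname write_sam
#' @param records a SAM record data frame.
#' @export
format_sam_records <- function(records) {
  if (nrow(records) == 0L) return(character(0))
  core <- paste(records$qname, records$flag, records$rname, records$pos,
                records$mapq, records$cigar, records$rnext, records$pnext,
                records$tlen, records$seq, records$qual, sep = "\t")
  ifelse(nzchar(records$tags), paste(core, records$tags, sep = "\t"), core)
}

#' Construct a SAM object from a record data frame
#'
#' @param records record data frame (see [read_sam()] for columns); missing
#'   `tags` column is added empty.
#' @param header character vector of header lines (default a minimal
#'   `@HD` line).
#' @param contig_lengths optional named integer vector; emits one `@SQ`
#'   header line per contig.
#' @return an object of class `"sam"`.
#' @export
sam_object <- function(records, header = NULL, contig_lengths = NULL) {
  if (is.null(records$tags)) records$tags <- rep("", nrow(records))
  if (is.null(header)) {
    header <- "@HD\tVN:1.6\tSO:unsorted"
    if (!is.null(contig_lengths)) {
      header <- c(header, paste0("@SQ\tSN:", names(contig_lengths),
                                 "\tLN:", as.integer(contig_lengths)))
    }
  }
  structure(list(header = header, records = records), class = "sam")
}

#' @export
print.sam <- function(x, ...) {
  cat("SAM: ", length(x$header), " header line(s), ",
      nrow(x$records), " record(s)\n", sep = "")
  invisible(x)
}

# reverse complement of a DNA string (A/C/G/T/N, case preserved for ACGTN)
revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", x), "")[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}
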