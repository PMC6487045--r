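#' CIGAR parsing and coordinate arithmetic
#'
#' A CIGAR string compactly describes how a read aligns to the reference:
#' runs of matches (`M`, `=`, `X`), insertions to the reference (`I`),
#' deletions from the reference (`D`), reference skips (`N`), soft clips
#' (`S`, bases retained in SEQ), hard clips (`H`, bases removed) and
#' padding (`P`). `parse_cigar()` turns the string into an operation table;
#' `format_cigar()` is its inverse. The `*` sentinel (missing CIGAR) maps to
#' an empty table.
#'
#' @param text a single CIGAR string, e.g. `"3M1I4M"`, or `"*"`.
#' @return A data frame with integer column `len` and character column `op`,
#'   one row per operation, in string order. `"*"` yields zero rows.
#' @examples
#' parse_cigar("3M1I4M")
#' format_cigar(parse_cigar("5M2D5M"))
#' @export
parse_cigar <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  empty <- data.frame(len = integer(0), op = character(0),
                      stringsAsFactors = FALSE)
  if (text == "*" || text == "") return(empty)
  m <- gregexpr("[0-9]+[MIDNSHP=X]", text)[[1]]
  tokens <- if (m[1] == -1L) character(0) else regmatches(text, gregexpr("[0-9]+[MIDNSHP=X]", text))[[1]]
  if (sum(nchar(tokens)) != nchar(text)) {
    # locate the first position not covered by a valid token
    covered <- rep(FALSE, nchar(text))
    if (length(tokens)) {
      for (i in seq_along(m)) {
        covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
      }
    }
    bad <- substr(text, which(!covered)[1], nchar(text))
    stop("malformed CIGAR token starting at '", bad, "' in '", text, "'")
  }
  len <- as.integer(sub("[MIDNSHP=X]$", "", tokens))
  op <- sub("^[0-9]+", "", tokens)
  if (any(len == 0L)) {
    stop("zero-length CIGAR op '", tokens[which(len == 0L)[1]], "' in '", text, "'")
  }
  data.frame(len = len, op = op, stringsAsFactors = FALSE)
}

#' @rdname parse_cigar
#' @param cigar an operation table as returned by [parse_cigar()].
#' @export
format_cigar <- function(cigar) {
  if (nrow(cigar) == 0L) return("*")
  paste0(cigar$len, cigar$op, collapse = "")
}

# op classes per the SAM specification
.CIGAR_QUERY_OPS <- c("M", "I", "S", "=", "X")
.CIGAR_REF_OPS   <- c("M", "D", "N", "=", "X")

#' Reference and query span of a CIGAR
#'
#' `reference_span()` sums the lengths of reference-consuming operations
#' (`M`, `D`, `N`, `=`, `X`); `query_span()` sums the query-consuming ones
#' (`M`, `I`, `S`, `=`, `X`). `H` and `P` consume neither. An empty table
#' spans 0.
#'
#' @param cigar operation table from [parse_cigar()].
#' @return integer number of bases.
#' @export
reference_span <- function(cigar) {
  as.integer(sum(cigar$len[cigar$op %in% .CIGAR_REF_OPS]))
}

#' @rdname reference_span
#' @export
query_span <- function(cigar) {
  as.integer(sum(cigar$len[cigar$op %in% .CIGAR_QUERY_OPS]))
}
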