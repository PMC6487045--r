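#' Reference loci evidenced as indels by one read's CIGAR
#'
#' Walks the CIGAR with a reference cursor starting at the record's
#' 0-based position. `M`/`=`/`X`/`D`/`N` advance the cursor; each deletion
#' of length L contributes the full deleted span `[cursor, cursor + L)`;
#' each insertion contributes a one-base anchor `[cursor, cursor + 1)` at
#' the reference base immediately following the insertion point. Soft and
#' hard clips, padding and insertions do not advance the cursor.
#'
#' @param pos1 1-based leftmost mapping position (SAM POS).
#' @param cigar CIGAR string (must not be `"*"`).
#' @param include_N if `TRUE`, `N` (reference skip) runs are also emitted
#'   as evidence intervals, like deletions. Off by default: for DNA data
#'   `N` is a spliced-alignment artifact, not indel evidence.
#' @return data frame with columns `start`, `end` (0-based half-open) and
#'   `op` (`"I"`, `"D"` or `"N"`); zero rows when the CIGAR has no indels.
#' @export
indel_loci <- function(pos1, cigar, include_N = FALSE) {
  if (identical(cigar, "*") || is.na(cigar)) {
    stop("indel_loci requires a CIGAR; record has none")
  }
  cg <- parse_cigar(cigar)
  cur <- as.integer(pos1) - 1L
  starts <- integer(0); ends <- integer(0); ops <- character(0)
  for (i in seq_len(nrow(cg))) {
    op <- cg$op[i]; len <- cg$len[i]
    if (op == "I") {
      starts <- c(starts, cur); ends <- c(ends, cur + 1L); ops <- c(ops, "I")
    } else if (op == "D" || (op == "N" && include_N)) {
      starts <- c(starts, cur); ends <- c(ends, cur + len); ops <- c(ops, op)
      cur <- cur + len
    } else if (op %in% c("M", "=", "X", "N")) {
      cur <- cur + len
    } # S, H, P: no reference consumption
  }
  data.frame(start = starts, end = ends, op = ops, stringsAsFactors = FALSE)
}

#' Collect indel-evidenced target regions from an alignment set
#'
#' The intensive-mode targeting algorithm: a single CIGAR walk over all
#' reads accumulates per-base evidence counts at every reference locus
#' where an insertion or deletion appears in a read's CIGAR. Bases
#' supported by at least `min_reads` reads are expanded by `padding` on
#' each side (clamped at 0 and at the contig length when known) and merged
#' into a normalized region set, suitable as a BED target list for a
#' downstream local-reassembly indel caller.
#'
#' Secondary and supplementary records are always skipped;
#' duplicate-flagged records are skipped unless `include_duplicates`.
#'
#' @param sam a `"sam"` object or record data frame.
#' @param padding bases of flanking context added to each side of a
#'   qualifying base run (default 10).
#' @param min_reads minimum per-base read support (default 1: the most
#'   permissive reading of "at least one read").
#' @param include_duplicates count duplicate-flagged reads as evidence
#'   (default `FALSE`; downstream callers are duplicate-aware).
#' @param include_N see [indel_loci()].
#' @param contig_lengths optional named integer vector used to clamp
#'   padded intervals at contig ends.
#' @return a normalized `region_set` of target intervals.
#' @export
collect_hotspots <- function(sam, padding = 10L, min_reads = 1L,
                             include_duplicates = FALSE, include_N = FALSE,
                             contig_lengths = NULL) {
  stopifnot(padding >= 0L, min_reads >= 1L)
  records <- if (inherits(sam, "sam")) sam$records else sam
  use <- !sam_flag_isset(records$flag, "unmapped") &
    !sam_flag_isset(records$flag, "secondary") &
    !sam_flag_isset(records$flag, "supplementary") &
    records$cigar != "*"
  if (!include_duplicates) {
    use <- use & !sam_flag_isset(records$flag, "duplicate")
  }
  records <- records[use, , drop = FALSE]
  if (nrow(records) == 0L) return(region_set())
  loci <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    li <- indel_loci(records$pos[i], records$cigar[i], include_N = include_N)
    if (nrow(li)) li$contig <- records$rname[i]
    loci[[i]] <- li
  }
  loci <- do.call(rbind, loci[vapply(loci, nrow, 1L) > 0L])
  if (is.null(loci) || nrow(loci) == 0L) return(region_set())
  out <- lapply(sort(unique(loci$contig)), function(ctg) {
    l <- loci[loci$contig == ctg, , drop = FALSE]
    ir <- IRanges::IRanges(start = l$start + 1L, end = l$end)
    cov <- IRanges::coverage(ir)
    hot <- IRanges::slice(cov, lower = min_reads, rangesOnly = TRUE)
    if (length(hot) == 0L) return(NULL)
    start0 <- pmax(IRanges::start(hot) - 1L - padding, 0L)
    end0 <- IRanges::end(hot) + padding
    if (!is.null(contig_lengths) && !is.na(contig_lengths[ctg])) {
      end0 <- pmin(end0, as.integer(contig_lengths[ctg]))
    }
    data.frame(contig = ctg, start = start0, end = end0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(region_set())
  merge_regions(region_set(out$contig, out$start, out$end))
}
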