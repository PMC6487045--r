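#' Decide whether a read should be realigned
#'
#' The alignment-refinement step selects soft-clipped and unmapped reads
#' for realignment with a more sensitive aligner. A record needs
#' realignment if its unmapped flag is set (reason `"unmapped"`), or if it
#' is mapped with any soft-clip run of length >= `min_clip` (reason
#' `"softclip"`). Hard clips do not trigger realignment: the clipped bases
#' are absent from the record, so there is nothing to realign.
#'
#' @param flag integer SAM FLAG.
#' @param cigar CIGAR string.
#' @param min_clip minimum soft-clip length that triggers realignment
#'   (default 1: any soft clip).
#' @return list with logical `realign` and character `reason`
#'   (`"unmapped"`, `"softclip"` or `NA`).
#' @export
needs_realignment <- function(flag, cigar, min_clip = 1L) {
  if (sam_flag_isset(flag, "unmapped")) {
    return(list(realign = TRUE, reason = "unmapped"))
  }
  cg <- parse_cigar(cigar)
  s <- cg$len[cg$op == "S"]
  if (length(s) && any(s >= min_clip)) {
    return(list(realign = TRUE, reason = "softclip"))
  }
  list(realign = FALSE, reason = NA_character_)
}

# vectorized reason over a record data frame; secondary/supplementary and
# duplicate records are ineligible and return NA
.triage_reason <- function(records, min_clip) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  eligible <- !sam_flag_isset(records$flag, "secondary") &
    !sam_flag_isset(records$flag, "supplementary") &
    !sam_flag_isset(records$flag, "duplicate")
  unm <- eligible & sam_flag_isset(records$flag, "unmapped")
  reason[unm] <- "unmapped"
  cand <- which(eligible & !unm & grepl("S", records$cigar, fixed = TRUE))
  for (i in cand) {
    cg <- parse_cigar(records$cigar[i])
    if (any(cg$len[cg$op == "S"] >= min_clip)) reason[i] <- "softclip"
  }
  reason
}

#' Partition alignments into retained and to-realign sets
#'
#' Implements the selection half of the refinement step: every input
#' record lands in exactly one partition. Primary, non-duplicate records
#' that are unmapped or carry a qualifying soft clip go to `to_realign`;
#' everything else (including secondary/supplementary and duplicate-flagged
#' records, which pass through untouched) is retained. Records emitted for
#' realignment have their alignment fields cleared (unmapped flag set,
#' contig/position/CIGAR unset) and their sequence and qualities restored
#' to original read orientation when the reverse flag was set.
#'
#' @param sam a `"sam"` object or record data frame.
#' @param min_clip see [needs_realignment()].
#' @return an object of class `"triage_result"`: list with `retained` and
#'   `to_realign` record data frames (input order preserved within each)
#'   and `counts` (`retained`, `to_realign_softclip`, `to_realign_unmapped`).
#' @export
triage <- function(sam, min_clip = 1L) {
  records <- if (inherits(sam, "sam")) sam$records else sam
  reason <- .triage_reason(records, min_clip)
  sel <- !is.na(reason)
  retained <- records[!sel, , drop = FALSE]
  out <- records[sel, , drop = FALSE]
  if (nrow(out)) {
    rev <- sam_flag_isset(out$flag, "reverse")
    out$seq[rev] <- revcomp(out$seq[rev])
    out$qual[rev] <- vapply(strsplit(out$qual[rev], ""), function(q)
      paste(rev(q), collapse = ""), "")
    keep_bits <- SAM_FLAGS[["paired"]] + SAM_FLAGS[["first_in_pair"]] +
      SAM_FLAGS[["second_in_pair"]]
    out$flag <- bitwOr(bitwAnd(out$flag, keep_bits), SAM_FLAGS[["unmapped"]])
    out$rname <- "*"; out$pos <- 0L; out$mapq <- 0L; out$cigar <- "*"
    out$rnext <- "*"; out$pnext <- "0"; out$tlen <- "0"
  }
  structure(list(
    retained = retained,
    to_realign = out,
    counts = c(retained = nrow(retained),
               to_realign_softclip = sum(reason == "softclip", na.rm = TRUE),
               to_realign_unmapped = sum(reason == "unmapped", na.rm = TRUE))
  ), class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat("read triage: ", x$counts[["retained"]], " retained, ",
      x$counts[["to_realign_softclip"]], " soft-clipped + ",
      x$counts[["to_realign_unmapped"]],
      " unmapped selected for realignment\n", sep = "")
  invisible(x)
}

#' Merge retained and realigned records into one coordinate-sorted set
#'
#' The merge half of the refinement step: the output contains every
#' retained record plus every realigned record, sorted by
#' (contig, position, query name), with unmapped records in a trailing
#' block. A (query name, pair segment) that appears as a primary record in
#' both inputs is an error — the two sources must partition the read set.
#'
#' @param retained,realigned `"sam"` objects or record data frames.
#' @return a record data frame, coordinate-sorted.
#' @export
merge_refined <- function(retained, realigned) {
  a <- if (inherits(retained, "sam")) retained$records else retained
  b <- if (inherits(realigned, "sam")) realigned$records else realigned
  primary_key <- function(r) {
    pri <- !sam_flag_isset(r$flag, "secondary") &
      !sam_flag_isset(r$flag, "supplementary")
    paste(r$qname[pri], read_segment(r$flag[pri]), sep = "\r")
  }
  dup <- intersect(primary_key(a), primary_key(b))
  if (length(dup)) {
    stop("read(s) present as primary in both inputs: ",
         paste(sub("\r.*", "", utils::head(dup, 5)), collapse = ", "))
  }
  all <- rbind(a, b)
  unmapped <- sam_flag_isset(all$flag, "unmapped")
  mapped <- all[!unmapped, , drop = FALSE]
  mapped <- mapped[order(mapped$rname, mapped$pos, mapped$qname), , drop = FALSE]
  tail <- all[unmapped, , drop = FALSE]
  tail <- tail[order(tail$qname), , drop = FALSE]
  out <- rbind(mapped, tail)
  rownames(out) <- NULL
  out
}
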