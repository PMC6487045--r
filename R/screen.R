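#' Computational-subtraction microbe screen
#'
#' The screen classifies sequencing reads by two alignment passes: a host
#' pass against the human reference and a database pass of the non-host
#' reads against a set of microbial genomes. Host reads are those whose
#' primary record maps to the host reference; microbial reads are non-host
#' reads mapping to at least one database genome; the remainder is
#' unknown. Per-genome evidence is summarized as the number of aligned
#' reads, the genome length, and the breadth of coverage (bases covered by
#' at least one read).
#'
#' @name microbe_screen
NULL

# primary-record key per (read, pair segment)
.primary_keys <- function(records) {
  pri <- !sam_flag_isset(records$flag, "secondary") &
    !sam_flag_isset(records$flag, "supplementary")
  r <- records[pri, , drop = FALSE]
  list(records = r, key = paste(r$qname, read_segment(r$flag), sep = "\r"))
}

#' Split reads into host and non-host by the host-pass alignment
#'
#' A read (per pair segment) is host iff its primary record in the host
#' pass is mapped; mates are classified independently.
#'
#' @param host_sam a `"sam"` object of the host-pass alignments.
#' @return list with character vectors `host` and `nonhost` of
#'   `"<qname>/<segment>"` keys and a `counts` vector.
#' @export
subtract_host <- function(host_sam) {
  pk <- .primary_keys(if (inherits(host_sam, "sam")) host_sam$records else host_sam)
  mapped <- !sam_flag_isset(pk$records$flag, "unmapped")
  host <- unique(pk$key[mapped])
  nonhost <- setdiff(unique(pk$key[!mapped]), host)
  list(host = host, nonhost = nonhost,
       counts = c(host = length(host), nonhost = length(nonhost)))
}

# 0-based half-open aligned (M/=/X) reference segments of one record.
# D/N gaps inside the alignment advance the cursor but are NOT covered:
# a base "covered by at least one read" means a base an aligned read base
# sits on.
aligned_segments <- function(pos1, cigar) {
  cg <- parse_cigar(cigar)
  cur <- as.integer(pos1) - 1L
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(nrow(cg))) {
    op <- cg$op[i]; len <- cg$len[i]
    if (op %in% c("M", "=", "X")) {
      starts <- c(starts, cur); ends <- c(ends, cur + len)
      cur <- cur + len
    } else if (op %in% c("D", "N")) {
      cur <- cur + len
    }
  }
  data.frame(start = starts, end = ends)
}

#' Summarize per-genome hits of the database pass
#'
#' For every database genome with at least one aligned read: the number of
#' distinct (read, segment) whose primary alignment maps to it (or every
#' genome a read aligns to, with `count_secondary = TRUE`), the genome
#' length, the number of bases covered by at least one read (union of
#' aligned `M`/`=`/`X` segments), and the breadth fraction. Genomes with
#' zero reads are omitted; rows are ranked by read count descending, ties
#' broken by genome id.
#'
#' @param microbe_sam a `"sam"` object of non-host reads aligned to the
#'   microbial database.
#' @param genome_lengths named integer vector (or 2+ column data frame /
#'   `.fai`-style table via [read_genome_lengths()]) giving each database
#'   sequence's length. Every contig seen in the alignments must be
#'   present.
#' @param count_secondary also count secondary alignments toward their
#'   genomes (default `FALSE`: one verdict per read).
#' @return data frame of class `"genome_hits"` with columns `genome_id`,
#'   `genome_length`, `read_count`, `covered_bases`, `breadth_fraction`.
#' @export
summarize_hits <- function(microbe_sam, genome_lengths,
                           count_secondary = FALSE) {
  genome_lengths <- .as_length_vector(genome_lengths)
  records <- if (inherits(microbe_sam, "sam")) microbe_sam$records else microbe_sam
  use <- !sam_flag_isset(records$flag, "unmapped") &
    !sam_flag_isset(records$flag, "supplementary")
  if (!count_secondary) {
    use <- use & !sam_flag_isset(records$flag, "secondary")
  }
  r <- records[use, , drop = FALSE]
  missing <- setdiff(unique(r$rname), names(genome_lengths))
  if (length(missing)) {
    stop("genome(s) absent from length table: ", paste(missing, collapse = ", "))
  }
  empty <- data.frame(genome_id = character(0), genome_length = integer(0),
                      read_count = integer(0), covered_bases = integer(0),
                      breadth_fraction = numeric(0), stringsAsFactors = FALSE)
  if (nrow(r) == 0L) {
    class(empty) <- c("genome_hits", "data.frame")
    return(empty)
  }
  key <- paste(r$qname, read_segment(r$flag), sep = "\r")
  out <- lapply(sort(unique(r$rname)), function(g) {
    idx <- which(r$rname == g)
    segs <- do.call(rbind, lapply(idx, function(i)
      aligned_segments(r$pos[i], r$cigar[i])))
    cov <- if (is.null(segs) || nrow(segs) == 0L) 0L else {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = segs$start + 1L, end = segs$end))))
    }
    len <- as.integer(genome_lengths[[g]])
    if (cov > len) {
      stop("covered bases (", cov, ") exceed genome length (", len,
           ") for ", g, "; check the length table")
    }
    data.frame(genome_id = g, genome_length = len,
               read_count = length(unique(key[idx])),
               covered_bases = as.integer(cov),
               breadth_fraction = cov / len, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$read_count, out$genome_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genome_hits", "data.frame")
  out
}

.as_length_vector <- function(genome_lengths) {
  if (is.data.frame(genome_lengths)) {
    setNames(as.integer(genome_lengths[[2]]),
             as.character(genome_lengths[[1]]))
  } else genome_lengths
}

#' Read a genome length table (.fai dialect or 2-column TSV)
#'
#' Only the first two columns (sequence name, length) are used, so both a
#' `samtools faidx` index and a plain 2-column TSV parse.
#'
#' @param path file path.
#' @return named integer vector of lengths.
#' @export
read_genome_lengths <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  setNames(as.integer(tab[[2]]), as.character(tab[[1]]))
}

#' Classify all reads and assemble the screen summary
#'
#' Combines host subtraction and the database pass into the full read
#' classification: `n_human + n_microbial + n_unknown == n_total` is
#' asserted on every run, and a read claimed as both host and microbial is
#' an error (the two passes must derive from the same read universe, with
#' only non-host reads entering the database pass).
#'
#' @param host_sam host-pass alignments (`"sam"`).
#' @param microbe_sam database-pass alignments of the non-host reads
#'   (`"sam"`).
#' @param genome_lengths see [summarize_hits()].
#' @param top_n how many top genomes to keep in the ranked report
#'   (default 20).
#' @param count_secondary see [summarize_hits()].
#' @return object of class `"screen_summary"`: list with `n_total`,
#'   `n_human`, `n_microbial`, `n_unknown`, `proportions`, `hits`
#'   (all genomes) and `top` (ranked top-N with a `log10_reads` column).
#' @export
screen_reads <- function(host_sam, microbe_sam, genome_lengths,
                         top_n = 20L, count_secondary = FALSE) {
  sub <- subtract_host(host_sam)
  mrec <- if (inherits(microbe_sam, "sam")) microbe_sam$records else microbe_sam
  mk <- .primary_keys(mrec)
  mapped_keys <- unique(mk$key[!sam_flag_isset(mk$records$flag, "unmapped")])
  clash <- intersect(mapped_keys, sub$host)
  if (length(clash)) {
    stop("read(s) classified as both host and microbial: ",
         paste(sub("\r.*", "", utils::head(clash, 5)), collapse = ", "))
  }
  microbial <- intersect(mapped_keys, sub$nonhost)
  n_total <- length(sub$host) + length(sub$nonhost)
  n_human <- length(sub$host)
  n_microbial <- length(microbial)
  n_unknown <- n_total - n_human - n_microbial
  stopifnot(n_human + n_microbial + n_unknown == n_total)
  props <- if (n_total > 0L) {
    c(human = n_human, microbial = n_microbial, unknown = n_unknown) / n_total
  } else c(human = 0, microbial = 0, unknown = 0)
  hits <- summarize_hits(microbe_sam, genome_lengths,
                         count_secondary = count_secondary)
  structure(list(n_total = n_total, n_human = n_human,
                 n_microbial = n_microbial, n_unknown = n_unknown,
                 proportions = props, hits = hits,
                 top = top_hits(hits, top_n)),
            class = "screen_summary")
}

#' Rank the top genomes by aligned read count
#'
#' @param hits a `"genome_hits"` data frame from [summarize_hits()].
#' @param n how many genomes to keep (default 20); more than available
#'   returns the whole list.
#' @return the first `n` hits by read count descending (ties by genome id
#'   ascending), with an added `log10_reads` column for log-scale
#'   plotting.
#' @export
top_hits <- function(hits, n = 20L) {
  out <- hits[order(-hits$read_count, hits$genome_id), , drop = FALSE]
  out <- utils::head(out, n)
  out$log10_reads <- ifelse(out$read_count > 0, log10(out$read_count), NA_real_)
  rownames(out) <- NULL
  out
}

#' @export
print.screen_summary <- function(x, digits = 3, ...) {
  cat("microbe screen over ", x$n_total, " reads\n", sep = "")
  cat(sprintf("  human:     %d (%.1f%%)\n", x$n_human,
              100 * x$proportions[["human"]]))
  cat(sprintf("  microbial: %d (%.1f%%)\n", x$n_microbial,
              100 * x$proportions[["microbial"]]))
  cat(sprintf("  unknown:   %d (%.1f%%)\n", x$n_unknown,
              100 * x$proportions[["unknown"]]))
  if (nrow(x$top)) {
    cat("top genomes by aligned reads:\n")
    print.data.frame(utils::head(as.data.frame(x$top), 5), digits = digits)
  }
  invisible(x)
}

#' Write the screen outputs
#'
#' Emits the per-genome hit table and ranked top-N as TSV and the class
#' tallies as JSON under a common prefix (`<prefix>_hits.tsv`,
#' `<prefix>_top.tsv`, `<prefix>_summary.json`).
#'
#' @param summary a `"screen_summary"`.
#' @param prefix output path prefix.
#' @return character vector of the paths written, invisibly.
#' @export
write_screen_summary <- function(summary, prefix) {
  paths <- c(hits = paste0(prefix, "_hits.tsv"),
             top = paste0(prefix, "_top.tsv"),
             json = paste0(prefix, "_summary.json"))
  utils::write.table(as.data.frame(summary$hits), paths[["hits"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(summary$top), paths[["top"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    n_total = summary$n_total, n_human = summary$n_human,
    n_microbial = summary$n_microbial, n_unknown = summary$n_unknown,
    proportions = as.list(summary$proportions)
  ), paths[["json"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
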