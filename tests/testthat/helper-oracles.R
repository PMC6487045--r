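# Independent brute-force oracles used to cross-check the package's
# interval and evaluation machinery. Each re-derives its answer from first
# principles (per-base arrays, direct formula evaluation) without calling
# the code path under test.

# per-base bitmap union of 0-based half-open intervals, with gap closure;
# returns a data.frame(contig, start, end)
oracle_merge <- function(regions, gap = 0L, max_len = 20000L) {
  out <- NULL
  for (ctg in sort(unique(regions$contig))) {
    r <- regions[regions$contig == ctg, , drop = FALSE]
    bits <- logical(max_len)
    for (i in seq_len(nrow(r))) bits[(r$start[i] + 1L):r$end[i]] <- TRUE
    if (gap > 0L) {
      # close gaps of length <= gap between covered runs
      runs <- rle(bits)
      pos <- cumsum(runs$lengths)
      for (j in seq_along(runs$values)) {
        if (!runs$values[j] && j > 1L && j < length(runs$values) &&
            runs$lengths[j] <= gap) {
          bits[(pos[j] - runs$lengths[j] + 1L):pos[j]] <- TRUE
        }
      }
    }
    runs <- rle(bits)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths
    keep <- runs$values
    if (any(keep)) {
      out <- rbind(out, data.frame(contig = ctg, start = starts[keep],
                                   end = ends[keep],
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) data.frame(contig = character(0), start = integer(0),
                               end = integer(0), stringsAsFactors = FALSE)
  else out
}

# independent CIGAR walk: returns indel-evidence bases (0-based) of one read
oracle_indel_bases <- function(pos1, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub(".$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  cur <- pos1 - 1L
  bases <- integer(0)
  for (i in seq_along(op)) {
    if (op[i] == "I") bases <- c(bases, cur)
    else if (op[i] == "D") {
      bases <- c(bases, cur:(cur + len[i] - 1L)); cur <- cur + len[i]
    } else if (op[i] %in% c("M", "=", "X", "N")) cur <- cur + len[i]
  }
  bases
}

# brute-force per-base pileup hotspot computation over a record data frame
oracle_hotspots <- function(records, min_reads = 1L, padding = 0L,
                            contig_lengths = NULL, max_len = 20000L) {
  elig <- !bitwAnd(records$flag, 4L) & !bitwAnd(records$flag, 256L) &
    !bitwAnd(records$flag, 2048L) & !bitwAnd(records$flag, 1024L) &
    records$cigar != "*"
  r <- records[elig, , drop = FALSE]
  out <- NULL
  for (ctg in sort(unique(r$rname))) {
    counts <- integer(max_len)
    idx <- which(r$rname == ctg)
    for (i in idx) {
      b <- oracle_indel_bases(r$pos[i], r$cigar[i])
      counts[b + 1L] <- counts[b + 1L] + 1L
    }
    hot <- counts >= min_reads
    if (!any(hot)) next
    bases <- which(hot) - 1L
    padded <- unique(unlist(lapply(bases, function(b)
      max(0L, b - padding):(b + padding))))
    if (!is.null(contig_lengths) && !is.na(contig_lengths[ctg])) {
      padded <- padded[padded < contig_lengths[ctg]]
    }
    bits <- logical(max_len)
    bits[padded + 1L] <- TRUE
    runs <- rle(bits)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths
    keep <- runs$values
    out <- rbind(out, data.frame(contig = ctg, start = starts[keep],
                                 end = ends[keep], stringsAsFactors = FALSE))
  }
  if (is.null(out)) data.frame(contig = character(0), start = integer(0),
                               end = integer(0), stringsAsFactors = FALSE)
  else out
}

# boolean-array breadth of coverage from aligned (M/=/X) bases
oracle_covered_bases <- function(records, genome, genome_length) {
  r <- records[records$rname == genome & !bitwAnd(records$flag, 4L) &
                 !bitwAnd(records$flag, 256L) &
                 !bitwAnd(records$flag, 2048L), , drop = FALSE]
  bits <- logical(genome_length)
  for (i in seq_len(nrow(r))) {
    ops <- regmatches(r$cigar[i], gregexpr("[0-9]+[MIDNSHP=X]",
                                           r$cigar[i]))[[1]]
    len <- as.integer(sub(".$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    cur <- r$pos[i] - 1L
    for (j in seq_along(op)) {
      if (op[j] %in% c("M", "=", "X")) {
        bits[(cur + 1L):(cur + len[j])] <- TRUE
        cur <- cur + len[j]
      } else if (op[j] %in% c("D", "N")) cur <- cur + len[j]
    }
  }
  sum(bits)
}

# direct evaluation of the three benchmarking formulas
oracle_metrics <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  s <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(p) && !is.na(s) && (p + s) > 0) 2 * p * s / (p + s)
       else NA_real_
  c(precision = p, sensitivity = s, f_measure = f)
}

# random mapped reads with random CIGARs over one contig, for property tests
random_read_records <- function(n, contig = "chrT", contig_len = 10000L) {
  recs <- lapply(seq_len(n), function(i) {
    nops <- sample(1:5, 1L)
    ops <- character(0)
    # alternate M with I/D/S so the CIGAR stays valid-ish and varied
    for (j in seq_len(nops)) {
      ops <- c(ops, paste0(sample(5:30, 1L), "M"))
      if (j < nops) {
        ops <- c(ops, paste0(sample(1:10, 1L), sample(c("I", "D"), 1L)))
      }
    }
    if (stats::runif(1) < 0.3) ops <- c(paste0(sample(1:15, 1L), "S"), ops)
    cigar <- paste(ops, collapse = "")
    cg <- seqscreen::parse_cigar(cigar)
    rspan <- seqscreen::reference_span(cg)
    qspan <- seqscreen::query_span(cg)
    pos1 <- sample.int(contig_len - rspan, 1L)
    data.frame(qname = sprintf("rand_%04d", i), flag = 0L, rname = contig,
               pos = pos1, mapq = 60L, cigar = cigar, rnext = "*",
               pnext = "0", tlen = "0",
               seq = paste(sample(c("A", "C", "G", "T"), qspan,
                                  replace = TRUE), collapse = ""),
               qual = strrep("I", qspan), tags = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

region_df <- function(rs) {
  d <- as.data.frame(rs)[, c("contig", "start", "end")]
  rownames(d) <- NULL
  d
}
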