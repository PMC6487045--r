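#' Synthetic fixtures with planted truth
#'
#' Every generator in this module is a pure function of `(seed,
#' parameters)`: the RNG state is saved and restored around each call, and
#' identical inputs reproduce byte-identical output. Alongside the data,
#' each generator returns a machine-readable manifest of everything it
#' planted (indel loci, selected read names, per-genome read counts and
#' coverage footprints, shared/only variant counts), so tests and the
#' acceptance script read ground truth from the manifest and nowhere else.
#'
#' The read model mirrors common short-read data shape (150 bp reads by
#' default) without simulating sequencing error: no in-scope stage
#' consumes base qualities, so an error model would only blur planted
#' truth.
#'
#' @name fixtures
NULL

# evaluate code under set.seed(seed), restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a random reference
#'
#' Uniform A/C/G/T sequence per contig, deterministic per seed.
#'
#' @param contigs named integer vector of contig lengths (>= 1).
#' @param seed integer seed (mandatory; no wall-clock default).
#' @return list with `sequences` (named character vector) and `lengths`
#'   (named integer vector).
#' @export
make_reference <- function(contigs, seed) {
  stopifnot(all(contigs >= 1L), !is.null(names(contigs)))
  with_seed(seed, {
    seqs <- vapply(as.integer(contigs), .random_dna, "")
    names(seqs) <- names(contigs)
    list(sequences = seqs, lengths = setNames(as.integer(contigs),
                                              names(contigs)))
  })
}

#' Write a FASTA file (60-column wrap) and its index-style length table
#'
#' @param sequences named character vector of sequences.
#' @param path output FASTA path; `write_fai()` writes `<path>.fai` unless
#'   `fai_path` is given.
#' @param width line wrap width (default 60).
#' @return the path written, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  out <- character(0)
  for (nm in names(sequences)) {
    s <- sequences[[nm]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    out <- c(out, paste0(">", nm),
             substring(s, starts, pmin(starts + width - 1L, n)))
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_fasta
#' @param fai_path output path for the length table.
#' @export
write_fai <- function(sequences, path, fai_path = paste0(path, ".fai"),
                      width = 60L) {
  offset <- 0L
  rows <- character(0)
  for (nm in names(sequences)) {
    n <- nchar(sequences[[nm]])
    offset <- offset + nchar(nm) + 2L  # ">name\n"
    rows <- c(rows, paste(nm, n, offset, width, width + 1L, sep = "\t"))
    nlines <- ceiling(n / width)
    offset <- offset + n + nlines      # sequence bytes + newlines
  }
  writeLines(rows, fai_path)
  invisible(fai_path)
}

.sam_rec <- function(qname, flag, rname = "*", pos = 0L, mapq = 0L,
                     cigar = "*", seq = "*", qual = NULL) {
  if (is.null(qual)) qual <- if (seq == "*") "*" else strrep("I", nchar(seq))
  data.frame(qname = qname, flag = as.integer(flag), rname = rname,
             pos = as.integer(pos), mapq = as.integer(mapq), cigar = cigar,
             rnext = "*", pnext = "0", tlen = "0", seq = seq, qual = qual,
             tags = "", stringsAsFactors = FALSE)
}

#' Simulate an alignment set with planted features
#'
#' Builds a SAM record set over a reference from [make_reference()]:
#' clean reads (all-M CIGARs drawn from the reference), soft-clipped reads
#' (terminal `S` runs of planned lengths), unmapped reads (FLAG 4), and
#' indel-evidence reads whose CIGARs spell planted insertions/deletions at
#' exact reference loci. A fraction of clean reads can be duplicate-flagged.
#'
#' @param reference list from [make_reference()].
#' @param plan list with any of: `n_clean`, `n_softclip`, `n_unmapped`
#'   (counts, default 0); `clip_lengths` (integer vector recycled over
#'   soft-clipped reads, default 5:30 sampled); `softclip_reverse_fraction`
#'   (fraction of soft-clipped reads stored reverse-complemented with the
#'   reverse flag, default 0); `dup_fraction` (fraction of clean reads
#'   flagged duplicate, default 0); `indels` (data frame with columns
#'   `contig`, `pos0` (0-based locus), `type` (`"I"`/`"D"`), `len`,
#'   `n_reads`); `read_length` (default 150).
#' @param seed integer seed.
#' @return list with `sam` (a `"sam"` object with `@SQ` headers) and
#'   `manifest`: `seed`, `indel_loci` (data frame `contig, start, end, op,
#'   n_reads` of expected hotspot evidence), `softclip_names`,
#'   `unmapped_names`, `duplicate_names`, `n_records`.
#' @export
simulate_alignments <- function(reference, plan, seed) {
  rl <- plan$read_length %||% 150L
  n_clean <- plan$n_clean %||% 0L
  n_soft <- plan$n_softclip %||% 0L
  n_unm <- plan$n_unmapped %||% 0L
  with_seed(seed, {
    seqs <- reference$sequences
    lens <- reference$lengths
    ok_contigs <- names(lens)[lens >= rl]
    if ((n_clean + n_soft) > 0L && !length(ok_contigs)) {
      stop("no contig long enough for read length ", rl)
    }
    recs <- list()
    # clean all-M reads
    for (i in seq_len(n_clean)) {
      ctg <- sample(ok_contigs, 1L)
      p1 <- sample.int(lens[[ctg]] - rl + 1L, 1L)
      recs[[length(recs) + 1L]] <- .sam_rec(
        sprintf("clean_%04d", i), 0L, ctg, p1, 60L, paste0(rl, "M"),
        substr(seqs[[ctg]], p1, p1 + rl - 1L))
    }
    dup_names <- character(0)
    if ((plan$dup_fraction %||% 0) > 0 && n_clean > 0L) {
      n_dup <- round(plan$dup_fraction * n_clean)
      dup_idx <- sort(sample.int(n_clean, n_dup))
      for (i in dup_idx) recs[[i]]$flag <- bitwOr(recs[[i]]$flag,
                                                  SAM_FLAGS[["duplicate"]])
      dup_names <- vapply(recs[dup_idx], function(r) r$qname, "")
    }
    # soft-clipped reads: leading clip of planned length, rest matches
    clip_lens <- plan$clip_lengths %||% sample(5:30, max(n_soft, 1L),
                                               replace = TRUE)
    clip_lens <- rep_len(as.integer(clip_lens), max(n_soft, 1L))
    rev_frac <- plan$softclip_reverse_fraction %||% 0
    soft_names <- character(0)
    for (i in seq_len(n_soft)) {
      ctg <- sample(ok_contigs, 1L)
      cl <- min(clip_lens[i], rl - 1L)
      ml <- rl - cl
      p1 <- sample.int(lens[[ctg]] - ml + 1L, 1L)
      nm <- sprintf("softclip_%04d", i)
      seq_fwd <- paste0(.random_dna(cl), substr(seqs[[ctg]], p1, p1 + ml - 1L))
      flag <- 0L; cg <- paste0(cl, "S", ml, "M"); sq <- seq_fwd
      if (stats::runif(1) < rev_frac) {
        flag <- SAM_FLAGS[["reverse"]]
      }
      recs[[length(recs) + 1L]] <- .sam_rec(nm, flag, ctg, p1, 60L, cg, sq)
      soft_names <- c(soft_names, nm)
    }
    # planted indel-evidence reads
    indel_loci <- data.frame(contig = character(0), start = integer(0),
                             end = integer(0), op = character(0),
                             n_reads = integer(0), stringsAsFactors = FALSE)
    if (!is.null(plan$indels) && nrow(plan$indels)) {
      for (k in seq_len(nrow(plan$indels))) {
        row <- plan$indels[k, ]
        ctg <- as.character(row$contig); pos0 <- as.integer(row$pos0)
        type <- as.character(row$type); len <- as.integer(row$len)
        clen <- lens[[ctg]]
        if (is.null(clen)) stop("planted indel on unknown contig ", ctg)
        if (type == "D") {
          f <- max(1L, min(pos0, rl %/% 2L))
          r <- rl - f
          if (pos0 + len + r > clen || pos0 - f < 0L) {
            stop("planted deletion at ", ctg, ":", pos0,
                 " does not fit within the contig")
          }
          cg <- paste0(f, "M", len, "D", r, "M")
          sq <- paste0(substr(seqs[[ctg]], pos0 - f + 1L, pos0),
                       substr(seqs[[ctg]], pos0 + len + 1L, pos0 + len + r))
          loc <- c(pos0, pos0 + len)
        } else if (type == "I") {
          f <- max(1L, min(pos0, (rl - len) %/% 2L))
          r <- rl - len - f
          if (r < 1L || pos0 + r > clen || pos0 - f < 0L) {
            stop("planted insertion at ", ctg, ":", pos0,
                 " does not fit within the contig")
          }
          cg <- paste0(f, "M", len, "I", r, "M")
          sq <- paste0(substr(seqs[[ctg]], pos0 - f + 1L, pos0),
                       .random_dna(len),
                       substr(seqs[[ctg]], pos0 + 1L, pos0 + r))
          loc <- c(pos0, pos0 + 1L)
        } else stop("indel type must be 'I' or 'D'")
        for (cp in seq_len(as.integer(row$n_reads))) {
          recs[[length(recs) + 1L]] <- .sam_rec(
            sprintf("indel_%03d_%02d", k, cp), 0L, ctg, pos0 - f + 1L, 60L,
            cg, sq)
        }
        indel_loci <- rbind(indel_loci, data.frame(
          contig = ctg, start = loc[1], end = loc[2], op = type,
          n_reads = as.integer(row$n_reads), stringsAsFactors = FALSE))
      }
    }
    # unmapped reads
    unm_names <- character(0)
    for (i in seq_len(n_unm)) {
      nm <- sprintf("unmapped_%04d", i)
      recs[[length(recs) + 1L]] <- .sam_rec(nm, SAM_FLAGS[["unmapped"]],
                                            seq = .random_dna(rl))
      unm_names <- c(unm_names, nm)
    }
    records <- do.call(rbind, recs)
    if (is.null(records)) records <- .sam_rec(character(0), integer(0))[0, ]
    list(
      sam = sam_object(records, contig_lengths = lens),
      manifest = list(seed = seed, indel_loci = indel_loci,
                      softclip_names = soft_names,
                      unmapped_names = unm_names,
                      duplicate_names = dup_names,
                      n_records = nrow(records))
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a truth/call VCF pair with a planted overlap structure
#'
#' Generates distinct variant sites on one contig and assigns them to
#' three disjoint groups: shared (present in truth and calls with the
#' same alleles and genotype), call-only and truth-only. Matching the pair
#' therefore returns exactly `(n_shared, n_call_only, n_truth_only)` as
#' (TP, FP, FN) under genotype matching. Call-set GQ and DP are drawn from
#' stated ranges, with `n_low_gq` / `n_low_dp` calls planted below the
#' default hard-filter thresholds (GQ in 0..19, DP in 0..9); the manifest
#' records which records fail.
#'
#' @param plan list with `n_shared`, `n_call_only`, `n_truth_only`
#'   (default 0); `p_indel` fraction of indel sites (default 0.2);
#'   `gq_range`, `dp_range` (call-set sampling ranges, defaults 30..90 and
#'   15..60); `n_low_gq`, `n_low_dp` planted low-quality calls
#'   (default 0); `contig` (default `"chrT"`).
#' @param seed integer seed.
#' @return list with `truth` and `calls` (`"vcf"` objects, sample
#'   `"SAMPLE"`) and `manifest` (`seed`, the three group sizes, positions
#'   per group, `n_fail` = number of call records failing the default
#'   GQ/DP filter, `fail_pos` their positions).
#' @export
simulate_vcf_pair <- function(plan, seed) {
  n_sh <- plan$n_shared %||% 0L
  n_co <- plan$n_call_only %||% 0L
  n_to <- plan$n_truth_only %||% 0L
  p_indel <- plan$p_indel %||% 0.2
  contig <- plan$contig %||% "chrT"
  with_seed(seed, {
    n <- n_sh + n_co + n_to
    pos <- sort(sample(seq(100L, 100L + 20L * max(n, 1L), by = 10L), n))
    grp <- sample(rep(c("shared", "call_only", "truth_only"),
                      c(n_sh, n_co, n_to)))
    bases <- c("A", "C", "G", "T")
    mk_site <- function(p) {
      if (stats::runif(1) < p_indel) {
        anchor <- sample(bases, 1L)
        extra <- .random_dna(sample(1:5, 1L))
        if (stats::runif(1) < 0.5) list(ref = paste0(anchor, extra), alt = anchor)
        else list(ref = anchor, alt = paste0(anchor, extra))
      } else {
        ref <- sample(bases, 1L)
        list(ref = ref, alt = sample(setdiff(bases, ref), 1L))
      }
    }
    sites <- lapply(seq_len(n), function(i) {
      s <- mk_site(p_indel)
      s$pos <- pos[i]; s$grp <- grp[i]
      s$gt <- sample(c("0/1", "1/1"), 1L)
      s
    })
    gq_range <- plan$gq_range %||% c(30L, 90L)
    dp_range <- plan$dp_range %||% c(15L, 60L)
    call_idx <- which(grp %in% c("shared", "call_only"))
    n_calls <- length(call_idx)
    gq <- sample(seq(gq_range[1], gq_range[2]), n_calls, replace = TRUE)
    dp <- sample(seq(dp_range[1], dp_range[2]), n_calls, replace = TRUE)
    n_low_gq <- min(plan$n_low_gq %||% 0L, n_calls)
    n_low_dp <- min(plan$n_low_dp %||% 0L, n_calls)
    low <- sample.int(n_calls, min(n_low_gq + n_low_dp, n_calls))
    if (n_low_gq > 0L) gq[low[seq_len(n_low_gq)]] <- sample(0:19, n_low_gq,
                                                            replace = TRUE)
    if (n_low_dp > 0L) {
      dp_idx <- low[seq.int(n_low_gq + 1L, length.out = min(n_low_dp, length(low) - n_low_gq))]
      if (length(dp_idx)) dp[dp_idx] <- sample(0:9, length(dp_idx),
                                               replace = TRUE)
    }
    vcf_rec <- function(s, gq, dp) data.frame(
      chrom = contig, pos = s$pos, id = ".", ref = s$ref, alt = s$alt,
      qual = "100", filter = "PASS", info = ".", format = "GT:GQ:DP",
      SAMPLE = paste(s$gt, gq, dp, sep = ":"), stringsAsFactors = FALSE)
    truth_recs <- do.call(rbind, lapply(sites[grp %in% c("shared", "truth_only")],
                                        vcf_rec, gq = 99L, dp = 50L))
    call_recs <- do.call(rbind, Map(function(s, g, d) vcf_rec(s, g, d),
                                    sites[call_idx], gq, dp))
    empty_rec <- vcf_rec(list(pos = 1L, ref = "A", alt = "C", gt = "0/1"),
                         1L, 1L)[0, ]
    if (is.null(truth_recs)) truth_recs <- empty_rec
    if (is.null(call_recs)) call_recs <- empty_rec
    truth_recs <- truth_recs[order(truth_recs$pos), , drop = FALSE]
    call_recs <- call_recs[order(call_recs$pos), , drop = FALSE]
    fail <- gq < 20L | dp < 10L
    clen <- setNames(max(c(pos, 0L)) + 1000L, contig)
    list(
      truth = vcf_object(truth_recs, samples = "SAMPLE",
                         contig_lengths = clen),
      calls = vcf_object(call_recs, samples = "SAMPLE",
                         contig_lengths = clen),
      manifest = list(seed = seed, n_shared = n_sh, n_call_only = n_co,
                      n_truth_only = n_to,
                      pos_shared = pos[grp == "shared"],
                      pos_call_only = pos[grp == "call_only"],
                      pos_truth_only = pos[grp == "truth_only"],
                      n_fail = sum(fail),
                      fail_pos = pos[call_idx][fail])
    )
  })
}

#' Simulate a microbe-screen read mixture with planted per-genome truth
#'
#' Places the planned number of reads on each database genome by
#' deterministic tiling (read k starts at `(k - 1) * read_length`, wrapping
#' to a shifted phase once the genome end is reached), so the generator
#' knows the exact coverage footprint; `covered_bases` in the manifest is
#' computed from a simple per-base bitmap over the planned placements,
#' independent of the interval machinery under test. Optionally also
#' builds the matching host-pass SAM: `n_human` reads mapped to a host
#' contig, plus every non-host read (microbial and `n_unknown` unclassified
#' reads) as unmapped records.
#'
#' @param genomes named integer vector of database genome lengths.
#' @param plan data frame with columns `genome_id`, `n_reads`.
#' @param seed integer seed.
#' @param read_length read length (default 150; clipped to short genomes).
#' @param n_unknown reads aligning to neither host nor database
#'   (default 0).
#' @param n_human host-mapped reads in the host pass (default 0).
#' @return list with `microbe_sam`, `host_sam` (`"sam"` objects),
#'   `lengths` (named vector incl. the host contig for the host pass) and
#'   `manifest` (`seed`, per-genome `read_count` and `covered_bases`,
#'   `n_human`, `n_microbial`, `n_unknown`).
#' @export
simulate_microbial_mixture <- function(genomes, plan, seed,
                                       read_length = 150L, n_unknown = 0L,
                                       n_human = 0L) {
  with_seed(seed, {
    mrecs <- list()
    truth <- list()
    microbial_names <- character(0)
    for (k in seq_len(nrow(plan))) {
      g <- as.character(plan$genome_id[k])
      n <- as.integer(plan$n_reads[k])
      glen <- as.integer(genomes[[g]])
      if (is.null(glen) || is.na(glen)) stop("unknown genome ", g)
      rl <- min(read_length, glen)
      covered <- logical(glen)
      for (i in seq_len(n)) {
        # tile; wrap with a phase shift so extra passes still extend coverage
        start0 <- ((i - 1L) * rl) %% max(glen - rl + 1L, 1L)
        covered[(start0 + 1L):(start0 + rl)] <- TRUE
        nm <- sprintf("microbe_%s_%04d", g, i)
        mrecs[[length(mrecs) + 1L]] <- .sam_rec(nm, 0L, g, start0 + 1L, 60L,
                                                paste0(rl, "M"),
                                                .random_dna(rl))
        microbial_names <- c(microbial_names, nm)
      }
      if (n > 0L) {
        truth[[g]] <- list(read_count = n, covered_bases = sum(covered))
      }
    }
    unknown_names <- sprintf("unknown_%04d", seq_len(n_unknown))
    for (nm in unknown_names) {
      mrecs[[length(mrecs) + 1L]] <- .sam_rec(nm, SAM_FLAGS[["unmapped"]],
                                              seq = .random_dna(read_length))
    }
    mrec_df <- if (length(mrecs)) do.call(rbind, mrecs) else
      .sam_rec(character(0), integer(0))[0, ]
    # host pass: human reads mapped to a host contig, non-host reads unmapped
    host_len <- max(10000L, read_length)
    hrecs <- list()
    for (i in seq_len(n_human)) {
      p1 <- sample.int(host_len - read_length + 1L, 1L)
      hrecs[[length(hrecs) + 1L]] <- .sam_rec(sprintf("human_%05d", i), 0L,
                                              "host_ref", p1, 60L,
                                              paste0(read_length, "M"),
                                              .random_dna(read_length))
    }
    for (nm in c(microbial_names, unknown_names)) {
      hrecs[[length(hrecs) + 1L]] <- .sam_rec(nm, SAM_FLAGS[["unmapped"]],
                                              seq = .random_dna(read_length))
    }
    hrec_df <- if (length(hrecs)) do.call(rbind, hrecs) else
      .sam_rec(character(0), integer(0))[0, ]
    lengths <- c(setNames(as.integer(genomes), names(genomes)),
                 host_ref = host_len)
    list(
      microbe_sam = sam_object(mrec_df, contig_lengths = genomes),
      host_sam = sam_object(hrec_df, contig_lengths = c(host_ref = host_len)),
      lengths = lengths,
      manifest = list(seed = seed, genomes = truth, n_human = n_human,
                      n_microbial = length(microbial_names),
                      n_unknown = n_unknown)
    )
  })
}
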