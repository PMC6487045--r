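#' Normalize variant records for matching
#'
#' Decomposes each record into one row per alternate allele and reduces
#' every (REF, ALT) pair to minimal left-anchored form: shared trailing
#' bases are removed first, then shared leading bases (advancing POS),
#' always keeping at least one base on each side. Symbolic alternate
#' alleles (`<DEL>`, breakends, `*`) cannot be trimmed and are excluded,
#' with the count recorded in the `n_symbolic` attribute. The per-sample
#' genotype is re-expressed against the split allele: allele indices equal
#' to the split alt become 1, everything else 0, and the pair is sorted
#' (unphased comparison).
#'
#' @param vcf a `"vcf"` object.
#' @param sample sample whose genotype is carried along; default the
#'   first sample, `NULL` genotypes if the VCF has none.
#' @return data frame with columns `chrom`, `pos`, `ref`, `alt`, `gt`
#'   (normalized unphased genotype string such as `"0/1"`, or `NA`) and
#'   `class` (from [classify_variant()]); attribute `n_symbolic` counts
#'   excluded symbolic alts. Idempotent: normalizing the output again
#'   changes nothing.
#' @export
normalize_variants <- function(vcf, sample = NULL) {
  recs <- vcf$records
  gt_raw <- if (length(vcf$samples)) vcf_format_field(vcf, "GT", sample)
            else rep(NA_character_, nrow(recs))
  rows <- list(); n_symbolic <- 0L
  for (i in seq_len(nrow(recs))) {
    alts <- strsplit(recs$alt[i], ",", fixed = TRUE)[[1]]
    for (j in seq_along(alts)) {
      alt <- alts[j]
      if (grepl("[][<>]", alt) || alt == "*" || alt == ".") {
        n_symbolic <- n_symbolic + 1L
        next
      }
      tr <- .trim_alleles(recs$pos[i], recs$ref[i], alt)
      gt <- .normalize_gt(gt_raw[i], j)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = recs$chrom[i], pos = tr$pos, ref = tr$ref, alt = tr$alt,
        gt = gt, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), gt = character(0), stringsAsFactors = FALSE)
  out$class <- classify_variant(out$ref, out$alt)
  attr(out, "n_symbolic") <- n_symbolic
  out
}

# minimal left-anchored representation: trim shared trailing bases, then
# shared leading bases (advancing pos), keeping >= 1 base each side
.trim_alleles <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  while (length(r) > 1L && length(a) > 1L &&
         r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

# project a raw GT string onto split-alt index j as sorted binary pair
.normalize_gt <- function(gt, j) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_character_)
  al <- strsplit(gt, "[/|]")[[1]]
  bin <- ifelse(al == ".", NA, ifelse(al == as.character(j), 1L, 0L))
  if (anyNA(bin)) return(NA_character_)
  paste(sort(as.integer(bin)), collapse = "/")
}

#' Match a call set against a truth set
#'
#' Both sets are normalized with [normalize_variants()] and (optionally)
#' restricted to a region set; a call is a true positive iff some truth
#' record shares contig, position, REF and ALT exactly — and, when
#' `genotype_match`, the unphased genotype as well. Each truth record
#' matches at most one call and vice versa. Unmatched calls are false
#' positives (classed by the call record), unmatched truth records are
#' false negatives (classed by the truth record).
#'
#' This is an exact-allele matcher, a documented approximation of
#' haplotype-aware benchmarking engines (RTG vcfeval): calls that are
#' haplotype-equivalent but spelled differently after normalization are
#' not credited.
#'
#' @param truth,calls `"vcf"` objects.
#' @param regions optional normalized `region_set`; restriction is applied
#'   to both sides before matching.
#' @param genotype_match require the unphased genotype to agree (default
#'   `TRUE`).
#' @param sample sample evaluated in each VCF (default: each file's first
#'   sample).
#' @return object of class `"eval_result"`: list with `counts` (data frame
#'   of `tp`, `fp`, `fn` for rows `snv`, `small_indel`, `total`) and
#'   `metrics` (same rows, `precision`, `sensitivity`, `f_measure`, `NA`
#'   where undefined).
#' @export
match_calls <- function(truth, calls, regions = NULL, genotype_match = TRUE,
                        sample = NULL) {
  t_norm <- normalize_variants(truth, sample)
  c_norm <- normalize_variants(calls, sample)
  if (!is.null(regions)) {
    t_norm <- t_norm[restrict_positions(t_norm$chrom, t_norm$pos - 1L, regions), ,
                     drop = FALSE]
    c_norm <- c_norm[restrict_positions(c_norm$chrom, c_norm$pos - 1L, regions), ,
                     drop = FALSE]
  }
  keep_classes <- c("snv", "small_indel")
  t_norm <- t_norm[t_norm$class %in% keep_classes, , drop = FALSE]
  c_norm <- c_norm[c_norm$class %in% keep_classes, , drop = FALSE]
  key <- function(d) {
    k <- paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
    if (genotype_match) k <- paste(k, d$gt, sep = "\r")
    k
  }
  tk <- key(t_norm); ck <- key(c_norm)
  tt <- table(tk); ct <- table(ck)
  shared <- intersect(names(tt), names(ct))
  tp_per_key <- pmin(tt[shared], ct[shared])
  # class of a shared key from either side (identical alleles -> same class)
  cls_of <- t_norm$class[match(shared, tk)]
  counts <- sapply(keep_classes, function(cl) {
    tp <- sum(tp_per_key[cls_of == cl])
    n_truth <- sum(t_norm$class == cl)
    n_calls <- sum(c_norm$class == cl)
    c(tp = tp, fp = n_calls - tp, fn = n_truth - tp)
  })
  counts <- as.data.frame(t(counts))
  counts <- rbind(counts, total = colSums(counts))
  metrics <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i)
    as.data.frame(compute_metrics(counts$tp[i], counts$fp[i], counts$fn[i]))))
  rownames(metrics) <- rownames(counts)
  structure(list(counts = counts, metrics = metrics,
                 genotype_match = genotype_match),
            class = "eval_result")
}

#' Precision, sensitivity and F-measure from match counts
#'
#' Precision = Tp / (Tp + Fp), Sensitivity = Tp / (Tp + Fn), and
#' F-measure = 2 x Precision x Sensitivity / (Precision + Sensitivity),
#' the harmonic mean of the two. A zero denominator leaves the affected
#' metric `NA` (never 0, which would misrank degenerate call sets); the
#' F-measure is `NA` unless both components are defined and Tp > 0 keeps
#' their sum positive.
#'
#' @param tp,fp,fn non-negative counts of true positives, false positives
#'   and false negatives.
#' @return list with `precision`, `sensitivity`, `f_measure` (each a
#'   number in \[0, 1\] or `NA`).
#' @export
compute_metrics <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f_measure <- if (!is.na(precision) && !is.na(sensitivity) &&
                   precision + sensitivity > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else NA_real_
  list(precision = precision, sensitivity = sensitivity,
       f_measure = f_measure)
}

#' @export
print.eval_result <- function(x, digits = 4, ...) {
  cat("variant-call evaluation (genotype matching ",
      if (x$genotype_match) "on" else "off", ")\n", sep = "")
  print(cbind(x$counts, round(x$metrics, digits)))
  invisible(x)
}

#' Write an evaluation result as TSV
#'
#' One row per variant class (plus the combined total) with the match
#' counts and metrics; undefined metrics render as `NA`.
#'
#' @param result an `"eval_result"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_result <- function(result, path) {
  tab <- cbind(class = rownames(result$counts), result$counts,
               result$metrics)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
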