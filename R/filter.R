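#' Classify a variant as SNV, small indel or SV-like
#'
#' An SNV has single-base REF and ALT; a small indel has REF and ALT of
#' different lengths with the longer allele at most 50 bp (the boundary of
#' the "small" class; larger events and symbolic alleles are SV-like and
#' out of scope for the hard-filter path). Equal-length multi-base
#' substitutions are also classed SV-like.
#'
#' @param ref,alt character vectors of explicit alleles (one alt per
#'   entry; split multiallelics first).
#' @param max_indel largest allele length still called a small indel
#'   (default 50).
#' @return character vector over `{"snv", "small_indel", "sv_like"}`.
#' @export
classify_variant <- function(ref, alt, max_indel = 50L) {
  symbolic <- grepl("[][<>]", alt) | alt == "*"
  lr <- nchar(ref); la <- nchar(alt)
  out <- rep("sv_like", length(ref))
  out[!symbolic & lr == 1L & la == 1L] <- "snv"
  small <- !symbolic & lr != la & pmax(lr, la) <= max_indel
  out[small] <- "small_indel"
  out
}

#' Hard-filter variant records on genotype quality and depth
#'
#' Applies the pipeline's hard filter: calls with genotype quality below
#' `min_gq` or depth below `min_dp` for the evaluated sample are discarded.
#' The thresholds are strict "smaller than" rules, so GQ = 20 and DP = 10
#' pass at the defaults. Missing GQ or DP fails by default (conservative
#' for a diagnostic-flavoured pipeline); set `missing_fails = FALSE` to let
#' a missing field pass its half of the test.
#'
#' @param vcf a `"vcf"` object.
#' @param min_gq minimum genotype quality (default 20).
#' @param min_dp minimum depth (default 10).
#' @param missing_fails treat missing GQ/DP as failing (default `TRUE`).
#' @param sample sample to evaluate; default the first sample. An unknown
#'   name is an error.
#' @return list with `passed` and `failed` (record data frames, original
#'   order preserved), `reasons` (character vector parallel to `failed`,
#'   comma-joined tags among `low_gq`, `low_dp`, `missing_gq`,
#'   `missing_dp`) and `counts` (`pass`, `fail`).
#' @export
apply_hard_filters <- function(vcf, min_gq = 20L, min_dp = 10L,
                               missing_fails = TRUE, sample = NULL) {
  stopifnot(min_gq >= 0L, min_dp >= 0L)
  gq <- suppressWarnings(as.integer(vcf_format_field(vcf, "GQ", sample)))
  dp <- suppressWarnings(as.integer(vcf_format_field(vcf, "DP", sample)))
  n <- nrow(vcf$records)
  tags <- vector("list", n)
  for (i in seq_len(n)) {
    t <- character(0)
    if (is.na(gq[i])) {
      if (missing_fails) t <- c(t, "missing_gq")
    } else if (gq[i] < min_gq) t <- c(t, "low_gq")
    if (is.na(dp[i])) {
      if (missing_fails) t <- c(t, "missing_dp")
    } else if (dp[i] < min_dp) t <- c(t, "low_dp")
    tags[[i]] <- t
  }
  fail <- lengths(tags) > 0L
  list(
    passed = vcf$records[!fail, , drop = FALSE],
    failed = vcf$records[fail, , drop = FALSE],
    reasons = vapply(tags[fail], paste, "", collapse = ","),
    counts = c(pass = sum(!fail), fail = sum(fail))
  )
}

#' Annotate rather than drop filter failures
#'
#' Rewrites the FILTER column of a VCF per the hard-filter verdicts:
#' failures get `lowGQ` and/or `lowDP` (semicolon-joined; missing fields
#' map to the same tags), passing records are left untouched. This is the
#' audit-friendly alternative to discarding failures.
#'
#' @inheritParams apply_hard_filters
#' @return a `"vcf"` object with updated FILTER values.
#' @export
tag_hard_filters <- function(vcf, min_gq = 20L, min_dp = 10L,
                             missing_fails = TRUE, sample = NULL) {
  res <- apply_hard_filters(vcf, min_gq, min_dp, missing_fails, sample)
  if (nrow(res$failed)) {
    tag <- gsub("missing_gq|low_gq", "lowGQ", res$reasons)
    tag <- gsub("missing_dp|low_dp", "lowDP", tag)
    tag <- gsub(",", ";", tag, fixed = TRUE)
    idx <- match(rownames(res$failed), rownames(vcf$records))
    vcf$records$filter[idx] <- tag
  }
  vcf
}

#' Restrict a call set to a region set
#'
#' Keeps records whose 0-based position (`POS - 1`) lies inside the region
#' union (point containment, the same convention as BED half-open
#' intervals).
#'
#' @param vcf a `"vcf"` object.
#' @param regions a normalized `region_set`.
#' @return the `"vcf"` with only the retained records, order preserved.
#' @export
restrict_calls <- function(vcf, regions) {
  keep <- restrict_positions(vcf$records$chrom, vcf$records$pos - 1L, regions)
  vcf$records <- vcf$records[keep, , drop = FALSE]
  vcf
}
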