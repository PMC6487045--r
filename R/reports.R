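#' Resolve a run mode into stage toggles
#'
#' The pipeline runs in three modes that trade speed for sensitivity:
#' `fast` (first-pass alignment only), `normal` (adds the soft-clip /
#' unmapped read refinement triage) and `intensive` (additionally targets
#' an intensive indel caller on CIGAR-evidenced hotspots). Since external
#' aligners and callers are out of process here, a mode is represented as
#' the toggle set of the in-library stages; explicit per-stage overrides
#' win over the mode default. The microbe screen is available in every
#' mode.
#'
#' @param mode one of `"fast"`, `"normal"`, `"intensive"`.
#' @param triage,hotspots,screen optional logical overrides.
#' @return list of class `"mode_config"`: `mode`, `triage_enabled`,
#'   `hotspots_enabled`, `screen_enabled`.
#' @export
resolve_mode <- function(mode, triage = NULL, hotspots = NULL,
                         screen = NULL) {
  modes <- list(
    fast      = c(triage = FALSE, hotspots = FALSE),
    normal    = c(triage = TRUE,  hotspots = FALSE),
    intensive = c(triage = TRUE,  hotspots = TRUE)
  )
  if (!mode %in% names(modes)) {
    stop("unknown mode '", mode, "'; valid modes: ",
         paste(names(modes), collapse = ", "))
  }
  cfg <- list(mode = mode,
              triage_enabled = triage %||% modes[[mode]][["triage"]],
              hotspots_enabled = hotspots %||% modes[[mode]][["hotspots"]],
              screen_enabled = screen %||% TRUE)
  class(cfg) <- "mode_config"
  cfg
}

#' @export
print.mode_config <- function(x, ...) {
  cat("mode '", x$mode, "': triage=", x$triage_enabled,
      " hotspots=", x$hotspots_enabled, " screen=", x$screen_enabled,
      "\n", sep = "")
  invisible(x)
}

#' Build the tab-delimited variant report
#'
#' One row per (variant, alternate allele) with the core columns `contig,
#' pos, ref, alt, class, GT, GQ, DP`; an optional annotation table (joined
#' on contig/pos/ref/alt) contributes extra columns to the right of the
#' core ones. Rows are ordered by (contig, pos, alt) and the header row is
#' always present, so an empty call set yields a header-only file.
#'
#' @param vcf a filtered (and optionally region-restricted) `"vcf"`.
#' @param annotations optional data frame whose first four columns are
#'   `contig, pos, ref, alt` followed by annotation columns; duplicate
#'   join keys are an error.
#' @param sample sample whose GT/GQ/DP are reported (default first).
#' @return data frame, one row per variant-alt.
#' @export
variant_report <- function(vcf, annotations = NULL, sample = NULL) {
  recs <- vcf$records
  gt <- if (length(vcf$samples)) vcf_format_field(vcf, "GT", sample) else NA
  gq <- if (length(vcf$samples)) vcf_format_field(vcf, "GQ", sample) else NA
  dp <- if (length(vcf$samples)) vcf_format_field(vcf, "DP", sample) else NA
  rows <- list()
  for (i in seq_len(nrow(recs))) {
    for (alt in strsplit(recs$alt[i], ",", fixed = TRUE)[[1]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = recs$chrom[i], pos = recs$pos[i], ref = recs$ref[i],
        alt = alt, class = classify_variant(recs$ref[i], alt),
        GT = gt[i], GQ = gq[i], DP = dp[i], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), pos = integer(0), ref = character(0),
               alt = character(0), class = character(0), GT = character(0),
               GQ = character(0), DP = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(annotations)) {
    key <- function(d) paste(d[[1]], d[[2]], d[[3]], d[[4]], sep = "\r")
    ak <- key(annotations)
    if (anyDuplicated(ak)) {
      stop("annotation join key collision at ",
           annotations[[1]][which(duplicated(ak))[1]], ":",
           annotations[[2]][which(duplicated(ak))[1]])
    }
    idx <- match(key(out), ak)
    extra <- annotations[idx, -(1:4), drop = FALSE]
    rownames(extra) <- NULL
    out <- cbind(out, extra)
  }
  out
}

#' @rdname variant_report
#' @param report data frame from `variant_report()`.
#' @param path output TSV path.
#' @export
write_variant_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble the machine-readable run summary
#'
#' Collects per-stage tallies into one schema-versioned list: triage
#' counts, hotspot target count and total target bases, filter pass/fail,
#' screen class tallies and proportions, and evaluation counts/metrics.
#' Stages that did not run are `NULL`.
#'
#' @param triage a `"triage_result"` or `NULL`.
#' @param hotspots a `region_set` of targets or `NULL`.
#' @param filter result of [apply_hard_filters()] or `NULL`.
#' @param screen a `"screen_summary"` or `NULL`.
#' @param eval an `"eval_result"` or `NULL`.
#' @return list with `schema_version` and one block per stage.
#' @export
run_summary <- function(triage = NULL, hotspots = NULL, filter = NULL,
                        screen = NULL, eval = NULL) {
  list(
    schema_version = "1.0",
    triage = if (!is.null(triage)) as.list(triage$counts),
    hotspots = if (!is.null(hotspots)) list(
      n_targets = nrow(hotspots),
      total_target_bases = sum(hotspots$end - hotspots$start)),
    filter = if (!is.null(filter)) as.list(filter$counts),
    screen = if (!is.null(screen)) list(
      n_total = screen$n_total, n_human = screen$n_human,
      n_microbial = screen$n_microbial, n_unknown = screen$n_unknown,
      proportions = as.list(screen$proportions)),
    eval = if (!is.null(eval)) list(
      counts = as.list(eval$counts["total", ]),
      metrics = as.list(eval$metrics["total", ]))
  )
}

#' @rdname run_summary
#' @param summary list from `run_summary()`.
#' @param path output JSON path.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
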