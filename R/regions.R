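#' Genomic region sets
#'
#' Regions are stored 0-based half-open (`[start, end)`), the native BED
#' convention and the internal convention of this package; SAM/VCF 1-based
#' positions are converted at the boundary. A `region_set` is a data frame
#' with columns `contig`, `start`, `end` (and optionally `name`), carrying
#' class `"region_set"`.
#'
#' @param contig character vector of contig names.
#' @param start,end integer vectors, 0-based half-open; `end > start >= 0`.
#' @param name optional character vector (e.g. BED column 4 gene symbols).
#' @return a `region_set`.
#' @export
region_set <- function(contig = character(0), start = integer(0),
                       end = integer(0), name = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L)) stop("region start must be >= 0")
  if (any(end <= start)) stop("region end must be > start")
  df <- data.frame(contig = as.character(contig), start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  class(df) <- c("region_set", "data.frame")
  df
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set with ", nrow(x), " interval(s) on ",
      length(unique(x$contig)), " contig(s)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Read and write BED files
#'
#' `read_bed()` parses 3+ column BED (0-based half-open coordinates kept
#' exactly); `track`, `browser` and `#` comment lines are skipped. A fourth
#' column, when present, is kept as `name` (used by [genes_to_regions()]);
#' further columns are ignored. `write_bed()` emits the first three columns
#' only.
#'
#' @param path file path.
#' @return `read_bed()` a `region_set`; `write_bed()` `path` invisibly.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) &
    !startsWith(lines, "track") & !startsWith(lines, "browser") &
    !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(region_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1]
    stop("BED line ", lineno[bad], ": expected >= 3 tab-separated columns")
  }
  contig <- vapply(parts, `[[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop("BED line ", lineno[bad], ": non-integer coordinates")
  }
  if (any(end <= start)) {
    bad <- which(end <= start)[1]
    stop("BED line ", lineno[bad], ": end (", end[bad],
         ") must be > start (", start[bad], ")")
  }
  name <- if (any(nf >= 4L)) {
    vapply(parts, function(p) if (length(p) >= 4L) p[[4]] else "", "")
  } else NULL
  region_set(contig, start, end, name = name)
}

#' @rdname read_bed
#' @param regions a `region_set`.
#' @export
write_bed <- function(regions, path) {
  writeLines(paste(regions$contig, regions$start, regions$end, sep = "\t"),
             path)
  invisible(path)
}

# region_set -> per-contig IRanges list (1-based closed for IRanges)
.regions_by_contig <- function(regions) {
  split(IRanges::IRanges(start = regions$start + 1L, end = regions$end),
        regions$contig)
}

#' Merge intervals into a normalized region set
#'
#' Produces the minimal sorted, non-overlapping set of intervals whose
#' union equals the input union, joining intervals at most `gap` bases
#' apart (`gap = 0` joins overlapping and abutting intervals). Idempotent
#' and order-insensitive.
#'
#' @param regions a `region_set` (any order, overlaps allowed).
#' @param gap non-negative integer; intervals separated by <= `gap` bases
#'   are joined.
#' @return a normalized `region_set`.
#' @export
merge_regions <- function(regions, gap = 0L) {
  stopifnot(gap >= 0L)
  if (nrow(regions) == 0L) return(region_set())
  by_contig <- .regions_by_contig(regions)
  out <- lapply(sort(names(by_contig)), function(ctg) {
    r <- IRanges::reduce(by_contig[[ctg]], min.gapwidth = gap + 1L)
    data.frame(contig = ctg, start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  region_set(out$contig, out$start, out$end)
}

#' Restrict intervals or positions to a region set
#'
#' `restrict_regions()` keeps query intervals overlapping the region union
#' by at least one base; `restrict_positions()` keeps 0-based point
#' positions contained in the union.
#'
#' @param query a `region_set` of query intervals.
#' @param regions a normalized `region_set`.
#' @return `restrict_regions()`: the retained subset of `query`, input
#'   order preserved. `restrict_positions()`: a logical vector.
#' @export
restrict_regions <- function(query, regions) {
  if (nrow(query) == 0L || nrow(regions) == 0L) return(query[integer(0), ])
  keep <- rep(FALSE, nrow(query))
  by_contig <- .regions_by_contig(regions)
  for (ctg in unique(query$contig)) {
    idx <- which(query$contig == ctg)
    if (is.null(by_contig[[ctg]])) next
    q <- IRanges::IRanges(start = query$start[idx] + 1L, end = query$end[idx])
    keep[idx] <- IRanges::countOverlaps(q, by_contig[[ctg]]) > 0L
  }
  query[keep, , drop = FALSE]
}

#' @rdname restrict_regions
#' @param contig character vector of contigs, parallel to `pos0`.
#' @param pos0 integer vector of 0-based positions.
#' @export
restrict_positions <- function(contig, pos0, regions) {
  keep <- rep(FALSE, length(pos0))
  if (nrow(regions) == 0L || !length(pos0)) return(keep)
  by_contig <- .regions_by_contig(regions)
  for (ctg in unique(contig)) {
    idx <- which(contig == ctg)
    if (is.null(by_contig[[ctg]])) next
    q <- IRanges::IRanges(start = pos0[idx] + 1L, width = 1L)
    keep[idx] <- IRanges::countOverlaps(q, by_contig[[ctg]]) > 0L
  }
  keep
}

#' Resolve gene names to regions via an annotation BED
#'
#' Maps requested gene symbols to the intervals of an annotation BED whose
#' fourth column carries the symbol (case-insensitive exact match). The
#' gene-list and whole-exome region options of the pipeline both reduce to
#' this lookup with a user-supplied annotation; no gene model is bundled.
#'
#' @param genes character vector of gene symbols (case-insensitively
#'   deduplicated).
#' @param annotation a `region_set` with a `name` column, e.g. from
#'   [read_bed()] on a 4+ column BED.
#' @return the union (merged) `region_set` of matching intervals; a warning
#'   lists any unmatched names, and all-miss yields an empty set.
#' @export
genes_to_regions <- function(genes, annotation) {
  if (is.null(annotation$name)) {
    stop("annotation BED must have a name (4th) column")
  }
  genes <- unique(toupper(genes))
  hit <- toupper(annotation$name) %in% genes
  missed <- setdiff(genes, unique(toupper(annotation$name[hit])))
  if (length(missed)) {
    warning("gene name(s) not found in annotation: ",
            paste(missed, collapse = ", "))
  }
  if (!any(hit)) return(region_set())
  merge_regions(annotation[hit, , drop = FALSE])
}
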