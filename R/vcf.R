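#' Read a VCF file
#'
#' Parses plain-text VCF v4.2: `##` meta lines are kept verbatim, the
#' `#CHROM` line defines the sample columns, and each record line is
#' split into the fixed columns plus one character column per sample.
#' POS is parsed as an integer; all other fields are kept as text so that
#' [write_vcf()] reproduces the input byte for byte.
#'
#' @param path path to an uncompressed VCF file.
#' @return An object of class `"vcf"`: list with `meta` (the `##` lines),
#'   `samples` (character vector, possibly empty) and `records` (data
#'   frame with columns `chrom, pos, id, ref, alt, qual, filter, info,
#'   format` and one column per sample).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "##")]
  chrom_line <- lines[startsWith(lines, "#CHROM")]
  if (length(chrom_line) != 1L) stop("VCF must have exactly one #CHROM line")
  cols <- strsplit(chrom_line, "\t", fixed = TRUE)[[1]]
  samples <- if (length(cols) > 9L) cols[-(1:9)] else character(0)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fixed_names <- c("chrom", "pos", "id", "ref", "alt", "qual", "filter",
                   "info", "format")
  n_fixed <- min(length(cols), 9L)
  if (!length(body)) {
    recs <- as.data.frame(setNames(rep(list(character(0)),
                                       n_fixed + length(samples)),
                                   c(fixed_names[1:n_fixed], samples)),
                          stringsAsFactors = FALSE)
    recs$pos <- integer(0)
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != length(cols))) {
      bad <- which(nf != length(cols))[1]
      stop("VCF record ", bad, ": expected ", length(cols), " fields, got ",
           nf[bad])
    }
    recs <- as.data.frame(lapply(seq_along(cols), function(i)
      vapply(parts, `[[`, "", i)), stringsAsFactors = FALSE)
    names(recs) <- c(fixed_names[1:n_fixed], samples)
    pos <- suppressWarnings(as.integer(recs$pos))
    if (anyNA(pos)) stop("VCF record ", which(is.na(pos))[1], ": non-integer POS")
    recs$pos <- pos
  }
  structure(list(meta = meta, samples = samples, records = recs),
            class = "vcf")
}

#' Write a VCF file
#'
#' @param vcf a `"vcf"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vcf, path) {
  stopifnot(inherits(vcf, "vcf"))
  chrom <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO",
                   if (length(vcf$samples) || !is.null(vcf$records$format))
                     "FORMAT",
                   vcf$samples), collapse = "\t")
  body <- if (nrow(vcf$records)) {
    do.call(paste, c(unname(as.list(vcf$records)), sep = "\t"))
  } else character(0)
  writeLines(c(vcf$meta, chrom, body), path)
  invisible(path)
}

#' @export
print.vcf <- function(x, ...) {
  cat("VCF: ", nrow(x$records), " record(s), sample(s): ",
      if (length(x$samples)) paste(x$samples, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

#' Extract a per-sample FORMAT field
#'
#' Looks a key (e.g. `"GT"`, `"GQ"`, `"DP"`) up in each record's FORMAT
#' string and returns the corresponding entry of the sample column.
#' Missing keys and `"."` entries return `NA`.
#'
#' @param vcf a `"vcf"` object.
#' @param key FORMAT key.
#' @param sample sample name; default the first sample.
#' @return character vector, one entry per record (`NA` when absent).
#' @export
vcf_format_field <- function(vcf, key, sample = NULL) {
  if (is.null(sample)) {
    if (!length(vcf$samples)) stop("VCF has no sample columns")
    sample <- vcf$samples[1]
  }
  if (!sample %in% vcf$samples) {
    stop("unknown sample '", sample, "'; VCF has: ",
         paste(vcf$samples, collapse = ", "))
  }
  recs <- vcf$records
  n <- nrow(recs)
  out <- rep(NA_character_, n)
  if (!n) return(out)
  fmt <- strsplit(recs$format, ":", fixed = TRUE)
  val <- strsplit(recs[[sample]], ":", fixed = TRUE)
  for (i in seq_len(n)) {
    j <- match(key, fmt[[i]])
    if (!is.na(j) && j <= length(val[[i]]) && val[[i]][j] != ".") {
      out[i] <- val[[i]][j]
    }
  }
  out
}

#' Construct a minimal VCF object from a record data frame
#'
#' @param records data frame with the `"vcf"` record columns.
#' @param samples sample names matching the trailing columns.
#' @param meta optional `##` meta lines; a minimal fileformat/GT/GQ/DP
#'   header is supplied by default.
#' @param contig_lengths optional named integer vector emitted as
#'   `##contig` lines.
#' @return a `"vcf"` object.
#' @export
vcf_object <- function(records, samples = character(0), meta = NULL,
                       contig_lengths = NULL) {
  if (is.null(meta)) {
    meta <- c("##fileformat=VCFv4.2",
              if (!is.null(contig_lengths))
                paste0("##contig=<ID=", names(contig_lengths), ",length=",
                       as.integer(contig_lengths), ">"),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">")
  }
  structure(list(meta = meta, samples = samples, records = records),
            class = "vcf")
}
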