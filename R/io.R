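SEGMENT_COLS <- c("sample1", "hap1", "sample2", "hap2", "chrom",
                  "start_bp", "end_bp", "lod", "length_cM")

empty_segments <- function() {
  data.frame(sample1 = character(), hap1 = integer(),
             sample2 = character(), hap2 = integer(),
             chrom = character(), start_bp = numeric(),
             end_bp = numeric(), lod = numeric(),
             length_cM = numeric(), stringsAsFactors = FALSE)
}

#' Read IBD or HBD/ROH segments
#'
#' Reads the 9-column whitespace-delimited segment dialect emitted by
#' refinedIBD-style detectors (and by [write_segments()]):
#' `sample1 hap1 sample2 hap2 chrom start end lod length_cM`.
#' Coordinates are 1-based inclusive base pairs; the cM length is taken
#' from column 9 and never recomputed from bp. Gzipped files are accepted.
#'
#' @param path file path (.ibd / .hbd, optionally .gz).
#' @param kind `"ibd"` for between-individual segments, `"hbd"` for
#'   within-individual ROH (sample1 must equal sample2, haplotypes differ).
#' @return data.frame with columns sample1, hap1, sample2, hap2, chrom,
#'   start_bp, end_bp, lod, length_cM; row order preserved.
#' @export
read_segments <- function(path, kind = c("ibd", "hbd")) {
  kind <- match.arg(kind)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_segments())

  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf != 9)) {
    i <- which(nf != 9)[1]
    stop(sprintf("malformed row at line %d: expected 9 fields, found %d",
                 line_no[i], nf[i]))
  }
  m <- matrix(unlist(parts, use.names = FALSE), ncol = 9, byrow = TRUE)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("malformed row at line %d: non-numeric %s '%s'",
                   line_no[i], what, m[i, col]))
    }
    v
  }
  seg <- data.frame(
    sample1 = m[, 1], hap1 = as.integer(num(2, "hap1")),
    sample2 = m[, 3], hap2 = as.integer(num(4, "hap2")),
    chrom = m[, 5],
    start_bp = num(6, "start"), end_bp = num(7, "end"),
    lod = num(8, "lod"), length_cM = num(9, "length_cM"),
    stringsAsFactors = FALSE)

  bad <- which(seg$start_bp > seg$end_bp | seg$length_cM <= 0 |
                 !(seg$hap1 %in% 1:2) | !(seg$hap2 %in% 1:2))
  if (length(bad))
    stop(sprintf("invalid segment at line %d", line_no[bad[1]]))
  same_hap <- seg$sample1 == seg$sample2 & seg$hap1 == seg$hap2
  if (any(same_hap))
    stop(sprintf("segment joins a haplotype to itself at line %d",
                 line_no[which(same_hap)[1]]))
  if (kind == "hbd") {
    bad <- which(seg$sample1 != seg$sample2)
    if (length(bad))
      stop(sprintf("hbd row with distinct samples at line %d", line_no[bad[1]]))
  }
  seg
}

#' Write segments in the 9-column dialect
#'
#' Inverse of [read_segments()]: `read_segments(write_segments(x))` returns
#' `x` exactly (numeric fields are written with full precision).
#'
#' @param segments segment data.frame.
#' @param path output path.
#' @export
write_segments <- function(segments, path) {
  stopifnot(all(SEGMENT_COLS %in% names(segments)))
  con <- file(path, "wt")
  on.exit(close(con))
  if (nrow(segments) == 0) return(invisible(path))
  lines <- sprintf("%s\t%d\t%s\t%d\t%s\t%d\t%d\t%.17g\t%.17g",
                   segments$sample1, segments$hap1,
                   segments$sample2, segments$hap2,
                   segments$chrom,
                   as.integer(segments$start_bp), as.integer(segments$end_bp),
                   segments$lod, segments$length_cM)
  writeLines(lines, con)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with header; requires `sample_id`, and optionally `region`,
#' `surname`, `surname_origin` (absent columns become NA).
#'
#' @param path TSV path.
#' @return data.frame sample_id, region, surname, surname_origin.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character",
                          na.strings = c("NA", ""))
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         df$sample_id[duplicated(df$sample_id)][1])
  for (col in c("region", "surname", "surname_origin"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  df[, c("sample_id", "region", "surname", "surname_origin")]
}

#' @rdname read_metadata
#' @param metadata metadata data.frame.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a genotype matrix
#'
#' TSV with header: first column `sample_id`, remaining columns one SNP
#' each, values in {0, 1, 2, NA} (alternate-allele counts).
#'
#' @param path TSV path.
#' @return integer matrix (samples x SNPs) with sample row names and SNP
#'   column names.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (!"sample_id" %in% names(df)) stop("genotype table must have sample_id")
  ids <- df$sample_id
  if (anyDuplicated(ids)) stop("duplicate sample_id in genotype table")
  g <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  if (!all(g %in% c("0", "1", "2") | is.na(g)))
    stop("genotype value outside {0,1,2,NA}")
  storage.mode(g) <- "integer"
  rownames(g) <- ids
  g
}

#' @rdname read_genotypes
#' @param genotypes integer matrix with sample row names.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(sample_id = rownames(genotypes),
                   genotypes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
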