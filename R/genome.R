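#' Genome map
#'
#' A genome map lists the chromosomes over which IBD/ROH segments live,
#' with their genetic (cM) and physical (bp) lengths. The total genetic
#' length L drives expected segment counts; the chromosome count K enters
#' the segment-count formula as an additive offset (each chromosome yields
#' at least one segment even without crossovers).
#'
#' @param chromosomes data.frame with columns `name`, `length_cM`
#'   (positive), `length_bp` (positive integer).
#' @return An object of class `genome_map`: list with `chromosomes`,
#'   `total_cM` and `n_chrom`.
#' @export
genome_map <- function(chromosomes) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_cM", "length_bp") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$name))
    stop("chromosome names must be unique")
  if (any(chromosomes$length_cM <= 0) || any(chromosomes$length_bp <= 0))
    stop("chromosome lengths must be positive")
  structure(
    list(chromosomes = chromosomes,
         total_cM = sum(chromosomes$length_cM),
         n_chrom = nrow(chromosomes)),
    class = "genome_map")
}

#' Default synthetic genome
#'
#' 22 autosome-like chromosomes with mildly decreasing lengths summing to
#' `total_cM` (default 3500 cM), and 1 cM = 1 Mb physical scale. Any other
#' map can be supplied wherever a `genome_map` is accepted.
#'
#' @param n_chrom number of chromosomes.
#' @param total_cM total genetic length in centimorgans.
#' @return a `genome_map`.
#' @export
default_genome <- function(n_chrom = 22, total_cM = 3500) {
  w <- (n_chrom + 1 - seq_len(n_chrom)) + 2
  len <- total_cM * w / sum(w)
  genome_map(data.frame(
    name = paste0("chr", seq_len(n_chrom)),
    length_cM = len,
    length_bp = round(len * 1e6),
    stringsAsFactors = FALSE))
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("<genome_map> %d chromosomes, total %.1f cM\n",
              x$n_chrom, x$total_cM))
  invisible(x)
}
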