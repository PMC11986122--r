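#' Simulate IBD segments under a demography
#'
#' Coalescent-Poisson generator: for every unordered haplotype pair (4 per
#' diploid pair) the number of detectable segments tracing to generation g
#' is Poisson with mean c(g) (2gL/100 + K) exp(-2gm/100), and detectable
#' lengths are m + Exponential(mean 100/(2g)) cM — an exact thinning of
#' the draw-then-discard model, by memorylessness of the exponential.
#' Segments are placed on chromosomes with probability proportional to
#' genetic length, at uniform starts (overlap between placements of the
#' same pair is ignored; downstream statistics use counts and totals).
#'
#' Sample ids are `<pop>_<i>`; the LOD column is a constant 10.
#'
#' @param model a `demography_model`.
#' @param samples_per_pop named integer vector, diploid sample count per
#'   population (names must match the model's populations).
#' @param genome a `genome_map`.
#' @param seed integer seed; output is deterministic given the seed.
#' @return segment data.frame in the 9-column dialect (see
#'   [read_segments()]).
#' @export
simulate_ibd <- function(model, samples_per_pop, genome, seed) {
  stopifnot(inherits(model, "demography_model"), inherits(genome, "genome_map"))
  check_samples_arg(model, samples_per_pop, min_n = 1L)
  set.seed(seed)
  ids <- sample_ids(samples_per_pop)
  pops <- names(samples_per_pop)
  out <- list()
  for (ai in seq_along(pops)) for (bi in ai:length(pops)) {
    a <- pops[ai]; b <- pops[bi]
    pairs <- diploid_pairs(ids[[a]], ids[[b]], within = (ai == bi))
    if (nrow(pairs) == 0) next
    cg <- coalescence_profile(model, a, b)
    out[[paste(a, b)]] <- draw_segments(cg, pairs, n_hap_pairs = 4L,
                                        model$m_cM, genome)
  }
  if (length(out) == 0) return(empty_segments())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate ROH (HBD) segments
#'
#' As [simulate_ibd()] but for the single within-individual haplotype pair
#' of each diploid, using the within-population coalescence profile:
#' sample1 = sample2 and hap1 = 1, hap2 = 2.
#'
#' @inheritParams simulate_ibd
#' @return ROH segment data.frame (9-column dialect).
#' @export
simulate_roh <- function(model, samples_per_pop, genome, seed) {
  stopifnot(inherits(model, "demography_model"), inherits(genome, "genome_map"))
  check_samples_arg(model, samples_per_pop, min_n = 1L)
  set.seed(seed)
  ids <- sample_ids(samples_per_pop)
  out <- list()
  for (a in names(samples_per_pop)) {
    if (length(ids[[a]]) == 0) next
    pairs <- data.frame(s1 = ids[[a]], s2 = ids[[a]],
                        stringsAsFactors = FALSE)
    cg <- coalescence_profile(model, a, a)
    out[[a]] <- draw_segments(cg, pairs, n_hap_pairs = 1L, model$m_cM, genome)
  }
  if (length(out) == 0) return(empty_segments())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

check_samples_arg <- function(model, samples_per_pop, min_n = 2L) {
  if (is.null(names(samples_per_pop)) ||
      !all(names(samples_per_pop) %in% model$pops))
    stop("samples_per_pop must be named by the model's populations")
  if (any(samples_per_pop < min_n))
    stop("need at least ", min_n, " diploid(s) per population")
}

sample_ids <- function(samples_per_pop) {
  lapply(stats::setNames(names(samples_per_pop), names(samples_per_pop)),
         function(p) paste0(p, "_", seq_len(samples_per_pop[[p]])))
}

diploid_pairs <- function(ids_a, ids_b, within) {
  if (within) {
    n <- length(ids_a)
    if (n < 2) return(data.frame(s1 = character(), s2 = character()))
    idx <- utils::combn(n, 2)
    data.frame(s1 = ids_a[idx[1, ]], s2 = ids_a[idx[2, ]],
               stringsAsFactors = FALSE)
  } else {
    expand.grid(s1 = ids_a, s2 = ids_b, stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)
  }
}

# Draw segments for all haplotype pairs of the given diploid pairs.
# n_hap_pairs = 4 (between individuals) or 1 (ROH: haps 1 and 2 of one
# individual).
draw_segments <- function(cg, pairs, n_hap_pairs, m_cM, genome) {
  G <- length(cg)
  g <- seq_len(G)
  L <- genome$total_cM; K <- genome$n_chrom
  lam <- cg * (2 * g * L / 100 + K) * exp(-2 * g * m_cM / 100)
  Lam <- sum(lam)
  hap_combo <- if (n_hap_pairs == 4L)
    cbind(h1 = c(1L, 1L, 2L, 2L), h2 = c(1L, 2L, 1L, 2L))
  else cbind(h1 = 1L, h2 = 2L)

  n_units <- nrow(pairs) * n_hap_pairs
  if (n_units == 0 || Lam <= 0) return(empty_segments())
  counts <- stats::rpois(n_units, Lam)
  M <- sum(counts)
  if (M == 0) return(empty_segments())

  unit <- rep.int(seq_len(n_units), counts)
  pair_idx <- ((unit - 1L) %/% n_hap_pairs) + 1L
  combo_idx <- ((unit - 1L) %% n_hap_pairs) + 1L

  gen <- sample.int(G, M, replace = TRUE, prob = lam)
  len <- m_cM + stats::rexp(M, rate = 2 * gen / 100)

  chrom_idx <- sample.int(K, M, replace = TRUE,
                          prob = genome$chromosomes$length_cM)
  chrom_bp <- genome$chromosomes$length_bp[chrom_idx]
  bp_per_cM <- genome$chromosomes$length_bp[chrom_idx] /
    genome$chromosomes$length_cM[chrom_idx]
  len_bp <- pmax(1, round(len * bp_per_cM))
  max_start <- pmax(1, chrom_bp - len_bp + 1)
  start <- 1 + floor(stats::runif(M) * max_start)
  end <- pmin(start + len_bp - 1, chrom_bp)

  data.frame(
    sample1 = pairs$s1[pair_idx],
    hap1 = hap_combo[combo_idx, "h1"],
    sample2 = pairs$s2[pair_idx],
    hap2 = hap_combo[combo_idx, "h2"],
    chrom = genome$chromosomes$name[chrom_idx],
    start_bp = start, end_bp = end,
    lod = 10.0, length_cM = len,
    stringsAsFactors = FALSE)
}

#' Simulate genotypes with a known inbreeding coefficient
#'
#' Per SNP, the alternate-allele frequency p is Uniform(0.05, 0.5) and
#' genotypes follow the inbreeding model
#' P(2) = p^2 + f p(1-p), P(1) = 2p(1-p)(1-f), P(0) = (1-p)^2 + f p(1-p).
#'
#' @param n_samples number of diploid samples.
#' @param n_snps number of SNPs.
#' @param f_inbreeding within-population inbreeding coefficient in [0, 1).
#' @param seed integer seed.
#' @param sample_ids optional sample id vector (default S1..Sn).
#' @return list with `genotypes` (integer matrix samples x SNPs) and
#'   `allele_freqs` (the true p per SNP).
#' @export
simulate_genotypes <- function(n_samples, n_snps, f_inbreeding, seed,
                               sample_ids = NULL) {
  if (f_inbreeding < 0 || f_inbreeding >= 1)
    stop("f_inbreeding must be in [0, 1)")
  set.seed(seed)
  p <- stats::runif(n_snps, 0.05, 0.5)
  f <- f_inbreeding
  P2 <- p^2 + f * p * (1 - p)
  P1 <- 2 * p * (1 - p) * (1 - f)
  u <- matrix(stats::runif(n_samples * n_snps), n_samples, n_snps)
  thr2 <- matrix(P2, n_samples, n_snps, byrow = TRUE)
  thr1 <- matrix(P2 + P1, n_samples, n_snps, byrow = TRUE)
  g <- (u < thr2) * 2L + (u >= thr2 & u < thr1) * 1L
  storage.mode(g) <- "integer"
  rownames(g) <- if (is.null(sample_ids)) paste0("S", seq_len(n_samples))
                 else sample_ids
  colnames(g) <- paste0("snp", seq_len(n_snps))
  list(genotypes = g, allele_freqs = p)
}

#' Simulate community-structured surname origins
#'
#' Each sample's surname-origin category is drawn from its community's row
#' of an enrichment matrix (rows = communities, columns = origin
#' categories, each row a probability vector). A synthetic surname string
#' is attached so the metadata round-trips through [write_metadata()].
#'
#' @param community_labels named character vector: sample_id -> community.
#' @param origin_categories character vector of origin category names.
#' @param enrichment_matrix numeric matrix, communities x origins; rows
#'   must sum to 1 (within 1e-9). Row names must cover the communities.
#' @param seed integer seed.
#' @return metadata data.frame (sample_id, region, surname,
#'   surname_origin); region carries the community label.
#' @export
simulate_surnames <- function(community_labels, origin_categories,
                              enrichment_matrix, seed) {
  stopifnot(!is.null(names(community_labels)),
            ncol(enrichment_matrix) == length(origin_categories))
  if (any(abs(rowSums(enrichment_matrix) - 1) > 1e-9))
    stop("enrichment_matrix rows must sum to 1")
  comms <- unique(community_labels)
  if (is.null(rownames(enrichment_matrix)) ||
      !all(comms %in% rownames(enrichment_matrix)))
    stop("enrichment_matrix rows must be named by community")
  set.seed(seed)
  origin <- character(length(community_labels))
  for (cm in comms) {
    idx <- which(community_labels == cm)
    origin[idx] <- sample(origin_categories, length(idx), replace = TRUE,
                          prob = enrichment_matrix[cm, ])
  }
  data.frame(
    sample_id = names(community_labels),
    region = unname(community_labels),
    surname = paste0(tolower(origin), "_", sample.int(25, length(origin),
                                                      replace = TRUE)),
    surname_origin = origin,
    stringsAsFactors = FALSE)
}
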