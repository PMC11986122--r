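#' Canonical IBD length bins
#'
#' The three time-proxy bins used throughout: [1,3), [3,5) and [5, Inf)
#' cM. Shorter segments trace to older coalescences, so the bins stratify
#' sharing into progressively more recent ancestry.
#'
#' @return list of numeric length-2 vectors.
#' @export
canonical_bins <- function() {
  list(c(1, 3), c(3, 5), c(5, Inf))
}

bin_label <- function(bin) {
  if (is.finite(bin[2])) sprintf("[%g,%g)", bin[1], bin[2])
  else sprintf("[%g,Inf)", bin[1])
}

#' Assign segments to length bins
#'
#' Left-closed, right-open binning on `length_cM`; segments below the
#' first bin edge are dropped (their count is reported in a message and in
#' the `dropped` attribute). Bins must be disjoint and ordered.
#'
#' @param segments segment data.frame.
#' @param bins list of c(lower, upper) vectors (default [canonical_bins()]).
#' @return the segments that fall in some bin, with an added `bin` column
#'   (label string); attribute `dropped` = number below the first edge.
#' @export
bin_segments <- function(segments, bins = canonical_bins()) {
  edges_lo <- vapply(bins, `[`, numeric(1), 1)
  edges_hi <- vapply(bins, `[`, numeric(1), 2)
  if (any(edges_lo >= edges_hi)) stop("each bin must have lower < upper")
  ord <- order(edges_lo)
  if (any(edges_hi[ord][-length(bins)] > edges_lo[ord][-1]))
    stop("bins must be disjoint and ordered")
  labels <- vapply(bins, bin_label, character(1))
  idx <- rep(NA_integer_, nrow(segments))
  for (b in seq_along(bins))
    idx[segments$length_cM >= edges_lo[b] &
          segments$length_cM < edges_hi[b]] <- b
  dropped <- sum(is.na(idx) & segments$length_cM < min(edges_lo))
  if (dropped > 0)
    message(dropped, " segment(s) below the first bin edge dropped")
  out <- segments[!is.na(idx), , drop = FALSE]
  out$bin <- labels[idx[!is.na(idx)]]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

# Matrix of per-pair totals between two member sets (all pairs, zeros
# included). For within (b = NULL) returns symmetric n x n with 0 diagonal.
pair_matrix <- function(segments, members_a, members_b = NULL,
                        value = c("total", "count")) {
  value <- match.arg(value)
  within <- is.null(members_b)
  if (within) members_b <- members_a
  m <- matrix(0, length(members_a), length(members_b),
              dimnames = list(members_a, members_b))
  i1 <- match(segments$sample1, members_a)
  j1 <- match(segments$sample2, members_b)
  i2 <- match(segments$sample2, members_a)
  j2 <- match(segments$sample1, members_b)
  use1 <- !is.na(i1) & !is.na(j1)
  use2 <- !is.na(i2) & !is.na(j2) & segments$sample1 != segments$sample2
  idx <- rbind(cbind(i1[use1], j1[use1]), cbind(i2[use2], j2[use2]))
  val <- if (value == "total") c(segments$length_cM[use1],
                                 segments$length_cM[use2])
         else rep(1, nrow(idx))
  if (nrow(idx) > 0) {
    key <- (idx[, 1] - 1) * length(members_b) + idx[, 2]
    agg <- rowsum(val, key)
    m[as.integer(rownames(agg))] <- agg[, 1]
  }
  if (within) {
    # each segment counted in both orientations above; keep one triangle
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
  }
  m
}

upper_vals <- function(m) m[upper.tri(m)]

#' Per-pair sharing totals between (or within) two sample groups
#'
#' Vector of total shared cM (or counts) over all individual pairs,
#' zero-sharing pairs included. Within-group when `members_b` is NULL.
#'
#' @param segments segment data.frame (typically one length bin).
#' @param members_a,members_b sample id vectors.
#' @param value `"total"` (cM) or `"count"` (segments).
#' @return numeric vector, one entry per individual pair.
#' @export
pair_totals <- function(segments, members_a, members_b = NULL,
                        value = c("total", "count")) {
  m <- pair_matrix(segments, members_a, members_b, match.arg(value))
  if (is.null(members_b)) upper_vals(m) else as.numeric(m)
}

#' Time-stratified sharing summaries between communities
#'
#' For every community pair (including within-community) and every length
#' bin: the mean segment count and mean total cM per individual pair
#' (zero-sharing pairs included), with 95% percentile bootstrap confidence
#' intervals obtained by resampling individuals (pairs that share an
#' individual are dependent, so pairs are not resampled directly).
#'
#' @param segments segment data.frame.
#' @param assignment community assignment data.frame (from
#'   [recursive_leiden()] or equivalent, column sample_id + level columns).
#' @param level level column to use, e.g. `"level3"` (or a plain label
#'   column name).
#' @param bins length bins (default [canonical_bins()]).
#' @param n_boot bootstrap replicates (default 500; 0 skips CIs).
#' @param seed integer seed for the bootstrap.
#' @param within_only if TRUE, only within-community rows are computed.
#' @return data.frame: community_a, community_b, bin, n_pairs, mean_count,
#'   count_ci_low/high, mean_total_cM, total_ci_low/high.
#' @export
pairwise_sharing <- function(segments, assignment, level = "level1",
                             bins = canonical_bins(), n_boot = 500,
                             seed = 1, within_only = FALSE) {
  if (!level %in% names(assignment)) stop("unknown level column: ", level)
  lab <- stats::setNames(assignment[[level]], assignment$sample_id)
  samp <- unique(c(segments$sample1, segments$sample2))
  unlab <- setdiff(samp, names(lab)[!is.na(lab)])
  if (length(unlab) > 0)
    stop("samples without a label at ", level, ": ", unlab[1], " ...")
  comms <- sort(unique(stats::na.omit(lab)))
  binned <- bin_segments(segments, bins)
  labels <- vapply(bins, bin_label, character(1))
  set.seed(seed)
  rows <- list()
  for (ci in seq_along(comms)) {
    for (cj in ci:length(comms)) {
      if (within_only && cj != ci) next
      a <- comms[ci]; b <- comms[cj]
      mem_a <- names(lab)[!is.na(lab) & lab == a]
      mem_b <- names(lab)[!is.na(lab) & lab == b]
      if (ci == cj && length(mem_a) < 2) {
        warning("community ", a, " has < 2 members; within-summary dropped")
        next
      }
      for (bl in labels) {
        segb <- binned[binned$bin == bl, , drop = FALSE]
        if (ci == cj) {
          tot <- pair_matrix(segb, mem_a)
          cnt <- pair_matrix(segb, mem_a, value = "count")
          n_pairs <- choose(length(mem_a), 2)
        } else {
          tot <- pair_matrix(segb, mem_a, mem_b)
          cnt <- pair_matrix(segb, mem_a, mem_b, value = "count")
          n_pairs <- length(mem_a) * length(mem_b)
        }
        # bootstrap resamples repeat individuals; pairs formed from two
        # copies of one individual are excluded, not scored as zero
        pm <- function(m, ia, ib) {
          if (ci == cj) {
            mm <- m[ia, ia, drop = FALSE]
            distinct <- outer(ia, ia, "!=")
            mean(mm[upper.tri(mm) & distinct])
          } else mean(m[ia, ib, drop = FALSE])
        }
        ia0 <- seq_along(mem_a); ib0 <- seq_along(mem_b)
        mean_cnt <- pm(cnt, ia0, ib0)
        mean_tot <- pm(tot, ia0, ib0)
        ci_c <- ci_t <- c(NA_real_, NA_real_)
        if (n_boot > 0) {
          bc <- bt <- numeric(n_boot)
          for (r in seq_len(n_boot)) {
            ia <- sample(ia0, replace = TRUE)
            ib <- if (ci == cj) ia else sample(ib0, replace = TRUE)
            bc[r] <- pm(cnt, ia, ib)
            bt[r] <- pm(tot, ia, ib)
          }
          ci_c <- stats::quantile(bc, c(0.025, 0.975), names = FALSE)
          ci_t <- stats::quantile(bt, c(0.025, 0.975), names = FALSE)
        }
        rows[[length(rows) + 1]] <- data.frame(
          community_a = a, community_b = b, bin = bl, n_pairs = n_pairs,
          mean_count = mean_cnt, count_ci_low = ci_c[1],
          count_ci_high = ci_c[2],
          mean_total_cM = mean_tot, total_ci_low = ci_t[1],
          total_ci_high = ci_t[2], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch comparison of per-pair sharing between two groups
#'
#' Welch two-sample t-test on per-pair total cM vectors (see
#' [pair_totals()]), one-sided as requested ("greater" tests whether group
#' A shares more than group B).
#'
#' @param totals_a,totals_b numeric vectors of per-pair totals.
#' @param side "greater", "less" or "two.sided".
#' @return list with `statistic`, `df`, `p.value`.
#' @export
mean_comparison_test <- function(totals_a, totals_b,
                                 side = c("greater", "less", "two.sided")) {
  side <- match.arg(side)
  if (length(totals_a) < 2 || length(totals_b) < 2)
    stop("each group needs >= 2 pairs")
  ht <- stats::t.test(totals_a, totals_b, alternative = side,
                      var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' ROH-based inbreeding coefficient F_ROH
#'
#' Fraction of the genome in runs of homozygosity:
#' F_ROH(i) = sum of i's ROH lengths >= `min_cM`, divided by the genome's
#' genetic length L. Values are clipped to [0, 1] with a warning.
#'
#' @param roh_segments HBD/ROH segment data.frame.
#' @param genome a `genome_map`.
#' @param min_cM minimum ROH length counted (default 1 cM).
#' @param samples optional roster; samples without ROH get 0.
#' @return named numeric vector of per-sample F_ROH.
#' @export
f_roh <- function(roh_segments, genome, min_cM = 1.0, samples = NULL) {
  stopifnot(inherits(genome, "genome_map"))
  ids <- sort(unique(c(roh_segments$sample1, samples)))
  out <- stats::setNames(rep(0, length(ids)), ids)
  seg <- roh_segments[roh_segments$length_cM >= min_cM, , drop = FALSE]
  if (nrow(seg) > 0) {
    tot <- tapply(seg$length_cM, seg$sample1, sum)
    out[names(tot)] <- tot / genome$total_cM
  }
  if (any(out > 1)) {
    warning("F_ROH above 1 clipped (overlapping placements)")
    out <- pmin(out, 1)
  }
  out
}

#' SNP-based inbreeding coefficient F_IS
#'
#' Heterozygote deficit relative to Hardy-Weinberg expectation:
#' F_IS = 1 - sum(Ho) / sum(He) over polymorphic SNPs (ratio of averages),
#' with Ho the observed heterozygote frequency and He = 2 p (1 - p) from
#' the observed allele frequency. Missing genotypes are excluded per SNP.
#'
#' @param genotypes integer matrix (samples x SNPs, values 0/1/2/NA).
#' @param sample_subset optional row (sample) subset.
#' @return F_IS (scalar).
#' @export
f_is <- function(genotypes, sample_subset = NULL) {
  g <- if (is.null(sample_subset)) genotypes
       else genotypes[sample_subset, , drop = FALSE]
  if (nrow(g) < 2) stop("need >= 2 samples")
  n_obs <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * n_obs)
  poly <- which(n_obs > 0 & p > 0 & p < 1)
  if (length(poly) == 0) stop("no polymorphic SNPs")
  ho <- colSums(g[, poly, drop = FALSE] == 1, na.rm = TRUE) / n_obs[poly]
  he <- 2 * p[poly] * (1 - p[poly])
  1 - sum(ho) / sum(he)
}

#' Hudson's F_ST (ratio of averages)
#'
#' Per SNP: num = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1),
#' den = p1(1-p2) + p2(1-p1); F_ST = sum(num)/sum(den). SNPs with den = 0
#' (monomorphic for the same allele in both populations) are excluded, as
#' are SNPs with fewer than 2 genotyped samples in either population.
#'
#' @param genotypes integer matrix (samples x SNPs).
#' @param pop_a_ids,pop_b_ids sample id vectors (row names).
#' @return F_ST (scalar).
#' @export
hudson_fst <- function(genotypes, pop_a_ids, pop_b_ids) {
  ga <- genotypes[pop_a_ids, , drop = FALSE]
  gb <- genotypes[pop_b_ids, , drop = FALSE]
  if (nrow(ga) < 2 || nrow(gb) < 2) stop("need >= 2 samples per population")
  na <- colSums(!is.na(ga)); nb <- colSums(!is.na(gb))
  p1 <- colSums(ga, na.rm = TRUE) / (2 * na)
  p2 <- colSums(gb, na.rm = TRUE) / (2 * nb)
  # n in the unbiasedness correction counts alleles
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * na - 1) -
    p2 * (1 - p2) / (2 * nb - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  use <- which(na >= 2 & nb >= 2 & den > 0)
  if (length(use) == 0) stop("no informative SNPs")
  sum(num[use]) / sum(den[use])
}

#' Map a canonical length bin to its time proxy
#'
#' The three canonical bins act as proxies for coalescence time:
#' [1,3) cM ~ 100 generations (~3000 years), [3,5) ~ 45 generations
#' (~1200 years), [5,Inf) ~ 15 generations (~450 years). The default
#' years are these conventional round figures (roughly 30 years per
#' generation); supplying `years_per_generation` recomputes the years as
#' an exact multiple instead.
#'
#' @param bin numeric length-2 vector.
#' @param years_per_generation optional conversion constant; NULL keeps
#'   the conventional rounded years.
#' @return list(generations_proxy, years_proxy), or NULL for a
#'   non-canonical bin.
#' @export
bin_to_time <- function(bin, years_per_generation = NULL) {
  hit <- if (isTRUE(all.equal(bin, c(1, 3)))) c(100, 3000)
         else if (isTRUE(all.equal(bin, c(3, 5)))) c(45, 1200)
         else if (bin[1] == 5 && is.infinite(bin[2])) c(15, 450)
         else return(NULL)
  years <- if (is.null(years_per_generation)) hit[2]
           else hit[1] * years_per_generation
  list(generations_proxy = hit[1], years_proxy = years)
}
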