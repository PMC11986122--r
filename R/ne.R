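#' Default fine length-bin edges for Ne fitting
#'
#' Edges {2,3,4,5,6,8,10,14,20,Inf} cM. Segments of 1-3 cM carry a higher
#' proportion of detection noise, so the default fitting spectrum starts
#' at 2 cM; the coarse three-bin time proxy is too blunt to constrain a
#' multi-epoch trajectory.
#'
#' @return numeric vector of bin edges.
#' @export
default_fine_edges <- function() c(2, 3, 4, 5, 6, 8, 10, 14, 20, Inf)

#' Default epoch grid for Ne fitting
#'
#' Contiguous generation ranges (1,10], (10,20], (20,40], (40,80],
#' (80,150].
#'
#' @return data.frame g_start, g_end (inclusive integer ranges).
#' @export
default_epochs <- function() {
  data.frame(g_start = c(1, 11, 21, 41, 81),
             g_end = c(10, 20, 40, 80, 150))
}

#' Observed IBD length spectrum
#'
#' Counts segments between retained samples into fine length bins.
#'
#' @param segments IBD segment data.frame.
#' @param sample_ids retained samples (>= 2).
#' @param edges bin edges (default [default_fine_edges()]); left-closed,
#'   right-open.
#' @return list with `k` (counts per bin), `edges`, and `P` = 4 * C(n,2)
#'   haplotype pairs.
#' @export
count_spectrum <- function(segments, sample_ids,
                           edges = default_fine_edges()) {
  n <- length(sample_ids)
  if (n < 2) stop("need >= 2 samples")
  stopifnot(!is.unsorted(edges), length(edges) >= 2)
  seg <- segments[segments$sample1 %in% sample_ids &
                    segments$sample2 %in% sample_ids &
                    segments$sample1 != segments$sample2, , drop = FALSE]
  nb <- length(edges) - 1
  k <- integer(nb)
  for (b in seq_len(nb))
    k[b] <- sum(seg$length_cM >= edges[b] & seg$length_cM < edges[b + 1])
  list(k = k, edges = edges, P = 4 * choose(n, 2))
}

# Expected per-haplotype-pair counts in each fine bin for an
# epoch-structured trajectory (values logN per epoch, last value carried
# to G_max).
mu_bins_epochs <- function(logN, epochs, edges, L, K, G_max) {
  N <- rep(exp(logN[length(logN)]), G_max)
  for (e in seq_len(nrow(epochs))) {
    lo <- max(1L, epochs$g_start[e]); hi <- min(G_max, epochs$g_end[e])
    N[lo:hi] <- exp(logN[e])
  }
  cg <- hazard_profile(N, 1L, G_max)
  g <- seq_len(G_max)
  npieces <- 2 * g * L / 100 + K
  tails <- vapply(edges, function(u)
    if (is.finite(u)) exp(-2 * g * u / 100) else rep(0, G_max),
    numeric(G_max))
  base <- cg * npieces
  vapply(seq_len(length(edges) - 1),
         function(b) sum(base * (tails[, b] - tails[, b + 1])),
         numeric(1))
}

#' Fit a piecewise-constant Ne trajectory by Poisson maximum likelihood
#'
#' Maximizes sum_b [k_b log(P mu_b) - P mu_b] - lambda * sum (delta log
#' N)^2 over per-epoch log N, where mu_b is the expected per-pair segment
#' count for the epoch trajectory under the coalescent-Poisson model.
#' Optimization is L-BFGS-B over log N with box [log 50, log 1e7] and
#' multi-starts around a constant method-of-moments initializer. This is a
#' desk-scale stand-in for IBDNe: it models no within-individual
#' haplotype structure and applies no gap-merging corrections.
#'
#' Confidence intervals (optional) are percentile bootstrap over
#' individuals: individuals are resampled, the spectrum recounted and the
#' model refit; this requires `segments` and `sample_ids`.
#'
#' @param k observed counts per fine bin.
#' @param P number of haplotype pairs (4 * C(n,2)).
#' @param edges fine bin edges.
#' @param epochs epoch grid data.frame (default [default_epochs()]).
#' @param genome a `genome_map`.
#' @param lambda smoothing weight on squared differences of consecutive
#'   log N (default 1).
#' @param n_starts optimizer multi-starts (default 5).
#' @param seed integer seed (start perturbations, bootstrap).
#' @param G_max generation horizon (default 300).
#' @param n_boot bootstrap replicates for CIs (default 0 = none).
#' @param segments,sample_ids required when `n_boot > 0`.
#' @return object of class `ne_trajectory`: list with `epochs` (data.frame
#'   g_start, g_end, Ne_hat, ci95_low, ci95_high), `loglik`, `lambda`,
#'   `convergence`.
#' @export
fit_piecewise_ne <- function(k, P, edges = default_fine_edges(),
                             epochs = default_epochs(),
                             genome = default_genome(), lambda = 1.0,
                             n_starts = 5, seed = 1, G_max = 300,
                             n_boot = 0, segments = NULL,
                             sample_ids = NULL) {
  stopifnot(length(k) == length(edges) - 1, all(is.finite(k)), P > 0)
  if (sum(k) == 0) stop("no IBD information: all-zero spectrum")
  if (sum(k > 0) < nrow(epochs))
    warning("fewer informative bins than epochs; fit relies on smoothing")
  L <- genome$total_cM; K <- genome$n_chrom
  lo <- log(50); hi <- log(1e7)
  E <- nrow(epochs)

  negloglik <- function(logN) {
    mu <- mu_bins_epochs(logN, epochs, edges, L, K, G_max)
    lam <- P * mu
    if (any(lam <= 0)) return(1e18)
    -sum(k * log(lam) - lam) + lambda * sum(diff(logN)^2)
  }

  set.seed(seed)
  # method-of-moments constant-N start: match the total count
  k_tot <- sum(k)
  f_tot <- function(lN) {
    mu <- mu_bins_epochs(rep(lN, E), epochs, edges, L, K, G_max)
    P * sum(mu) - k_tot
  }
  init <- tryCatch(stats::uniroot(f_tot, c(lo, hi))$root,
                   error = function(e) log(5000))
  starts <- rbind(rep(init, E),
                  matrix(init + stats::rnorm((n_starts - 1) * E, 0, 0.5),
                         ncol = E))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(starts[s, ], lo), hi), negloglik,
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimizer failed to converge from any start")

  ci <- matrix(NA_real_, E, 2)
  if (n_boot > 0) {
    if (is.null(segments) || is.null(sample_ids))
      stop("bootstrap CIs need segments and sample_ids")
    bootN <- matrix(NA_real_, n_boot, E)
    for (r in seq_len(n_boot)) {
      ids_r <- sample(sample_ids, replace = TRUE)
      # resampled pair structure: count pairs of distinct individuals
      ids_u <- unique(ids_r)
      cnt <- table(ids_r)[ids_u]
      segs_r <- segments[segments$sample1 %in% ids_u &
                           segments$sample2 %in% ids_u &
                           segments$sample1 != segments$sample2, ,
                         drop = FALSE]
      w <- as.numeric(cnt[segs_r$sample1] * cnt[segs_r$sample2])
      nb <- length(edges) - 1
      kr <- vapply(seq_len(nb), function(b)
        sum(w[segs_r$length_cM >= edges[b] &
                segs_r$length_cM < edges[b + 1]]), numeric(1))
      n <- length(ids_r)
      Pr <- 4 * (choose(n, 2) - sum(choose(as.numeric(cnt), 2)))
      if (sum(kr) == 0 || Pr <= 0) next
      fr <- tryCatch(
        stats::optim(best$par, function(lN) {
          mu <- mu_bins_epochs(lN, epochs, edges, L, K, G_max)
          lam <- Pr * mu
          if (any(lam <= 0)) return(1e18)
          -sum(kr * log(lam) - lam) + lambda * sum(diff(lN)^2)
        }, method = "L-BFGS-B", lower = lo, upper = hi,
        control = list(maxit = 500)),
        error = function(e) NULL)
      if (!is.null(fr)) bootN[r, ] <- exp(fr$par)
    }
    ok <- stats::complete.cases(bootN)
    if (sum(ok) >= 10)
      ci <- t(apply(bootN[ok, , drop = FALSE], 2, stats::quantile,
                    probs = c(0.025, 0.975)))
  }

  structure(list(
    epochs = data.frame(g_start = epochs$g_start, g_end = epochs$g_end,
                        Ne_hat = exp(best$par),
                        ci95_low = ci[, 1], ci95_high = ci[, 2]),
    loglik = -best$value, lambda = lambda,
    convergence = best$convergence), class = "ne_trajectory")
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat("<ne_trajectory>\n")
  print(x$epochs, row.names = FALSE)
  invisible(x)
}

#' Ne snapshot at a length bin's proxy generation
#'
#' Looks up the fitted epoch containing the bin's generations proxy (see
#' [bin_to_time()]).
#'
#' @param trajectory an `ne_trajectory`.
#' @param bin canonical length bin c(u, v).
#' @return Ne_hat of the covering epoch.
#' @export
ne_snapshot <- function(trajectory, bin) {
  tm <- bin_to_time(bin)
  if (is.null(tm)) stop("not a canonical bin")
  g <- tm$generations_proxy
  ep <- trajectory$epochs
  hit <- which(ep$g_start <= g & g <= ep$g_end)
  if (length(hit) == 0) stop("trajectory does not cover generation ", g)
  ep$Ne_hat[hit[1]]
}
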