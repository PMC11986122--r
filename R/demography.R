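#' Demography model
#'
#' A set of populations with piecewise-constant effective sizes N(g) over
#' discrete generations g = 1..G_max, pairwise split times to a shared
#' ancestral population, and the ancestral trajectory. This is the ground
#' truth for the coalescent-Poisson segment simulator and the target of
#' effective-population-size inference.
#'
#' Trajectories are given either as a single constant N, a numeric vector
#' of length `G_max`, or a data.frame of epochs with columns
#' `g_start`, `g_end`, `N` (inclusive generation ranges; the last value is
#' carried forward to `G_max`).
#'
#' @param populations named list of trajectories (see above).
#' @param splits data.frame with columns `a`, `b`, `generation`: the
#'   generation at which populations a and b merge into the ancestral
#'   population. Required for every pair when there is more than one
#'   population.
#' @param ancestral ancestral trajectory (same forms as `populations`
#'   entries). Required when more than one population.
#' @param G_max generation horizon (default 300; contributions of deeper
#'   generations to detectable segments are negligible at human-scale N).
#' @param m_cM segment detection threshold in cM (default 1).
#' @return object of class `demography_model`.
#' @export
demography_model <- function(populations, splits = NULL, ancestral = NULL,
                             G_max = 300, m_cM = 1.0) {
  stopifnot(is.list(populations), length(populations) >= 1,
            !is.null(names(populations)), G_max >= 1, m_cM > 0)
  pops <- names(populations)
  N <- sapply(populations, expand_trajectory, G_max = G_max)
  if (any(N <= 0)) stop("all N must be positive")

  n_pop <- length(pops)
  T_split <- matrix(0, n_pop, n_pop, dimnames = list(pops, pops))
  N_anc <- NULL
  if (n_pop > 1) {
    if (is.null(splits) || is.null(ancestral))
      stop("splits and ancestral trajectory required for >1 population")
    for (r in seq_len(nrow(splits))) {
      a <- as.character(splits$a[r]); b <- as.character(splits$b[r])
      if (!a %in% pops || !b %in% pops) stop("unknown population in splits: ", a, "/", b)
      T_split[a, b] <- T_split[b, a] <- splits$generation[r]
    }
    off <- T_split[upper.tri(T_split)]
    if (any(off <= 0)) stop("a split time must be given for every population pair")
    if (max(T_split) > G_max) stop("G_max must be >= the largest split time")
    N_anc <- expand_trajectory(ancestral, G_max)
    if (any(N_anc <= 0)) stop("all N must be positive")
  }
  structure(list(pops = pops, N = N, T_split = T_split, N_anc = N_anc,
                 G_max = as.integer(G_max), m_cM = m_cM),
            class = "demography_model")
}

expand_trajectory <- function(x, G_max) {
  if (is.numeric(x) && length(x) == 1) return(rep(as.numeric(x), G_max))
  if (is.numeric(x)) {
    if (length(x) != G_max) stop("trajectory vector must have length G_max")
    return(as.numeric(x))
  }
  stopifnot(is.data.frame(x), all(c("g_start", "g_end", "N") %in% names(x)))
  out <- rep(NA_real_, G_max)
  for (r in seq_len(nrow(x))) {
    lo <- max(1L, as.integer(x$g_start[r]))
    hi <- min(G_max, as.integer(x$g_end[r]))
    if (lo <= hi) out[lo:hi] <- x$N[r]
  }
  if (is.na(out[1])) stop("trajectory must cover generation 1")
  for (g in seq_len(G_max)[-1]) if (is.na(out[g])) out[g] <- out[g - 1]
  out
}

#' @export
print.demography_model <- function(x, ...) {
  cat(sprintf("<demography_model> %d population(s), G_max = %d, m = %g cM\n",
              length(x$pops), x$G_max, x$m_cM))
  invisible(x)
}

#' Per-generation coalescence probabilities for a haplotype pair
#'
#' For two haplotypes drawn from populations `pop_a` and `pop_b`, returns
#' c(g), g = 1..G_max: the probability that the pair coalesces exactly g
#' generations ago. Within a population (a = b) the hazard at generation g
#' is 1/(2N_a(g)) with survival through earlier generations; across
#' populations coalescence is impossible before the split time T(a,b) and
#' proceeds in the ancestral population thereafter.
#'
#' @param model a `demography_model`.
#' @param pop_a,pop_b population ids.
#' @return numeric vector of length `G_max`, summing to at most 1.
#' @export
coalescence_profile <- function(model, pop_a, pop_b) {
  stopifnot(inherits(model, "demography_model"))
  if (!pop_a %in% model$pops) stop("unknown population: ", pop_a)
  if (!pop_b %in% model$pops) stop("unknown population: ", pop_b)
  G <- model$G_max
  if (pop_a == pop_b) {
    return(hazard_profile(model$N[, pop_a], 1L, G))
  }
  Tab <- model$T_split[pop_a, pop_b]
  cg <- rep(0, G)
  anc <- hazard_profile(model$N_anc, as.integer(Tab), G)
  cg[Tab:G] <- anc[Tab:G]
  cg
}

# c(g) = haz(g) * prod_{j=g0..g-1} (1 - haz(j)) for g >= g0, else 0
hazard_profile <- function(N, g0, G) {
  haz <- 1 / (2 * N)
  cg <- rep(0, G)
  idx <- g0:G
  surv <- cumprod(c(1, 1 - haz[idx[-length(idx)]]))
  cg[idx] <- haz[idx] * surv
  cg
}

#' Expected IBD segment count per haplotype pair in a length bin
#'
#' Under the coalescent-Poisson model, a pair coalescing g generations ago
#' carries Poisson(2gL/100 + K) segments with Exponential(mean 100/(2g) cM)
#' lengths, where L is the genome's genetic length (cM) and K its
#' chromosome count. Summing over the coalescence profile gives the
#' expected count per haplotype pair with length in [u, v):
#' mu(u,v) = sum_g c(g) (2gL/100 + K) (exp(-2gu/100) - exp(-2gv/100)).
#'
#' @param model a `demography_model`.
#' @param pop_a,pop_b population ids.
#' @param bin numeric length-2 vector c(u, v); v may be `Inf`. u must be at
#'   least the model's detection threshold.
#' @param genome a `genome_map`.
#' @return expected segment count per haplotype pair (non-negative real).
#' @export
expected_segment_count <- function(model, pop_a, pop_b, bin, genome) {
  stopifnot(inherits(model, "demography_model"), inherits(genome, "genome_map"),
            length(bin) == 2, bin[1] < bin[2] || bin[1] == bin[2])
  if (bin[1] < model$m_cM)
    stop("bin lower edge below detection threshold m_cM = ", model$m_cM)
  cg <- coalescence_profile(model, pop_a, pop_b)
  mu_from_profile(cg, bin[1], bin[2], genome$total_cM, genome$n_chrom)
}

mu_from_profile <- function(cg, u, v, L, K) {
  g <- seq_along(cg)
  npieces <- 2 * g * L / 100 + K
  tail_u <- exp(-2 * g * u / 100)
  tail_v <- if (is.finite(v)) exp(-2 * g * v / 100) else 0
  sum(cg * npieces * (tail_u - tail_v))
}
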