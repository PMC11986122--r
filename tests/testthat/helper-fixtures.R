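# Shared fixtures: small demographies, planted networks, and independent
# oracle implementations used to cross-check the package's formulas.

pop_of <- function(ids) sub("_.*$", "", ids)

truth_assignment <- function(segments, level = "level1") {
  ids <- sort(unique(c(segments$sample1, segments$sample2)))
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  out[[level]] <- pop_of(ids)
  out
}

two_pop_split_model <- function(N = 2000, T_split = 50, N_anc = 2000) {
  demography_model(
    list(A = N, B = N),
    splits = data.frame(a = "A", b = "B", generation = T_split),
    ancestral = N_anc)
}

# four populations: P1-P3 split recently (T=20), P1-P2 at 50, everything
# else deep (T=100); gives P1/P2 members distinct profiles over P3/P4
four_pop_model <- function() {
  demography_model(
    list(P1 = 1000, P2 = 1000, P3 = 1000, P4 = 1000),
    splits = data.frame(
      a = c("P1", "P1", "P1", "P2", "P2", "P3"),
      b = c("P2", "P3", "P4", "P3", "P4", "P4"),
      generation = c(50, 20, 100, 100, 100, 100)),
    ancestral = 2000)
}

# 2 top blocks x 3 sub-blocks x block_n nodes, within-sub weight >>
# within-top >> between-top; returns network plus true labels
planted_hierarchy <- function(seed = 42, block_n = 10,
                              w_sub = 40, w_top = 20, w_between = 1) {
  set.seed(seed)
  n <- 6 * block_n
  nodes <- sprintf("n%02d", seq_len(n))
  top <- rep(1:2, each = 3 * block_n)
  sub <- rep(1:6, each = block_n)
  idx <- utils::combn(n, 2)
  i <- idx[1, ]; j <- idx[2, ]
  w <- ifelse(sub[i] == sub[j], runif(ncol(idx), w_sub * 0.8, w_sub * 1.2),
       ifelse(top[i] == top[j], runif(ncol(idx), w_top * 0.8, w_top * 1.2),
              runif(ncol(idx), w_between * 0.5, w_between * 1.5)))
  seg <- data.frame(sample1 = nodes[i], hap1 = 1L, sample2 = nodes[j],
                    hap2 = 1L, chrom = "chr1", start_bp = 1, end_bp = 2,
                    lod = 10, length_cM = w, stringsAsFactors = FALSE)
  list(network = build_network(seg, min_segment_cM = 0.1),
       top = stats::setNames(top, nodes), sub = stats::setNames(sub, nodes))
}

random_segments <- function(n, seed, samples = paste0("s", 1:8)) {
  set.seed(seed)
  s1 <- sample(samples, n, replace = TRUE)
  s2 <- sample(samples, n, replace = TRUE)
  keep <- s1 != s2
  s1 <- s1[keep]; s2 <- s2[keep]
  m <- length(s1)
  data.frame(sample1 = s1, hap1 = sample(1:2, m, TRUE),
             sample2 = s2, hap2 = sample(1:2, m, TRUE),
             chrom = sample(paste0("chr", 1:3), m, TRUE),
             start_bp = sample.int(1e6, m), end_bp = 2e6,
             lod = round(runif(m, 3, 12), 2),
             length_cM = round(runif(m, 0.5, 30), 4),
             stringsAsFactors = FALSE)
}

# ---- independent textbook oracles -----------------------------------------

oracle_welch <- function(x, y, side = "greater") {
  mx <- mean(x); my <- mean(y)
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  tt <- (mx - my) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- switch(side,
              greater = pt(tt, df, lower.tail = FALSE),
              less = pt(tt, df),
              two.sided = 2 * pt(-abs(tt), df))
  list(statistic = tt, df = df, p.value = p)
}

oracle_chi2 <- function(tab) {
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - E)^2 / E)
  dof <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chi2 = chi2, dof = dof, p.value = pchisq(chi2, dof, lower.tail = FALSE))
}

oracle_cramers_v <- function(tab, adjusted) {
  chi2 <- oracle_chi2(tab)$chi2
  n <- sum(tab); r <- nrow(tab); cc <- ncol(tab)
  if (!adjusted) return(sqrt(chi2 / (n * min(r - 1, cc - 1))))
  phi2p <- max(0, chi2 / n - (r - 1) * (cc - 1) / (n - 1))
  sqrt(phi2p / min(r - (r - 1)^2 / (n - 1) - 1,
                   cc - (cc - 1)^2 / (n - 1) - 1))
}

random_table <- function(seed, rmax = 5, cmax = 6) {
  set.seed(seed)
  r <- sample(2:rmax, 1); cc <- sample(2:cmax, 1)
  repeat {
    tab <- matrix(rpois(r * cc, lambda = runif(1, 2, 30)), r, cc)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}

# two-population binomial drift simulator (independent oracle for Hudson
# F_ST recovery; expectation ~ t / (2N) for small t/N)
drift_fst_replicate <- function(n_snps = 2000, N = 1000, t = 20,
                                n_samples = 60) {
  p0 <- runif(n_snps, 0.05, 0.5)
  drift <- function(p) {
    for (i in seq_len(t)) p <- rbinom(length(p), 2 * N, p) / (2 * N)
    p
  }
  p1 <- drift(p0); p2 <- drift(p0)
  gA <- vapply(p1, function(p) rbinom(n_samples, 2, p), integer(n_samples))
  gB <- vapply(p2, function(p) rbinom(n_samples, 2, p), integer(n_samples))
  rownames(gA) <- paste0("a", seq_len(n_samples))
  rownames(gB) <- paste0("b", seq_len(n_samples))
  hudson_fst(rbind(gA, gB), rownames(gA), rownames(gB))
}
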