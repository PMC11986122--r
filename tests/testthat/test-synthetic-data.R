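test_that("coalescence profile matches the constant-N closed form", {
  m <- demography_model(list(A = 1000))
  cg <- coalescence_profile(m, "A", "A")
  expect_equal(cg[1], 1 / 2000)

  m500 <- demography_model(list(A = 500))
  cg <- coalescence_profile(m500, "A", "A")
  closed <- (1 / 1000) * (1 - 1 / 1000)^(seq_along(cg) - 1)
  expect_equal(cg, closed, tolerance = 1e-12)
  expect_lte(sum(cg), 1)

  m2 <- two_pop_split_model(T_split = 50)
  cross <- coalescence_profile(m2, "A", "B")
  expect_true(all(cross[1:49] == 0))
  expect_gt(cross[50], 0)
  expect_error(coalescence_profile(m2, "A", "Z"), "unknown")
})

test_that("coalescence mass is always a sub-probability", {
  for (N in c(60, 500, 5000, 2e5)) {
    m <- demography_model(list(A = N), G_max = 300)
    expect_lte(sum(coalescence_profile(m, "A", "A")), 1)
  }
  # equality approached for small N as G_max grows
  m <- demography_model(list(A = 60), G_max = 2000)
  expect_gt(sum(coalescence_profile(m, "A", "A")), 0.999)
})

test_that("expected counts: degenerate bin, diverging N, thresholds", {
  g <- default_genome()
  m <- demography_model(list(A = 2000))
  expect_equal(expected_segment_count(m, "A", "A", c(2, 2), g), 0)
  mbig <- demography_model(list(A = 1e9))
  expect_lt(expected_segment_count(mbig, "A", "A", c(1, 3), g), 1e-3)
  expect_error(expected_segment_count(m, "A", "A", c(0.5, 3), g),
               "threshold")
  # non-increasing in the lower edge at fixed width
  mus <- sapply(c(1, 2, 4, 8), function(u)
    expected_segment_count(m, "A", "A", c(u, u + 2), g))
  expect_true(all(diff(mus) <= 0))
})

test_that("simulated per-bin counts agree with the formula and are Poisson-dispersed", {
  g <- default_genome()
  m <- demography_model(list(A = 2000))
  n <- 40 # 3120 haplotype pairs
  seg <- simulate_ibd(m, c(A = n), g, seed = 101)
  P <- 4 * choose(n, 2)
  for (bin in canonical_bins()) {
    mu <- expected_segment_count(m, "A", "A", bin, g)
    obs <- sum(seg$length_cM >= bin[1] & seg$length_cM < bin[2])
    expect_lt(abs(obs - P * mu), 4 * sqrt(P * mu))
  }
  # per-pair dispersion in [3,5): Poisson variance/mean near 1
  cnt <- pair_totals(seg[seg$length_cM >= 3 & seg$length_cM < 5, ],
                     paste0("A_", 1:n), value = "count")
  # per *individual* pair the count is a sum of 4 Poissons, still Poisson
  disp <- var(cnt) / mean(cnt)
  expect_gt(disp, 0.8)
  expect_lt(disp, 1.25)
})

test_that("simulator edge cases: no pairs, determinism, split isolation", {
  g <- default_genome()
  m1 <- demography_model(list(A = 1000))
  expect_equal(nrow(simulate_ibd(m1, c(A = 1), g, seed = 1)), 0)

  m <- two_pop_split_model()
  s1 <- simulate_ibd(m, c(A = 5, B = 5), g, seed = 7)
  s2 <- simulate_ibd(m, c(A = 5, B = 5), g, seed = 7)
  expect_identical(s1, s2)
  expect_false(identical(s1, simulate_ibd(m, c(A = 5, B = 5), g, seed = 8)))

  # deep-split isolation: long cross-pop segments are rare and a tiny
  # fraction of the within-pop expectation
  iso <- demography_model(list(A = 1000, B = 1000),
                          splits = data.frame(a = "A", b = "B",
                                              generation = 50),
                          ancestral = 1e4)
  mu_x <- expected_segment_count(iso, "A", "B", c(5, Inf), g)
  mu_w <- expected_segment_count(iso, "A", "A", c(5, Inf), g)
  expect_lt(mu_x, 0.02)
  expect_lt(mu_x, 0.05 * mu_w)

  r1 <- simulate_roh(m, c(A = 4, B = 4), g, seed = 3)
  expect_true(all(r1$sample1 == r1$sample2))
  expect_true(all(r1$hap1 != r1$hap2))
  huge <- demography_model(list(A = 1e7))
  expect_lt(nrow(simulate_roh(huge, c(A = 30), g, seed = 4)), 5)
})

test_that("genotype simulator respects HWE at f = 0 and rejects bad f", {
  expect_error(simulate_genotypes(10, 10, 1, seed = 1), "f_inbreeding")
  expect_error(simulate_genotypes(10, 10, -0.1, seed = 1), "f_inbreeding")
  sim <- simulate_genotypes(400, 3000, 0, seed = 2)
  ho <- mean(colMeans(sim$genotypes == 1))
  he <- mean(2 * sim$allele_freqs * (1 - sim$allele_freqs))
  expect_lt(abs(ho - he), 0.01)
})

test_that("surname simulator is calibrated and deterministic", {
  labs <- stats::setNames(rep(c("c1", "c2"), each = 100),
                          paste0("s", 1:200))
  em <- matrix(c(0.5, 0.3, 0.2, 0.5, 0.3, 0.2), 2, 3, byrow = TRUE,
               dimnames = list(c("c1", "c2"), NULL))
  # identical rows: chi2 should be non-significant in >= 90% of reps
  set.seed(11)
  sig <- 0
  for (r in 1:100) {
    meta <- simulate_surnames(labs, c("Irish", "Scottish", "English"),
                              em, seed = r)
    asg <- data.frame(sample_id = meta$sample_id, level1 = meta$region)
    tab <- build_table(meta, asg, "level1")
    if (chi2_test(tab)$p.value < 0.05) sig <- sig + 1
  }
  expect_lte(sig, 10)

  m1 <- simulate_surnames(labs, c("a", "b", "c"), em, seed = 5)
  m2 <- simulate_surnames(labs, c("a", "b", "c"), em, seed = 5)
  expect_identical(m1, m2)

  bad <- em; bad[1, 1] <- 0.6
  expect_error(simulate_surnames(labs, c("a", "b", "c"), bad, "sum"),
               "sum to 1")

  # one-hot rows: perfect association, adjusted V -> 1 with n
  onehot <- matrix(c(1, 0, 0, 1), 2, 2,
                   dimnames = list(c("c1", "c2"), NULL))
  labs2 <- stats::setNames(rep(c("c1", "c2"), each = 500),
                           paste0("t", 1:1000))
  meta <- simulate_surnames(labs2, c("x", "y"), onehot, seed = 1)
  tab <- build_table(meta,
                     data.frame(sample_id = meta$sample_id,
                                level1 = meta$region), "level1")
  expect_gt(cramers_v(tab, adjusted = TRUE), 0.99)
})
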