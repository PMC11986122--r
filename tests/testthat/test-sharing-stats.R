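test_that("binning uses the half-open convention and partitions counts", {
  seg <- random_segments(300, seed = 7)
  seg$length_cM[1:2] <- c(2.99, 3.0)
  binned <- suppressMessages(bin_segments(seg))
  expect_equal(binned$bin[binned$length_cM == 2.99][1], "[1,3)")
  expect_equal(binned$bin[binned$length_cM == 3.0][1], "[3,5)")
  expect_equal(nrow(binned), sum(seg$length_cM >= 1))
  expect_equal(attr(binned, "dropped"), sum(seg$length_cM < 1))
  expect_error(bin_segments(seg, list(c(1, 4), c(3, 5))), "disjoint")
})

test_that("pairwise sharing means include zero pairs and match by hand", {
  seg <- data.frame(sample1 = "a1", hap1 = 1L, sample2 = "a2", hap2 = 1L,
                    chrom = "chr1", start_bp = 1, end_bp = 2, lod = 10,
                    length_cM = 2, stringsAsFactors = FALSE)
  asg <- data.frame(sample_id = c("a1", "a2"), level1 = "X")
  sm <- pairwise_sharing(seg, asg, "level1", n_boot = 0)
  row <- sm[sm$bin == "[1,3)", ]
  expect_equal(row$mean_count, 1)
  expect_equal(row$mean_total_cM, 2)
  expect_equal(row$n_pairs, 1)
  expect_equal(sm$mean_total_cM[sm$bin != "[1,3)"], c(0, 0))

  # zero-sharing pairs dilute the mean: add a third silent member
  asg3 <- data.frame(sample_id = c("a1", "a2", "a3"), level1 = "X")
  sm3 <- pairwise_sharing(seg, asg3, "level1", n_boot = 0)
  expect_equal(sm3$mean_total_cM[sm3$bin == "[1,3)"], 2 / 3)

  # between-community sharing of disconnected groups is zero
  asg2 <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                     level1 = c("X", "X", "Y", "Y"))
  segx <- rbind(seg, transform(seg, sample1 = "b1", sample2 = "b2"))
  smx <- pairwise_sharing(segx, asg2, "level1", n_boot = 0)
  expect_true(all(smx$mean_count[smx$community_a != smx$community_b] == 0))
})

test_that("sharing means are invariant to row order and file chunking", {
  g <- default_genome()
  seg <- simulate_ibd(two_pop_split_model(N = 1200), c(A = 10, B = 10),
                      g, seed = 19)
  asg <- truth_assignment(seg)
  a <- pairwise_sharing(seg, asg, "level1", n_boot = 0)
  b <- pairwise_sharing(seg[sample(nrow(seg)), ], asg, "level1", n_boot = 0)
  expect_equal(a, b)
})

test_that("bootstrap CIs bracket the mean and tighten with sample size", {
  g <- default_genome()
  m <- demography_model(list(A = 800))
  seg <- simulate_ibd(m, c(A = 30), g, seed = 23)
  asg <- truth_assignment(seg)
  small_ids <- asg$sample_id[1:10]
  seg_small <- seg[seg$sample1 %in% small_ids &
                     seg$sample2 %in% small_ids, ]
  sm_small <- pairwise_sharing(seg_small, asg[1:10, ], "level1",
                               n_boot = 200, seed = 2)
  sm_big <- pairwise_sharing(seg, asg, "level1", n_boot = 200, seed = 2)
  r1 <- sm_small[sm_small$bin == "[1,3)", ]
  r2 <- sm_big[sm_big$bin == "[1,3)", ]
  expect_lte(r1$total_ci_low, r1$mean_total_cM)
  expect_gte(r1$total_ci_high, r1$mean_total_cM)
  expect_lt(r2$total_ci_high - r2$total_ci_low,
            r1$total_ci_high - r1$total_ci_low)
})

test_that("Welch comparison matches the textbook formula", {
  expect_error(mean_comparison_test(1, 1:5), ">= 2")
  set.seed(31)
  for (r in 1:20) {
    x <- rnorm(40, sd = runif(1, 0.5, 3))
    y <- rnorm(60, mean = runif(1, -1, 1))
    for (side in c("greater", "less", "two.sided")) {
      got <- mean_comparison_test(x, y, side)
      want <- oracle_welch(x, y, side)
      expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
      expect_equal(got$p.value, want$p.value, tolerance = 1e-12)
    }
  }
  # symmetry: identical distributions give one-sided p of 0.5 on average
  set.seed(32)
  ps <- replicate(200,
    mean_comparison_test(rnorm(50), rnorm(50), "greater")$p.value)
  expect_lt(abs(mean(ps) - 0.5), 0.1)
  # clean separation
  p2 <- mean_comparison_test(rnorm(1000) + 10, rnorm(1000), "greater")$p.value
  expect_lt(p2, 1e-6)
})

test_that("F_ROH definition and monotonicity in Ne", {
  g <- default_genome()
  one <- data.frame(sample1 = "s", hap1 = 1L, sample2 = "s", hap2 = 2L,
                    chrom = "chr1", start_bp = 1, end_bp = 2, lod = 10,
                    length_cM = 35, stringsAsFactors = FALSE)
  expect_equal(unname(f_roh(one, g)["s"]), 0.01)
  expect_equal(unname(f_roh(one[0, ], g, samples = "s")["s"]), 0)

  ms <- demography_model(list(S = 500, L = 5e4),
                         splits = data.frame(a = "S", b = "L",
                                             generation = 200),
                         ancestral = 1e4)
  roh <- simulate_roh(ms, c(S = 40, L = 40), g, seed = 37)
  fr <- f_roh(roh, g, samples = c(paste0("S_", 1:40), paste0("L_", 1:40)))
  expect_gt(median(fr[paste0("S_", 1:40)]),
            5 * median(fr[paste0("L_", 1:40)]))
})

test_that("F_IS handles the all-heterozygote edge and recovers f", {
  allhet <- matrix(1L, 10, 20,
                   dimnames = list(paste0("s", 1:10), NULL))
  expect_equal(f_is(allhet), -1)
  expect_error(f_is(matrix(2L, 5, 4)), "polymorphic")
  for (f in c(0, 0.2)) {
    sim <- simulate_genotypes(200, 5000, f, seed = 40 + round(10 * f))
    expect_lt(abs(f_is(sim$genotypes) - f), 0.02)
  }
})

test_that("Hudson F_ST endpoints: identical pops ~0, fixed opposite = 1", {
  sim <- simulate_genotypes(100, 2000, 0, seed = 43)
  gmat <- rbind(sim$genotypes, sim$genotypes)
  rownames(gmat) <- c(paste0("a", 1:100), paste0("b", 1:100))
  expect_lt(abs(hudson_fst(gmat, paste0("a", 1:100), paste0("b", 1:100))),
            0.01)
  fixed <- rbind(matrix(2L, 10, 50), matrix(0L, 10, 50))
  rownames(fixed) <- c(paste0("a", 1:10), paste0("b", 1:10))
  expect_equal(hudson_fst(fixed, paste0("a", 1:10), paste0("b", 1:10)), 1)
  expect_error(hudson_fst(fixed, "a1", paste0("b", 1:10)), ">= 2")
})

test_that("drift simulation recovers F_ST ~ t/(2N)", {
  set.seed(47)
  fst <- replicate(10, drift_fst_replicate(n_snps = 2000))
  expect_lt(abs(mean(fst) - 0.01), 0.3 * 0.01)
})

test_that("length bins map to their canonical time proxies", {
  expect_equal(bin_to_time(c(1, 3)),
               list(generations_proxy = 100, years_proxy = 3000))
  expect_equal(bin_to_time(c(3, 5)),
               list(generations_proxy = 45, years_proxy = 1200))
  expect_equal(bin_to_time(c(5, Inf)),
               list(generations_proxy = 15, years_proxy = 450))
  expect_null(bin_to_time(c(2, 4)))
  expect_equal(bin_to_time(c(3, 5), years_per_generation = 25)$years_proxy,
               1125)
})
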