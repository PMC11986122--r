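test_that("profiles accumulate sharing by partner community, excluding self", {
  # fixture: 4 samples, 2 communities; brute-force accumulation
  seg <- data.frame(
    sample1 = c("a1", "a1", "a2", "b1"),
    hap1 = 1L,
    sample2 = c("a2", "b1", "b2", "b2"),
    hap2 = 2L, chrom = "chr1", start_bp = 1, end_bp = 2, lod = 10,
    length_cM = c(4, 6, 10, 3), stringsAsFactors = FALSE)
  asg <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                    level1 = c("A", "A", "B", "B"))
  prof <- sample_profiles(seg, asg, "level1")
  expect_equal(prof["a1", ], c(A = 4, B = 6))
  expect_equal(prof["a2", ], c(A = 4, B = 10))
  expect_equal(prof["b2", ], c(A = 10, B = 3))
  # row permutation leaves profiles unchanged
  expect_equal(sample_profiles(seg[c(3, 1, 4, 2), ], asg, "level1"), prof)
  # one-hot after normalization when a sample shares with one community
  only <- sample_profiles(seg[2, ], asg, "level1", normalize = TRUE)
  expect_equal(only["a1", ], c(A = 0, B = 1))
  expect_true("a2" %in% attr(only, "zero_samples"))

  # random fixture vs brute force
  segr <- random_segments(200, seed = 61)
  asgr <- data.frame(sample_id = paste0("s", 1:8),
                     level1 = rep(c("X", "Y"), 4))
  lab <- stats::setNames(asgr$level1, asgr$sample_id)
  pr <- sample_profiles(segr, asgr, "level1")
  for (s in rownames(pr)) for (cm in colnames(pr)) {
    partners <- names(lab)[lab == cm & names(lab) != s]
    hit <- (segr$sample1 == s & segr$sample2 %in% partners) |
      (segr$sample2 == s & segr$sample1 %in% partners)
    expect_equal(pr[s, cm], sum(segr$length_cM[hit]))
  }
})

test_that("TVD is the half L1 metric on the simplex", {
  expect_equal(tvd(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(tvd(c(1, 0), c(0, 1)), 1)
  expect_equal(tvd(c(0.5, 0.5), c(0.2, 0.8)), 0.3)
  expect_error(tvd(c(0.5, 0.6), c(0.5, 0.5)), "normalized")
  expect_error(tvd(c(1), c(0.5, 0.5)), "support")
  set.seed(63)
  for (r in 1:25) {
    p <- prop.table(runif(5)); q <- prop.table(runif(5))
    s <- prop.table(runif(5))
    expect_equal(tvd(p, q), tvd(q, p))
    expect_lte(tvd(p, q), tvd(p, s) + tvd(s, q) + 1e-12)
    expect_gte(tvd(p, q), 0); expect_lte(tvd(p, q), 1)
  }
})

test_that("the permutation p-value formula is exact at the boundary", {
  # profiles where only the exact observed partition attains TVD = 1, so
  # every permuted TVD falls below the observed value
  prof <- rbind(matrix(c(10, 0), 20, 2, byrow = TRUE),
                matrix(c(0, 10), 20, 2, byrow = TRUE))
  rownames(prof) <- paste0("s", 1:40)
  colnames(prof) <- c("c1", "c2")
  tv <- tvd_permutation_test(prof, paste0("s", 1:20), paste0("s", 21:40),
                             n_perm = 99, seed = 1)
  expect_equal(tv$tvd_obs, 1)
  expect_equal(tv$p.value, 0.01)
  expect_error(tvd_permutation_test(prof, paste0("s", 1:20),
                                    paste0("s", 20:40), n_perm = 99),
               "disjoint")
  expect_error(tvd_permutation_test(prof, paste0("s", 1:20),
                                    paste0("s", 21:40), n_perm = 10),
               "99")
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(67)
  prof <- matrix(rexp(40 * 3), 40, 3,
                 dimnames = list(paste0("s", 1:40), c("c1", "c2", "c3")))
  pvals <- vapply(1:500, function(r) {
    ids <- sample(rownames(prof), 16)
    tvd_permutation_test(prof, ids[1:8], ids[9:16], n_perm = 199,
                         seed = r)$p.value
  }, numeric(1))
  grid <- seq(0.005, 1, by = 0.005)
  d_plus <- max(vapply(grid, function(t) mean(pvals <= t) - t, numeric(1)))
  # one-sided KS bound at alpha = 0.01 for n = 500, plus the 1/200
  # discreteness of the permutation grid
  expect_lt(d_plus, sqrt(-log(0.01) / 2) / sqrt(500) + 1 / 200)
})

test_that("bootstrap dendrogram groups near-identical communities", {
  set.seed(71)
  base <- runif(12)
  prof <- rbind(t1 = base + rnorm(12, 0, 0.001),
                t2 = base + rnorm(12, 0, 0.001),
                t3 = runif(12), t4 = runif(12) + 2)
  dd <- bootstrap_dendrogram(prof, n_boot = 200, seed = 3)
  sib <- vapply(dd$leaf_sets, function(s) identical(s, c("t1", "t2")),
                logical(1))
  expect_true(any(sib))
  expect_gte(dd$supports[which(sib)], 0.9)
  expect_true(all(dd$supports >= 0 & dd$supports <= 1))
  # root contains all leaves in every bootstrap tree
  expect_equal(dd$supports[length(dd$supports)], 1)
  expect_match(dd$newick, "^\\(.*\\)[0-9.]*;$")
  expect_error(bootstrap_dendrogram(prof[1:2, ]), ">= 3")

  # duplicate profiles merge first (zero distance)
  dup <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  d2 <- bootstrap_dendrogram(dup, n_boot = 10, seed = 1)
  expect_equal(d2$leaf_sets[[1]], c("a", "b"))
  expect_equal(d2$hclust$height[1], 0)
})

test_that("dendrogram topology is invariant to community order", {
  set.seed(73)
  prof <- matrix(runif(5 * 8), 5, 8,
                 dimnames = list(paste0("c", 1:5), NULL))
  d1 <- bootstrap_dendrogram(prof, n_boot = 50, seed = 2)
  d2 <- bootstrap_dendrogram(prof[c(3, 1, 5, 2, 4), ], n_boot = 50,
                             seed = 2)
  key <- function(d) sort(vapply(d$leaf_sets, paste, character(1),
                                 collapse = "|"))
  expect_equal(key(d1), key(d2))
})
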