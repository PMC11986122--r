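test_that("edges obey the 4 cM threshold and brute-force totals", {
  seg <- data.frame(sample1 = c("A", "A"), hap1 = 1L,
                    sample2 = c("B", "B"), hap2 = 2L, chrom = "chr1",
                    start_bp = 1, end_bp = 2, lod = 10,
                    length_cM = c(5, 3), stringsAsFactors = FALSE)
  net <- build_network(seg)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight_total_cM, 5)
  expect_equal(net$edges$weight_mean_cM, 5)

  net0 <- build_network(seg[seg$length_cM < 4, ])
  expect_equal(nrow(net0$edges), 0)

  seg <- random_segments(400, seed = 13)
  net <- build_network(seg, min_segment_cM = 4)
  for (r in seq_len(nrow(net$edges))) {
    a <- net$edges$from[r]; b <- net$edges$to[r]
    hit <- seg$length_cM >= 4 &
      ((seg$sample1 == a & seg$sample2 == b) |
         (seg$sample1 == b & seg$sample2 == a))
    expect_equal(net$edges$weight_total_cM[r], sum(seg$length_cM[hit]))
    expect_equal(net$edges$weight_mean_cM[r], mean(seg$length_cM[hit]))
  }
})

test_that("two-pop data yields stronger within-pop than cross-pop edges", {
  g <- default_genome()
  seg <- simulate_ibd(two_pop_split_model(N = 1000), c(A = 15, B = 15),
                      g, seed = 17)
  net <- build_network(seg)
  within <- pop_of(net$edges$from) == pop_of(net$edges$to)
  expect_gt(mean(net$edges$weight_total_cM[within]),
            mean(net$edges$weight_total_cM[!within]))
})

test_that("relative filtering removes exactly the offending nodes", {
  seg <- random_segments(200, seed = 3)
  net <- build_network(seg, min_segment_cM = 1)
  keep_all <- filter_relatives(net, max_total_cM = 1e6)
  expect_equal(sort(keep_all$retained), sort(net$nodes))
  expect_length(keep_all$removed, 0)
  expect_error(filter_relatives(net, -1), "positive")

  pair <- data.frame(sample1 = "X", hap1 = 1L, sample2 = "Y", hap2 = 1L,
                     chrom = "chr1", start_bp = 1, end_bp = 2, lod = 10,
                     length_cM = 2000, stringsAsFactors = FALSE)
  net2 <- build_network(pair)
  filt <- filter_relatives(net2, 1500)
  expect_length(filt$removed, 1)
  expect_length(filt$retained, 1)

  # planted trio on background: parent shares ~1750 cM with each child
  bg <- random_segments(300, seed = 23)
  trio <- data.frame(sample1 = c("par", "par"), hap1 = 1L,
                     sample2 = c("kid1", "kid2"), hap2 = 1L,
                     chrom = "chr1", start_bp = 1, end_bp = 2, lod = 10,
                     length_cM = 1750, stringsAsFactors = FALSE)
  net3 <- build_network(rbind(bg, trio), min_segment_cM = 1)
  filt3 <- filter_relatives(net3, 1400)
  expect_false(all(c("par", "kid1") %in% filt3$retained))
  expect_false(all(c("par", "kid2") %in% filt3$retained))
  # post-condition: no remaining edge above threshold
  expect_true(all(filt3$network$edges$weight_total_cM <= 1400))
})

test_that("recursive Leiden recovers a planted hierarchy deterministically", {
  skip_if_not_installed("mclust")
  ph <- planted_hierarchy(seed = 42)
  asg <- recursive_leiden(ph$network, levels = 3,
                          resolutions = c(1, 1, 1), min_size = 10,
                          seed = 5)
  expect_gte(mclust::adjustedRandIndex(asg$level1, ph$top[asg$sample_id]),
             0.9)
  expect_gte(mclust::adjustedRandIndex(asg$level2, ph$sub[asg$sample_id]),
             0.9)
  # child labels extend parent labels; level 1 covers everyone
  expect_true(all(startsWith(asg$level2, asg$level1)))
  expect_true(all(startsWith(asg$level3, asg$level2)))
  expect_false(any(is.na(asg$level1)))

  asg2 <- recursive_leiden(ph$network, levels = 3,
                           resolutions = c(1, 1, 1), min_size = 10,
                           seed = 5)
  expect_identical(asg, asg2)
  expect_error(recursive_leiden(build_network(random_segments(10, 1)[0, ])),
               "empty")
})

test_that("two weakly joined cliques split into exactly two communities", {
  nodes <- c(paste0("a", 1:20), paste0("b", 1:20))
  idx <- utils::combn(40, 2)
  same <- (idx[1, ] <= 20) == (idx[2, ] <= 20)
  seg <- data.frame(sample1 = nodes[idx[1, same]], hap1 = 1L,
                    sample2 = nodes[idx[2, same]], hap2 = 1L,
                    chrom = "chr1", start_bp = 1, end_bp = 2, lod = 10,
                    length_cM = 10, stringsAsFactors = FALSE)
  bridge <- data.frame(sample1 = "a1", hap1 = 1L, sample2 = "b1",
                       hap2 = 1L, chrom = "chr1", start_bp = 1,
                       end_bp = 2, lod = 10, length_cM = 0.5,
                       stringsAsFactors = FALSE)
  net <- build_network(rbind(seg, bridge), min_segment_cM = 0.1)
  asg <- recursive_leiden(net, levels = 1, resolutions = 1, min_size = 5,
                          seed = 1)
  expect_equal(length(unique(asg$level1)), 2)
  expect_equal(length(unique(asg$level1[startsWith(asg$sample_id, "a")])), 1)
})

test_that("top-k edges equal the brute-force per-node selection", {
  seg <- random_segments(500, seed = 29,
                         samples = paste0("v", 1:12))
  net <- build_network(seg, min_segment_cM = 1)
  for (k in c(1, 3, 10)) {
    got <- top_k_edges(net, k)
    want <- unique(do.call(rbind, lapply(net$nodes, function(v) {
      e <- net$edges[net$edges$from == v | net$edges$to == v, ,
                     drop = FALSE]
      e[order(-e$weight_mean_cM, -e$weight_total_cM, e$from,
              e$to), ][seq_len(min(k, nrow(e))), ]
    })))
    key <- function(d) sort(paste(d$from, d$to))
    expect_equal(key(got), key(want))
  }
  # star graph, k = 1: every spoke survives via its leaf
  star <- data.frame(sample1 = "hub", hap1 = 1L,
                     sample2 = paste0("leaf", 1:6), hap2 = 1L,
                     chrom = "chr1", start_bp = 1, end_bp = 2, lod = 10,
                     length_cM = 5 + (1:6), stringsAsFactors = FALSE)
  snet <- build_network(star)
  expect_equal(nrow(top_k_edges(snet, 1)), 6)
})
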