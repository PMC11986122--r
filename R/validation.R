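#' Per-sample IBD-sharing profiles over reference communities
#'
#' For each sample, the total cM it shares with the members of each
#' community (own contribution excluded from its own community's entry).
#' Optionally restricted to one length bin, and optionally row-normalized
#' to the probability simplex.
#'
#' @param segments IBD segment data.frame.
#' @param assignment community assignment data.frame.
#' @param level level column name.
#' @param bin optional c(u, v) length bin filter.
#' @param normalize row-normalize to sum 1 (default FALSE). Zero-sum rows
#'   are left at zero and flagged in the `zero_samples` attribute.
#' @return matrix samples x communities.
#' @export
sample_profiles <- function(segments, assignment, level = "level1",
                            bin = NULL, normalize = FALSE) {
  if (!level %in% names(assignment)) stop("unknown level column: ", level)
  lab <- stats::setNames(assignment[[level]], assignment$sample_id)
  lab <- lab[!is.na(lab)]
  if (!is.null(bin))
    segments <- segments[segments$length_cM >= bin[1] &
                           segments$length_cM < bin[2], , drop = FALSE]
  ids <- sort(names(lab))
  comms <- sort(unique(lab))
  prof <- matrix(0, length(ids), length(comms),
                 dimnames = list(ids, comms))
  seg <- segments[segments$sample1 %in% ids & segments$sample2 %in% ids &
                    segments$sample1 != segments$sample2, , drop = FALSE]
  if (nrow(seg) > 0) {
    # each segment credits both endpoints with its partner's community, so
    # a sample's own sharing is never self-counted
    nC <- length(comms)
    flat <- as.numeric(t(prof))
    i <- match(seg$sample1, ids); j <- match(unname(lab[seg$sample2]), comms)
    a1 <- rowsum(seg$length_cM, (i - 1) * nC + j)
    i <- match(seg$sample2, ids); j <- match(unname(lab[seg$sample1]), comms)
    a2 <- rowsum(seg$length_cM, (i - 1) * nC + j)
    flat[as.integer(rownames(a1))] <- flat[as.integer(rownames(a1))] + a1[, 1]
    flat[as.integer(rownames(a2))] <- flat[as.integer(rownames(a2))] + a2[, 1]
    prof <- matrix(flat, nrow = length(ids), byrow = TRUE,
                   dimnames = list(ids, comms))
  }
  zero <- rownames(prof)[rowSums(prof) == 0]
  if (normalize) {
    rs <- rowSums(prof)
    nz <- rs > 0
    prof[nz, ] <- prof[nz, , drop = FALSE] / rs[nz]
  }
  attr(prof, "zero_samples") <- zero
  prof
}

#' Total variation distance between two probability vectors
#'
#' 0.5 * sum |p - q|. Inputs must be normalized (sum to 1 within 1e-8).
#'
#' @param p,q numeric vectors on the same support.
#' @return TVD in [0, 1].
#' @export
tvd <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have the same support")
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    stop("p and q must be normalized")
  0.5 * sum(abs(p - q))
}

#' TVD permutation test between two sample groups
#'
#' Tests whether groups A and B have distinguishable mean sharing
#' profiles. The profile support excludes the communities of membership of
#' A and B themselves (`exclude_communities`), mirroring the exclusion of
#' self-copying; each group's raw profiles are averaged and normalized,
#' the observed TVD computed, and group labels permuted among A union B
#' preserving sizes. p = (1 + #{TVD_perm >= TVD_obs}) / (n_perm + 1).
#' Zero-sum profiles are dropped with a warning.
#'
#' @param profiles raw (unnormalized) sample x community profile matrix.
#' @param members_a,members_b disjoint sample id vectors (>= 2 each).
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed.
#' @param exclude_communities community columns to drop from the support
#'   (typically the communities A and B belong to). NULL keeps all.
#' @return list with `tvd_obs`, `p.value`, `n_perm`.
#' @export
tvd_permutation_test <- function(profiles, members_a, members_b,
                                 n_perm = 999, seed = 1,
                                 exclude_communities = NULL) {
  if (length(intersect(members_a, members_b)) > 0)
    stop("groups A and B must be disjoint")
  if (n_perm < 99) stop("n_perm must be >= 99")
  keep_cols <- setdiff(colnames(profiles), exclude_communities)
  if (length(keep_cols) == 0) stop("no profile support left after exclusion")
  prof <- profiles[c(members_a, members_b), keep_cols, drop = FALSE]
  zero <- rowSums(prof) == 0
  if (any(zero)) {
    warning(sum(zero), " zero-sum profile(s) dropped")
    members_a <- setdiff(members_a, rownames(prof)[zero])
    members_b <- setdiff(members_b, rownames(prof)[zero])
    prof <- prof[!zero, , drop = FALSE]
  }
  if (length(members_a) < 2 || length(members_b) < 2)
    stop("each group needs >= 2 members with nonzero profiles")
  grp_tvd <- function(ids_a, ids_b) {
    ma <- colMeans(prof[ids_a, , drop = FALSE])
    mb <- colMeans(prof[ids_b, , drop = FALSE])
    tvd(ma / sum(ma), mb / sum(mb))
  }
  obs <- grp_tvd(members_a, members_b)
  pool <- c(members_a, members_b)
  na <- length(members_a)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(r) {
    sh <- sample(pool)
    grp_tvd(sh[seq_len(na)], sh[-seq_len(na)])
  }, numeric(1))
  list(tvd_obs = obs,
       p.value = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_perm = n_perm)
}

# leaf sets under each merge of an hclust tree
merge_leaf_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[m, ]
    s <- c()
    for (kk in kids)
      s <- c(s, if (kk < 0) hc$labels[-kk] else sets[[kk]])
    sets[[m]] <- sort(s)
  }
  sets
}

#' Bootstrap-supported dendrogram of community profiles
#'
#' Hierarchical clustering (Euclidean distance on row-normalized community
#' mean profiles, agglomerative linkage) with per-branch bootstrap
#' support: the fraction of trees built on column-resampled profiles that
#' contain the same leaf grouping. An ordinary bootstrap proportion is
#' reported (not a multiscale-bootstrap AU value); the contract is the
#' same — high support marks a robust branch.
#'
#' @param community_profiles matrix communities x features (e.g. community
#'   mean sharing profiles, possibly per bin).
#' @param n_boot bootstrap replicates (default 1000).
#' @param linkage hclust linkage method (default "average").
#' @param seed integer seed.
#' @return list of class `supported_dendrogram`: `hclust`, `supports`
#'   (per merge, in hclust merge order), `leaf_sets`, `linkage`, `newick`.
#' @export
bootstrap_dendrogram <- function(community_profiles, n_boot = 1000,
                                 linkage = "average", seed = 1) {
  if (nrow(community_profiles) < 3) stop("need >= 3 communities")
  x <- community_profiles / pmax(rowSums(community_profiles), 1e-300)
  hc <- stats::hclust(stats::dist(x), method = linkage)
  hc$labels <- rownames(x)
  sets <- merge_leaf_sets(hc)
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  hits <- numeric(length(keys))
  set.seed(seed)
  for (r in seq_len(n_boot)) {
    cols <- sample.int(ncol(x), replace = TRUE)
    hb <- stats::hclust(stats::dist(x[, cols, drop = FALSE]),
                        method = linkage)
    hb$labels <- rownames(x)
    kb <- vapply(merge_leaf_sets(hb), paste, character(1), collapse = "\r")
    hits <- hits + (keys %in% kb)
  }
  supports <- hits / n_boot
  structure(list(hclust = hc, supports = supports, leaf_sets = sets,
                 linkage = linkage,
                 newick = hclust_newick(hc, supports)),
            class = "supported_dendrogram")
}

# Newick string with bootstrap supports as internal node labels
hclust_newick <- function(hc, supports) {
  rec <- function(node) {
    if (node < 0) return(hc$labels[-node])
    kids <- hc$merge[node, ]
    sprintf("(%s,%s)%.3f", rec(kids[1]), rec(kids[2]), supports[node])
  }
  paste0(rec(nrow(hc$merge)), ";")
}

#' @export
print.supported_dendrogram <- function(x, ...) {
  cat("<supported_dendrogram>", x$newick, "\n")
  invisible(x)
}
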