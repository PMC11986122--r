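#' Community x reference affinity matrix for one length bin
#'
#' Entry (t, r) is the total cM of bin-qualifying segments between members
#' of target community t and external reference cluster r, divided by
#' n_t * n_r (mean per cross pair). Target and reference sample sets must
#' be disjoint.
#'
#' @param segments IBD segment data.frame.
#' @param target_assignment assignment data.frame for target samples.
#' @param reference_assignment assignment data.frame for reference
#'   samples.
#' @param bin c(u, v) length bin.
#' @param target_level,reference_level label columns (defaults "level1").
#' @return numeric matrix targets x references with a `bin` attribute.
#' @export
affinity_matrix <- function(segments, target_assignment,
                            reference_assignment, bin,
                            target_level = "level1",
                            reference_level = "level1") {
  tlab <- stats::setNames(target_assignment[[target_level]],
                          target_assignment$sample_id)
  rlab <- stats::setNames(reference_assignment[[reference_level]],
                          reference_assignment$sample_id)
  tlab <- tlab[!is.na(tlab)]; rlab <- rlab[!is.na(rlab)]
  if (length(intersect(names(tlab), names(rlab))) > 0)
    stop("target and reference sample sets overlap")
  seg <- segments[segments$length_cM >= bin[1] &
                    segments$length_cM < bin[2], , drop = FALSE]
  tc <- sort(unique(tlab)); rc <- sort(unique(rlab))
  m <- matrix(0, length(tc), length(rc), dimnames = list(tc, rc))
  t1 <- unname(tlab[seg$sample1]); r2 <- unname(rlab[seg$sample2])
  t2 <- unname(tlab[seg$sample2]); r1 <- unname(rlab[seg$sample1])
  u1 <- !is.na(t1) & !is.na(r2)
  u2 <- !is.na(t2) & !is.na(r1)
  pairs <- rbind(cbind(match(t1[u1], tc), match(r2[u1], rc)),
                 cbind(match(t2[u2], tc), match(r1[u2], rc)))
  vals <- c(seg$length_cM[u1], seg$length_cM[u2])
  if (nrow(pairs) > 0) {
    agg <- rowsum(vals, (pairs[, 1] - 1) * length(rc) + pairs[, 2])
    flat <- as.numeric(t(m))
    flat[as.integer(rownames(agg))] <- agg[, 1]
    m <- matrix(flat, nrow = length(tc), byrow = TRUE, dimnames = dimnames(m))
  }
  nt <- table(tlab)[tc]; nr <- table(rlab)[rc]
  m <- m / outer(as.numeric(nt), as.numeric(nr))
  attr(m, "bin") <- bin
  m
}

#' PCA biplot decomposition of an affinity matrix
#'
#' Columns (reference clusters) are centered, and unit-scaled when
#' `scale_columns` (default), then decomposed by SVD. Row scores are the
#' projections of the target communities on the first two components;
#' column loadings weight the reference clusters. The sign of each
#' component is fixed so that its largest-magnitude loading is positive.
#'
#' @param m affinity matrix (>= 3 rows, >= 2 columns).
#' @param scale_columns unit-scale columns (default TRUE).
#' @return list of class `biplot_result`: `scores` (rows x 2),
#'   `loadings` (columns x 2), `var_explained` (all components).
#' @export
pca_biplot <- function(m, scale_columns = TRUE) {
  if (nrow(m) < 3 || ncol(m) < 2) stop("need >= 3 rows and >= 2 columns")
  x <- scale(m, center = TRUE, scale = FALSE)
  if (scale_columns) {
    sdv <- apply(x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    x <- sweep(x, 2, sdv, "/")
  }
  if (all(abs(x) < 1e-12)) stop("no variance in affinity matrix")
  sv <- svd(x)
  varexp <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2)
  loadings <- sv$v[, 1:2, drop = FALSE]
  for (j in 1:2) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(m), c("PC1", "PC2"))
  dimnames(loadings) <- list(colnames(m), c("PC1", "PC2"))
  structure(list(scores = scores, loadings = loadings,
                 var_explained = varexp),
            class = "biplot_result")
}

#' @export
print.biplot_result <- function(x, ...) {
  cat(sprintf("<biplot_result> PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$var_explained[1], 100 * x$var_explained[2]))
  invisible(x)
}
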