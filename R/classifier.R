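#' Per-bin sharing feature matrix for ancestry classification
#'
#' For each query sample: concatenation over length bins of the total cM
#' shared with each reference community (the sample's own contribution is
#' excluded when it is itself a reference member). Missing sharing is 0.
#'
#' @param segments IBD segment data.frame.
#' @param reference_assignment assignment data.frame for the reference
#'   panel (column `level` gives reference community labels).
#' @param samples query sample ids.
#' @param bins length bins (default [canonical_bins()]).
#' @param level reference level column (default "level2").
#' @return numeric matrix samples x (bins * communities); column names
#'   `<community>|<bin>`.
#' @export
feature_matrix <- function(segments, reference_assignment, samples,
                           bins = canonical_bins(), level = "level2") {
  if (!level %in% names(reference_assignment))
    stop("unknown level column: ", level)
  lab <- stats::setNames(reference_assignment[[level]],
                         reference_assignment$sample_id)
  lab <- lab[!is.na(lab)]
  ref_ids <- names(lab)
  comms <- sort(unique(lab))
  feats <- NULL
  for (bin in bins) {
    seg <- segments[segments$length_cM >= bin[1] &
                      segments$length_cM < bin[2] &
                      segments$sample1 != segments$sample2, , drop = FALSE]
    m <- matrix(0, length(samples), length(comms),
                dimnames = list(samples,
                                paste0(comms, "|", bin_label(bin))))
    s1q <- match(seg$sample1, samples); c2 <- match(unname(lab[seg$sample2]), comms)
    s2q <- match(seg$sample2, samples); c1 <- match(unname(lab[seg$sample1]), comms)
    u1 <- !is.na(s1q) & !is.na(c2)
    u2 <- !is.na(s2q) & !is.na(c1)
    idx <- c((s1q[u1] - 1) * length(comms) + c2[u1],
             (s2q[u2] - 1) * length(comms) + c1[u2])
    val <- c(seg$length_cM[u1], seg$length_cM[u2])
    if (length(idx) > 0) {
      agg <- rowsum(val, idx)
      flat <- as.numeric(t(m))
      flat[as.integer(rownames(agg))] <- agg[, 1]
      m <- matrix(flat, nrow = length(samples), byrow = TRUE,
                  dimnames = dimnames(m))
    }
    feats <- cbind(feats, m)
  }
  feats
}

#' Train a Gaussian naive Bayes classifier
#'
#' Class priors are empirical frequencies; each (class, feature) gets an
#' independent Gaussian with the class-conditional mean and variance
#' (variance floored at `var_floor`).
#'
#' @param features numeric matrix samples x features.
#' @param labels class label per sample (>= 2 classes, each >= 5 samples).
#' @param var_floor variance floor (default 1e-6).
#' @return object of class `nb_model`: priors, means, vars, classes,
#'   feature_names.
#' @export
nb_train <- function(features, labels, var_floor = 1e-6) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes")
  cnt <- table(labels)
  if (any(cnt < 5)) stop("every class needs >= 5 training samples")
  mu <- s2 <- matrix(NA_real_, length(classes), ncol(features),
                     dimnames = list(classes, colnames(features)))
  for (cl in classes) {
    x <- features[labels == cl, , drop = FALSE]
    mu[cl, ] <- colMeans(x)
    v <- apply(x, 2, stats::var)
    s2[cl, ] <- pmax(v, var_floor)
  }
  structure(list(classes = classes,
                 priors = as.numeric(cnt[classes]) / length(labels),
                 means = mu, vars = s2, var_floor = var_floor,
                 feature_names = colnames(features)),
            class = "nb_model")
}

#' Predict with a Gaussian naive Bayes model
#'
#' Log-posterior = log prior + sum of Gaussian log-densities; posteriors
#' are normalized via log-sum-exp. Argmax label, ties broken
#' lexicographically.
#'
#' @param model an `nb_model`.
#' @param features numeric matrix (or vector) of query features, same
#'   dimension as training.
#' @return data.frame sample, predicted, max_posterior, plus one posterior
#'   column per class.
#' @export
nb_predict <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != ncol(model$means))
    stop("feature dimension mismatch: ", ncol(features), " vs ",
         ncol(model$means))
  n <- nrow(features)
  post <- matrix(NA_real_, n, length(model$classes),
                 dimnames = list(rownames(features), model$classes))
  for (ci in seq_along(model$classes)) {
    mu <- model$means[ci, ]; s2 <- model$vars[ci, ]
    ll <- -0.5 * (log(2 * pi * s2)[col(features)] +
                    (sweep(features, 2, mu))^2 / s2[col(features)])
    post[, ci] <- log(model$priors[ci]) + rowSums(ll)
  }
  mx <- apply(post, 1, max)
  post <- exp(post - mx)
  post <- post / rowSums(post)
  pred <- model$classes[apply(post, 1, which.max)]
  out <- data.frame(sample = rownames(features) %||% as.character(seq_len(n)),
                    predicted = pred,
                    max_posterior = apply(post, 1, max),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(post))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified train/validation split
#'
#' @param labels class label per sample.
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `validation`.
#' @export
stratified_split <- function(labels, fraction = 0.8, seed = 1) {
  set.seed(seed)
  train <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- max(1, round(fraction * length(idx)))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, validation = setdiff(seq_along(labels), train))
}

#' Evaluate a naive Bayes model on held-out data
#'
#' @param model an `nb_model`.
#' @param features held-out feature matrix.
#' @param labels held-out true labels.
#' @return list with `confusion` (true x predicted), `accuracy`,
#'   `recall` (per class).
#' @export
nb_evaluate <- function(model, features, labels) {
  if (length(labels) == 0) stop("held-out set is empty")
  labels <- as.character(labels)
  unseen <- setdiff(unique(labels), model$classes)
  if (length(unseen) > 0)
    warning("label(s) unseen in training: ", paste(unseen, collapse = ", "))
  pred <- nb_predict(model, features)$predicted
  lev <- sort(unique(c(labels, model$classes)))
  confusion <- table(true = factor(labels, lev),
                     predicted = factor(pred, lev))
  recall <- diag(confusion) / pmax(rowSums(confusion), 1)
  list(confusion = confusion,
       accuracy = mean(pred == labels),
       recall = recall[rownames(confusion) %in% unique(labels)])
}
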