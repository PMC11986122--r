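#' Surname-origin x community contingency table
#'
#' Counts samples per (surname_origin, community) cell at the chosen
#' level. Samples missing either field are excluded (count reported in a
#' message).
#'
#' @param metadata metadata data.frame (needs sample_id, surname_origin).
#' @param assignment community assignment data.frame.
#' @param level level column name.
#' @return integer matrix origins x communities.
#' @export
build_table <- function(metadata, assignment, level = "level3") {
  if (!level %in% names(assignment)) stop("unknown level column: ", level)
  df <- merge(metadata[, c("sample_id", "surname_origin")],
              assignment[, c("sample_id", level)], by = "sample_id")
  ok <- !is.na(df$surname_origin) & !is.na(df[[level]])
  if (sum(!ok) > 0)
    message(sum(!ok), " sample(s) missing origin or label excluded")
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) stop("no samples with both surname origin and label")
  tab <- table(origin = df$surname_origin, community = df[[level]])
  matrix(as.integer(tab), nrow = nrow(tab),
         dimnames = dimnames(tab))
}

#' Pearson chi-squared test of origin-community independence
#'
#' @param tab contingency matrix (counts).
#' @return list with `chi2`, `dof`, `p.value`.
#' @export
chi2_test <- function(tab) {
  check_table(tab)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), dof = unname(ht$parameter),
       p.value = ht$p.value)
}

check_table <- function(tab) {
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in contingency table")
  if (min(dim(tab)) < 2) stop("table needs >= 2 rows and columns")
  invisible(tab)
}

#' Cramer's V, optionally bias-corrected
#'
#' Unadjusted: V = sqrt(chi2 / (n * min(r-1, c-1))). The bias-corrected
#' version shrinks phi^2 = chi2/n by its independence expectation and
#' shrinks the effective dimensions:
#' phi2+ = max(0, phi2 - (r-1)(c-1)/(n-1)); r+ = r - (r-1)^2/(n-1),
#' c+ = c - (c-1)^2/(n-1); V_adj = sqrt(phi2+ / min(r+ - 1, c+ - 1)).
#'
#' @param tab contingency matrix.
#' @param adjusted apply the bias correction (default TRUE).
#' @return V in [0, 1].
#' @export
cramers_v <- function(tab, adjusted = TRUE) {
  check_table(tab)
  chi2 <- chi2_test(tab)$chi2
  n <- sum(tab); r <- nrow(tab); cc <- ncol(tab)
  if (!adjusted) return(sqrt(chi2 / (n * min(r - 1, cc - 1))))
  phi2 <- chi2 / n
  phi2p <- max(0, phi2 - (r - 1) * (cc - 1) / (n - 1))
  rp <- r - (r - 1)^2 / (n - 1)
  cp <- cc - (cc - 1)^2 / (n - 1)
  sqrt(phi2p / min(rp - 1, cp - 1))
}

#' Per-cell enrichment and depletion
#'
#' Standardized Pearson residuals r = (O - E) / sqrt(E (1 - row/n)
#' (1 - col/n)) with two-sided normal p-values, Benjamini-Hochberg
#' adjusted across all cells. A cell is `enriched` when r > 0 and
#' p_adj < alpha, `depleted` when r < 0 and p_adj < alpha.
#'
#' @param tab contingency matrix.
#' @param alpha significance level for direction calls (default 0.05).
#' @return data.frame: origin, community, observed, expected, residual,
#'   p, p_adj, direction.
#' @export
enrichment_cells <- function(tab, alpha = 0.05) {
  check_table(tab)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  res <- ht$stdres
  p <- 2 * stats::pnorm(-abs(res))
  p_adj <- matrix(stats::p.adjust(p, method = "BH"), nrow = nrow(tab))
  dir <- ifelse(p_adj < alpha & res > 0, "enriched",
                ifelse(p_adj < alpha & res < 0, "depleted", "ns"))
  out <- data.frame(
    origin = rep(rownames(tab), times = ncol(tab)),
    community = rep(colnames(tab), each = nrow(tab)),
    observed = as.integer(tab),
    expected = as.numeric(ht$expected),
    residual = as.numeric(res),
    p = as.numeric(p), p_adj = as.numeric(p_adj),
    direction = as.character(dir), stringsAsFactors = FALSE)
  out
}
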