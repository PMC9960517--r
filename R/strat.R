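# Population-stratification correction: PCA of the standardized dosage
# matrix and automatic selection of significant components with the
# Tracy-Widom statistic.

#' PCA of a genotype dataset
#'
#' Columns are standardized to mean zero and unit binomial variance: for
#' allele frequency p (= mean dosage / 2) the column is centred at 2p and
#' divided by sqrt(p(1-p)). Monomorphic columns are skipped. The
#' decomposition is of the sample-by-sample covariance
#' K = X X' / m over the m retained columns.
#'
#' @param dataset a \code{genotype_dataset} with no missing dosages
#' @param n_components number of score columns to return
#' @return a \code{pca_result}: \code{eigenvalues} (all n - 1, descending),
#'   \code{scores} (n x n_components), \code{n_variants_used}
#' @export
pca_dataset <- function(dataset, n_components = 20) {
  dos <- dataset$dosages
  if (anyNA(dos))
    stop("missing dosages present; impute before PCA")
  Xs <- standardize_dosages(dos)
  m <- ncol(Xs)
  if (m == 0) stop("no polymorphic variants")
  K <- tcrossprod(Xs) / m
  ei <- eigen(K, symmetric = TRUE)
  nev <- max(nrow(dos) - 1L, 1L)
  vals <- pmax(ei$values[seq_len(nev)], 0)
  k <- min(n_components, nev)
  scores <- ei$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  rownames(scores) <- dataset$sample_ids
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(eigenvalues = vals, scores = scores, n_variants_used = m,
                 n_samples = nrow(dos)),
            class = "pca_result")
}

# center at 2p, scale by sqrt(p(1-p)); drop monomorphic columns
standardize_dosages <- function(dos) {
  p <- colMeans(dos) / 2
  poly <- p > 0 & p < 1
  dosp <- dos[, poly, drop = FALSE]
  pp <- p[poly]
  sweep(sweep(dosp, 2, 2 * pp), 2, sqrt(pp * (1 - pp)), "/")
}

# Upper-tail critical values of the Tracy-Widom distribution (beta = 1),
# standard published quantiles; interpolated linearly in log10(alpha).
.tw1_critical <- data.frame(
  alpha = c(0.10, 0.05, 0.025, 0.01, 0.005, 0.001),
  value = c(0.4501, 0.9793, 1.4538, 2.0234, 2.4224, 3.2724))

tw1_critical_value <- function(alpha) {
  tb <- .tw1_critical
  if (alpha > max(tb$alpha) || alpha < min(tb$alpha)) {
    warning("alpha clamped to the tabulated Tracy-Widom range [0.001, 0.10]")
    alpha <- min(max(alpha, min(tb$alpha)), max(tb$alpha))
  }
  stats::approx(log10(tb$alpha), tb$value, xout = log10(alpha))$y
}

#' Tracy-Widom selection of significant principal components
#'
#' Sequential testing of the leading eigenvalues: for each candidate, the
#' effective number of markers is estimated from the remaining eigenvalues
#' by the moment estimator
#' n_eff = (k + 1) S1^2 / ((k - 1) S2 - S1^2) (k remaining eigenvalues,
#' S1 and S2 their first two power sums); the leading eigenvalue is then
#' centred and scaled to the Tracy-Widom variable
#' x = (l - mu) / sigma with l = k * lambda / S1,
#' mu = (sqrt(n_eff - 1) + sqrt(k))^2 / n_eff and
#' sigma = (sqrt(n_eff - 1) + sqrt(k)) / n_eff *
#' (1/sqrt(n_eff - 1) + 1/sqrt(k))^(1/3), and compared with the TW(1)
#' critical value at \code{alpha}. Testing stops at the first
#' non-significant eigenvalue.
#'
#' @param eigenvalues descending eigenvalues from \code{pca_dataset}
#' @param alpha upper-tail significance level (tabulated range 0.001-0.10)
#' @return integer: number of significant components
#' @export
tracy_widom_select <- function(eigenvalues, alpha = 0.05) {
  ev <- eigenvalues[eigenvalues > .Machine$double.eps]
  if (length(ev) < 2) stop("need at least 2 positive eigenvalues")
  crit <- tw1_critical_value(alpha)
  n_sig <- 0L
  repeat {
    k <- length(ev)
    if (k < 3) break
    s1 <- sum(ev); s2 <- sum(ev^2)
    denom <- (k - 1) * s2 - s1^2
    if (denom <= 0) break  # eigenvalues numerically equal: nothing to test
    neff <- (k + 1) * s1^2 / denom
    l <- k * ev[1] / s1
    mu <- (sqrt(neff - 1) + sqrt(k))^2 / neff
    sigma <- (sqrt(neff - 1) + sqrt(k)) / neff *
      (1 / sqrt(neff - 1) + 1 / sqrt(k))^(1 / 3)
    x <- (l - mu) / sigma
    if (!is.finite(x) || x < crit) break
    n_sig <- n_sig + 1L
    ev <- ev[-1]
  }
  n_sig
}

#' PCA plus Tracy-Widom selection in one call
#'
#' @param dataset a complete \code{genotype_dataset}
#' @param max_pcs maximum number of components to return scores for
#' @param alpha Tracy-Widom significance level
#' @return a \code{pca_result} with an added \code{n_selected} element and
#'   scores truncated to \code{max(n_selected, 1)} columns
#' @export
select_pcs <- function(dataset, max_pcs = 20, alpha = 0.05) {
  res <- pca_dataset(dataset, n_components = max_pcs)
  res$n_selected <- tracy_widom_select(res$eigenvalues, alpha = alpha)
  res$selected_scores <-
    res$scores[, seq_len(min(max(res$n_selected, 0), ncol(res$scores))),
               drop = FALSE]
  res
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", x$n_samples, "samples,", x$n_variants_used,
      "variants; top eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  if (!is.null(x$n_selected))
    cat("Tracy-Widom significant components:", x$n_selected, "\n")
  invisible(x)
}
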