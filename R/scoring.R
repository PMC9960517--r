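# PRS computation, LD clumping, clumping + p-value-threshold model search,
# and the incremental (full-minus-reduced) PRS R-squared.

#' Construct a PRS model
#'
#' @param id variant ids
#' @param effect_allele counted allele per variant
#' @param weight per-variant weight (effect size)
#' @param denominator_mode \code{"allele_count"} (score divided by twice the
#'   per-sample number of non-missing model variants), \code{"n_samples_literal"}
#'   (divided by the cohort sample count) or \code{"none"}. All three are
#'   positive affine transforms of one another on complete data, so the
#'   incremental R-squared and min-max-normalized scores are identical
#'   across modes.
#' @param threshold,engine optional provenance annotations
#' @return a \code{prs_model} data.frame
#' @export
prs_model <- function(id, effect_allele, weight,
                      denominator_mode = c("allele_count",
                                           "n_samples_literal", "none"),
                      threshold = NA_real_, engine = NA_character_) {
  denominator_mode <- match.arg(denominator_mode)
  if (anyDuplicated(id)) stop("duplicate variant ids in model")
  if (any(!is.finite(weight))) stop("model weights must be finite")
  m <- data.frame(id = as.character(id),
                  effect_allele = as.character(effect_allele),
                  weight = as.numeric(weight), stringsAsFactors = FALSE)
  attr(m, "denominator_mode") <- denominator_mode
  attr(m, "threshold") <- threshold
  attr(m, "engine") <- engine
  class(m) <- c("prs_model", "data.frame")
  m
}

#' Compute per-sample raw polygenic scores
#'
#' score_s = sum_i w_i * dosage_si / D, with D set by the model's
#' denominator mode. Model variants absent from the dataset are skipped
#' with a warning. Effect alleles are reconciled against the dataset's
#' counted allele with the same flip/switch logic used at merge time:
#' a model effect allele equal to the variant's allele2 (or its strand
#' complement) contributes through the switched dosage 2 - d.
#'
#' @param dataset a \code{genotype_dataset}
#' @param model a \code{prs_model}
#' @return named numeric vector of raw scores (one per sample)
#' @export
compute_prs <- function(dataset, model) {
  idx <- match(model$id, dataset$variants$id)
  if (all(is.na(idx))) stop("no model variant overlaps the dataset")
  if (anyNA(idx))
    warning(sum(is.na(idx)), " model variant(s) absent from dataset; skipped")
  keep <- !is.na(idx)
  mi <- idx[keep]
  ea <- model$effect_allele[keep]
  a1 <- dataset$variants$allele1[mi]; a2 <- dataset$variants$allele2[mi]
  same <- ea == a1 | ea == dna_complement(a1)
  swit <- ea == a2 | ea == dna_complement(a2)
  unmatched <- !(same | swit)
  if (any(unmatched)) {
    warning(sum(unmatched), " model variant(s) with irreconcilable effect allele; skipped")
    keep[keep][unmatched] <- FALSE
    mi <- mi[!unmatched]; same <- same[!unmatched]; swit <- swit[!unmatched]
  }
  if (!length(mi)) stop("no model variant overlaps the dataset")
  w <- model$weight[keep]
  G <- dataset$dosages[, mi, drop = FALSE]
  G[, swit & !same] <- 2 - G[, swit & !same, drop = FALSE]
  obs <- !is.na(G)
  G[!obs] <- 0
  raw <- as.vector(G %*% w)
  mode <- attr(model, "denominator_mode") %||% "allele_count"
  D <- switch(mode,
              allele_count = pmax(2 * rowSums(obs), 1),
              n_samples_literal = n_samples(dataset),
              none = 1)
  scores <- raw / D
  names(scores) <- dataset$sample_ids
  scores
}

#' Min-max normalization of scores to [0, 1]
#'
#' @param scores numeric vector with at least two distinct values; a
#'   constant vector maps to all 0.5 with a warning
#' @return rescaled vector (x - min) / (max - min)
#' @export
minmax_normalize <- function(scores) {
  rng <- range(scores)
  if (rng[1] == rng[2]) {
    warning("constant score vector; returning 0.5 for all samples")
    return(rep(0.5, length(scores)))
  }
  (scores - rng[1]) / (rng[2] - rng[1])
}

#' Greedy LD clumping
#'
#' Variants are visited in order of ascending p-value; a variant is
#' retained unless its squared dosage correlation with an already-retained
#' variant within \code{window_kb} on the same chromosome exceeds
#' \code{r2_max}.
#'
#' @param sumstats a \code{summary_stats} table (needs id, chrom, pos, p)
#' @param dataset the \code{genotype_dataset} supplying LD (dosage
#'   correlations)
#' @param r2_max maximum squared correlation tolerated with a retained variant
#' @param window_kb window half-width in kilobases
#' @param ld optional precomputed \code{ld_band} for \code{dataset}
#'   (see \code{ld_band}); computed on the fly when absent
#' @return character vector of retained variant ids
#' @export
clump <- function(sumstats, dataset, r2_max = 0.1, window_kb = 250,
                  ld = NULL) {
  ss <- sumstats[order(sumstats$p, sumstats$id), , drop = FALSE]
  vi <- match(ss$id, dataset$variants$id)
  if (anyNA(vi)) stop("sumstats contain variants absent from dataset")
  if (is.null(ld)) ld <- ld_band(dataset, window_kb = window_kb)
  m <- n_variants(dataset)
  accepted <- logical(m)
  # only columns within maxlag can carry nonzero band r2 (the band is
  # already masked by chromosome and physical window)
  for (r in seq_along(vi)) {
    j <- vi[r]
    near <- seq(max(1L, j - ld$maxlag), min(m, j + ld$maxlag))
    near <- near[accepted[near]]
    ok <- TRUE
    if (length(near)) {
      off <- abs(near - j)
      ok <- !any(ld$band[cbind(pmin(near, j), off)] > r2_max)
    }
    if (ok) accepted[j] <- TRUE
  }
  # report retained ids in ascending-p (acceptance) order
  ss$id[accepted[vi]]
}

#' Banded LD (squared correlation) cache for clumping
#'
#' Precomputes dosage correlations between every variant pair within
#' \code{window_kb} (same chromosome), stored as a band matrix keyed by
#' column offset. Missing dosages are mean-imputed for the correlation
#' computation only.
#'
#' @param dataset a \code{genotype_dataset}
#' @param window_kb window half-width in kilobases
#' @return an \code{ld_band} object
#' @export
ld_band <- function(dataset, window_kb = 250) {
  dos <- dataset$dosages
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    na <- which(is.na(dos))
    dos[na] <- mu[(na - 1) %/% nrow(dos) + 1]
  }
  n <- nrow(dos); m <- ncol(dos)
  sds <- apply(dos, 2, stats::sd)
  Z <- sweep(dos, 2, colMeans(dos))
  Z <- sweep(Z, 2, ifelse(sds > 0, sds, 1), "/")
  chrom <- dataset$variants$chrom; pos <- dataset$variants$pos
  # maximum column offset that can fall inside the physical window
  maxlag <- 0L
  for (d in seq_len(m - 1)) {
    within <- chrom[seq_len(m - d)] == chrom[seq(d + 1, m)] &
      abs(pos[seq(d + 1, m)] - pos[seq_len(m - d)]) <= window_kb * 1000
    if (!any(within)) break
    maxlag <- d
  }
  band <- matrix(0, nrow = m, ncol = max(maxlag, 1))
  if (maxlag > 0) {
    L <- maxlag
    # blockwise crossprod: all pairs within L columns of one another
    for (s in seq(1, m, by = L)) {
      e <- min(s + L - 1, m)
      e2 <- min(e + L, m)
      B <- crossprod(Z[, s:e, drop = FALSE], Z[, s:e2, drop = FALSE]) /
        (n - 1)
      for (d in seq_len(L)) {
        j <- s:e
        j <- j[j + d <= e2]
        if (!length(j)) next
        band[j, d] <- B[cbind(j - s + 1, j + d - s + 1)]^2
      }
    }
    # zero out cross-chromosome or out-of-window pairs
    for (d in seq_len(L)) {
      i1 <- seq_len(m - d); i2 <- i1 + d
      bad <- chrom[i1] != chrom[i2] |
        abs(pos[i2] - pos[i1]) > window_kb * 1000
      band[i1[bad], d] <- 0
    }
  }
  structure(list(band = band, maxlag = maxlag), class = "ld_band")
}

ld_band_r2 <- function(ld, j, k) {
  d <- abs(j - k)
  if (d == 0) return(1)
  if (d > ld$maxlag) return(0)
  ld$band[min(j, k), d]
}

#' Incremental PRS R-squared (full minus reduced model)
#'
#' R2(phenotype ~ PRS + covariates) - R2(phenotype ~ covariates), with the
#' PRS coefficient and its t-test p-value taken from the full model.
#'
#' @param scores per-sample PRS (numeric)
#' @param phenotype response vector
#' @param covariates optional numeric matrix/data.frame of covariates
#' @return a \code{prs_fit} list: prs_r2, p_value, beta_prs, n
#' @export
prs_r2 <- function(scores, phenotype, covariates = NULL) {
  n <- length(phenotype)
  C <- cbind(rep(1, n))
  if (!is.null(covariates) && NCOL(covariates) > 0)
    C <- cbind(C, as.matrix(covariates))
  if (n <= ncol(C) + 1) stop("fewer samples than model parameters")
  if (anyNA(scores) || anyNA(phenotype) || anyNA(C))
    stop("complete cases required")
  qrC <- qr(C)
  ry <- qr.resid(qrC, phenotype)
  rg <- qr.resid(qrC, scores)
  tss <- sum((phenotype - mean(phenotype))^2)
  rss0 <- sum(ry^2)
  gg <- sum(rg^2)
  if (gg <= n * 1e-14) {
    fit <- list(prs_r2 = 0, p_value = 1, beta_prs = 0, n = n)
    class(fit) <- "prs_fit"
    return(fit)
  }
  b <- sum(rg * ry) / gg
  rss1 <- rss0 - b^2 * gg
  r2 <- (rss0 - rss1) / tss
  df <- n - ncol(C) - 1
  se <- sqrt(max(rss1, 0) / df / gg)
  pval <- if (se > 0) 2 * stats::pt(-abs(b / se), df) else 0
  fit <- list(prs_r2 = max(r2, 0), p_value = pval, beta_prs = b, n = n)
  class(fit) <- "prs_fit"
  fit
}

#' Clumping + p-value-threshold search for the best per-iteration PRS
#'
#' Clumps once, then for each threshold in the grid builds a model from the
#' clumped variants with p at or below the threshold (weights = betas),
#' scores the target dataset, and measures the incremental R-squared over
#' the covariates. Returns the best threshold's model and fit; ties are
#' resolved toward the stricter threshold (fewer SNPs).
#'
#' @param sumstats a \code{summary_stats} table (from the training split)
#' @param target_dataset dataset to score (the held-out split)
#' @param phenotype response vector for the target samples
#' @param covariates covariate matrix for the target samples
#' @param thresholds descending-inclusive p-value grid
#' @param r2_max,window_kb clumping parameters
#' @param ld optional precomputed \code{ld_band} for the LD source
#' @param ld_dataset dataset supplying LD for clumping (defaults to
#'   \code{target_dataset})
#' @return list: \code{model} (a \code{prs_model}), \code{fit}
#'   (a \code{prs_fit} with \code{n_snps} and \code{threshold} added)
#' @export
ct_search <- function(sumstats, target_dataset, phenotype, covariates = NULL,
                      thresholds = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01, 0.05,
                                     0.1, 0.5, 1),
                      r2_max = 0.1, window_kb = 250, ld = NULL,
                      ld_dataset = NULL) {
  ld_src <- ld_dataset %||% target_dataset
  kept <- clump(sumstats, ld_src, r2_max = r2_max, window_kb = window_kb,
                ld = ld)
  ss <- sumstats[match(kept, sumstats$id), , drop = FALSE]
  ss <- ss[order(ss$p, ss$id), , drop = FALSE]
  grid <- sort(thresholds)  # strictest first: ties keep fewer SNPs
  if (!any(ss$p <= max(grid)))
    stop("no clumped variant passes the loosest threshold")

  # nested thresholds: score every candidate in one cumulative pass over
  # the p-ordered clumped variants (constant shifts from allele switches
  # are absorbed by the intercept of the R-squared regression)
  vi <- match(ss$id, target_dataset$variants$id)
  G <- target_dataset$dosages[, vi, drop = FALSE]
  a1 <- target_dataset$variants$allele1[vi]
  a2 <- target_dataset$variants$allele2[vi]
  ea <- ss$effect_allele
  swit <- (ea == a2 | ea == dna_complement(a2)) &
    !(ea == a1 | ea == dna_complement(a1))
  G[, swit] <- 2 - G[, swit, drop = FALSE]
  G[is.na(G)] <- 0
  ks <- vapply(sort(thresholds), function(th) sum(ss$p <= th), integer(1))
  ks <- unique(ks[ks > 0])
  W <- vapply(ks, function(k) {
    w <- numeric(nrow(ss)); w[seq_len(k)] <- ss$beta[seq_len(k)]; w
  }, numeric(nrow(ss)))
  S <- G %*% W  # one score column per distinct threshold cut

  n <- length(phenotype)
  C <- cbind(rep(1, n))
  if (!is.null(covariates) && NCOL(covariates) > 0)
    C <- cbind(C, as.matrix(covariates))
  qrC <- qr(C)
  ry <- qr.resid(qrC, phenotype)
  tss <- sum((phenotype - mean(phenotype))^2)
  best <- NULL
  for (th in grid) {
    k <- sum(ss$p <= th)
    if (k == 0) next
    sc <- S[, match(k, ks)]
    rg <- qr.resid(qrC, sc)
    gg <- sum(rg^2)
    r2 <- if (gg <= n * 1e-14) 0 else max((sum(rg * ry))^2 / gg / tss, 0)
    if (is.null(best) || r2 > best$fit$prs_r2) {
      fit <- prs_r2(sc, phenotype, covariates)
      fit$n_snps <- k
      fit$threshold <- th
      model <- prs_model(ss$id[seq_len(k)], ss$effect_allele[seq_len(k)],
                         ss$beta[seq_len(k)], threshold = th,
                         engine = attr(sumstats, "engine") %||% NA_character_)
      best <- list(model = model, fit = fit)
    }
  }
  best
}
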