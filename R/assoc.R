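# Per-variant association summary statistics for a quantitative phenotype,
# with covariate (and principal-component) adjustment. Two mathematically
# distinct engines sit behind one interface:
#   wald_ols   - OLS of phenotype on [dosage, covariates]; beta/SE/p from
#                the t-test on the dosage coefficient,
#   score_test - 1-df score test of the dosage residualized against the
#                covariates under the covariate-only null model.
# Externally produced summary statistics can be supplied as a further
# "engine" through precomputed_engine().

.engines <- c("wald_ols", "score_test")

#' Covariate-adjusted per-variant summary statistics
#'
#' Both engines project phenotype and dosages onto the orthogonal
#' complement of the covariate space (intercept always included), which for
#' \code{wald_ols} is numerically identical to the full multiple regression
#' (Frisch-Waugh). Variants that are monomorphic or collinear with the
#' covariates are skipped. Per-variant missing dosages are handled by
#' casewise deletion.
#'
#' @param dataset a \code{genotype_dataset} with a phenotype table
#' @param phenotype_name column of the phenotype table to use as response
#' @param covariates character vector of covariate columns (may be empty)
#' @param pcs optional numeric matrix of principal-component scores
#'   (rows aligned with samples) appended to the covariates
#' @param engine \code{"wald_ols"} or \code{"score_test"}
#' @param sample_idx optional integer subset of samples to use (e.g. a
#'   training split)
#' @return a \code{summary_stats} data.frame: id, chrom, pos,
#'   effect_allele, other_allele, beta, se, p, n; engine, covariates and
#'   PC count recorded as attributes
#' @export
summary_stats <- function(dataset, phenotype_name = "phenotype",
                          covariates = c("sex", "age", "status1", "status2"),
                          pcs = NULL, engine = "wald_ols",
                          sample_idx = NULL) {
  if (!engine %in% .engines)
    stop("unknown engine '", engine, "'; available: ",
         paste(.engines, collapse = ", "))
  if (is.null(dataset$pheno)) stop("dataset has no phenotype table")
  si <- sample_idx %||% seq_len(n_samples(dataset))
  y <- dataset$pheno[[phenotype_name]][si]
  if (is.null(y)) stop("phenotype column '", phenotype_name, "' not found")
  C <- cbind(`(Intercept)` = rep(1, length(si)))
  if (length(covariates))
    C <- cbind(C, as.matrix(dataset$pheno[si, covariates, drop = FALSE]))
  if (!is.null(pcs))
    C <- cbind(C, as.matrix(pcs)[si, , drop = FALSE])
  if (anyNA(y) || anyNA(C))
    stop("phenotype and covariates must be complete")
  G <- dataset$dosages[si, , drop = FALSE]
  n <- length(y); q <- ncol(C)

  qrC <- qr(C)
  ry <- qr.resid(qrC, y)
  beta <- se <- p <- rep(NA_real_, ncol(G))
  nused <- rep(n, ncol(G))
  complete <- !anyNA(G)
  if (complete) {
    RG <- qr.resid(qrC, G)
    gg <- colSums(RG^2)
    gy <- colSums(RG * ry)
    ok <- gg > n * 1e-12
    if (engine == "wald_ols") {
      df <- n - q - 1
      b <- gy / gg
      rss <- sum(ry^2) - b^2 * gg
      s2 <- rss / df
      beta[ok] <- b[ok]
      se[ok] <- sqrt(s2[ok] / gg[ok])
      tval <- beta[ok] / se[ok]
      p[ok] <- 2 * stats::pt(-abs(tval), df)
    } else {
      sigma0 <- sum(ry^2) / n
      stat <- gy^2 / (sigma0 * gg)
      beta[ok] <- gy[ok] / gg[ok]
      se[ok] <- abs(beta[ok]) / sqrt(pmax(stat[ok], 1e-300))
      p[ok] <- stats::pchisq(stat[ok], df = 1, lower.tail = FALSE)
    }
  } else {
    for (j in seq_len(ncol(G))) {
      g <- G[, j]
      use <- !is.na(g)
      nused[j] <- sum(use)
      if (nused[j] <= q + 1) next
      qrCj <- qr(C[use, , drop = FALSE])
      ryj <- qr.resid(qrCj, y[use])
      rg <- qr.resid(qrCj, g[use])
      gg <- sum(rg^2)
      if (gg <= nused[j] * 1e-12) next
      gy <- sum(rg * ryj)
      if (engine == "wald_ols") {
        df <- nused[j] - q - 1
        b <- gy / gg
        rss <- sum(ryj^2) - b^2 * gg
        beta[j] <- b
        se[j] <- sqrt(rss / df / gg)
        p[j] <- 2 * stats::pt(-abs(b / se[j]), df)
      } else {
        sigma0 <- sum(ryj^2) / nused[j]
        stat <- gy^2 / (sigma0 * gg)
        beta[j] <- gy / gg
        se[j] <- abs(beta[j]) / sqrt(max(stat, 1e-300))
        p[j] <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
      }
    }
  }
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  out <- data.frame(id = dataset$variants$id, chrom = dataset$variants$chrom,
                    pos = dataset$variants$pos,
                    effect_allele = dataset$variants$allele1,
                    other_allele = dataset$variants$allele2,
                    beta = beta, se = se, p = p, n = nused,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$beta), , drop = FALSE]
  attr(out, "engine") <- engine
  attr(out, "covariates") <- covariates
  attr(out, "n_pcs") <- if (is.null(pcs)) 0L else ncol(as.matrix(pcs))
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Read an externally produced summary-statistics table
#'
#' Allows real GWAS tooling to act as an additional association engine:
#' the TSV must carry the columns id, chrom, pos, effect_allele,
#' other_allele, beta, se, p, n. The result can be passed to
#' \code{ct_search} like an internally computed table.
#'
#' @param path TSV file
#' @param engine label recorded for provenance
#' @return a \code{summary_stats} data.frame
#' @export
read_sumstats <- function(path, engine = "external") {
  out <- read_table(path, required = c("id", "chrom", "pos",
                                       "effect_allele", "other_allele",
                                       "beta", "se", "p", "n"))
  if (any(out$p <= 0 | out$p > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  attr(out, "engine") <- engine
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Rank association engines by mean PRS R-squared
#'
#' Emulates the comparative engine-selection step: each engine's
#' per-iteration PRS R-squared values are averaged and the engine with the
#' highest mean is selected. Ties are broken by the declared engine order.
#'
#' @param per_engine_r2 named list of equal-length numeric vectors, one per
#'   engine, in declared priority order
#' @return data.frame (engine, mean_r2, sd_r2, p_min, p_median, p_max if
#'   p-values supplied) ordered as declared, with attribute
#'   \code{selected} = the winning engine name
#' @export
compare_engines <- function(per_engine_r2) {
  if (!length(per_engine_r2)) stop("no engine results supplied")
  len <- unique(vapply(per_engine_r2, length, integer(1)))
  if (length(len) != 1 || len == 0)
    stop("engines must have equal, nonempty R-squared lists")
  tab <- data.frame(engine = names(per_engine_r2),
                    mean_r2 = vapply(per_engine_r2, mean, numeric(1)),
                    sd_r2 = vapply(per_engine_r2, stats::sd, numeric(1)),
                    stringsAsFactors = FALSE)
  best <- which.max(tab$mean_r2)  # which.max takes the first maximum: ties
  attr(tab, "selected") <- tab$engine[best]  # resolve by declared order
  tab
}
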