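# The iterative-aggregation PRS pipeline: repeated train/test derivation,
# SNP-frequency aggregation, size-penalized model selection, empirical
# bootstrap significance, and leave-out evaluation.

#' Run repeated train/test PRS derivation iterations
#'
#' Each iteration splits the samples 80/20 (configurable), derives
#' covariate-adjusted summary statistics on the training split with every
#' requested engine, and runs a clumping + p-value-threshold search scored
#' on the held-out split. The per-iteration incremental R-squared values of
#' each engine form that engine's baseline distribution; the engine with
#' the highest mean is selected for aggregation.
#'
#' Principal components enter the association and evaluation models as
#' additional covariates. By default they are computed once on the full
#' dataset (\code{pca_mode = "global"}); \code{"per_split"} recomputes them
#' on each training split (and on the test split for its evaluation
#' regression), at a substantial computational cost.
#'
#' @param dataset a complete, QC'd \code{genotype_dataset} with phenotype
#'   table
#' @param phenotype_name response column
#' @param covariates covariate columns used in every regression
#' @param n_iter number of train/test iterations
#' @param train_frac fraction of samples in the training split
#' @param engines character vector of association engines to compare
#' @param master_seed integer; all splits derive from it
#' @param pca_mode \code{"global"} or \code{"per_split"}
#' @param max_pcs,tw_alpha PCA/Tracy-Widom parameters
#' @param thresholds p-value grid for the threshold search
#' @param r2_max,window_kb clumping parameters
#' @return a \code{prs_iterations} object
#' @export
run_iterations <- function(dataset, phenotype_name = "phenotype",
                           covariates = c("sex", "age", "status1", "status2"),
                           n_iter = 100, train_frac = 0.8,
                           engines = c("wald_ols", "score_test"),
                           master_seed = 1L,
                           pca_mode = c("global", "per_split"),
                           max_pcs = 20, tw_alpha = 0.05,
                           thresholds = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01,
                                          0.05, 0.1, 0.5, 1),
                           r2_max = 0.1, window_kb = 250) {
  pca_mode <- match.arg(pca_mode)
  if (anyNA(dataset$dosages))
    stop("dataset must be complete (impute before running iterations)")
  n <- n_samples(dataset)
  n_train <- round(train_frac * n)
  if (n_train < 10 || n - n_train < 10)
    stop("dataset too small for a ", train_frac, " train split")
  ld <- ld_band(dataset, window_kb = window_kb)
  pcs_global <- NULL
  if (pca_mode == "global") {
    pr <- select_pcs(dataset, max_pcs = max_pcs, alpha = tw_alpha)
    pcs_global <- pr$selected_scores
    if (pr$n_selected == 0) pcs_global <- NULL
  }
  covmat <- as.matrix(dataset$pheno[, covariates, drop = FALSE])

  results <- vector("list", n_iter)
  baselines <- stats::setNames(
    replicate(length(engines), numeric(n_iter), simplify = FALSE), engines)
  for (it in seq_len(n_iter)) {
    tr <- with_seed(substream_seed(master_seed, paste0("split", it)),
                    sort(sample.int(n, n_train)))
    te <- setdiff(seq_len(n), tr)
    target <- subset_dataset(dataset, samples = te)
    if (pca_mode == "global") {
      pcs_tr <- pcs_global
      pcs_te <- if (is.null(pcs_global)) NULL
                else pcs_global[te, , drop = FALSE]
    } else {
      ptr <- select_pcs(subset_dataset(dataset, samples = tr),
                        max_pcs = max_pcs, alpha = tw_alpha)
      pte <- select_pcs(target, max_pcs = max_pcs, alpha = tw_alpha)
      pcs_tr <- matrix(0, n, max(ptr$n_selected, 1))
      pcs_tr[tr, ] <- ptr$selected_scores
      if (ptr$n_selected == 0) pcs_tr <- NULL
      pcs_te <- if (pte$n_selected == 0) NULL else pte$selected_scores
    }
    cov_te <- covmat[te, , drop = FALSE]
    if (!is.null(pcs_te)) cov_te <- cbind(cov_te, pcs_te)
    y_te <- dataset$pheno[[phenotype_name]][te]

    per_engine <- list()
    for (eng in engines) {
      ss <- summary_stats(dataset, phenotype_name = phenotype_name,
                          covariates = covariates, pcs = pcs_tr,
                          engine = eng, sample_idx = tr)
      hit <- ct_search(ss, target, y_te, cov_te, thresholds = thresholds,
                       r2_max = r2_max, window_kb = window_kb,
                       ld = ld, ld_dataset = dataset)
      per_engine[[eng]] <- hit
      baselines[[eng]][it] <- hit$fit$prs_r2
    }
    results[[it]] <- list(iteration = it, train_idx = tr, test_idx = te,
                          per_engine = per_engine)
  }
  tab <- compare_engines(baselines)
  structure(list(results = results, baselines = baselines,
                 engine_table = tab, engine = attr(tab, "selected"),
                 phenotype_name = phenotype_name, covariates = covariates,
                 pcs = pcs_global, pca_mode = pca_mode,
                 master_seed = master_seed, n_iter = n_iter,
                 train_frac = train_frac, ld_window_kb = window_kb),
            class = "prs_iterations")
}

#' @export
print.prs_iterations <- function(x, ...) {
  cat("prs_iterations:", x$n_iter, "iterations, engines:",
      paste(names(x$baselines), collapse = ", "), "\n")
  tb <- x$engine_table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %s: mean PRS R2 = %.4f (sd %.4f)%s\n", tb$engine[i],
                tb$mean_r2[i], tb$sd_r2[i],
                if (tb$engine[i] == x$engine) "  <- selected" else ""))
  invisible(x)
}

#' Aggregate selected SNPs across iterations
#'
#' Counts, for one engine, how often each variant appears in the
#' per-iteration selected models, keeping variants appearing at least
#' \code{min_freq} times; the aggregated weight is the arithmetic mean of
#' the variant's beta over the iterations where it appears.
#'
#' @param iterations a \code{prs_iterations} object (or its results list)
#' @param engine engine whose models to aggregate; defaults to the selected
#'   engine
#' @param min_freq minimum appearance count
#' @return data.frame (id, effect_allele, count, beta), ordered by
#'   decreasing count then id
#' @export
aggregate_snps <- function(iterations, engine = NULL, min_freq = 5) {
  results <- if (inherits(iterations, "prs_iterations")) iterations$results
             else iterations
  engine <- engine %||%
    (if (inherits(iterations, "prs_iterations")) iterations$engine
     else names(results[[1]]$per_engine)[1])
  models <- lapply(results, function(r) r$per_engine[[engine]]$model)
  if (!length(models) || all(vapply(models, is.null, logical(1))))
    stop("no selected models for engine ", engine)
  ids <- unlist(lapply(models, `[[`, "id"))
  if (!length(ids)) stop("all selected SNP sets are empty")
  betas <- unlist(lapply(models, `[[`, "weight"))
  eas <- unlist(lapply(models, `[[`, "effect_allele"))
  agg <- stats::aggregate(betas, by = list(id = ids), FUN = mean)
  cnt <- table(ids)
  agg$count <- as.integer(cnt[agg$id])
  agg$effect_allele <- eas[match(agg$id, ids)]
  agg <- agg[agg$count >= min_freq,
             c("id", "effect_allele", "count", "x"), drop = FALSE]
  names(agg)[4] <- "beta"
  agg <- agg[order(-agg$count, agg$id), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "engine") <- engine
  attr(agg, "min_freq") <- min_freq
  agg
}

#' Evaluate one candidate PRS per observed appearance frequency
#'
#' For each distinct appearance count f (at or above the aggregation
#' minimum), assembles the PRS of all variants appearing at least f times
#' (weights = mean betas) and evaluates its incremental R-squared on every
#' stored test split. Candidates are nested: higher frequency thresholds
#' give subsets. Reports mean and sd of R-squared across splits, the
#' size-penalized R-squared, and the empirical bootstrap p-value against
#' the selected engine's baseline distribution.
#'
#' @param freq_table output of \code{aggregate_snps}
#' @param dataset the full \code{genotype_dataset}
#' @param iterations the \code{prs_iterations} the splits came from
#' @param log_base base of the logarithm in the size penalty
#' @return data.frame (freq_threshold, n_snps, mean_r2, sd_r2,
#'   penalized_r2, boot_p), ordered by increasing n_snps, with the
#'   per-candidate \code{prs_model}s attached as attribute \code{models}
#' @export
candidate_scan <- function(freq_table, dataset, iterations,
                           log_base = exp(1)) {
  if (!nrow(freq_table)) stop("empty frequency table")
  freqs <- sort(unique(freq_table$count), decreasing = TRUE)
  # freq_table is ordered by decreasing count: candidate f = leading rows
  ord <- order(-freq_table$count, freq_table$id)
  ft <- freq_table[ord, , drop = FALSE]
  vi <- match(ft$id, dataset$variants$id)
  if (anyNA(vi)) stop("aggregated variants missing from dataset")
  cuts <- vapply(freqs, function(f) sum(ft$count >= f), integer(1))

  covariates <- iterations$covariates
  pheno <- dataset$pheno[[iterations$phenotype_name]]
  covmat <- as.matrix(dataset$pheno[, covariates, drop = FALSE])
  if (!is.null(iterations$pcs)) covmat <- cbind(covmat, iterations$pcs)
  baseline <- iterations$baselines[[iterations$engine]]

  r2_mat <- matrix(NA_real_, nrow = length(freqs),
                   ncol = length(iterations$results))
  W <- vapply(cuts, function(k) {
    w <- numeric(nrow(ft)); w[seq_len(k)] <- ft$beta[seq_len(k)]; w
  }, numeric(nrow(ft)))
  for (t in seq_along(iterations$results)) {
    te <- iterations$results[[t]]$test_idx
    S <- dataset$dosages[te, vi, drop = FALSE] %*% W
    C <- cbind(1, covmat[te, , drop = FALSE])
    qrC <- qr(C)
    y <- pheno[te]
    ry <- qr.resid(qrC, y)
    tss <- sum((y - mean(y))^2)
    RS <- qr.resid(qrC, S)
    for (ci in seq_along(freqs)) {
      rg <- RS[, ci]
      gg <- sum(rg^2)
      r2_mat[ci, t] <- if (gg <= length(te) * 1e-14) 0 else
        max((sum(rg * ry))^2 / gg / tss, 0)
    }
  }
  mean_r2 <- rowMeans(r2_mat)
  sd_r2 <- apply(r2_mat, 1, stats::sd)
  n_snps <- cuts
  pen <- ifelse(n_snps >= 2,
                mean_r2 / (log(n_snps) / log(log_base)), NA_real_)
  boot <- vapply(mean_r2, function(r) bootstrap_p(baseline, r), numeric(1))
  out <- data.frame(freq_threshold = freqs, n_snps = n_snps,
                    mean_r2 = mean_r2, sd_r2 = sd_r2, penalized_r2 = pen,
                    boot_p = boot)
  o <- order(out$n_snps)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  models <- lapply(out$freq_threshold, function(f) {
    sel <- seq_len(sum(ft$count >= f))
    prs_model(ft$id[sel], ft$effect_allele[sel], ft$beta[sel],
              engine = iterations$engine)
  })
  attr(out, "models") <- models
  attr(out, "log_base") <- log_base
  class(out) <- c("candidate_scan", "data.frame")
  out
}

#' Size-penalized PRS R-squared
#'
#' @param r2 incremental R-squared of a candidate PRS
#' @param n_snps number of SNPs in the candidate (>= 2)
#' @param log_base base of the logarithm (default natural)
#' @return r2 / log_base(n_snps)
#' @export
penalize <- function(r2, n_snps, log_base = exp(1)) {
  if (any(n_snps < 2)) stop("n_snps must be >= 2 (log must be positive)")
  r2 / (log(n_snps) / log(log_base))
}

#' Local maxima of a candidate sequence
#'
#' Applied to penalized R-squared values ordered by n_snps: an element
#' qualifies when it is >= each existing neighbour; among runs of equal
#' values (plateaus) only the first index is kept. Candidates with
#' undefined penalty (n_snps < 2) are ineligible.
#'
#' @param values numeric vector (NA = ineligible)
#' @return integer indices of local maxima
#' @export
find_local_maxima <- function(values) {
  n <- length(values)
  if (n == 0) stop("need at least one candidate")
  if (n == 1) return(if (is.na(values)) integer(0) else 1L)
  ok <- !is.na(values)
  v <- values
  qual <- vapply(seq_len(n), function(i) {
    if (!ok[i]) return(FALSE)
    leftok <- i == 1 || !ok[i - 1] || v[i] >= v[i - 1]
    rightok <- i == n || !ok[i + 1] || v[i] >= v[i + 1]
    leftok && rightok
  }, logical(1))
  first_of_run <- c(TRUE, v[-1] != v[-n] | !ok[-n])
  which(qual & first_of_run)
}

#' Select the final PRS among scan candidates
#'
#' The winner is the local maximum of the penalized R-squared with the
#' highest value; ties resolve toward fewer SNPs.
#'
#' @param candidates a \code{candidate_scan} result
#' @return list: \code{model} (the winning \code{prs_model}),
#'   \code{candidate} (its scan row), \code{maxima_idx}
#' @export
select_final <- function(candidates) {
  if (!nrow(candidates)) stop("no candidates")
  lm_idx <- find_local_maxima(candidates$penalized_r2)
  if (!length(lm_idx)) lm_idx <- which(!is.na(candidates$penalized_r2))
  if (!length(lm_idx)) stop("no candidate with a defined penalized R-squared")
  sub <- candidates[lm_idx, , drop = FALSE]
  best_val <- max(sub$penalized_r2)
  tied <- lm_idx[sub$penalized_r2 == best_val]
  pick <- tied[which.min(candidates$n_snps[tied])]
  list(model = attr(candidates, "models")[[pick]],
       candidate = candidates[pick, , drop = FALSE],
       maxima_idx = lm_idx)
}

#' Empirical bootstrap p-value of an aggregated PRS
#'
#' The fraction of baseline per-iteration R-squared values strictly greater
#' than the aggregated PRS R-squared.
#'
#' @param baseline numeric vector of per-iteration baseline R-squared values
#' @param aggregated_r2 the aggregated candidate's (mean) R-squared
#' @return p-value in [0, 1]
#' @export
bootstrap_p <- function(baseline, aggregated_r2) {
  if (!length(baseline)) stop("empty baseline distribution")
  sum(baseline > aggregated_r2) / length(baseline)
}

#' Leave-out evaluation of a final PRS
#'
#' For each left-out fraction, repeats \code{reps_per_frac} random
#' holdouts: the full (covariates + PRS) and reduced (covariates only)
#' models are fitted on the retained samples and the incremental R-squared
#' recorded. Also reports the whole-dataset fit, and supports evaluating
#' an alternative phenotype column.
#'
#' @param dataset a complete \code{genotype_dataset}
#' @param model a \code{prs_model}
#' @param phenotype_name response column (e.g. the primary phenotype or an
#'   alternative such as raw weight)
#' @param covariates covariate columns
#' @param pcs optional PC score matrix used as extra covariates
#' @param leftout_fracs fractions in (0, 0.5]
#' @param reps_per_frac holdout repetitions per fraction
#' @param seed integer seed
#' @return list: \code{table} (frac, mean_r2, sd_r2, median_p),
#'   \code{whole_fit} (a \code{prs_fit} on all samples)
#' @export
evaluate_final <- function(dataset, model, phenotype_name = "phenotype",
                           covariates = c("sex", "age", "status1", "status2"),
                           pcs = NULL,
                           leftout_fracs = seq(0.05, 0.50, by = 0.05),
                           reps_per_frac = 10, seed = 1L) {
  if (!nrow(model)) stop("empty model")
  if (any(leftout_fracs <= 0 | leftout_fracs > 0.5))
    stop("left-out fractions must lie in (0, 0.5]")
  y <- dataset$pheno[[phenotype_name]]
  if (is.null(y)) stop("phenotype column '", phenotype_name, "' not found")
  covmat <- as.matrix(dataset$pheno[, covariates, drop = FALSE])
  if (!is.null(pcs)) covmat <- cbind(covmat, as.matrix(pcs))
  scores <- compute_prs(dataset, model)
  n <- n_samples(dataset)
  rows <- lapply(seq_along(leftout_fracs), function(fi) {
    frac <- leftout_fracs[fi]
    r2s <- ps <- numeric(reps_per_frac)
    for (r in seq_len(reps_per_frac)) {
      out_idx <- with_seed(
        substream_seed(seed, sprintf("holdout_%d_%d", fi, r)),
        sample.int(n, round(frac * n)))
      keep <- setdiff(seq_len(n), out_idx)
      fit <- prs_r2(scores[keep], y[keep], covmat[keep, , drop = FALSE])
      r2s[r] <- fit$prs_r2; ps[r] <- fit$p_value
    }
    data.frame(leftout_frac = frac, mean_r2 = mean(r2s),
               sd_r2 = stats::sd(r2s), median_p = stats::median(ps))
  })
  list(table = do.call(rbind, rows),
       whole_fit = prs_r2(scores, y, covmat))
}
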