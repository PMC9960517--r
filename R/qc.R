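# Variant and sample quality control.
#
# Default thresholds: INFO >= 0.9, SNP call rate >= 95%, MAF >= 5%,
# sample call rate >= 90%, and an exact Hardy-Weinberg test at p >= 1e-9
# applied as a second pass on the variants surviving the first. The HWE
# filter uses an exact enumeration test rather than the chi-square
# approximation because a 1e-9 tail is far outside the chi-square's
# reliable range.

#' Exact two-sided Hardy-Weinberg equilibrium test
#'
#' Conditional on the observed allele counts, the number of heterozygotes
#' under HWE follows a hypergeometric-type distribution over heterozygote
#' counts of the same parity. The two-sided p-value sums the probabilities
#' of all heterozygote counts whose probability does not exceed that of the
#' observed count (Wigginton-style enumeration).
#'
#' @param n_hom1 count of homozygotes for allele 1
#' @param n_het count of heterozygotes
#' @param n_hom2 count of homozygotes for allele 2
#' @return p-value in (0, 1]
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  if (any(c(n_hom1, n_het, n_hom2) < 0)) stop("genotype counts must be >= 0")
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) stop("all genotype counts are zero")
  n1 <- 2 * n_hom1 + n_het           # copies of allele 1
  n2 <- 2 * n_hom2 + n_het
  rare <- min(n1, n2)
  if (rare == 0) return(1)           # monomorphic: single configuration
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(het = h | allele counts) up to a constant:
  # P(h) proportional to n! / (h1! h! h2!) * 2^h with h1=(n1-h)/2, h2=(n2-h)/2
  logp <- vapply(hets, function(h) {
    h1 <- (n1 - h) / 2; h2 <- (n2 - h) / 2
    h * log(2) - lgamma(h + 1) - lgamma(h1 + 1) - lgamma(h2 + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  if (is.na(obs)) stop("heterozygote count incompatible with allele counts")
  sum(p[p <= obs * (1 + 1e-12)])
}

#' Per-variant call rate, minor allele frequency and HWE p-value
#' @param dataset a \code{genotype_dataset}
#' @return data.frame: id, call_rate, maf, hwe_p
#' @export
variant_summary <- function(dataset) {
  dos <- dataset$dosages
  n <- nrow(dos)
  nobs <- colSums(!is.na(dos))
  call_rate <- nobs / n
  af <- colSums(dos, na.rm = TRUE) / (2 * pmax(nobs, 1))
  maf <- pmin(af, 1 - af)
  hwe <- vapply(seq_len(ncol(dos)), function(j) {
    g <- dos[, j]
    if (all(is.na(g))) return(NA_real_)
    hwe_exact_p(sum(g == 2, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                sum(g == 0, na.rm = TRUE))
  }, numeric(1))
  data.frame(id = dataset$variants$id, call_rate = call_rate, maf = maf,
             hwe_p = hwe, stringsAsFactors = FALSE)
}

#' Variant-level filtering
#'
#' Drops variants failing any of: imputation INFO score below
#' \code{info_min} (skipped when the dataset carries no INFO scores), call
#' rate below \code{call_min}, minor allele frequency below \code{maf_min}
#' (computed from non-missing calls), and - in a second pass over the
#' survivors - exact HWE p-value below \code{hwe_min}.
#'
#' @param dataset a \code{genotype_dataset}
#' @param info_min,call_min,maf_min,hwe_min thresholds in [0, 1]
#' @return list: \code{dataset} (filtered), \code{report} (a
#'   \code{qc_report} with per-filter removal counts)
#' @export
filter_variants <- function(dataset, info_min = 0.9, call_min = 0.95,
                            maf_min = 0.05, hwe_min = 1e-9) {
  thr <- c(info_min, call_min, maf_min, hwe_min)
  if (any(thr < 0) || any(thr > 1)) stop("thresholds must be in [0, 1]")
  vs <- variant_summary(dataset)
  fail_info <- if (is.null(dataset$info)) rep(FALSE, n_variants(dataset))
               else dataset$info < info_min
  fail_call <- vs$call_rate < call_min
  fail_maf <- vs$maf < maf_min
  pass1 <- !(fail_info | fail_call | fail_maf)
  # HWE applied as a second round on the survivors of the first pass
  fail_hwe <- rep(FALSE, n_variants(dataset))
  fail_hwe[pass1] <- !is.na(vs$hwe_p[pass1]) & vs$hwe_p[pass1] < hwe_min
  keep <- pass1 & !fail_hwe
  report <- structure(list(
    axis = "variants",
    n_in = n_variants(dataset), n_out = sum(keep),
    removed = c(info = sum(fail_info), call_rate = sum(fail_call & !fail_info),
                maf = sum(fail_maf & !fail_call & !fail_info),
                hwe = sum(fail_hwe)),
    thresholds = c(info_min = info_min, call_min = call_min,
                   maf_min = maf_min, hwe_min = hwe_min)),
    class = "qc_report")
  list(dataset = subset_dataset(dataset, variants = which(keep)),
       report = report)
}

#' Sample-level filtering by call rate
#'
#' @param dataset a \code{genotype_dataset}
#' @param call_min minimum sample call rate in [0, 1]
#' @return list: \code{dataset}, \code{report}
#' @export
filter_samples <- function(dataset, call_min = 0.90) {
  if (call_min < 0 || call_min > 1) stop("thresholds must be in [0, 1]")
  cr <- rowMeans(!is.na(dataset$dosages))
  keep <- cr >= call_min
  report <- structure(list(
    axis = "samples", n_in = n_samples(dataset), n_out = sum(keep),
    removed = c(call_rate = sum(!keep)),
    thresholds = c(call_min = call_min)), class = "qc_report")
  list(dataset = subset_dataset(dataset, samples = which(keep)),
       report = report)
}

#' Drop samples with incomplete required covariates
#'
#' @param dataset a \code{genotype_dataset} with a phenotype table
#' @param required character vector of covariate column names
#' @return list: \code{dataset}, \code{report}
#' @export
drop_incomplete_covariates <- function(dataset,
                                       required = c("phenotype", "sex", "age",
                                                    "status1", "status2")) {
  if (is.null(dataset$pheno)) stop("dataset has no phenotype table")
  miss <- setdiff(required, names(dataset$pheno))
  if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(dataset$pheno[, required, drop = FALSE])
  report <- structure(list(
    axis = "samples", n_in = n_samples(dataset), n_out = sum(keep),
    removed = c(incomplete_covariates = sum(!keep)),
    thresholds = c()), class = "qc_report")
  list(dataset = subset_dataset(dataset, samples = which(keep)),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC (", x$axis, "): ", x$n_in, " in -> ", x$n_out, " out\n", sep = "")
  for (nm in names(x$removed))
    cat("  removed by ", nm, ": ", x$removed[[nm]], "\n", sep = "")
  invisible(x)
}
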