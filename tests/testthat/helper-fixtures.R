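# Shared fixture builders. Everything is generated in code; no stored data.

# tiny hand-specified dataset: explicit dosages, alleles, phenotype
tiny_dataset <- function(dosages, alleles = NULL, pheno = NULL,
                         chrom = "1", pos_step = 1000L) {
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(alleles))
    alleles <- matrix(rep(c("A", "G"), m), ncol = 2, byrow = TRUE)
  variants <- data.frame(id = sprintf("v%02d", seq_len(m)),
                         chrom = chrom, pos = seq_len(m) * pos_step,
                         allele1 = alleles[, 1], allele2 = alleles[, 2],
                         stringsAsFactors = FALSE)
  ids <- sprintf("s%02d", seq_len(n))
  if (!is.null(pheno)) pheno <- cbind(sample_id = ids, pheno)
  genotype_dataset(dosages, variants, ids, pheno = pheno)
}

# small simulated cohort for integration-style tests
small_cohort <- function(n = 300, m = 400, n_causal = 15, h2 = 0.3,
                         seed = 42, ...) {
  simulate_cohort(cohort_spec(n_samples = n, n_snps = m,
                              n_causal = min(n_causal, m %/% 2),
                              heritability = h2, seed = seed, ...))
}

# independent brute-force HWE enumeration (oracle): walks every possible
# heterozygote count explicitly with exact rational-free probabilities
hwe_enum_oracle <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n1 <- 2 * n_hom1 + n_het
  n2 <- 2 * n_hom2 + n_het
  rare <- min(n1, n2)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- sapply(hets, function(h) {
    h1 <- (n1 - h) / 2; h2 <- (n2 - h) / 2
    exp(lfactorial(n) - lfactorial(h1) - lfactorial(h) - lfactorial(h2) +
          h * log(2) +
          lfactorial(n1) + lfactorial(n2) - lfactorial(2 * n))
  })
  probs <- probs / sum(probs)  # guard rounding
  obs <- probs[hets == n_het]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# literal-rule clumping oracle: no shared code with clump()
clump_oracle <- function(sumstats, dataset, r2_max = 0.1, window_kb = 250) {
  ss <- sumstats[order(sumstats$p, sumstats$id), ]
  kept <- character(0)
  for (i in seq_len(nrow(ss))) {
    v <- ss$id[i]
    j <- match(v, dataset$variants$id)
    ok <- TRUE
    for (k in kept) {
      kj <- match(k, dataset$variants$id)
      if (dataset$variants$chrom[kj] != dataset$variants$chrom[j]) next
      if (abs(dataset$variants$pos[kj] - dataset$variants$pos[j]) >
          window_kb * 1000) next
      r <- suppressWarnings(cor(dataset$dosages[, j], dataset$dosages[, kj]))
      if (!is.na(r) && r^2 > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, v)
  }
  kept
}

# two-lm() nested-model oracle for the incremental R-squared
prs_r2_oracle <- function(scores, phenotype, covariates = NULL) {
  if (is.null(covariates)) {
    full <- lm(phenotype ~ scores)
    red <- lm(phenotype ~ 1)
  } else {
    covariates <- as.data.frame(covariates)
    full <- lm(phenotype ~ ., data = cbind(covariates, scores = scores))
    red <- lm(phenotype ~ ., data = covariates)
  }
  summary(full)$r.squared - summary(red)$r.squared
}

# literal neighbour-scan local-maxima oracle
local_maxima_oracle <- function(v) {
  n <- length(v)
  qual <- logical(n)
  for (i in seq_len(n)) {
    if (is.na(v[i])) next
    lo <- if (i > 1 && !is.na(v[i - 1])) v[i] >= v[i - 1] else TRUE
    hi <- if (i < n && !is.na(v[i + 1])) v[i] >= v[i + 1] else TRUE
    qual[i] <- lo && hi
  }
  keep <- logical(n)
  for (i in which(qual)) {
    keep[i] <- !(i > 1 && !is.na(v[i - 1]) && !is.na(v[i]) &&
                   v[i - 1] == v[i])
  }
  which(keep)
}
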