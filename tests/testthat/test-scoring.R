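test_that("raw PRS matches hand computation in every denominator mode", {
  dos <- matrix(c(2, 1, 0, 2), 2, 2)
  ds <- tiny_dataset(dos)
  w <- c(0.5, -1.0)
  m_none <- prs_model(c("v01", "v02"), c("A", "A"), w,
                      denominator_mode = "none")
  expect_equal(unname(compute_prs(ds, m_none)), c(1.0, -1.5))
  m_ac <- prs_model(c("v01", "v02"), c("A", "A"), w,
                    denominator_mode = "allele_count")
  expect_equal(unname(compute_prs(ds, m_ac)), c(0.25, -0.375))
  m_ns <- prs_model(c("v01", "v02"), c("A", "A"), w,
                    denominator_mode = "n_samples_literal")
  expect_equal(unname(compute_prs(ds, m_ns)), c(0.5, -0.75))
  zero <- prs_model(c("v01", "v02"), c("A", "A"), c(0, 0),
                    denominator_mode = "none")
  expect_equal(unname(compute_prs(ds, zero)), c(0, 0))
})

test_that("effect alleles reconcile via switch and strand complement", {
  dos <- matrix(c(2, 1, 0, 2), 2, 2)
  ds <- tiny_dataset(dos)  # all variants A/G
  # effect allele G = dataset allele2 -> dosage switches to 2 - d
  m_sw <- prs_model(c("v01", "v02"), c("G", "G"), c(0.5, -1.0),
                    denominator_mode = "none")
  expect_equal(unname(compute_prs(ds, m_sw)),
               c(0.5 * 0 - 1.0 * 2, 0.5 * 1 - 1.0 * 0))
  # complemented strand representation of the effect allele (T ~ A)
  m_fl <- prs_model(c("v01", "v02"), c("T", "T"), c(0.5, -1.0),
                    denominator_mode = "none")
  expect_equal(unname(compute_prs(ds, m_fl)), c(1.0, -1.5))
  # absent and irreconcilable variants are skipped with warnings
  m_abs <- prs_model(c("v01", "nope"), c("A", "A"), c(0.5, 1),
                     denominator_mode = "none")
  expect_warning(sc <- compute_prs(ds, m_abs), "absent")
  expect_equal(unname(sc), c(1, 0.5))
  expect_error(suppressWarnings(
    compute_prs(ds, prs_model("zzz", "A", 1))), "overlap")
})

test_that("PRS is linear in weights (mode none)", {
  sim <- small_cohort(n = 40, m = 25, seed = 15, missing_rate = 0)
  ds <- sim$dataset
  ids <- ds$variants$id[1:10]
  ea <- ds$variants$allele1[1:10]
  set.seed(3)
  w1 <- rnorm(10); w2 <- rnorm(10)
  s1 <- compute_prs(ds, prs_model(ids, ea, w1, denominator_mode = "none"))
  s2 <- compute_prs(ds, prs_model(ids, ea, w2, denominator_mode = "none"))
  s12 <- compute_prs(ds, prs_model(ids, ea, w1 + w2,
                                   denominator_mode = "none"))
  expect_equal(s12, s1 + s2, tolerance = 1e-12)
})

test_that("allele-count scores are invariant to duplicating every sample", {
  sim <- small_cohort(n = 30, m = 20, seed = 25, missing_rate = 0)
  ds <- sim$dataset
  set.seed(9)
  model <- prs_model(ds$variants$id[1:8], ds$variants$allele1[1:8],
                     rnorm(8), denominator_mode = "allele_count")
  sc <- compute_prs(ds, model)
  dup <- genotype_dataset(rbind(ds$dosages, ds$dosages),
                          ds$variants,
                          c(ds$sample_ids, paste0("dup_", ds$sample_ids)))
  sc2 <- compute_prs(dup, model)
  expect_equal(unname(sc2), unname(c(sc, sc)), tolerance = 1e-12)
})

test_that("min-max normalization rescales to [0,1] preserving order", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(2)
  x <- rnorm(50)
  nx <- minmax_normalize(x)
  expect_equal(range(nx), c(0, 1))
  expect_equal(cor(x, nx, method = "spearman"), 1)
  # affine invariance
  expect_equal(minmax_normalize(3 * x + 7), nx, tolerance = 1e-12)
  expect_warning(cst <- minmax_normalize(rep(1, 4)), "constant")
  expect_equal(cst, rep(0.5, 4))
})

test_that("clumping keeps the stronger of two duplicate variants", {
  set.seed(5)
  g <- rbinom(80, 2, 0.4)
  dos <- cbind(g, g, rbinom(80, 2, 0.4))
  ds <- tiny_dataset(dos)
  ss <- data.frame(id = c("v01", "v02", "v03"), chrom = "1",
                   pos = ds$variants$pos, p = c(1e-4, 1e-8, 0.5),
                   stringsAsFactors = FALSE)
  kept <- clump(ss, ds)
  expect_true("v02" %in% kept)   # smaller p of the duplicate pair
  expect_false("v01" %in% kept)
  expect_true("v03" %in% kept)
})

test_that("variants on different chromosomes are never clumped together", {
  set.seed(6)
  g <- rbinom(60, 2, 0.4)
  ds <- tiny_dataset(cbind(g, g))
  ds$variants$chrom <- c("1", "2")
  ss <- data.frame(id = c("v01", "v02"), chrom = c("1", "2"),
                   pos = ds$variants$pos, p = c(1e-8, 1e-4))
  expect_setequal(clump(ss, ds), c("v01", "v02"))
})

test_that("greedy clumping matches the literal-rule oracle", {
  for (s in 1:4) {
    sim <- small_cohort(n = 150, m = 20, seed = 400 + s, ld_rho = 0.8,
                        missing_rate = 0)
    ds <- sim$dataset
    set.seed(500 + s)
    ss <- data.frame(id = ds$variants$id, chrom = ds$variants$chrom,
                     pos = ds$variants$pos, p = runif(20),
                     stringsAsFactors = FALSE)
    expect_identical(clump(ss, ds, r2_max = 0.1, window_kb = 250),
                     clump_oracle(ss, ds, r2_max = 0.1, window_kb = 250))
  }
})

test_that("incremental R2 equals the two-regression oracle", {
  set.seed(7)
  n <- 120
  cov <- data.frame(sex = rbinom(n, 1, 0.5), age = rnorm(n, 50, 8))
  sc <- rnorm(n)
  y <- 0.4 * sc + 0.3 * cov$sex + 0.02 * cov$age + rnorm(n)
  fit <- prs_r2(sc, y, cov)
  expect_equal(fit$prs_r2, prs_r2_oracle(sc, y, cov), tolerance = 1e-10)
  full <- lm(y ~ sc + sex + age, data = cov)
  expect_equal(fit$beta_prs, unname(coef(full)["sc"]), tolerance = 1e-10)
  expect_equal(fit$p_value,
               summary(full)$coefficients["sc", 4], tolerance = 1e-10)
  # degenerate cases
  expect_equal(prs_r2(y, y)$prs_r2, 1, tolerance = 1e-12)
  noise_fit <- prs_r2(rnorm(n), y, cov)
  expect_lt(noise_fit$prs_r2, 3 / sqrt(n))
  expect_gte(noise_fit$prs_r2, 0)
})

test_that("threshold search finds a planted causal variant", {
  set.seed(12)
  n <- 400
  g <- rbinom(n, 2, 0.3)
  dos <- cbind(g, sapply(1:9, function(i) rbinom(n, 2, 0.3)))
  y <- g + rnorm(n, 0, 1)
  ds <- tiny_dataset(dos, pheno = data.frame(phenotype = y))
  tr <- 1:300; te <- 301:400
  ss <- summary_stats(ds, covariates = character(0), sample_idx = tr)
  hit <- ct_search(ss, subset_dataset(ds, samples = te), y[te])
  expect_true("v01" %in% hit$model$id)
  expect_gt(hit$fit$prs_r2, 0.1)
  # degenerate one-threshold grid equals a direct fit of that model
  hit1 <- ct_search(ss, subset_dataset(ds, samples = te), y[te],
                    thresholds = 1)
  direct <- prs_r2(compute_prs(subset_dataset(ds, samples = te),
                               hit1$model), y[te])
  expect_equal(hit1$fit$prs_r2, direct$prs_r2, tolerance = 1e-12)
})

test_that("ct_search fit is self-consistent with its returned model", {
  sim <- small_cohort(n = 250, m = 60, seed = 52, missing_rate = 0)
  ds <- sim$dataset
  tr <- 1:200; te <- 201:250
  ss <- summary_stats(ds, sample_idx = tr)
  cov_te <- as.matrix(ds$pheno[te, c("sex", "age", "status1", "status2")])
  y_te <- ds$pheno$phenotype[te]
  hit <- ct_search(ss, subset_dataset(ds, samples = te), y_te, cov_te)
  recompute <- prs_r2(compute_prs(subset_dataset(ds, samples = te),
                                  hit$model), y_te, cov_te)
  expect_equal(hit$fit$prs_r2, recompute$prs_r2, tolerance = 1e-12)
  expect_equal(hit$fit$n_snps, nrow(hit$model))
})
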