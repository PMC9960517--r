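make_pair <- function(a1a, a2a, a1b, a2b, pos_b = 1000L) {
  dosA <- matrix(c(0, 1, 2), 3, 1)
  dosB <- matrix(c(2, 1, 0), 3, 1)
  a <- genotype_dataset(dosA, data.frame(id = "v1", chrom = "1", pos = 1000L,
                                         allele1 = a1a, allele2 = a2a),
                        c("a1", "a2", "a3"))
  b <- genotype_dataset(dosB, data.frame(id = "v1", chrom = "1", pos = pos_b,
                                         allele1 = a1b, allele2 = a2b),
                        c("b1", "b2", "b3"))
  list(a = a, b = b)
}

test_that("classify_variants resolves identity, flips, switches and drops", {
  p <- make_pair("A", "G", "A", "G")
  expect_equal(classify_variants(p$a, p$b)$class, "identical")
  p <- make_pair("A", "G", "T", "C")
  expect_equal(classify_variants(p$a, p$b)$class, "flip")
  p <- make_pair("A", "G", "G", "A")
  expect_equal(classify_variants(p$a, p$b)$class, "switch")
  p <- make_pair("A", "G", "C", "T")
  expect_equal(classify_variants(p$a, p$b)$class, "flip_switch")
  p <- make_pair("A", "G", "A", "C")
  expect_equal(classify_variants(p$a, p$b)$class, "drop")
  # palindromic pairs are ambiguous under strand flips
  p <- make_pair("A", "T", "A", "T")
  expect_equal(classify_variants(p$a, p$b)$class, "drop")
  p <- make_pair("C", "G", "C", "G")
  expect_equal(classify_variants(p$a, p$b)$class, "drop")
  # conflicting coordinates for a shared id are a hard error
  p <- make_pair("A", "G", "A", "G", pos_b = 2000L)
  expect_error(classify_variants(p$a, p$b), "coordinates")
})

test_that("an offline allele authority rescues palindromic variants", {
  p <- make_pair("A", "T", "A", "T")
  auth <- data.frame(id = "v1", risk_allele = "A")
  expect_equal(classify_variants(p$a, p$b, auth)$class, "identical")
  p2 <- make_pair("A", "T", "T", "A")
  expect_equal(classify_variants(p2$a, p2$b, auth)$class, "switch")
  # authority naming an allele absent from the pair does not rescue
  auth2 <- data.frame(id = "v1", risk_allele = "C")
  expect_equal(classify_variants(p$a, p$b, auth2)$class, "drop")
})

test_that("classification is symmetric up to orientation relabelling", {
  sim <- small_cohort(n = 10, m = 60, seed = 31, missing_rate = 0)
  pert <- perturb_for_merge(sim$dataset, 0.2, 0.2, 0.1, 0.1, seed = 5)
  ab <- classify_variants(sim$dataset, pert$dataset)
  ba <- classify_variants(pert$dataset, sim$dataset)
  get <- function(pl, cls) sort(plan_ids(pl, cls))
  expect_identical(get(ab, "identical"), get(ba, "identical"))
  expect_identical(get(ab, "flip"), get(ba, "flip"))
  expect_identical(get(ab, "switch"), get(ba, "switch"))
  expect_identical(get(ab, "drop"), get(ba, "drop"))
  expect_identical(get(ab, "unique_a"), get(ba, "unique_b"))
  expect_identical(get(ab, "unique_b"), get(ba, "unique_a"))
})

test_that("merge restores perturbed dosages at every resolvable variant", {
  sim <- small_cohort(n = 40, m = 120, seed = 19, missing_rate = 0)
  pert <- perturb_for_merge(sim$dataset, 0.15, 0.15, 0.1, 0.1, seed = 7)
  b <- pert$dataset
  b$sample_ids <- paste0("B", b$sample_ids)
  rownames(b$dosages) <- b$sample_ids
  b$pheno$sample_id <- b$sample_ids
  plan <- classify_variants(sim$dataset, b)
  man <- pert$manifest
  # flips and switches are resolvable; unresolvable manifest entries drop
  expect_true(all(man$id[man$action == "flip"] %in% plan_ids(plan, "flip")))
  expect_true(all(man$id[man$action == "switch"] %in%
                    plan_ids(plan, "switch")))
  expect_true(all(man$id[man$action == "unresolvable"] %in%
                    plan_ids(plan, "drop")))
  merged <- merge_datasets(sim$dataset, b, plan)
  expect_false(any(plan_ids(plan, "drop") %in% merged$variants$id))
  resolvable <- c(plan_ids(plan, "identical"), plan_ids(plan, "flip"),
                  plan_ids(plan, "switch"))
  bblock <- merged$dosages[merged$pheno$cohort == "B", resolvable]
  orig <- sim$dataset$dosages[, resolvable]
  dimnames(orig) <- dimnames(bblock)
  expect_identical(bblock, orig)
  # per-sample dosage sums at identical variants are preserved exactly
  idv <- plan_ids(plan, "identical")
  expect_identical(rowSums(merged$dosages[merged$pheno$cohort == "A", idv]),
                   rowSums(sim$dataset$dosages[, idv]))
})

test_that("merging rejects duplicate sample ids; disjoint panels go missing", {
  sim <- small_cohort(n = 10, m = 20, seed = 3, missing_rate = 0)
  plan <- classify_variants(sim$dataset, sim$dataset)
  expect_true(all(plan$class == "identical"))
  expect_error(merge_datasets(sim$dataset, sim$dataset, plan), "duplicate")

  a <- subset_dataset(sim$dataset, samples = 1:5, variants = 1:10)
  b <- subset_dataset(sim$dataset, samples = 6:10, variants = 11:20)
  plan2 <- classify_variants(a, b)
  expect_setequal(unique(plan2$class), c("unique_a", "unique_b"))
  merged <- merge_datasets(a, b, plan2)
  expect_equal(dim(merged), c(10L, 20L))
  expect_true(all(is.na(merged$dosages[1:5, 11:20])))
  expect_true(all(is.na(merged$dosages[6:10, 1:10])))
})

test_that("regression imputation restores a perfectly correlated variant", {
  set.seed(11)
  g <- rbinom(60, 2, 0.4)
  dos <- cbind(g, g, rbinom(60, 2, 0.3))
  dos[1:10, 1] <- NA
  ds <- tiny_dataset(dos)
  out <- impute_regression(ds, window_snps = 2, r2_min = 0.9)
  expect_identical(unname(out$dataset$dosages[1:10, 1]),
                   as.double(g[1:10]))
  expect_equal(sum(out$report$imputed), 10)
  # an impossible bar: r2_min = 1 with no perfect proxy imputes nothing
  dos2 <- cbind(g, pmin(g + rbinom(60, 1, 0.5), 2), rbinom(60, 2, 0.3))
  dos2[1:10, 1] <- NA
  out2 <- impute_regression(tiny_dataset(dos2), window_snps = 2, r2_min = 1)
  expect_equal(sum(out2$report$imputed), 0)
  expect_true(anyNA(out2$dataset$dosages))
})

test_that("regression imputation beats the modal baseline on LD data", {
  sim <- small_cohort(n = 400, m = 150, n_causal = 0, seed = 77,
                      ld_rho = 0.9, missing_rate = 0)
  truth <- sim$dataset$dosages
  masked <- truth
  set.seed(5)
  mask <- which(matrix(runif(length(truth)) < 0.05, nrow(truth)))
  masked[mask] <- NA
  ds <- sim$dataset; ds$dosages <- masked
  out <- impute_regression(ds, window_snps = 10, r2_min = 0.5)$dataset
  imputed_now <- mask[!is.na(out$dosages[mask])]
  acc <- mean(out$dosages[imputed_now] == truth[imputed_now])
  modal <- apply(masked, 2, iterprs:::modal_value)
  modal_mat <- matrix(modal, nrow(truth), ncol(truth), byrow = TRUE)
  acc_modal <- mean(modal_mat[imputed_now] == truth[imputed_now])
  expect_gte(acc, acc_modal)
})

test_that("k-NN imputation copies from a duplicate sample at k = 1", {
  set.seed(2)
  base <- rbinom(30, 2, 0.5)
  dos <- rbind(base, base, rbinom(30, 2, 0.5), rbinom(30, 2, 0.5))
  dos[1, 1:5] <- NA
  ds <- tiny_dataset(dos)
  out <- impute_knn(ds, k = 1)
  expect_identical(unname(out$dosages[1, 1:5]), as.double(base[1:5]))
  expect_false(anyNA(out$dosages))
})

test_that("k-NN neighbour ranking matches exhaustive distances", {
  dos <- rbind(c(0, 1, 2, NA), c(0, 1, 1, 0), c(2, NA, 0, 1),
               c(1, 1, 2, 2), c(NA, 0, 2, 2))
  D <- knn_distances(dos)
  n <- nrow(dos)
  Dref <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    ok <- !is.na(dos[i, ]) & !is.na(dos[j, ])
    Dref[i, j] <- if (any(ok)) mean(abs(dos[i, ok] - dos[j, ok])) else Inf
  }
  diag(Dref) <- 0
  expect_equal(D, Dref)
})

test_that("regression followed by k-NN leaves zero missingness in {0,1,2}", {
  sim <- small_cohort(n = 80, m = 60, seed = 41, missing_rate = 0.1,
                      ld_rho = 0.6)
  out <- impute_knn(impute_regression(sim$dataset)$dataset, k = 5)
  expect_false(anyNA(out$dosages))
  expect_true(all(out$dosages %in% c(0, 1, 2)))
})

test_that("three-cohort merge recovers masked genotypes end to end", {
  sim <- small_cohort(n = 90, m = 90, n_causal = 0, seed = 55, ld_rho = 0.9,
                      missing_rate = 0)
  full <- sim$dataset
  idxA <- 1:30; idxB <- 31:60; idxC <- 61:90
  # cohorts genotyped on overlapping but distinct panels
  set.seed(6)
  pa <- sort(sample(90, 70)); pb <- sort(sample(90, 70))
  pc <- sort(sample(90, 70))
  mk <- function(samples, panel, tag) {
    d <- subset_dataset(full, samples = samples, variants = panel)
    d$sample_ids <- paste0(tag, d$sample_ids)
    rownames(d$dosages) <- d$sample_ids
    d$pheno$sample_id <- d$sample_ids
    d
  }
  A <- mk(idxA, pa, "A"); B <- mk(idxB, pb, "B"); C <- mk(idxC, pc, "C")
  ab <- merge_datasets(A, B, classify_variants(A, B))
  ab <- subset_dataset(ab, variants = order(ab$variants$chrom,
                                            ab$variants$pos))
  abc <- merge_datasets(ab, C, classify_variants(ab, C))
  abc <- subset_dataset(abc, variants = order(abc$variants$chrom,
                                              abc$variants$pos))
  imp <- suppressWarnings(
    impute_knn(impute_regression(abc, window_snps = 8,
                                 r2_min = 0.6)$dataset, k = 5))
  expect_false(anyNA(imp$dosages))
  # accuracy at genotypes absent from a cohort's panel but known in truth
  truthm <- full$dosages[c(idxA, idxB, idxC), imp$variants$id]
  was_missing <- is.na(abc$dosages)
  acc <- mean(imp$dosages[was_missing] == truthm[was_missing])
  expect_gt(acc, 0.6)
})
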