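# Synthetic cohort generator with known causal architecture.
#
# The generator exists so that every downstream stage (merging, QC,
# stratification correction, association, score construction, aggregation)
# can be validated against a known truth: which variants are causal, their
# effect sizes, the planted heritability, and each sample's ancestral
# cluster.

#' Specify a synthetic cohort
#'
#' @param n_samples number of samples
#' @param n_snps number of variants
#' @param maf_range interval in (0, 0.5] from which ancestral minor-allele
#'   frequencies are drawn uniformly
#' @param n_causal number of causal variants (must not exceed \code{n_snps})
#' @param heritability fraction of phenotypic variance explained by the true
#'   genetic score, in [0, 1]
#' @param missing_rate fraction of dosage entries set missing at random
#' @param n_pops number of ancestral clusters; when > 1 per-population allele
#'   frequencies are drawn by the Balding-Nichols construction
#' @param fst differentiation parameter in [0, 1) for the Balding-Nichols
#'   draws
#' @param ld_rho first-order latent correlation between adjacent variants
#'   (Gaussian copula on the haplotype level); 0 disables LD
#' @param covariate_effects named numeric vector of effects for
#'   \code{sex}, \code{age}, \code{status1}, \code{status2} on the phenotype
#' @param seed integer seed; all substreams derive from it
#' @return a \code{cohort_spec} list
#' @export
cohort_spec <- function(n_samples = 2000, n_snps = 5000,
                        maf_range = c(0.05, 0.5), n_causal = 50,
                        heritability = 0.3, missing_rate = 0,
                        n_pops = 1, fst = 0.05, ld_rho = 0.3,
                        covariate_effects = c(sex = 0.5, age = 0.025,
                                              status1 = 0.25,
                                              status2 = 0.25),
                        seed = 1L) {
  spec <- list(n_samples = n_samples, n_snps = n_snps, maf_range = maf_range,
               n_causal = n_causal, heritability = heritability,
               missing_rate = missing_rate, n_pops = n_pops, fst = fst,
               ld_rho = ld_rho, covariate_effects = covariate_effects,
               seed = seed)
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  chk_count <- function(x, nm, min = 1) {
    if (length(x) != 1 || !is.finite(x) || x != round(x) || x < min)
      stop(nm, " must be a single integer >= ", min)
  }
  chk_count(spec$n_samples, "n_samples", 2)
  chk_count(spec$n_snps, "n_snps")
  chk_count(spec$n_causal, "n_causal", 0)
  chk_count(spec$n_pops, "n_pops")
  if (spec$n_causal > spec$n_snps) stop("n_causal must not exceed n_snps")
  mr <- spec$maf_range
  if (length(mr) != 2 || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
    stop("maf_range must lie inside (0, 0.5]")
  if (spec$heritability < 0 || spec$heritability > 1)
    stop("heritability must be in [0, 1]")
  if (spec$missing_rate < 0 || spec$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (spec$fst < 0 || spec$fst >= 1) stop("fst must be in [0, 1)")
  if (abs(spec$ld_rho) >= 1) stop("ld_rho must be in (-1, 1)")
  invisible(spec)
}

# non-palindromic allele pairs (palindromic A/T, C/G pairs are ambiguous
# under strand flips and are generated only on request via perturbation)
.allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                          "G", "A", "C", "A", "G", "T", "C", "T"),
                        ncol = 2, byrow = TRUE)

# one AR(1) latent Gaussian haplotype matrix (n x m)
.latent_haplo <- function(n, m, rho) {
  z <- matrix(stats::rnorm(n * m), n, m)
  if (rho != 0 && m > 1) {
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
  }
  z
}

#' Simulate a cohort with known genetic architecture
#'
#' Dosages are drawn per variant as two correlated haplotype indicators
#' (adjacent-variant LD via a first-order Gaussian copula). With
#' \code{n_pops > 1}, per-population allele frequencies come from the
#' Balding-Nichols model: for ancestral frequency p and differentiation F,
#' population frequencies are Beta(p(1-F)/F, (1-p)(1-F)/F). The quantitative
#' phenotype has unit total variance and decomposes exactly: the causal
#' genetic score contributes the heritability share (effects rescaled so
#' the realized share equals the target), covariate terms (sex, age and
#' two binary disease statuses) contribute theirs, and in-sample
#' orthogonalized Gaussian noise fills the remainder.
#'
#' @param spec a \code{cohort_spec}
#' @return list with elements \code{dataset} (a \code{genotype_dataset})
#'   and \code{truth} (causal ids, true betas, realized heritability target,
#'   covariate effects, population labels, true genetic score)
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  validate_cohort_spec(spec)
  n <- spec$n_samples; m <- spec$n_snps
  maf <- with_seed(substream_seed(spec$seed, "maf"),
                   stats::runif(m, spec$maf_range[1], spec$maf_range[2]))

  pops <- with_seed(substream_seed(spec$seed, "pops"),
                    sort(sample.int(spec$n_pops, n, replace = TRUE)))
  pf <- matrix(maf, nrow = spec$n_pops, ncol = m, byrow = TRUE)
  if (spec$n_pops > 1 && spec$fst > 0) {
    a <- (1 - spec$fst) / spec$fst
    pf <- with_seed(substream_seed(spec$seed, "bn"), {
      matrix(stats::rbeta(spec$n_pops * m,
                          rep(maf, each = spec$n_pops) * a,
                          rep(1 - maf, each = spec$n_pops) * a),
             nrow = spec$n_pops, ncol = m)
    })
    pf <- pmin(pmax(pf, 1e-4), 1 - 1e-4)
  }

  thr <- stats::qnorm(pf[pops, , drop = FALSE])  # n x m per-sample thresholds
  dos <- with_seed(substream_seed(spec$seed, "genotypes"), {
    h1 <- .latent_haplo(n, m, spec$ld_rho) < thr
    h2 <- .latent_haplo(n, m, spec$ld_rho) < thr
    h1 + h2
  })
  storage.mode(dos) <- "double"

  variants <- data.frame(
    id = sprintf("snp%05d", seq_len(m)),
    chrom = "1",
    pos = seq_len(m) * 3000L,  # ~3 kb spacing: 250 kb window ~ 83 neighbours
    allele1 = NA_character_, allele2 = NA_character_,
    stringsAsFactors = FALSE)
  ap <- with_seed(substream_seed(spec$seed, "alleles"),
                  .allele_pairs[sample.int(nrow(.allele_pairs), m,
                                           replace = TRUE), , drop = FALSE])
  variants$allele1 <- ap[, 1]; variants$allele2 <- ap[, 2]

  covar <- with_seed(substream_seed(spec$seed, "covariates"), data.frame(
    sex = stats::rbinom(n, 1, 0.5),
    age = stats::rnorm(n, 55, 10),
    status1 = stats::rbinom(n, 1, 0.3),
    status2 = stats::rbinom(n, 1, 0.2)))

  causal_idx <- with_seed(substream_seed(spec$seed, "causal"),
                          sort(sample.int(m, spec$n_causal)))
  h2 <- spec$heritability
  betas <- numeric(spec$n_causal)
  g <- numeric(n)
  # the phenotype has unit total variance: the genetic score contributes
  # exactly the heritability share, covariates their (modest) share, and
  # Gaussian noise the remainder
  if (spec$n_causal > 0 && h2 > 0) {
    sdcol <- apply(dos[, causal_idx, drop = FALSE], 2, stats::sd)
    sdcol[sdcol == 0] <- 1
    b_std <- with_seed(substream_seed(spec$seed, "effects"),
                       stats::rnorm(spec$n_causal, 0,
                                    sqrt(h2 / spec$n_causal)))
    betas <- b_std / sdcol
    g <- as.vector(dos[, causal_idx, drop = FALSE] %*% betas)
    # rescale effects so the REALIZED genetic variance share is exactly h2
    vg <- stats::var(g)
    if (vg > 0) {
      k <- sqrt(h2 / vg)
      betas <- betas * k
      g <- g * k
    }
  }

  ce <- spec$covariate_effects
  cterm <- as.vector(as.matrix(covar) %*%
                       ce[c("sex", "age", "status1", "status2")])
  eps <- with_seed(substream_seed(spec$seed, "noise"), stats::rnorm(n))
  base <- g + cterm
  var_e <- 1 - stats::var(base)
  if (var_e <= 0.005)
    stop("covariate effects leave no room for noise at this heritability; ",
         "reduce covariate_effects or heritability")
  # orthogonalize the noise in-sample against the signal so the realized
  # variance decomposition is exact, not just in expectation
  eps <- qr.resid(qr(cbind(1, g, cterm)), eps)
  se <- stats::sd(eps)
  eps <- if (se > 0) eps * sqrt(var_e) / se else numeric(n)
  phenotype <- base + eps

  if (spec$missing_rate > 0) {
    dos <- with_seed(substream_seed(spec$seed, "missingness"), {
      mask <- stats::runif(n * m) < spec$missing_rate
      dos[mask] <- NA
      dos
    })
  }

  sample_ids <- sprintf("S%04d", seq_len(n))
  pheno <- data.frame(sample_id = sample_ids, phenotype = phenotype, covar,
                      stringsAsFactors = FALSE)
  dataset <- genotype_dataset(dos, variants, sample_ids, pheno = pheno)
  truth <- list(causal_variant_ids = variants$id[causal_idx],
                true_betas = betas,
                heritability = h2,
                covariate_effects = ce,
                population_labels = pops,
                genetic_score = g)
  list(dataset = dataset, truth = truth)
}

#' Perturb a cohort into a second-panel view for merge testing
#'
#' Produces the same cohort as it would appear if genotyped on a different
#' array: a fraction of variants strand-flipped (alleles complemented,
#' dosages unchanged), a fraction allele-switched (allele order and dosage
#' coding reversed), a fraction dropped (panel-unique to the original), and
#' a fraction given an unresolvable allele pair. A manifest of the applied
#' perturbations is attached for round-trip checks.
#'
#' @param dataset a \code{genotype_dataset}
#' @param frac_flip,frac_switch,frac_unique,frac_unresolvable fractions of
#'   variants to perturb; must sum to at most 1
#' @param seed integer seed
#' @return list with \code{dataset} (the perturbed view) and \code{manifest}
#'   (data.frame: id, action)
#' @export
perturb_for_merge <- function(dataset, frac_flip = 0.1, frac_switch = 0.1,
                              frac_unique = 0.05, frac_unresolvable = 0.05,
                              seed = 1L) {
  fr <- c(frac_flip, frac_switch, frac_unique, frac_unresolvable)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("perturbation fractions must be in [0, 1] and sum to at most 1")
  m <- n_variants(dataset)
  counts <- floor(fr * m)
  idx <- with_seed(seed, sample.int(m, sum(counts)))
  grp <- rep(c("flip", "switch", "unique_a", "unresolvable"), counts)
  manifest <- data.frame(id = dataset$variants$id[idx], action = grp,
                         orig_allele1 = dataset$variants$allele1[idx],
                         orig_allele2 = dataset$variants$allele2[idx],
                         stringsAsFactors = FALSE)

  v <- dataset$variants
  dos <- dataset$dosages
  fl <- idx[grp == "flip"]
  v$allele1[fl] <- dna_complement(v$allele1[fl])
  v$allele2[fl] <- dna_complement(v$allele2[fl])
  sw <- idx[grp == "switch"]
  tmp <- v$allele1[sw]; v$allele1[sw] <- v$allele2[sw]; v$allele2[sw] <- tmp
  dos[, sw] <- 2 - dos[, sw]
  un <- idx[grp == "unresolvable"]
  for (j in un) {
    pair <- c(v$allele1[j], v$allele2[j])
    # new second allele making the pair irreconcilable: the unordered pair
    # must differ from the original and from its strand complement, and must
    # not become palindromic (which would be dropped for a different reason)
    cand <- setdiff(c("A", "C", "G", "T"), pair)
    ok <- vapply(cand, function(cc) {
      cc != dna_complement(pair[1]) &&
        !setequal(c(pair[1], cc), dna_complement(pair))
    }, logical(1))
    v$allele2[j] <- if (any(ok)) cand[which(ok)[1]] else cand[1]
  }
  keep <- setdiff(seq_len(m), idx[grp == "unique_a"])
  out <- genotype_dataset(dos[, keep, drop = FALSE], v[keep, , drop = FALSE],
                          dataset$sample_ids, pheno = dataset$pheno)
  list(dataset = out, manifest = manifest)
}

#' Body-mass index and its WHO category
#'
#' @param weight_kg body weight in kilograms (> 0)
#' @param height_m body height in metres (> 0)
#' @return \code{bmi}: numeric BMI in kg/m^2
#' @export
bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0) || any(height_m <= 0))
    stop("weight and height must be positive")
  weight_kg / height_m^2
}

#' @rdname bmi
#' @param bmi_value numeric BMI value(s)
#' @return \code{bmi_class}: factor with levels underweight, normal,
#'   overweight, obese (cut points 18.5, 25, 30 kg/m^2)
#' @export
bmi_class <- function(bmi_value) {
  cut(bmi_value, breaks = c(-Inf, 18.5, 25, 30, Inf),
      labels = c("underweight", "normal", "overweight", "obese"),
      right = FALSE)
}
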