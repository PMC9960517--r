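# Harmonization and merging of two genotype datasets, plus genotype
# imputation of the missingness the merge creates.

#' Classify shared and unique variants between two datasets
#'
#' For every variant id in either dataset, decides how dataset B's
#' representation relates to dataset A's:
#' \itemize{
#'   \item \code{identical}: same allele pair, same orientation;
#'   \item \code{flip}: B's alleles are the strand complement of A's;
#'   \item \code{switch}: B counts the other allele (order reversed), so
#'     B's dosages must be recoded d -> 2 - d;
#'   \item \code{flip_switch}: both at once;
#'   \item \code{drop}: alleles cannot be reconciled, or the pair is
#'     palindromic (A/T, C/G), which is ambiguous under strand flips;
#'   \item \code{unique_a} / \code{unique_b}: present in only one dataset.
#' }
#' A shared id with conflicting position is a hard error: the inputs
#' disagree on coordinates and must be fixed upstream.
#'
#' An optional allele authority (data.frame: id, risk_allele) can force
#' orientation for otherwise ambiguous palindromic variants: if the
#' authority names one of the alleles as the risk allele in both datasets,
#' the variant is reclassified identical/switch accordingly.
#'
#' @param a,b \code{genotype_dataset} objects
#' @param allele_authority optional data.frame with columns \code{id},
#'   \code{risk_allele}
#' @return a \code{merge_plan}: data.frame (id, class) plus per-class id
#'   lists as attributes
#' @export
classify_variants <- function(a, b, allele_authority = NULL) {
  va <- a$variants; vb <- b$variants
  shared <- intersect(va$id, vb$id)
  ia <- match(shared, va$id); ib <- match(shared, vb$id)
  conflict <- va$pos[ia] != vb$pos[ib] | va$chrom[ia] != vb$chrom[ib]
  if (any(conflict))
    stop("datasets disagree on coordinates for shared variant(s): ",
         paste(utils::head(shared[conflict], 5), collapse = ", "))
  a1 <- va$allele1[ia]; a2 <- va$allele2[ia]
  b1 <- vb$allele1[ib]; b2 <- vb$allele2[ib]
  palindromic <- a1 == dna_complement(a2)
  cls <- rep("drop", length(shared))
  cls[b1 == a1 & b2 == a2] <- "identical"
  cls[dna_complement(b1) == a1 & dna_complement(b2) == a2] <- "flip"
  cls[b1 == a2 & b2 == a1] <- "switch"
  cls[dna_complement(b1) == a2 & dna_complement(b2) == a1] <- "flip_switch"
  cls[palindromic] <- "drop"
  if (!is.null(allele_authority)) {
    # palindromic variants whose risk allele is declared offline can be
    # rescued: same literal pair means orientation is decided by whether the
    # declared risk allele sits in A1 of both datasets
    ri <- match(shared, allele_authority$id)
    can <- palindromic & !is.na(ri) & (b1 == a1 & b2 == a2 | b1 == a2 & b2 == a1)
    risk <- allele_authority$risk_allele[ri]
    same <- can & b1 == a1 & (risk == a1 | risk == a2)
    swap <- can & b1 == a2 & (risk == a1 | risk == a2)
    cls[same] <- "identical"
    cls[swap] <- "switch"
  }
  plan <- data.frame(id = c(shared, setdiff(va$id, shared),
                            setdiff(vb$id, shared)),
                     class = c(cls,
                               rep("unique_a", length(setdiff(va$id, shared))),
                               rep("unique_b", length(setdiff(vb$id, shared)))),
                     stringsAsFactors = FALSE)
  class(plan) <- c("merge_plan", "data.frame")
  plan
}

#' Extract the id list of one class from a merge plan
#' @param plan a \code{merge_plan}
#' @param class_name one of identical, flip, switch, flip_switch, drop,
#'   unique_a, unique_b
#' @return character vector of variant ids
#' @export
plan_ids <- function(plan, class_name) plan$id[plan$class == class_name]

#' Merge two genotype datasets according to a merge plan
#'
#' The output carries the union of samples and of retained variants
#' (everything except \code{drop}), in dataset A's allele orientation.
#' B's dosages at \code{switch}/\code{flip_switch} variants are recoded
#' d -> 2 - d so that every dosage still counts copies of the same effect
#' allele. Genotypes absent from a source cohort are missing. Phenotype
#' tables are joined on their common columns.
#'
#' @param a,b \code{genotype_dataset} objects
#' @param plan a \code{merge_plan} from \code{classify_variants(a, b)}
#' @return a \code{genotype_dataset} with a \code{cohort} column appended to
#'   the phenotype table recording sample provenance
#' @export
merge_datasets <- function(a, b, plan) {
  if (length(intersect(a$sample_ids, b$sample_ids)))
    stop("duplicate sample ids across cohorts; rename before merging")
  keepA <- a$variants$id[!a$variants$id %in% plan_ids(plan, "drop")]
  uniqB <- plan_ids(plan, "unique_b")
  ids <- c(keepA, uniqB)
  va <- a$variants[match(keepA, a$variants$id), , drop = FALSE]
  vbu <- b$variants[match(uniqB, b$variants$id), , drop = FALSE]
  variants <- rbind(va, vbu)

  nA <- n_samples(a); nB <- n_samples(b); m <- length(ids)
  dos <- matrix(NA_real_, nA + nB, m)
  dos[seq_len(nA), seq_along(keepA)] <- a$dosages[, keepA, drop = FALSE]
  sharedB <- intersect(keepA, b$variants$id)
  jb <- match(sharedB, ids)
  bdos <- b$dosages[, sharedB, drop = FALSE]
  sw <- sharedB %in% c(plan_ids(plan, "switch"), plan_ids(plan, "flip_switch"))
  bdos[, sw] <- 2 - bdos[, sw]
  dos[nA + seq_len(nB), jb] <- bdos
  if (length(uniqB))
    dos[nA + seq_len(nB), match(uniqB, ids)] <-
      b$dosages[, uniqB, drop = FALSE]

  pheno <- NULL
  if (!is.null(a$pheno) && !is.null(b$pheno)) {
    common <- intersect(names(a$pheno), names(b$pheno))
    pheno <- rbind(a$pheno[, common, drop = FALSE],
                   b$pheno[, common, drop = FALSE])
    pheno$cohort <- rep(c("A", "B"), c(nA, nB))
  }
  genotype_dataset(dos, variants, c(a$sample_ids, b$sample_ids),
                   pheno = pheno)
}

#' Iterative regression-based genotype imputation
#'
#' For each variant with missing entries, fits an ordinary least-squares
#' model of its observed dosages on the \code{window_snps} nearest
#' neighbouring variants (by position on the same chromosome), using samples
#' where target and all predictors are observed. If the fit R-squared
#' reaches \code{r2_min}, missing entries with complete predictors are
#' predicted and rounded to the nearest of \{0, 1, 2\}. Whole passes over
#' the dataset repeat until no value changes or \code{max_rounds} is
#' reached. Variants that cannot be imputed stay missing.
#'
#' @param dataset a \code{genotype_dataset} with variants sorted by
#'   (chrom, pos)
#' @param window_snps neighbours considered on each side combined (the
#'   nearest \code{window_snps} columns by distance)
#' @param r2_min minimum training R-squared to accept a model
#' @param max_rounds maximum number of whole-dataset passes
#' @return list: \code{dataset} (imputed), \code{report} (data.frame with
#'   per-round imputed counts)
#' @export
impute_regression <- function(dataset, window_snps = 10, r2_min = 0.8,
                              max_rounds = 10) {
  dos <- dataset$dosages
  v <- dataset$variants
  o <- order(v$chrom, v$pos)
  if (!identical(o, seq_along(o)))
    stop("variants must be sorted by (chrom, pos) before regression imputation")
  m <- ncol(dos)
  rounds <- integer(0)
  for (round in seq_len(max_rounds)) {
    changed <- 0L
    for (j in seq_len(m)) {
      miss <- is.na(dos[, j])
      if (!any(miss) || all(miss)) next
      same <- which(v$chrom == v$chrom[j])
      same <- setdiff(same, j)
      if (!length(same)) next
      nb <- same[order(abs(v$pos[same] - v$pos[j]))]
      nb <- utils::head(nb, window_snps)
      X <- dos[, nb, drop = FALSE]
      cp <- stats::complete.cases(X)
      tr <- cp & !miss
      pr <- cp & miss
      if (sum(tr) < length(nb) + 2 || !any(pr)) next
      Xt <- cbind(1, X[tr, , drop = FALSE])
      keep <- c(TRUE, apply(X[tr, , drop = FALSE], 2, stats::sd) > 0)
      fit <- stats::lm.fit(Xt[, keep, drop = FALSE], dos[tr, j])
      y <- dos[tr, j]
      tss <- sum((y - mean(y))^2)
      if (tss <= 0) next
      r2 <- 1 - sum(fit$residuals^2) / tss
      if (is.na(r2) || r2 < r2_min) next
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0  # aliased (collinear) predictors contribute nothing
      pred <- cbind(1, X[pr, , drop = FALSE])[, keep, drop = FALSE] %*% cf
      dos[pr, j] <- pmin(pmax(round(pred), 0), 2)
      changed <- changed + sum(pr)
    }
    rounds <- c(rounds, changed)
    if (changed == 0L) break
  }
  out <- dataset
  out$dosages <- dos
  list(dataset = out,
       report = data.frame(round = seq_along(rounds), imputed = rounds))
}

#' k-nearest-neighbour genotype imputation
#'
#' Fills every remaining missing entry with the modal dosage of the
#' \code{k} nearest samples, where distance between two samples is the mean
#' absolute dosage difference over their mutually observed variants. A
#' sample sharing no observed variant with another gets distance Inf; if all
#' its neighbours are uninformative the variant's cohort-wide modal dosage
#' is used (with a warning). Output has zero missingness.
#'
#' @param dataset a \code{genotype_dataset}
#' @param k number of neighbours (>= 1)
#' @return a \code{genotype_dataset} with no missing dosages
#' @export
impute_knn <- function(dataset, k = 10) {
  if (k < 1) stop("k must be >= 1")
  dos <- dataset$dosages
  n <- nrow(dos)
  if (!anyNA(dos)) return(dataset)
  D <- knn_distances(dos)
  col_modes <- apply(dos, 2, modal_value)
  warned <- FALSE
  for (i in seq_len(n)) {
    miss <- which(is.na(dos[i, ]))
    if (!length(miss)) next
    d <- D[i, ]; d[i] <- Inf
    if (all(!is.finite(d))) {
      dos[i, miss] <- col_modes[miss]
      warned <- TRUE
      next
    }
    nb <- order(d)[seq_len(min(k, n - 1))]
    for (j in miss) {
      val <- modal_value(dataset$dosages[nb, j])
      if (is.na(val)) { val <- col_modes[j]; warned <- TRUE }
      if (is.na(val)) val <- 0
      dos[i, j] <- val
    }
  }
  if (warned)
    warning("some entries fell back to cohort modal dosage (no informative neighbour)")
  out <- dataset
  out$dosages <- dos
  out
}

#' Pairwise sample distances for k-NN imputation
#'
#' Mean absolute dosage difference over mutually observed variants;
#' \code{Inf} where two samples share no observed variant.
#'
#' @param dos dosage matrix
#' @return symmetric n x n distance matrix
#' @export
knn_distances <- function(dos) {
  obs <- !is.na(dos)
  x <- dos; x[!obs] <- 0
  # sum over mutually observed |xi - xj| decomposed with 0/1 masks would be
  # approximate; with dosage domain {0,1,2} we use exact indicator algebra:
  # |a-b| = sum_{t in {0,1}} [a<=t != b<=t]  for a,b in {0,1,2}
  le0 <- (x <= 0) & obs
  le1 <- (x <= 1) & obs
  both <- tcrossprod(obs * 1)
  mism <- function(ind) {
    a <- ind * 1
    tcrossprod(a, (obs & !ind) * 1) + tcrossprod((obs & !ind) * 1, a)
  }
  tot <- mism(le0) + mism(le1)
  d <- tot / both
  d[both == 0] <- Inf
  diag(d) <- 0
  d
}
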