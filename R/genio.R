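# Genotype container and PLINK 1 / tabular I/O.
#
# Internal representation: dosages count copies of allele1, the designated
# effect (risk) allele, following the PLINK convention that A1 is the counted
# allele. Coordinates are 1-based as in BIM files.

#' Construct a genotype dataset
#'
#' The central container used by every module: a samples x variants dosage
#' matrix (entries 0, 1, 2 or \code{NA} for missing), variant metadata, and a
#' per-sample phenotype/covariate table.
#'
#' @param dosages numeric matrix, n_samples x n_variants, entries in
#'   \{0, 1, 2, NA\}; dosage counts copies of \code{allele1}.
#' @param variants data.frame with columns \code{id}, \code{chrom},
#'   \code{pos}, \code{allele1}, \code{allele2}. \code{allele1} is the
#'   counted (effect) allele.
#' @param sample_ids character vector of unique sample identifiers.
#' @param pheno optional data.frame of per-sample phenotype and covariates;
#'   must contain a \code{sample_id} column aligned with \code{sample_ids}.
#' @param info optional numeric vector of per-variant imputation INFO scores
#'   in [0, 1].
#' @return an object of class \code{genotype_dataset}
#' @export
genotype_dataset <- function(dosages, variants, sample_ids, pheno = NULL,
                             info = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages); m <- ncol(dosages)
  if (length(sample_ids) != n)
    stop("sample_ids length (", length(sample_ids),
         ") does not match dosage rows (", n, ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "allele1", "allele2")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variant table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(variants) != m)
    stop("variant table rows (", nrow(variants),
         ") do not match dosage columns (", m, ")")
  if (anyDuplicated(variants$id)) stop("duplicate variant ids")
  if (any(variants$pos <= 0)) stop("variant positions must be positive")
  if (any(variants$allele1 == variants$allele2))
    stop("allele1 must differ from allele2")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (any(bad < 0) || any(bad > 2)))
    stop("dosages must lie in [0, 2]")
  if (!is.null(pheno)) {
    pheno <- as.data.frame(pheno, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(pheno)) stop("pheno needs a sample_id column")
    if (!identical(as.character(pheno$sample_id), as.character(sample_ids)))
      stop("pheno sample_id column must align with sample_ids")
  }
  if (!is.null(info)) {
    if (length(info) != m) stop("info length must equal number of variants")
    if (any(info < 0 | info > 1, na.rm = TRUE)) stop("INFO scores must be in [0, 1]")
  }
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = variants,
                 sample_ids = as.character(sample_ids), pheno = pheno,
                 info = info),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", n_samples(x), "samples x", n_variants(x),
      "variants\n")
  mr <- mean(is.na(x$dosages))
  cat(sprintf("  missingness: %.2f%%", 100 * mr))
  if (!is.null(x$pheno))
    cat("; phenotype columns:",
        paste(setdiff(names(x$pheno), "sample_id"), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosages)

#' Number of samples / variants in a genotype dataset
#' @param x a \code{genotype_dataset}
#' @return integer count
#' @export
n_samples <- function(x) nrow(x$dosages)

#' @rdname n_samples
#' @export
n_variants <- function(x) ncol(x$dosages)

#' Subset a genotype dataset by sample and/or variant index
#'
#' @param x a \code{genotype_dataset}
#' @param samples integer, logical or character index of samples to keep
#' @param variants integer, logical or character index of variants to keep
#' @return a \code{genotype_dataset}
#' @export
subset_dataset <- function(x, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(x)) else samples
  if (is.character(si)) si <- match(si, x$sample_ids)
  vi <- if (is.null(variants)) seq_len(n_variants(x)) else variants
  if (is.character(vi)) vi <- match(vi, x$variants$id)
  genotype_dataset(x$dosages[si, vi, drop = FALSE],
                   x$variants[vi, , drop = FALSE],
                   x$sample_ids[si],
                   pheno = if (is.null(x$pheno)) NULL else
                     x$pheno[si, , drop = FALSE],
                   info = if (is.null(x$info)) NULL else x$info[vi])
}

# ---- PLINK 1 binary (BED/BIM/FAM), SNP-major ------------------------------

# 2-bit codes, PLINK 1.9: 00 = hom A1 (dosage 2), 01 = missing,
# 10 = het (dosage 1), 11 = hom A2 (dosage 0). First sample occupies the
# low-order bits of each byte.
.bed_code_to_dosage <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
.dosage_to_bed_code <- function(d) {
  code <- integer(length(d))
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 2] <- 0L
  code[!is.na(d) & d == 1] <- 2L
  code[!is.na(d) & d == 0] <- 3L
  code
}

#' Read a PLINK 1 binary fileset
#'
#' Reads \code{<prefix>.bed}, \code{.bim} and \code{.fam} (SNP-major BED
#' layout). Dosages count copies of the BIM A1 allele, which the package
#' treats as the effect allele. If a file \code{<prefix>.pheno.tsv} exists it
#' is attached as the phenotype table.
#'
#' @param prefix path prefix of the fileset
#' @return a \code{genotype_dataset}
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  bimt <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("chrom", "id", "cm", "pos",
                                          "allele1", "allele2"),
                            colClasses = c("character", "character",
                                           "numeric", "integer",
                                           "character", "character"))
  famt <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(famt); m <- nrow(bimt)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK 1 BED file: bad magic bytes at offset 0")
  if (raw[3] != as.raw(0x01))
    stop("BED file is not SNP-major (mode byte at offset 2 is not 0x01)")
  bpv <- ceiling(n / 4)
  if (length(raw) - 3L != bpv * m)
    stop("BED payload size (", length(raw) - 3L, " bytes) does not match ",
         n, " samples x ", m, " variants from FAM/BIM")
  payload <- raw[-(1:3)]
  ints <- as.integer(payload)
  # expand each byte into its four 2-bit fields, low bits first
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, ints %/% 64L)
  dim(codes) <- c(4L * bpv, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  dos <- matrix(.bed_code_to_dosage[codes + 1L], nrow = n, ncol = m)
  sample_ids <- as.character(famt[[2]])
  pheno <- NULL
  pfile <- paste0(prefix, ".pheno.tsv")
  if (file.exists(pfile)) pheno <- read_table(pfile)
  genotype_dataset(dos, bimt[, c("id", "chrom", "pos", "allele1", "allele2")],
                   sample_ids, pheno = pheno)
}

#' Write a PLINK 1 binary fileset
#'
#' Writes SNP-major \code{<prefix>.bed}, \code{.bim}, \code{.fam}; if the
#' dataset carries a phenotype table it is written to
#' \code{<prefix>.pheno.tsv}. Round trips exactly with \code{read_plink}.
#'
#' @param dataset a \code{genotype_dataset}
#' @param prefix output path prefix
#' @return \code{prefix}, invisibly
#' @export
write_plink <- function(dataset, prefix) {
  n <- n_samples(dataset); m <- n_variants(dataset)
  v <- dataset$variants
  utils::write.table(
    data.frame(v$chrom, v$id, 0, v$pos, v$allele1, v$allele2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  ph <- if (!is.null(dataset$pheno) && "sex" %in% names(dataset$pheno))
    dataset$pheno$sex + 1 else rep(0, n)
  utils::write.table(
    data.frame(dataset$sample_ids, dataset$sample_ids, 0, 0, ph, -9),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  bpv <- ceiling(n / 4)
  codes <- matrix(1L, nrow = 4L * bpv, ncol = m)  # pad with "missing"
  codes[seq_len(n), ] <- apply(dataset$dosages, 2, .dosage_to_bed_code)
  codes[seq(n + 1, length.out = 4L * bpv - n), ] <- 0L  # PLINK pads with 0 bits
  bytes <- codes[c(TRUE, FALSE, FALSE, FALSE), , drop = FALSE] +
    4L * codes[c(FALSE, TRUE, FALSE, FALSE), , drop = FALSE] +
    16L * codes[c(FALSE, FALSE, TRUE, FALSE), , drop = FALSE] +
    64L * codes[c(FALSE, FALSE, FALSE, TRUE), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  if (!is.null(dataset$pheno))
    write_table(dataset$pheno, paste0(prefix, ".pheno.tsv"))
  invisible(prefix)
}

# ---- plain-text dialect ----------------------------------------------------

#' Read/write the whitespace text dialect of a genotype fileset
#'
#' A human-readable equivalent of the binary fileset used for fixtures:
#' \code{<prefix>.tgeno.tsv} holds one variant per row (id, chrom, pos,
#' allele1, allele2, then one dosage column per sample; missing = NA).
#'
#' @param prefix path prefix
#' @return \code{read_plink_text}: a \code{genotype_dataset}
#' @export
read_plink_text <- function(prefix) {
  f <- paste0(prefix, ".tgeno.tsv")
  tb <- utils::read.table(f, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  meta <- tb[, 1:5]
  dos <- t(as.matrix(tb[, -(1:5), drop = FALSE]))
  pheno <- NULL
  pfile <- paste0(prefix, ".pheno.tsv")
  if (file.exists(pfile)) pheno <- read_table(pfile)
  genotype_dataset(dos, meta, rownames(dos), pheno = pheno)
}

#' @rdname read_plink_text
#' @param dataset a \code{genotype_dataset}
#' @export
write_plink_text <- function(dataset, prefix) {
  tb <- cbind(dataset$variants[, c("id", "chrom", "pos", "allele1", "allele2")],
              as.data.frame(t(dataset$dosages), check.names = FALSE))
  utils::write.table(tb, paste0(prefix, ".tgeno.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$pheno))
    write_table(dataset$pheno, paste0(prefix, ".pheno.tsv"))
  invisible(prefix)
}

# ---- generic typed TSV -----------------------------------------------------

#' Read a tab-separated table with NA handling and optional schema check
#'
#' @param path file path
#' @param required character vector of column names that must be present
#' @return data.frame with typed columns; "NA" cells become missing
#' @export
read_table <- function(path, required = NULL) {
  if (!file.exists(path)) stop("missing file: ", path)
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(tb))
    if (length(miss)) stop("missing required column(s) in ", path, ": ",
                           paste(miss, collapse = ", "))
  }
  tb
}

#' Write a tab-separated table (deterministic formatting)
#'
#' @param x data.frame
#' @param path output path
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
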