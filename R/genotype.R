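#' Genotype matrices
#'
#' A `geno_matrix` bundles a subjects-by-variants minor-allele dosage matrix
#' (integers 0/1/2 or `NA` for missing) with per-variant metadata: variant id,
#' gene annotation (or `NA`), and -- once computed -- the folded minor allele
#' frequency in \[0, 0.5\].
#'
#' @param dosage integer matrix, subjects in rows (rownames = subject labels),
#'   variants in columns (colnames = variant ids); values in `{0, 1, 2, NA}`.
#' @param gene optional character vector of gene labels per variant.
#' @param maf optional numeric vector of per-variant minor allele frequencies.
#' @return a `geno_matrix`: a list with elements `dosage` and `meta`
#'   (data.frame `variant_id`, `gene`, `maf`).
#' @export
geno_matrix <- function(dosage, gene = NULL, maf = NULL) {
  if (!is.matrix(dosage)) stop_fmt("dosage must be a matrix")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    stop_fmt("dosage must carry subject rownames and variant colnames")
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop_fmt("dosages must be 0, 1, 2 or missing")
  }
  m <- ncol(dosage)
  if (is.null(gene)) gene <- rep(NA_character_, m)
  if (is.null(maf)) maf <- rep(NA_real_, m)
  stopifnot(length(gene) == m, length(maf) == m)
  if (any(!is.na(maf) & (maf < 0 | maf > 0.5))) {
    stop_fmt("maf values must lie in [0, 0.5]")
  }
  structure(list(dosage = dosage,
                 meta = data.frame(variant_id = colnames(dosage),
                                   gene = as.character(gene), maf = maf,
                                   stringsAsFactors = FALSE)),
            class = "geno_matrix")
}

#' @export
subject_labels.geno_matrix <- function(x) rownames(x$dosage)

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d subjects x %d variants (%d annotated to %d genes)\n",
              nrow(x$dosage), ncol(x$dosage), sum(!is.na(x$meta$gene)),
              length(unique(stats::na.omit(x$meta$gene)))))
  invisible(x)
}

n_variants <- function(g) ncol(g$dosage)

#' Minor allele frequencies
#'
#' Per variant, the allele frequency of the counted (dosage) allele over
#' non-missing subjects, folded into \[0, 0.5\]:
#' `maf = min(freq, 1 - freq)` with
#' `freq = sum(dosages) / (2 * n_nonmissing)`.
#'
#' `add_maf()` returns the `geno_matrix` with the frequencies written into
#' `meta$maf`; most downstream operations require this.
#'
#' @param g a `geno_matrix`.
#' @return `minor_allele_freq`: named numeric vector of folded MAFs.
#' @examples
#' d <- matrix(c(0, 0, 1, 1), 4, 1, dimnames = list(paste0("s", 1:4), "v1"))
#' minor_allele_freq(geno_matrix(d))   # 0.25
#' @export
minor_allele_freq <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  nn <- colSums(!is.na(g$dosage))
  if (any(nn == 0L)) {
    bad <- colnames(g$dosage)[nn == 0L]
    stop_fmt("variant(s) with all dosages missing: %s",
             paste(utils::head(bad, 5L), collapse = ", "))
  }
  freq <- colSums(g$dosage, na.rm = TRUE) / (2 * nn)
  maf <- pmin(freq, 1 - freq)
  names(maf) <- colnames(g$dosage)
  maf
}

#' @rdname minor_allele_freq
#' @export
add_maf <- function(g) {
  g$meta$maf <- unname(minor_allele_freq(g))
  g
}

require_maf <- function(g, op) {
  if (anyNA(g$meta$maf)) stop_fmt("%s requires computed MAFs; call add_maf() first", op)
  g
}

#' Filter variants by minor allele frequency
#'
#' Keeps variants whose folded MAF satisfies the requested bounds; order and
#' metadata are preserved. Strict flags select open (`>`/`<`) versus closed
#' (`>=`/`<=`) comparisons; the defaults are strict, matching the usual
#' "MAF < 0.01" rare-variant and "MAF > 0.05" common-marker selections.
#'
#' @param g a `geno_matrix` with MAFs computed.
#' @param min_maf,max_maf bounds (either may be `NULL` for unbounded).
#' @param strict_min,strict_max logical; strict (open) comparison at each bound.
#' @return the filtered `geno_matrix`.
#' @export
filter_variants <- function(g, min_maf = NULL, max_maf = NULL,
                            strict_min = TRUE, strict_max = TRUE) {
  require_maf(g, "filter_variants")
  if (!is.null(min_maf) && !is.null(max_maf) && min_maf > max_maf) {
    stop_fmt("min_maf (%g) exceeds max_maf (%g)", min_maf, max_maf)
  }
  keep <- rep(TRUE, n_variants(g))
  maf <- g$meta$maf
  if (!is.null(min_maf)) keep <- keep & (if (strict_min) maf > min_maf else maf >= min_maf)
  if (!is.null(max_maf)) keep <- keep & (if (strict_max) maf < max_maf else maf <= max_maf)
  subset_variants(g, which(keep))
}

subset_variants <- function(g, j) {
  geno_matrix(g$dosage[, j, drop = FALSE],
              gene = g$meta$gene[j], maf = g$meta$maf[j])
}

#' Sample variants without replacement
#'
#' Uniform, seeded, order-preserving sample of `count` variants; used to draw
#' the random marker panel behind the IBS matrix.
#'
#' @param g a `geno_matrix`.
#' @param count number of variants to keep.
#' @param seed integer seed making the draw reproducible.
#' @return a `geno_matrix` with `count` variants.
#' @export
sample_markers <- function(g, count, seed) {
  m <- n_variants(g)
  if (count > m) stop_fmt("cannot sample %d markers from %d available", count, m)
  j <- with_seed(seed, sort(sample.int(m, count)))
  subset_variants(g, j)
}

#' Identity-by-state similarity matrix
#'
#' Mean allele sharing between subject pairs:
#' \eqn{s(i,j) = \mathrm{mean}_v (1 - |g_{iv} - g_{jv}|/2)} over variants where
#' both dosages are observed (pairwise deletion). The diagonal is forced to 1
#' exactly. Used unscaled as the random-effect covariance in the IBS models.
#'
#' Computed via cross-products of indicator matrices, so it is exact and fast
#' for hundreds of subjects and thousands of markers.
#'
#' @param g a `geno_matrix` with at least one variant and MAFs computed.
#' @return a `relmat` of kind `"ibs"`.
#' @export
ibs_matrix <- function(g) {
  require_maf(g, "ibs_matrix")
  if (n_variants(g) < 1L) stop_fmt("ibs_matrix requires at least one variant")
  G <- g$dosage
  obs <- !is.na(G)
  G0 <- G
  G0[!obs] <- 0
  Mo <- matrix(as.numeric(obs), nrow(G), ncol(G))
  n_joint <- tcrossprod(Mo)
  if (any(n_joint == 0)) {
    pair <- which(n_joint == 0, arr.ind = TRUE)[1L, ]
    stop_fmt("subjects '%s' and '%s' share no jointly observed variants",
             rownames(G)[pair[1L]], rownames(G)[pair[2L]])
  }
  # sum_v |gi - gj| = sum (gi - gj)^2 - 2 * #(0,2) discordant pairs,
  # since |a-b| = (a-b)^2 for dosage differences 0/1 and 4 -> 2 for the 0-vs-2 case.
  sq <- G0^2
  S2 <- tcrossprod(sq, Mo)            # sum of gi^2 over jointly observed v
  cross <- tcrossprod(G0)
  Z0 <- matrix(as.numeric(obs & G0 == 0), nrow(G), ncol(G))
  Z2 <- matrix(as.numeric(G0 == 2), nrow(G), ncol(G))
  C02 <- tcrossprod(Z0, Z2)
  absdiff <- S2 + t(S2) - 2 * cross - 2 * (C02 + t(C02))
  s <- 1 - absdiff / (2 * n_joint)
  diag(s) <- 1
  s <- (s + t(s)) / 2
  dimnames(s) <- list(rownames(G), rownames(G))
  relmat(pmin(pmax(s, 0), 1), "ibs")
}

#' Principal-component covariates from genotypes
#'
#' Eigenstrat-style PCA: per variant, missing dosages are imputed with the
#' variant mean, the column is centred, and scaled by
#' \eqn{\sqrt{\hat p (1 - \hat p)}} with the shrunk frequency estimate
#' \eqn{\hat p = (1 + \sum g) / (2 + 2n)} over non-missing subjects. Variants
#' with zero variance after normalisation are dropped with a warning. The
#' subject-by-subject covariance of the normalised matrix is
#' eigendecomposed and the top `k` eigenvectors returned as population
#' structure covariates. Eigenvector signs are fixed by making the
#' largest-magnitude entry positive. No outlier-removal iterations are
#' performed.
#'
#' @param g a `geno_matrix` with MAFs computed.
#' @param k number of eigenvectors (\eqn{k \le \min(n - 1, m)}).
#' @return a `pc_covariates` object: an n-by-k matrix of eigenvectors with
#'   attributes `eigenvalues` (descending) and `variance_captured` (fraction
#'   of the sum of positive eigenvalues).
#' @export
pca_eigenvectors <- function(g, k) {
  require_maf(g, "pca_eigenvectors")
  G <- g$dosage
  n <- nrow(G)
  if (k < 1L || k > min(n - 1L, ncol(G))) {
    stop_fmt("k = %d outside valid range 1..%d", k, min(n - 1L, ncol(G)))
  }
  nn <- colSums(!is.na(G))
  sums <- colSums(G, na.rm = TRUE)
  mu <- sums / nn
  phat <- (1 + sums) / (2 + 2 * nn)
  sdv <- sqrt(phat * (1 - phat))
  M <- G
  miss <- is.na(M)
  if (any(miss)) M[miss] <- mu[col(M)][miss]
  M <- sweep(M, 2L, mu, "-")
  keep <- which(matrixStats_colSds(M) > 0 & sdv > 0)
  if (length(keep) < ncol(M)) {
    warn_fmt("dropping %d zero-variance variant(s) before PCA", ncol(M) - length(keep))
  }
  if (!length(keep)) stop_fmt("no variants left after dropping zero-variance columns")
  M <- sweep(M[, keep, drop = FALSE], 2L, sdv[keep], "/")
  C <- tcrossprod(M) / length(keep)
  ev <- eigen(C, symmetric = TRUE)
  if (k > sum(ev$values > 1e-12)) {
    stop_fmt("k = %d exceeds the available rank %d", k, sum(ev$values > 1e-12))
  }
  vec <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  rownames(vec) <- rownames(G)
  colnames(vec) <- paste0("PC", seq_len(k))
  pos <- ev$values[ev$values > 0]
  structure(vec,
            eigenvalues = ev$values[seq_len(k)],
            variance_captured = sum(ev$values[seq_len(k)]) / sum(pos),
            covariance = C,
            class = c("pc_covariates", "matrix"))
}

# colSds without extra deps
matrixStats_colSds <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  sqrt(colSums(sweep(m, 2L, mu, "-")^2) / (n - 1L))
}

#' @export
subject_labels.pc_covariates <- function(x) rownames(x)

#' @export
print.pc_covariates <- function(x, ...) {
  cat(sprintf("pc_covariates: %d subjects x %d eigenvectors (%.1f%% variance captured)\n",
              nrow(x), ncol(x), 100 * attr(x, "variance_captured")))
  invisible(x)
}

#' Read / write genotype dosage tables
#'
#' The dosage table is whitespace/TAB-delimited with a header row of variant
#' ids and the subject id in the first column. The optional variant annotation
#' TSV has columns `variant_id` and `gene`.
#'
#' @param path dosage table path.
#' @param annotation optional path to the variant-annotation TSV.
#' @return a `geno_matrix` (MAFs not yet computed).
#' @export
read_genotypes <- function(path, annotation = NULL) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(tab[[1L]])
  gene <- NULL
  if (!is.null(annotation)) {
    ann <- utils::read.table(annotation, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    gene <- ann$gene[match(colnames(m), ann$variant_id)]
  }
  geno_matrix(m, gene = gene)
}

#' @rdname read_genotypes
#' @param g a `geno_matrix` to write.
#' @export
write_genotypes <- function(g, path, annotation = NULL) {
  df <- data.frame(subject = rownames(g$dosage), g$dosage, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (!is.null(annotation)) {
    utils::write.table(g$meta[c("variant_id", "gene")], annotation, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE, na = "NA")
  }
  invisible(path)
}

#' Read dosages from a VCF file
#'
#' Optional reader for biallelic sites: the ALT-allele count is taken from the
#' GT field (`NA` for missing genotypes). Multi-allelic records are dropped
#' with a warning. Requires the `vcfR` package.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @return a `geno_matrix` of ALT dosages.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_fmt("read_genotypes_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- !grepl(",", vcfR::getALT(v), fixed = TRUE)
  if (!all(biallelic)) {
    warn_fmt("dropping %d multi-allelic VCF record(s)", sum(!biallelic))
    v <- v[biallelic, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & !grepl("\\.", x)
    alleles <- strsplit(gsub("\\|", "/", x[ok]), "/", fixed = FALSE)
    out[ok] <- vapply(alleles, function(a) sum(a == "1"), integer(1))
    out
  }
  m <- t(apply(gt, 1L, count_alt))
  dimnames(m) <- dimnames(gt)
  ids <- vcfR::getID(v)
  if (anyNA(ids)) ids <- paste0("var", seq_len(nrow(m)))
  rownames(m) <- ids
  geno_matrix(t(m))
}
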