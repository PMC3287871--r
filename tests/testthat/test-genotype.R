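mk_geno <- function(d, gene = NULL) {
  if (is.null(dim(d))) d <- matrix(d, ncol = 1)
  dimnames(d) <- list(sprintf("s%d", seq_len(nrow(d))),
                      sprintf("v%d", seq_len(ncol(d))))
  storage.mode(d) <- "integer"
  geno_matrix(d, gene = gene)
}

test_that("minor allele frequencies are folded and skip missing dosages", {
  expect_equal(unname(minor_allele_freq(mk_geno(c(0L, 0L, 1L, 1L)))), 0.25)
  expect_equal(unname(minor_allele_freq(mk_geno(c(2L, 2L, 2L)))), 0)  # folded from 1
  expect_equal(unname(minor_allele_freq(mk_geno(c(2L, 1L, 0L, NA)))), 0.5)
  g <- mk_geno(cbind(c(NA, NA), c(0L, 1L)))
  expect_error(minor_allele_freq(g), "all dosages missing.*v1")
})

test_that("MAF filters honour strict and closed bounds", {
  d <- matrix(0L, 2, 3, dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  g <- geno_matrix(d, maf = c(0.005, 0.02, 0.2))
  expect_equal(filter_variants(g, min_maf = 0.10)$meta$variant_id, "c")
  expect_equal(filter_variants(g, max_maf = 0.01)$meta$variant_id, "a")
  expect_equal(filter_variants(g, max_maf = 0.02, strict_max = FALSE)$meta$variant_id,
               c("a", "b"))
  expect_equal(filter_variants(g)$meta$variant_id, c("a", "b", "c"))
  expect_error(filter_variants(g, min_maf = 0.2, max_maf = 0.1), "exceeds")
})

test_that("marker sampling is seeded, order-preserving and bounded", {
  g <- rand_geno(8, 30, seed = 2, miss = 0)
  expect_equal(sample_markers(g, 30, seed = 1)$meta$variant_id, g$meta$variant_id)
  s1 <- sample_markers(g, 10, seed = 9)
  s2 <- sample_markers(g, 10, seed = 9)
  expect_identical(s1$meta$variant_id, s2$meta$variant_id)
  expect_true(all(s1$meta$variant_id %in% g$meta$variant_id))
  expect_error(sample_markers(g, 31, seed = 1), "cannot sample")
})

test_that("IBS matches hand values and forces a unit diagonal", {
  g <- add_maf(mk_geno(rbind(c(0L, 2L), c(2L, 0L))))
  s <- ibs_matrix(g)
  expect_equal(s["s1", "s2"], 0)           # maximal dissimilarity
  g2 <- add_maf(mk_geno(rbind(c(1L, 1L), c(1L, 1L))))
  expect_equal(ibs_matrix(g2)["s1", "s2"], 1)
  g3 <- add_maf(mk_geno(rbind(c(1L, 1L), c(0L, 2L))))
  expect_equal(ibs_matrix(g3)["s1", "s2"], 0.5)
  g4 <- add_maf(mk_geno(rbind(c(1L, NA), c(0L, 2L))))
  expect_equal(unname(diag(ibs_matrix(g4))), c(1, 1))
})

test_that("IBS equals the double-loop oracle and is allele-label invariant", {
  for (seed in 1:5) {
    g <- rand_geno(10, 20, seed = seed, miss = 0.15)
    s <- ibs_matrix(g)
    expect_equal(unclass(s), oracle_ibs(g$dosage), ignore_attr = TRUE,
                 tolerance = 1e-12)
    flipped <- g
    flipped$dosage <- 2L - g$dosage
    flipped <- add_maf(flipped)
    expect_equal(unclass(ibs_matrix(flipped)), unclass(s), tolerance = 1e-12)
  }
})

test_that("a subject pair with no jointly observed variants is an error", {
  d <- rbind(c(1L, NA), c(NA, 2L))
  dimnames(d) <- list(c("s1", "s2"), c("v1", "v2"))
  g <- geno_matrix(d, maf = c(0.1, 0.1))
  expect_error(ibs_matrix(g), "s1.*s2|s2.*s1")
})

test_that("gene-dropped parent-offspring pairs share more IBS than unrelated pairs", {
  cfg <- sim_config(n_families = 2, generations = 3, n_genes = 0,
                    n_common_markers = 500, subpop_split = FALSE,
                    n_replicates = 1, seed = 4)
  ped <- simulate_pedigree(cfg)
  g <- add_maf(gene_drop(ped, cfg))
  s <- ibs_matrix(g)
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$id
  po <- cbind(idx[ped$id[!is.na(ped$father)]], idx[ped$father[!is.na(ped$father)]])
  fam <- ped$fid[idx]
  unrel <- which(outer(fam, fam, "!="), arr.ind = TRUE)
  expect_gt(mean(s[po]), mean(s[unrel]))
})

test_that("PCA eigenvectors are orthonormal and reconstruct the covariance", {
  g <- rand_geno(25, 80, seed = 11, miss = 0.05)
  pcs <- pca_eigenvectors(g, 5)
  gram <- crossprod(unclass(pcs))
  expect_equal(gram, diag(5), ignore_attr = TRUE, tolerance = 1e-8)
  C <- attr(pcs, "covariance")
  ev <- attr(pcs, "eigenvalues")
  for (j in 1:5) {
    expect_lt(max(abs(C %*% pcs[, j] - ev[j] * pcs[, j])), 1e-8)
  }
  expect_true(all(diff(ev) <= 1e-12))
  vc <- attr(pcs, "variance_captured")
  expect_true(vc > 0 && vc <= 1)
})

test_that("the leading eigenvector separates two diverged subpopulations", {
  set.seed(21)
  n <- 40
  m <- 300
  pop <- rep(1:2, each = n / 2)
  p1 <- runif(m, 0.1, 0.9)
  shift <- runif(m, -0.2, 0.2)
  p2 <- pmin(pmax(p1 + shift, 0.05), 0.95)
  D <- t(vapply(pop, function(g) {
    rbinom(m, 2, if (g == 1) p1 else p2)
  }, integer(m)))
  dimnames(D) <- list(sprintf("s%d", 1:n), sprintf("v%d", 1:m))
  storage.mode(D) <- "integer"
  pcs <- pca_eigenvectors(add_maf(geno_matrix(D)), 2)
  pc1 <- pcs[, 1]
  # sign-clustering: the two groups sit on opposite sides of the PC1 origin
  expect_true(abs(mean(sign(pc1[pop == 1])) - mean(sign(pc1[pop == 2]))) > 1.5)
})

test_that("zero-variance variants are dropped with a warning and k is bounded", {
  d <- cbind(c(0L, 0L, 0L, 0L), c(0L, 1L, 2L, 1L), c(1L, 2L, 0L, 1L))
  dimnames(d) <- list(sprintf("s%d", 1:4), sprintf("v%d", 1:3))
  g <- add_maf(geno_matrix(d))
  expect_warning(pcs <- pca_eigenvectors(g, 2), "zero-variance")
  expect_equal(ncol(pcs), 2)
  expect_error(pca_eigenvectors(g, 4), "outside valid range")
})

test_that("genotype tables round-trip through the TSV writer and reader", {
  g <- rand_geno(6, 9, seed = 3, miss = 0.1)
  f <- withr::local_tempfile(fileext = ".tsv")
  a <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, f, annotation = a)
  back <- read_genotypes(f, annotation = a)
  expect_identical(back$dosage, g$dosage)
  expect_identical(back$meta$gene, g$meta$gene)
})

test_that("dosages can be read from a VCF (biallelic GT field)", {
  skip_if_not_installed("vcfR")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t0|1\t./.\t0/0"), f)
  g <- read_genotypes_vcf(f)
  expect_equal(unname(g$dosage[, "v1"]), c(0L, 1L, 2L))
  expect_equal(unname(g$dosage[, "v2"]), c(1L, NA, 0L))
})
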