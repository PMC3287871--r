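test_that("pedigree simulation matches the template and is seed-deterministic", {
  cfg <- sim_config(n_families = 1, generations = 2, offspring_range = 2L,
                    offspring_prob = 1, n_genes = 1, n_common_markers = 10,
                    n_replicates = 1, seed = 5)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 4)                       # couple + 2 children
  phi <- kinship_matrix(ped)
  sibs <- ped$id[!is.na(ped$father)]
  expect_equal(phi[sibs[1], sibs[2]], 0.25)
  expect_identical(simulate_pedigree(cfg), ped)

  cfg8 <- sim_config(seed = 5)
  ped8 <- simulate_pedigree(cfg8)
  expect_equal(length(unique(ped8$fid)), 8)
  expect_true(nrow(ped8) > 450 && nrow(ped8) < 950)
  # between-family kinship exactly 0
  phi8 <- kinship_matrix(ped8)
  f1 <- ped8$fid == ped8$fid[1]
  expect_equal(max(abs(phi8[f1, !f1])), 0)
})

test_that("an unreachable target size range is a configuration error", {
  cfg <- sim_config(n_families = 1, generations = 2, offspring_range = 2L,
                    offspring_prob = 1, target_size_range = c(100, 200), seed = 5)
  expect_error(simulate_pedigree(cfg), "outside target range")
})

test_that("gene dropping is Mendelian-consistent at every variant", {
  cfg <- sim_config(n_families = 2, generations = 3, n_genes = 5,
                    rare_maf_range = c(0.05, 0.3), n_common_markers = 60,
                    n_replicates = 1, seed = 6)
  ped <- simulate_pedigree(cfg)
  g <- gene_drop(ped, cfg)
  D <- g$dosage
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$id
  kids <- which(!is.na(ped$father))
  for (i in kids) {
    df <- D[idx[ped$father[i]], ]
    dm <- D[idx[ped$mother[i]], ]
    lo <- (df == 2) + (dm == 2)
    hi <- (df >= 1) + (dm >= 1)
    expect_true(all(D[i, ] >= lo & D[i, ] <= hi))
  }
})

test_that("founder MAF 0 gives all-zero dosages; realised MAF tracks founder MAF", {
  cfg0 <- sim_config(n_families = 1, generations = 3, n_genes = 2,
                     rare_maf_range = c(0, 0), n_common_markers = 0,
                     n_replicates = 1, seed = 7)
  g0 <- gene_drop(simulate_pedigree(cfg0), cfg0)
  expect_true(all(g0$dosage == 0))

  cfg <- sim_config(n_families = 8, n_genes = 100, variants_per_gene = c(5L, 5L),
                    rare_maf_range = c(0.005, 0.005), n_common_markers = 0,
                    subpop_split = FALSE, n_replicates = 1, seed = 8)
  ped <- simulate_pedigree(cfg)
  g <- add_maf(gene_drop(ped, cfg))
  founders <- is_founder_rows(ped)
  freq <- colMeans(g$dosage[founders, , drop = FALSE]) / 2
  # averaged over 500 variants, the founder-sample frequency concentrates
  # near the generating value
  expect_equal(mean(freq), 0.005, tolerance = 0.25)
})

test_that("trait variance decomposes into fixed, polygenic and residual parts", {
  causal <- data.frame(gene = "G001", beta = 1.2)
  st <- small_study(seed = 9, n_replicates = 150, causal = causal, h2 = 0.4)
  cfg <- st$config
  sigma2_g <- 0.4 / 0.6 * cfg$sigma2_e
  x <- collapse_gene(st$genotypes, "G001", cfg$maf_threshold)$indicator
  expected <- 1.2^2 * var(x) + sigma2_g * 1 + cfg$sigma2_e
  observed <- mean(apply(st$traits, 2, var))
  expect_equal(observed, expected, tolerance = 0.15)
})

test_that("trait covariance follows the pedigree: iid when h2=0, phi-scaled otherwise", {
  st0 <- small_study(seed = 10, n_replicates = 250, h2 = 0)
  ped <- st0$pedigree
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$id
  kids <- which(!is.na(ped$father))
  po <- cbind(idx[ped$father[kids]], kids)
  cov_po0 <- mean(vapply(seq_len(nrow(po)), function(r) {
    cov(st0$traits[po[r, 1], ], st0$traits[po[r, 2], ])
  }, 0))
  expect_equal(cov_po0, 0, tolerance = 0.06)

  st <- small_study(seed = 10, n_replicates = 250, h2 = 0.5)
  sigma2_g <- 0.5 / 0.5 * st$config$sigma2_e
  cov_po <- mean(vapply(seq_len(nrow(po)), function(r) {
    cov(st$traits[po[r, 1], ], st$traits[po[r, 2], ])
  }, 0))
  expect_equal(cov_po, 0.5 * sigma2_g, tolerance = 0.15)
})

test_that("a causal gene with zero carriers warns and stays in the truth table", {
  cfg <- sim_config(n_families = 1, generations = 2, offspring_range = 2L,
                    offspring_prob = 1, n_genes = 2, rare_maf_range = c(0, 0),
                    n_common_markers = 0, n_replicates = 2,
                    causal_genes = data.frame(gene = "G001", beta = 1), seed = 11)
  ped <- simulate_pedigree(cfg)
  geno <- add_maf(gene_drop(ped, cfg))
  expect_warning(st <- simulate_traits(ped, geno, cfg), "zero carriers")
  expect_true(st$truth$causal[st$truth$gene == "G001"])
  expect_equal(st$truth$carriers[st$truth$gene == "G001"], 0L)
})

test_that("studies round-trip through write_study/read_study field by field", {
  causal <- data.frame(gene = "G002", beta = 0.7)
  st <- small_study(seed = 12, n_replicates = 5, causal = causal)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(all(file.exists(file.path(dir, c("study.fam", "genotypes.tsv",
                                               "variants.tsv", "truth.tsv",
                                               "config.yaml")))))
  expect_equal(length(list.files(file.path(dir, "traits"))), 5)
  back <- read_study(dir)
  expect_equal(as.data.frame(back$pedigree), as.data.frame(st$pedigree),
               ignore_attr = TRUE)
  expect_identical(back$genotypes$dosage, st$genotypes$dosage)
  expect_equal(back$genotypes$meta, st$genotypes$meta)
  expect_identical(back$traits, st$traits)
  expect_equal(back$truth, st$truth)
  expect_equal(back$config$causal_genes, st$config$causal_genes)
  expect_equal(unclass(back$config)[setdiff(names(back$config), "causal_genes")],
               unclass(st$config)[setdiff(names(st$config), "causal_genes")])
})

test_that("the whole simulation is reproducible from the master seed", {
  a <- small_study(seed = 13, n_replicates = 3)
  b <- small_study(seed = 13, n_replicates = 3)
  expect_identical(a$traits, b$traits)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  c <- small_study(seed = 14, n_replicates = 3)
  expect_false(identical(a$traits, c$traits))
})
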