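mk_design <- function(ind, gene = "G1") {
  ind <- as.integer(ind)
  names(ind) <- sprintf("s%02d", seq_along(ind))
  structure(list(gene = gene, indicator = ind,
                 carrier_count = sum(ind), n_rare_variants = 1L,
                 maf_threshold = 0.01,
                 testable = sum(ind) > 0 && sum(ind) < length(ind)),
            class = "collapsed_design")
}

mk_pcs <- function(n, k, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(n * k), n, k)))
  rownames(q) <- sprintf("s%02d", seq_len(n))
  colnames(q) <- paste0("PC", seq_len(k))
  q
}

test_that("model specs encode the six methods' adjustment structure", {
  expect_equal(model_spec("REG")$covariance_kind, "none")
  expect_equal(model_spec("PC")$n_pcs, 10L)
  expect_equal(model_spec("KIN")$covariance_kind, "relationship_2phi")
  expect_equal(model_spec("PC-IBS")$covariance_kind, "ibs")
  expect_error(model_spec("KIN", n_pcs = 5), "does not use PCs")
  expect_error(model_spec("PC", n_pcs = 0), "requires n_pcs")
})

test_that("fixed designs have intercept, X, then PCs, and flag degenerate X", {
  x <- mk_design(c(1, 0, 0, 1, 0, 0, 0, 0))
  F <- build_fixed_design(x)
  expect_equal(ncol(F), 2)
  expect_true(attr(F, "testable"))
  q <- mk_pcs(8, 3)
  expect_equal(ncol(build_fixed_design(x, q)), 5)
  expect_false(attr(build_fixed_design(mk_design(rep(0, 8))), "testable"))
  # X identical to a covariate column adds no rank: untestable
  q2 <- cbind(q, X2 = scale(as.numeric(x$indicator), scale = FALSE)[, 1])
  expect_false(attr(build_fixed_design(x, q2), "testable"))
})

test_that("OLS recovers a hand-computed slope and nails the perfect fit", {
  x <- c(0, 1, 0, 1)
  y <- c(0, 1, 0.5, 1.5)
  F <- cbind(intercept = 1, X = x)
  fit <- ols_test(y, F)
  expect_equal(fit$beta, 1)
  expect_equal(fit$df, 2)
  # cross-check against lm()
  lmfit <- summary(lm(y ~ x))$coefficients
  expect_equal(fit$se, lmfit["x", "Std. Error"])
  expect_equal(fit$p_value, lmfit["x", "Pr(>|t|)"])
  y2 <- 3 * c(0, 1, 0, 1, 1, 0)
  fit2 <- ols_test(y2, cbind(1, c(0, 1, 0, 1, 1, 0)))
  expect_equal(fit2$beta, 3)
  expect_lt(fit2$p_value, 1e-10)
})

test_that("the mixed model collapses to OLS when K is the identity", {
  set.seed(31)
  ids <- sprintf("s%02d", 1:30)
  K <- identity_relmat(ids)
  for (rep in 1:10) {
    x <- mk_design(rbinom(30, 1, 0.3))
    y <- rnorm(30) + 0.3 * x$indicator
    names(y) <- ids
    F <- build_fixed_design(x)
    vc <- reml_fit(y, F, K)
    mixed <- gls_wald_test(y, F, vc, K)
    ols <- ols_test(y, F)
    expect_equal(mixed$p_value, ols$p_value, tolerance = 1e-8)
    expect_equal(mixed$beta, ols$beta, tolerance = 1e-8)
  }
})

test_that("the restricted likelihood at the optimum dominates the whole grid", {
  set.seed(32)
  g <- rand_geno(25, 40, seed = 32, miss = 0)
  K <- ibs_matrix(g)
  y <- rnorm(25)
  names(y) <- rownames(g$dosage)
  F <- cbind(intercept = rep(1, 25), X = rbinom(25, 1, 0.4))
  vc <- reml_fit(y, F, K)
  expect_true(all(vc$reml_loglik >= vc$grid_loglik - 1e-9))
  expect_true(vc$sigma2_g >= 0)
  expect_true(vc$sigma2_e > 0)
  expect_equal(vc$delta, vc$sigma2_e / vc$sigma2_g)
})

test_that("the restricted likelihood is invariant to subject permutation", {
  set.seed(33)
  st <- small_study(seed = 33, n_replicates = 1)
  K <- relationship_matrix(kinship_matrix(st$pedigree))
  n <- nrow(st$pedigree)
  y <- st$traits[, 1]
  F <- cbind(intercept = rep(1, n), X = rbinom(n, 1, 0.2))
  vc <- reml_fit(y, F, K)
  perm <- sample(n)
  Kp <- relmat(unclass(K)[perm, perm], "relationship_2phi")
  vcp <- reml_fit(y[perm], F[perm, , drop = FALSE], Kp)
  expect_equal(vcp$reml_loglik, vc$reml_loglik, tolerance = 1e-8)
  expect_equal(vcp$delta, vc$delta, tolerance = 1e-4)
})

test_that("the spectral REML agrees with a dense-matrix optimizer on small problems", {
  # quick version of the full acceptance sweep: a handful of n <= 50 problems
  set.seed(34)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    A <- matrix(rnorm(n * 80), n, 80)
    K <- tcrossprod(A) / 80
    d <- sqrt(diag(K))
    K <- K / tcrossprod(d)
    diag(K) <- 1
    ids <- sprintf("s%02d", 1:n)
    dimnames(K) <- list(ids, ids)
    F <- cbind(intercept = 1, X = rbinom(n, 1, 0.3))
    L <- chol(2 * K + diag(1, n))
    y <- drop(crossprod(L, rnorm(n)))
    names(y) <- ids
    Kr <- relmat(K, "relationship_2phi")
    vc <- reml_fit(y, F, Kr)
    orc <- oracle_reml(y, F, unclass(Kr))
    expect_equal(vc$reml_loglik, orc$loglik, tolerance = 1e-4)
    expect_lt(abs(vc$delta - orc$delta) / orc$delta, 0.01)
  }
})

test_that("run_method dispatches per method and annotates results", {
  st <- small_study(seed = 35, n_replicates = 1)
  mats <- study_matrices(st, ibs_markers = 200, seed = 35)
  geno <- st$genotypes
  designs <- collapse_all(geno, 0.15)
  x <- designs[[which(vapply(designs, `[[`, TRUE, "testable"))[1]]]
  y <- st$traits[, 1]
  relmats <- list(relationship_2phi = mats$relationship_2phi, ibs = mats$ibs)
  res <- lapply(assoc_methods(), run_method, x = x, y = y, q = mats$pcs,
                relmats = relmats)
  expect_equal(vapply(res, `[[`, "", "method"), assoc_methods())
  expect_true(all(vapply(res, `[[`, "", "gene") == x$gene))
  expect_equal(unique(vapply(res, `[[`, 0L, "carrier_count")), x$carrier_count)
  expect_true(all(vapply(res, `[[`, "", "status") == "ok"))
  # PC-KIN carries intercept + X + 10 PCs
  F <- build_fixed_design(x, mats$pcs)
  expect_equal(ncol(F), 12)
  expect_error(run_method("KIN", x, y, relmats = list()), "KIN requires")
})

test_that("run_all scans the gene-by-method product and records untestables", {
  st <- small_study(seed = 36, n_replicates = 1, n_genes = 5)
  mats <- study_matrices(st, ibs_markers = 200, seed = 36)
  designs <- collapse_all(st$genotypes, 0.15)
  y <- st$traits[, 1]
  relmats <- list(relationship_2phi = mats$relationship_2phi, ibs = mats$ibs)
  specs <- list(model_spec("REG"), model_spec("KIN"), model_spec("PC-IBS"))
  res <- run_all(specs, designs, y, q = mats$pcs, relmats = relmats)
  expect_equal(nrow(res), 3 * length(designs))
  untestable <- names(designs)[!vapply(designs, `[[`, TRUE, "testable")]
  expect_setequal(res$gene[res$status == "untestable"],
                  res$gene[res$gene %in% untestable])
  res2 <- run_all(specs, designs, y, q = mats$pcs, relmats = relmats)
  expect_identical(res, res2)
})

test_that("null p-values from the KIN model are approximately uniform", {
  # traits are pure familial noise; the collapsed X is a real (null) gene
  st <- small_study(seed = 37, n_replicates = 40, n_genes = 4)
  K <- relationship_matrix(kinship_matrix(st$pedigree))
  designs <- Filter(function(d) d$testable, collapse_all(st$genotypes, 0.15))
  res <- assoc_scan(designs, st$traits, methods = "KIN",
                    relmats = list(relationship_2phi = K))
  ks <- suppressWarnings(ks.test(res$p_value[res$status == "ok"], "punif"))
  expect_gt(ks$p.value, 0.01)
})
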