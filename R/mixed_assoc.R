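#' Model specifications for the six association methods
#'
#' The unified mixed model is `Y = Xb + Qv + Zu + e`, where `X` is the
#' collapsed rare-variant carrier indicator of the gene under test, `Q` holds
#' optional principal-component covariates for population structure, and `u`
#' is a random polygenic effect (one per individual, `Z = I`) whose covariance
#' structure is set by a relatedness matrix. The six methods differ only in
#' which adjustments are present:
#'
#' | method | PCs in Q | covariance of u        |
#' |--------|----------|------------------------|
#' | REG    | none     | none (plain regression)|
#' | PC     | top k    | none                   |
#' | KIN    | none     | pedigree `2 * kinship` |
#' | PC-KIN | top k    | pedigree `2 * kinship` |
#' | IBS    | none     | marker IBS (unscaled)  |
#' | PC-IBS | top k    | marker IBS (unscaled)  |
#'
#' @param method one of `"REG"`, `"PC"`, `"KIN"`, `"PC-KIN"`, `"IBS"`,
#'   `"PC-IBS"`.
#' @param n_pcs number of principal-component covariates; defaults to 10 for
#'   the PC methods and must be 0 for the others.
#' @return a `model_spec` list with `method`, `n_pcs`, `covariance_kind`.
#' @export
model_spec <- function(method, n_pcs = NULL) {
  method <- match.arg(method, assoc_methods())
  uses_pc <- method %in% c("PC", "PC-KIN", "PC-IBS")
  if (is.null(n_pcs)) n_pcs <- if (uses_pc) 10L else 0L
  if (uses_pc && n_pcs < 1L) stop_fmt("method %s requires n_pcs > 0", method)
  if (!uses_pc && n_pcs != 0L) stop_fmt("method %s does not use PCs", method)
  kind <- switch(method,
                 REG = , PC = "none",
                 KIN = , `PC-KIN` = "relationship_2phi",
                 IBS = , `PC-IBS` = "ibs")
  structure(list(method = method, n_pcs = as.integer(n_pcs),
                 covariance_kind = kind),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
assoc_methods <- function() c("REG", "PC", "KIN", "PC-KIN", "IBS", "PC-IBS")

#' Fixed-effect design matrix for a collapsed gene
#'
#' Columns are intercept, the carrier indicator X, then any PC covariates.
#' A constant X (no carriers or all carriers) marks the design untestable;
#' PC columns that are collinear with the rest of the design are dropped
#' with a warning; X collinear with the covariates also marks the design
#' untestable.
#'
#' @param x a `collapsed_design`.
#' @param q optional `pc_covariates` (or numeric matrix) with matching
#'   subject labels.
#' @return numeric design matrix with attribute `testable`.
#' @export
build_fixed_design <- function(x, q = NULL) {
  ind <- x$indicator
  F <- cbind(intercept = 1, X = as.numeric(ind))
  rownames(F) <- names(ind)
  if (!is.null(q)) {
    check_subjects(names(ind), rownames(q), "collapsed design", "PC covariates")
    Q <- unclass(q)
    attributes(Q)[setdiff(names(attributes(Q)), c("dim", "dimnames"))] <- NULL
    base <- cbind(1, Q)
    qrq <- qr(base)
    if (qrq$rank < ncol(base)) {
      keep <- sort(qrq$pivot[seq_len(qrq$rank)])
      keep <- setdiff(keep, 1L) - 1L
      warn_fmt("dropping %d collinear PC column(s)", ncol(Q) - length(keep))
      Q <- Q[, keep, drop = FALSE]
    }
    F <- cbind(F, Q)
  }
  testable <- isTRUE(x$testable)
  if (testable && ncol(F) > 2L) {
    r_full <- qr(F)$rank
    r_wo_x <- qr(F[, -2L, drop = FALSE])$rank
    if (r_full < ncol(F)) {
      testable <- r_full > r_wo_x   # X adds no rank: untestable
      if (r_wo_x < ncol(F) - 1L) stop_fmt("fixed design rank-deficient beyond X")
    }
  }
  attr(F, "testable") <- testable
  F
}

#' Spectral decomposition of a relatedness matrix
#'
#' One eigendecomposition of the random-effect covariance structure `K` is
#' shared by every REML fit that uses it (K is the same for all genes and
#' trait replicates of a study). Eigenvalues below 0 but above `-1e-8` are
#' clipped to 0; matrices indefinite beyond that tolerance are rejected.
#'
#' @param k a `relmat` (or an already-decomposed `relmat_eigen`, returned
#'   unchanged).
#' @return a `relmat_eigen` list: `U` (eigenvectors), `d` (eigenvalues,
#'   clipped), `labels`, `kind`.
#' @export
decompose_relmat <- function(k) {
  if (inherits(k, "relmat_eigen")) return(k)
  if (!inherits(k, "relmat")) stop_fmt("expected a relmat or relmat_eigen")
  ev <- eigen(unclass(k), symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop_fmt("relatedness matrix is not positive semidefinite (min eigenvalue %.3e)",
             min(ev$values))
  }
  structure(list(U = ev$vectors, d = pmax(ev$values, 0),
                 labels = rownames(k), kind = relmat_kind(k)),
            class = "relmat_eigen")
}

#' @export
subject_labels.relmat_eigen <- function(x) x$labels

# ---- REML internals --------------------------------------------------------
#
# Model: Var(y) = sigma2_g * K + sigma2_e * I, delta = sigma2_e / sigma2_g.
# With K = U diag(d) U', work in rotated coordinates yt = U'y, Ft = U'F where
# the covariance is diagonal: sigma2_g * (d + delta). The restricted
# log-likelihood profiled over sigma2_g is
#   l(delta) = -1/2 [ (n-p)(log(2 pi s2) + 1) + sum log(d + delta)
#                     + log det(F' W F) - log det(F'F) ],
# with W = diag(1/(d + delta)) and s2 = r' W r / (n - p) the REML estimate of
# sigma2_g at that delta. Maximised by a grid over log10(delta) followed by
# Brent refinement in each local-maximum bracket.

reml_ll_scalar <- function(lg, yt, Ft, d, logdetFF) {
  delta <- 10^lg
  w <- 1 / (d + delta)
  n <- length(yt)
  p <- ncol(Ft)
  Fw <- Ft * w
  A <- crossprod(Ft, Fw)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  fy <- crossprod(Fw, yt)
  b <- backsolve(ch, forwardsolve(t(ch), fy))
  R <- sum(w * yt^2) - sum(b * fy)
  if (!is.finite(R) || R <= 0) return(-Inf)
  -0.5 * ((n - p) * (log(2 * pi * R / (n - p)) + 1) +
            sum(log(d + delta)) + 2 * sum(log(diag(ch))) - logdetFF)
}

# Per-gene precomputation shared across trait replicates: the weight matrix
# over the delta grid and the p x p cross-products F' W F at every grid point.
reml_grid_parts <- function(Ft, d, log10_grid) {
  deltas <- 10^log10_grid
  Dd <- outer(d, deltas, "+")
  W <- 1 / Dd
  sumlog <- colSums(log(Dd))
  p <- ncol(Ft)
  pr <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  P <- Ft[, pr[, 1L], drop = FALSE] * Ft[, pr[, 2L], drop = FALSE]
  FWF <- crossprod(P, W)                      # npairs x G
  list(W = W, sumlog = sumlog, FWF = FWF, pairs = pr, p = p,
       n = nrow(Ft), log10_grid = log10_grid)
}

# Grid restricted log-likelihoods for one rotated trait vector.
reml_grid_ll <- function(parts, Ft, yt, logdetFF) {
  W <- parts$W
  n <- parts$n
  p <- parts$p
  G <- ncol(W)
  FWy <- crossprod(Ft * yt, W)               # p x G
  yWy <- colSums(W * yt^2)
  if (p == 2L) {
    a11 <- parts$FWF[1L, ]
    a12 <- parts$FWF[2L, ]
    a22 <- parts$FWF[3L, ]
    det <- a11 * a22 - a12^2
    b1 <- (a22 * FWy[1L, ] - a12 * FWy[2L, ]) / det
    b2 <- (a11 * FWy[2L, ] - a12 * FWy[1L, ]) / det
    R <- yWy - b1 * FWy[1L, ] - b2 * FWy[2L, ]
    logdetA <- log(det)
    bad <- !is.finite(R) | R <= 0 | det <= 0
  } else {
    R <- numeric(G)
    logdetA <- numeric(G)
    bad <- logical(G)
    A <- matrix(0, p, p)
    ij <- parts$pairs
    for (g in seq_len(G)) {
      A[cbind(ij[, 1L], ij[, 2L])] <- parts$FWF[, g]
      A[cbind(ij[, 2L], ij[, 1L])] <- parts$FWF[, g]
      ch <- tryCatch(chol(A), error = function(e) NULL)
      if (is.null(ch)) {
        bad[g] <- TRUE
        next
      }
      b <- backsolve(ch, forwardsolve(t(ch), FWy[, g]))
      R[g] <- yWy[g] - sum(b * FWy[, g])
      logdetA[g] <- 2 * sum(log(diag(ch)))
      if (!is.finite(R[g]) || R[g] <= 0) bad[g] <- TRUE
    }
  }
  ll <- -0.5 * ((n - p) * (log(2 * pi * R / (n - p)) + 1) +
                  parts$sumlog + logdetA - logdetFF)
  ll[bad] <- -Inf
  ll
}

# Full 1-D REML for one rotated problem: grid + Brent refinement of every
# local-maximum bracket; returns the global maximiser.
reml_fit_core <- function(yt, Ft, d, log10_grid, logdetFF, parts = NULL) {
  if (is.null(parts)) parts <- reml_grid_parts(Ft, d, log10_grid)
  ll <- reml_grid_ll(parts, Ft, yt, logdetFF)
  G <- length(ll)
  f <- function(lg) reml_ll_scalar(lg, yt, Ft, d, logdetFF)
  locmax <- which(ll >= c(-Inf, ll[-G]) & ll >= c(ll[-1L], -Inf) & is.finite(ll))
  best_lg <- log10_grid[which.max(ll)]
  best_ll <- max(ll)
  for (i in locmax) {
    lo <- log10_grid[max(i - 1L, 1L)]
    hi <- log10_grid[min(i + 1L, G)]
    if (hi > lo) {
      opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
      if (opt$objective > best_ll) {
        best_ll <- opt$objective
        best_lg <- opt$maximum
      }
    }
  }
  delta <- 10^best_lg
  w <- 1 / (d + delta)
  Fw <- Ft * w
  A <- crossprod(Ft, Fw)
  ch <- chol(A)
  fy <- crossprod(Fw, yt)
  b <- backsolve(ch, forwardsolve(t(ch), fy))
  R <- sum(w * yt^2) - sum(b * fy)
  n <- length(yt)
  p <- ncol(Ft)
  s2g <- R / (n - p)
  step <- if (G > 1L) log10_grid[2L] - log10_grid[1L] else 0
  list(sigma2_g = s2g, sigma2_e = delta * s2g, delta = delta,
       reml_loglik = best_ll, grid_loglik = ll,
       boundary = best_lg <= log10_grid[1L] + step / 2 ||
         best_lg >= log10_grid[G] - step / 2,
       beta = drop(b), cov_unscaled = chol2inv(ch), n = n, p = p)
}

#' REML variance components for the polygenic mixed model
#'
#' Fits `Var(y) = sigma2_g * K + sigma2_e * I` by restricted maximum
#' likelihood, profiling the likelihood down to the single variance ratio
#' `delta = sigma2_e / sigma2_g` via one spectral decomposition of `K`
#' (EMMA-style). The ratio is searched on a `log10(delta)` grid (default
#' \[-10, 10\] at 0.2 spacing) and refined by Brent's method in each
#' local-maximum bracket; the global restricted-likelihood maximiser is
#' returned. A solution at a grid end is flagged `boundary = TRUE`, not an
#' error.
#'
#' @param y numeric trait vector (named by subject).
#' @param fixed fixed-effect design matrix (from [build_fixed_design()]).
#' @param k a `relmat` or cached `relmat_eigen` defining the covariance
#'   structure of the polygenic effect.
#' @param delta_grid numeric `c(lo, hi, step)` for the `log10(delta)` grid.
#' @return a `variance_components` list: `sigma2_g`, `sigma2_e`, `delta`,
#'   `reml_loglik`, `boundary`, `n`, `p`, plus the grid log-likelihoods.
#' @export
reml_fit <- function(y, fixed, k, delta_grid = c(-10, 10, 0.2)) {
  ed <- decompose_relmat(k)
  if (!is.null(names(y))) check_subjects(names(y), ed$labels, "trait", "relatedness matrix")
  if (length(y) != nrow(fixed)) stop_fmt("trait and design dimensions disagree")
  if (length(y) <= ncol(fixed)) stop_fmt("need n > number of fixed-effect columns")
  yt <- drop(crossprod(ed$U, y))
  Ft <- crossprod(ed$U, fixed)
  logdetFF <- 2 * sum(log(diag(chol(crossprod(fixed)))))
  grid <- seq(delta_grid[1L], delta_grid[2L], by = delta_grid[3L])
  fit <- reml_fit_core(yt, Ft, ed$d, grid, logdetFF)
  structure(fit[c("sigma2_g", "sigma2_e", "delta", "reml_loglik", "boundary",
                  "grid_loglik", "n", "p")],
            log10_grid = grid, class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("REML variance components: sigma2_g = %.4g, sigma2_e = %.4g (delta = %.4g)%s\n",
              x$sigma2_g, x$sigma2_e, x$delta,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

assoc_result <- function(gene = NA_character_, method = NA_character_,
                         beta = NA_real_, se = NA_real_, statistic = NA_real_,
                         df = NA_real_, p_value = NA_real_,
                         carrier_count = NA_integer_, status = "ok",
                         sigma2_g = NA_real_, sigma2_e = NA_real_) {
  structure(list(gene = gene, method = method, beta = beta, se = se,
                 statistic = statistic, df = df, p_value = p_value,
                 carrier_count = carrier_count, status = status,
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("assoc_result [%s/%s]: beta = %.4g (se %.4g), t = %.3f, p = %.3g [%s]\n",
              x$gene, x$method, x$beta, x$se, x$statistic, x$p_value, x$status))
  invisible(x)
}

#' Wald test of the collapsed-gene effect under the fitted mixed model
#'
#' Generalised least squares at the REML variance components:
#' `bhat = (F' V^-1 F)^-1 F' V^-1 y` with `V = sigma2_g K + sigma2_e I`; the
#' standard error comes from the corresponding diagonal of `(F' V^-1 F)^-1`,
#' and `bhat / se` is referred to a t distribution with `n - p` degrees of
#' freedom (p = number of fixed-effect columns).
#'
#' @inheritParams reml_fit
#' @param vc a `variance_components` fit from [reml_fit()] on the same
#'   `(y, fixed, k)`.
#' @param test_column index of the tested fixed effect (2 = the collapsed X).
#' @return an `assoc_result`.
#' @export
gls_wald_test <- function(y, fixed, vc, k, test_column = 2L) {
  ed <- decompose_relmat(k)
  yt <- drop(crossprod(ed$U, y))
  Ft <- crossprod(ed$U, fixed)
  w <- 1 / (ed$d + vc$delta)
  Fw <- Ft * w
  A <- crossprod(Ft, Fw)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(assoc_result(status = "fit_failure"))
  fy <- crossprod(Fw, yt)
  b <- backsolve(ch, forwardsolve(t(ch), fy))
  covb <- vc$sigma2_g * chol2inv(ch)
  se <- sqrt(covb[test_column, test_column])
  df <- vc$n - vc$p
  tval <- b[test_column] / se
  assoc_result(beta = b[test_column], se = se, statistic = tval, df = df,
               p_value = 2 * stats::pt(-abs(tval), df),
               sigma2_g = vc$sigma2_g, sigma2_e = vc$sigma2_e)
}

#' Ordinary least-squares test of the collapsed-gene effect
#'
#' The REG/PC path: the same Wald t-test with `V = sigma2 I`, `sigma2`
#' estimated by the residual mean square.
#'
#' @inheritParams gls_wald_test
#' @return an `assoc_result` with `sigma2_e` the residual mean square.
#' @export
ols_test <- function(y, fixed, test_column = 2L) {
  n <- nrow(fixed)
  p <- ncol(fixed)
  ch <- tryCatch(chol(crossprod(fixed)), error = function(e) NULL)
  if (is.null(ch)) return(assoc_result(status = "fit_failure"))
  xtxinv <- chol2inv(ch)
  b <- drop(xtxinv %*% crossprod(fixed, y))
  res <- y - fixed %*% b
  sigma2 <- sum(res^2) / (n - p)
  se <- sqrt(sigma2 * xtxinv[test_column, test_column])
  tval <- b[test_column] / se
  assoc_result(beta = b[test_column], se = se, statistic = tval, df = n - p,
               p_value = 2 * stats::pt(-abs(tval), n - p),
               sigma2_e = sigma2)
}

relmat_for <- function(spec, relmats) {
  kind <- spec$covariance_kind
  if (kind == "none") return(NULL)
  k <- relmats[[kind]]
  if (is.null(k)) {
    stop_fmt("method %s requires a relatedness matrix of kind '%s'",
             spec$method, kind)
  }
  ed <- decompose_relmat(k)
  if (ed$kind != kind) {
    stop_fmt("method %s requires kind '%s' but matrix has kind '%s'",
             spec$method, kind, ed$kind)
  }
  ed
}

#' Run one association method on one collapsed gene
#'
#' Dispatches to [ols_test()] (REG, PC) or [reml_fit()] + [gls_wald_test()]
#' (KIN, PC-KIN, IBS, PC-IBS) and annotates the result with the gene and
#' carrier count. An untestable design (constant indicator) yields a result
#' with `status = "untestable"` and no p-value.
#'
#' @param spec a `model_spec` (or a method name).
#' @param x a `collapsed_design`.
#' @param y named numeric trait vector.
#' @param q `pc_covariates` for the PC methods (ignored otherwise).
#' @param relmats named list of relatedness matrices keyed by kind
#'   (`relationship_2phi`, `ibs`); entries may be `relmat` or cached
#'   `relmat_eigen` objects.
#' @param delta_grid REML search grid, see [reml_fit()].
#' @return an `assoc_result`.
#' @export
run_method <- function(spec, x, y, q = NULL, relmats = list(),
                       delta_grid = c(-10, 10, 0.2)) {
  if (is.character(spec)) spec <- model_spec(spec)
  check_subjects(names(x$indicator), names(y), "collapsed design", "trait")
  ed <- relmat_for(spec, relmats)
  qq <- if (spec$n_pcs > 0L) {
    if (is.null(q)) stop_fmt("method %s requires PC covariates", spec$method)
    q[, seq_len(min(spec$n_pcs, ncol(q))), drop = FALSE]
  }
  F <- build_fixed_design(x, qq)
  out <- if (!attr(F, "testable")) {
    assoc_result(status = "untestable")
  } else if (is.null(ed)) {
    ols_test(y, F)
  } else {
    check_subjects(names(y), ed$labels, "trait", "relatedness matrix")
    vc <- reml_fit(y, F, ed, delta_grid)
    gls_wald_test(y, F, vc, ed)
  }
  out$gene <- x$gene
  out$method <- spec$method
  out$carrier_count <- x$carrier_count
  out
}

#' Scan all genes with all requested methods
#'
#' `run_all()` applies every `model_spec` to every collapsed design for a
#' single trait vector; `assoc_scan()` is the multi-replicate engine behind
#' it (and behind [run_study()]): the spectral decomposition of each
#' relatedness matrix, the rotated designs, and the grid cross-products are
#' computed once per gene and reused across trait replicates. Per-gene
#' failures are recorded in `status`, never abort the scan.
#'
#' @param specs list of `model_spec` (or character method names).
#' @param designs list of `collapsed_design` (from [collapse_all()]).
#' @param y named trait vector.
#' @inheritParams run_method
#' @return a data.frame with one row per gene x method (x replicate for
#'   `assoc_scan`): `gene`, `method`, `beta`, `se`, `statistic`, `df`,
#'   `p_value`, `carrier_count`, `status`, `sigma2_g`, `sigma2_e`.
#' @export
run_all <- function(specs, designs, y, q = NULL, relmats = list(),
                    delta_grid = c(-10, 10, 0.2)) {
  Y <- matrix(y, ncol = 1, dimnames = list(names(y), "y1"))
  out <- assoc_scan(designs, Y, methods = specs, q = q, relmats = relmats,
                    delta_grid = delta_grid)
  out$replicate <- NULL
  out
}

#' @rdname run_all
#' @param Y numeric matrix of trait replicates (subjects x replicates,
#'   subject labels as rownames).
#' @param methods character vector of method names or list of `model_spec`s.
#' @export
assoc_scan <- function(designs, Y, methods = assoc_methods(), q = NULL,
                       relmats = list(), delta_grid = c(-10, 10, 0.2)) {
  specs <- lapply(methods, function(m) if (is.character(m)) model_spec(m) else m)
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1, dimnames = list(names(Y), "y1"))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("r", seq_len(ncol(Y)))
  R <- ncol(Y)
  grid <- seq(delta_grid[1L], delta_grid[2L], by = delta_grid[3L])

  # cache spectral decompositions and rotated traits per covariance kind
  kinds <- unique(vapply(specs, `[[`, "", "covariance_kind"))
  cache <- list()
  for (kind in setdiff(kinds, "none")) {
    ed <- relmat_for(list(method = kind, covariance_kind = kind), relmats)
    check_subjects(rownames(Y), ed$labels, "traits", "relatedness matrix")
    cache[[kind]] <- list(ed = ed, Yt = crossprod(ed$U, Y))
  }

  rows <- vector("list", length(specs) * length(designs) * R)
  slot <- 1L
  for (spec in specs) {
    qq <- if (spec$n_pcs > 0L) {
      if (is.null(q)) stop_fmt("method %s requires PC covariates", spec$method)
      q[, seq_len(min(spec$n_pcs, ncol(q))), drop = FALSE]
    }
    mixed <- spec$covariance_kind != "none"
    for (x in designs) {
      F <- build_fixed_design(x, qq)
      if (!attr(F, "testable")) {
        for (r in seq_len(R)) {
          rows[[slot]] <- data.frame(gene = x$gene, method = spec$method,
                                     replicate = colnames(Y)[r],
                                     beta = NA_real_, se = NA_real_,
                                     statistic = NA_real_, df = NA_real_,
                                     p_value = NA_real_,
                                     carrier_count = x$carrier_count,
                                     status = "untestable",
                                     sigma2_g = NA_real_, sigma2_e = NA_real_,
                                     stringsAsFactors = FALSE)
          slot <- slot + 1L
        }
        next
      }
      n <- nrow(F)
      p <- ncol(F)
      if (!mixed) {
        fit <- ols_scan(F, Y)
        for (r in seq_len(R)) {
          rows[[slot]] <- data.frame(gene = x$gene, method = spec$method,
                                     replicate = colnames(Y)[r],
                                     beta = fit$beta[r], se = fit$se[r],
                                     statistic = fit$statistic[r], df = fit$df,
                                     p_value = fit$p_value[r],
                                     carrier_count = x$carrier_count,
                                     status = "ok", sigma2_g = NA_real_,
                                     sigma2_e = fit$sigma2[r],
                                     stringsAsFactors = FALSE)
          slot <- slot + 1L
        }
      } else {
        cc <- cache[[spec$covariance_kind]]
        Ft <- crossprod(cc$ed$U, F)
        logdetFF <- 2 * sum(log(diag(chol(crossprod(F)))))
        parts <- reml_grid_parts(Ft, cc$ed$d, grid)
        for (r in seq_len(R)) {
          res <- tryCatch({
            fit <- reml_fit_core(cc$Yt[, r], Ft, cc$ed$d, grid, logdetFF, parts)
            covb <- fit$sigma2_g * fit$cov_unscaled
            se <- sqrt(covb[2L, 2L])
            tval <- fit$beta[2L] / se
            df <- n - p
            data.frame(gene = x$gene, method = spec$method,
                       replicate = colnames(Y)[r],
                       beta = fit$beta[2L], se = se, statistic = tval,
                       df = df, p_value = 2 * stats::pt(-abs(tval), df),
                       carrier_count = x$carrier_count, status = "ok",
                       sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e,
                       stringsAsFactors = FALSE)
          }, error = function(e) {
            data.frame(gene = x$gene, method = spec$method,
                       replicate = colnames(Y)[r],
                       beta = NA_real_, se = NA_real_, statistic = NA_real_,
                       df = NA_real_, p_value = NA_real_,
                       carrier_count = x$carrier_count, status = "fit_failure",
                       sigma2_g = NA_real_, sigma2_e = NA_real_,
                       stringsAsFactors = FALSE)
          })
          rows[[slot]] <- res
          slot <- slot + 1L
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Vectorised OLS across trait replicates (shared design).
ols_scan <- function(F, Y, test_column = 2L) {
  n <- nrow(F)
  p <- ncol(F)
  xtxinv <- chol2inv(chol(crossprod(F)))
  B <- xtxinv %*% crossprod(F, Y)
  res <- Y - F %*% B
  rss <- colSums(res^2)
  sigma2 <- rss / (n - p)
  se <- sqrt(sigma2 * xtxinv[test_column, test_column])
  tval <- B[test_column, ] / se
  list(beta = B[test_column, ], se = se, statistic = tval, df = n - p,
       p_value = 2 * stats::pt(-abs(tval), n - p), sigma2 = sigma2)
}

#' Write an association results table as TSV
#'
#' @param results data.frame from [run_all()] or [assoc_scan()].
#' @param path output path.
#' @export
write_assoc_results <- function(results, path) {
  write_tsv_det(results, path)
}
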