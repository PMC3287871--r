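#' Empirical rejection rate at a p-value threshold
#'
#' Proportion of p-values at or below `alpha` (inclusive rejection), with an
#' exact Clopper-Pearson binomial confidence interval. Applied to null tests
#' this is the empirical false-positive rate; applied to causal tests, the
#' empirical power.
#'
#' @param pvals numeric vector of p-values.
#' @param alpha rejection threshold in (0, 1\] (at 1 every test is rejected).
#' @param conf_level confidence level of the attached interval.
#' @return list with `rate`, `n`, `rejected`, `ci_lo`, `ci_hi`.
#' @examples
#' empirical_rate(c(0.01, 0.2, 0.6), 0.05)$rate   # 1/3
#' @export
empirical_rate <- function(pvals, alpha, conf_level = 0.95) {
  if (!length(pvals)) stop_fmt("empirical_rate needs a nonempty p-value list")
  if (alpha <= 0 || alpha > 1) stop_fmt("alpha must lie in (0, 1]")
  n <- length(pvals)
  k <- sum(pvals <= alpha)
  ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
  list(rate = k / n, n = n, rejected = k, ci_lo = ci[1L], ci_hi = ci[2L])
}

#' Q-Q data and genomic inflation factor
#'
#' Observed versus expected `-log10` p-value quantiles with Blom-like
#' plotting positions `(i - 0.5) / m`, plus the genomic inflation factor
#' `lambda = median(qchisq(p, 1, lower.tail = FALSE)) / qchisq(0.5, 1)`
#' (about 1 for a calibrated test, above 1 under inflation). Zero p-values
#' are clamped to the smallest positive double with a warning.
#'
#' @param pvals numeric vector of p-values in (0, 1\].
#' @return list with `expected`, `observed` (both `-log10` scale, sorted so
#'   the most significant pair comes first), `lambda`, `n`.
#' @export
qq_data <- function(pvals) {
  if (!length(pvals)) stop_fmt("qq_data needs a nonempty p-value list")
  if (any(pvals <= 0)) {
    warn_fmt("clamping %d p-value(s) <= 0 to the smallest positive double",
             sum(pvals <= 0))
    pvals[pvals <= 0] <- .Machine$double.xmin
  }
  m <- length(pvals)
  observed <- sort(-log10(pvals), decreasing = TRUE)
  expected <- -log10((seq_len(m) - 0.5) / m)
  lambda <- stats::median(stats::qchisq(pvals, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
  list(expected = expected, observed = observed, lambda = lambda, n = m)
}

#' Truncated ROC curve over causal and null tests
#'
#' Sweeps the p-value rejection threshold over the observed values; at each
#' threshold `t`, TPR is the fraction of causal tests with `p <= t` and FPR
#' the same fraction among null tests. The curve is truncated at
#' `FPR <= fpr_max` (default 0.1: in practice only the low-FPR region
#' matters) and the partial area under the truncated staircase is reported.
#'
#' @param table data.frame with columns `p_value` and `causal` (logical);
#'   rows with missing p-values are dropped.
#' @param fpr_max truncation point on the FPR axis.
#' @return list with `points` (data.frame `threshold`, `fpr`, `tpr`),
#'   `pauc`, `fpr_max`, `n_causal`, `n_null`.
#' @export
roc_curve <- function(table, fpr_max = 0.1) {
  tab <- table[!is.na(table$p_value), , drop = FALSE]
  pc <- tab$p_value[tab$causal]
  pn <- tab$p_value[!tab$causal]
  if (!length(pc)) stop_fmt("roc_curve needs causal rows")
  if (!length(pn)) stop_fmt("roc_curve needs null rows")
  thr <- sort(unique(tab$p_value))
  tpr <- stats::ecdf(pc)(thr)
  fpr <- stats::ecdf(pn)(thr)
  keep <- fpr <= fpr_max
  pts <- data.frame(threshold = thr[keep], fpr = fpr[keep], tpr = tpr[keep])
  # achieved-TPR staircase: best TPR at each FPR level, integrated to fpr_max
  if (nrow(pts)) {
    best <- stats::aggregate(tpr ~ fpr, data = pts, FUN = max)
    grid_f <- c(best$fpr, fpr_max)
    grid_t <- c(best$tpr)
    if (best$fpr[1L] > 0) {
      grid_f <- c(0, grid_f)
      grid_t <- c(0, grid_t)
    }
    pauc <- sum(diff(grid_f) * grid_t)
  } else {
    pauc <- 0
  }
  list(points = pts, pauc = pauc, fpr_max = fpr_max,
       n_causal = length(pc), n_null = length(pn))
}

#' Relatedness and covariate matrices for a study
#'
#' Builds the three adjustment inputs the six methods need: the pedigree
#' `2 * kinship` relationship matrix (KIN), the IBS matrix from a seeded
#' random sample of common markers with MAF above `ibs_min_maf` (IBS), and
#' Eigenstrat-style principal components from markers with MAF above
#' `pca_min_maf` (PC). The marker sample is drawn once per study.
#'
#' @param study a `replicate_study`.
#' @param ibs_markers number of markers to sample for the IBS matrix
#'   (capped at the number available, with a warning).
#' @param ibs_min_maf strict lower MAF bound for IBS markers.
#' @param pca_min_maf strict lower MAF bound for PCA markers.
#' @param n_pcs number of eigenvectors.
#' @param seed seed for the marker sample.
#' @return list with `relationship_2phi`, `ibs` (both `relmat`), and `pcs`
#'   (`pc_covariates`).
#' @export
study_matrices <- function(study, ibs_markers = 5000L, ibs_min_maf = 0.05,
                           pca_min_maf = 0.10, n_pcs = 10L, seed = 1L) {
  geno <- study$genotypes
  if (anyNA(geno$meta$maf)) geno <- add_maf(geno)
  k2 <- relationship_matrix(kinship_matrix(study$pedigree))
  common <- filter_variants(geno, min_maf = ibs_min_maf)
  if (n_variants(common) < ibs_markers) {
    warn_fmt("only %d markers with MAF > %g available; using all of them",
             n_variants(common), ibs_min_maf)
    ibs_markers <- n_variants(common)
  }
  panel <- sample_markers(common, ibs_markers, seed = seed + 33L)
  ibs <- ibs_matrix(panel)
  pcs <- pca_eigenvectors(filter_variants(geno, min_maf = pca_min_maf), n_pcs)
  list(relationship_2phi = k2, ibs = ibs, pcs = pcs)
}

#' Association scan for a whole study
#'
#' Collapses every annotated gene at the study MAF threshold and runs the
#' requested methods over every trait replicate.
#'
#' @param study a `replicate_study`.
#' @param mats matrices from [study_matrices()].
#' @param methods character vector of method names.
#' @param maf_threshold rare-variant collapsing threshold.
#' @param delta_grid REML search grid.
#' @return results data.frame (see [assoc_scan()]).
#' @export
study_assoc <- function(study, mats, methods = assoc_methods(),
                        maf_threshold = 0.01, delta_grid = c(-10, 10, 0.2)) {
  geno <- study$genotypes
  if (anyNA(geno$meta$maf)) geno <- add_maf(geno)
  designs <- collapse_all(geno, maf_threshold)
  relmats <- list(relationship_2phi = decompose_relmat(mats$relationship_2phi),
                  ibs = decompose_relmat(mats$ibs))
  assoc_scan(designs, study$traits, methods = methods, q = mats$pcs,
             relmats = relmats, delta_grid = delta_grid)
}

#' Evaluate an association results table against truth labels
#'
#' Joins the per-gene causal flags onto the results and derives, per method:
#' the genomic inflation factor and Q-Q data over null tests, the empirical
#' FPR at each `alpha` (with exact binomial intervals), and -- when causal
#' genes are present -- the empirical power at each `alpha` and the truncated
#' ROC with its partial AUC. Rows with `status != "ok"` are excluded from all
#' denominators and their counts reported. Causal genes never enter the null
#' summaries.
#'
#' @param results data.frame from [study_assoc()] / [assoc_scan()].
#' @param truth data.frame with columns `gene` and `causal`.
#' @param alphas rejection thresholds to tabulate.
#' @param fpr_max ROC truncation point.
#' @return an `evaluation` list: `table` (results + causal flag), `summary`
#'   (long data.frame of metrics), `qq` (per-method Q-Q data), `roc`
#'   (per-method ROC, `NULL` when no causal genes), `excluded` (per-method
#'   non-ok counts).
#' @export
evaluate_results <- function(results, truth, alphas = c(0.01, 0.05, 0.1),
                             fpr_max = 0.1) {
  results$causal <- truth$causal[match(results$gene, truth$gene)]
  if (anyNA(results$causal)) stop_fmt("truth table lacks some scanned genes")
  methods <- unique(results$method)
  any_causal <- any(results$causal)
  qq <- list()
  roc <- list()
  excl <- list()
  rows <- list()
  for (m in methods) {
    sub <- results[results$method == m, , drop = FALSE]
    ok <- sub[sub$status == "ok", , drop = FALSE]
    excl[[m]] <- data.frame(method = m,
                            excluded = nrow(sub) - nrow(ok),
                            untestable = sum(sub$status == "untestable"),
                            fit_failure = sum(sub$status == "fit_failure"),
                            stringsAsFactors = FALSE)
    pnull <- ok$p_value[!ok$causal]
    if (length(pnull)) {
      qq[[m]] <- qq_data(pnull)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, metric = "lambda", alpha = NA_real_,
        value = qq[[m]]$lambda, ci_lo = NA_real_, ci_hi = NA_real_,
        n = length(pnull), stringsAsFactors = FALSE)
      for (a in alphas) {
        er <- empirical_rate(pnull, a)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, metric = "fpr", alpha = a, value = er$rate,
          ci_lo = er$ci_lo, ci_hi = er$ci_hi, n = er$n,
          stringsAsFactors = FALSE)
      }
    }
    if (any_causal) {
      pcausal <- ok$p_value[ok$causal]
      if (length(pcausal)) {
        for (a in alphas) {
          er <- empirical_rate(pcausal, a)
          rows[[length(rows) + 1L]] <- data.frame(
            method = m, metric = "power", alpha = a, value = er$rate,
            ci_lo = er$ci_lo, ci_hi = er$ci_hi, n = er$n,
            stringsAsFactors = FALSE)
        }
        roc[[m]] <- roc_curve(ok, fpr_max = fpr_max)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, metric = "pauc", alpha = NA_real_,
          value = roc[[m]]$pauc, ci_lo = NA_real_, ci_hi = NA_real_,
          n = nrow(ok), stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(table = results,
                 summary = do.call(rbind, rows),
                 qq = qq,
                 roc = if (any_causal) roc else NULL,
                 excluded = do.call(rbind, excl)),
            class = "evaluation")
}

#' @export
print.evaluation <- function(x, ...) {
  cat("evaluation of", length(x$qq), "method(s)\n")
  lam <- if (is.null(x$summary)) data.frame() else
    x$summary[x$summary$metric == "lambda", c("method", "value")]
  if (nrow(lam)) {
    cat("  lambda:", paste(sprintf("%s=%.3f", lam$method, lam$value),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

default_study_config <- function() {
  list(sim = list(),
       methods = assoc_methods(),
       maf_threshold = 0.01,
       n_pcs = 10L,
       ibs_markers = 5000L,
       ibs_min_maf = 0.05,
       pca_min_maf = 0.10,
       alphas = c(0.01, 0.05, 0.1),
       fpr_max = 0.1,
       delta_grid = c(-10, 10, 0.2),
       plots = TRUE,
       seed = 1L)
}

resolve_study_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_study_config(), config)
  cfg$methods <- match.arg(as.character(cfg$methods), assoc_methods(),
                           several.ok = TRUE)
  cfg
}

#' Run a full simulated comparison study
#'
#' End-to-end pipeline: simulate (or read) a replicate study, build the
#' kinship / IBS / PCA matrices, collapse every gene, run the requested
#' methods on every trait replicate, and evaluate. Writes deterministic
#' `results.tsv`, `summary.tsv`, `excluded.tsv` and `report.json` (plus Q-Q
#' and ROC PNG figures unless `plots = FALSE`) to `out_dir`; repeated runs
#' with the same config and seed produce byte-identical TSV/JSON outputs.
#'
#' @param config a list or YAML path. Recognised fields: `sim` (arguments to
#'   [sim_config()]), or `study_dir` to read a study written by
#'   [write_study()]; `methods`, `maf_threshold`, `n_pcs`, `ibs_markers`,
#'   `ibs_min_maf`, `pca_min_maf`, `alphas`, `fpr_max`, `delta_grid`,
#'   `plots`, `seed`.
#' @param out_dir output directory (created); `NULL` writes nothing.
#' @param seed optional override of the config seed.
#' @return the `evaluation`, invisibly, with the study and matrices attached
#'   as attributes.
#' @export
run_study <- function(config = list(), out_dir = NULL, seed = NULL) {
  cfg <- resolve_study_config(if (is.list(config)) config else config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(cfg$study_dir)) {
    study <- read_study(cfg$study_dir)
  } else {
    sim_args <- cfg$sim
    sim_args$seed <- cfg$seed
    if (is.null(sim_args$maf_threshold)) sim_args$maf_threshold <- cfg$maf_threshold
    study <- simulate_study(do.call(sim_config, sim_args))
  }
  message(sprintf("study: %d subjects, %d families, %d genes, %d replicates",
                  nrow(study$pedigree), length(unique(study$pedigree$fid)),
                  length(unique(stats::na.omit(study$genotypes$meta$gene))),
                  ncol(study$traits)))
  mats <- study_matrices(study, ibs_markers = cfg$ibs_markers,
                         ibs_min_maf = cfg$ibs_min_maf,
                         pca_min_maf = cfg$pca_min_maf,
                         n_pcs = cfg$n_pcs, seed = cfg$seed)
  results <- study_assoc(study, mats, methods = cfg$methods,
                         maf_threshold = cfg$maf_threshold,
                         delta_grid = cfg$delta_grid)
  ev <- evaluate_results(results, study$truth, alphas = cfg$alphas,
                         fpr_max = cfg$fpr_max)
  if (!is.null(out_dir)) {
    write_evaluation(ev, out_dir, cfg, plots = isTRUE(cfg$plots))
  }
  attr(ev, "study") <- study
  attr(ev, "matrices") <- mats
  invisible(ev)
}

#' Write evaluation outputs
#'
#' @param ev an `evaluation`.
#' @param out_dir output directory.
#' @param cfg resolved study config echoed into the JSON report.
#' @param plots write Q-Q and ROC PNG figures.
#' @export
write_evaluation <- function(ev, out_dir, cfg = NULL, plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_det(ev$table, file.path(out_dir, "results.tsv"))
  if (!is.null(ev$summary)) {
    write_tsv_det(ev$summary, file.path(out_dir, "summary.tsv"))
  }
  write_tsv_det(ev$excluded, file.path(out_dir, "excluded.tsv"))
  report <- list(
    config = cfg[setdiff(names(cfg), "plots")],
    n_tests = nrow(ev$table),
    methods = unique(ev$table$method),
    lambda = stats::setNames(
      as.list(ev$summary$value[ev$summary$metric == "lambda"]),
      ev$summary$method[ev$summary$metric == "lambda"]),
    summary = ev$summary,
    excluded = ev$excluded)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  if (plots) {
    for (m in names(ev$qq)) {
      grDevices::png(file.path(out_dir, sprintf("qq_%s.png", m)),
                     width = 600, height = 600)
      plot_qq(ev$qq[[m]], main = sprintf("Q-Q, %s", m))
      grDevices::dev.off()
    }
    if (!is.null(ev$roc) && length(ev$roc)) {
      grDevices::png(file.path(out_dir, "roc.png"), width = 700, height = 600)
      plot_roc(ev$roc)
      grDevices::dev.off()
    }
  }
  invisible(out_dir)
}

#' Base-graphics Q-Q and ROC plots
#'
#' @param qq output of [qq_data()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_qq <- function(qq, ...) {
  graphics::plot(qq$expected, qq$observed, pch = 20, col = "red",
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)), ...)
  graphics::abline(0, 1)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("lambda = %.3f (n = %d)", qq$lambda, qq$n))
}

#' @rdname plot_qq
#' @param roc named list of [roc_curve()] outputs (one per method).
#' @export
plot_roc <- function(roc, ...) {
  fmax <- roc[[1L]]$fpr_max
  cols <- grDevices::hcl.colors(max(3L, length(roc)), "Dark 3")
  graphics::plot(NA, xlim = c(0, fmax), ylim = c(0, 1), xlab = "FPR",
                 ylab = "TPR", ...)
  for (i in seq_along(roc)) {
    p <- roc[[i]]$points
    graphics::lines(c(0, p$fpr, fmax), c(0, p$tpr, max(p$tpr, 0)),
                    type = "s", col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", bty = "n", lwd = 2, col = cols[seq_along(roc)],
                   legend = sprintf("%s (pAUC %.4f)", names(roc),
                                    vapply(roc, `[[`, 0, "pauc")))
}
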