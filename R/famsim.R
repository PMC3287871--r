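#' Configuration for the synthetic family study
#'
#' Describes a multi-family quantitative-trait study in the mould of a large
#' family-based mini-exome design: a fixed set of extended pedigrees, a rare
#' variant panel annotated to genes, a common marker panel (for the IBS and
#' PCA adjustments), fixed genotypes, and repeatedly re-simulated traits with
#' a polygenic familial component plus optional collapsed-gene effects.
#'
#' The defaults emulate the target design: 8 extended families of 4
#' generations whose expected total size is about 697 subjects, 60 genes with
#' 4-12 rare variants each (founder MAF uniform on \[0.0005, 0.009\]), an
#' 8,000-marker common panel (founder MAF uniform on \[0.05, 0.5\], with a
#' mild two-subpopulation founder-frequency split, Fst 0.02, so PCA has
#' structure to find), polygenic heritability 0.6 over a unit residual
#' variance, and 200 trait replicates.
#'
#' @param n_families number of independent extended families.
#' @param generations generations per family (founder couple at the top;
#'   spouses marrying in are new founders; the last generation is unmarried).
#' @param offspring_range,offspring_prob support and probabilities of the
#'   per-couple offspring count.
#' @param n_genes number of rare-variant genes.
#' @param variants_per_gene integer range `c(lo, hi)`; per-gene count uniform.
#' @param rare_maf_range founder minor-allele-frequency range for rare
#'   variants.
#' @param n_common_markers size of the common marker panel.
#' @param common_maf_range founder MAF range for common markers.
#' @param subpop_split logical; draw common-marker founder frequencies from
#'   two Balding-Nichols subpopulations (families split half and half).
#' @param fst divergence of the two subpopulations when `subpop_split`.
#' @param causal_genes `NULL`, or a data.frame/list with `gene` and `beta`
#'   (trait-unit effect of the collapsed carrier indicator).
#' @param per_variant_effects logical; if `TRUE` the causal betas act per
#'   rare-allele dosage instead of on the collapsed indicator (a model
#'   misspecification stress mode).
#' @param heritability_polygenic narrow-sense polygenic heritability in
#'   \[0, 1); sets `sigma2_g = h2 / (1 - h2) * sigma2_e`.
#' @param sigma2_e residual trait variance.
#' @param n_replicates number of trait replicates (genotypes stay fixed).
#' @param maf_threshold rare-variant threshold used when attaching causal
#'   collapsed-gene effects.
#' @param target_size_range optional `c(lo, hi)`; error if the simulated
#'   total pedigree size falls outside it.
#' @param seed integer master seed; pedigree, genotypes and each trait
#'   replicate use streams derived from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_families = 8L,
                       generations = 4L,
                       offspring_range = 2:5,
                       offspring_prob = c(0.1, 0.3, 0.4, 0.2),
                       n_genes = 60L,
                       variants_per_gene = c(4L, 12L),
                       rare_maf_range = c(0.0005, 0.009),
                       n_common_markers = 8000L,
                       common_maf_range = c(0.05, 0.5),
                       subpop_split = TRUE,
                       fst = 0.02,
                       causal_genes = NULL,
                       per_variant_effects = FALSE,
                       heritability_polygenic = 0.6,
                       sigma2_e = 1,
                       n_replicates = 200L,
                       maf_threshold = 0.01,
                       target_size_range = NULL,
                       seed = 1L) {
  if (heritability_polygenic < 0 || heritability_polygenic >= 1) {
    stop_fmt("heritability_polygenic must lie in [0, 1)")
  }
  if (sigma2_e <= 0) stop_fmt("sigma2_e must be positive")
  if (n_replicates < 1L) stop_fmt("n_replicates must be >= 1")
  if (length(offspring_range) != length(offspring_prob)) {
    stop_fmt("offspring_range and offspring_prob lengths differ")
  }
  if (!is.null(causal_genes)) {
    causal_genes <- as.data.frame(causal_genes, stringsAsFactors = FALSE)
    if (!all(c("gene", "beta") %in% names(causal_genes))) {
      stop_fmt("causal_genes needs columns 'gene' and 'beta'")
    }
    causal_genes$gene <- as.character(causal_genes$gene)
    causal_genes$beta <- as.numeric(causal_genes$beta)
  }
  structure(list(n_families = as.integer(n_families),
                 generations = as.integer(generations),
                 offspring_range = as.integer(offspring_range),
                 offspring_prob = as.numeric(offspring_prob),
                 n_genes = as.integer(n_genes),
                 variants_per_gene = as.integer(variants_per_gene),
                 rare_maf_range = as.numeric(rare_maf_range),
                 n_common_markers = as.integer(n_common_markers),
                 common_maf_range = as.numeric(common_maf_range),
                 subpop_split = isTRUE(subpop_split),
                 fst = as.numeric(fst),
                 causal_genes = causal_genes,
                 per_variant_effects = isTRUE(per_variant_effects),
                 heritability_polygenic = as.numeric(heritability_polygenic),
                 sigma2_e = as.numeric(sigma2_e),
                 n_replicates = as.integer(n_replicates),
                 maf_threshold = as.numeric(maf_threshold),
                 target_size_range = target_size_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-family extended pedigree
#'
#' Each family starts from one founder couple; every couple has a number of
#' children drawn from the configured offspring distribution; children in
#' non-terminal generations marry new founders (spouses carry no pedigree
#' ancestry). Families are mutually unrelated, so between-family kinship is
#' exactly zero. Deterministic for a fixed config seed.
#'
#' @param cfg a `sim_config`.
#' @return a `fam_pedigree`.
#' @export
simulate_pedigree <- function(cfg) {
  rows <- with_seed(cfg$seed + 11L, {
    all <- list()
    for (f in seq_len(cfg$n_families)) {
      fid <- sprintf("F%d", f)
      counter <- 0L
      nid <- function() {
        counter <<- counter + 1L
        sprintf("%s_I%03d", fid, counter)
      }
      recs <- list()
      add <- function(id, fa, mo, sex) {
        recs[[length(recs) + 1L]] <<- data.frame(
          fid = fid, id = id, father = fa, mother = mo, sex = sex,
          stringsAsFactors = FALSE)
      }
      pa <- nid(); ma <- nid()
      add(pa, NA, NA, 1L)
      add(ma, NA, NA, 2L)
      couples <- list(c(pa, ma))
      for (g in 2:cfg$generations) {
        nxt <- list()
        for (cp in couples) {
          k <- cfg$offspring_range[sample.int(length(cfg$offspring_range), 1L,
                                              prob = cfg$offspring_prob)]
          for (ch in seq_len(k)) {
            sex <- sample(1:2, 1L)
            child <- nid()
            add(child, cp[1L], cp[2L], sex)
            if (g < cfg$generations) {
              sp <- nid()
              add(sp, NA, NA, 3L - sex)
              nxt[[length(nxt) + 1L]] <-
                if (sex == 1L) c(child, sp) else c(sp, child)
            }
          }
        }
        couples <- nxt
      }
      all[[f]] <- do.call(rbind, recs)
    }
    do.call(rbind, all)
  })
  if (!is.null(cfg$target_size_range)) {
    n <- nrow(rows)
    if (n < cfg$target_size_range[1L] || n > cfg$target_size_range[2L]) {
      stop_fmt("simulated pedigree size %d outside target range [%d, %d]; adjust the family template",
               n, cfg$target_size_range[1L], cfg$target_size_range[2L])
    }
  }
  pedigree_from_df(rows)
}

#' Drop genes through a pedigree
#'
#' Founders receive two alleles per variant i.i.d. Bernoulli(founder MAF);
#' each non-founder inherits one uniformly chosen allele from each parent,
#' independently across variants (no linkage). Dosage is the allele sum.
#' Rare variants are annotated to genes `G001 ...`; common markers carry no
#' gene label. Realised sample MAFs are left to [add_maf()].
#'
#' @param ped a `fam_pedigree`.
#' @param cfg a `sim_config`.
#' @return a `geno_matrix` (with an extra `founder_maf` element recording the
#'   generating frequencies; realised MAF not yet computed).
#' @export
gene_drop <- function(ped, cfg) {
  n <- nrow(ped)
  with_seed(cfg$seed + 22L, {
    vcount <- if (cfg$n_genes > 0L) {
      sample(seq(cfg$variants_per_gene[1L], cfg$variants_per_gene[2L]),
             cfg$n_genes, replace = TRUE)
    } else integer(0)
    gene <- rep(sprintf("G%03d", seq_len(cfg$n_genes)), vcount)
    rare_ids <- unlist(lapply(seq_len(cfg$n_genes), function(g) {
      sprintf("G%03d_V%02d", g, seq_len(vcount[g]))
    }), use.names = FALSE)
    if (is.null(rare_ids)) rare_ids <- character(0)
    rare_p <- stats::runif(length(rare_ids), cfg$rare_maf_range[1L],
                           cfg$rare_maf_range[2L])
    m_common <- cfg$n_common_markers
    common_ids <- if (m_common > 0L) sprintf("M%05d", seq_len(m_common)) else character(0)
    common_p <- stats::runif(m_common, cfg$common_maf_range[1L],
                             cfg$common_maf_range[2L])
    if (cfg$subpop_split && m_common > 0L && cfg$fst > 0) {
      a <- common_p * (1 - cfg$fst) / cfg$fst
      b <- (1 - common_p) * (1 - cfg$fst) / cfg$fst
      p1 <- stats::rbeta(m_common, a, b)
      p2 <- stats::rbeta(m_common, a, b)
    } else {
      p1 <- p2 <- common_p
    }
    m <- length(rare_ids) + m_common
    ids <- c(rare_ids, common_ids)
    genes <- c(gene, rep(NA_character_, m_common))
    # family -> subpopulation assignment (alternating)
    fam_pop <- (match(ped$fid, unique(ped$fid)) - 1L) %% 2L + 1L
    freq_for <- function(pop) {
      if (pop == 1L) c(rare_p, p1) else c(rare_p, p2)
    }
    pat <- matrix(0L, n, m)
    mat <- matrix(0L, n, m)
    idx <- seq_len(n)
    names(idx) <- ped$id
    fa <- idx[ped$father]
    mo <- idx[ped$mother]
    for (i in attr(ped, "topo_order")) {
      if (is.na(fa[i]) && is.na(mo[i])) {
        p <- freq_for(fam_pop[i])
        pat[i, ] <- stats::rbinom(m, 1L, p)
        mat[i, ] <- stats::rbinom(m, 1L, p)
      } else {
        pick <- stats::runif(m) < 0.5
        pat[i, ] <- ifelse(pick, pat[fa[i], ], mat[fa[i], ])
        pick <- stats::runif(m) < 0.5
        mat[i, ] <- ifelse(pick, pat[mo[i], ], mat[mo[i], ])
      }
    }
    dos <- pat + mat
    dimnames(dos) <- list(ped$id, ids)
    g <- geno_matrix(dos, gene = genes)
    g$founder_maf <- stats::setNames(c(rare_p, common_p), ids)
    g
  })
}

#' Simulate trait replicates over fixed genotypes
#'
#' Per replicate `r`, the trait is generated from the model the association
#' methods assume:
#' `y = sum_c beta_c X_c + u + e`, where `X_c` is the collapsed carrier
#' indicator of causal gene `c` (at the study MAF threshold), `u` is
#' multivariate normal with covariance `sigma2_g * 2 Phi` from the pedigree,
#' and `e` is i.i.d. normal with variance `sigma2_e`. `u` and `e` are redrawn
#' per replicate; genotypes are fixed across replicates. Causal genes with no
#' carriers are kept in the truth table with a zero-power flag and a warning.
#'
#' @param ped a `fam_pedigree`.
#' @param geno a `geno_matrix` from [gene_drop()] (MAF computed internally if
#'   absent).
#' @param cfg a `sim_config`.
#' @return a `replicate_study`: list with `pedigree`, `genotypes` (MAFs
#'   filled), `traits` (subjects x replicates matrix), `truth` (per-gene
#'   `gene`, `causal`, `beta`, `carriers`), and `config`.
#' @export
simulate_traits <- function(ped, geno, cfg) {
  if (anyNA(geno$meta$maf)) geno <- add_maf(geno)
  check_subjects(ped$id, rownames(geno$dosage), "pedigree", "genotypes")
  n <- nrow(ped)
  genes <- unique(stats::na.omit(geno$meta$gene))
  truth <- data.frame(gene = genes, causal = FALSE, beta = 0,
                      carriers = NA_integer_, stringsAsFactors = FALSE)
  fixed <- numeric(n)
  if (!is.null(cfg$causal_genes) && nrow(cfg$causal_genes)) {
    missing_g <- setdiff(cfg$causal_genes$gene, genes)
    if (length(missing_g)) {
      stop_fmt("causal gene(s) absent from genotype annotation: %s",
               paste(missing_g, collapse = ", "))
    }
    for (i in seq_len(nrow(cfg$causal_genes))) {
      gname <- cfg$causal_genes$gene[i]
      beta <- cfg$causal_genes$beta[i]
      x <- collapse_gene(geno, gname, cfg$maf_threshold)
      j <- which(truth$gene == gname)
      truth$causal[j] <- TRUE
      truth$beta[j] <- beta
      truth$carriers[j] <- x$carrier_count
      if (x$carrier_count == 0L) {
        warn_fmt("causal gene %s has zero carriers (zero power)", gname)
      }
      if (cfg$per_variant_effects) {
        vr <- which(!is.na(geno$meta$gene) & geno$meta$gene == gname &
                      geno$meta$maf < cfg$maf_threshold)
        if (length(vr)) {
          d <- geno$dosage[, vr, drop = FALSE]
          d[is.na(d)] <- 0L
          fixed <- fixed + beta * rowSums(d)
        }
      } else {
        fixed <- fixed + beta * x$indicator
      }
    }
  }
  noncausal <- !(truth$gene %in% truth$gene[truth$causal])
  truth$carriers[noncausal] <- vapply(truth$gene[noncausal], function(gname) {
    collapse_gene(geno, gname, cfg$maf_threshold)$carrier_count
  }, integer(1))

  h2 <- cfg$heritability_polygenic
  sigma2_g <- if (h2 > 0) h2 / (1 - h2) * cfg$sigma2_e else 0
  L <- if (sigma2_g > 0) chol(unclass(relationship_matrix(kinship_matrix(ped)))) else NULL
  traits <- matrix(NA_real_, n, cfg$n_replicates,
                   dimnames = list(ped$id, sprintf("rep%03d", seq_len(cfg$n_replicates))))
  for (r in seq_len(cfg$n_replicates)) {
    traits[, r] <- with_seed(cfg$seed + 1000L + r, {
      u <- if (!is.null(L)) sqrt(sigma2_g) * drop(crossprod(L, stats::rnorm(n))) else 0
      fixed + u + sqrt(cfg$sigma2_e) * stats::rnorm(n)
    })
  }
  structure(list(pedigree = ped, genotypes = geno, traits = traits,
                 truth = truth, config = cfg),
            class = "replicate_study")
}

#' Simulate a complete replicate study
#'
#' Convenience wrapper: [simulate_pedigree()], [gene_drop()], [add_maf()],
#' [simulate_traits()].
#'
#' @param cfg a `sim_config`.
#' @return a `replicate_study`.
#' @export
simulate_study <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  geno <- add_maf(gene_drop(ped, cfg))
  simulate_traits(ped, geno, cfg)
}

#' @export
print.replicate_study <- function(x, ...) {
  cat(sprintf(
    "replicate_study: %d subjects / %d families, %d variants, %d trait replicate(s), %d causal gene(s)\n",
    nrow(x$pedigree), length(unique(x$pedigree$fid)), ncol(x$genotypes$dosage),
    ncol(x$traits), sum(x$truth$causal)))
  invisible(x)
}

#' Write / read a replicate study as plain-text files
#'
#' Emits `study.fam` (PLINK-dialect pedigree), `genotypes.tsv`,
#' `variants.tsv` (variant id, gene, founder and realised MAF), `truth.tsv`,
#' `config.yaml` (the resolved `sim_config`), and one `traits/repNNN.tsv`
#' per replicate. Numeric values are written at full precision so the study
#' round-trips through [read_study()] bit-exactly.
#'
#' @param study a `replicate_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "traits"), showWarnings = FALSE)
  write_pedigree(study$pedigree, file.path(dir, "study.fam"))
  write_genotypes(study$genotypes, file.path(dir, "genotypes.tsv"))
  vm <- study$genotypes$meta
  vm$founder_maf <- unname(study$genotypes$founder_maf[vm$variant_id])
  write_tsv_det(vm, file.path(dir, "variants.tsv"))
  write_tsv_det(study$truth, file.path(dir, "truth.tsv"))
  cfg <- study$config
  cfg$causal_genes <- if (is.null(cfg$causal_genes)) NULL else as.list(cfg$causal_genes)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"),
                   precision = 17L)
  for (r in seq_len(ncol(study$traits))) {
    df <- data.frame(subject = rownames(study$traits),
                     value = study$traits[, r], stringsAsFactors = FALSE)
    write_tsv_det(df, file.path(dir, "traits", sprintf("%s.tsv", colnames(study$traits)[r])))
  }
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  cfg_raw <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- do.call(sim_config, cfg_raw)
  ped <- read_pedigree(file.path(dir, "study.fam"))
  vm <- utils::read.table(file.path(dir, "variants.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  geno <- read_genotypes(file.path(dir, "genotypes.tsv"))
  ord <- match(colnames(geno$dosage), vm$variant_id)
  geno$meta$gene <- as.character(vm$gene[ord])
  geno$meta$maf <- vm$maf[ord]
  geno$founder_maf <- stats::setNames(vm$founder_maf[ord], vm$variant_id[ord])
  truth <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  tfiles <- sort(list.files(file.path(dir, "traits"), pattern = "\\.tsv$",
                            full.names = TRUE))
  traits <- vapply(tfiles, function(f) {
    utils::read.table(f, header = TRUE, sep = "\t")$value
  }, numeric(nrow(ped)))
  colnames(traits) <- sub("\\.tsv$", "", basename(tfiles))
  rownames(traits) <- ped$id
  structure(list(pedigree = ped, genotypes = geno, traits = traits,
                 truth = truth, config = cfg),
            class = "replicate_study")
}
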