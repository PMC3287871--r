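#' Collapse a gene's rare variants into a carrier indicator
#'
#' Li-Leal presence/absence (CMC) coding: the gene's rare set is its variants
#' with folded MAF strictly below `maf_threshold`; a subject's indicator is 1
#' iff it carries at least one minor allele (dosage >= 1) at at least one rare
#' variant. Missing dosages count as non-carrier (conservative
#' presence/absence reading). The indicator is the collapsed predictor X of
#' the unified mixed model.
#'
#' @param g a `geno_matrix` with MAFs computed and gene annotations.
#' @param gene gene label to collapse.
#' @param maf_threshold rare-variant MAF cutoff (strict `<`); default 0.01.
#' @return a `collapsed_design`: list with `gene`, `indicator` (named 0/1
#'   vector over subjects), `carrier_count`, `n_rare_variants`,
#'   `maf_threshold`, and `testable` (indicator not constant).
#' @examples
#' d <- matrix(c(1L, 0L, 0L, 0L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("v1", "v2")))
#' g <- add_maf(geno_matrix(d, gene = c("G1", "G1"), maf = NULL))
#' collapse_gene(g, "G1", maf_threshold = 0.3)
#' @export
collapse_gene <- function(g, gene, maf_threshold = 0.01) {
  require_maf(g, "collapse_gene")
  j <- which(!is.na(g$meta$gene) & g$meta$gene == gene)
  if (!length(j)) stop_fmt("gene '%s' not present in variant annotation", gene)
  rare <- j[g$meta$maf[j] < maf_threshold]
  n <- nrow(g$dosage)
  if (length(rare)) {
    d <- g$dosage[, rare, drop = FALSE]
    d[is.na(d)] <- 0L
    ind <- as.integer(rowSums(d >= 1L) > 0L)
  } else {
    ind <- integer(n)
  }
  names(ind) <- rownames(g$dosage)
  cc <- sum(ind)
  structure(list(gene = gene, indicator = ind, carrier_count = cc,
                 n_rare_variants = length(rare), maf_threshold = maf_threshold,
                 testable = cc > 0L && cc < n),
            class = "collapsed_design")
}

#' @export
subject_labels.collapsed_design <- function(x) names(x$indicator)

#' @export
print.collapsed_design <- function(x, ...) {
  cat(sprintf("collapsed_design '%s': %d rare variant(s) < %g, %d carrier(s)%s\n",
              x$gene, x$n_rare_variants, x$maf_threshold, x$carrier_count,
              if (x$testable) "" else " [untestable]"))
  invisible(x)
}

#' Collapse every annotated gene
#'
#' One `collapsed_design` per distinct gene label, in first-appearance order.
#' Genes whose indicator is constant (no carriers, or all carriers) are
#' flagged `testable = FALSE` rather than dropped, so downstream
#' false-positive-rate denominators can account for them.
#'
#' @inheritParams collapse_gene
#' @return named list of `collapsed_design` objects.
#' @export
collapse_all <- function(g, maf_threshold = 0.01) {
  genes <- unique(stats::na.omit(g$meta$gene))
  if (!length(genes)) stop_fmt("no gene annotations present in geno_matrix")
  out <- lapply(genes, collapse_gene, g = g, maf_threshold = maf_threshold)
  names(out) <- genes
  out
}

#' Export collapsed designs as a subjects-by-genes 0/1 table
#'
#' @param designs list of `collapsed_design` (from [collapse_all()]).
#' @param path output TSV path.
#' @export
write_collapsed <- function(designs, path) {
  m <- vapply(designs, function(d) d$indicator, integer(length(designs[[1L]]$indicator)))
  df <- data.frame(subject = names(designs[[1L]]$indicator), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
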