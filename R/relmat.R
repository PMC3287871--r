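#' Relatedness matrices
#'
#' A `relmat` is a symmetric subject-by-subject matrix carrying a `kind`
#' attribute saying how it was built and hence how the mixed model should
#' interpret it:
#'
#' * `"pedigree_kinship"` -- kinship coefficients \eqn{\phi} from a pedigree;
#'   diagonal \eqn{\ge 0.5}, all entries in \[0, 1\].
#' * `"relationship_2phi"` -- \eqn{2\phi}, the additive genetic covariance
#'   multiplier used as the random-effect covariance in the KIN models.
#' * `"ibs"` -- marker-based identity-by-state sharing; entries in \[0, 1\]
#'   with unit diagonal, used directly (unscaled) in the IBS models.
#'
#' @param values symmetric numeric matrix with subject labels as dimnames.
#' @param kind one of `"pedigree_kinship"`, `"relationship_2phi"`, `"ibs"`.
#' @return `relmat()` returns a validated `relmat` object (a matrix with a
#'   `kind` attribute).
#' @examples
#' m <- diag(2) * 0.5
#' dimnames(m) <- list(c("a", "b"), c("a", "b"))
#' relmat(m, "pedigree_kinship")
#' @export
relmat <- function(values, kind = c("pedigree_kinship", "relationship_2phi", "ibs")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop_fmt("relmat values must be a square matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_fmt("relmat values must carry subject labels as dimnames")
  }
  if (!all(rownames(values) == colnames(values))) {
    stop_fmt("relmat row and column labels disagree")
  }
  if (max(abs(values - t(values))) > 1e-12) {
    stop_fmt("relmat values not symmetric within 1e-12")
  }
  values <- (values + t(values)) / 2
  if (kind == "pedigree_kinship") {
    if (any(values < 0) || any(values > 1)) {
      stop_fmt("pedigree kinship entries must lie in [0, 1]")
    }
    if (any(diag(values) < 0.5)) {
      stop_fmt("pedigree kinship diagonal entries must be >= 0.5")
    }
  } else if (kind == "ibs") {
    if (any(values < -1e-12) || any(values > 1 + 1e-12)) {
      stop_fmt("IBS entries must lie in [0, 1]")
    }
    if (any(diag(values) != 1)) stop_fmt("IBS diagonal must equal 1 exactly")
  }
  structure(values, kind = kind, class = c("relmat", "matrix"))
}

#' @rdname relmat
#' @param x object to query.
#' @export
relmat_kind <- function(x) attr(x, "kind")

#' @rdname relmat
#' @export
subject_labels <- function(x) UseMethod("subject_labels")

#' @export
subject_labels.relmat <- function(x) rownames(x)

#' @export
subject_labels.default <- function(x) {
  if (is.matrix(x)) rownames(x) else names(x)
}

#' Scale a kinship matrix to the additive relationship matrix
#'
#' Doubles every kinship coefficient so the random polygenic effect has
#' covariance proportional to \eqn{2\Phi} (diagonal 1 for non-inbred
#' individuals), the conventional additive-genetic scale.
#'
#' @param k a `relmat` of kind `"pedigree_kinship"`.
#' @return a `relmat` of kind `"relationship_2phi"`.
#' @examples
#' ped <- pedigree_from_df(data.frame(
#'   fid = "f", id = c("p", "m", "c"), father = c("0", "0", "p"),
#'   mother = c("0", "0", "m"), sex = c(1, 2, 1)))
#' relationship_matrix(kinship_matrix(ped))
#' @export
relationship_matrix <- function(k) {
  if (!inherits(k, "relmat") || relmat_kind(k) != "pedigree_kinship") {
    stop_fmt("relationship_matrix expects a relmat of kind 'pedigree_kinship'")
  }
  out <- unclass(k) * 2
  attr(out, "kind") <- NULL
  structure(out, kind = "relationship_2phi", class = c("relmat", "matrix"))
}

#' Write / read a relatedness matrix as labelled TSV
#'
#' Full symmetric matrix with a header row and a leading label column.
#'
#' @param x a `relmat`.
#' @param path file path.
#' @return `read_relmat` returns a `relmat`; `write_relmat` returns `path`
#'   invisibly.
#' @export
write_relmat <- function(x, path) {
  df <- data.frame(subject = rownames(x), unclass(x), check.names = FALSE)
  write_tsv_det(df, path)
}

#' @rdname write_relmat
#' @param kind kind to stamp on the matrix read back.
#' @export
read_relmat <- function(path, kind) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = c("character", rep("numeric", NA)))
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$subject
  relmat(m, kind)
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("relmat [%s]: %d x %d subjects\n", relmat_kind(x), nrow(x), ncol(x)))
  invisible(x)
}
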