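#' Pedigrees
#'
#' A `fam_pedigree` holds family / individual / father / mother / sex records
#' in a canonical subject order (the row order of the source file). Individual
#' ids must be unique across the whole pedigree; parent ids must refer to
#' records in the pedigree ("0" codes a missing parent); the parent relation
#' must be acyclic.
#'
#' @param df data.frame with columns `fid`, `id`, `father`, `mother`, `sex`
#'   (character ids; sex coded 1 = male, 2 = female, anything else unknown).
#' @return a validated `fam_pedigree` (a data.frame with extra class).
#' @examples
#' pedigree_from_df(data.frame(
#'   fid = "f1", id = c("dad", "mum", "kid"),
#'   father = c("0", "0", "dad"), mother = c("0", "0", "mum"),
#'   sex = c(1, 2, 2)))
#' @export
pedigree_from_df <- function(df) {
  need <- c("fid", "id", "father", "mother", "sex")
  if (!all(need %in% names(df))) {
    stop_fmt("pedigree needs columns %s", paste(need, collapse = ", "))
  }
  df <- df[need]
  for (col in c("fid", "id", "father", "mother")) df[[col]] <- as.character(df[[col]])
  sex <- suppressWarnings(as.integer(df$sex))
  sex[!(sex %in% c(1L, 2L))] <- NA_integer_
  df$sex <- sex
  df$father[df$father == "0"] <- NA_character_
  df$mother[df$mother == "0"] <- NA_character_

  dup <- df$id[duplicated(df$id)]
  if (length(dup)) {
    stop_fmt("duplicate individual id in pedigree: %s", dup[[1L]])
  }
  for (col in c("father", "mother")) {
    bad <- setdiff(stats::na.omit(df[[col]]), df$id)
    if (length(bad)) {
      stop_fmt("%s id '%s' does not refer to an individual in the pedigree",
               col, bad[[1L]])
    }
  }
  ord <- pedigree_topo_order(df)   # errors on cycles
  attr(df, "topo_order") <- ord
  class(df) <- c("fam_pedigree", "data.frame")
  df
}

# Kahn topological order (parents before children); reports one individual on
# a cycle if the parent relation is not acyclic.
pedigree_topo_order <- function(df) {
  n <- nrow(df)
  idx <- seq_len(n)
  names(idx) <- df$id
  fa <- idx[df$father]
  mo <- idx[df$mother]
  indeg <- as.integer(!is.na(fa)) + as.integer(!is.na(mo))
  children <- vector("list", n)
  for (i in idx) {
    if (!is.na(fa[i])) children[[fa[i]]] <- c(children[[fa[i]]], i)
    if (!is.na(mo[i])) children[[mo[i]]] <- c(children[[mo[i]]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[[1L]]
    queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    left <- setdiff(idx, ord)
    stop_fmt("pedigree contains an ancestry cycle involving individual '%s'",
             df$id[left[[1L]]])
  }
  ord
}

#' Read a pedigree from a PLINK-style .fam file
#'
#' Whitespace-delimited with at least five columns: family id, individual id,
#' father id, mother id, sex. A sixth (phenotype) column, if present, is
#' ignored. "0" codes a missing parent; founders have both parents missing.
#' The canonical subject order is the file row order.
#'
#' @param path path to the pedigree file.
#' @param dialect file dialect; only `"fam6col"` is supported.
#' @return a `fam_pedigree`.
#' @export
read_pedigree <- function(path, dialect = "fam6col") {
  dialect <- match.arg(dialect, "fam6col")
  if (!file.exists(path)) stop_fmt("pedigree file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 5L) {
    stop_fmt("pedigree file must have >= 5 whitespace-delimited columns, got %d",
             ncol(tab))
  }
  pedigree_from_df(data.frame(fid = tab[[1L]], id = tab[[2L]],
                              father = tab[[3L]], mother = tab[[4L]],
                              sex = tab[[5L]], stringsAsFactors = FALSE))
}

#' @rdname read_pedigree
#' @param ped a `fam_pedigree` to write.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(fid = ped$fid, id = ped$id,
                    father = ifelse(is.na(ped$father), "0", ped$father),
                    mother = ifelse(is.na(ped$mother), "0", ped$mother),
                    sex = ifelse(is.na(ped$sex), 0L, ped$sex),
                    phe = -9L)
  utils::write.table(out, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
subject_labels.fam_pedigree <- function(x) x$id

is_founder <- function(ped) is.na(ped$father) & is.na(ped$mother)

#' Pedigree kinship matrix
#'
#' Computes the kinship coefficient \eqn{\phi(i,j)} -- the probability that
#' an allele sampled from i and an allele sampled from j at an autosomal
#' locus are identical by descent -- for every pair in the pedigree, by the
#' standard recursion evaluated over a topological order (parents before
#' children): \eqn{\phi(i,i) = (1 + \phi(f_i, m_i))/2} and, for j processed
#' before i, \eqn{\phi(i,j) = (\phi(f_i,j) + \phi(m_i,j))/2}, a missing
#' parent contributing 0. Individuals in different families have kinship
#' exactly 0 (computed blockwise). Inbreeding is fully supported through the
#' diagonal recursion; sex is ignored (autosomal kinship).
#'
#' @param ped a `fam_pedigree`.
#' @return a `relmat` of kind `"pedigree_kinship"` in the pedigree's subject
#'   order.
#' @examples
#' trio <- pedigree_from_df(data.frame(
#'   fid = "f", id = c("p", "m", "c"), father = c("0", "0", "p"),
#'   mother = c("0", "0", "m"), sex = c(1, 2, 1)))
#' kinship_matrix(trio)["p", "c"]   # parent-offspring: 0.25
#' @export
kinship_matrix <- function(ped) {
  if (!inherits(ped, "fam_pedigree")) stop_fmt("kinship_matrix expects a fam_pedigree")
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  idx <- seq_len(n)
  names(idx) <- ped$id
  fa <- idx[ped$father]
  mo <- idx[ped$mother]
  ord <- attr(ped, "topo_order")
  for (fam in unique(ped$fid)) {
    members <- which(ped$fid == fam)
    ford <- ord[ord %in% members]
    done <- integer(0)
    for (i in ford) {
      f <- fa[[i]]
      m <- mo[[i]]
      pf <- if (!is.na(f) && length(done)) phi[f, done] else rep(0, length(done))
      pm <- if (!is.na(m) && length(done)) phi[m, done] else rep(0, length(done))
      if (length(done)) {
        phi[i, done] <- (pf + pm) / 2
        phi[done, i] <- phi[i, done]
      }
      pfm <- if (!is.na(f) && !is.na(m)) phi[f, m] else 0
      phi[i, i] <- (1 + pfm) / 2
      done <- c(done, i)
    }
  }
  relmat(phi, "pedigree_kinship")
}

#' @export
print.fam_pedigree <- function(x, ...) {
  cat(sprintf("fam_pedigree: %d individuals, %d families, %d founders\n",
              nrow(x), length(unique(x$fid)), sum(is_founder(x))))
  invisible(x)
}
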