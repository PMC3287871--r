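# Pedigree and genotype fixtures built in code.

mk_ped <- function(id, father, mother, fid = "f1", sex = NULL) {
  n <- length(id)
  if (is.null(sex)) sex <- rep(c(1, 2), length.out = n)
  pedigree_from_df(data.frame(fid = rep(fid, length.out = n), id = id,
                              father = father, mother = mother, sex = sex,
                              stringsAsFactors = FALSE))
}

# Library of hand-constructed pedigrees (<= 12 members), including inbred
# loops; each has every individual with both parents known or both missing so
# the enumeration oracle applies.
ped_library <- function() {
  list(
    trio = mk_ped(c("a", "b", "c"), c(NA, NA, "a"), c(NA, NA, "b")),
    nuclear = mk_ped(c("a", "b", "c", "d", "e"),
                     c(NA, NA, "a", "a", "a"), c(NA, NA, "b", "b", "b")),
    unrelated = mk_ped(c("a", "b", "c", "d"), rep(NA, 4), rep(NA, 4)),
    fullsib_mating = mk_ped(c("a", "b", "c", "d", "e"),
                            c(NA, NA, "a", "a", "c"),
                            c(NA, NA, "b", "b", "d")),
    halfsibs = mk_ped(c("a", "b", "c", "d", "e"),
                      c(NA, NA, NA, "a", "a"), c(NA, NA, NA, "b", "c")),
    first_cousins = mk_ped(c("a", "b", "c", "d", "e", "f", "g", "h"),
                           c(NA, NA, "a", "a", NA, NA, "c", "d"),
                           c(NA, NA, "b", "b", NA, NA, "e", "f")),
    three_gen = mk_ped(c("a", "b", "c", "d", "e"),
                       c(NA, NA, "a", NA, "c"), c(NA, NA, "b", NA, "d")),
    avuncular = mk_ped(c("a", "b", "c", "d", "e", "f"),
                       c(NA, NA, "a", "a", NA, "d"),
                       c(NA, NA, "b", "b", NA, "e")),
    double_first_cousins = mk_ped(
      c("a", "b", "c", "d", "s1", "s2", "s3", "s4", "x", "y"),
      c(NA, NA, NA, NA, "a", "a", "c", "c", "s1", "s2"),
      c(NA, NA, NA, NA, "b", "b", "d", "d", "s3", "s4")),
    parent_offspring_mating = mk_ped(c("a", "b", "c", "d"),
                                     c(NA, NA, "a", "a"),
                                     c(NA, NA, "b", "c")),
    two_families = pedigree_from_df(data.frame(
      fid = c("f1", "f1", "f1", "f2", "f2", "f2"),
      id = c("a", "b", "c", "p", "q", "r"),
      father = c(NA, NA, "a", NA, NA, "p"),
      mother = c(NA, NA, "b", NA, NA, "q"),
      sex = c(1, 2, 1, 1, 2, 2), stringsAsFactors = FALSE)),
    cousin_mating = mk_ped(
      c("a", "b", "c", "d", "e", "f", "g", "h", "i"),
      c(NA, NA, "a", "a", NA, NA, "c", "d", "g"),
      c(NA, NA, "b", "b", NA, NA, "e", "f", "h"))
  )
}

is_founder_rows <- function(ped) is.na(ped$father) & is.na(ped$mother)

# Random small genotype matrix with optional missingness and gene labels.
rand_geno <- function(n, m, seed, n_genes = 2, miss = 0.1,
                      freq = NULL) {
  set.seed(seed)
  if (is.null(freq)) freq <- runif(m, 0.05, 0.5)
  D <- sapply(freq, function(p) rbinom(n, 2, p))
  if (miss > 0) D[runif(n * m) < miss] <- NA
  # keep at least one observation per variant
  for (j in seq_len(m)) if (all(is.na(D[, j]))) D[1, j] <- 0L
  dimnames(D) <- list(sprintf("s%02d", seq_len(n)), sprintf("v%02d", seq_len(m)))
  storage.mode(D) <- "integer"
  genes <- sample(sprintf("g%d", seq_len(n_genes)), m, replace = TRUE)
  add_maf(geno_matrix(D, gene = genes))
}

# Identity relationship matrix (unrelated non-inbred founders) usable as the
# covariance of the KIN models.
identity_relmat <- function(ids) {
  ped <- mk_ped(ids, rep(NA, length(ids)), rep(NA, length(ids)))
  relationship_matrix(kinship_matrix(ped))
}

# A small but testable simulated study: few families, inflated rare MAFs so
# collapsed genes have carriers.
small_study <- function(seed = 1, n_replicates = 4, causal = NULL,
                        h2 = 0.5, n_genes = 10) {
  cfg <- sim_config(n_families = 3, generations = 3,
                    offspring_range = 2:4, offspring_prob = c(0.3, 0.4, 0.3),
                    n_genes = n_genes, variants_per_gene = c(3L, 6L),
                    rare_maf_range = c(0.02, 0.08), maf_threshold = 0.15,
                    n_common_markers = 300L, n_replicates = n_replicates,
                    heritability_polygenic = h2, causal_genes = causal,
                    seed = seed)
  simulate_study(cfg)
}
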