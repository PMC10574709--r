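# Shared fixtures: small synthetic designs and matrix helpers.
# Cohort sizes here are scaled-down versions of the default three-class
# design so unit tests stay fast; the acceptance tests use larger cohorts.

small_species_design <- function(seed, sizes = c(cLJF = 16, wLJF = 8, LF = 8),
                                 noise_sd = 0.01) {
  cohort_design(class_sizes = sizes, noise_sd = noise_sd, seed = seed)
}

# bucket table of a small species cohort, scaled training matrix + labels
small_species_matrix <- function(seed, sizes = c(cLJF = 16, wLJF = 8, LF = 8)) {
  tab <- assemble_table(simulate_cohort(small_species_design(seed, sizes)))
  sc <- suppressWarnings(scale_columns(tab$values, "uv"))
  list(X = sc$values, labels = tab$labels, table = tab, scaling = sc)
}

# deterministic random matrix, centered (and optionally uv-scaled) columns
random_centered <- function(n, p, seed, scale = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- sweep(X, 2, colMeans(X))
  if (scale) X <- sweep(X, 2, apply(X, 2, sd), "/")
  X
}

# mean silhouette width of two labelled groups in a score matrix
two_group_silhouette <- function(scores, labels, a, b) {
  keep <- labels %in% c(a, b)
  S <- scores[keep, , drop = FALSE]
  l <- labels[keep]
  D <- as.matrix(dist(S))
  sil <- vapply(seq_along(l), function(i) {
    own <- mean(D[i, l == l[i] & seq_along(l) != i])
    other <- mean(D[i, l != l[i]])
    (other - own) / max(own, other)
  }, numeric(1))
  mean(sil)
}
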