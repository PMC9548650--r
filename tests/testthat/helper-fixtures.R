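# Shared fixtures and independent oracles. Oracles are written from the
# definitions (nested loops, closed forms) and never call the package's own
# fast paths.

# minimal 4-region scheme, two "primary" pairs, rows in scheme order
minimal_scheme <- function() {
  parcellation_scheme(data.frame(
    region_id = c("L1", "L2", "R1", "R2"),
    label = c("a", "b", "a", "b"),
    hemisphere = c("L", "L", "R", "R"),
    pair_index = c(1L, 2L, 1L, 2L),
    submodule = "primary"))
}

# 4-region scheme with interleaved rows, to exercise index bookkeeping
interleaved_scheme <- function() {
  parcellation_scheme(data.frame(
    region_id = c("L2", "R1", "L1", "R2"),
    label = c("b", "a", "a", "b"),
    hemisphere = c("L", "R", "L", "R"),
    pair_index = c(2L, 1L, 1L, 2L),
    submodule = "primary"))
}

# 12-region scheme (6 pairs): 3 primary pairs + 3 unimodal pairs
two_module_scheme <- function() {
  parcellation_scheme(data.frame(
    region_id = c(sprintf("L%d", 1:6), sprintf("R%d", 1:6)),
    label = rep(c("p1", "p2", "u1", "p3", "u2", "u3"), 2L),
    hemisphere = rep(c("L", "R"), each = 6L),
    pair_index = rep(1:6, 2L),
    submodule = rep(c("primary", "primary", "unimodal", "primary",
                      "unimodal", "unimodal"), 2L)))
}

random_timeseries <- function(scheme, t = 50L, subject_id = "S1", seed = 1L) {
  set.seed(seed)
  roi_timeseries(subject_id,
                 matrix(rnorm(t * nrow(scheme)), t, nrow(scheme)), scheme)
}

# brute-force Pearson correlation from the defining formula
brute_pearson <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# brute-force FC matrix: two nested loops over region pairs
brute_fc <- function(X) {
  n <- ncol(X)
  out <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) out[i, j] <- brute_pearson(X[, i], X[, j])
  out
}

# slow identification under relabelled database entries: rebuilds the
# database with permuted subject labels and re-runs the argmax matching
# per target, independent of the fast label-permutation path
slow_permuted_success <- function(edges, perm, direction = "lr",
                                  ipsilateral_included = FALSE) {
  n <- length(edges$subject_ids)
  target_h <- if (direction == "lr") "L" else "R"
  contra_h <- if (direction == "lr") "R" else "L"
  correct <- 0L
  for (i in seq_len(n)) {
    vecs <- edges[[contra_h]]
    labels <- edges$subject_ids[perm]          # relabelled contra entries
    if (ipsilateral_included) {
      vecs <- rbind(vecs, edges[[target_h]][-i, , drop = FALSE])
      labels <- c(labels, edges$subject_ids[perm][-i])
    }
    r <- apply(vecs, 1L, brute_pearson, y = edges[[target_h]][i, ])
    if (labels[which.max(r)] == edges$subject_ids[i]) correct <- correct + 1L
  }
  correct / n
}
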