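make_edge_set <- function(L, R, ids) {
  structure(list(L = L, R = R, subject_ids = ids,
                 level = "hemisphere", scale = "fisher_z"),
            class = "edge_set")
}

test_that("identify_one picks the database entry with maximal correlation", {
  set.seed(41)
  target <- rnorm(30)

  db <- structure(list(
    vectors = rbind(rnorm(30), rnorm(30), target),
    subject_ids = c("S1", "S2", "S3"),
    hemispheres = rep("R", 3L)), class = "fc_database")
  hit <- identify_one(target, db)
  expect_equal(hit$predicted_id, "S3")
  expect_equal(hit$max_correlation, 1)
  expect_false(hit$ambiguous)

  # noisy copy among near-orthogonal entries: brute-force correlations agree
  noisy <- target + 0.4 * rnorm(30)
  db2 <- structure(list(
    vectors = rbind(rnorm(30), noisy, rnorm(30)),
    subject_ids = c("A", "B", "C"),
    hemispheres = rep("R", 3L)), class = "fc_database")
  hit2 <- identify_one(target, db2)
  brute <- apply(db2$vectors, 1L, brute_pearson, y = target)
  expect_equal(hit2$predicted_id, "B")
  expect_equal(hit2$correlations, unname(brute), tolerance = 1e-12)

  # exact tie: first entry wins, flagged ambiguous
  db3 <- structure(list(
    vectors = rbind(target, target),
    subject_ids = c("S9", "S1"),
    hemispheres = rep("R", 2L)), class = "fc_database")
  hit3 <- identify_one(target, db3)
  expect_equal(hit3$predicted_id, "S9")
  expect_true(hit3$ambiguous)

  expect_error(identify_one(rep(1, 30), db), "zero-variance")
  expect_error(identify_one(rnorm(10), db), "length")
})

test_that("database contents follow the with/without-ipsilateral contract", {
  set.seed(42)
  ed <- make_edge_set(matrix(rnorm(4 * 20), 4L), matrix(rnorm(4 * 20), 4L),
                      sprintf("S%d", 1:4))

  woih <- build_database(ed, target_hemisphere = "L", target_id = "S2")
  expect_equal(woih$subject_ids, sprintf("S%d", 1:4))
  expect_true(all(woih$hemispheres == "R"))

  wih <- build_database(ed, target_hemisphere = "L", target_id = "S2",
                        ipsilateral_included = TRUE)
  expect_equal(nrow(wih$vectors), 7L)   # 4 contralateral + 3 ipsilateral
  expect_equal(wih$subject_ids, c("S1", "S2", "S3", "S4", "S1", "S3", "S4"))
  expect_equal(wih$hemispheres, c(rep("R", 4L), rep("L", 3L)))
  # the target's own ipsilateral vector is absent
  expect_false(any(wih$hemispheres == "L" & wih$subject_ids == "S2"))

  expect_error(build_database(ed, "L", target_id = "nope",
                              ipsilateral_included = TRUE), "not found")
})

test_that("strong fingerprints are identified perfectly in both directions", {
  cf <- cohort_config(n_subjects = 20, b2 = 0.5, c02 = 0.1,
                      noise_variance = 0.1, n_timepoints = 300, seed = 43)
  ed <- edge_vectors(generate_cohort(cf))
  for (dir in c("lr", "rl")) {
    expect_equal(run_identification(ed, dir)$success_rate, 1.0)
    expect_equal(run_identification(ed, dir,
                                    ipsilateral_included = TRUE)$success_rate,
                 1.0)
  }
})

test_that("without a fingerprint component identification is at chance", {
  cf <- cohort_config(n_subjects = 20, a2 = 1, b2 = 0, c02 = 0, seed = 44)
  ed <- edge_vectors(generate_cohort(cf))
  res <- run_identification(ed, "lr")
  # success count consistent with Binomial(20, 1/20)
  bt <- stats::binom.test(sum(res$matches$correct), 20L, p = 1 / 20)
  expect_gt(bt$p.value, 0.01)
})

test_that("identification requires at least two subjects", {
  ed <- make_edge_set(matrix(rnorm(20), 1L), matrix(rnorm(20), 1L), "S1")
  expect_error(run_identification(ed, "lr"), "at least 2 subjects")
})

test_that("the identity permutation reproduces the observed rate and
           n_iter must be positive", {
  cf <- cohort_config(n_subjects = 10, seed = 45)
  ed <- edge_vectors(generate_cohort(cf))
  pt <- permutation_test(ed, "lr", permutations = list(1:10))
  expect_equal(pt$null_rates, pt$observed_rate)
  expect_equal(pt$empirical_p, 1)

  expect_error(permutation_test(ed, "lr", n_iter = 0L), "n_iter")
  expect_error(permutation_test(ed, "lr", permutations = list(c(1:9, 9L))),
               "not a permutation")
})

test_that("fast label-permutation path agrees exactly with a slow relabelled
           re-identification", {
  cf <- cohort_config(n_subjects = 12, seed = 46)
  ed <- edge_vectors(generate_cohort(cf))
  set.seed(460)
  perms <- replicate(10, sample.int(12L), simplify = FALSE)

  for (wih in c(FALSE, TRUE)) {
    fast <- permutation_test(ed, "lr", ipsilateral_included = wih,
                             permutations = perms)
    slow <- vapply(perms, slow_permuted_success, numeric(1L),
                   edges = ed, direction = "lr",
                   ipsilateral_included = wih)
    expect_identical(fast$null_rates, slow)
  }
})

test_that("permutation results are seed-reproducible and the null mean
           success count is ~1 for exchangeable cohorts", {
  for (n in c(20L, 50L)) {
    cf <- cohort_config(n_subjects = n, a2 = 1, b2 = 0, c02 = 0,
                        seed = 47L + n)
    ed <- edge_vectors(generate_cohort(cf))
    pt <- permutation_test(ed, "lr", n_iter = 500L, seed = 48L)
    pt2 <- permutation_test(ed, "lr", n_iter = 500L, seed = 48L)
    expect_identical(pt$null_rates, pt2$null_rates)
    se <- stats::sd(pt$null_counts) / sqrt(length(pt$null_counts))
    expect_lt(abs(mean(pt$null_counts) - 1), 3 * se)
  }
})
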