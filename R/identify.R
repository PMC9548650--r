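#' Edge vectors for a cohort at one analysis level
#'
#' Runs each subject through the FC pipeline (optional GSR, Pearson FC,
#' Fisher-z by default, hemisphere split, optional sub-module extraction) and
#' stacks the left- and right-hemisphere edge vectors into two aligned
#' matrices. This is the input to HSFC-based fingerprint identification.
#'
#' @param cohort a `synthetic_cohort` or list of [roi_timeseries].
#' @param level `"hemisphere"` or a sub-module name.
#' @param scheme required when `cohort` is a plain list.
#' @param gsr logical; parcel-level global signal regression.
#' @param scale `"fisher_z"` (default analysis scale) or `"pearson_r"`.
#' @return an object of class `edge_set`: list with `L` and `R` (N x m
#'   matrices of edge vectors, rows named by subject), `subject_ids`,
#'   `level`, `scale`.
#' @export
edge_vectors <- function(cohort, level = "hemisphere", scheme = NULL,
                         gsr = FALSE, scale = c("fisher_z", "pearson_r")) {
  scale <- match.arg(scale)
  level <- match.arg(level, .HSFC_LEVELS)
  ts_list <- cohort_timeseries(cohort)
  if (is.null(scheme)) scheme <- cohort_scheme(cohort)
  ids <- vapply(ts_list, function(ts) ts$subject_id, character(1L))
  if (anyDuplicated(ids))
    stop("duplicate subject ids in cohort")
  vecs <- lapply(ts_list, function(ts) {
    fc <- compute_fc(ts, gsr = gsr)
    if (scale == "fisher_z") fc <- fisher_z(fc)
    hemis <- split_hemispheres(fc, scheme)
    if (level != "hemisphere")
      hemis <- lapply(hemis, extract_submodule, module = level)
    list(L = vectorize_upper(hemis$L), R = vectorize_upper(hemis$R))
  })
  structure(list(
    L = do.call(rbind, lapply(vecs, `[[`, "L")),
    R = do.call(rbind, lapply(vecs, `[[`, "R")),
    subject_ids = ids, level = level, scale = scale),
    class = "edge_set")
}

#' Build an identification database
#'
#' The database against which one target edge vector is matched. Without the
#' ipsilateral hemisphere it holds every subject's contralateral edge vector;
#' with it, it additionally holds every same-hemisphere (ipsilateral) vector
#' except the target subject's own.
#'
#' @param edges an `edge_set` (see [edge_vectors]).
#' @param target_hemisphere hemisphere of the target vector, `"L"` or `"R"`.
#' @param target_id the target subject's id (needed to exclude their own
#'   ipsilateral entry when `ipsilateral_included = TRUE`).
#' @param ipsilateral_included logical.
#' @return a list of class `fc_database` with `vectors` (M x m matrix),
#'   `subject_ids` (length M), `hemispheres` (length M).
#' @export
build_database <- function(edges, target_hemisphere = c("L", "R"),
                           target_id = NULL, ipsilateral_included = FALSE) {
  stopifnot(inherits(edges, "edge_set"))
  target_hemisphere <- match.arg(target_hemisphere)
  contra <- if (target_hemisphere == "L") "R" else "L"
  vectors <- edges[[contra]]
  ids <- edges$subject_ids
  hemis <- rep(contra, length(ids))
  if (ipsilateral_included) {
    if (is.null(target_id))
      stop("target_id is required when ipsilateral_included = TRUE")
    keep <- edges$subject_ids != target_id
    if (all(keep))
      stop("target_id '", target_id, "' not found in edge set")
    vectors <- rbind(vectors, edges[[target_hemisphere]][keep, , drop = FALSE])
    ids <- c(ids, edges$subject_ids[keep])
    hemis <- c(hemis, rep(target_hemisphere, sum(keep)))
  }
  structure(list(vectors = vectors, subject_ids = ids, hemispheres = hemis),
            class = "fc_database")
}

#' Match one target edge vector against a database
#'
#' Computes the Pearson correlation between the target vector and every
#' database entry and predicts the subject id of the entry with the maximum
#' correlation (the fingerprinting rule). Exact ties are broken by the first
#' entry in database order and flagged `ambiguous`.
#'
#' @param target numeric edge vector.
#' @param db an `fc_database` (see [build_database]).
#' @return list with `predicted_id`, `max_correlation`, `correlations`
#'   (one per database entry), `ambiguous`.
#' @export
identify_one <- function(target, db) {
  stopifnot(inherits(db, "fc_database"))
  if (length(target) != ncol(db$vectors))
    stop("target vector length ", length(target),
         " does not match database entries (", ncol(db$vectors), ")")
  if (stats::var(target) == 0) stop("zero-variance target vector")
  if (any(apply(db$vectors, 1L, stats::var) == 0))
    stop("zero-variance database entry")
  r <- as.vector(stats::cor(target, t(db$vectors))[1L, ])
  best <- which.max(r)
  list(predicted_id = db$subject_ids[best],
       max_correlation = r[best],
       correlations = r,
       ambiguous = sum(r == r[best]) > 1L)
}

#' Cross-hemisphere individual identification over a cohort
#'
#' Each subject's hemisphere at the requested level is used in turn as the
#' target and matched (by maximal Pearson correlation of edge vectors)
#' against the database of the contralateral hemisphere of all subjects --
#' optionally augmented with every ipsilateral vector except the target's
#' own. A subject is correctly identified when the best-matching entry
#' belongs to them; with the ipsilateral hemisphere included this can only
#' happen via their contralateral entry, since their own ipsilateral entry is
#' excluded from the database.
#'
#' @param edges an `edge_set` with at least 2 subjects (see [edge_vectors]).
#' @param direction `"lr"` (left-hemisphere targets identified in the
#'   right-hemisphere database) or `"rl"`.
#' @param ipsilateral_included logical (the WIH condition).
#' @return an object of class `identification_result`: list with `matches`
#'   (data.frame: `target_id`, `predicted_id`, `max_correlation`, `correct`,
#'   `ambiguous`), `success_rate`, `n_subjects`, `direction`,
#'   `ipsilateral_included`, `level`, and `best_db_index` (index into
#'   `subject_ids` of each target's best-matching database subject, used by
#'   the fast permutation path).
#' @export
run_identification <- function(edges, direction = c("lr", "rl"),
                               ipsilateral_included = FALSE) {
  stopifnot(inherits(edges, "edge_set"))
  direction <- match.arg(direction)
  n <- length(edges$subject_ids)
  if (n < 2L) stop("need at least 2 subjects, got ", n)
  target_h <- if (direction == "lr") "L" else "R"
  contra_h <- if (direction == "lr") "R" else "L"
  targets <- edges[[target_h]]
  if (any(apply(targets, 1L, stats::var) == 0) ||
      any(apply(edges[[contra_h]], 1L, stats::var) == 0))
    stop("zero-variance edge vector in cohort")

  # correlations of every target against every contralateral (and, for WIH,
  # ipsilateral) entry, computed once
  C_contra <- stats::cor(t(targets), t(edges[[contra_h]]))   # n x n
  if (ipsilateral_included) {
    C_ipsi <- stats::cor(t(targets), t(targets))             # n x n
    diag(C_ipsi) <- -Inf    # a target's own ipsilateral entry is excluded
  }
  best_idx <- integer(n)
  best_r <- numeric(n)
  ambiguous <- logical(n)
  for (i in seq_len(n)) {
    r <- C_contra[i, ]
    lab <- seq_len(n)
    if (ipsilateral_included) {
      r <- c(r, C_ipsi[i, -i])
      lab <- c(lab, seq_len(n)[-i])
    }
    b <- which.max(r)
    best_idx[i] <- lab[b]
    best_r[i] <- r[b]
    ambiguous[i] <- sum(r == r[b]) > 1L
  }
  correct <- best_idx == seq_len(n)
  matches <- data.frame(
    target_id = edges$subject_ids,
    predicted_id = edges$subject_ids[best_idx],
    max_correlation = best_r,
    correct = correct,
    ambiguous = ambiguous,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(matches = matches,
                 success_rate = mean(correct),
                 n_subjects = n,
                 direction = direction,
                 ipsilateral_included = ipsilateral_included,
                 level = edges$level,
                 best_db_index = best_idx),
            class = "identification_result")
}

#' Permutation test for identification accuracy
#'
#' Assesses the significance of an observed identification success rate by
#' randomly shuffling which database matrix belongs to which subject: each
#' iteration draws a uniform random permutation of the database subject
#' labels, recomputes the number of correct identifications under the
#' shuffled labels, and records the null success rate. Because relabelling
#' does not change any correlation, the identity of each target's
#' best-matching database entry is fixed, and the null success count of a
#' permutation equals the number of targets whose best-matching subject is
#' relabelled back to themselves -- so the precomputed correlations from
#' [run_identification] are reused and each iteration costs O(N).
#'
#' @param edges an `edge_set`.
#' @param direction,ipsilateral_included as in [run_identification].
#' @param n_iter number of random permutations (>= 1), default 1000.
#' @param seed integer seed for reproducibility (optional).
#' @param permutations optional list of explicit permutations of
#'   `1..N` to use instead of random ones (overrides `n_iter`/`seed`);
#'   intended for validation against an independent slow re-identification.
#' @return an object of class `permutation_result`: list with `n_iterations`,
#'   `null_rates`, `max_null_rate`, `observed_rate`, `empirical_p` (raw
#'   proportion of null rates >= observed; can be exactly 0),
#'   `empirical_p_add_one` (the (k+1)/(n+1) corrected version), `seed`, and
#'   the underlying `identification` result.
#' @export
permutation_test <- function(edges, direction = c("lr", "rl"),
                             ipsilateral_included = FALSE, n_iter = 1000L,
                             seed = NULL, permutations = NULL) {
  res <- run_identification(edges, direction = direction,
                            ipsilateral_included = ipsilateral_included)
  n <- res$n_subjects
  if (is.null(permutations)) {
    if (n_iter < 1L) stop("n_iter must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    permutations <- replicate(n_iter, sample.int(n), simplify = FALSE)
  } else {
    bad <- !vapply(permutations, function(p)
      length(p) == n && all(sort(p) == seq_len(n)), logical(1L))
    if (any(bad))
      stop("permutations[[", which(bad)[1L], "]] is not a permutation of 1..n")
    n_iter <- length(permutations)
  }
  best <- res$best_db_index
  null_counts <- vapply(permutations, function(p) sum(p[best] == seq_len(n)),
                        numeric(1L))
  null_rates <- null_counts / n
  structure(list(n_iterations = length(permutations),
                 null_rates = null_rates,
                 null_counts = null_counts,
                 max_null_rate = max(null_rates),
                 observed_rate = res$success_rate,
                 empirical_p = mean(null_rates >= res$success_rate),
                 empirical_p_add_one =
                   (sum(null_rates >= res$success_rate) + 1) /
                   (length(permutations) + 1),
                 seed = seed,
                 identification = res),
            class = "permutation_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat("Cross-hemisphere identification (", x$level, " level, ",
      if (x$direction == "lr") "LH->RH" else "RH->LH",
      if (x$ipsilateral_included) ", with ipsilateral" else
        ", without ipsilateral",
      ")\n", sep = "")
  cat(sprintf("  %d/%d correct (success rate %.3f)\n",
              sum(x$matches$correct), x$n_subjects, x$success_rate))
  invisible(x)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test:", x$n_iterations, "label shuffles\n")
  cat(sprintf("  observed success rate %.3f; max null rate %.3f; p = %.4g\n",
              x$observed_rate, x$max_null_rate, x$empirical_p))
  invisible(x)
}
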