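#' Hemispheric similarity of functional connectivity (HSFC)
#'
#' HSFC is the Pearson correlation between a subject's left- and
#' right-hemisphere FC edge vectors: 1 means perfectly mirrored intra-
#' hemisphere connectomes, values near 0 mean the two hemispheres' connection
#' patterns are unrelated. Because both hemisphere matrices are ordered by
#' homotopic pair index, the k-th edge of each vector connects the same two
#' homotopic region pairs on either side of the brain.
#'
#' @param L,R `hemi_fc` matrices of the same dimension and scale (see
#'   [split_hemispheres]); plain symmetric matrices are also accepted.
#' @return HSFC, a real number in [-1, 1].
#' @details Only within-hemisphere, strictly-upper-triangle edges enter the
#'   correlation (n(n-1)/2 of them); the diagonal is excluded because the
#'   Fisher-z of a unit self-correlation is infinite. Errors if there are
#'   fewer than 3 edges or either edge vector has zero variance.
#' @examples
#' m <- matrix(c(1, .5, .2, .5, 1, .1, .2, .1, 1), 3)
#' compute_hsfc(m, m)  # identical hemispheres: HSFC = 1
#' @export
compute_hsfc <- function(L, R) {
  vL <- vectorize_upper(L)
  vR <- vectorize_upper(R)
  if (length(vL) != length(vR))
    stop("hemisphere matrices have different dimensions")
  if (inherits(L, "fc_matrix") && inherits(R, "fc_matrix") &&
      !identical(fc_scale(L), fc_scale(R)))
    stop("hemisphere matrices have different scales")
  if (length(vL) < 3L)
    stop("need at least 3 edges, got ", length(vL))
  if (stats::var(vL) == 0 || stats::var(vR) == 0)
    stop("zero-variance edge vector")
  stats::cor(vL, vR)
}

#' Per-subject HSFC profile across hemisphere and sub-module levels
#'
#' Computes HSFC at the whole-hemisphere level and within each functional
#' sub-module block present in the scheme, from one subject's whole-brain FC
#' matrix.
#'
#' @param fc a whole-brain [fc_matrix] for one subject (scale `pearson_r` or
#'   `fisher_z`).
#' @param scheme the matching [parcellation_scheme].
#' @param levels which levels to compute; default `"hemisphere"` plus every
#'   sub-module with at least 2 pairs in the scheme. Requesting a sub-module
#'   the scheme lacks is an error.
#' @param use_fisher logical; if `fc` is on the `pearson_r` scale, apply the
#'   Fisher-z transform before computing HSFC (the default analysis scale).
#'   Set `FALSE` for a raw-correlation sensitivity check.
#' @param subject_id identifier recorded in the output.
#' @return a data.frame of HSFC records with columns `subject_id`, `level`,
#'   `hsfc`.
#' @export
hsfc_profile <- function(fc, scheme, levels = NULL, use_fisher = TRUE,
                         subject_id = "subject") {
  stopifnot(inherits(fc, "fc_matrix"))
  if (use_fisher && fc_scale(fc) == "pearson_r") fc <- fisher_z(fc)
  hemis <- split_hemispheres(fc, scheme)
  if (is.null(levels)) {
    levels <- c("hemisphere", scheme_submodules(scheme))
  } else {
    levels <- match.arg(levels, .HSFC_LEVELS, several.ok = TRUE)
  }
  vals <- vapply(levels, function(lv) {
    if (lv == "hemisphere") {
      compute_hsfc(hemis$L, hemis$R)
    } else {
      compute_hsfc(extract_submodule(hemis$L, lv),
                   extract_submodule(hemis$R, lv))
    }
  }, numeric(1L))
  data.frame(subject_id = subject_id, level = levels, hsfc = unname(vals),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' HSFC records for a whole cohort
#'
#' Runs the full per-subject pipeline (optional global-signal regression,
#' Pearson FC, Fisher-z, hemisphere split, HSFC at each level) over a list of
#' time series or a synthetic cohort.
#'
#' @param cohort a `synthetic_cohort` (see [generate_cohort]) or a list of
#'   [roi_timeseries].
#' @param scheme required when `cohort` is a plain list.
#' @param levels,use_fisher passed to [hsfc_profile].
#' @param gsr logical; apply parcel-level global signal regression.
#' @return a data.frame of HSFC records (`subject_id`, `level`, `hsfc`).
#' @export
hsfc_cohort <- function(cohort, scheme = NULL, levels = NULL,
                        use_fisher = TRUE, gsr = FALSE) {
  ts_list <- cohort_timeseries(cohort)
  if (is.null(scheme)) scheme <- cohort_scheme(cohort)
  recs <- lapply(ts_list, function(ts) {
    hsfc_profile(compute_fc(ts, gsr = gsr), scheme, levels = levels,
                 use_fisher = use_fisher, subject_id = ts$subject_id)
  })
  do.call(rbind, recs)
}

#' Group-level HSFC summary (mean +/- SD per age group and level)
#'
#' @param records HSFC records as returned by [hsfc_cohort].
#' @param meta subject metadata data.frame with columns `subject_id` and
#'   either `group` or `age` (groups derived via [assign_group]).
#' @return a data.frame with one row per (group, level): `n`, `mean`, `sd`
#'   (sample SD, n-1 denominator). Empty groups get `n = 0` and `NA`
#'   statistics.
#' @export
group_summary <- function(records, meta) {
  if (!all(c("subject_id", "level", "hsfc") %in% names(records)))
    stop("records must have columns subject_id, level, hsfc")
  if (!"group" %in% names(meta)) {
    if (!"age" %in% names(meta))
      stop("meta needs a 'group' or 'age' column")
    meta$group <- vapply(meta$age, assign_group, character(1L))
  }
  missing_meta <- setdiff(records$subject_id, meta$subject_id)
  if (length(missing_meta) > 0L)
    stop("no metadata for subject(s): ",
         paste(utils::head(missing_meta, 5L), collapse = ", "))
  records$group <- meta$group[match(records$subject_id, meta$subject_id)]
  groups <- c("Young", "Middle", "Old")
  levels <- unique(records$level)
  out <- expand.grid(group = groups, level = levels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats_ <- t(mapply(function(g, lv) {
    x <- records$hsfc[records$group == g & records$level == lv]
    c(n = length(x),
      mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1L) stats::sd(x) else NA_real_)
  }, out$group, out$level))
  cbind(out, as.data.frame(stats_))
}
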