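#' Configuration for the synthetic cohort generator
#'
#' The generator draws each subject's hemispheric connectivity from a latent
#' factor model with three loading components: a group template `B_g` shared
#' by everyone, a subject "fingerprint" `B_i` shared by a subject's two
#' hemispheres, and a hemisphere-specific asymmetry term. Their variance
#' weights `a2` (group), `b2` (fingerprint) and `c2` (asymmetry) control how
#' identifiable subjects are across hemispheres and how similar the two
#' hemispheres' connectomes are: HSFC falls as the asymmetry share
#' `c2 / (b2 + c2)` grows. The asymmetry weight may drift linearly with age
#' (`age_slope`), giving an age-declining HSFC by construction, and may be
#' amplified per sub-module (`asym_multipliers`), giving sub-module HSFC
#' heterogeneity.
#'
#' @param n_subjects number of subjects.
#' @param regions_per_hemisphere homotopic pairs per hemisphere (default 40).
#' @param n_timepoints timepoints T per subject (default 200).
#' @param n_factors latent factors K (default 10).
#' @param a2,b2,c02 non-negative variance weights of the group, fingerprint
#'   and baseline asymmetry components, `a2 + b2 + c02 <= 1`; each subject's
#'   realized weights are renormalized to sum to 1 after the age shift,
#'   preserving the `a2 : b2` ratio. Defaults 0.4 / 0.5 / 0.1.
#' @param age_slope shift of the asymmetry weight `c2` per unit of normalized
#'   age `u = (age - 18)/70` (default 0: no age effect). Must satisfy
#'   `c02 + max(0, age_slope) <= 1 - a2` so the shifted weight stays
#'   clippable without exhausting the non-group variance.
#' @param noise_variance observation noise variance `psi` added to each
#'   region's unit-variance signal (default 0.2).
#' @param submodule_pairs named integer vector: homotopic pairs per
#'   sub-module; must sum to `regions_per_hemisphere`. Default
#'   `c(heteromodal = 12, paralimbic = 6, primary = 8, unimodal = 10,
#'   subcortical = 4)`.
#' @param asym_multipliers named non-negative multipliers applied to the
#'   asymmetry loading rows of each sub-module's regions (default all 1).
#' @param seed integer seed; all of the generator's randomness derives from
#'   it.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects,
                          regions_per_hemisphere = 40L,
                          n_timepoints = 200L,
                          n_factors = 10L,
                          a2 = 0.4, b2 = 0.5, c02 = 0.1,
                          age_slope = 0,
                          noise_variance = 0.2,
                          submodule_pairs = c(heteromodal = 12L,
                                              paralimbic = 6L,
                                              primary = 8L,
                                              unimodal = 10L,
                                              subcortical = 4L),
                          asym_multipliers = NULL,
                          seed = 1L) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (n_timepoints < 3L) stop("n_timepoints must be >= 3")
  if (n_factors < 1L) stop("n_factors must be >= 1")
  if (a2 < 0 || b2 < 0 || c02 < 0)
    stop("variance weights must be non-negative")
  if (a2 + b2 + c02 > 1 + 1e-12)
    stop("a2 + b2 + c02 must be <= 1, got ", a2 + b2 + c02)
  if (c02 + max(0, age_slope) > 1 - a2 + 1e-12)
    stop("c02 + max(0, age_slope) exceeds 1 - a2: the age-shifted ",
         "asymmetry weight would leave no room for the fingerprint")
  if (!all(names(submodule_pairs) %in% .SUBMODULES))
    stop("unknown submodule in submodule_pairs")
  if (sum(submodule_pairs) != regions_per_hemisphere)
    stop("submodule_pairs must sum to regions_per_hemisphere (",
         sum(submodule_pairs), " vs ", regions_per_hemisphere, ")")
  if (noise_variance < 0) stop("noise_variance must be >= 0")
  m <- stats::setNames(rep(1, length(submodule_pairs)),
                       names(submodule_pairs))
  if (!is.null(asym_multipliers)) {
    if (is.null(names(asym_multipliers)) ||
        !all(names(asym_multipliers) %in% names(submodule_pairs)))
      stop("asym_multipliers must be named by sub-modules in submodule_pairs")
    if (any(asym_multipliers < 0)) stop("asym_multipliers must be >= 0")
    m[names(asym_multipliers)] <- asym_multipliers
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 regions_per_hemisphere = as.integer(regions_per_hemisphere),
                 n_timepoints = as.integer(n_timepoints),
                 n_factors = as.integer(n_factors),
                 a2 = a2, b2 = b2, c02 = c02,
                 age_slope = age_slope,
                 noise_variance = noise_variance,
                 submodule_pairs = submodule_pairs,
                 asym_multipliers = m,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Build the generator's parcellation scheme
#'
#' Regions are laid out as the full left hemisphere followed by the full
#' right hemisphere, pairs grouped by sub-module in the order of
#' `submodule_pairs`.
#'
#' @param config a [cohort_config].
#' @return a [parcellation_scheme].
#' @export
config_scheme <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  submods <- rep(names(config$submodule_pairs), config$submodule_pairs)
  n <- config$regions_per_hemisphere
  labels <- paste0(submods, "_", unlist(lapply(config$submodule_pairs,
                                               seq_len)))
  parcellation_scheme(data.frame(
    region_id = c(sprintf("L%03d", seq_len(n)), sprintf("R%03d", seq_len(n))),
    label = rep(labels, 2L),
    hemisphere = rep(c("L", "R"), each = n),
    pair_index = rep(seq_len(n), 2L),
    submodule = rep(submods, 2L)))
}

#' Generate a synthetic bihemispheric cohort
#'
#' For subject i with normalized age `u_i = (age_i - 18)/70`, the asymmetry
#' weight is `c_i^2 = c02 + age_slope * u_i`, clipped to `[0, 1 - a2]`; the
#' group and fingerprint weights are then rescaled (preserving their ratio)
#' so the three weights sum to 1. The loading matrix of hemisphere h is
#' `B_ih = a_i B_g + b_i B_i + c_i diag(m) B_ih^asym`, where all component
#' matrices are (R/2) x K with i.i.d. N(0, 1/K) entries, homotopic partners
#' use the same rows of `B_g` and `B_i`, `diag(m)` applies each region's
#' sub-module asymmetry multiplier, and each row is renormalized to unit
#' length so every region's signal variance is 1. The time series are
#' `x_t = B_ih u_t + sqrt(psi) eps_t` with independent standard-normal factor
#' scores `u_t` per hemisphere and white observation noise, so hemispheric
#' similarity and cross-hemisphere identifiability flow through the shared
#' loadings only, not through shared realization noise.
#'
#' @param config a [cohort_config].
#' @return an object of class `synthetic_cohort`: list with `scheme`
#'   ([parcellation_scheme]), `meta` (data.frame `subject_id`, `age`, `sex`,
#'   `group`), `timeseries` (list of [roi_timeseries]), `loadings` (the
#'   realized per-subject, per-hemisphere loading matrices, so the implied
#'   population FC `(B B' + psi I) / (1 + psi)` is available for checks) and
#'   `config`. Ages
#'   are uniform on [18, 88]. Running twice with the same config (hence
#'   seed) gives identical output.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$regions_per_hemisphere
  K <- config$n_factors
  Tt <- config$n_timepoints
  N <- config$n_subjects
  scheme <- config_scheme(config)
  m_row <- config$asym_multipliers[
    rep(names(config$submodule_pairs), config$submodule_pairs)]

  age <- stats::runif(N, 18, 88)
  sex <- sample(c("male", "female"), N, replace = TRUE)
  ids <- sprintf("S%04d", seq_len(N))
  u <- (age - 18) / 70
  c2 <- pmin(pmax(config$c02 + config$age_slope * u, 0), 1 - config$a2)
  ab <- config$a2 + config$b2
  if (ab > 0) {
    s <- (1 - c2) / ab
    a2i <- config$a2 * s
    b2i <- config$b2 * s
  } else {
    if (any(abs(c2 - 1) > 1e-12))
      stop("a2 = b2 = 0 requires the asymmetry weight to be exactly 1")
    a2i <- b2i <- rep(0, N)
  }

  Bg <- matrix(stats::rnorm(n * K), n, K) / sqrt(K)
  ts_list <- vector("list", N)
  loadings <- vector("list", N)
  for (i in seq_len(N)) {
    Bi <- matrix(stats::rnorm(n * K), n, K) / sqrt(K)
    X <- matrix(0, Tt, 2L * n)
    Bs <- list()
    for (h in 1:2) {
      Basym <- matrix(stats::rnorm(n * K), n, K) / sqrt(K)
      B <- sqrt(a2i[i]) * Bg + sqrt(b2i[i]) * Bi +
        sqrt(c2[i]) * (m_row * Basym)
      B <- B / sqrt(rowSums(B^2))
      U <- matrix(stats::rnorm(Tt * K), Tt, K)
      E <- matrix(stats::rnorm(Tt * n), Tt, n)
      X[, (h - 1L) * n + seq_len(n)] <-
        U %*% t(B) + sqrt(config$noise_variance) * E
      Bs[[c("L", "R")[h]]] <- B
    }
    ts_list[[i]] <- roi_timeseries(ids[i], X, scheme)
    loadings[[i]] <- Bs
  }
  names(loadings) <- ids
  meta <- data.frame(subject_id = ids, age = age, sex = sex,
                     group = vapply(age, assign_group, character(1L)),
                     stringsAsFactors = FALSE)
  structure(list(scheme = scheme, meta = meta, timeseries = ts_list,
                 loadings = loadings, config = config),
            class = "synthetic_cohort")
}

#' Coarsen a parcellation and its time series
#'
#' Merges `merge_factor` consecutive homotopic pairs (within hemisphere and
#' sub-module, in pair order) into one coarse region whose series is the
#' mean of its members' series, emulating the re-analysis of the same
#' signals under a second, coarser parcellation. Homotopic pairing and
#' sub-module labels are induced from the members; merging across a
#' sub-module boundary is never performed, so every sub-module's pair count
#' must be divisible by `merge_factor`.
#'
#' @param scheme a [parcellation_scheme].
#' @param ts_list a list of [roi_timeseries] on `scheme`, or a
#'   `synthetic_cohort`.
#' @param merge_factor pairs merged per coarse region (default 2);
#'   `merge_factor = 1` returns the inputs unchanged.
#' @return list with `scheme` (coarse [parcellation_scheme]) and
#'   `timeseries` (list of coarse [roi_timeseries]).
#' @export
derive_coarse_scheme <- function(scheme, ts_list, merge_factor = 2L) {
  if (inherits(ts_list, "synthetic_cohort")) ts_list <- ts_list$timeseries
  stopifnot(inherits(scheme, "parcellation_scheme"))
  merge_factor <- as.integer(merge_factor)
  if (merge_factor < 1L) stop("merge_factor must be >= 1")
  if (merge_factor == 1L)
    return(list(scheme = scheme, timeseries = ts_list))
  half <- n_pairs(scheme)
  if (half %% merge_factor != 0L)
    stop("regions_per_hemisphere (", half,
         ") is not divisible by merge_factor ", merge_factor)
  submods <- pair_submodules(scheme)
  counts <- table(submods)
  bad <- names(counts)[as.vector(counts) %% merge_factor != 0L]
  if (length(bad) > 0L)
    stop("sub-module '", bad[1L], "' has ", counts[bad[1L]],
         " pairs, not divisible by merge_factor ", merge_factor,
         "; refusing to merge across sub-module boundaries")

  # group consecutive pairs within each sub-module, keeping pair order
  ord <- order(match(submods, unique(submods)), seq_len(half))
  groups <- split(ord, ceiling(seq_len(half) / merge_factor))
  n_coarse <- length(groups)
  g_sub <- vapply(groups, function(g) submods[g[1L]], character(1L))
  stopifnot(all(vapply(groups, function(g)
    length(unique(submods[g])) == 1L, logical(1L))))

  coarse_scheme <- parcellation_scheme(data.frame(
    region_id = c(sprintf("Lc%03d", seq_len(n_coarse)),
                  sprintf("Rc%03d", seq_len(n_coarse))),
    label = rep(paste0(g_sub, "_c", seq_len(n_coarse)), 2L),
    hemisphere = rep(c("L", "R"), each = n_coarse),
    pair_index = rep(seq_len(n_coarse), 2L),
    submodule = rep(g_sub, 2L)))

  row_of <- function(h, p) which(scheme$hemisphere == h &
                                   scheme$pair_index == p)
  coarse_ts <- lapply(ts_list, function(ts) {
    X <- matrix(0, nrow(ts$data), 2L * n_coarse)
    for (k in seq_len(n_coarse)) {
      for (h in c("L", "R")) {
        cols <- vapply(groups[[k]], function(p) row_of(h, p), integer(1L))
        j <- (if (h == "L") 0L else n_coarse) + k
        X[, j] <- rowMeans(ts$data[, cols, drop = FALSE])
      }
    }
    roi_timeseries(ts$subject_id, X, coarse_scheme)
  })
  list(scheme = coarse_scheme, timeseries = coarse_ts)
}

#' Extract the time-series list from a cohort-like object
#' @param cohort a `synthetic_cohort`, a list with a `timeseries` element,
#'   or a plain list of [roi_timeseries].
#' @return list of [roi_timeseries].
#' @export
cohort_timeseries <- function(cohort) {
  if (inherits(cohort, "synthetic_cohort") ||
      (is.list(cohort) && !is.null(cohort$timeseries)))
    return(cohort$timeseries)
  if (is.list(cohort) && length(cohort) > 0L &&
      all(vapply(cohort, inherits, logical(1L), "roi_timeseries")))
    return(cohort)
  stop("cannot extract time series from this object")
}

#' Extract the scheme from a cohort-like object
#' @param cohort as in [cohort_timeseries].
#' @return a [parcellation_scheme].
#' @export
cohort_scheme <- function(cohort) {
  if (!is.null(cohort$scheme)) return(cohort$scheme)
  ts <- cohort_timeseries(cohort)
  ts[[1L]]$scheme
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cf <- x$config
  cat("Synthetic cohort:", cf$n_subjects, "subjects,",
      cf$regions_per_hemisphere, "regions/hemisphere,",
      cf$n_timepoints, "timepoints\n")
  cat(sprintf("  weights a2=%.3g b2=%.3g c02=%.3g, age slope %.3g, noise %.3g, seed %d\n",
              cf$a2, cf$b2, cf$c02, cf$age_slope, cf$noise_variance, cf$seed))
  cat("  ages", sprintf("%.1f-%.1f", min(x$meta$age), max(x$meta$age)),
      "; groups:", paste(names(table(x$meta$group)),
                         table(x$meta$group), collapse = ", "), "\n")
  invisible(x)
}
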