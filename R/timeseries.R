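#' ROI time series
#'
#' One subject's preprocessed parcel-level signal: a T x R matrix whose
#' columns follow the parcellation scheme order. Construction validates the
#' column count, column order (by region id) and that no region has zero
#' variance -- a constant parcel signal makes its Pearson correlations
#' undefined.
#'
#' @param subject_id subject identifier (character scalar).
#' @param data numeric T x R matrix; if it has column names they must equal
#'   the scheme's `region_id`s in scheme order.
#' @param scheme a [parcellation_scheme].
#' @return an object of class `roi_timeseries`: a list with elements
#'   `subject_id`, `data` (T x R matrix, columns named by region id) and
#'   `scheme`.
#' @export
roi_timeseries <- function(subject_id, data, scheme) {
  stopifnot(inherits(scheme, "parcellation_scheme"))
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time-series data must be numeric")
  if (ncol(data) != nrow(scheme))
    stop("time series has ", ncol(data), " columns but scheme has ",
         nrow(scheme), " regions")
  if (nrow(data) < 3L)
    stop("need at least 3 timepoints, got ", nrow(data))
  if (!is.null(colnames(data)) &&
      !identical(colnames(data), scheme$region_id)) {
    bad <- which(colnames(data) != scheme$region_id)
    stop("column order does not match scheme order; mismatched ids: ",
         paste(utils::head(colnames(data)[bad], 5L), collapse = ", "))
  }
  zv <- zero_variance_cols(data)
  if (any(zv))
    stop("zero-variance region(s): ",
         paste(scheme$region_id[zv], collapse = ", "))
  colnames(data) <- scheme$region_id
  structure(list(subject_id = as.character(subject_id),
                 data = data, scheme = scheme),
            class = "roi_timeseries")
}

#' Read a subject's ROI time series from a TSV file
#'
#' @param path tab-separated file whose header row holds the scheme's region
#'   ids in scheme order, followed by T rows of signal values.
#' @param scheme a [parcellation_scheme] the file must match.
#' @param subject_id subject identifier; defaults to the file name without
#'   extension.
#' @return a validated [roi_timeseries].
#' @export
read_timeseries <- function(path, scheme,
                            subject_id = sub("\\.[^.]*$", "", basename(path))) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (!identical(colnames(m), scheme$region_id)) {
    extra <- setdiff(colnames(m), scheme$region_id)
    miss <- setdiff(scheme$region_id, colnames(m))
    if (length(extra) || length(miss))
      stop("header does not match scheme regions; unexpected: [",
           paste(utils::head(extra, 5L), collapse = ", "), "], missing: [",
           paste(utils::head(miss, 5L), collapse = ", "), "]")
    stop("header columns are permuted relative to the scheme order")
  }
  roi_timeseries(subject_id, m, scheme)
}

#' Write a subject's ROI time series to a TSV file
#'
#' @param ts a [roi_timeseries].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  df <- as.data.frame(ts$data)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parcel-level global signal regression
#'
#' Regresses each region's series on an intercept and the global mean series
#' (the mean of all parcel series at each timepoint) by ordinary least
#' squares, returning the residuals. Each residual column has zero mean and is
#' numerically orthogonal to the global mean series. This is the parcel-level
#' counterpart of voxelwise global-signal regression performed during fMRI
#' denoising; it reproduces the GSR-vs-NGSR contrast qualitatively at the
#' level this package operates on.
#'
#' Applying the operation twice gives the same result as applying it once (up
#' to floating-point error): after the first pass the new global mean is the
#' zero-mean residual of the old one, which spans the same regressor space.
#'
#' @param ts a [roi_timeseries].
#' @return a [roi_timeseries] of residuals.
#' @export
regress_global_signal <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  g <- rowMeans(ts$data)
  if (stats::var(g) == 0)
    stop("global mean series is constant; cannot regress it out")
  if (stats::var(g) <= 1e-24 * mean(apply(ts$data, 2L, stats::var))) {
    # the global mean is zero up to round-off (e.g. the input is already a
    # set of GSR residuals): only the intercept is identifiable, so demean
    resid <- sweep(ts$data, 2L, colMeans(ts$data))
  } else {
    X <- cbind(1, g)
    beta <- solve(crossprod(X), crossprod(X, ts$data))
    resid <- ts$data - X %*% beta
  }
  # residual columns can be constant (e.g. every region equal to the global
  # signal); bypass the zero-variance check, downstream FC will catch it
  out <- ts
  out$data <- resid
  colnames(out$data) <- ts$scheme$region_id
  out
}

# a column counts as zero-variance when its variance is negligible relative
# to its mean square: catches exactly-constant columns and the all-but-
# round-off-constant residuals that OLS regression leaves behind
zero_variance_cols <- function(X, ref = NULL) {
  v <- apply(X, 2L, stats::var)
  if (is.null(ref)) ref <- colMeans(X^2)
  v <= 1e-24 * (ref + .Machine$double.xmin)
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("ROI time series: subject", x$subject_id, "-",
      nrow(x$data), "timepoints x", ncol(x$data), "regions\n")
  invisible(x)
}
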