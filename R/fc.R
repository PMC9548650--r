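#' Functional connectivity matrices
#'
#' An FC matrix is the region-by-region Pearson correlation matrix of a
#' subject's parcel time series (scale `"pearson_r"`), or its Fisher-z
#' transform (scale `"fisher_z"`, diagonal masked as `NA` since atanh(1)
#' diverges). Hemisphere matrices (`hemi_fc`) carry the additional guarantee
#' that row k of the left and right matrices refer to homotopic partners
#' (rows ordered by `pair_index`), which makes their edge vectors element-wise
#' comparable -- the property the HSFC statistic relies on.
#'
#' @name fc_matrix
#' @keywords internal
NULL

new_fc_matrix <- function(values, scale, region_ids,
                          hemisphere = NULL, pair_index = NULL,
                          submodule = NULL) {
  dimnames(values) <- list(region_ids, region_ids)
  structure(values,
            scale = scale, hemisphere = hemisphere,
            pair_index = pair_index, submodule = submodule,
            class = if (is.null(hemisphere)) "fc_matrix"
                    else c("hemi_fc", "fc_matrix"))
}

#' FC scale of a matrix
#' @param fc an [fc_matrix].
#' @return `"pearson_r"` or `"fisher_z"`.
#' @export
fc_scale <- function(fc) attr(fc, "scale")

#' Compute a whole-brain FC matrix from ROI time series
#'
#' The connectivity between two regions is the Pearson correlation
#' coefficient of their mean time series, yielding an R x R symmetric matrix
#' with unit diagonal.
#'
#' @param ts a [roi_timeseries].
#' @param gsr logical; regress the parcel-level global signal out of every
#'   region first (see [regress_global_signal]).
#' @return an [fc_matrix] with scale `"pearson_r"`.
#' @export
compute_fc <- function(ts, gsr = FALSE) {
  stopifnot(inherits(ts, "roi_timeseries"))
  raw_ms <- colMeans(ts$data^2)
  if (gsr) ts <- regress_global_signal(ts)
  # reference the pre-GSR signal magnitude, so a region flattened by the
  # regression is caught even though its round-off residuals vary slightly
  zv <- zero_variance_cols(ts$data, ref = raw_ms)
  if (any(zv))
    stop("zero-variance region(s): ",
         paste(ts$scheme$region_id[zv], collapse = ", "))
  r <- stats::cor(ts$data)
  r[r > 1] <- 1; r[r < -1] <- -1   # guard FP overshoot
  diag(r) <- 1
  new_fc_matrix(r, "pearson_r", ts$scheme$region_id)
}

#' Fisher-z transform an FC matrix
#'
#' Applies z = atanh(r) to every off-diagonal entry, the standard
#' variance-stabilizing normalization of correlation coefficients. The
#' diagonal is masked (`NA`): atanh(1) is infinite and self-edges carry no
#' information. Off-diagonal entries with |r| = 1 are clipped to
#' 1 - 1e-7 in magnitude before transforming, which keeps z finite while
#' preserving the ordering of correlations.
#'
#' @param fc an [fc_matrix] with scale `"pearson_r"`.
#' @return an [fc_matrix] (or `hemi_fc`) with scale `"fisher_z"`.
#' @export
fisher_z <- function(fc) {
  stopifnot(inherits(fc, "fc_matrix"))
  if (fc_scale(fc) != "pearson_r")
    stop("fisher_z expects a pearson_r matrix, got scale '", fc_scale(fc), "'")
  bound <- 1 - 1e-7
  r <- unclass(fc)
  r[r > bound] <- bound
  r[r < -bound] <- -bound
  z <- atanh(r)
  diag(z) <- NA_real_
  new_fc_matrix(z, "fisher_z", rownames(fc),
                hemisphere = attr(fc, "hemisphere"),
                pair_index = attr(fc, "pair_index"),
                submodule = attr(fc, "submodule"))
}

#' Split a whole-brain FC matrix into hemisphere matrices
#'
#' Extracts the left- and right-hemisphere intra-hemisphere blocks, each
#' reordered by homotopic `pair_index` so that row k of the two outputs
#' refers to homotopic partners. Inter-hemispheric entries are discarded.
#'
#' @param fc an R x R [fc_matrix] whose dimension matches `scheme`.
#' @param scheme the [parcellation_scheme] that defined the matrix order.
#' @return a list with elements `L` and `R`, each a `hemi_fc` of dimension
#'   (R/2) x (R/2).
#' @export
split_hemispheres <- function(fc, scheme) {
  stopifnot(inherits(fc, "fc_matrix"),
            inherits(scheme, "parcellation_scheme"))
  if (nrow(fc) != nrow(scheme))
    stop("matrix dimension ", nrow(fc), " does not match scheme (",
         nrow(scheme), " regions)")
  submods <- pair_submodules(scheme)
  out <- lapply(c(L = "L", R = "R"), function(h) {
    rows <- which(scheme$hemisphere == h)
    rows <- rows[order(scheme$pair_index[rows])]
    new_fc_matrix(unclass(fc)[rows, rows, drop = FALSE], fc_scale(fc),
                  scheme$region_id[rows], hemisphere = h,
                  pair_index = seq_along(rows), submodule = submods)
  })
  out
}

#' Extract a sub-module block from a hemisphere matrix
#'
#' Restricts a hemisphere FC matrix to the rows/columns whose homotopic pair
#' carries the requested sub-module label, preserving pair order. Sub-module
#' HSFC and sub-module identification operate on these within-module blocks.
#'
#' @param hemi a `hemi_fc` (see [split_hemispheres]).
#' @param module one of `"heteromodal"`, `"paralimbic"`, `"primary"`,
#'   `"unimodal"`, `"subcortical"`.
#' @return a `hemi_fc` restricted to the module's regions.
#' @export
extract_submodule <- function(hemi, module) {
  stopifnot(inherits(hemi, "hemi_fc"))
  module <- match.arg(module, .SUBMODULES)
  sel <- which(attr(hemi, "submodule") == module)
  if (length(sel) < 2L)
    stop("sub-module '", module, "' has ", length(sel),
         " pair(s) in this scheme; need >= 2 for any off-diagonal edge")
  new_fc_matrix(unclass(hemi)[sel, sel, drop = FALSE], fc_scale(hemi),
                rownames(hemi)[sel], hemisphere = attr(hemi, "hemisphere"),
                pair_index = attr(hemi, "pair_index")[sel],
                submodule = attr(hemi, "submodule")[sel])
}

#' Vectorize the strict upper triangle of a square matrix
#'
#' Returns the strictly-upper-triangle entries in row-major order
#' (m12, m13, ..., m1n, m23, ...), length n(n-1)/2. This is the edge vector
#' used by the HSFC statistic and by fingerprint identification: the diagonal
#' is always excluded (Fisher-z diagonals are infinite and self-edges are
#' uninformative) and each undirected edge appears exactly once.
#'
#' @param m a square symmetric matrix (n >= 2); `fc_matrix` attributes are
#'   ignored.
#' @return numeric vector of length n(n-1)/2.
#' @export
vectorize_upper <- function(m) {
  m <- unclass(m)
  n <- nrow(m)
  if (is.null(n) || n != ncol(m) || n < 2L)
    stop("need a square matrix with n >= 2")
  t(m)[lower.tri(m)]   # row-major strict upper triangle
}

#' Rebuild a symmetric matrix from a row-major upper-triangle edge vector
#'
#' Inverse of [vectorize_upper] off the diagonal; the diagonal is filled with
#' `diag_value`.
#'
#' @param v edge vector of length n(n-1)/2.
#' @param diag_value value for the diagonal (default `NA`).
#' @return n x n symmetric matrix.
#' @export
devectorize_upper <- function(v, diag_value = NA_real_) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (n != round(n))
    stop("length ", length(v), " is not n(n-1)/2 for integer n")
  n <- as.integer(n)
  m <- matrix(diag_value, n, n)
  m[lower.tri(m)] <- v
  m <- t(m)
  m[lower.tri(m)] <- v
  m
}

#' Write an FC matrix to a TSV file
#'
#' The first line is a comment recording the scale (`# scale: pearson_r`),
#' followed by a header of region ids and the dense matrix. Values are
#' written with 17 significant digits so a write/read round trip is the
#' identity to better than 1e-12.
#'
#' @param fc an [fc_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(fc, path) {
  stopifnot(inherits(fc, "fc_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scale: ", fc_scale(fc)), con)
  writeLines(paste(rownames(fc), collapse = "\t"), con)
  vals <- format(unclass(fc), digits = 17, trim = TRUE, scientific = TRUE)
  writeLines(apply(vals, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read an FC matrix from a TSV file
#'
#' @param path file written by [write_matrix].
#' @param scheme optional [parcellation_scheme]; when given, the matrix
#'   dimension and region ids must match it.
#' @return an [fc_matrix].
#' @details Errors if the stored matrix is not symmetric, or if a
#'   `pearson_r` matrix has entries outside [-1, 1] or an off-unit diagonal.
#' @export
read_matrix <- function(path, scheme = NULL) {
  first <- readLines(path, n = 1L)
  scale <- sub("^#\\s*scale:\\s*", "", first)
  if (!scale %in% c("pearson_r", "fisher_z"))
    stop("missing or unknown scale header line in ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE)
  m <- as.matrix(tab)
  ids <- colnames(m)
  if (nrow(m) != ncol(m))
    stop("matrix is not square: ", nrow(m), " x ", ncol(m))
  if (!is.null(scheme)) {
    if (!identical(ids, scheme$region_id))
      stop("matrix region ids do not match the scheme")
  }
  off <- abs(m - t(m))
  if (any(off > 1e-9, na.rm = TRUE)) {
    ij <- which(off == max(off, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    stop("matrix is not symmetric at (", ij[1L], ",", ij[2L], ")")
  }
  if (scale == "pearson_r") {
    if (any(abs(m) > 1 + 1e-12))
      stop("pearson_r matrix has entries outside [-1, 1]")
    if (any(abs(diag(m) - 1) > 1e-12))
      stop("pearson_r matrix diagonal must be 1")
  }
  new_fc_matrix(m, scale, ids)
}

#' @export
print.fc_matrix <- function(x, ...) {
  h <- attr(x, "hemisphere")
  cat(if (is.null(h)) "FC matrix:" else paste0("Hemisphere (", h, ") FC matrix:"),
      nrow(x), "x", ncol(x), "- scale", fc_scale(x), "\n")
  invisible(x)
}
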