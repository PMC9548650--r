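#' Parcellation schemes
#'
#' A parcellation scheme maps the rows/columns of a functional connectivity
#' (FC) matrix to named brain regions, each carrying a hemisphere label, a
#' homotopic pair index, and a functional sub-module label. The scheme defines
#' every matrix ordering downstream: within a hemisphere, regions are compared
#' by `pair_index`, so row k of the left-hemisphere matrix and row k of the
#' right-hemisphere matrix always refer to homotopic partners.
#'
#' @name parcellation_scheme
#' @keywords internal
NULL

.SUBMODULES <- c("heteromodal", "paralimbic", "primary", "unimodal",
                 "subcortical")
.SUBMODULE_LEVELS <- c(.SUBMODULES, "none")
.HSFC_LEVELS <- c("hemisphere", .SUBMODULES)

#' Construct and validate a parcellation scheme
#'
#' @param regions a data.frame with columns `region_id`, `label`,
#'   `hemisphere` (`"L"`/`"R"`), `pair_index` (positive integer; each value
#'   `1..R/2` appears exactly once per hemisphere) and `submodule` (one of
#'   `"heteromodal"`, `"paralimbic"`, `"primary"`, `"unimodal"`,
#'   `"subcortical"`, `"none"`). Row order is the matrix order.
#' @return an object of class `parcellation_scheme` (a validated data.frame).
#' @details Validation enforces: an even region count split equally between
#'   hemispheres; a bijective homotopic pairing (`pair_index` `1..R/2` once per
#'   hemisphere); and that the two members of each pair share the same
#'   sub-module label. Errors name the offending row or pair.
#' @examples
#' sc <- parcellation_scheme(data.frame(
#'   region_id = c("L1", "L2", "R1", "R2"),
#'   label = c("a", "b", "a", "b"),
#'   hemisphere = c("L", "L", "R", "R"),
#'   pair_index = c(1, 2, 1, 2),
#'   submodule = "primary"))
#' nrow(sc)
#' @export
parcellation_scheme <- function(regions) {
  required <- c("region_id", "label", "hemisphere", "pair_index", "submodule")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols) > 0L)
    stop("scheme is missing column(s): ", paste(missing_cols, collapse = ", "))
  regions <- as.data.frame(regions)[required]
  regions$region_id <- as.character(regions$region_id)
  regions$label <- as.character(regions$label)
  regions$hemisphere <- as.character(regions$hemisphere)
  regions$pair_index <- as.integer(regions$pair_index)
  regions$submodule <- as.character(regions$submodule)

  n <- nrow(regions)
  if (n < 4L || n %% 2L != 0L)
    stop("scheme must have an even number of regions (>= 4), got ", n)
  if (anyDuplicated(regions$region_id)) {
    dup <- regions$region_id[duplicated(regions$region_id)][1L]
    stop("duplicate region_id '", dup, "'")
  }
  bad_hemi <- which(!regions$hemisphere %in% c("L", "R"))
  if (length(bad_hemi) > 0L)
    stop("row ", bad_hemi[1L], ": hemisphere must be 'L' or 'R', got '",
         regions$hemisphere[bad_hemi[1L]], "'")
  bad_sub <- which(!regions$submodule %in% .SUBMODULE_LEVELS)
  if (length(bad_sub) > 0L)
    stop("row ", bad_sub[1L], ": unknown submodule '",
         regions$submodule[bad_sub[1L]], "'")
  if (any(is.na(regions$pair_index)) || any(regions$pair_index < 1L))
    stop("pair_index must be a positive integer")

  half <- n %/% 2L
  for (h in c("L", "R")) {
    idx <- regions$pair_index[regions$hemisphere == h]
    if (length(idx) != half)
      stop("hemisphere ", h, " has ", length(idx), " regions; expected ", half)
    if (anyDuplicated(idx)) {
      dup <- idx[duplicated(idx)][1L]
      stop("duplicate pair_index ", dup, " in hemisphere ", h)
    }
    if (!setequal(idx, seq_len(half)))
      stop("pair_index values in hemisphere ", h,
           " must be exactly 1..", half)
  }
  subL <- regions$submodule[regions$hemisphere == "L"][
    order(regions$pair_index[regions$hemisphere == "L"])]
  subR <- regions$submodule[regions$hemisphere == "R"][
    order(regions$pair_index[regions$hemisphere == "R"])]
  mism <- which(subL != subR)
  if (length(mism) > 0L)
    stop("pair ", mism[1L], ": members have different submodules ('",
         subL[mism[1L]], "' vs '", subR[mism[1L]], "')")

  rownames(regions) <- NULL
  class(regions) <- c("parcellation_scheme", "data.frame")
  regions
}

#' Read a parcellation scheme from a TSV file
#'
#' @param path path to a tab-separated file with header columns `region_id`,
#'   `label`, `hemisphere`, `pair_index`, `submodule`. File row order becomes
#'   the scheme (and matrix) order.
#' @return a validated [parcellation_scheme].
#' @export
read_scheme <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  parcellation_scheme(tab)
}

#' Write a parcellation scheme to a TSV file
#'
#' @param scheme a [parcellation_scheme].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "parcellation_scheme"))
  utils::write.table(as.data.frame(scheme), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Number of homotopic pairs in a scheme
#' @param scheme a [parcellation_scheme].
#' @return integer, R/2.
#' @export
n_pairs <- function(scheme) nrow(scheme) %/% 2L

#' Sub-module label of each homotopic pair, in pair_index order
#' @param scheme a [parcellation_scheme].
#' @return character vector of length R/2.
#' @export
pair_submodules <- function(scheme) {
  left <- scheme[scheme$hemisphere == "L", ]
  left$submodule[order(left$pair_index)]
}

#' Sub-modules present in a scheme with at least `min_pairs` pairs
#' @param scheme a [parcellation_scheme].
#' @param min_pairs minimum number of homotopic pairs (default 2, the smallest
#'   block with an off-diagonal edge).
#' @return character vector of sub-module names, in canonical order.
#' @export
scheme_submodules <- function(scheme, min_pairs = 2L) {
  counts <- table(pair_submodules(scheme))
  present <- names(counts)[counts >= min_pairs]
  .SUBMODULES[.SUBMODULES %in% present]
}

#' @export
print.parcellation_scheme <- function(x, ...) {
  cat("Parcellation scheme:", nrow(x), "regions (",
      n_pairs(x), "homotopic pairs per hemisphere )\n")
  tab <- table(pair_submodules(x))
  cat("Pairs per sub-module:\n")
  print(tab)
  invisible(x)
}
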