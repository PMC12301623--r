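# Tissue barcodes: 1-D longitudinal profiles, two-means clustering,
# midpoint threshold, and the PS-OCT / MRI agreement report.

#' Longitudinal 1-D profile of a carpet-like image
#'
#' One value per image row (longitudinal position): the mean over unmasked
#' columns. Rows with fewer than `min_frac` unmasked columns are flagged;
#' fully masked rows are linearly interpolated from their neighbors.
#'
#' @param image Numeric matrix, rows indexed by longitudinal position (or a
#'   `carpet_view` / `unfolded_roi`, in which case `mask` and
#'   `row_spacing_mm` are taken from the object).
#' @param mask Logical matrix of the same shape (TRUE = use the pixel);
#'   `NULL` uses every finite pixel.
#' @param row_spacing_mm Longitudinal spacing between rows.
#' @param min_frac Flagging threshold on the unmasked-column fraction.
#' @param source Free-text tag ("retardance", "mri", ...).
#' @return A list of class `profile_1d` with `values`, `row_spacing_mm`,
#'   `flagged`, `source`.
#' @export
longitudinal_profile <- function(image, mask = NULL, row_spacing_mm = NULL,
                                 min_frac = 0.25, source = "retardance") {
  if (inherits(image, "carpet_view")) {
    # low retardance is signal for a retardance profile: use every finite
    # carpet pixel unless the caller masks explicitly (the carpet's own mask
    # marks where *orientation* is defined)
    if (is.null(row_spacing_mm)) row_spacing_mm <- image$pitch_mm
    image <- image$ret_deg100
  } else if (inherits(image, "unfolded_roi")) {
    if (is.null(row_spacing_mm)) row_spacing_mm <- image$slice_spacing_mm
    if (source == "retardance") source <- "mri"
    image <- image$data
  }
  stopifnot(is.matrix(image), nrow(image) >= 4, !is.null(row_spacing_mm))
  if (is.null(mask)) mask <- is.finite(image)
  mask <- mask & is.finite(image)
  n <- nrow(image)
  frac <- rowMeans(mask)
  if (all(frac == 0)) stop("every row is fully masked: no profile")
  vals <- vapply(seq_len(n), function(j) {
    k <- mask[j, ]
    if (any(k)) mean(image[j, k]) else NA_real_
  }, numeric(1))
  flagged <- frac < min_frac
  if (anyNA(vals)) {
    ok <- which(is.finite(vals))
    vals <- stats::approx(ok, vals[ok], xout = seq_len(n), rule = 2)$y
  }
  structure(list(values = vals, row_spacing_mm = row_spacing_mm,
                 flagged = flagged, source = source),
            class = "profile_1d")
}

#' Deterministic 1-D two-means clustering
#'
#' Two-means on scalars is threshold-separable: the optimal clusters are
#' contiguous runs of the sorted values. The centers are therefore computed
#' exactly, by scanning every contiguous split of the sorted profile for
#' the minimum within-cluster sum of squares. The result is the global
#' optimum and a fixed point of Lloyd's iteration (the split boundary lies
#' at the midpoint of the two centers); ties between equally good splits go
#' to the one with the larger low cluster.
#'
#' @param profile A `profile_1d` or numeric vector with at least two
#'   distinct values.
#' @return Sorted numeric vector of the two cluster centers.
#' @export
kmeans_1d <- function(profile) {
  x <- if (inherits(profile, "profile_1d")) profile$values else as.numeric(profile)
  stopifnot(length(x) >= 2, all(is.finite(x)))
  if (diff(range(x)) == 0) stop("no tissue contrast: constant profile")
  xs <- sort(x)
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1)
  lo_ss <- cs2[k] - cs[k]^2 / k
  hi_n <- n - k
  hi_sum <- cs[n] - cs[k]
  hi_ss <- (cs2[n] - cs2[k]) - hi_sum^2 / hi_n
  ss <- lo_ss + hi_ss
  best <- max(which(ss <= min(ss) + 1e-12))  # ties: larger low cluster
  sort(c(cs[best] / best, hi_sum[best] / hi_n[best]))
}

#' Binary tissue barcode from a profile
#'
#' Thresholds at the midpoint of the two cluster centers: values strictly
#' above the midpoint are the high (white-matter-like) cluster 1, values at
#' or below it the low (grey-matter-like) cluster 0.
#'
#' @param profile A `profile_1d` (or numeric vector plus `row_spacing_mm`).
#' @param centers Two distinct cluster centers, e.g. from [kmeans_1d()];
#'   computed from the profile when omitted.
#' @param row_spacing_mm Required when `profile` is a bare vector.
#' @return A list of class `tissue_barcode` with `code` (integer 0/1),
#'   `centers`, `threshold`, `row_spacing_mm`.
#' @export
binarize <- function(profile, centers = NULL, row_spacing_mm = NULL) {
  if (inherits(profile, "profile_1d")) {
    x <- profile$values
    row_spacing_mm <- profile$row_spacing_mm
  } else {
    x <- as.numeric(profile)
    stopifnot(!is.null(row_spacing_mm))
  }
  if (is.null(centers)) centers <- kmeans_1d(x)
  stopifnot(length(centers) == 2, centers[1] != centers[2])
  centers <- sort(centers)
  thr <- mean(centers)
  structure(list(code = as.integer(x > thr), centers = centers,
                 threshold = thr, row_spacing_mm = row_spacing_mm),
            class = "tissue_barcode")
}

#' Transition positions of a barcode
#'
#' @param barcode A `tissue_barcode`.
#' @return Positions (mm from the first row's start) of the boundaries
#'   between rows where the binary code changes.
#' @export
barcode_transitions <- function(barcode) {
  stopifnot(inherits(barcode, "tissue_barcode"))
  j <- which(diff(barcode$code) != 0)
  j * barcode$row_spacing_mm
}

#' Agreement between two tissue barcodes
#'
#' Maps each row of the first (finely sampled, PS-OCT) barcode to its MRI
#' slice through a [longitudinal_mapping()] and reports the overall
#' agreement fraction, per-class Dice coefficients, and the transition
#' positions of both barcodes.
#'
#' @param psoct,mri `tissue_barcode`s.
#' @param index_map A `longitudinal_map` (defaults to the map implied by the
#'   two row spacings).
#' @return A list of class `barcode_agreement` with `agreement`, `dice`
#'   (named, classes "0" and "1"), `transitions_psoct_mm`,
#'   `transitions_mri_mm`, `n`.
#' @export
compare_barcodes <- function(psoct, mri, index_map = NULL) {
  stopifnot(inherits(psoct, "tissue_barcode"), inherits(mri, "tissue_barcode"))
  if (is.null(index_map)) {
    index_map <- longitudinal_mapping(length(psoct$code), length(mri$code),
                                      pitch_mm = psoct$row_spacing_mm,
                                      slice_mm = mri$row_spacing_mm)
  }
  map <- index_map$map[seq_along(psoct$code)]
  keep <- !is.na(map) & map >= 1 & map <= length(mri$code)
  if (!any(keep)) stop("no overlap between the two barcodes")
  a <- psoct$code[keep]
  b <- mri$code[map[keep]]
  dice <- vapply(c(`0` = 0L, `1` = 1L), function(cl) {
    den <- sum(a == cl) + sum(b == cl)
    if (den == 0) NA_real_ else 2 * sum(a == cl & b == cl) / den
  }, numeric(1))
  structure(list(agreement = mean(a == b), dice = dice,
                 transitions_psoct_mm = barcode_transitions(psoct),
                 transitions_mri_mm = barcode_transitions(mri),
                 n = sum(keep)),
            class = "barcode_agreement")
}
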