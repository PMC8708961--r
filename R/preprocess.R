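#' Preprocessing configuration
#'
#' Parameters of the model-input preparation chain: merge the two views side
#' by side, replicate the merged plane into three identical channels,
#' standardize the intensity scale by the mean count in a rectangle around the
#' right thigh, and downscale to the model resolution.
#'
#' @param thigh_roi Integer vector `(row_start, row_end, col_start, col_end)`
#'   in merged-image coordinates, zero-based and half-open (rows
#'   `[row_start, row_end)`). `NULL` (default) scales the reference rectangle
#'   — rows `[700, 820)`, columns `[32, 96)` of a 1024 x 512 merged image,
#'   i.e. the right femoral region of the anterior half under standard
#'   display (patient right = image left) — to the actual merged size.
#' @param target_size Output spatial size, default `c(256, 256)`.
#' @param interpolation Resize scheme; `"area"` (default, anti-aliased block
#'   mean), `"bilinear"`, or `"none"` (nearest neighbour).
#' @param mean_floor Small positive guard: normalization divides by
#'   `max(roi_mean, mean_floor)` so near-empty ROIs cannot blow up the image.
#' @return A `preproc_config` object.
#' @export
preproc_config <- function(thigh_roi = NULL, target_size = c(256, 256),
                           interpolation = c("area", "bilinear", "none"),
                           mean_floor = 1e-3) {
  interpolation <- match.arg(interpolation)
  if (any(target_size < 1)) stop("target dimensions must be positive", call. = FALSE)
  if (mean_floor <= 0) stop("mean_floor must be positive", call. = FALSE)
  if (!is.null(thigh_roi)) {
    thigh_roi <- as.integer(thigh_roi)
    if (length(thigh_roi) != 4 || thigh_roi[1] >= thigh_roi[2] ||
        thigh_roi[3] >= thigh_roi[4] || any(thigh_roi < 0)) {
      stop("thigh_roi must be (row_start, row_end, col_start, col_end), half-open, nonempty",
           call. = FALSE)
    }
  }
  structure(list(thigh_roi = thigh_roi, target_size = as.integer(target_size),
                 interpolation = interpolation, mean_floor = mean_floor),
            class = "preproc_config")
}

# reference ROI fractions of the merged image: rows 700:820, cols 32:96 of 1024x512
default_thigh_roi <- function(merged_height, merged_width) {
  c(floor(700 / 1024 * merged_height), floor(820 / 1024 * merged_height),
    floor(32 / 512 * merged_width), floor(96 / 512 * merged_width))
}

#' Merge anterior and posterior views side by side
#'
#' Two H x W views become one H x 2W image with the anterior view in columns
#' `[0, W)` and the posterior view in `[W, 2W)`; values are unchanged. (Two
#' 1024 x 256 views give the clinical 1024 x 512 merged image.)
#'
#' @param pair A [scan_pair()], or a list with `anterior`/`posterior` matrices.
#' @return Real matrix H x 2W.
#' @export
merge_views <- function(pair) {
  if (!identical(dim(pair$anterior), dim(pair$posterior))) {
    stop("anterior and posterior views must share the same shape", call. = FALSE)
  }
  cbind(pair$anterior, pair$posterior)
}

#' Replicate a 2-D image into three identical channels
#'
#' @param grid 2-D matrix.
#' @return H x W x 3 array with equal channel planes.
#' @export
replicate_channels <- function(grid) {
  if (length(dim(grid)) != 2) stop("input must be a 2-D matrix", call. = FALSE)
  array(grid, dim = c(dim(grid), 3))
}

#' Mean intensity over a rectangular ROI
#'
#' @param grid 2-D matrix (or 3-D array, in which case channel 1 is used).
#' @param roi `(row_start, row_end, col_start, col_end)`, zero-based, half-open.
#' @return Arithmetic mean over the rectangle.
#' @export
roi_mean <- function(grid, roi) {
  if (length(dim(grid)) == 3) grid <- grid[, , 1]
  roi <- as.numeric(roi)
  if (roi[1] >= roi[2] || roi[3] >= roi[4]) stop("empty ROI", call. = FALSE)
  if (roi[1] < 0 || roi[3] < 0 || roi[2] > nrow(grid) || roi[4] > ncol(grid)) {
    stop("ROI exceeds image bounds", call. = FALSE)
  }
  mean(grid[(roi[1] + 1):roi[2], (roi[3] + 1):roi[4]])
}

#' Divide an image by a (floored) reference mean
#'
#' Standardizes the global intensity scale: after division by the thigh-ROI
#' mean, the ROI mean of the output is 1 whenever the reference mean is above
#' the floor, and two scans differing only by a global activity factor map to
#' the same image.
#'
#' @param grid 2-D or 3-D numeric array.
#' @param m Reference mean (>= 0).
#' @param mean_floor Positive guard used when `m` is smaller.
#' @return `grid / max(m, mean_floor)`.
#' @export
normalize_by_roi <- function(grid, m, mean_floor = 1e-3) {
  if (m < 0) stop("reference mean must be nonnegative", call. = FALSE)
  grid / max(m, mean_floor)
}

#' Downscale an image to the model resolution
#'
#' Anti-aliased reduction applied per channel, so identical channels stay
#' identical. The default `"area"` scheme averages non-overlapping source
#' blocks whenever the reduction factors are integers — the appropriate
#' filter for photon-count images, since point-sampling a 4x reduction can
#' skip focal hot spots entirely; it preserves the image mean exactly and
#' falls back to bilinear (via \pkg{EBImage}) for non-integer factors.
#' The target must not exceed the input in either spatial dimension.
#'
#' @param grid H x W matrix or H x W x C array.
#' @param target `(height, width)` of the output.
#' @param interpolation `"area"`, `"bilinear"` or `"none"`.
#' @return Array of shape `target` (x C if the input had channels).
#' @export
downscale <- function(grid, target = c(256, 256), interpolation = "area") {
  nd <- length(dim(grid))
  d <- dim(grid)
  if (target[1] > d[1] || target[2] > d[2]) {
    stop("target size exceeds the input image", call. = FALSE)
  }
  block <- interpolation == "area" &&
    d[1] %% target[1] == 0 && d[2] %% target[2] == 0
  resize1 <- function(m) {
    if (block) return(block_mean(m, target))
    filt <- if (interpolation == "none") "none" else "bilinear"
    EBImage::resize(m, w = target[1], h = target[2], filter = filt)
  }
  if (nd == 2) return(resize1(grid))
  out <- array(0, dim = c(target[1], target[2], d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- resize1(grid[, , ch])
  out
}

# average non-overlapping (fh x fw) blocks; exact mean preservation
block_mean <- function(m, target) {
  fh <- nrow(m) %/% target[1]
  fw <- ncol(m) %/% target[2]
  x <- array(m, dim = c(fh, target[1], fw, target[2]))
  colMeans(aperm(x, c(1, 3, 2, 4)), dims = 2)
}

#' Full preprocessing of one scan pair
#'
#' Applies, in order: [merge_views()], [replicate_channels()],
#' [normalize_by_roi()] with the thigh-ROI mean, and [downscale()] to the
#' target size. The ROI mean actually used is recorded on the result.
#'
#' @param pair A [scan_pair()].
#' @param cfg A [preproc_config()].
#' @return A `preprocessed_image`: list with `pixels`
#'   (`target_size[1] x target_size[2] x 3`), `label`, `patient_id`,
#'   `roi_mean_used`.
#' @export
preprocess_pair <- function(pair, cfg = preproc_config()) {
  merged <- merge_views(pair)
  roi <- cfg$thigh_roi
  if (is.null(roi)) roi <- default_thigh_roi(nrow(merged), ncol(merged))
  stacked <- replicate_channels(merged)
  m <- roi_mean(stacked, roi)
  normed <- normalize_by_roi(stacked, m, cfg$mean_floor)
  pixels <- downscale(normed, cfg$target_size, cfg$interpolation)
  structure(list(pixels = pixels, label = pair$label,
                 patient_id = pair$patient_id, roi_mean_used = m),
            class = "preprocessed_image")
}

#' @export
print.preprocessed_image <- function(x, ...) {
  cat(sprintf("preprocessed_image %s: %s, label = %d, roi mean = %.3f\n",
              x$patient_id, paste(dim(x$pixels), collapse = "x"),
              x$label, x$roi_mean_used))
  invisible(x)
}

#' Preprocess a list of scans into a model-input batch
#'
#' Convenience wrapper used by the training code: preprocesses every scan and
#' stacks the results into one `(H, W, 3, N)` array. Since the three channels
#' are identical by construction, only one channel is resized and replicated.
#'
#' @param scans List of [scan_pair()] objects.
#' @param cfg A [preproc_config()].
#' @return List with `x` (array `H x W x 3 x N`), `labels` (integer vector),
#'   `patient_id` (character vector).
#' @export
preprocess_batch <- function(scans, cfg = preproc_config()) {
  n <- length(scans)
  h <- cfg$target_size[1]; w <- cfg$target_size[2]
  x <- array(0, dim = c(h, w, 3, n))
  labels <- integer(n); ids <- character(n)
  for (i in seq_len(n)) {
    merged <- merge_views(scans[[i]])
    roi <- cfg$thigh_roi
    if (is.null(roi)) roi <- default_thigh_roi(nrow(merged), ncol(merged))
    m <- roi_mean(merged, roi)
    plane <- downscale(normalize_by_roi(merged, m, cfg$mean_floor),
                       cfg$target_size, cfg$interpolation)
    x[, , 1, i] <- plane; x[, , 2, i] <- plane; x[, , 3, i] <- plane
    labels[i] <- scans[[i]]$label
    ids[i] <- scans[[i]]$patient_id
  }
  list(x = x, labels = labels, patient_id = ids)
}
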