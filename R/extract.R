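#' Time-average an image stack
#'
#' @param stack `ny x nx x n_frames` array (>= 1 frame).
#' @return The per-pixel mean image (`ny x nx` matrix).
#' @export
time_average <- function(stack) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  if (length(dim(stack)) != 3L || dim(stack)[3] < 1L) {
    stop("`stack` must be a ny x nx x n_frames array with >= 1 frame",
         call. = FALSE)
  }
  rowMeans(stack, dims = 2)
}

#' Detect fluorescent puncta in a time-averaged image
#'
#' Finds local maxima exceeding a robust threshold (`median + k * MAD`
#' of the whole image, i.e. `threshold_sigmas` robust sigmas above
#' background) and applies non-maximum suppression: of any two detections
#' closer than `min_separation` pixels, only the brighter survives.
#' Detections are returned in deterministic order: descending peak value,
#' ties broken row-major.
#'
#' @param avg_image 2-D image (e.g. from [time_average()]).
#' @param min_separation suppression radius, pixels (Euclidean).
#' @param threshold_sigmas detection threshold in robust sigmas above the
#'   image median.
#' @return A tibble with `x`, `y` (0-based pixel coordinates of the peak
#'   pixel center) and `peak` (its time-averaged value); possibly empty.
#' @export
detect_puncta <- function(avg_image, min_separation = 4,
                          threshold_sigmas = 5) {
  bg <- stats::median(avg_image)
  sigma <- stats::mad(avg_image)
  thr <- bg + threshold_sigmas * sigma
  ny <- nrow(avg_image); nx <- ncol(avg_image)
  # local maximum within the 8-neighborhood (image border excluded)
  cand <- which(avg_image > thr, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    if (r == 1L || r == ny || c == 1L || c == nx) next
    v <- avg_image[r, c]
    nb <- avg_image[(r - 1):(r + 1), (c - 1):(c + 1)]
    keep[i] <- v >= max(nb)
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(tibble::tibble(x = numeric(0), y = numeric(0), peak = numeric(0)))
  }
  peak <- avg_image[cand]
  # order: descending peak, then row-major (y, then x)
  ord <- order(-peak, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  peak <- peak[ord]
  sel <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { sel[1] <- TRUE; next }
    prev <- which(sel[seq_len(i - 1L)])
    d2 <- (cand[prev, 1] - cand[i, 1])^2 + (cand[prev, 2] - cand[i, 2])^2
    sel[i] <- all(d2 >= min_separation^2)
  }
  cand <- cand[sel, , drop = FALSE]
  tibble::tibble(x = cand[, 2] - 1, y = cand[, 1] - 1, peak = peak[sel])
}

#' Extract a background-subtracted intensity trace by aperture photometry
#'
#' For each frame, sums the pixels within `aperture_radius` of the punctum
#' and subtracts a local background estimated as the median pixel value in
#' a surrounding annulus, scaled by the aperture area (the annulus median
#' is robust to neighboring molecules). A punctum whose aperture or annulus
#' is clipped by the image border is flagged and excluded (returns `NULL`
#' with a warning).
#'
#' @param stack `ny x nx x n_frames` array.
#' @param x,y punctum position, 0-based pixel coordinates.
#' @param aperture_radius aperture radius, pixels.
#' @param annulus `c(inner, outer)` annulus radii, pixels.
#' @return A list of class `kinfp_raw_trace` with `intensity` (per frame),
#'   `x`, `y`, `n_aperture_px`; or `NULL` if clipped.
#' @export
extract_trace <- function(stack, x, y, aperture_radius = 3,
                          annulus = c(5, 8)) {
  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nf <- dim(stack)[3]
  r_out <- annulus[2]
  if (x - r_out < 0 || x + r_out > nx - 1 ||
      y - r_out < 0 || y + r_out > ny - 1) {
    warning(sprintf("punctum at (%g, %g) clipped by image border; excluded",
                    x, y), call. = FALSE)
    return(NULL)
  }
  px <- rep(seq_len(nx) - 1L, each = ny)
  py <- rep(seq_len(ny) - 1L, times = nx)
  d2 <- (px - x)^2 + (py - y)^2
  ap <- d2 <= aperture_radius^2
  an <- d2 > annulus[1]^2 & d2 <= r_out^2
  n_ap <- sum(ap)
  flat <- matrix(stack, nrow = ny * nx)
  intensity <- colSums(flat[ap, , drop = FALSE]) -
    apply(flat[an, , drop = FALSE], 2, stats::median) * n_ap
  structure(list(intensity = intensity, x = x, y = y, n_aperture_px = n_ap),
            class = "kinfp_raw_trace")
}

#' Detect puncta and extract all traces from a stack
#'
#' Front end chaining [time_average()], [detect_puncta()] and
#' [extract_trace()]; border-clipped molecules are dropped.
#'
#' @inheritParams detect_puncta
#' @inheritParams extract_trace
#' @param stack `ny x nx x n_frames` array.
#' @param frame_dt frame interval, seconds.
#' @return A list with `traces` (frames x molecules matrix), `puncta`
#'   (tibble of retained detections) and `frame_dt`.
#' @export
extract_all_traces <- function(stack, frame_dt, min_separation = 4,
                               threshold_sigmas = 5, aperture_radius = 3,
                               annulus = c(5, 8)) {
  puncta <- detect_puncta(time_average(stack), min_separation,
                          threshold_sigmas)
  traces <- list()
  kept <- logical(nrow(puncta))
  for (i in seq_len(nrow(puncta))) {
    tr <- suppressWarnings(
      extract_trace(stack, puncta$x[i], puncta$y[i], aperture_radius,
                    annulus))
    if (!is.null(tr)) {
      traces[[length(traces) + 1L]] <- tr$intensity
      kept[i] <- TRUE
    }
  }
  mat <- if (length(traces)) do.call(cbind, traces) else
    matrix(numeric(0), nrow = dim(stack)[3], ncol = 0)
  list(traces = mat, puncta = puncta[kept, , drop = FALSE],
       frame_dt = frame_dt)
}
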