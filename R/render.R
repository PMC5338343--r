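#' Lay molecules out on a grid of well-separated positions
#'
#' Convenience helper producing deterministic, non-overlapping positions
#' (0-based pixel coordinates, pixel centers) with a guaranteed margin from
#' the image border.
#'
#' @param n number of molecules.
#' @param image_shape `c(ny, nx)` in pixels.
#' @param margin border margin in pixels.
#' @param spacing grid spacing in pixels.
#' @return An `n x 2` matrix of `(x, y)` coordinates.
#' @export
grid_positions <- function(n, image_shape = c(48L, 48L), margin = 8,
                           spacing = 8) {
  xs <- seq(margin, image_shape[2] - 1 - margin, by = spacing)
  ys <- seq(margin, image_shape[1] - 1 - margin, by = spacing)
  grid <- expand.grid(x = xs, y = ys)
  if (n > nrow(grid)) {
    stop("image too small for ", n, " molecules at this spacing",
         call. = FALSE)
  }
  as.matrix(grid[seq_len(n), , drop = FALSE])
}

#' Render traces into a synthetic TIRF image stack
#'
#' Each molecule is drawn as an immobile 2-D Gaussian punctum whose
#' amplitude follows its intensity trace (scaled to photons), on a constant
#' baseline. Per-pixel Poisson shot noise is applied to the expected photon
#' image and Gaussian read noise added on top, emulating an EMCCD
#' acquisition. Positions closer than `min_separation` trigger a warning
#' (downstream detection may merge them) but rendering proceeds.
#'
#' @param traces frames-by-molecules intensity matrix (one column per
#'   molecule); 0 molecules gives a noise-only stack.
#' @param positions `n x 2` matrix of `(x, y)` pixel coordinates (0-based,
#'   pixel centers), inside the image bounds.
#' @param psf_sigma Gaussian PSF standard deviation, pixels.
#' @param image_shape `c(ny, nx)` image size in pixels.
#' @param baseline camera baseline, photons per pixel per frame.
#' @param photons_per_unit photons emitted per unit trace intensity.
#' @param read_sd Gaussian read-noise standard deviation, photons.
#' @param shot_noise apply Poisson shot noise (disable, together with
#'   `read_sd = 0`, for a deterministic noiseless rendering).
#' @param min_separation minimum pairwise distance checked, pixels.
#' @param n_frames frame count when `traces` has 0 columns.
#' @param seed integer seed for the noise draws.
#' @return A `ny x nx x n_frames` numeric array (photon counts).
#' @export
render_movie <- function(traces, positions, psf_sigma = 1.2,
                         image_shape = c(48L, 48L), baseline = 100,
                         photons_per_unit = 200, read_sd = 2,
                         shot_noise = TRUE, min_separation = 4,
                         n_frames = NULL, seed = NULL) {
  n_mol <- if (is.null(traces)) 0L else ncol(traces)
  if (n_mol > 0) {
    n_frames <- nrow(traces)
    positions <- matrix(as.numeric(positions), ncol = 2)
    if (nrow(positions) != n_mol) {
      stop("`positions` must have one row per molecule", call. = FALSE)
    }
    if (any(positions[, 1] < 0 | positions[, 1] > image_shape[2] - 1) ||
        any(positions[, 2] < 0 | positions[, 2] > image_shape[1] - 1)) {
      stop("positions outside image bounds", call. = FALSE)
    }
    if (n_mol > 1) {
      d <- as.matrix(stats::dist(positions))
      diag(d) <- Inf
      if (min(d) < min_separation) {
        warning("some positions are closer than `min_separation`",
                call. = FALSE)
      }
    }
  }
  if (is.null(n_frames)) stop("`n_frames` required for 0 molecules",
                              call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ny <- image_shape[1]; nx <- image_shape[2]
  npix <- ny * nx
  expected <- matrix(baseline, nrow = npix, ncol = n_frames)
  if (n_mol > 0) {
    px <- rep(seq_len(nx) - 1L, each = ny)   # column-major pixel coords
    py <- rep(seq_len(ny) - 1L, times = nx)
    psf <- matrix(0, nrow = npix, ncol = n_mol)
    for (m in seq_len(n_mol)) {
      psf[, m] <- exp(-((px - positions[m, 1])^2 + (py - positions[m, 2])^2) /
                        (2 * psf_sigma^2))
    }
    expected <- expected + psf %*% t(traces * photons_per_unit)
  }
  counts <- if (shot_noise) {
    rpois(length(expected), lambda = pmax(expected, 0))
  } else {
    as.vector(expected)
  }
  if (read_sd > 0) counts <- counts + rnorm(length(expected), sd = read_sd)
  array(counts, dim = c(ny, nx, n_frames))
}

#' Read/write image stacks as multi-page TIFF
#'
#' Stacks are stored frame-major as 32-bit float TIFF, one page per frame.
#' TIFF float samples are expected in `[0, 1]`: scale photon counts before
#' writing (dividing by a power of two, e.g. `2^16`, is lossless at float32
#' precision) and rescale after reading.
#'
#' @param stack `ny x nx x n_frames` array with values in `[0, 1]`.
#' @param path file path.
#' @return `write_movie_tiff()` returns the path invisibly;
#'   `read_movie_tiff()` returns the array.
#' @export
write_movie_tiff <- function(stack, path) {
  if (min(stack) < 0 || max(stack) > 1) {
    stop("stack values must lie in [0, 1]; divide photon counts by a ",
         "power of two (e.g. 2^16) before writing", call. = FALSE)
  }
  frames <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f])
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  array(unlist(frames), dim = c(dim(frames[[1]])[1:2], length(frames)))
}
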