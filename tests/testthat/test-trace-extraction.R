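test_that("time averaging is the per-pixel mean across frames", {
  one <- matrix(runif(64), 8, 8)
  stack <- array(c(one, one, one), dim = c(8, 8, 3))
  expect_equal(time_average(stack), one)
  expect_equal(time_average(array(one, dim = c(8, 8, 1))), one)
  stack2 <- array(0, dim = c(4, 4, 2)); stack2[, , 2] <- 2
  expect_equal(time_average(stack2), matrix(1, 4, 4))
  expect_error(time_average(array(0, dim = c(4, 4, 0))), ">= 1 frame")
})

test_that("detection finds rendered puncta and rejects blank noise", {
  set.seed(41)
  blank <- matrix(rnorm(64 * 64, mean = 100, sd = 2), 64, 64)
  expect_equal(nrow(detect_puncta(blank, threshold_sigmas = 5)), 0L)

  pos <- grid_positions(10, image_shape = c(64L, 64L), margin = 10,
                        spacing = 12)
  traces <- matrix(1, nrow = 200, ncol = 10)
  stack <- render_movie(traces, pos, psf_sigma = 1.2,
                        image_shape = c(64L, 64L), seed = 42)
  det <- detect_puncta(time_average(stack), min_separation = 4,
                       threshold_sigmas = 5)
  # recall and precision both >= 0.95 (here: exact recovery)
  d2 <- outer(det$x, pos[, 1], "-")^2 + outer(det$y, pos[, 2], "-")^2
  matched <- apply(d2, 2, min) <= 1  # within 1 pixel of truth
  expect_gte(sum(matched) / nrow(pos), 0.95)
  expect_gte(sum(apply(d2, 1, min) <= 1) / nrow(det), 0.95)
})

test_that("non-maximum suppression keeps the brighter of two close puncta", {
  pos <- rbind(c(20, 20), c(22, 20))
  traces <- cbind(rep(2, 100), rep(1, 100))
  stack <- suppressWarnings(
    render_movie(traces, pos, image_shape = c(48L, 48L), read_sd = 0,
                 shot_noise = FALSE))
  expect_warning(
    render_movie(traces, pos, image_shape = c(48L, 48L), read_sd = 0,
                 shot_noise = FALSE, min_separation = 4),
    "min_separation")
  det <- detect_puncta(time_average(stack), min_separation = 4,
                       threshold_sigmas = 5)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x - 20), 1.5)  # the brighter one
})

test_that("aperture photometry subtracts local background and tracks signal", {
  # zero-signal stack: trace mean ~ 0
  set.seed(43)
  stack0 <- array(rnorm(32 * 32 * 50, 100, 2), dim = c(32, 32, 50))
  tr0 <- extract_trace(stack0, x = 15, y = 15)
  # per-frame sd ~ 2 * sqrt(n_aperture_px) ~ 11; mean of 50 frames within 3 sd
  expect_lt(abs(mean(tr0$intensity)), 3 * 2 * sqrt(tr0$n_aperture_px) / sqrt(50))

  # noiseless single molecule: extracted trace proportional to the input
  dw <- simulate_dwell_sequence(snv_rates(), 120, seed = 44)
  src <- discretize_trajectory(dw, 2, noise = NULL)
  stack <- render_movie(matrix(src$intensity, ncol = 1),
                        rbind(c(15, 15)), image_shape = c(32L, 32L),
                        read_sd = 0, shot_noise = FALSE)
  tr <- extract_trace(stack, x = 15, y = 15)
  expect_gt(stats::cor(tr$intensity, src$intensity), 0.999)

  # constant +100 offset everywhere leaves the trace unchanged
  tr_off <- extract_trace(stack + 100, x = 15, y = 15)
  expect_equal(tr_off$intensity, tr$intensity, tolerance = 1e-10)

  # border-clipped aperture: flagged and excluded
  expect_warning(out <- extract_trace(stack, x = 2, y = 15), "clipped")
  expect_null(out)
})

test_that("rendering then extraction preserves the idealized dwell structure", {
  # SNR >= 5 end-to-end: idealization of the extracted trace agrees with
  # idealization of the source trace on >= 95% of frames
  dw <- simulate_dwell_sequence(snv_rates(), 300, seed = 45)
  src <- discretize_trajectory(dw, 2, noise = noise_model(), seed = 46)
  stack <- render_movie(matrix(src$intensity, ncol = 1),
                        rbind(c(15, 15)), image_shape = c(32L, 32L),
                        photons_per_unit = 500, seed = 47)
  ext <- extract_all_traces(stack, frame_dt = 0.5)
  expect_equal(ncol(ext$traces), 1L)
  id_src <- fit_two_state_hmm(src$intensity, 0.5)
  id_ext <- fit_two_state_hmm(ext$traces[, 1], 0.5)
  expect_gte(mean(id_src$bound == id_ext$bound), 0.95)
})

test_that("movie TIFF round trip preserves the stack", {
  stack <- render_movie(matrix(1, 20, 2), rbind(c(10, 10), c(20, 20)),
                        image_shape = c(32L, 32L), seed = 48)
  path <- withr::local_tempfile(fileext = ".tif")
  scale <- 2^16  # stored as float32 in [0, 1)
  write_movie_tiff(stack / scale, path)
  back <- read_movie_tiff(path) * scale
  expect_equal(dim(back), dim(stack))
  expect_equal(back, stack, tolerance = 1e-4)
})

test_that("rendering handles empty fields, localizes single molecules, and zero amplitude", {
  # 0 molecules: noise-only stack at the camera baseline
  stack0 <- render_movie(matrix(numeric(0), nrow = 0, ncol = 0), NULL,
                         image_shape = c(24L, 24L), n_frames = 30, seed = 49)
  expect_equal(dim(stack0), c(24, 24, 30))
  expect_lt(abs(mean(stack0) - 100), 1)

  # 1 bright molecule: brightest time-averaged pixel within 1 px of truth
  stack1 <- render_movie(matrix(2, 50, 1), rbind(c(11, 17)),
                         image_shape = c(32L, 32L), seed = 50)
  avg <- time_average(stack1)
  peak <- which(avg == max(avg), arr.ind = TRUE)
  expect_lte(abs((peak[1, 2] - 1) - 11), 1)  # x = column - 1
  expect_lte(abs((peak[1, 1] - 1) - 17), 1)  # y = row - 1

  # amplitude 0 throughout: indistinguishable from the noise floor
  stack_z <- render_movie(matrix(0, 50, 1), rbind(c(11, 17)),
                          image_shape = c(32L, 32L), seed = 51)
  expect_equal(nrow(detect_puncta(time_average(stack_z),
                                  threshold_sigmas = 5)), 0L)
})
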