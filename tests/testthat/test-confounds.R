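# Framewise displacement, outlier detection, scrubbing, aCompCor and the
# assembled confound designs.

test_that("framewise displacement follows the translation+rotation formula", {
  z <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(motion_trace(z)), rep(0, 10))

  step <- z; step[5:10, 1] <- 0.5            # single 0.5 mm x step
  fd <- framewise_displacement(motion_trace(step))
  expect_equal(fd[5], 0.5)
  expect_equal(fd[-5], rep(0, 9))

  rot <- z; rot[4:10, 5] <- 0.01             # 0.01 rad -> 50 * 0.01 = 0.5 mm
  fd <- framewise_displacement(motion_trace(rot))
  expect_equal(fd[4], 0.5)

  # invariant to constant offsets (depends on differences only)
  set.seed(2)
  m <- matrix(rnorm(60, sd = 0.1), 10, 6)
  shifted <- sweep(m, 2, c(5, -3, 2, 0.1, -0.2, 0.3), "+")
  expect_equal(framewise_displacement(motion_trace(m)),
               framewise_displacement(motion_trace(shifted)))
  expect_equal(mean_framewise_displacement(fd), mean(fd[-1]))
})

test_that("outlier detection flags by within-subject percentile on either series", {
  set.seed(4)
  shape <- c(6, 6, 4)
  Y <- matrix(rnorm(100 * prod(shape)), 100)
  run <- run_from_matrix(Y, shape)
  mt <- motion_trace(matrix(rnorm(600, sd = 0.05), 100, 6))
  out <- detect_outliers(run, mt)
  # clean data: at most ceil(0.03 * 99) = 3 frames per criterion, union <= 6
  expect_lte(sum(out$motion_mm > quantile(out$motion_mm, 0.97)), 3)
  expect_lte(sum(out$flag), 6)
  expect_length(out$flag, 100)

  # constant image, zero motion: nothing flagged (strict threshold rule)
  cz <- run_from_matrix(matrix(7, 50, prod(shape)), shape)
  mz <- motion_trace(matrix(0, 50, 6))
  out0 <- detect_outliers(cz, mz)
  expect_equal(sum(out0$flag), 0)
  expect_equal(out0$motion_mm, rep(0, 50))
  expect_equal(out0$global_z, rep(0, 50))

  expect_error(detect_outliers(run, mt, percentile = 30), "percentile")
  expect_error(detect_outliers(run, mt, percentile = 100), "percentile")
})

test_that("injected spikes in synthetic runs are flagged", {
  # at 80 frames a 97th-percentile rule can only flag ~2-3 frames per
  # series, so runs that drew more spikes than that budget may miss some;
  # runs within budget must recover everything, and the aggregate stays
  # high (the full >= 95% criterion runs at default scale in acceptance)
  co <- tiny_cohort()
  total <- 0L; hit <- 0L
  for (s in seq_along(co$runs)) {
    out <- detect_outliers(co$runs[[s]], co$motion[[s]],
                           brain_mask = co$masks$brain)
    spk <- co$truth$spikes[[s]]
    total <- total + length(spk)
    hit <- hit + sum(spk %in% which(out$flag))
    if (length(spk) <= 2)
      expect_true(all(spk %in% which(out$flag)),
                  label = sprintf("subject %d spikes flagged", s))
  }
  expect_gte(hit / max(total, 1), 0.8)
})

test_that("scrub regressors are one-hot indicator columns", {
  flags <- rep(FALSE, 12); flags[c(4, 9)] <- TRUE
  S <- scrub_regressors(flags)
  expect_identical(dim(S), c(12L, 2L))
  expect_equal(colSums(S), c(scrub_4 = 1, scrub_9 = 1))
  expect_equal(crossprod(S), diag(2), ignore_attr = TRUE)  # orthogonal
  expect_identical(ncol(scrub_regressors(rep(FALSE, 12))), 0L)
})

test_that("aCompCor recovers shared structure and is orthogonal", {
  set.seed(8)
  shape <- c(5, 5, 4)
  mask <- array(FALSE, shape); mask[2:4, 2:4, 2] <- TRUE   # 9 voxels
  s_t <- sin(seq(0, 6 * pi, length.out = 40))
  Y <- matrix(rnorm(40 * prod(shape)), 40)
  Y[, which(mask)] <- s_t + matrix(rnorm(40 * 9, sd = 1e-3), 40)
  run <- run_from_matrix(Y, shape)
  comp <- acompcor(run, mask, 5)
  # compare against the shared signal after the same detrending projection
  X <- cbind(1, 1:40)
  s_dt <- s_t - X %*% solve(crossprod(X), crossprod(X, s_t))
  expect_gt(abs(cor(comp[, 1], s_dt)), 0.999)
  cc <- cor(comp)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  expect_equal(apply(comp, 2, sd), rep(1, 5), ignore_attr = TRUE)

  # rank deficiency is reported with the achievable rank
  Yr <- matrix(rnorm(40), 40) %*% t(rep(1, prod(shape)))
  expect_error(acompcor(run_from_matrix(Yr, shape), mask, 5),
               "only 1 nonzero")
})

test_that("aCompCor equals a brute-force eigendecomposition oracle", {
  set.seed(10)
  shape <- c(5, 2, 1)                         # 10 voxels, 20 frames
  mask <- full_mask(shape)
  Y <- matrix(rnorm(20 * 10), 20)
  run <- run_from_matrix(Y, shape)
  comp <- acompcor(run, mask, 3)

  # oracle: detrend independently, eigendecompose the t x t covariance
  X <- cbind(1, 1:20)
  Yd <- Y - X %*% solve(crossprod(X), crossprod(X, Y))
  ev <- eigen(tcrossprod(Yd), symmetric = TRUE)
  for (j in 1:3) {
    ref <- ev$vectors[, j] / sd(ev$vectors[, j])
    if (sum(ref * comp[, j]) < 0) ref <- -ref
    expect_lt(max(abs(comp[, j] - ref)), 1e-8)
  }
})

test_that("assembled designs match the published column census", {
  co <- tiny_cohort()
  run <- co$runs[[1]]; mt <- co$motion[[1]]
  none <- rep(FALSE, co$config$n_timepoints)
  ac <- assemble_confounds(mt, none, run, co$masks, "acompcor")
  expect_identical(ncol(ac$matrix), 22L)      # 6 + 6 + 5 WM + 5 CSF
  expect_identical(sum(ac$sources == "compcor_wm"), 5L)
  gs <- assemble_confounds(mt, none, run, co$masks, "gsr")
  expect_identical(ncol(gs$matrix), 15L)      # 6 + 6 + 3 mean signals
  expect_setequal(unique(gs$sources),
                  c("motion", "motion_derivative", "global_signal",
                    "wm_mean", "csf_mean"))
  two <- none; two[c(5, 9)] <- TRUE
  ac2 <- assemble_confounds(mt, two, run, co$masks, "acompcor")
  expect_identical(ncol(ac2$matrix), 24L)
  # derivative at the first frame is zero (backward differences)
  expect_equal(unname(ac$matrix[1, 7:12]), rep(0, 6))
  expect_error(assemble_confounds(mt, none, run, co$masks, "pca"), "arg")

  p <- tempfile(fileext = ".tsv")
  write_confounds(ac, p)
  expect_identical(ncol(read.delim(p)), 22L)
})

test_that("aCompCor is wired to unsmoothed data in the pipeline", {
  co <- tiny_cohort()
  run <- co$runs[[1]]
  comp_unsmoothed <- acompcor(run, co$masks$wm, 5)
  comp_smoothed <- acompcor(smooth_gaussian(run, 6), co$masks$wm, 5)
  # smoothing changes the components, so the wiring must use the raw run
  expect_gt(max(abs(comp_unsmoothed - comp_smoothed)), 1e-4)
  sm <- placeboconn:::.subject_maps(run, co$motion[[1]], co$masks, "acompcor",
                                    denoise_params(), seed_spec(co$config$seed_center_mm))
  pipeline_wm <- sm$confounds$matrix[, sm$confounds$sources == "compcor_wm"]
  expect_equal(unname(pipeline_wm), unname(comp_unsmoothed), tolerance = 1e-12)
})
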