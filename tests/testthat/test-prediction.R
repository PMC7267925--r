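# Elastic-net LOOCV prediction, permutation inference and weight clusters.

# build a prediction fixture: n subject maps over a small mask with an
# outcome driven by a handful of planted voxels
planted_fixture <- function(n = 30, shape = c(5, 4, 3), n_signal = 5,
                            noise = 0, seed = 1) {
  # 5-sparse signal in 60 voxels at n = 30 sits comfortably above the
  # n ~ 2 k log(p) support-recovery threshold; weights are strong by design
  set.seed(seed)
  mask <- full_mask(shape)
  V <- prod(shape)
  X <- matrix(rnorm(n * V), n)
  w <- numeric(V); w[sample(V, n_signal)] <- runif(n_signal, 1, 2)
  y <- as.vector(X %*% w) + rnorm(n, sd = noise)
  maps <- lapply(seq_len(n), function(i)
    map_from_values(X[i, ], mask, "seed_fc_z", id = sprintf("sub-%02d", i)))
  subjects <- data.frame(subject_id = sprintf("sub-%02d", 1:n),
                         age = rnorm(n, 45, 10), sex = rbinom(n, 1, 0.5),
                         hdrs_baseline = pmax(8, round(rnorm(n, 22, 6))),
                         hdrs_post = 19, mean_fd = runif(n, 0.05, 0.3))
  subjects$hdrs_pct_change <- y
  list(maps = maps, subjects = subjects, w = w, y = y)
}

fast_spec <- function(...) prediction_spec(feature_kind = "seed_fc_z",
                                           l1_ratio_grid = 0.5,
                                           n_lambda = 10, n_perm = 199, ...)

test_that("a noiseless planted linear signal is recovered", {
  fx <- planted_fixture(n = 30, noise = 0, seed = 41)
  spec <- prediction_spec(feature_kind = "seed_fc_z", n_lambda = 10,
                          n_perm = 199, rng_seed = 7,
                          reuse_hyperparams = TRUE)
  res <- loocv_predict(fx$maps, fx$subjects, spec)
  expect_gt(res$r, 0.9)
  res <- permutation_test(fx$maps, fx$subjects, spec, res)
  expect_lte(res$p_r, 0.01)
  expect_lte(res$p_mse, 0.01)
  # weight map lives on the mask and points at planted voxels
  w_est <- res$weight_map$values[res$weight_map$mask]
  expect_gt(cor(w_est, fx$w), 0.5)
})

test_that("LOOCV has no leakage from the held-out subject", {
  fx <- planted_fixture(n = 12, noise = 0.3, seed = 42)
  spec <- fast_spec(rng_seed = 3)
  res <- loocv_predict(fx$maps, fx$subjects, spec)
  # corrupting a held-out subject's outcome must not move its prediction
  corrupted <- fx$subjects
  corrupted$hdrs_pct_change[4] <- corrupted$hdrs_pct_change[4] + 100
  res2 <- loocv_predict(fx$maps, corrupted, spec)
  expect_equal(res2$predicted[4], res$predicted[4], tolerance = 1e-10)
  # while other folds (which train on subject 4) do change
  expect_gt(max(abs(res2$predicted[-4] - res$predicted[-4])), 1e-6)
})

test_that("prediction is deterministic and duplicates predict identically", {
  fx <- planted_fixture(n = 8, noise = 0.2, seed = 43)
  spec <- fast_spec(rng_seed = 11)
  r1 <- loocv_predict(fx$maps, fx$subjects, spec)
  r2 <- loocv_predict(fx$maps, fx$subjects, spec)
  expect_identical(r1$predicted, r2$predicted)
  expect_identical(r1$modal_hyperparams, r2$modal_hyperparams)

  # duplicated cohort: each twin gets the same prediction (training sets
  # differ only in row order, so near-ties in hyperparameter selection may
  # resolve differently at machine precision — hence the loose tolerance)
  maps2 <- c(fx$maps, fx$maps)
  subj2 <- rbind(fx$subjects, fx$subjects)
  rd <- loocv_predict(maps2, subj2, spec)
  expect_equal(rd$predicted[1:8], rd$predicted[9:16], tolerance = 1e-3)
})

test_that("permutation p-values follow the add-one counting formula", {
  fx <- planted_fixture(n = 10, noise = 0.1, seed = 44)
  spec <- fast_spec(rng_seed = 13, reuse_hyperparams = TRUE)
  res <- loocv_predict(fx$maps, fx$subjects, spec)
  res <- permutation_test(fx$maps, fx$subjects, spec, res)
  expect_equal(res$p_r,
               (1 + sum(res$perm_r >= res$r)) / (1 + spec$n_perm))
  expect_equal(res$p_mse,
               (1 + sum(res$perm_mse <= res$mse)) / (1 + spec$n_perm))
  expect_gte(res$p_r, 1 / (spec$n_perm + 1))
  expect_lte(res$p_r, 1)
  if (all(res$perm_r < res$r))
    expect_equal(res$p_r, 1 / 200)            # 199 shuffles -> 0.005 floor
  # re-supplying the unshuffled outcome (identity shuffle) through the same
  # procedure reproduces the observed statistic exactly
  core <- placeboconn:::.loocv_core(
    do.call(rbind, lapply(fx$maps, function(m) m$values[m$mask])),
    fx$subjects$hdrs_pct_change,
    cbind(fx$subjects$age, fx$subjects$sex, fx$subjects$mean_fd),
    spec)
  expect_equal(core$r, res$r, tolerance = 1e-12)
  # reproducible from the seed
  resb <- permutation_test(fx$maps, fx$subjects, spec, res)
  expect_identical(resb$perm_r, res$perm_r)
  low <- spec; low$n_perm <- 50L
  expect_error(permutation_test(fx$maps, fx$subjects, low, res), ">= 100")
})

test_that("weight clusters are sign-separated and size-thresholded", {
  shape <- c(12, 10, 6)
  mask <- full_mask(shape)
  w <- array(0, shape)
  w[1:6, 1:5, 1:4] <- 0.5                     # 120-voxel positive blob
  w[9:12, 8:10, 1:4] <- 0.3                   # 48-voxel positive blob
  wm <- map_from_values(w[mask], mask, "weight")
  wc <- weight_clusters(wm, min_cluster_voxels = 100)
  expect_identical(nrow(wc$table), 1L)
  expect_identical(wc$table$n_voxels, 120L)
  expect_equal(sum(wc$map$values != 0, na.rm = TRUE), 120)

  wc_all <- weight_clusters(wm, min_cluster_voxels = 1)
  expect_identical(sort(wc_all$table$n_voxels), c(48L, 120L))

  # adjacent opposite-sign blobs never merge
  w2 <- array(0, shape)
  w2[1:6, 1:5, 1:4] <- 0.5
  w2[7:12, 1:5, 1:4] <- -0.5                  # touching the positive blob
  wm2 <- map_from_values(w2[mask], mask, "weight")
  wc2 <- weight_clusters(wm2, min_cluster_voxels = 100)
  expect_identical(nrow(wc2$table), 2L)
  expect_setequal(wc2$table$sign, c("positive", "negative"))
})

test_that("baseline control shares the schema and finds no false signal", {
  fx <- planted_fixture(n = 10, noise = 0.2, seed = 45)
  spec <- fast_spec(rng_seed = 17, reuse_hyperparams = TRUE)
  res <- baseline_control(fx$maps, fx$subjects, spec)
  expect_s3_class(res, "prediction_result")
  expect_identical(res$outcome, "hdrs_baseline")
  expect_identical(sort(names(res)),
                   sort(names(loocv_predict(fx$maps, fx$subjects, spec))))
  expect_length(res$predicted, 10)
  expect_error(loocv_predict(fx$maps[1:4], fx$subjects[1:4, ], spec),
               ">= 6 subjects")
})
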