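# Elastic-net prediction of the clinical outcome from voxelwise connectivity
# maps under leave-one-out cross-validation, with nuisance-covariate
# residualization fitted on training folds only, nested hyperparameter
# selection, permutation inference for r and MSE, and cluster reporting of
# the voxel weight map.

#' Prediction specification
#'
#' @param feature_kind `"gbc"` or `"seed_fc_z"` — which map feeds the model.
#' @param l1_ratio_grid Elastic-net mixing grid (glmnet `alpha`); default
#'   `c(0.1, 0.5, 0.9)`.
#' @param n_lambda Number of log-spaced penalty strengths per mixing value
#'   (default 20).
#' @param lambda_min_ratio Smallest lambda as a fraction of the fold's
#'   lambda-max (default 1e-3).
#' @param n_perm Number of outcome shuffles for the permutation test
#'   (default 1000; >= 100 enforced where used).
#' @param min_cluster_voxels Cluster-size threshold for weight reporting
#'   (default 100).
#' @param rng_seed Integer seed for the permutation shuffles.
#' @param reuse_hyperparams When `TRUE`, permutation replicates reuse the
#'   observed fit's modal hyperparameters instead of re-running nested
#'   selection (a speed-only reduction; default `FALSE`).
#' @param covariates_in_model When `TRUE`, covariates enter the elastic net
#'   unpenalized instead of being residualized out of the outcome.
#' @return A `prediction_spec` list.
#' @export
prediction_spec <- function(feature_kind = c("gbc", "seed_fc_z"),
                            l1_ratio_grid = c(0.1, 0.5, 0.9),
                            n_lambda = 20L,
                            lambda_min_ratio = 1e-3,
                            n_perm = 1000L,
                            min_cluster_voxels = 100L,
                            rng_seed = 1L,
                            reuse_hyperparams = FALSE,
                            covariates_in_model = FALSE) {
  feature_kind <- match.arg(feature_kind)
  stopifnot(length(l1_ratio_grid) >= 1, all(l1_ratio_grid > 0),
            all(l1_ratio_grid <= 1), n_lambda >= 1,
            min_cluster_voxels >= 1)
  structure(list(feature_kind = feature_kind,
                 l1_ratio_grid = sort(l1_ratio_grid),
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 n_perm = as.integer(n_perm),
                 min_cluster_voxels = as.integer(min_cluster_voxels),
                 rng_seed = as.integer(rng_seed),
                 reuse_hyperparams = isTRUE(reuse_hyperparams),
                 covariates_in_model = isTRUE(covariates_in_model)),
            class = "prediction_spec")
}

# lambda grid for one mixing value on (standardized X, centered y)
.lambda_grid <- function(X, y, alpha, n_lambda, min_ratio) {
  lmax <- max(abs(crossprod(X, y - mean(y)))) / (nrow(X) * max(alpha, 0.01))
  lmax <- max(lmax, 1e-8)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}


# vectorized column standard deviations (hot path: called per CV fold)
.col_sds <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  v <- (colSums(X^2) - n * mu^2) / (n - 1)
  sqrt(pmax(v, 0))
}

.standardize_cols <- function(X, center, scl) {
  scl0 <- ifelse(scl == 0, 1, scl)
  Z <- sweep(sweep(X, 2, center), 2, scl0, "/")
  Z[, scl == 0] <- 0
  Z
}

# glmnet is unreliable when handed a single lambda; always fit a short
# descending path ending at the smallest requested value
.lambda_path <- function(lambdas) {
  if (length(lambdas) >= 2) return(lambdas)
  c(lambdas * c(100, 10), lambdas)
}

# fit glmnet over a descending lambda sequence, return predictions at each
# requested lambda; the requested values sit exactly on the fitted path, so
# coefficients are read off directly (predict()'s interpolation machinery is
# a hot-path cost at LOOCV-permutation scale)
.enet_predict <- function(Xtr, ytr, Xte, alpha, lambdas) {
  fit <- glmnet::glmnet(Xtr, ytr, alpha = alpha,
                        lambda = .lambda_path(lambdas),
                        standardize = FALSE, intercept = TRUE)
  idx <- match(lambdas, fit$lambda)
  if (anyNA(idx))
    return(stats::predict(fit, newx = Xte, s = lambdas, exact = FALSE))
  pr <- as.matrix(Xte %*% fit$beta[, idx, drop = FALSE])
  sweep(pr, 2, fit$a0[idx], "+")
}

.enet_coef <- function(Xtr, ytr, alpha, lambdas, lambda) {
  fit <- glmnet::glmnet(Xtr, ytr, alpha = alpha,
                        lambda = .lambda_path(lambdas),
                        standardize = FALSE, intercept = TRUE)
  j <- match(lambda, fit$lambda)
  if (is.na(j))
    return(as.numeric(stats::coef(fit, s = lambda, exact = FALSE)))
  c(fit$a0[j], as.numeric(fit$beta[, j]))
}

# inner-LOOCV hyperparameter selection on one training fold
.select_hyperparams <- function(Xz, y, alpha_grid, n_lambda, min_ratio) {
  n <- nrow(Xz)
  grids <- lapply(alpha_grid, function(a)
    .lambda_grid(Xz, y, a, n_lambda, min_ratio))
  if (length(alpha_grid) == 1L && n_lambda == 1L)
    return(list(alpha = alpha_grid[1], lambda = grids[[1]][1],
                lambda_index = 1L))
  best <- NULL
  for (ai in seq_along(alpha_grid)) {
    lambdas <- grids[[ai]]
    se <- matrix(NA_real_, n, length(lambdas))
    for (j in seq_len(n)) {
      ctr <- colMeans(Xz[-j, , drop = FALSE])
      scl <- .col_sds(Xz[-j, , drop = FALSE])
      Ztr <- .standardize_cols(Xz[-j, , drop = FALSE], ctr, scl)
      Zte <- .standardize_cols(Xz[j, , drop = FALSE], ctr, scl)
      pr <- .enet_predict(Ztr, y[-j], Zte, alpha_grid[ai], lambdas)
      se[j, ] <- (as.numeric(pr) - y[j])^2
    }
    mse <- colMeans(se)
    li <- which.min(mse)
    if (is.null(best) || mse[li] < best$mse) {
      best <- list(alpha = alpha_grid[ai], lambda = lambdas[li],
                   lambda_index = li, mse = mse[li])
    }
  }
  best[c("alpha", "lambda", "lambda_index")]
}

# per-fold quantities that do not depend on the outcome: standardized
# feature blocks and the training covariate QR. Computing them once lets a
# permutation test reuse them across all outcome shuffles.
.fold_cache <- function(X, C, spec) {
  n <- nrow(X)
  lapply(seq_len(n), function(i) {
    tr <- setdiff(seq_len(n), i)
    if (spec$covariates_in_model && !is.null(C)) {
      Xtr_raw <- cbind(X[tr, , drop = FALSE], C[tr, , drop = FALSE])
      Xte_raw <- cbind(X[i, , drop = FALSE], C[i, , drop = FALSE])
    } else {
      Xtr_raw <- X[tr, , drop = FALSE]
      Xte_raw <- X[i, , drop = FALSE]
    }
    ctr <- colMeans(Xtr_raw)
    scl <- .col_sds(Xtr_raw)
    qrC <- if (spec$covariates_in_model || is.null(C)) NULL else
      qr(cbind(1, C[tr, , drop = FALSE]))
    list(tr = tr,
         Ztr = .standardize_cols(Xtr_raw, ctr, scl),
         Zte = .standardize_cols(Xte_raw, ctr, scl),
         qrC = qrC,
         Ci = if (is.null(C)) NULL else c(1, C[i, ]))
  })
}

# one full LOOCV pass; fixed_hp (alpha, lambda_index) skips inner selection
.loocv_core <- function(X, y, C, spec, fixed_hp = NULL, cache = NULL) {
  n <- nrow(X)
  if (is.null(cache)) cache <- .fold_cache(X, C, spec)
  preds <- numeric(n)
  hp <- vector("list", n)
  for (i in seq_len(n)) {
    fc <- cache[[i]]
    tr <- fc$tr
    if (is.null(fc$qrC)) {
      rtr <- y[tr]; cov_component <- 0
    } else {
      coefs <- qr.coef(fc$qrC, y[tr])
      # a covariate constant within the training fold yields an NA
      # coefficient; treat it as zero (the column carried no information)
      coefs[is.na(coefs)] <- 0
      rtr <- y[tr] - as.vector(cbind(1, C[tr, , drop = FALSE]) %*% coefs)
      cov_component <- sum(fc$Ci * coefs)
    }
    Ztr <- fc$Ztr
    Zte <- fc$Zte
    sel <- if (is.null(fixed_hp)) {
      .select_hyperparams(Ztr, rtr, spec$l1_ratio_grid, spec$n_lambda,
                          spec$lambda_min_ratio)
    } else {
      g <- .lambda_grid(Ztr, rtr, fixed_hp$alpha, spec$n_lambda,
                        spec$lambda_min_ratio)
      list(alpha = fixed_hp$alpha, lambda = g[fixed_hp$lambda_index],
           lambda_index = fixed_hp$lambda_index)
    }
    g <- .lambda_grid(Ztr, rtr, sel$alpha, spec$n_lambda,
                      spec$lambda_min_ratio)
    pr <- .enet_predict(Ztr, rtr, Zte, sel$alpha, g)[, sel$lambda_index]
    preds[i] <- as.numeric(pr) + cov_component
    hp[[i]] <- sel
  }
  s <- stats::sd(preds)
  r <- if (!is.finite(s) || s == 0) 0 else stats::cor(preds, y)
  list(predicted = preds, r = r, mse = mean((preds - y)^2), hp = hp)
}

.modal_hp <- function(hp) {
  key <- vapply(hp, function(h) paste(h$alpha, h$lambda_index), character(1))
  tab <- sort(table(key), decreasing = TRUE)
  pick <- names(tab)[1]
  parts <- strsplit(pick, " ")[[1]]
  list(alpha = as.numeric(parts[1]), lambda_index = as.integer(parts[2]))
}

# features over the shared mask, excluding zero-variance voxels
.feature_matrix <- function(maps) {
  st <- .stack_maps(maps)
  sds <- .col_sds(st$Y)
  keep <- sds > 0
  if (any(!keep))
    message("excluding ", sum(!keep), " zero-variance voxel(s) from features")
  vox <- which(st$mask)[keep]
  list(X = st$Y[, keep, drop = FALSE], vox = vox, mask = st$mask,
       affine = st$affine)
}

.subject_covariates <- function(subjects) {
  cbind(age = subjects$age, sex = subjects$sex, mean_fd = subjects$mean_fd)
}

#' Elastic-net LOOCV prediction of the clinical outcome
#'
#' For each held-out subject: the outcome is residualized on the nuisance
#' covariates (age, sex, mean FD) fitted on the training subjects only;
#' voxel features are standardized by training-fold mean/SD; the mixing and
#' penalty-strength hyperparameters are chosen by inner LOOCV MSE on the
#' training fold; the held-out residualized outcome is predicted and its
#' covariate component re-added. Performance is Pearson r and MSE over the
#' held-out predictions (fraction units). The final weight map is a fit on
#' all subjects at the modal selected hyperparameters, with weights mapped
#' back to unstandardized voxel scale.
#'
#' @param maps List of subject [connectivity_map()]s (one per subject, in
#'   subjects-table order).
#' @param subjects Subjects data.frame with `age`, `sex`, `mean_fd` and the
#'   outcome column.
#' @param spec A [prediction_spec()].
#' @param outcome Outcome column name (default `"hdrs_pct_change"`).
#' @return A `prediction_result` list: `predicted`, `observed`, `r`, `mse`,
#'   `p_r`, `p_mse` (NA until [permutation_test()]), `weight_map`,
#'   `clusters`, `fold_hyperparams`, `modal_hyperparams`.
#' @export
loocv_predict <- function(maps, subjects, spec = prediction_spec(),
                          outcome = "hdrs_pct_change") {
  n <- length(maps)
  if (n < 6L) stop("need >= 6 subjects for LOOCV prediction")
  if (nrow(subjects) != n)
    stop("subjects table (", nrow(subjects), ") does not match maps (", n, ")")
  y <- subjects[[outcome]]
  if (is.null(y)) stop("no outcome column '", outcome, "' in subjects table")
  if (stats::sd(y) == 0) stop("constant outcome; prediction undefined")
  fm <- .feature_matrix(maps)
  C <- .subject_covariates(subjects)
  core <- .loocv_core(fm$X, y, C, spec)
  modal <- .modal_hp(core$hp)

  # final whole-sample fit at the modal hyperparameters
  if (spec$covariates_in_model) {
    rfull <- y
    Xfull <- cbind(fm$X, C)
  } else {
    cf <- stats::lm.fit(cbind(1, C), y)
    rfull <- cf$residuals
    Xfull <- fm$X
  }
  ctr <- colMeans(Xfull)
  scl <- .col_sds(Xfull)
  Z <- .standardize_cols(Xfull, ctr, scl)
  g <- .lambda_grid(Z, rfull, modal$alpha, spec$n_lambda,
                    spec$lambda_min_ratio)
  beta <- .enet_coef(Z, rfull, modal$alpha, g, g[modal$lambda_index])[-1]
  beta_vox <- beta[seq_along(fm$vox)]
  wvals <- array(NA_real_, dim = dim(fm$mask))
  wvals[fm$mask] <- 0
  wvals[fm$vox] <- beta_vox / ifelse(scl[seq_along(fm$vox)] == 0, 1,
                                     scl[seq_along(fm$vox)])
  wmap <- connectivity_map(wvals, fm$mask, "weight", fm$affine, "group")
  wc <- weight_clusters(wmap, spec$min_cluster_voxels)

  structure(list(predicted = core$predicted, observed = y,
                 r = core$r, mse = core$mse,
                 p_r = NA_real_, p_mse = NA_real_,
                 weight_map = wmap, clusters = wc$table,
                 fold_hyperparams = core$hp,
                 modal_hyperparams = modal,
                 feature_kind = spec$feature_kind,
                 outcome = outcome, spec = spec),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result %s -> %s: r = %.3f, MSE = %.4f",
              x$feature_kind, x$outcome, x$r, x$mse))
  if (!is.na(x$p_r))
    cat(sprintf(", p_r = %.4g, p_mse = %.4g", x$p_r, x$p_mse))
  cat(sprintf(", %d subjects>\n", length(x$observed)))
  invisible(x)
}

#' Permutation test of prediction performance
#'
#' Shuffles the outcome vector `n_perm` times (covariates stay aligned with
#' their subjects; only the outcome moves) and re-runs the full LOOCV
#' procedure on each shuffle. When `spec$reuse_hyperparams` is `TRUE` the
#' replicates reuse the observed modal hyperparameters instead of re-running
#' nested selection. Add-one p-values:
#' `p_r = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)` and
#' `p_mse = (1 + #\{mse_perm <= mse_obs\}) / (1 + n_perm)`.
#'
#' @param maps,subjects,spec As in [loocv_predict()] (identical spec).
#' @param observed The observed `prediction_result`.
#' @param outcome Outcome column name.
#' @return The `prediction_result` with `p_r`, `p_mse` and the permutation
#'   distributions (`perm_r`, `perm_mse`) filled in.
#' @export
permutation_test <- function(maps, subjects, spec, observed,
                             outcome = "hdrs_pct_change") {
  if (spec$n_perm < 100L) stop("n_perm must be >= 100")
  y <- subjects[[outcome]]
  fm <- .feature_matrix(maps)
  C <- .subject_covariates(subjects)
  fixed <- if (spec$reuse_hyperparams) observed$modal_hyperparams else NULL
  cache <- .fold_cache(fm$X, C, spec)         # outcome-independent, reused
  set.seed(spec$rng_seed)
  perm_r <- numeric(spec$n_perm)
  perm_mse <- numeric(spec$n_perm)
  for (b in seq_len(spec$n_perm)) {
    yp <- sample(y)
    res <- .loocv_core(fm$X, yp, C, spec, fixed_hp = fixed, cache = cache)
    perm_r[b] <- res$r
    perm_mse[b] <- res$mse
  }
  observed$p_r <- (1 + sum(perm_r >= observed$r)) / (1 + spec$n_perm)
  observed$p_mse <- (1 + sum(perm_mse <= observed$mse)) / (1 + spec$n_perm)
  observed$perm_r <- perm_r
  observed$perm_mse <- perm_mse
  observed
}

#' Threshold a weight map by cluster size
#'
#' Nonzero-weight voxels are labeled at 18-connectivity, positive and
#' negative weights separately (adjacent opposite-sign blobs are never
#' merged); clusters smaller than `min_cluster_voxels` are zeroed.
#'
#' @param weight_map A [connectivity_map()] of kind `"weight"`.
#' @param min_cluster_voxels Minimum surviving cluster size (default 100).
#' @param connectivity Cluster connectivity (default 18).
#' @return A list: `map` (thresholded [connectivity_map()]) and `table`
#'   (clusters with `sign`, size and peak-|weight| location in world mm).
#' @export
weight_clusters <- function(weight_map, min_cluster_voxels = 100L,
                            connectivity = 18) {
  stopifnot(inherits(weight_map, "connectivity_map"))
  vals <- weight_map$values
  mask <- weight_map$mask
  out <- vals
  out[mask] <- 0
  rows <- NULL
  for (sgn in c("positive", "negative")) {
    bin <- array(FALSE, dim = dim(mask))
    bin[mask] <- if (sgn == "positive") vals[mask] > 0 else vals[mask] < 0
    lab <- label_clusters(bin, connectivity, weight_map$affine, vals)
    tab <- lab$table
    if (!nrow(tab)) next
    tab$sign <- sgn
    keep <- tab$n_voxels >= min_cluster_voxels
    for (cid in tab$cluster_id[keep])
      out[lab$labels == cid] <- vals[lab$labels == cid]
    rows <- rbind(rows, tab[keep, , drop = FALSE])
  }
  if (is.null(rows))
    rows <- data.frame(cluster_id = integer(0), n_voxels = integer(0),
                       peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                       peak_z_mm = numeric(0), peak_value = numeric(0),
                       sign = character(0))
  rows <- rows[order(-rows$n_voxels), , drop = FALSE]
  if (nrow(rows)) rows$cluster_id <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  tmap <- connectivity_map(out, mask, "weight", weight_map$affine,
                           weight_map$subject_id)
  list(map = tmap, table = rows)
}

#' Specificity control: predict baseline severity instead of change
#'
#' Runs the identical LOOCV elastic-net procedure with `hdrs_baseline` as
#' the outcome. A null result here supports the specificity of a positive
#' percent-change prediction.
#'
#' @param maps,subjects,spec As in [loocv_predict()].
#' @return A `prediction_result` for the baseline outcome.
#' @export
baseline_control <- function(maps, subjects, spec = prediction_spec()) {
  loocv_predict(maps, subjects, spec, outcome = "hdrs_baseline")
}
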