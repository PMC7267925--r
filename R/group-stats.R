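# Group-level inference on subject connectivity maps: voxelwise one-sample
# t-maps with mean-centered nuisance covariates, connected-component cluster
# labeling, and cluster-extent family-wise-error control by Freedman-Lane
# sign-flip permutation of the maximum supra-threshold cluster size.

#' Group design (intercept + mean-centered nuisance covariates)
#'
#' @param age,sex,mean_fd Per-subject covariates (sex coded 0 male /
#'   1 female). Each is mean-centered before fitting; constant covariates
#'   are dropped with a warning.
#' @return A `group_design` list with the centered covariate matrix.
#' @export
group_design <- function(age = NULL, sex = NULL, mean_fd = NULL) {
  covs <- list(age = age, sex = sex, mean_fd = mean_fd)
  covs <- covs[!vapply(covs, is.null, logical(1))]
  n <- if (length(covs)) length(covs[[1]]) else NA_integer_
  X <- NULL
  for (nm in names(covs)) {
    x <- covs[[nm]]
    if (stats::sd(x) == 0) {
      warning("covariate '", nm, "' is constant across subjects; dropped")
      next
    }
    X <- cbind(X, x - mean(x))
    colnames(X)[ncol(X)] <- nm
  }
  structure(list(covariates = X, n_subjects = n), class = "group_design")
}

# stack subject maps into an n x V matrix over the shared mask
.stack_maps <- function(maps) {
  mask <- maps[[1]]$mask
  aff <- maps[[1]]$affine
  for (m in maps) {
    if (!identical(m$mask, mask) || !isTRUE(all.equal(m$affine, aff)))
      stop("all subject maps must share mask and affine")
  }
  Y <- do.call(rbind, lapply(maps, function(m) m$values[mask]))
  list(Y = Y, mask = mask, affine = aff)
}

# intercept t-statistics for Y (n x V) given centered covariates (may be NULL)
.intercept_t <- function(Y, C) {
  n <- nrow(Y)
  X <- if (is.null(C)) matrix(1, n, 1) else cbind(1, C)
  p <- ncol(X)
  df <- n - p
  if (df <= 0) stop("non-positive degrees of freedom (n = ", n,
                    ", model columns = ", p, ")")
  XtXinv <- solve(crossprod(X))
  B <- XtXinv %*% crossprod(X, Y)
  resid <- Y - X %*% B
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * XtXinv[1, 1])
  tval <- ifelse(se == 0, ifelse(B[1, ] == 0, 0, Inf * sign(B[1, ])),
                 B[1, ] / se)
  list(t = tval, df = df)
}

#' Voxelwise one-sample t-map with nuisance covariates
#'
#' Per voxel, OLS of the subject map values on an intercept plus the
#' mean-centered covariates; the reported statistic is the intercept t with
#' `df = n - 1 - n_covariates`. Zero residual variance yields an infinite t
#' marker with a warning.
#'
#' @param maps List of subject [connectivity_map()]s sharing mask/affine.
#' @param design A [group_design()] (covariates may be empty).
#' @return A [connectivity_map()] of kind `"t_stat"` with attributes `df`
#'   and `n_subjects`.
#' @export
one_sample_t_map <- function(maps, design = group_design()) {
  st <- .stack_maps(maps)
  ft <- .intercept_t(st$Y, design$covariates)
  if (any(is.infinite(ft$t)))
    warning(sum(is.infinite(ft$t)),
            " voxel(s) with zero residual variance reported as infinite t")
  vals <- array(NA_real_, dim = dim(st$mask))
  vals[st$mask] <- ft$t
  out <- connectivity_map(vals, st$mask, "t_stat", st$affine, "group")
  attr(out, "df") <- ft$df
  attr(out, "n_subjects") <- nrow(st$Y)
  out
}

.neighbor_offsets <- function(connectivity, dims) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3,
                 stop("connectivity must be 6, 18 or 26"))
  as.matrix(g[keep, ])
}

# connected components of a 3-D logical array; returns integer label array
.label_components <- function(binary, connectivity = 18) {
  dims <- dim(binary)
  offs <- .neighbor_offsets(connectivity, dims)
  labels <- array(0L, dim = dims)
  idx <- which(binary)
  if (!length(idx)) return(labels)
  coord <- arrayInd(idx, dims)
  in_set <- array(FALSE, dim = dims)
  in_set[idx] <- TRUE
  lab <- 0L
  for (start in idx) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- arrayInd(cur, dims)
      nb <- sweep(offs, 2, as.integer(cc), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      ni <- nb[, 1] + (nb[, 2] - 1L) * dims[1] +
        (nb[, 3] - 1L) * dims[1] * dims[2]
      ni <- ni[in_set[ni] & labels[ni] == 0L]
      if (length(ni)) {
        labels[ni] <- lab
        queue <- c(queue, ni)
      }
    }
  }
  labels
}

#' Label clusters in a binary map
#'
#' Connected-component labeling under 6-, 18- or 26-connectivity (default
#' 18, the SPM convention: voxels sharing a face or an edge are connected,
#' corners are not).
#'
#' @param binary_map 3-D logical array.
#' @param connectivity 6, 18 or 26.
#' @param affine Optional 4x4 affine for peak coordinates; identity when
#'   omitted.
#' @param values Optional 3-D statistic array used to locate each cluster's
#'   peak (largest |value|); cluster order is by decreasing size.
#' @return A list: `table` (data.frame `cluster_id`, `n_voxels`,
#'   `peak_x_mm`, `peak_y_mm`, `peak_z_mm`, `peak_value`) and `labels`
#'   (integer array).
#' @export
label_clusters <- function(binary_map, connectivity = 18, affine = diag(4),
                           values = NULL) {
  labels <- .label_components(binary_map, connectivity)
  n_lab <- max(labels)
  if (n_lab == 0L)
    return(list(table = data.frame(cluster_id = integer(0),
                                   n_voxels = integer(0),
                                   peak_x_mm = numeric(0),
                                   peak_y_mm = numeric(0),
                                   peak_z_mm = numeric(0),
                                   peak_value = numeric(0)),
                labels = labels))
  if (is.null(values)) values <- array(1, dim = dim(binary_map))
  rows <- lapply(seq_len(n_lab), function(l) {
    vox <- which(labels == l)
    peak <- vox[which.max(abs(values[vox]))]
    pc <- arrayInd(peak, dim(binary_map)) - 1L
    mm <- voxel_to_world(affine, as.numeric(pc))
    data.frame(cluster_id = l, n_voxels = length(vox),
               peak_x_mm = mm[1], peak_y_mm = mm[2], peak_z_mm = mm[3],
               peak_value = values[peak])
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$n_voxels, tab$cluster_id)
  tab <- tab[ord, , drop = FALSE]
  remap <- integer(n_lab)
  remap[tab$cluster_id] <- seq_len(n_lab)
  tab$cluster_id <- seq_len(n_lab)
  rownames(tab) <- NULL
  relabeled <- labels
  relabeled[labels > 0L] <- remap[labels[labels > 0L]]
  list(table = tab, labels = relabeled)
}

# cluster sizes of supra-threshold voxels (both signs), given t values on the
# mask; returns list(sizes_pos, sizes_neg, labels info) -- internal
.threshold_clusters <- function(tvals, mask, thr, connectivity, affine) {
  pos <- array(FALSE, dim = dim(mask)); pos[mask] <- tvals > thr
  neg <- array(FALSE, dim = dim(mask)); neg[mask] <- tvals < -thr
  tarr <- array(0, dim = dim(mask)); tarr[mask] <- tvals
  lp <- label_clusters(pos, connectivity, affine, tarr)
  ln <- label_clusters(neg, connectivity, affine, tarr)
  list(pos = lp, neg = ln)
}

#' Cluster-extent FWE inference by sign-flip permutation
#'
#' Thresholds the observed one-sample t-map at a two-sided voxel-level p
#' (Student t at the model's df), labels supra-threshold voxels at the
#' given connectivity (positive and negative clusters separately), and
#' builds the null distribution of the maximum cluster size by
#' Freedman-Lane sign flipping: subject maps are residualized on the
#' covariate-only model, residuals are sign-flipped, the covariate fit is
#' added back, and the full model is refit and re-thresholded. Corrected
#' cluster p = (1 + #\{max null size >= observed size\}) / (1 + n_perm).
#'
#' @param maps List of subject [connectivity_map()]s.
#' @param design A [group_design()].
#' @param voxel_p Two-sided voxel-forming p threshold (default .001).
#' @param cluster_alpha Corrected cluster-level alpha (default .05).
#' @param n_perm Number of sign-flip permutations (>= 100).
#' @param rng_seed Integer seed for the flips.
#' @param connectivity Cluster connectivity (default 18).
#' @return A list of class `cluster_fwe_result`: `clusters` (data.frame with
#'   `cluster_id`, `sign`, `n_voxels`, peak coordinates/statistic, `p_corr`,
#'   `significant`), `t_map`, `df`, `null_max_size`, and the thresholds
#'   used.
#' @export
cluster_fwe <- function(maps, design = group_design(), voxel_p = 0.001,
                        cluster_alpha = 0.05, n_perm = 999L,
                        rng_seed = 1L, connectivity = 18) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  st <- .stack_maps(maps)
  C <- design$covariates
  n <- nrow(st$Y)
  ft <- .intercept_t(st$Y, C)
  thr <- stats::qt(1 - voxel_p / 2, ft$df)
  obs <- .threshold_clusters(ft$t, st$mask, thr, connectivity, st$affine)

  # Freedman-Lane: residualize on the covariate-only (reduced) model
  if (is.null(C)) {
    fitted_red <- matrix(0, n, ncol(st$Y))
    resid_red <- st$Y
  } else {
    Bc <- solve(crossprod(C), crossprod(C, st$Y))
    fitted_red <- C %*% Bc
    resid_red <- st$Y - fitted_red
  }
  set.seed(rng_seed)
  null_max <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    Yb <- fitted_red + s * resid_red
    tb <- .intercept_t(Yb, C)$t
    supra_pos <- array(FALSE, dim = dim(st$mask)); supra_pos[st$mask] <- tb > thr
    supra_neg <- array(FALSE, dim = dim(st$mask)); supra_neg[st$mask] <- tb < -thr
    mx <- 0L
    if (any(supra_pos))
      mx <- max(mx, max(label_clusters(supra_pos, connectivity)$table$n_voxels))
    if (any(supra_neg))
      mx <- max(mx, max(label_clusters(supra_neg, connectivity)$table$n_voxels))
    null_max[b] <- mx
  }
  mk <- function(tab, sign_lab) {
    if (!nrow(tab)) return(NULL)
    tab$sign <- sign_lab
    tab$p_corr <- vapply(tab$n_voxels, function(sz)
      (1 + sum(null_max >= sz)) / (1 + n_perm), numeric(1))
    tab
  }
  clusters <- rbind(mk(obs$pos$table, "positive"), mk(obs$neg$table, "negative"))
  if (is.null(clusters)) {
    clusters <- data.frame(cluster_id = integer(0), n_voxels = integer(0),
                           peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                           peak_z_mm = numeric(0), peak_value = numeric(0),
                           sign = character(0), p_corr = numeric(0))
  } else {
    clusters <- clusters[order(clusters$p_corr, -clusters$n_voxels), ,
                         drop = FALSE]
    clusters$cluster_id <- seq_len(nrow(clusters))
    rownames(clusters) <- NULL
  }
  clusters$significant <- clusters$p_corr < cluster_alpha
  tmap <- one_sample_t_map(maps, design)
  structure(list(clusters = clusters, t_map = tmap, df = ft$df,
                 voxel_threshold_t = thr, voxel_p = voxel_p,
                 cluster_alpha = cluster_alpha, n_perm = n_perm,
                 rng_seed = rng_seed, null_max_size = null_max),
            class = "cluster_fwe_result")
}
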