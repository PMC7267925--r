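# Per-subject connectivity maps: voxelwise global brain connectivity (mean
# squared correlation with every in-brain voxel, self-term included) and
# seed-based Fisher-z functional connectivity from a spherical seed.

#' Seed specification
#'
#' @param center_mm World coordinate of the sphere center (default the
#'   rostral ACC point (0, 38, 4)).
#' @param diameter_mm Sphere diameter in mm (default 6).
#' @return A `seed_spec` list.
#' @export
seed_spec <- function(center_mm = c(0, 38, 4), diameter_mm = 6) {
  stopifnot(length(center_mm) == 3L, diameter_mm > 0)
  structure(list(center_mm = as.numeric(center_mm),
                 diameter_mm = diameter_mm),
            class = "seed_spec")
}

# standardized in-mask series (t x n), dropping zero-variance voxels from the
# mask with a warning; returns list(Z, mask)
.standardized_series <- function(run, brain_mask) {
  v <- which(as.vector(brain_mask))
  if (length(v) < 2L) stop("brain mask must contain >= 2 voxels")
  Y <- .run_matrix(run)[, v, drop = FALSE]
  sds <- .col_sds(Y)
  bad <- sds == 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " zero-variance voxel(s) from the mask")
    mask <- brain_mask
    mask[v[bad]] <- FALSE
    return(.standardized_series(run, mask))
  }
  Z <- scale(Y)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  list(Z = Z, mask = brain_mask)
}

#' Global brain connectivity map
#'
#' `GBC_i = (1/n) * sum_j r_ij^2` over all `n` in-mask voxels `j`, including
#' the self term (`r_ii = 1`); values lie in (0, 1]. A signed-mean variant
#' (`exponent = "r"`) averaging raw correlations is provided for sensitivity
#' analysis. Computation is chunked; the result is independent of
#' `chunk_size`.
#'
#' @param run A denoised [bold_run()].
#' @param brain_mask 3-D logical mask (zero-variance voxels are dropped with
#'   a warning).
#' @param exponent `"r2"` (default, squared correlation) or `"r"` (signed).
#' @param chunk_size Voxels per chunk (memory/speed trade-off only).
#' @return A [connectivity_map()] of kind `"gbc"`.
#' @export
gbc_map <- function(run, brain_mask, exponent = c("r2", "r"),
                    chunk_size = 1024L) {
  exponent <- match.arg(exponent)
  ss <- .standardized_series(run, brain_mask)
  Z <- ss$Z
  n <- ncol(Z)
  n_t <- nrow(Z)
  gbc <- numeric(n)
  for (start in seq(1, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1, n)
    r <- crossprod(Z[, idx, drop = FALSE], Z) / (n_t - 1)
    r[r > 1] <- 1; r[r < -1] <- -1
    gbc[idx] <- if (exponent == "r2") rowMeans(r^2) else rowMeans(r)
  }
  vals <- array(NA_real_, dim = dim(ss$mask))
  vals[ss$mask] <- gbc
  connectivity_map(vals, ss$mask, "gbc", run$affine, run$subject_id)
}

#' Mean time series of a spherical seed
#'
#' Averages the series of all in-mask voxels whose centers lie within
#' `diameter_mm / 2` (inclusive) of the seed center, distances measured in
#' world mm via the affine.
#'
#' @param run A [bold_run()].
#' @param seed A [seed_spec()].
#' @param brain_mask 3-D logical mask.
#' @return Numeric per-timepoint seed series.
#' @export
seed_timeseries <- function(run, seed = seed_spec(), brain_mask) {
  d <- dim(run$data)[1:3]
  idx0 <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                                z = 0:(d[3] - 1)))
  world <- voxel_to_world(run$affine, idx0)
  dist <- sqrt(colSums((t(world) - seed$center_mm)^2))
  inside <- dist <= seed$diameter_mm / 2 & as.vector(brain_mask)
  if (!any(inside)) {
    near <- min(dist[as.vector(brain_mask)])
    stop("seed sphere at (", paste(seed$center_mm, collapse = ", "),
         "), diameter ", seed$diameter_mm,
         " mm contains no in-mask voxel; nearest in-mask voxel center is ",
         round(near, 2), " mm away")
  }
  rowMeans(.run_matrix(run)[, inside, drop = FALSE])
}

#' Seed-based Fisher-z functional connectivity map
#'
#' `z_i = atanh(r_i)` between the seed series and every in-mask voxel, with
#' `r` clipped to +/- (1 - 1e-7). Seed-interior voxels are included.
#' Constant voxel series get z = 0 with a warning reporting their count.
#'
#' @param run A denoised [bold_run()].
#' @param seed_series Seed time series from [seed_timeseries()].
#' @param brain_mask 3-D logical mask.
#' @return A [connectivity_map()] of kind `"seed_fc_z"`.
#' @export
seed_fc_map <- function(run, seed_series, brain_mask) {
  if (stats::sd(seed_series) == 0) stop("seed series is constant")
  v <- which(as.vector(brain_mask))
  Y <- .run_matrix(run)[, v, drop = FALSE]
  sds <- .col_sds(Y)
  bad <- sds == 0
  r <- numeric(length(v))
  r[!bad] <- as.vector(stats::cor(seed_series, Y[, !bad, drop = FALSE]))
  if (any(bad))
    warning(sum(bad), " constant voxel series set to z = 0")
  clip <- 1 - 1e-7
  r <- pmin(pmax(r, -clip), clip)
  r[bad] <- 0
  vals <- array(NA_real_, dim = dim(brain_mask))
  vals[v] <- atanh(r)
  connectivity_map(vals, brain_mask, "seed_fc_z", run$affine, run$subject_id)
}
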