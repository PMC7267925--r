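# Nuisance design construction: framewise displacement, artifact (scrubbing)
# detection from within-subject empirical percentiles of the motion and
# global-signal-change series, aCompCor components from WM/CSF, and the two
# assembled confound strategies (aCompCor vs whole-brain signal regression).

#' Framewise displacement (Power convention)
#'
#' `FD_t = sum |delta translations| + r * sum |delta rotations|` with
#' rotations projected to arc length on a sphere of radius `head_radius_mm`;
#' the first frame has FD = 0.
#'
#' @param motion A [motion_trace()].
#' @param head_radius_mm Sphere radius for rotation projection (default 50).
#' @return Numeric vector of per-frame FD in mm.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  m <- unclass(motion)
  if (!all(is.finite(m))) stop("non-finite motion values")
  if (nrow(m) < 2L) stop("need >= 2 timepoints")
  d <- abs(diff(m))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Mean framewise displacement
#'
#' Mean of the FD series excluding the (identically zero) first frame.
#'
#' @param fd FD series from [framewise_displacement()].
#' @return Scalar mean FD in mm.
#' @export
mean_framewise_displacement <- function(fd) {
  mean(fd[-1])
}

#' Detect outlier frames (scrubbing targets)
#'
#' Computes two per-frame diagnostic series — composite motion (FD, mm) and
#' the z-scored frame-to-frame change of the global mean signal — and flags
#' frames strictly exceeding the within-subject empirical `percentile` on
#' either series. Constant series yield no flags (strict inequality at the
#' threshold).
#'
#' @param run A [bold_run()].
#' @param motion The matching [motion_trace()].
#' @param percentile Percentile threshold in (50, 100); default 97.
#' @param brain_mask Optional 3-D logical mask for the global signal
#'   (defaults to all voxels).
#' @return An `outlier_series` list: `flag` (logical), `motion_mm` (FD),
#'   `global_z` (|z| of global-signal change), `percentile`.
#' @export
detect_outliers <- function(run, motion, percentile = 97, brain_mask = NULL) {
  if (percentile <= 50 || percentile >= 100)
    stop("percentile must lie in (50, 100)")
  n_t <- dim(run$data)[4]
  if (nrow(motion) != n_t)
    stop("motion trace (", nrow(motion), " rows) does not match run (",
         n_t, " frames)")
  fd <- framewise_displacement(motion)
  Y <- .run_matrix(run)
  if (!is.null(brain_mask)) Y <- Y[, as.vector(brain_mask), drop = FALSE]
  g <- rowMeans(Y)
  dg <- c(0, diff(g))
  s <- stats::sd(dg)
  gz <- if (s == 0) rep(0, n_t) else abs((dg - mean(dg)) / s)
  q_fd <- stats::quantile(fd, percentile / 100, names = FALSE)
  q_gz <- stats::quantile(gz, percentile / 100, names = FALSE)
  flag <- (fd > q_fd) | (gz > q_gz)
  if (mean(flag) > 0.5)
    stop("more than 50% of frames flagged as outliers; data unusable")
  structure(list(flag = flag, motion_mm = fd, global_z = gz,
                 percentile = percentile),
            class = "outlier_series")
}

#' Scrubbing indicator regressors
#'
#' One column per flagged frame: 1 at that frame, 0 elsewhere.
#'
#' @param outliers An `outlier_series` from [detect_outliers()], or a logical
#'   vector of flags.
#' @return t x n_flagged numeric matrix (zero columns when nothing flagged).
#' @export
scrub_regressors <- function(outliers) {
  flag <- if (inherits(outliers, "outlier_series")) outliers$flag else outliers
  idx <- which(flag)
  out <- matrix(0, length(flag), length(idx))
  for (j in seq_along(idx)) out[idx[j], j] <- 1
  colnames(out) <- if (length(idx)) paste0("scrub_", idx) else character(0)
  out
}

# t x V matrix view of a run (frames in rows)
.run_matrix <- function(run) {
  d <- dim(run$data)
  t(matrix(run$data, prod(d[1:3]), d[4]))
}

#' Anatomical component correction (aCompCor) time series
#'
#' Extracts the top principal component time series from the voxels of an
#' anatomical noise mask (WM or CSF), computed from unsmoothed data: each
#' voxel series is mean-centered and linearly detrended, then the principal
#' directions of the time-by-time covariance are taken. Components are
#' returned unit-variance and mutually orthogonal, with a deterministic sign
#' convention (largest-magnitude element positive).
#'
#' @param run_unsmoothed A [bold_run()] that has not been spatially smoothed.
#' @param mask 3-D logical mask with at least `n_components` voxels.
#' @param n_components Number of components (default 5).
#' @return t x n_components matrix of component time series.
#' @export
acompcor <- function(run_unsmoothed, mask, n_components = 5L) {
  stopifnot(is.logical(mask))
  v <- which(as.vector(mask))
  if (length(v) < n_components)
    stop("mask has ", length(v), " voxels; need >= ", n_components)
  Y <- .run_matrix(run_unsmoothed)[, v, drop = FALSE]
  n_t <- nrow(Y)
  X <- cbind(1, seq_len(n_t))
  Y <- Y - X %*% qr.coef(qr(X), Y)            # center + linear detrend
  sv <- svd(Y, nu = n_components, nv = 0)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (rank < n_components)
    stop("rank-deficient data: only ", rank, " nonzero components available")
  comp <- sv$u[, seq_len(n_components), drop = FALSE]
  comp <- scale(comp, center = TRUE, scale = TRUE)   # unit variance
  for (j in seq_len(ncol(comp))) {
    k <- which.max(abs(comp[, j]))
    if (comp[k, j] < 0) comp[, j] <- -comp[, j]
  }
  attr(comp, "scaled:center") <- NULL
  attr(comp, "scaled:scale") <- NULL
  colnames(comp) <- paste0("comp_", seq_len(n_components))
  comp
}

#' Assemble the nuisance design matrix
#'
#' Builds the full confound model for one run under one of the two
#' denoising strategies:
#' \describe{
#'   \item{`"acompcor"`}{6 motion + 6 motion derivatives + per-outlier
#'     scrubbing indicators + 5 WM + 5 CSF aCompCor components (22 columns
#'     with no outliers).}
#'   \item{`"gsr"`}{6 motion + 6 derivatives + scrubbing indicators + global
#'     mean + WM mean + CSF mean signals (15 columns with no outliers).}
#' }
#' Motion derivatives are backward differences with 0 at the first frame.
#' aCompCor components must come from unsmoothed data, so `run` here is the
#' unsmoothed run.
#'
#' @param motion A [motion_trace()].
#' @param outliers An `outlier_series` (or logical flag vector).
#' @param run The unsmoothed [bold_run()].
#' @param masks A [mask_set()].
#' @param strategy `"acompcor"` or `"gsr"`.
#' @param n_components Components per anatomical mask (default 5).
#' @return A `confound_model` list: `matrix` (t x k), `labels`, `sources`.
#' @export
assemble_confounds <- function(motion, outliers, run, masks,
                               strategy = c("acompcor", "gsr"),
                               n_components = 5L) {
  strategy <- match.arg(strategy)
  mp <- unclass(motion)
  n_t <- nrow(mp)
  deriv <- rbind(0, diff(mp))
  scrub <- scrub_regressors(outliers)
  cols <- cbind(mp, deriv, scrub)
  labels <- c(colnames(mp), paste0("d_", colnames(mp)), colnames(scrub))
  sources <- c(rep("motion", 6), rep("motion_derivative", 6),
               rep("scrub", ncol(scrub)))
  if (strategy == "acompcor") {
    wm <- acompcor(run, masks$wm, n_components)
    csf <- acompcor(run, masks$csf, n_components)
    cols <- cbind(cols, wm, csf)
    labels <- c(labels, paste0("wm_", colnames(wm)),
                paste0("csf_", colnames(csf)))
    sources <- c(sources, rep("compcor_wm", ncol(wm)),
                 rep("compcor_csf", ncol(csf)))
  } else {
    Y <- .run_matrix(run)
    gs <- rowMeans(Y[, as.vector(masks$brain), drop = FALSE])
    wm_mean <- rowMeans(Y[, as.vector(masks$wm), drop = FALSE])
    csf_mean <- rowMeans(Y[, as.vector(masks$csf), drop = FALSE])
    cols <- cbind(cols, gs, wm_mean, csf_mean)
    labels <- c(labels, "global_signal", "wm_mean", "csf_mean")
    sources <- c(sources, "global_signal", "wm_mean", "csf_mean")
  }
  colnames(cols) <- labels
  structure(list(matrix = cols, labels = labels, sources = sources,
                 strategy = strategy),
            class = "confound_model")
}

#' Export a confound model as TSV
#' @param model A `confound_model`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_confounds <- function(model, path) {
  df <- as.data.frame(model$matrix)
  names(df) <- model$labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
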