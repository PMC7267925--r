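# Temporal denoising chain, applied in the stated order: confound regression
# -> linear detrend -> hyperbolic-tangent despiking -> band-pass (ideal
# frequency-domain filter). Spatial Gaussian smoothing is a separate op,
# applied to the BOLD input before connectivity but never before aCompCor
# extraction.

#' Denoising parameters
#'
#' @param band_low_hz,band_high_hz Band-pass edges in Hz (defaults 0.01 and
#'   0.1); must satisfy `0 < low < high < 1/(2 TR)` for the run they are
#'   applied to.
#' @param despike_k Squash scale of the tanh despiker in robust-SD units
#'   (default 3).
#' @param smoothing_fwhm_mm Gaussian smoothing FWHM in mm (default 6; 0
#'   disables smoothing).
#' @return A `denoise_params` list.
#' @export
denoise_params <- function(band_low_hz = 0.01, band_high_hz = 0.1,
                           despike_k = 3, smoothing_fwhm_mm = 6) {
  stopifnot(band_low_hz > 0, band_high_hz > band_low_hz, despike_k > 0,
            smoothing_fwhm_mm >= 0)
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 despike_k = despike_k,
                 smoothing_fwhm_mm = smoothing_fwhm_mm),
            class = "denoise_params")
}

.matrix_to_run <- function(Y, run) {
  d <- dim(run$data)
  run$data <- array(t(Y), dim = d)
  run
}

#' Regress confounds out of a run
#'
#' Per-voxel ordinary least squares on the confound design (augmented with an
#' intercept); returns the residual run. Rank-deficient designs have the
#' offending columns dropped with a warning naming their labels.
#'
#' @param run A [bold_run()].
#' @param model A `confound_model` from [assemble_confounds()], or a plain
#'   t x k matrix.
#' @return The residual [bold_run()].
#' @export
regress_confounds <- function(run, model) {
  M <- if (inherits(model, "confound_model")) model$matrix else as.matrix(model)
  labels <- colnames(M)
  if (is.null(labels)) labels <- paste0("c", seq_len(ncol(M)))
  n_t <- dim(run$data)[4]
  if (nrow(M) != n_t)
    stop("confound rows (", nrow(M), ") do not match run frames (", n_t, ")")
  X <- cbind(intercept = 1, M)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- setdiff(seq_len(ncol(X)), keep)
    warning("dropping ", length(dropped), " rank-deficient confound column(s): ",
            paste(colnames(X)[dropped], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    qrx <- qr(X)
  }
  Y <- .run_matrix(run)
  resid <- Y - X %*% qr.coef(qrx, Y)
  .matrix_to_run(resid, run)
}

#' Remove per-voxel linear trends
#'
#' @param run A [bold_run()] with t >= 3.
#' @return The detrended [bold_run()] (per-voxel OLS line removed).
#' @export
detrend_linear <- function(run) {
  n_t <- dim(run$data)[4]
  if (n_t < 3L) stop("need t >= 3 to detrend")
  X <- cbind(1, seq_len(n_t))
  Y <- .run_matrix(run)
  .matrix_to_run(Y - X %*% qr.coef(qr(X), Y), run)
}

#' Despike with a hyperbolic-tangent squashing function
#'
#' Per voxel, with center `c = median` and scale `a = k * 1.4826 * MAD`,
#' maps `x` to `c + a * tanh((x - c)/a)`: small excursions pass through
#' nearly unchanged while spikes are squashed to within `a` of the center.
#' Voxels with zero MAD are returned unchanged.
#'
#' @param run A [bold_run()].
#' @param k Squash scale in robust-SD units (default 3).
#' @return The despiked [bold_run()].
#' @export
despike_tanh <- function(run, k = 3) {
  stopifnot(k > 0)
  Y <- .run_matrix(run)
  ctr <- apply(Y, 2, stats::median)
  scl <- k * 1.4826 * apply(Y, 2, stats::mad, constant = 1)
  ok <- scl > 0
  Yc <- sweep(Y[, ok, drop = FALSE], 2, ctr[ok])
  Ys <- sweep(Yc, 2, scl[ok], "/")
  Y[, ok] <- sweep(sweep(tanh(Ys), 2, scl[ok], "*"), 2, ctr[ok], "+")
  .matrix_to_run(Y, run)
}

#' Ideal band-pass filter
#'
#' Zero-phase frequency-domain filter: per voxel, Fourier bins with
#' frequency inside `[band_low_hz, band_high_hz]` (inclusive) are retained
#' and all others — including DC — are zeroed.
#'
#' @param run A [bold_run()].
#' @param params A [denoise_params()] (or a list with the band fields).
#' @param tr_seconds Repetition time; defaults to the run's.
#' @return The filtered [bold_run()] (zero-mean by construction).
#' @export
bandpass <- function(run, params = denoise_params(),
                     tr_seconds = run$tr_seconds) {
  n_t <- dim(run$data)[4]
  nyq <- 1 / (2 * tr_seconds)
  if (params$band_high_hz >= nyq)
    stop("band_high_hz (", params$band_high_hz, ") must be < Nyquist (",
         nyq, " Hz) for TR = ", tr_seconds, " s")
  freq <- (seq_len(n_t) - 1) / (n_t * tr_seconds)
  freq <- pmin(freq, 1 / tr_seconds - freq)    # mirrored (negative) bins
  keep <- freq >= params$band_low_hz & freq <= params$band_high_hz
  if (!any(keep))
    stop("no Fourier bins inside [", params$band_low_hz, ", ",
         params$band_high_hz, "] Hz for t = ", n_t, ", TR = ", tr_seconds)
  Y <- .run_matrix(run)
  Yf <- stats::mvfft(Y)
  Yf[!keep, ] <- 0
  .matrix_to_run(Re(stats::mvfft(Yf, inverse = TRUE)) / n_t, run)
}

# 1-D Gaussian smoothing matrix with kernels renormalized inside the grid
.gauss_smooth_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(5 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1, i - r):min(n, i + r)
    w <- k[j - i + r + 1]
    S[i, j] <- w / sum(w)
  }
  S
}

#' Spatial Gaussian smoothing
#'
#' Separable per-volume Gaussian with `sigma = fwhm / (2 sqrt(2 ln 2))` per
#' axis; near the grid boundary the truncated kernel is renormalized so
#' constant volumes are preserved exactly.
#'
#' @param run A [bold_run()].
#' @param fwhm_mm Full width at half maximum in mm (0 = identity).
#' @param voxel_size_mm Voxel size per axis (scalar or length 3); defaults
#'   to the affine's column norms.
#' @return The smoothed [bold_run()].
#' @export
smooth_gaussian <- function(run, fwhm_mm = 6, voxel_size_mm = NULL) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(run)
  if (is.null(voxel_size_mm))
    voxel_size_mm <- sqrt(colSums(run$affine[1:3, 1:3]^2))
  voxel_size_mm <- rep_len(voxel_size_mm, 3)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  d <- dim(run$data)
  S <- lapply(1:3, function(a) .gauss_smooth_matrix(d[a], sigma[a]))
  # one matrix product per axis for the whole 4-D array
  v <- array(S[[1]] %*% matrix(run$data, d[1]), dim = d)
  v <- aperm(array(S[[2]] %*% matrix(aperm(v, c(2, 1, 3, 4)), d[2]),
                   dim = d[c(2, 1, 3, 4)]), c(2, 1, 3, 4))
  v <- aperm(array(S[[3]] %*% matrix(aperm(v, c(3, 1, 2, 4)), d[3]),
                   dim = d[c(3, 1, 2, 4)]), c(2, 3, 1, 4))
  run$data <- v
  run
}

#' Run the full temporal denoising chain
#'
#' Exact stage order: confound regression, linear detrend, tanh despiking,
#' band-pass. Smoothing is not part of this chain — apply
#' [smooth_gaussian()] to the BOLD input beforehand (and never before
#' [acompcor()] extraction).
#'
#' @param run A [bold_run()] (smoothed, if smoothing is wanted).
#' @param model A `confound_model`.
#' @param params A [denoise_params()].
#' @return The denoised [bold_run()]; stage parameters are recorded in the
#'   `chain_log` attribute.
#' @export
run_denoise_chain <- function(run, model, params = denoise_params()) {
  out <- regress_confounds(run, model)
  out <- detrend_linear(out)
  out <- despike_tanh(out, k = params$despike_k)
  out <- bandpass(out, params)
  attr(out, "chain_log") <- list(
    stages = c("regress_confounds", "detrend_linear", "despike_tanh",
               "bandpass"),
    n_confounds = if (inherits(model, "confound_model"))
      ncol(model$matrix) else ncol(as.matrix(model)),
    despike_k = params$despike_k,
    band = c(params$band_low_hz, params$band_high_hz))
  out
}
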