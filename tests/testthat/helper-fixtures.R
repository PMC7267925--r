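# Shared fixtures. Cohorts are generated in code (no stored binaries) and
# cached per session so several test files can reuse the same small worlds.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small default-parameter cohort used across modules
tiny_cohort <- function() cached("tiny", generate_cohort(
  synth_config(grid_shape = c(14, 14, 10), n_timepoints = 80,
               n_subjects = 8, rng_seed = 421)))

# build a bold_run from a t x V matrix and a grid shape
run_from_matrix <- function(Y, shape, tr = 2, affine = NULL) {
  if (is.null(affine)) affine <- diag(c(3, 3, 3, 1))
  bold_run(array(t(Y), dim = c(shape, nrow(Y))), tr, affine, "fixture")
}

# full-grid logical mask
full_mask <- function(shape) array(TRUE, dim = shape)

# connectivity map from a vector of in-mask values
map_from_values <- function(vals, mask, kind = "seed_fc_z",
                            affine = diag(c(3, 3, 3, 1)), id = "fixture") {
  arr <- array(NA_real_, dim = dim(mask))
  arr[mask] <- vals
  connectivity_map(arr, mask, kind, affine, id)
}

# small ellipsoid mask for group/prediction fixtures
ellipsoid_mask <- function(shape) {
  ct <- (shape - 1) / 2
  idx <- arrayInd(seq_len(prod(shape)), shape) - 1
  r <- ((idx[, 1] - ct[1]) / (ct[1] + 0.5))^2 +
    ((idx[, 2] - ct[2]) / (ct[2] + 0.5))^2 +
    ((idx[, 3] - ct[3]) / (ct[3] + 0.5))^2
  array(r <= 1, dim = shape)
}

# smoothed gaussian-noise subject maps: the null world for group inference
# (zero-mean by construction; spatially correlated like real stat maps)
null_subject_maps <- function(n_subjects, shape, fwhm = 6, seed = 1) {
  set.seed(seed)
  mask <- ellipsoid_mask(shape)
  lapply(seq_len(n_subjects), function(s) {
    arr <- array(stats::rnorm(prod(shape)), dim = c(shape, 1))
    run <- bold_run(array(rep(arr, 2), dim = c(shape, 2)), 2,
                    diag(c(3, 3, 3, 1)), sprintf("sub-%02d", s))
    sm <- smooth_gaussian(run, fwhm)$data[, , , 1]
    map_from_values(sm[mask], mask, "seed_fc_z")
  })
}

flood_fill_oracle <- function(binary, connectivity) {
  # naive recursive flood fill, independent of the package's labeling
  dims <- dim(binary)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0 &
               rowSums(abs(offs)) <= switch(as.character(connectivity),
                                            "6" = 1, "18" = 2, "26" = 3), ]
  lab <- array(0L, dims)
  cur <- 0L
  for (s in which(binary)) {
    if (lab[s] > 0) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      if (lab[v] > 0) next
      lab[v] <- cur
      cc <- arrayInd(v, dims)
      for (k in seq_len(nrow(offs))) {
        p <- cc + as.integer(offs[k, ])
        if (all(p >= 1) && all(p <= dims)) {
          li <- p[1] + (p[2] - 1) * dims[1] + (p[3] - 1) * dims[1] * dims[2]
          if (binary[li] && lab[li] == 0) stack <- c(stack, li)
        }
      }
    }
  }
  lab
}

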