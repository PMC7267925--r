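# Shared geometric data model: BOLD runs, mask sets, motion traces and
# connectivity maps. Internal indexing is 0-based voxel space; all reported
# coordinates are world mm via the affine.

#' Construct a BOLD run
#'
#' @param data 4-D numeric array (x, y, z, t), arbitrary signal units.
#' @param tr_seconds Repetition time in seconds (positive).
#' @param affine 4x4 voxel-to-world transform (mm), must be invertible.
#' @param subject_id Subject identifier string.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, tr_seconds, affine, subject_id = "unknown") {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("BOLD data must be a 4-D array, got ", length(dim(data)), " dims")
  if (dim(data)[4] < 2L) stop("BOLD run needs t >= 2 timepoints")
  nbad <- sum(!is.finite(data))
  if (nbad > 0L) stop("BOLD data contains ", nbad, " non-finite values")
  stopifnot(is.numeric(tr_seconds), tr_seconds > 0)
  .check_affine(affine)
  structure(list(data = data, tr_seconds = tr_seconds, affine = affine,
                 subject_id = as.character(subject_id)),
            class = "bold_run")
}

.check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4, 4)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stop("affine is not invertible")
  invisible(affine)
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run %s: %dx%dx%d voxels, %d timepoints, TR = %gs>\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' Construct a mask set
#'
#' Brain, gray-matter, white-matter and CSF masks on a common grid. WM and
#' CSF must be disjoint and every tissue mask a subset of the brain mask.
#'
#' @param brain,gm,wm,csf 3-D logical arrays of identical shape.
#' @param affine 4x4 voxel-to-world transform shared with the runs.
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(brain, gm, wm, csf, affine) {
  masks <- list(brain = brain, gm = gm, wm = wm, csf = csf)
  shp <- dim(brain)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.array(m) || length(dim(m)) != 3L || !identical(dim(m), shp))
      stop("mask '", nm, "' must be a 3-D array matching the brain mask shape")
    if (!is.logical(m)) stop("mask '", nm, "' must be logical")
  }
  if (sum(brain) < 2L) stop("brain mask must contain at least 2 voxels")
  if (any(wm & csf)) stop("WM and CSF masks overlap")
  for (nm in c("gm", "wm", "csf"))
    if (any(masks[[nm]] & !brain)) stop("mask '", nm, "' exceeds the brain mask")
  .check_affine(affine)
  structure(c(masks, list(affine = affine)), class = "mask_set")
}

#' Construct a motion trace
#'
#' @param params t x 6 numeric matrix: translations x, y, z in mm then
#'   rotations pitch, roll, yaw in radians (SPM column convention).
#' @return An object of class `motion_trace` (the validated matrix).
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("motion trace must have 6 columns")
  if (nrow(params) < 2L) stop("motion trace needs >= 2 timepoints")
  if (!all(is.finite(params))) stop("non-finite motion parameters")
  colnames(params) <- c("trans_x", "trans_y", "trans_z",
                        "rot_pitch", "rot_roll", "rot_yaw")
  structure(params, class = c("motion_trace", "matrix"))
}

.map_kinds <- c("gbc", "seed_fc_z", "t_stat", "weight")

#' Construct a connectivity map
#'
#' A per-subject or group 3-D statistic map restricted to the brain mask;
#' off-mask voxels carry `NA`.
#'
#' @param values 3-D numeric array; must be finite on the mask.
#' @param mask 3-D logical brain mask of the same shape.
#' @param kind One of `"gbc"`, `"seed_fc_z"`, `"t_stat"`, `"weight"`.
#' @param affine 4x4 voxel-to-world transform.
#' @param subject_id Subject identifier or `"group"`.
#' @return An object of class `connectivity_map`.
#' @export
connectivity_map <- function(values, mask, kind, affine, subject_id = "group") {
  if (!kind %in% .map_kinds)
    stop("kind must be one of: ", paste(.map_kinds, collapse = ", "))
  stopifnot(identical(dim(values), dim(mask)))
  onmask <- values[mask]
  if (kind == "t_stat") {
    # infinite t markers (zero residual variance) are permitted
    if (anyNA(onmask)) stop("NA values on the brain mask")
  } else if (!all(is.finite(onmask))) {
    stop("non-finite values on the brain mask")
  }
  values[!mask] <- NA_real_
  .check_affine(affine)
  structure(list(values = values, mask = mask, kind = kind, affine = affine,
                 subject_id = as.character(subject_id)),
            class = "connectivity_map")
}

#' Read a 4-D BOLD NIfTI file
#'
#' The repetition time is supplied by the caller (headers are unreliable);
#' a header TR differing by more than 1e-3 s triggers a warning only.
#'
#' @param path Path to a 4-D NIfTI-1 file.
#' @param tr_seconds Repetition time in seconds.
#' @param subject_id Subject identifier.
#' @return A [bold_run()].
#' @export
read_bold <- function(path, tr_seconds, subject_id = "unknown") {
  img <- read_nifti(path)
  if (length(dim(img$data)) != 4L)
    stop("expected a 4-D BOLD image, got ", length(dim(img$data)),
         "-D file: ", path)
  nbad <- sum(!is.finite(img$data))
  if (nbad > 0L)
    stop("BOLD file contains ", nbad, " non-finite voxels: ", path)
  if (is.finite(img$tr) && img$tr > 0 && abs(img$tr - tr_seconds) > 1e-3)
    warning("header TR (", img$tr, " s) differs from supplied TR (",
            tr_seconds, " s); using supplied value")
  bold_run(img$data, tr_seconds, img$affine, subject_id)
}

#' Convert a world coordinate to a voxel index
#'
#' Applies the inverse affine and rounds to the nearest 0-based voxel index;
#' half-way ties round toward +Inf per axis.
#'
#' @param affine 4x4 voxel-to-world transform.
#' @param point_mm Length-3 world coordinate in mm.
#' @param dim Optional grid shape; when given, out-of-grid points raise an
#'   error naming the offending axis.
#' @return Integer length-3 vector of 0-based voxel indices.
#' @export
world_to_voxel <- function(affine, point_mm, dim = NULL) {
  .check_affine(affine)
  stopifnot(length(point_mm) == 3L)
  v <- solve(affine, c(point_mm, 1))[1:3]
  idx <- as.integer(floor(v + 0.5))    # ties toward +Inf
  if (!is.null(dim)) {
    for (ax in 1:3) {
      if (idx[ax] < 0L || idx[ax] >= dim[ax])
        stop("point (", paste(point_mm, collapse = ", "),
             ") maps outside the grid on axis ", c("x", "y", "z")[ax],
             " (voxel index ", idx[ax], ", extent ", dim[ax], ")")
    }
  }
  idx
}

#' Convert 0-based voxel indices to world mm
#'
#' @param affine 4x4 voxel-to-world transform.
#' @param idx0 Length-3 0-based voxel index, or an n x 3 matrix of them.
#' @return World coordinates in mm (vector or n x 3 matrix).
#' @export
voxel_to_world <- function(affine, idx0) {
  if (is.matrix(idx0)) {
    out <- cbind(idx0, 1) %*% t(affine)
    return(out[, 1:3, drop = FALSE])
  }
  (affine %*% c(idx0, 1))[1:3]
}

#' Write a connectivity map to NIfTI
#'
#' Off-mask (`NA`) voxels are written as 0; the brain mask is stored
#' alongside as `<stem>_mask.nii[.gz]` and the map kind is recorded in the
#' NIfTI description field.
#'
#' @param map A [connectivity_map()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "connectivity_map"))
  vals <- map$values
  vals[is.na(vals)] <- 0
  write_nifti(vals, map$affine, path, datatype = "float32",
              descrip = paste0("placeboconn kind=", map$kind))
  mask_path <- sub("(\\.nii)(\\.gz)?$", "_mask\\1\\2", path)
  if (identical(mask_path, path)) mask_path <- paste0(path, "_mask.nii")
  write_nifti(array(as.double(map$mask), dim = dim(map$mask)), map$affine,
              mask_path, datatype = "uint8")
  invisible(path)
}

#' Read a connectivity map written by [write_map()]
#'
#' @param path Path to the map NIfTI; the sibling `_mask` file must exist.
#' @param subject_id Subject identifier to attach.
#' @return A [connectivity_map()].
#' @export
read_map <- function(path, subject_id = "group") {
  img <- read_nifti(path)
  mask_path <- sub("(\\.nii)(\\.gz)?$", "_mask\\1\\2", path)
  if (!file.exists(mask_path)) stop("mask sibling not found: ", mask_path)
  mask <- read_nifti(mask_path)$data > 0.5
  kind <- sub("^placeboconn kind=", "", img$descrip)
  if (!kind %in% .map_kinds) kind <- "t_stat"
  connectivity_map(img$data, mask, kind, img$affine, subject_id)
}

#' Write a motion trace as 6-column whitespace-delimited text
#' @param motion A [motion_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(format(unclass(motion), digits = 10), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column motion parameter text file
#' @param path Input path.
#' @return A [motion_trace()].
#' @export
read_motion <- function(path) {
  motion_trace(as.matrix(utils::read.table(path, header = FALSE)))
}

#' Read / write the subjects table
#'
#' TSV with columns `subject_id`, `age`, `sex` (0 male / 1 female),
#' `hdrs_baseline`, `hdrs_post` and optionally `mean_fd`,
#' `hdrs_pct_change`.
#'
#' @param path TSV path.
#' @return `read_subjects`: a data.frame with `hdrs_pct_change` derived when
#'   absent.
#' @export
read_subjects <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "hdrs_baseline", "hdrs_post")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("subjects table missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(df$hdrs_pct_change))
    df$hdrs_pct_change <- pct_change(df$hdrs_baseline, df$hdrs_post)
  df
}

#' @rdname read_subjects
#' @param subjects Subjects data.frame.
#' @export
write_subjects <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a cluster table as TSV
#'
#' Columns: `cluster_id`, `n_voxels`, `peak_x_mm`, `peak_y_mm`, `peak_z_mm`,
#' `peak_value` (plus any extra columns present, e.g. `p_corr`, `sign`).
#'
#' @param clusters Cluster table data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
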