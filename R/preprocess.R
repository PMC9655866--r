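#' Truncate CT values to the pelvic window
#'
#' Clamps every voxel to \[-600, 1000\] HU. Below -600 HU is essentially air
#' for the pelvis and above 1000 HU adds no soft-tissue/bone contrast, so the
#' window preserves the information the model uses while bounding the
#' normalization range.
#'
#' @param ct A [volume_grid] (or 3D array) of CT values in HU.
#' @return Same type as input, values clamped to \[-600, 1000\].
#' @export
truncate_hu <- function(ct) {
  v <- as_values(ct)
  stop_if_not_finite(v, "CT")
  out <- pmin(pmax(v, -600), 1000)
  dim(out) <- dim(v)
  if (is_volume_grid(ct)) volume_grid(out, ct$spacing, ct$origin) else out
}

#' Label-encode structure masks as image channels
#'
#' Each structure becomes its own channel in which foreground voxels carry
#' the structure's label value (body -400, femur-head-R -200, femur-head-L
#' 200, rectum 600, bladder 800, PTV 1000) and background voxels -600, so
#' that mask channels live on the same intensity scale as truncated CT.
#'
#' @param structures A [structure_set].
#' @param roles Which structures to encode; defaults to all present.
#' @return Named list of 3D arrays of label values.
#' @export
encode_structure_channels <- function(structures, roles = names(structures$masks)) {
  labels <- structure_labels()
  missing <- setdiff(roles, names(structures$masks))
  if (length(missing))
    stop("missing required structure mask: ", paste(missing, collapse = ", "))
  out <- lapply(roles, function(role) {
    if (!role %in% names(labels)) stop("unknown structure role: ", role)
    m <- structures$masks[[role]]
    arr <- ifelse(m == 1, labels[[role]], labels[["background"]])
    array(arr, dim(m))
  })
  names(out) <- roles
  out
}

#' Resample a volume to isotropic spacing
#'
#' Resamples to `target_spacing_mm` on every axis, preserving the physical
#' extent to within one voxel. CT and dose use trilinear interpolation
#' (`mode = "linear"`); masks use nearest-neighbour (`mode = "nearest"`) so
#' they stay strictly binary. Samples are taken at voxel centres
#' (half-pixel convention).
#'
#' @param grid A [volume_grid].
#' @param target_spacing_mm Positive scalar, mm (default 3.5).
#' @param mode `"linear"` or `"nearest"`.
#' @return A [volume_grid] with spacing `rep(target_spacing_mm, 3)`.
#' @export
resample_isotropic <- function(grid, target_spacing_mm = 3.5,
                               mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (!is.finite(target_spacing_mm) || target_spacing_mm <= 0)
    stop("target spacing must be > 0")
  d <- dim(grid$values)
  out_dim <- pmax(1L, as.integer(round(d * grid$spacing / target_spacing_mm)))
  if (all(out_dim == d) && all(abs(grid$spacing - target_spacing_mm) < 1e-12))
    return(grid)
  vals <- cpp_resize3d(grid$values, out_dim, if (mode == "linear") 0L else 1L)
  volume_grid(vals, spacing = rep(target_spacing_mm, 3L), origin = grid$origin)
}

#' Crop or pad a volume about a centre
#'
#' Extracts a window of exactly `size` voxels per axis centred on `center`
#' (1-based voxel coordinates; defaults to the volume centre, and callers
#' typically pass the body-mask centroid). Out-of-bounds regions are padded
#' with `background` (-600 for CT/label channels, 0 for dose).
#'
#' @param grid A [volume_grid] or 3D array.
#' @param size Integer target extent per axis (scalar or length 3).
#' @param center Centre voxel (1-based, length 3); default volume centre.
#' @param background Pad value.
#' @return Same type as input with dimensions `size`.
#' @export
crop_or_pad_center <- function(grid, size, center = NULL, background = -600) {
  v <- as_values(grid)
  d <- dim(v)
  if (any(d < 1L)) stop("grid is empty")
  size <- rep_len(as.integer(size), 3L)
  if (any(size <= 0L)) stop("size must be > 0 per axis")
  if (is.null(center)) center <- (d + 1) / 2
  center <- rep_len(as.numeric(center), 3L)
  # half-open window [start, start + size) in 0-based indices
  start0 <- as.integer(round(center - 1 - size / 2 + 0.5))
  out <- array(background, size)
  src_lo <- pmax(start0, 0L)
  src_hi <- pmin(start0 + size, d)
  if (all(src_hi > src_lo)) {
    dst_lo <- src_lo - start0
    out[(dst_lo[1] + 1):(dst_lo[1] + src_hi[1] - src_lo[1]),
        (dst_lo[2] + 1):(dst_lo[2] + src_hi[2] - src_lo[2]),
        (dst_lo[3] + 1):(dst_lo[3] + src_hi[3] - src_lo[3])] <-
      v[(src_lo[1] + 1):src_hi[1],
        (src_lo[2] + 1):src_hi[2],
        (src_lo[3] + 1):src_hi[3]]
  }
  if (is_volume_grid(grid)) {
    volume_grid(out, grid$spacing, grid$origin + start0 * grid$spacing)
  } else out
}

#' Centroid of a mask in 1-based voxel coordinates
#' @param mask 3D binary array.
#' @return Numeric length 3.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask == 1)
  if (!length(idx)) stop("mask is empty")
  ai <- arrayInd(idx, dim(mask))
  colMeans(ai)
}

#' Affine normalization onto \[-1, 1\] and its inverse
#'
#' Maps a declared value range linearly onto \[-1, 1\] (the generator ends in
#' a hyperbolic tangent, so every channel must live there). CT and label
#' channels use \[-600, 1000\]; dose uses \[0, 1.2 x prescription\].
#'
#' @param values Numeric array.
#' @param value_range Length-2 numeric, the declared (min, max).
#' @return Array of the same shape.
#' @export
normalize_affine <- function(values, value_range) {
  r <- as.numeric(value_range)
  if (length(r) != 2L || !all(is.finite(r)) || r[2] <= r[1])
    stop("degenerate value range")
  2 * (values - r[1]) / (r[2] - r[1]) - 1
}

#' @rdname normalize_affine
#' @export
denormalize_affine <- function(values, value_range) {
  r <- as.numeric(value_range)
  if (length(r) != 2L || !all(is.finite(r)) || r[2] <= r[1])
    stop("degenerate value range")
  (values + 1) / 2 * (r[2] - r[1]) + r[1]
}

hu_range <- function() as.numeric(fd_config()$normalization$hu_range)

dose_range <- function(prescription) {
  c(0, fd_config()$normalization$dose_range_rx_mult * prescription)
}

scheme_channel_names <- function(scheme, with_dose = TRUE) {
  ch <- switch(scheme,
    A = c("dose", "ct", "ptv", "body", "femur_head_r", "femur_head_l",
          "rectum", "bladder"),
    B = c("dose", "ct", "ptv"),
    C = c("dose", "ct"),
    stop("scheme must be one of 'A', 'B', 'C'")
  )
  if (!with_dose) ch <- setdiff(ch, "dose")
  ch
}

#' Assemble a normalized multichannel training sample
#'
#' Stacks the input channels for one of the three dataset schemes:
#' scheme A = (dose, CT, PTV, body, femur-R, femur-L, rectum, bladder),
#' scheme B = (dose, CT, PTV), scheme C = (dose, CT). The dose channel is
#' present only when `dose` is supplied (training); at inference it is
#' omitted. All channels are normalized onto \[-1, 1\].
#'
#' @param ct [volume_grid] of truncated CT (HU).
#' @param structures [structure_set] on the same geometry.
#' @param dose Optional [dose_distribution] on the same geometry.
#' @param scheme `"A"`, `"B"` or `"C"`.
#' @param prescription Prescription in cGy; required when `dose` is NULL
#'   only for later denormalization bookkeeping, otherwise taken from `dose`.
#' @return A `channel_stack`: 4D array (x, y, z, channel) with attributes
#'   `scheme`, `channels`, `spacing`, `prescription`.
#' @export
assemble_channel_stack <- function(ct, structures, dose = NULL,
                                   scheme = c("A", "B", "C"),
                                   prescription = NULL) {
  scheme <- match.arg(scheme)
  d <- dim(ct$values)
  if (!all(dim(structures$masks[[1]]) == d))
    stop("geometry mismatch between CT and structures")
  if (!is.null(dose)) {
    if (!all(dim(dose$grid$values) == d))
      stop("geometry mismatch between CT and dose")
    prescription <- dose$prescription
  }
  if (is.null(prescription)) stop("prescription required")
  want <- scheme_channel_names(scheme, with_dose = !is.null(dose))
  roles <- setdiff(want, c("dose", "ct"))
  enc <- if (length(roles)) encode_structure_channels(structures, roles) else list()
  hur <- hu_range()
  chans <- lapply(want, function(nm) {
    switch(nm,
      dose = normalize_affine(dose$grid$values, dose_range(prescription)),
      ct = normalize_affine(truncate_hu(ct)$values, hur),
      normalize_affine(enc[[nm]], hur)
    )
  })
  stack <- array(unlist(chans, use.names = FALSE), c(d, length(chans)))
  structure(stack,
            scheme = scheme, channels = want, spacing = structures$spacing,
            prescription = prescription, class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("<channel_stack> scheme %s, %d channels (%s), %s voxels\n",
              attr(x, "scheme"), dim(x)[4],
              paste(attr(x, "channels"), collapse = ", "),
              paste(dim(x)[1:3], collapse = "x")))
  invisible(x)
}

#' Convert stored dose grids via the RTDOSE scale-factor convention
#'
#' Treatment-planning exports store dose as an integer grid plus a dose-grid
#' scale factor (Gy per stored unit); voxel dose is the product of the two.
#' NIfTI dose volumes are taken to be in cGy already and pass through.
#'
#' @param x Path to a NIfTI dose file, or a numeric/integer array of stored
#'   values.
#' @param scale_gy Dose-grid scale factor in Gy per stored unit. Required
#'   when `x` is an integer grid.
#' @param prescription Prescription in cGy.
#' @return A [dose_distribution] in cGy.
#' @export
load_rtdose_scaled <- function(x, scale_gy = NULL, prescription) {
  if (is.character(x)) {
    grid <- read_volume(x)
    vals <- grid$values
    if (!is.null(scale_gy)) vals <- vals * scale_gy * 100
    return(dose_distribution(volume_grid(vals, grid$spacing, grid$origin),
                             prescription))
  }
  if (is.integer(x) && is.null(scale_gy))
    stop("missing dose grid scale factor for integer-stored dose")
  vals <- as.numeric(x)
  if (!is.null(scale_gy)) vals <- vals * scale_gy * 100  # Gy -> cGy
  dim(vals) <- dim(x)
  dose_distribution(volume_grid(vals), prescription)
}
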