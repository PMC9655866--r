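#' 3D scalar volume on a regular grid
#'
#' A `volume_grid` carries a 3D array of voxel values together with the voxel
#' spacing (mm per axis) and the physical origin (mm). It is the common
#' container for CT images (HU), dose maps (cGy) and binary masks. The array
#' axis order is (transverse slice, row, column).
#'
#' @param values 3D numeric array.
#' @param spacing Numeric length-3 (or scalar, recycled), mm per axis; all > 0.
#' @param origin Numeric length-3, mm offset of the first voxel. Default 0.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all three spacing components must be > 0")
  structure(
    list(values = values, spacing = spacing, origin = rep_len(as.numeric(origin), 3L)),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf(
    "<volume_grid> %s voxels @ %s mm, range [%.6g, %.6g]\n",
    paste(dim(x$values), collapse = "x"),
    paste(format(x$spacing, digits = 4), collapse = "x"),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

is_volume_grid <- function(x) inherits(x, "volume_grid")

as_values <- function(x) if (is_volume_grid(x)) x$values else x

stop_if_not_finite <- function(values, what = "volume") {
  bad <- which(!is.finite(values))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(values))
    stop(sprintf(
      "%s contains a non-finite voxel at index (%d, %d, %d)",
      what, idx[1], idx[2], idx[3]
    ))
  }
  invisible(TRUE)
}

#' Named binary structure masks on a shared grid
#'
#' Holds the delineation masks used throughout the pipeline, keyed by role:
#' `body`, `ptv`, `bladder`, `rectum`, `femur_head_l`, `femur_head_r`.
#' Masks must be strictly 0/1, share one shape, and the PTV must lie inside
#' the body.
#'
#' @param masks Named list of 3D arrays (logical or 0/1 numeric).
#' @param spacing Voxel spacing in mm.
#' @param origin Physical origin in mm.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("masks must be a named list")
  dims <- lapply(masks, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L)
    stop("all masks must share one shape")
  masks <- lapply(masks, function(m) {
    v <- as.numeric(m)
    if (!all(v %in% c(0, 1))) stop("masks must be strictly {0,1}")
    array(v, dim(m))
  })
  if (all(c("ptv", "body") %in% names(masks)) &&
      any(masks$ptv == 1 & masks$body == 0))
    stop("PTV mask must be contained in the body mask")
  structure(
    list(masks = masks, spacing = rep_len(as.numeric(spacing), 3L),
         origin = rep_len(as.numeric(origin), 3L)),
    class = "structure_set"
  )
}

#' @export
print.structure_set <- function(x, ...) {
  vox <- vapply(x$masks, sum, numeric(1))
  cat("<structure_set>", paste(dim(x$masks[[1]]), collapse = "x"), "voxels\n")
  for (nm in names(x$masks)) cat(sprintf("  %-14s %d voxels\n", nm, as.integer(vox[[nm]])))
  invisible(x)
}

#' Dose distribution with its prescription
#'
#' @param grid A [volume_grid] of dose values in cGy (all >= 0).
#' @param prescription Prescription dose in cGy (> 0).
#' @return An object of class `dose_distribution`.
#' @export
dose_distribution <- function(grid, prescription) {
  if (!is_volume_grid(grid)) grid <- volume_grid(grid)
  if (any(grid$values < 0)) stop("dose must be >= 0 everywhere")
  if (!is.finite(prescription) || prescription <= 0)
    stop("prescription must be > 0")
  structure(list(grid = grid, prescription = prescription),
            class = "dose_distribution")
}

#' @export
print.dose_distribution <- function(x, ...) {
  cat(sprintf("<dose_distribution> Rx %.0f cGy\n", x$prescription))
  print(x$grid)
  invisible(x)
}

#' Read / write a volume as NIfTI
#'
#' NIfTI (.nii / .nii.gz) is the interchange format; voxel spacing is carried
#' in the pixdim fields.
#'
#' @param file Path to a NIfTI file.
#' @return `read_volume()` returns a [volume_grid].
#' @export
read_volume <- function(file) {
  img <- RNifti::readNifti(file)
  sp <- attr(img, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(img)
  volume_grid(array(as.numeric(img), dim(img)[1:3]), spacing = sp[1:3])
}

#' @rdname read_volume
#' @param grid A [volume_grid] to write.
#' @export
write_volume <- function(grid, file) {
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read / write a case manifest
#'
#' A case is stored as NIfTI volumes plus a JSON manifest mapping structure
#' roles to files and recording the prescription in cGy.
#'
#' @param dir Directory holding the case.
#' @param name Case identifier (file stem of the manifest).
#' @return `read_case()` returns a list with elements `ct` ([volume_grid]),
#'   `structures` ([structure_set]) and, when present, `dose`
#'   ([dose_distribution]).
#' @export
read_case <- function(dir, name = "case") {
  man <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                             simplifyVector = TRUE)
  ct <- read_volume(file.path(dir, man$ct))
  masks <- lapply(man$structures, function(f) {
    v <- read_volume(file.path(dir, f))$values
    (v > 0.5) * 1
  })
  structures <- structure_set(masks, spacing = ct$spacing, origin = ct$origin)
  out <- list(ct = ct, structures = structures)
  if (!is.null(man$dose)) {
    dg <- read_volume(file.path(dir, man$dose))
    out$dose <- dose_distribution(dg, man$prescription_cgy)
  }
  out
}

#' @rdname read_case
#' @param case List with `ct`, `structures` and optionally `dose`.
#' @export
write_case <- function(case, dir, name = "case") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list(ct = paste0(name, "_ct.nii.gz"), structures = list())
  write_volume(case$ct, file.path(dir, man$ct))
  for (role in names(case$structures$masks)) {
    f <- sprintf("%s_%s.nii.gz", name, role)
    write_volume(volume_grid(case$structures$masks[[role]],
                             spacing = case$ct$spacing), file.path(dir, f))
    man$structures[[role]] <- f
  }
  if (!is.null(case$dose)) {
    man$dose <- paste0(name, "_dose.nii.gz")
    man$prescription_cgy <- case$dose$prescription
    write_volume(case$dose$grid, file.path(dir, man$dose))
  }
  jsonlite::write_json(man, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
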