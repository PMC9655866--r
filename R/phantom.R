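#' Specification of a synthetic pelvic phantom
#'
#' Describes the geometry and intensity statistics of a seeded synthetic
#' pelvis: a soft-tissue body ellipsoid containing a central PTV, an
#' anterior bladder, a posterior rectum and two lateral bone-density femoral
#' heads, plus an analytic reference dose field that covers the PTV at the
#' prescription and falls off exponentially with distance from the PTV
#' surface. Default geometry scales with the grid's physical extent so the
#' same anatomy fits 48^3 test grids and 128^3 full-size grids.
#'
#' @param shape Grid extent per axis (scalar or length 3), default 64.
#' @param spacing Voxel spacing in mm, default 3.5.
#' @param prescription Prescription dose in cGy, default 5400 (54 Gy).
#' @param falloff_mm Exponential dose falloff length-scale, default 25 mm.
#' @param hu Named list of HU levels: `soft` 30, `bone` 700, `air` -600,
#'   `bladder` 15, `rectum` 35.
#' @param noise_hu CT noise standard deviation in HU, default 20.
#' @param noise_dose_frac Dose noise sd as a fraction of prescription,
#'   default 0.005 (0.5 %).
#' @param seed Integer seed; the phantom is deterministic given the spec.
#' @param geometry Optional list overriding centres (mm, relative to the
#'   grid centre) and semi-axes (mm) per structure.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = 64, spacing = 3.5, prescription = 5400,
                         falloff_mm = 25,
                         hu = list(soft = 30, bone = 700, air = -600,
                                   bladder = 15, rectum = 35),
                         noise_hu = 20, noise_dose_frac = 0.005, seed = 1L,
                         geometry = NULL) {
  shape <- rep_len(as.integer(shape), 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (falloff_mm <= 0) stop("falloff scale must be > 0")
  extent <- shape * spacing
  sc <- min(extent) / 224          # reference anatomy designed at 224 mm
  if (is.null(geometry)) {
    geometry <- list(
      body = list(center = c(0, 0, 0), semi = c(0.47, 0.44, 0.46) * extent),
      ptv = list(center = c(0, 0, 0), semi = c(28, 30, 30) * sc),
      bladder = list(center = c(0, -58, 0) * sc, semi = rep(20 * sc, 3)),
      rectum = list(center = c(0, 52, 0) * sc, semi = rep(14 * sc, 3)),
      femur_head_l = list(center = c(0, 6, 68) * sc, semi = rep(18 * sc, 3)),
      femur_head_r = list(center = c(0, 6, -68) * sc, semi = rep(18 * sc, 3))
    )
  }
  if (any(vapply(geometry, function(g) any(g$semi <= 0), logical(1))))
    stop("all semi-axes must be > 0")
  structure(list(shape = shape, spacing = spacing, prescription = prescription,
                 falloff_mm = falloff_mm, hu = hu, noise_hu = noise_hu,
                 noise_dose_frac = noise_dose_frac, seed = as.integer(seed),
                 geometry = geometry),
            class = "phantom_spec")
}

# physical coordinates (mm, centred) of every voxel along one axis
axis_coords <- function(n, sp) (seq_len(n) - (n + 1) / 2) * sp

ellipsoid_mask <- function(shape, spacing, center, semi) {
  x1 <- axis_coords(shape[1], spacing[1]) - center[1]
  x2 <- axis_coords(shape[2], spacing[2]) - center[2]
  x3 <- axis_coords(shape[3], spacing[3]) - center[3]
  r2 <- outer(outer((x1 / semi[1])^2, (x2 / semi[2])^2, `+`), (x3 / semi[3])^2, `+`)
  (r2 <= 1) * 1
}

#' Generate the synthetic CT and structure masks
#'
#' Deterministic given the spec (including its seed): air background at
#' -600 HU, soft-tissue body with additive Gaussian noise, organ-specific
#' mean HU for bladder and rectum, bone-level femoral heads. Masks are the
#' analytic ellipsoid indicators and therefore consistent with the HU
#' painting.
#'
#' @param spec A [phantom_spec()].
#' @return List with `ct` ([volume_grid]) and `structures` ([structure_set]).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  g <- spec$geometry
  masks <- lapply(g, function(p)
    ellipsoid_mask(spec$shape, spec$spacing, p$center, p$semi))
  body <- masks$body
  for (nm in setdiff(names(masks), "body"))
    if (any(masks[[nm]] == 1 & body == 0))
      stop(sprintf("structure '%s' extends beyond the body ellipsoid", nm))
  ct <- with_seed(spec$seed, {
    v <- array(spec$hu$air, spec$shape)
    noise <- array(rnorm(prod(spec$shape), sd = spec$noise_hu), spec$shape)
    inside <- body == 1
    v[inside] <- spec$hu$soft + noise[inside]
    v[masks$bladder == 1] <- spec$hu$bladder + noise[masks$bladder == 1]
    v[masks$rectum == 1] <- spec$hu$rectum + noise[masks$rectum == 1]
    v[masks$femur_head_l == 1] <- spec$hu$bone + noise[masks$femur_head_l == 1]
    v[masks$femur_head_r == 1] <- spec$hu$bone + noise[masks$femur_head_r == 1]
    v
  })
  list(
    ct = volume_grid(ct, spacing = spec$spacing),
    structures = structure_set(masks, spacing = spec$spacing)
  )
}

#' Generate the analytic reference dose
#'
#' `dose(v) = Rx * exp(-d(v) / falloff)` where `d(v)` is the Euclidean
#' distance in mm from voxel `v` to the PTV (zero inside), plus seeded
#' Gaussian noise, clipped at zero. With zero noise the PTV DVH is a step at
#' the prescription and dose decreases monotonically with distance.
#'
#' @param structures A [structure_set] containing a nonempty `ptv` mask.
#' @param prescription Prescription in cGy.
#' @param falloff_mm Falloff length-scale in mm.
#' @param seed Seed for the dose noise.
#' @param noise_frac Noise sd as a fraction of prescription (0 disables).
#' @return A [dose_distribution].
#' @export
generate_reference_dose <- function(structures, prescription = 5400,
                                    falloff_mm = 25, seed = 1L,
                                    noise_frac = 0.005) {
  ptv <- structures$masks$ptv
  if (is.null(ptv) || !any(ptv == 1)) stop("PTV mask is empty")
  d <- cpp_edt3d(array(ptv == 1, dim(ptv)), structures$spacing)
  dose <- prescription * exp(-d / falloff_mm)
  if (noise_frac > 0) {
    dose <- dose + with_seed(seed + 211L,
      array(rnorm(length(dose), sd = noise_frac * prescription), dim(dose)))
  }
  dose <- pmax(dose, 0)
  dim(dose) <- dim(ptv)
  dose_distribution(volume_grid(dose, spacing = structures$spacing),
                    prescription)
}

#' Generate a complete phantom case (CT, structures, dose)
#'
#' @param spec A [phantom_spec()].
#' @return List with `ct`, `structures` and `dose`.
#' @export
generate_phantom_case <- function(spec = phantom_spec()) {
  ph <- generate_phantom(spec)
  ph$dose <- generate_reference_dose(ph$structures, spec$prescription,
                                     spec$falloff_mm, seed = spec$seed,
                                     noise_frac = spec$noise_dose_frac)
  ph
}

#' Generate a set of phantom cases with independent seeds
#'
#' @param n Number of cases.
#' @param spec Template [phantom_spec()]; case i uses seed `spec$seed + i`.
#' @return List of phantom cases.
#' @export
generate_phantom_set <- function(n, spec = phantom_spec()) {
  lapply(seq_len(n), function(i) {
    s <- spec
    s$seed <- spec$seed + i
    generate_phantom_case(s)
  })
}
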