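#' Mean absolute dose error relative to prescription
#'
#' Mean over masked voxels of |clinical - predicted|, expressed as a
#' percentage of the prescription dose.
#'
#' @param gt,pred [dose_distribution]s (or arrays in cGy) on one geometry.
#' @param mask 3D binary array selecting the voxels to evaluate.
#' @param prescription Prescription in cGy (defaults to `gt`'s).
#' @return MAE in percent of prescription.
#' @export
mae_percent <- function(gt, pred, mask, prescription = NULL) {
  gv <- dose_values(gt); pv <- dose_values(pred)
  if (!identical(dim(gv), dim(pv))) stop("geometry mismatch")
  if (is.null(prescription)) prescription <- dose_rx(gt)
  sel <- mask == 1
  if (!any(sel)) stop("empty mask")
  100 * mean(abs(gv[sel] - pv[sel])) / prescription
}

dose_values <- function(x) {
  if (inherits(x, "dose_distribution")) x$grid$values else as_values(x)
}

dose_rx <- function(x) {
  if (inherits(x, "dose_distribution")) x$prescription
  else stop("prescription required when dose is a bare array")
}

#' Cumulative dose-volume histogram
#'
#' Fraction of a structure's volume receiving at least each dose level, on a
#' regular grid of bin edges from zero to just past the maximum dose.
#'
#' @param dose [dose_distribution] or array (cGy).
#' @param mask 3D binary array (nonempty).
#' @param bin_width Bin width in cGy (default 10).
#' @return A `dvh_curve` tibble with columns `dose` (cGy) and `volume_pct`.
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 10) {
  dv <- dose_values(dose)
  sel <- mask == 1
  if (!any(sel)) stop("empty mask")
  x <- dv[sel]
  edges <- seq(0, max(x) + bin_width, by = bin_width)
  vol <- vapply(edges, function(e) 100 * mean(x >= e), numeric(1))
  structure(tibble::tibble(dose = edges, volume_pct = vol),
            class = c("dvh_curve", "tbl_df", "tbl", "data.frame"))
}

#' Dose-volume queries Dp and Vd
#'
#' `Dp` is the minimum dose received by the hottest p% of the structure
#' (the largest dose d such that at least p% of the volume receives >= d;
#' rank `ceiling(p * m / 100)` of the descending-sorted doses). `Vd` is the
#' percentage of the structure receiving at least dose d.
#'
#' @param dose [dose_distribution] or array (cGy).
#' @param mask 3D binary array.
#' @param mode `"D"` (q = volume percentage) or `"V"` (q = dose in cGy).
#' @param q Query value.
#' @return Dose in cGy (`mode = "D"`) or volume percent (`mode = "V"`).
#' @export
dvh_query <- function(dose, mask, mode = c("D", "V"), q) {
  mode <- match.arg(mode)
  dv <- dose_values(dose)
  x <- dv[mask == 1]
  if (!length(x)) stop("empty mask")
  if (mode == "D") {
    if (q <= 0 || q > 100) stop("volume percentage must be in (0, 100]")
    sorted <- sort(x, decreasing = TRUE)
    sorted[min(length(x), max(1L, ceiling(q * length(x) / 100)))]
  } else {
    100 * mean(x >= q)
  }
}

#' Homogeneity index
#'
#' `HI = (D2% - D98%) / D50%`: zero for a perfectly uniform target dose and
#' invariant to global dose scaling.
#'
#' @param indices Named list or vector containing `D2`, `D98`, `D50` (cGy).
#' @return HI (dimensionless).
#' @export
homogeneity_index <- function(indices) {
  ind <- as.list(indices)
  if (!all(c("D2", "D98", "D50") %in% names(ind)))
    stop("indices must provide D2, D98 and D50")
  if (ind$D50 <= 0) stop("D50 must be > 0")
  (ind$D2 - ind$D98) / ind$D50
}

#' Conformity index of the prescription isodose
#'
#' `CI = V_TP^2 / (V_T * V_P)` where `V_T` is the PTV volume, `V_P` the
#' volume covered by the prescription isodose (restricted to the body when a
#' body mask is given) and `V_TP` their intersection. Zero when the
#' prescription isodose is empty.
#'
#' @param ptv_mask Nonempty 3D binary array.
#' @param dose [dose_distribution] or array (cGy).
#' @param prescription Prescription in cGy.
#' @param body_mask Optional body mask restricting `V_P`.
#' @return CI in \[0, 1\].
#' @export
conformity_index <- function(ptv_mask, dose, prescription, body_mask = NULL) {
  dv <- dose_values(dose)
  if (!any(ptv_mask == 1)) stop("empty PTV mask")
  iso <- dv >= prescription
  if (!is.null(body_mask)) iso <- iso & body_mask == 1
  v_t <- sum(ptv_mask == 1)
  v_p <- sum(iso)
  if (v_p == 0) return(0)
  v_tp <- sum(iso & ptv_mask == 1)
  v_tp^2 / (v_t * v_p)
}

#' Dice coefficient of two isodose volumes
#'
#' Dice overlap of the clinical and predicted >= level volumes, with level
#' expressed as a percentage of the prescription. When both isodose volumes
#' are empty the coefficient is reported as 1 (identical empty sets) with a
#' warning.
#'
#' @param gt_dose,pred_dose [dose_distribution]s or arrays (cGy).
#' @param level Isodose level in percent of prescription.
#' @param prescription Prescription in cGy (defaults to `gt_dose`'s).
#' @return DSC in \[0, 1\].
#' @export
isodose_dsc <- function(gt_dose, pred_dose, level, prescription = NULL) {
  gv <- dose_values(gt_dose); pv <- dose_values(pred_dose)
  if (is.null(prescription)) prescription <- dose_rx(gt_dose)
  thr <- level / 100 * prescription
  a <- gv >= thr; b <- pv >= thr
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    warning("both isodose volumes empty; DSC reported as 1")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' 3D gamma analysis
#'
#' For every reference voxel above the low-dose threshold, the gamma index
#' is the minimum over a spatial neighbourhood of
#' `sqrt((dose difference / (dd% of Rx))^2 + (distance / DTA)^2)`, with the
#' evaluated dose interpolated trilinearly on a grid of at most DTA/10 mm
#' steps within a search radius of three DTA. Dose differences are
#' normalized globally to the prescription. A voxel passes when gamma <= 1;
#' the passing rate is reported globally and per structure.
#'
#' @param ref Reference (clinical) [dose_distribution].
#' @param eval Evaluated (predicted) [dose_distribution] or array.
#' @param masks Optional named list of structure masks for per-structure
#'   rates.
#' @param dd_pct Dose-difference criterion, percent of prescription
#'   (default 3).
#' @param dta_mm Distance-to-agreement criterion in mm (default 3).
#' @param threshold_pct Low-dose threshold, percent of prescription
#'   (default 10): reference voxels below it are excluded.
#' @param step_mm Interpolation step of the neighbourhood search (default
#'   DTA/10).
#' @param spacing Voxel spacing in mm (defaults to the reference grid's).
#' @param prescription Prescription in cGy (defaults to `ref`'s).
#' @return A `gamma_result`: list with the per-voxel `gamma` array (NA where
#'   not evaluated), a `rates` tibble (structure, gpr, n_eval) and the
#'   criteria.
#' @export
gamma_passing_rate <- function(ref, eval, masks = NULL, dd_pct = 3,
                               dta_mm = 3, threshold_pct = 10,
                               spacing = NULL, prescription = NULL,
                               step_mm = dta_mm / 10) {
  rv <- dose_values(ref); ev <- dose_values(eval)
  if (!identical(dim(rv), dim(ev))) stop("geometry mismatch")
  if (is.null(prescription)) prescription <- dose_rx(ref)
  if (is.null(spacing)) {
    if (inherits(ref, "dose_distribution")) spacing <- ref$grid$spacing
    else stop("voxel spacing must be supplied")
  }
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing must be positive and finite")
  eligible <- rv >= threshold_pct / 100 * prescription
  gam <- cpp_gamma3d(rv, ev, array(eligible, dim(rv)), spacing,
                     dd_pct / 100 * prescription, dta_mm, step_mm,
                     3 * dta_mm)
  gpr <- function(sel) {
    n <- sum(sel & eligible)
    if (n == 0) return(c(NA_real_, 0))
    c(100 * sum(gam[sel & eligible] <= 1, na.rm = TRUE) / n, n)
  }
  rows <- list()
  g <- gpr(array(TRUE, dim(rv)))
  rows[["global"]] <- tibble::tibble(structure = "global", gpr = g[1],
                                     n_eval = g[2])
  for (nm in names(masks)) {
    g <- gpr(masks[[nm]] == 1)
    rows[[nm]] <- tibble::tibble(structure = nm, gpr = g[1], n_eval = g[2])
  }
  structure(list(gamma = gam, rates = dplyr::bind_rows(rows),
                 criteria = list(dd_pct = dd_pct, dta_mm = dta_mm,
                                 threshold_pct = threshold_pct)),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm, threshold %g%%\n",
              x$criteria$dd_pct, x$criteria$dta_mm, x$criteria$threshold_pct))
  print(x$rates)
  invisible(x)
}

#' Histogram of voxel dose differences
#'
#' 1D histogram of (predicted - clinical) in cGy over masked voxels, with
#' the distribution's bias (mean) and standard deviation.
#'
#' @param gt,pred [dose_distribution]s or arrays (cGy).
#' @param mask 3D binary array.
#' @param bins Number of histogram bins (default 51).
#' @return A `diff_histogram` tibble (bin_mid, count) with attributes
#'   `bias`, `sd`, `n`.
#' @export
difference_histogram <- function(gt, pred, mask, bins = 51) {
  gv <- dose_values(gt); pv <- dose_values(pred)
  if (!identical(dim(gv), dim(pv))) stop("geometry mismatch")
  diffs <- (pv - gv)[mask == 1]
  rng <- range(diffs)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- graphics::hist(diffs, breaks = edges, plot = FALSE)
  structure(tibble::tibble(bin_mid = h$mids, count = h$counts),
            bias = mean(diffs), sd = stats::sd(diffs), n = length(diffs),
            class = c("diff_histogram", "tbl_df", "tbl", "data.frame"))
}

#' Two-sided paired t-test
#'
#' Wraps `stats::t.test(..., paired = TRUE)`. When the paired differences
#' have zero variance the test statistic is undefined; the result is flagged
#' degenerate and no p-value is emitted.
#'
#' @param values_a,values_b Equal-length numeric vectors (n >= 2).
#' @return List with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("inputs must have equal length")
  if (length(values_a) < 2) stop("need at least two pairs")
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1L,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate),
       degenerate = FALSE)
}

# dose indices for one structure; HI/CI only computed for the PTV
structure_indices <- function(dose, mask, prescription, body_mask = NULL,
                              is_ptv = FALSE, with_v40 = FALSE) {
  x <- dose_values(dose)[mask == 1]
  out <- list(
    D99 = dvh_query(dose, mask, "D", 99), D98 = dvh_query(dose, mask, "D", 98),
    D95 = dvh_query(dose, mask, "D", 95), D50 = dvh_query(dose, mask, "D", 50),
    D2 = dvh_query(dose, mask, "D", 2),
    Dmax = max(x), Dmean = mean(x)
  )
  if (with_v40) out$V40 <- dvh_query(dose, mask, "V", 4000)
  if (is_ptv) {
    out$HI <- homogeneity_index(out)
    out$CI <- conformity_index(mask, dose, prescription, body_mask)
  }
  out
}

#' Evaluate a predicted dose against the clinical reference
#'
#' Assembles the full per-case report: dose indices per structure (PTV:
#' D99/D98/D95/D50/D2, Dmax, Dmean, HI, CI; organs at risk: Dmax, Dmean, and
#' V40 for bladder and rectum), MAE per structure and for the body, isodose
#' Dice coefficients over a grid of levels, the 3%/3 mm gamma analysis, and
#' the voxel difference histogram.
#'
#' @param gt Clinical [dose_distribution].
#' @param pred Predicted [dose_distribution] (or array in cGy).
#' @param structures A [structure_set] (must contain `body` and `ptv`).
#' @param prescription Prescription in cGy (defaults to `gt`'s).
#' @param dsc_levels Isodose levels in percent of prescription.
#' @param dvh_bin DVH bin width in cGy.
#' @return A `dose_eval` with tibbles `indices`, `mae`, `dsc`, `gamma_rates`,
#'   `dvh`, `histogram`, plus the `gamma_result`.
#' @export
evaluate_case <- function(gt, pred, structures, prescription = NULL,
                          dsc_levels = seq(10, 100, by = 10), dvh_bin = 10) {
  if (is.null(prescription)) prescription <- dose_rx(gt)
  masks <- structures$masks
  if (!all(c("body", "ptv") %in% names(masks)))
    stop("structures must include body and ptv")
  oars <- intersect(c("bladder", "rectum", "femur_head_l", "femur_head_r"),
                    names(masks))
  idx_rows <- list()
  add_idx <- function(structure, metric, clin, prd) {
    idx_rows[[length(idx_rows) + 1]] <<- tibble::tibble(
      structure = structure, metric = metric,
      clinical = clin, predicted = prd, diff = prd - clin)
  }
  ptv_g <- structure_indices(gt, masks$ptv, prescription, masks$body, TRUE)
  ptv_p <- structure_indices(pred, masks$ptv, prescription, masks$body, TRUE)
  for (m in names(ptv_g)) add_idx("ptv", m, ptv_g[[m]], ptv_p[[m]])
  for (nm in oars) {
    v40 <- nm %in% c("bladder", "rectum")
    gi <- structure_indices(gt, masks[[nm]], prescription, with_v40 = v40)
    pi_ <- structure_indices(pred, masks[[nm]], prescription, with_v40 = v40)
    for (m in c("Dmax", "Dmean", if (v40) "V40"))
      add_idx(nm, m, gi[[m]], pi_[[m]])
  }
  bg <- structure_indices(gt, masks$body, prescription)
  bp <- structure_indices(pred, masks$body, prescription)
  for (m in c("Dmax", "Dmean")) add_idx("body", m, bg[[m]], bp[[m]])

  mae <- dplyr::bind_rows(lapply(c("body", "ptv", oars), function(nm)
    tibble::tibble(structure = nm,
                   mae_pct = mae_percent(gt, pred, masks[[nm]], prescription))))

  dsc <- dplyr::bind_rows(lapply(dsc_levels, function(lv)
    tibble::tibble(level_pct = lv,
                   dsc = isodose_dsc(gt, pred, lv, prescription))))

  gam <- gamma_passing_rate(gt, pred, masks[c("ptv", oars, "body")],
                            prescription = prescription)
  hist <- difference_histogram(gt, pred, masks$body)

  dvh <- dplyr::bind_rows(lapply(c("ptv", oars), function(nm) {
    dplyr::bind_rows(
      dplyr::mutate(cumulative_dvh(gt, masks[[nm]], dvh_bin),
                    structure = nm, source = "clinical"),
      dplyr::mutate(cumulative_dvh(pred, masks[[nm]], dvh_bin),
                    structure = nm, source = "predicted"))
  }))

  structure(list(indices = dplyr::bind_rows(idx_rows), mae = mae, dsc = dsc,
                 gamma_rates = gam$rates, gamma = gam, dvh = dvh,
                 histogram = hist, prescription = prescription),
            class = "dose_eval")
}

#' @export
print.dose_eval <- function(x, ...) {
  cat(sprintf("<dose_eval> Rx %.0f cGy\n", x$prescription))
  cat(sprintf("  body MAE %.2f%% | mean DSC %.3f | global GPR %.1f%%\n",
              x$mae$mae_pct[x$mae$structure == "body"], mean(x$dsc$dsc),
              x$gamma_rates$gpr[x$gamma_rates$structure == "global"]))
  invisible(x)
}

#' @describeIn evaluate_case Long tibble of every metric in the report.
#' @param x A `dose_eval`.
#' @param ... Unused.
#' @method tidy dose_eval
#' @export
tidy.dose_eval <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::transmute(x$indices, structure = .data$structure,
                     metric = .data$metric, clinical = .data$clinical,
                     predicted = .data$predicted, diff = .data$diff),
    dplyr::transmute(x$mae, structure = .data$structure, metric = "MAE_pct",
                     clinical = 0, predicted = .data$mae_pct,
                     diff = .data$mae_pct),
    dplyr::transmute(x$gamma_rates, structure = .data$structure,
                     metric = "GPR_pct", clinical = 100,
                     predicted = .data$gpr, diff = .data$gpr - 100)
  )
}

#' @describeIn evaluate_case One-row summary (body MAE, mean DSC, global
#'   GPR, PTV HI/CI differences).
#' @method glance dose_eval
#' @export
glance.dose_eval <- function(x, ...) {
  hi <- x$indices[x$indices$structure == "ptv" & x$indices$metric == "HI", ]
  ci <- x$indices[x$indices$structure == "ptv" & x$indices$metric == "CI", ]
  tibble::tibble(
    mae_body_pct = x$mae$mae_pct[x$mae$structure == "body"],
    mean_dsc = mean(x$dsc$dsc),
    gpr_global_pct = x$gamma_rates$gpr[x$gamma_rates$structure == "global"],
    hi_diff = hi$diff, ci_diff = ci$diff
  )
}

#' Write an evaluation report to disk
#'
#' CSV files for the tabular components and one JSON with everything.
#'
#' @param x A `dose_eval`.
#' @param dir Output directory (created if needed).
#' @export
write_eval_report <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$indices, file.path(dir, "indices.csv"), row.names = FALSE)
  utils::write.csv(x$mae, file.path(dir, "mae.csv"), row.names = FALSE)
  utils::write.csv(x$dsc, file.path(dir, "dsc.csv"), row.names = FALSE)
  utils::write.csv(x$gamma_rates, file.path(dir, "gamma.csv"), row.names = FALSE)
  utils::write.csv(x$dvh, file.path(dir, "dvh.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(prescription = x$prescription, indices = x$indices, mae = x$mae,
         dsc = x$dsc, gamma = x$gamma_rates,
         histogram = list(bias = attr(x$histogram, "bias"),
                          sd = attr(x$histogram, "sd"))),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
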