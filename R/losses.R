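#' Loss weights for the composite generator objective
#'
#' The total generator loss is
#' `lambda_cGAN * L_cGAN + lambda_AVD * L_AVD + lambda_L1 * L_L1`.
#' The adversarial weight keeps the discriminator in play, the
#' adjacent-voxel-difference term preserves dose gradients at structure
#' boundaries, and the dominant L1 term anchors the overall dose level
#' (pix2pix-style weighting; all three are configurable).
#'
#' @param cgan,avd,l1 Non-negative scalars; at least one must be positive.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(cgan = 1, avd = 10, l1 = 100) {
  w <- c(cgan = cgan, avd = avd, l1 = l1)
  if (any(w < 0) || all(w == 0))
    stop("weights must be non-negative with at least one > 0")
  structure(as.list(w), class = "loss_weights")
}

#' Discriminator objective (binary cross-entropy with sigmoid)
#'
#' Real patch logit maps are pushed toward label 1 and predicted-dose maps
#' toward label 0; the discriminator loss is the average of the two terms.
#' Uses the numerically stable softplus identity, so it is exact for
#' arbitrarily large logits.
#'
#' @param logits_gt Patch logit map for the stack containing the clinical
#'   dose.
#' @param logits_pred Patch logit map for the stack containing the generated
#'   dose.
#' @return List with `L_D_GT`, `L_D_Pre` and their average `L_D`.
#' @export
discriminator_loss <- function(logits_gt, logits_pred) {
  if (!length(logits_gt) || !length(logits_pred)) stop("empty logit map")
  L_D_GT <- mean(softplus(-as.numeric(logits_gt)))
  L_D_Pre <- mean(softplus(as.numeric(logits_pred)))
  list(L_D_GT = L_D_GT, L_D_Pre = L_D_Pre, L_D = (L_D_GT + L_D_Pre) / 2)
}

#' Generator adversarial term
#'
#' Non-saturating form: the generator drives the discriminator's logits for
#' its own output toward the "real" label, `-mean log sigma(logit)`.
#'
#' @param logits_pred Patch logit map for the generated dose.
#' @return Scalar loss.
#' @export
generator_adversarial_loss <- function(logits_pred) {
  if (!length(logits_pred)) stop("empty logit map")
  mean(softplus(-as.numeric(logits_pred)))
}

# shared AVD implementation: squared mismatch of consecutive-slice
# differences along the three anatomical axes, with the gradient wrt the
# prediction. reduction "mean" divides by the total number of adjacent pairs.
avd_core <- function(gt, pred, reduction = "mean") {
  d <- dim(gt)
  if (is.null(d) || length(d) < 3L) stop("inputs must be (at least) 3D arrays")
  if (!identical(dim(gt), dim(pred))) stop("shape mismatch between gt and prediction")
  if (any(d[1:3] < 2L)) stop("every axis must have length >= 2")
  total <- 0
  grad <- array(0, d)
  npairs <- 0
  for (ax in 1:3) {
    n <- d[ax]
    idx_hi <- slice_index(d, ax, 2:n)
    idx_lo <- slice_index(d, ax, 1:(n - 1))
    e <- (gt[idx_hi] - gt[idx_lo]) - (pred[idx_hi] - pred[idx_lo])
    total <- total + sum(e^2)
    g <- array(0, d)
    g[idx_hi] <- g[idx_hi] - 2 * e
    g[idx_lo] <- g[idx_lo] + 2 * e
    grad <- grad + g
    npairs <- npairs + length(e)
  }
  if (reduction == "mean") {
    total <- total / npairs
    grad <- grad / npairs
  }
  list(loss = total, grad_pred = grad)
}

# logical index selecting planes `take` along axis `ax`
slice_index <- function(d, ax, take) {
  sel <- array(FALSE, d)
  if (length(d) == 3L) {
    switch(ax, sel[take, , ] <- TRUE, sel[, take, ] <- TRUE, sel[, , take] <- TRUE)
  } else {
    switch(ax,
           sel[take, , , , ] <- TRUE,
           sel[, take, , , ] <- TRUE,
           sel[, , take, , ] <- TRUE)
  }
  sel
}

#' Adjacent-voxel-difference loss
#'
#' Penalizes the squared mismatch between the clinical and predicted dose
#' *gradients*: for each of the transverse, coronal and sagittal axes, the
#' difference of consecutive-slice differences is squared and accumulated,
#' then reduced to the mean over all adjacent pairs (set
#' `reduction = "sum"` for the unnormalized sum). Adding a constant to the
#' prediction leaves the loss unchanged; only edges matter.
#'
#' @param gt,pred Dose arrays of identical shape, length >= 2 on every axis.
#' @param reduction `"mean"` (default) or `"sum"`.
#' @return Scalar loss.
#' @export
avd_loss <- function(gt, pred, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  avd_core(gt, pred, reduction)$loss
}

#' L1 distance term
#'
#' Mean absolute voxel difference between clinical and predicted dose
#' (`reduction = "sum"` gives the literal L1 norm).
#'
#' @inheritParams avd_loss
#' @return Scalar loss.
#' @export
l1_term <- function(gt, pred, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (!identical(dim(gt), dim(pred))) stop("shape mismatch between gt and prediction")
  if (reduction == "mean") mean(abs(gt - pred)) else sum(abs(gt - pred))
}

#' Total generator objective
#'
#' @param parts List with elements `cgan`, `avd`, `l1` (scalar losses).
#' @param weights A [loss_weights()].
#' @return Weighted sum.
#' @export
total_generator_loss <- function(parts, weights = loss_weights()) {
  stopifnot(all(c("cgan", "avd", "l1") %in% names(parts)))
  vals <- unlist(parts[c("cgan", "avd", "l1")])
  if (any(!is.finite(vals))) stop("non-finite loss part")
  weights$cgan * parts$cgan + weights$avd * parts$avd + weights$l1 * parts$l1
}
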