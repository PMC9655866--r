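# Shared fixtures, built once per test run.

test_env <- new.env()

# small complete phantom case (32^3 at 3.5 mm), cached
tiny_case <- function(seed = 7) {
  key <- paste0("case", seed)
  if (is.null(test_env[[key]]))
    test_env[[key]] <- generate_phantom_case(phantom_spec(shape = 32, seed = seed))
  test_env[[key]]
}

# noise-free phantom case (step-function PTV dose)
clean_case <- function(seed = 3) {
  key <- paste0("clean", seed)
  if (is.null(test_env[[key]])) {
    sp <- phantom_spec(shape = 32, seed = seed, noise_hu = 0, noise_dose_frac = 0)
    test_env[[key]] <- generate_phantom_case(sp)
  }
  test_env[[key]]
}

rand_vol <- function(d, lo = 0, hi = 6000) {
  array(runif(prod(rep_len(d, 3)), lo, hi), rep_len(d, 3))
}

# direct elementwise oracle for the adjacent-voxel-difference loss
avd_oracle <- function(gt, pred, reduction = "mean") {
  d <- dim(gt)
  total <- 0; pairs <- 0
  for (i in 1:(d[1] - 1)) for (j in 1:d[2]) for (k in 1:d[3]) {
    total <- total + ((gt[i + 1, j, k] - gt[i, j, k]) -
                      (pred[i + 1, j, k] - pred[i, j, k]))^2
    pairs <- pairs + 1
  }
  for (i in 1:d[1]) for (j in 1:(d[2] - 1)) for (k in 1:d[3]) {
    total <- total + ((gt[i, j + 1, k] - gt[i, j, k]) -
                      (pred[i, j + 1, k] - pred[i, j, k]))^2
    pairs <- pairs + 1
  }
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:(d[3] - 1)) {
    total <- total + ((gt[i, j, k + 1] - gt[i, j, k]) -
                      (pred[i, j, k + 1] - pred[i, j, k]))^2
    pairs <- pairs + 1
  }
  if (reduction == "mean") total / pairs else total
}
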