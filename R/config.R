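.fd_env <- new.env(parent = emptyenv())

#' Package architecture and protocol configuration
#'
#' Reads the recorded architecture and training-protocol constants shipped
#' with the package: the resolved generator block plan (stem width, encoder
#' widths and refinement-conv multiplicities, skip width), the discriminator
#' channel ladder and stride plan, normalization ranges, structure label
#' values, and the default training protocol.
#'
#' @return A nested list mirroring `inst/config/architecture.json`.
#' @export
fd_config <- function() {
  if (is.null(.fd_env$config)) {
    path <- system.file("config", "architecture.json", package = "fusedose")
    if (!nzchar(path)) stop("architecture config not found")
    .fd_env$config <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  .fd_env$config
}

#' Structure label values used for mask channels
#'
#' @return Named numeric vector of label values (background -600, body -400,
#'   femur-head-R -200, femur-head-L 200, rectum 600, bladder 800, PTV 1000).
#' @export
structure_labels <- function() {
  unlist(fd_config()$structure_labels)
}

# canonical structure roles, in channel order for scheme A after (dose, CT)
fd_structure_roles <- function() {
  c("ptv", "body", "femur_head_r", "femur_head_l", "rectum", "bladder")
}

# evaluate expr with a local RNG stream, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
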