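## Model serialization: a versioned JSON text bundle holding the window,
## per-group peptides, weights, matrix deltas and thresholds, plus the
## seed, control settings and a checksum of the training data.  Numbers
## are written at full precision so that write -> read -> write is
## byte-identical.

#' Write a fitted model to a JSON file
#'
#' @param model A \code{"lipid_model"}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "lipid_model"))
  x <- unclass(model)
  x$window <- as.list(x$window)
  x$sp_levels <- as.list(x$sp_levels)
  x$groups <- lapply(x$groups, function(g) {
    g$thresholds <- as.list(g$thresholds)
    g$objective_trace <- as.list(g$objective_trace)
    g
  })
  x$control <- control_to_list(x$control)
  json <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

control_to_list <- function(control) {
  x <- unclass(control)
  x$mls_grid <- unname(as.matrix(x$mls_grid))
  x$sp_levels <- as.list(x$sp_levels)
  x
}

#' Read a fitted model from a JSON file
#'
#' @param path Path written by \code{\link{write_model}}.
#' @return A \code{"lipid_model"}.
#' @export
read_model <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (is.null(x$version)) stop("not a lipid model file: ", path)
  x$window <- c(m = as.integer(x$window$m), n = as.integer(x$window$n))
  x$sp_levels <- unlist(x$sp_levels)
  x$groups <- lapply(x$groups, function(g) {
    g$thresholds <- unlist(g$thresholds)
    g$objective_trace <- unlist(g$objective_trace)
    g
  })
  ctl <- x$control
  ctl$mls_grid <- matrix(ctl$mls_grid, ncol = 2)
  ctl$sp_levels <- unlist(ctl$sp_levels)
  ctl$dw_bounds <- as.numeric(ctl$dw_bounds)
  ctl$ds_bounds <- as.numeric(ctl$ds_bounds)
  class(ctl) <- "train_control"
  x$control <- ctl
  class(x) <- "lipid_model"
  x
}
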