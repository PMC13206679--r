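# Data tensors: N-dimensional numeric grids with per-axis role labels.

#' Construct a data tensor
#'
#' A data tensor is an N-dimensional numeric array in which every axis is
#' labelled either `"spatial"` or `"channel"`. The cyclic-shift transform
#' operates on spatial axes by default; the channel axis (colour bands,
#' imaging modalities) is protected unless explicitly opted in.
#'
#' @param values A numeric (or integer/logical) vector, matrix or array.
#'   Vectors are treated as one-axis tensors.
#' @param axis_roles Character vector, one of `"spatial"` or `"channel"` per
#'   axis. Defaults to all-spatial.
#' @return An object of class `data_tensor`: a list with elements `values`
#'   (the array) and `axis_roles`.
#' @examples
#' x <- data_tensor(array(1:24, c(2, 3, 4)), c("channel", "spatial", "spatial"))
#' dim(x$values)
#' @export
data_tensor <- function(values, axis_roles = NULL) {
  if (!(is.numeric(values) || is.logical(values))) {
    sulba_stop("values must be numeric or logical", "invalid_tensor_error")
  }
  if (is.null(dim(values))) {
    dim(values) <- length(values)
  }
  d <- dim(values)
  if (any(d < 1L)) {
    sulba_stop("every axis must have extent >= 1", "invalid_tensor_error")
  }
  if (is.null(axis_roles)) {
    axis_roles <- rep("spatial", length(d))
  }
  if (length(axis_roles) != length(d)) {
    sulba_stop("axis_roles length must equal the number of axes",
               "invalid_tensor_error")
  }
  if (!all(axis_roles %in% c("spatial", "channel"))) {
    sulba_stop("axis_roles entries must be 'spatial' or 'channel'",
               "invalid_tensor_error")
  }
  if (!any(axis_roles == "spatial")) {
    sulba_stop("at least one spatial axis is required", "invalid_tensor_error")
  }
  structure(list(values = values, axis_roles = axis_roles),
            class = "data_tensor")
}

#' Coerce to a data tensor
#'
#' Arrays and vectors pass through [data_tensor()] with all-spatial roles;
#' existing data tensors are returned unchanged.
#'
#' @param x An array, vector, or `data_tensor`.
#' @param axis_roles Optional axis roles used when `x` is not already a
#'   `data_tensor`.
#' @return A `data_tensor`.
#' @export
as_data_tensor <- function(x, axis_roles = NULL) {
  if (inherits(x, "data_tensor")) return(x)
  data_tensor(x, axis_roles)
}

#' @export
print.data_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("<data_tensor> ", paste(d, collapse = " x "),
      " [", paste(substr(x$axis_roles, 1, 1), collapse = ""), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.data_tensor <- function(x) dim(x$values)

#' Spatial axis indices of a tensor
#'
#' @param x A `data_tensor` (or array, in which case all axes are spatial).
#' @return Integer vector of axis indices whose role is `"spatial"`.
#' @export
spatial_axes <- function(x) {
  x <- as_data_tensor(x)
  which(x$axis_roles == "spatial")
}

#' Shiftable axes of a tensor
#'
#' An axis is eligible for the cyclic shift when its role is permitted by the
#' axis policy and its extent is at least 2 (an axis of extent 1 has no valid
#' step).
#'
#' @param x A `data_tensor` or array.
#' @param axis_policy `"spatial_only"` (default) or `"include_channel"`.
#' @return Integer vector of eligible axis indices (possibly empty).
#' @export
eligible_axes <- function(x, axis_policy = c("spatial_only", "include_channel")) {
  x <- as_data_tensor(x)
  axis_policy <- match.arg(axis_policy)
  roles <- if (axis_policy == "include_channel") {
    c("spatial", "channel")
  } else {
    "spatial"
  }
  which(x$axis_roles %in% roles & dim(x$values) >= 2L)
}

# internal: classed errors so callers can distinguish failure modes
sulba_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sulba_error", "error", "condition")))
}

# internal: run expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
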