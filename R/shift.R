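# The cyclic-shift transform: a pure index permutation along one axis.

#' Cyclic shift along one axis
#'
#' Moves the content of `x` along a single axis by `step` positions with
#' wrap-around: position `d` of the output holds position
#' `(d + step) mod D` of the input, where `D` is the axis extent. The
#' transform is a pure index permutation — no value is modified, interpolated
#' or dropped, and the output dtype equals the input dtype.
#'
#' Valid steps are `1, ..., D - 1`; a step of `D` would be the identity and
#' is rejected, as is any axis of extent 1. By default only spatial axes may
#' be shifted; set `allow_channel = TRUE` to permit shifting a channel axis
#' (this cycles colour bands / modalities and is a semantically different,
#' riskier transform).
#'
#' @param x A `data_tensor`, array or vector.
#' @param axis 1-based axis index.
#' @param step Integer step in `1, ..., D - 1`.
#' @param allow_channel Permit shifting a channel axis. Default `FALSE`.
#' @return An object of the same type as `x` (array in, array out;
#'   `data_tensor` in, `data_tensor` out) with identical shape and roles.
#' @examples
#' cyclic_shift(c(10, 20, 30, 40), axis = 1, step = 1)  # 20 30 40 10
#' m <- matrix(1:4, 2, byrow = TRUE)
#' cyclic_shift(m, axis = 1, step = 1)                  # rows swapped
#' @export
cyclic_shift <- function(x, axis, step, allow_channel = FALSE) {
  was_plain <- !inherits(x, "data_tensor")
  xt <- as_data_tensor(x)
  v <- xt$values
  d <- dim(v)
  check_shift_axis(xt, axis, allow_channel)
  D <- d[axis]
  step <- check_shift_step(step, D)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- ((seq_len(D) - 1L + step) %% D) + 1L
  out <- do.call(`[`, c(list(v), idx, list(drop = FALSE)))
  dim(out) <- d
  if (was_plain) {
    if (is.null(dim(x))) dim(out) <- NULL
    out
  } else {
    data_tensor(out, xt$axis_roles)
  }
}

#' Invert a cyclic shift
#'
#' Recovers the pre-shift tensor exactly by applying the complementary shift
#' `D - step` along the same axis. Cyclic shifts lose no information, so the
#' round trip `inverse_shift(cyclic_shift(x, k, s), k, s)` is bit-identical
#' to `x` for every valid axis and step.
#'
#' @inheritParams cyclic_shift
#' @param step The step of the *forward* shift being undone.
#' @return The recovered tensor.
#' @export
inverse_shift <- function(x, axis, step, allow_channel = FALSE) {
  xt <- as_data_tensor(x)
  check_shift_axis(xt, axis, allow_channel)
  D <- dim(xt$values)[axis]
  step <- check_shift_step(step, D)
  cyclic_shift(x, axis, D - step, allow_channel = allow_channel)
}

#' Size of the shift sample space
#'
#' The number of distinct (axis, step) shift configurations available for a
#' given shape: the sum over eligible axes of `D_k - 1`. Axes of extent 1
#' contribute nothing. This is how the pool of novel views scales with image
#' resolution and dimensionality — larger or higher-dimensional inputs yield
#' more configurations with no tuning.
#'
#' @param shape Integer vector of per-axis extents.
#' @param eligible_axes Integer vector of axis indices to count over.
#'   Defaults to all axes. An empty set yields 0.
#' @return Non-negative integer count.
#' @examples
#' enumerate_sample_space(c(28, 28))      # 54
#' enumerate_sample_space(c(32, 32, 32))  # 93
#' @export
enumerate_sample_space <- function(shape, eligible_axes = seq_along(shape)) {
  shape <- as.integer(shape)
  if (any(shape < 1L)) {
    sulba_stop("shape entries must be >= 1", "invalid_tensor_error")
  }
  if (length(eligible_axes) == 0L) return(0L)
  eligible_axes <- as.integer(eligible_axes)
  if (any(eligible_axes < 1L | eligible_axes > length(shape))) {
    sulba_stop("eligible axis index out of range", "invalid_axis_error")
  }
  sum(pmax(shape[eligible_axes] - 1L, 0L))
}

#' Count distinct shifted tensors by brute force
#'
#' Materializes every (axis, step) configuration in the sample space and
#' counts how many produce a tensor different from the original and from each
#' other. For tensors whose entries are all distinct this equals
#' [enumerate_sample_space()]; symmetric content (e.g. constant tensors)
#' collapses configurations, so the count is never larger.
#'
#' @param x A `data_tensor` or array.
#' @param eligible_axes Axis indices to enumerate over; defaults to the
#'   tensor's spatial axes of extent >= 2.
#' @return Number of distinct novel outputs (original excluded).
#' @export
count_distinct_outputs <- function(x, eligible_axes = NULL) {
  xt <- as_data_tensor(x)
  d <- dim(xt$values)
  if (is.null(eligible_axes)) {
    eligible_axes <- eligible_axes(xt)
  } else {
    eligible_axes <- as.integer(eligible_axes)
    if (any(eligible_axes < 1L | eligible_axes > length(d))) {
      sulba_stop("eligible axis index out of range", "invalid_axis_error")
    }
  }
  orig_key <- tensor_key(xt$values)
  seen <- character(0)
  for (k in eligible_axes) {
    if (d[k] < 2L) next
    for (s in seq_len(d[k] - 1L)) {
      key <- tensor_key(cyclic_shift(xt, k, s, allow_channel = TRUE)$values)
      if (!identical(key, orig_key)) seen <- c(seen, key)
    }
  }
  length(unique(seen))
}

# internal: canonical string key for exact tensor comparison (small tensors)
tensor_key <- function(v) {
  paste(format(c(v), digits = 17), collapse = ",")
}

check_shift_axis <- function(xt, axis, allow_channel) {
  d <- dim(xt$values)
  if (length(axis) != 1L || is.na(axis) || axis < 1L || axis > length(d) ||
      axis != as.integer(axis)) {
    sulba_stop("axis index out of range", "invalid_axis_error")
  }
  axis <- as.integer(axis)
  if (!allow_channel && xt$axis_roles[axis] == "channel") {
    sulba_stop("channel axis is not shiftable unless explicitly allowed",
               "invalid_axis_error")
  }
  if (d[axis] < 2L) {
    sulba_stop("axis of extent < 2 has no valid shift step",
               "invalid_axis_error")
  }
  invisible(axis)
}

check_shift_step <- function(step, D) {
  if (length(step) != 1L || is.na(step) || step != as.integer(step)) {
    sulba_stop("step must be a single integer", "invalid_step_error")
  }
  step <- as.integer(step)
  if (step < 1L || step > D - 1L) {
    sulba_stop(sprintf("step must lie in 1..%d", D - 1L),
               "invalid_step_error")
  }
  step
}
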