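# Stochastic application protocol: probability-gated sampling of one
# (axis, step) move, paired image/mask synchronization, record/replay.

#' Configuration for stochastic augmentation
#'
#' @param application_probability Probability in `[0, 1]` that the transform
#'   is applied at all (per-sample Bernoulli gate). The default of 1.0 is the
#'   recommended tuning-free setting; 0.5 is the other commonly benchmarked
#'   value.
#' @param axis_policy `"spatial_only"` (default) or `"include_channel"`.
#' @param explicit_axes Optional integer vector restricting sampling to a
#'   subset of the policy-eligible axes.
#' @param seed Optional non-negative integer. When given, each sampling call
#'   is seeded with it (and the caller's RNG state is left untouched);
#'   when `NULL`, the current RNG stream is consumed.
#' @return An object of class `sulba_config`.
#' @export
sulba_config <- function(application_probability = 1.0,
                         axis_policy = c("spatial_only", "include_channel"),
                         explicit_axes = NULL,
                         seed = NULL) {
  axis_policy <- match.arg(axis_policy)
  ap <- application_probability
  if (length(ap) != 1L || is.na(ap) || ap < 0 || ap > 1) {
    sulba_stop("application_probability must lie in [0, 1]",
               "invalid_config_error")
  }
  if (!is.null(explicit_axes)) {
    explicit_axes <- as.integer(explicit_axes)
    if (length(explicit_axes) == 0L || anyNA(explicit_axes)) {
      sulba_stop("explicit_axes must be a non-empty integer vector",
                 "invalid_config_error")
    }
  }
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed) || seed < 0L) {
      sulba_stop("seed must be a non-negative integer", "invalid_config_error")
    }
  }
  structure(list(application_probability = ap,
                 axis_policy = axis_policy,
                 explicit_axes = explicit_axes,
                 seed = seed),
            class = "sulba_config")
}

#' @export
print.sulba_config <- function(x, ...) {
  cat("<sulba_config> ap=", x$application_probability,
      " policy=", x$axis_policy,
      if (!is.null(x$seed)) paste0(" seed=", x$seed), "\n", sep = "")
  invisible(x)
}

# internal: constructor for the provenance record of one application.
# `axis` indexes the axes of the stated role positionally, so a record
# sampled on a channel-first image replays correctly on a channel-less mask.
shift_record <- function(applied, axis_role = NULL, axis = NULL, step = NULL,
                         spatial_shape, seed_context = NULL) {
  structure(list(applied = isTRUE(applied),
                 axis_role = axis_role,
                 axis = if (is.null(axis)) NULL else as.integer(axis),
                 step = if (is.null(step)) NULL else as.integer(step),
                 spatial_shape = as.integer(spatial_shape),
                 seed_context = seed_context),
            class = "shift_record")
}

#' @export
print.shift_record <- function(x, ...) {
  if (x$applied) {
    cat("<shift_record> applied: ", x$axis_role, " axis ", x$axis,
        ", step ", x$step, " (spatial ",
        paste(x$spatial_shape, collapse = "x"), ")\n", sep = "")
  } else {
    cat("<shift_record> not applied (spatial ",
        paste(x$spatial_shape, collapse = "x"), ")\n", sep = "")
  }
  invisible(x)
}

# internal: axes a config permits on a tensor, requiring extent >= 2
config_eligible_axes <- function(xt, config) {
  el <- eligible_axes(xt, config$axis_policy)
  if (!is.null(config$explicit_axes)) {
    bad <- setdiff(config$explicit_axes, el)
    if (length(bad) > 0L) {
      sulba_stop("explicit_axes contains axes not eligible under the policy",
                 "invalid_axis_error")
    }
    el <- config$explicit_axes
  }
  el
}

#' Sample one shift move
#'
#' Draws the provenance record of a single stochastic application: a
#' Bernoulli(`application_probability`) gate decides whether the transform is
#' applied; only when the gate opens are an axis (uniform over eligible axes)
#' and a step (uniform over `1, ..., D_axis - 1`) drawn. The gate-then-sample
#' order makes random-stream consumption well defined for replay.
#'
#' @param x A `data_tensor`, array, or integer shape vector (all-spatial).
#' @param config A [sulba_config()].
#' @return A `shift_record`.
#' @export
sample_shift <- function(x, config = sulba_config()) {
  xt <- if (is.numeric(x) && is.null(dim(x)) && !inherits(x, "data_tensor")) {
    data_tensor(array(0, as.integer(x)))
  } else {
    as_data_tensor(x)
  }
  el <- config_eligible_axes(xt, config)
  if (length(el) == 0L && config$application_probability > 0) {
    sulba_stop("no eligible axis with extent >= 2", "no_eligible_axis_error")
  }
  sp_shape <- dim(xt$values)[spatial_axes(xt)]
  with_seed(config$seed, {
    applied <- stats::runif(1) < config$application_probability
    if (!applied) {
      shift_record(FALSE, spatial_shape = sp_shape,
                   seed_context = config$seed)
    } else {
      ax <- el[sample.int(length(el), 1L)]
      D <- dim(xt$values)[ax]
      s <- sample.int(D - 1L, 1L)
      role <- xt$axis_roles[ax]
      within <- sum(xt$axis_roles[seq_len(ax)] == role)
      shift_record(TRUE, axis_role = role, axis = within, step = s,
                   spatial_shape = sp_shape, seed_context = config$seed)
    }
  })
}

# internal: map a record's role-relative axis onto a concrete tensor
resolve_record_axis <- function(xt, record) {
  sp <- spatial_axes(xt)
  if (!identical(as.integer(dim(xt$values)[sp]),
                 as.integer(record$spatial_shape))) {
    sulba_stop("tensor spatial shape does not match the record",
               "shape_mismatch_error")
  }
  if (!record$applied) return(NULL)
  if (record$axis_role == "spatial") {
    sp[record$axis]
  } else {
    ch <- which(xt$axis_roles == "channel")
    if (length(ch) < record$axis) {
      sulba_stop("record refers to a channel axis the tensor lacks",
                 "shape_mismatch_error")
    }
    ch[record$axis]
  }
}

#' Replay a recorded shift
#'
#' Deterministically re-applies the transform captured in a record to any
#' tensor with the same spatial shape (identity when the record's gate did
#' not open). This is how a move sampled on an image is applied to its mask,
#' and how an augmented stream is reproduced exactly.
#'
#' @param x A `data_tensor` or array.
#' @param record A `shift_record`.
#' @return The transformed tensor, same type as `x`.
#' @export
replay <- function(x, record) {
  stopifnot(inherits(record, "shift_record"))
  xt <- as_data_tensor(x)
  ax <- resolve_record_axis(xt, record)
  if (is.null(ax)) return(x)
  cyclic_shift(x, ax, record$step, allow_channel = TRUE)
}

#' Invert a recorded shift
#'
#' Exactly recovers the pre-augmentation tensor from an augmented one by
#' applying the complementary shift `D - step` along the recorded axis
#' (identity when the record was not applied).
#'
#' @param x_aug The augmented `data_tensor` or array.
#' @param record The `shift_record` that produced it.
#' @return The original tensor, bit-identical.
#' @export
invert_record <- function(x_aug, record) {
  stopifnot(inherits(record, "shift_record"))
  xt <- as_data_tensor(x_aug)
  ax <- resolve_record_axis(xt, record)
  if (is.null(ax)) return(x_aug)
  inverse_shift(x_aug, ax, record$step, allow_channel = TRUE)
}

#' Stochastically augment one tensor
#'
#' Samples a shift move under `config` and applies it (or not, per the
#' Bernoulli gate). With a fixed `config$seed` the result is fully
#' deterministic.
#'
#' @param x A `data_tensor` or array.
#' @param config A [sulba_config()].
#' @return A list with elements `x` (the possibly-shifted tensor, same type
#'   as the input) and `record` (the `shift_record`).
#' @examples
#' img <- matrix(1:12, 3, 4)
#' out <- apply_sulba(img, sulba_config(seed = 42))
#' out$record
#' @export
apply_sulba <- function(x, config = sulba_config()) {
  record <- sample_shift(x, config)
  list(x = replay(x, record), record = record)
}

#' Synchronously augment an image and its segmentation mask
#'
#' One move is sampled and the identical (axis, step) is applied to both
#' tensors, so pixel/voxel correspondence between image content and mask
#' labels is preserved exactly. The mask may be channel-less or carry a
#' singleton channel axis; spatial axes are matched by position.
#'
#' @param image A `data_tensor` or array.
#' @param mask A `data_tensor` or array with identical spatial extents.
#' @param config A [sulba_config()].
#' @return A list with elements `image`, `mask` and `record`.
#' @export
apply_sulba_paired <- function(image, mask, config = sulba_config()) {
  it <- as_data_tensor(image)
  mt <- as_data_tensor(mask)
  isp <- dim(it$values)[spatial_axes(it)]
  msp <- dim(mt$values)[spatial_axes(mt)]
  if (!identical(as.integer(isp), as.integer(msp))) {
    sulba_stop("image and mask spatial shapes differ", "shape_mismatch_error")
  }
  mch <- which(mt$axis_roles == "channel")
  if (length(mch) > 1L || (length(mch) == 1L && dim(mt$values)[mch] != 1L)) {
    sulba_stop("mask must be channel-less or have a singleton channel axis",
               "shape_mismatch_error")
  }
  record <- sample_shift(it, config)
  list(image = replay(image, record),
       mask = replay(mask, record),
       record = record)
}

#' Write a shift record as a JSON sidecar
#'
#' @param record A `shift_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_shift_record <- function(record, path) {
  stopifnot(inherits(record, "shift_record"))
  obj <- list(applied = record$applied,
              axis_role = record$axis_role,
              axis = record$axis,
              step = record$step,
              spatial_shape = as.integer(record$spatial_shape),
              seed_context = record$seed_context)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Read a shift record from a JSON sidecar
#'
#' @param path File written by [write_shift_record()].
#' @return A `shift_record`.
#' @export
read_shift_record <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  shift_record(applied = isTRUE(obj$applied),
               axis_role = obj$axis_role,
               axis = obj$axis,
               step = obj$step,
               spatial_shape = obj$spatial_shape,
               seed_context = obj$seed_context)
}
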