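# Shared generators for random test tensors.

# random array with the requested number of axes; extents in 2..max_extent
random_array <- function(n_axes, max_extent = 6, dtype = c("double",
                                                           "integer")) {
  dtype <- match.arg(dtype)
  d <- sample(2:max_extent, n_axes, replace = TRUE)
  n <- prod(d)
  v <- if (dtype == "integer") {
    sample.int(1000L, n, replace = TRUE)
  } else {
    stats::rnorm(n)
  }
  array(v, d)
}

# array whose entries are all distinct (so every shift is detectable)
injective_array <- function(n_axes, max_extent = 4) {
  d <- sample(2:max_extent, n_axes, replace = TRUE)
  array(sample.int(prod(d)), d)
}

# naive reference: shift along `axis` by looping over every index,
# out[d] = in[(d + step) mod D]; independent of the package's vectorized path
naive_shift <- function(a, axis, step) {
  d <- dim(a)
  out <- array(a[1], d)
  idx_grid <- as.matrix(expand.grid(lapply(d, seq_len)))
  src <- idx_grid
  src[, axis] <- ((idx_grid[, axis] - 1L + step) %% d[axis]) + 1L
  out[idx_grid] <- a[src]
  out
}
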