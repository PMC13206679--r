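# Deterministic synthetic fixtures: geometric phantoms with ground-truth
# masks, a positional-confound classification set, and metrics/timing tables
# with planted structure. Every generator is a pure function of its
# arguments and seed.

#' Generate a geometric phantom with a ground-truth mask
#'
#' Places `n_objects` filled geometric objects (disks and axis-aligned
#' squares in 2D; balls and cubes in 3D) at random positions, fully inside
#' the spatial extent, over an additive Gaussian noise background. The mask
#' labels object voxels 1 and background 0.
#'
#' @param spatial_shape Integer vector of 2 or 3 spatial extents.
#' @param channels Number of channel bands (0 for a channel-less tensor).
#'   Object intensity is replicated across channels.
#' @param n_objects Number of objects, >= 1.
#' @param intensity_range Length-2 numeric range for object intensities.
#' @param noise_sd Standard deviation of the background Gaussian noise.
#' @param seed Integer seed; fully determines the output.
#' @return List with `image` and `mask` (`data_tensor`s; the mask is
#'   channel-less).
#' @export
make_phantom <- function(spatial_shape = c(28, 28), channels = 1,
                         n_objects = 2, intensity_range = c(0.6, 1.0),
                         noise_sd = 0.05, seed = 1) {
  spatial_shape <- as.integer(spatial_shape)
  nd <- length(spatial_shape)
  if (!nd %in% c(2L, 3L)) {
    sulba_stop("spatial_shape must have 2 or 3 axes", "invalid_spec_error")
  }
  max_r <- (min(spatial_shape) - 1) %/% 4
  if (max_r < 1) {
    sulba_stop("spatial extent too small to fit any object",
               "invalid_spec_error")
  }
  with_seed(seed, {
    noise <- array(stats::rnorm(prod(spatial_shape), 0, noise_sd),
                   spatial_shape)
    mask <- array(0L, spatial_shape)
    canvas <- array(0, spatial_shape)
    for (i in seq_len(n_objects)) {
      r <- sample.int(max_r, 1L)
      center <- vapply(spatial_shape, function(D) {
        r + sample.int(D - 2L * r, 1L)
      }, numeric(1))
      shape_kind <- if (i %% 2L == 1L) "round" else "box"
      obj <- object_support(spatial_shape, center, r, shape_kind)
      intensity <- stats::runif(1, intensity_range[1], intensity_range[2])
      canvas[obj] <- intensity
      mask[obj] <- 1L
    }
    img <- canvas + noise
    if (channels >= 1) {
      img <- array(rep(img, each = channels), c(channels, spatial_shape))
      image <- data_tensor(img, c("channel", rep("spatial", nd)))
    } else {
      image <- data_tensor(img)
    }
    list(image = image, mask = data_tensor(mask))
  })
}

# internal: logical support of a ball/cube of radius r centred at `center`
object_support <- function(spatial_shape, center, r, kind) {
  grids <- lapply(seq_along(spatial_shape), function(k) {
    g <- slice.index(array(0, spatial_shape), k)
    g - center[k]
  })
  switch(kind,
         round = Reduce(`+`, lapply(grids, function(g) g^2)) <= r^2,
         diamond = Reduce(`+`, lapply(grids, function(g) abs(g))) <= r,
         box = Reduce(`&`, lapply(grids, function(g) abs(g) <= r)))
}

#' Positional-confound two-class dataset
#'
#' Builds a shape-classification task in which object position is confounded
#' with the data split: the two classes — a filled diamond of radius `r`
#' (area `2r^2 + 2r + 1`) and a filled square of matched area — are
#' distinguishable by shape alone and carry identical total intensity mass,
#' but in the training split all object centres sit inside a fixed position
#' band, while the test split is generated identically and then cyclically
#' displaced by `test_shift` along the first spatial axis. A model that keys
#' on absolute position collapses on the displaced test set; a
#' position-invariant one does not. Matching the class masses keeps the
#' residual discriminative signal purely geometric (the classes' marginal
#' intensity profiles), which is exactly what survives position
#' marginalization.
#'
#' @param n_per_class Training (and test) images per class.
#' @param spatial_shape 2D spatial extents.
#' @param radius Diamond radius; the square's half-width is chosen so the
#'   two areas match (exactly at the default radius 3: 25 pixels each).
#' @param band Length-2 integer range of permitted object-centre coordinates
#'   (applied to both axes). The default is a single fixed position — the
#'   purest positional confound; widening the band smears the class
#'   templates and weakens the demonstration.
#' @param test_shift Cyclic displacement of the test images along axis 1.
#' @param noise_sd Background noise SD.
#' @param seed Integer seed.
#' @return List with `train` and `test`, each a list of `images` (list of
#'   2D arrays) and `labels` (integer 1/2, exactly balanced).
#' @export
make_positional_confound_dataset <- function(n_per_class = 100,
                                             spatial_shape = c(16, 16),
                                             radius = 3,
                                             band = NULL,
                                             test_shift = 8,
                                             noise_sd = 0.1,
                                             seed = 1) {
  spatial_shape <- as.integer(spatial_shape)
  if (length(spatial_shape) != 2L) {
    sulba_stop("positional-confound dataset is 2D", "invalid_spec_error")
  }
  if (is.null(band)) {
    band <- c(radius + 2L, radius + 2L)
  }
  if (band[1] <= radius || band[2] + radius > min(spatial_shape)) {
    sulba_stop("band and radius do not fit the spatial extent",
               "invalid_spec_error")
  }
  if (test_shift < 0 || test_shift >= spatial_shape[1]) {
    sulba_stop("test_shift must lie in 0..D1-1 (cyclic)",
               "invalid_spec_error")
  }
  # square half-width matching the diamond's area 2r^2 + 2r + 1
  square_hw <- max(1L, as.integer(round((sqrt(2 * radius^2 + 2 * radius + 1)
                                         - 1) / 2)))
  draw_split <- function() {
    labels <- rep(c(1L, 2L), each = n_per_class)
    band_positions <- seq(band[1], band[2])
    images <- lapply(labels, function(lab) {
      center <- c(band_positions[sample.int(length(band_positions), 1L)],
                  band_positions[sample.int(length(band_positions), 1L)])
      kind <- if (lab == 1L) "diamond" else "box"
      r_use <- if (lab == 1L) radius else square_hw
      obj <- object_support(spatial_shape, center, r_use, kind)
      img <- array(stats::rnorm(prod(spatial_shape), 0, noise_sd),
                   spatial_shape)
      img[obj] <- img[obj] + 1
      img
    })
    list(images = images, labels = labels)
  }
  with_seed(seed, {
    train <- draw_split()
    test <- draw_split()
    if (test_shift > 0) {
      test$images <- lapply(test$images, cyclic_shift,
                            axis = 1, step = test_shift)
    }
    list(train = train, test = test)
  })
}

#' Metrics-table fixture with a planted dominant technique
#'
#' Draws a long-format metrics table on the 0-100 scale in which
#' `planted_best` strictly dominates every (dataset, architecture, metric)
#' cell; the other techniques (including `"baseline"`) scatter around a
#' per-cell base level.
#'
#' @param n_techniques Total number of techniques, >= 2 (includes the
#'   baseline and the planted best).
#' @param n_datasets,n_architectures Table extents, >= 1.
#' @param n_metrics Metrics per cell.
#' @param planted_best Name of the dominant technique.
#' @param seed Integer seed.
#' @return A validated metrics data.frame; technique names are `"baseline"`,
#'   `planted_best`, and `"technique_3"`, ... for the rest.
#' @export
make_metrics_fixture <- function(n_techniques = 4, n_datasets = 3,
                                 n_architectures = 2, n_metrics = 5,
                                 planted_best = "sulba", seed = 1) {
  if (n_techniques < 2L) {
    sulba_stop("need at least baseline + planted best",
               "invalid_spec_error")
  }
  techniques <- c("baseline", planted_best)
  if (n_techniques > 2L) {
    techniques <- c(techniques,
                    paste0("technique_", seq(3L, n_techniques)))
  }
  datasets <- paste0("dataset_", seq_len(n_datasets))
  archs <- paste0("arch_", seq_len(n_architectures))
  metrics <- paste0("metric_", seq_len(n_metrics))
  with_seed(seed, {
    rows <- list()
    for (d in datasets) for (a in archs) for (m in metrics) {
      base_level <- stats::runif(1, 65, 85)
      vals <- stats::setNames(
        pmin(pmax(base_level + stats::rnorm(length(techniques), 0, 3), 0),
             95),
        techniques)
      vals[planted_best] <- min(max(vals) + stats::runif(1, 1, 5), 100)
      rows[[length(rows) + 1L]] <-
        data.frame(technique = techniques, dataset = d, architecture = a,
                   metric = m, value = unname(vals),
                   stringsAsFactors = FALSE)
    }
    t <- do.call(rbind, rows)
    rownames(t) <- NULL
    validate_metrics_table(t)
    t
  })
}

#' Timing-table fixture with planted per-epoch overheads
#'
#' Baseline epochs cost `base_seconds`; each listed technique's epochs cost
#' `base_seconds + overhead + jitter`. With zero jitter the measured
#' overhead over E epochs and n experiments is exactly
#' `n * E * planted_overhead`.
#'
#' @param n_experiments,n_epochs Grid extents, >= 1.
#' @param overheads Named numeric vector of per-epoch overheads in seconds,
#'   one per technique (the baseline is added automatically at overhead 0).
#' @param base_seconds Baseline cost per epoch.
#' @param jitter_sd SD of Gaussian per-epoch jitter (costs floored at 0).
#' @param seed Integer seed.
#' @return A timing data.frame with columns
#'   `technique, experiment, epoch, seconds`.
#' @export
make_timing_fixture <- function(n_experiments = 1, n_epochs = 100,
                                overheads = c(sulba = 0.45),
                                base_seconds = 1.0, jitter_sd = 0,
                                seed = 1) {
  if (any(overheads < 0)) {
    sulba_stop("overheads must be non-negative", "invalid_spec_error")
  }
  all_over <- c(baseline = 0, overheads)
  with_seed(seed, {
    rows <- list()
    for (tech in names(all_over)) {
      for (ex in seq_len(n_experiments)) {
        secs <- base_seconds + all_over[[tech]] +
          stats::rnorm(n_epochs, 0, jitter_sd)
        rows[[length(rows) + 1L]] <-
          data.frame(technique = tech,
                     experiment = paste0("experiment_", ex),
                     epoch = seq_len(n_epochs),
                     seconds = pmax(secs, 0),
                     stringsAsFactors = FALSE)
      }
    }
    t <- do.call(rbind, rows)
    rownames(t) <- NULL
    t
  })
}
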