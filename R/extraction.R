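# Per-phase, per-ROI feature extraction with the fixed study configuration:
# fixed 25 HU bin width anchored at the ROI minimum, original + LoG (sigma
# 1.5 mm) image types, no resampling, no re-segmentation window, no shape
# features. 93 features per image type per ROI; with two image types and
# two ROIs this gives 372 features per phase.

#' Extraction configuration
#'
#' @param bin_width fixed discretisation bin width in HU (default 25).
#' @param log_sigma Laplacian-of-Gaussian scale in mm (default 1.5, medium
#'   edge texture); `NULL` disables the LoG image type.
#' @param engine_version identifier recorded in output metadata (feature
#'   counts are engine-version dependent).
#' @return An `extraction_config` object.
#' @export
extraction_config <- function(bin_width = 25, log_sigma = 1.5,
                              engine_version = "phase4d-features-1") {
  stopifnot(bin_width > 0)
  image_types <- "original"
  if (!is.null(log_sigma)) {
    stopifnot(log_sigma > 0)
    image_types <- c(image_types, sprintf("log-sigma-%g", log_sigma))
  }
  structure(list(bin_width = bin_width, log_sigma = log_sigma,
                 image_types = image_types, engine_version = engine_version),
            class = "extraction_config")
}

# separable 1-D convolution along one axis, replicate padding at the edges
convolve_axis <- function(arr, kernel, axis) {
  dims <- dim(arr)
  r <- (length(kernel) - 1L) / 2L
  out <- apply(arr, setdiff(1:3, axis), function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    vapply(seq_len(n), function(i) sum(kernel * vp[i:(i + 2 * r)]), numeric(1))
  })
  perm <- order(c(axis, setdiff(1:3, axis)))
  aperm(array(out, c(dims[axis], dims[setdiff(1:3, axis)])), perm)
}

gauss_kernels <- function(sigma, spacing) {
  lapply(spacing, function(s) {
    r <- max(1L, ceiling(4 * sigma / s))
    x <- (-r:r) * s
    g0 <- exp(-x^2 / (2 * sigma^2))
    g0 <- g0 / sum(g0)
    g2 <- (x^2 / sigma^4 - 1 / sigma^2) * exp(-x^2 / (2 * sigma^2))
    g2 <- (g2 - mean(g2)) * s / (sigma * sqrt(2 * pi))  # zero-sum: flat fields map to 0
    list(g0 = g0, g2 = g2)
  })
}

#' Laplacian-of-Gaussian filtered image
#'
#' Separable LoG at physical scale `sigma` mm on anisotropic spacing:
#' the sum over axes of the second Gaussian derivative along that axis and
#' Gaussian smoothing along the others. Edges use replicate padding; the
#' second-derivative kernels are zero-sum, so constant images map to zero.
#'
#' @param image an [image_volume].
#' @param sigma scale in mm.
#' @return An [image_volume] of filtered values.
#' @export
log_filter <- function(image, sigma = 1.5) {
  stopifnot(inherits(image, "image_volume"), sigma > 0)
  ks <- gauss_kernels(sigma, image$spacing)
  acc <- array(0, dim(image$data))
  for (axis in 1:3) {
    tmp <- image$data
    for (ax2 in 1:3) {
      k <- if (ax2 == axis) ks[[ax2]]$g2 else ks[[ax2]]$g0
      tmp <- convolve_axis(tmp, k, ax2)
    }
    acc <- acc + tmp
  }
  structure(list(data = acc, spacing = image$spacing, origin = image$origin),
            class = "image_volume")
}

#' Extract the feature panel from one image/ROI pair
#'
#' Computes the 93 first-order and texture features per configured image
#' type. Discretisation starts at the ROI minimum of the (possibly filtered)
#' image with the configured bin width. ROIs below the 64-voxel minimum are
#' rejected.
#'
#' @param image an [image_volume] (original HU).
#' @param mask a [binary_mask] on the same grid.
#' @param config an [extraction_config].
#' @param filtered optional pre-computed named list of filtered
#'   [image_volume]s keyed by image type, to avoid re-filtering per ROI.
#' @return Named numeric vector, names `imagetype|class|Feature`.
#' @export
extract_roi_features <- function(image, mask, config = extraction_config(),
                                 filtered = NULL) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "binary_mask"),
            inherits(config, "extraction_config"))
  if (!identical(dim(image$data), dim(mask$mask)))
    stop("image and mask grids are not congruent")
  if (!min_volume_check(mask))
    stop("exclusion: ROI below the 64-voxel minimum (",
         mask_voxel_count(mask), " voxels)")
  roi_idx <- which(mask$mask)
  voxel_volume <- prod(image$spacing)
  out <- numeric(0)
  for (it in config$image_types) {
    vals <- if (it == "original") {
      image$data
    } else if (!is.null(filtered) && it %in% names(filtered)) {
      filtered[[it]]$data
    } else {
      log_filter(image, config$log_sigma)$data
    }
    panel <- compute_feature_panel(vals, roi_idx, dim(image$data),
                                   config$bin_width, voxel_volume)
    if (any(!is.finite(panel)))
      warning("non-finite feature value(s): ",
              paste(names(panel)[!is.finite(panel)], collapse = ", "))
    out <- c(out, setNames(panel, paste0(it, "|", names(panel))))
  }
  out
}

#' Extract a cohort phase-feature table
#'
#' Loops over patients, phases and the two ROIs (tumour, peritumour),
#' applying [extract_roi_features()]. A patient missing any phase, or with an
#' ROI below the volume minimum on any phase, is skipped with a logged
#' reason, mirroring upstream cohort exclusions.
#'
#' @param images nested list `images[[patient]][[phase]]` of [image_volume].
#' @param masks nested list `masks[[patient]][[phase]]`, each a list with
#'   elements `tumour` and `peritumour` ([binary_mask]).
#' @param config an [extraction_config].
#' @param phases character vector of phase labels (default from the images).
#' @param verbose log per-patient progress via `message()`.
#' @return A [phase_feature_table]; skipped patients recorded in attribute
#'   `"skipped"` (named character vector of reasons).
#' @export
extract_cohort <- function(images, masks, config = extraction_config(),
                           phases = NULL, verbose = FALSE) {
  patients <- names(images)
  stopifnot(length(patients) > 0, identical(sort(patients), sort(names(masks))))
  phases <- phases %||% names(images[[1]])
  rois <- c("tumour", "peritumour")
  skipped <- character(0)
  results <- list()
  feature_names <- NULL
  for (pat in patients) {
    have <- phases %in% names(images[[pat]]) & phases %in% names(masks[[pat]])
    if (!all(have)) {
      skipped[pat] <- paste("missing phase(s):", paste(phases[!have], collapse = ", "))
      message("skipping ", pat, ": ", skipped[pat])
      next
    }
    pat_vals <- list()
    ok <- TRUE
    for (ph in phases) {
      img <- images[[pat]][[ph]]
      flt <- NULL
      if (!is.null(config$log_sigma)) {
        flt <- setNames(list(log_filter(img, config$log_sigma)), config$image_types[2])
      }
      for (roi in rois) {
        fv <- tryCatch(
          extract_roi_features(img, masks[[pat]][[ph]][[roi]], config, filtered = flt),
          error = function(e) e)
        if (inherits(fv, "error")) {
          skipped[pat] <- paste0(roi, " phase ", ph, ": ", conditionMessage(fv))
          message("skipping ", pat, ": ", skipped[pat])
          ok <- FALSE
          break
        }
        pat_vals[[paste(ph, roi, sep = "\r")]] <- fv
      }
      if (!ok) break
    }
    if (!ok) next
    if (is.null(feature_names)) feature_names <- names(pat_vals[[1]])
    results[[pat]] <- pat_vals
    if (verbose) message("extracted ", pat, " (", length(phases), " phases)")
  }
  if (!length(results)) stop("no patients could be extracted")
  tab <- phase_feature_table(NULL, features = feature_names,
                             patients = names(results), phases = phases, rois = rois)
  for (pat in names(results)) {
    for (key in names(results[[pat]])) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      tab$values[, pat, parts[1], parts[2]] <- results[[pat]][[key]][feature_names]
    }
  }
  attr(tab, "skipped") <- skipped
  attr(tab, "metadata") <- list(engine_version = config$engine_version,
                                bin_width = config$bin_width,
                                log_sigma = config$log_sigma)
  tab
}
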