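# Per-phase ROI geometry: mask translation, motion amplitude, the 3 mm
# peritumoural band, high-density correction, and the 64-voxel minimum.
#
# Images and masks are plain 3-D arrays carrying physical voxel spacing (mm).
# Distances are Euclidean on physical spacing with voxel membership decided
# by centre position.

#' Construct a CT image volume
#'
#' @param data numeric 3-D array of Hounsfield units.
#' @param spacing numeric length-3 voxel spacing in mm (x, y, z).
#' @param origin physical position of the first voxel centre, mm.
#' @return An `image_volume` object.
#' @export
image_volume <- function(data, spacing = c(1.17, 1.17, 3), origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3, length(spacing) == 3, all(spacing > 0))
  rng <- range(data, na.rm = TRUE)
  if (rng[1] < -1100 || rng[2] > 3100)
    stop("HU values outside plausible CT range [-1100, 3100]")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' Construct a binary mask on an image grid
#'
#' @param mask logical 3-D array (TRUE = inside the region).
#' @param spacing voxel spacing in mm, must match the paired volume.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(mask, spacing = c(1.17, 1.17, 3)) {
  stopifnot(length(dim(mask)) == 3, is.logical(mask), length(spacing) == 3)
  structure(list(mask = mask, spacing = as.numeric(spacing)), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %s grid, %d voxels set, spacing %s mm\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

mask_voxel_count <- function(mask) sum(mask$mask)

#' Translate a mask by a physical displacement
#'
#' Shifts the mask by the nearest whole number of voxels per axis
#' (`round(t / spacing)`); no interpolation, so the voxel count is preserved.
#' An error is raised if any set voxel would leave the grid.
#'
#' @param mask a [binary_mask].
#' @param t numeric length-3 translation in mm.
#' @return Translated [binary_mask] on the same grid.
#' @export
translate_mask <- function(mask, t) {
  stopifnot(inherits(mask, "binary_mask"), length(t) == 3, all(is.finite(t)))
  shift <- round(t / mask$spacing)
  dims <- dim(mask$mask)
  idx <- which(mask$mask, arr.ind = TRUE)
  if (!nrow(idx)) return(mask)
  new_idx <- sweep(idx, 2, shift, "+")
  if (any(new_idx < 1) || any(new_idx[, 1] > dims[1]) ||
      any(new_idx[, 2] > dims[2]) || any(new_idx[, 3] > dims[3]))
    stop("out-of-bounds: translation pushes mask voxels off the grid")
  out <- array(FALSE, dims)
  out[new_idx] <- TRUE
  binary_mask(out, mask$spacing)
}

#' Tumour motion amplitude from per-phase translations
#'
#' Combines the per-axis range (max minus min) of the tumour translations
#' over all phases as a vector: `||(range_x, range_y, range_z)||_2`, in mm.
#'
#' @param translations numeric matrix, one row per phase, columns tx, ty, tz
#'   in mm; the reference phase row is the zero vector.
#' @return Motion amplitude in mm (scalar).
#' @export
motion_amplitude <- function(translations) {
  translations <- as.matrix(translations)
  if (nrow(translations) < 2) stop("need translations for at least 2 phases")
  stopifnot(ncol(translations) == 3, all(is.finite(translations)))
  rng <- apply(translations, 2, function(v) diff(range(v)))
  sqrt(sum(rng^2))
}

# Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
# separable per axis with physical spacing. Returns, for every voxel, the
# squared distance (mm^2) to the nearest TRUE voxel centre.
edt_squared <- function(mask, spacing) {
  if (!any(mask)) stop("distance transform of an empty mask")
  BIG <- 1e30
  f <- array(ifelse(mask, 0, BIG), dim(mask))
  dims <- dim(f)
  for (axis in 1:3) {
    s <- spacing[axis]
    f <- apply(f, setdiff(1:3, axis), edt_1d, s = s)
    # apply() returns axis-first; restore original axis order
    perm <- order(c(axis, setdiff(1:3, axis)))
    f <- aperm(array(f, c(dims[axis], dims[setdiff(1:3, axis)])), perm)
  }
  f[f > BIG / 2] <- Inf
  f
}

# 1-D lower envelope of parabolas on sample positions x_i = (i-1)*s.
edt_1d <- function(f, s) {
  n <- length(f)
  if (n == 1L) return(f)
  x <- (seq_len(n) - 1) * s
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      p <- v[k]
      sx <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * x[q] - 2 * x[p])
      if (sx <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- sx
    z[k + 1] <- Inf
  }
  d <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1] < x[q]) k <- k + 1L
    p <- v[k]
    d[q] <- (x[q] - x[p])^2 + f[p]
  }
  d
}

#' Peritumoural band around a tumour mask
#'
#' Voxels whose centre lies within `inner` mm inside or `outer` mm outside
#' the tumour surface, measured as Euclidean distance (on physical spacing)
#' to the nearest voxel centre across the surface. The band, the remaining
#' tumour core and the exterior partition the grid.
#'
#' @param gtv a non-empty [binary_mask] of the gross tumour volume.
#' @param inner,outer band half-widths in mm (defaults 3 and 3).
#' @return [binary_mask] of the band.
#' @export
peritumour_band <- function(gtv, inner = 3, outer = 3) {
  stopifnot(inherits(gtv, "binary_mask"))
  if (!any(gtv$mask)) stop("empty GTV mask")
  if (all(gtv$mask)) stop("GTV fills the grid; band undefined")
  d_to_gtv <- sqrt(edt_squared(gtv$mask, gtv$spacing))
  d_to_ext <- sqrt(edt_squared(!gtv$mask, gtv$spacing))
  band <- (!gtv$mask & d_to_gtv <= outer) | (gtv$mask & d_to_ext <= inner)
  if (!any(band)) stop("peritumoural band is empty (sub-voxel structure?)")
  binary_mask(band, gtv$spacing)
}

# 26-connected neighbour offsets (excluding the centre).
offsets26 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

# One 26-neighbourhood dilation by explicit shifting (grid edges clipped).
dilate26 <- function(mask, dims) {
  out <- mask
  for (r in seq_len(nrow(offsets26))) {
    out <- out | shift_array(mask, offsets26[r, ], dims)
  }
  out
}

shift_array <- function(mask, off, dims) {
  out <- array(FALSE, dims)
  src <- lapply(1:3, function(a) {
    i <- seq_len(dims[a]) - off[a]
    i[i >= 1 & i <= dims[a]]
  })
  dst <- lapply(1:3, function(a) src[[a]] + off[a])
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

#' Remove high-density normal tissue from a peritumoural band
#'
#' Band voxels outside the tumour whose Hounsfield value exceeds
#' `hu_threshold` (chest wall, diaphragm, bone) are removed together with
#' the band voxels 26-adjacent to them; the surviving band is then eroded
#' by one voxel against removed and exterior voxels so that only voxels fully
#' interior to the corrected band (or abutting the tumour core) remain.
#' Removal is deliberately local (one-voxel adjacency, not a transitive fill
#' of the band): the band shell is a single connected region, so a
#' transitive rule would discard the whole band whenever any high-density
#' structure touches it, instead of trimming the attached structure.
#'
#' @param band peritumoural band [binary_mask].
#' @param gtv tumour [binary_mask] on the same grid.
#' @param image paired [image_volume].
#' @param hu_threshold removal threshold in HU (default 0: soft tissue kept).
#' @return [binary_mask] of the corrected band; if it is empty the mask is
#'   returned with attribute `excluded = TRUE` and a warning, signalling the
#'   patient must be dropped from peritumoural analysis.
#' @export
correct_high_density <- function(band, gtv, image, hu_threshold = 0) {
  stopifnot(inherits(band, "binary_mask"), inherits(gtv, "binary_mask"),
            inherits(image, "image_volume"))
  dims <- dim(band$mask)
  stopifnot(identical(dims, dim(gtv$mask)), identical(dims, dim(image$data)))
  outside <- band$mask & !gtv$mask
  seeds <- outside & (image$data > hu_threshold)
  removed <- (seeds | dilate26(seeds, dims)) & outside
  surviving <- band$mask & !removed
  # keep voxels whose whole 26-neighbourhood lies in the surviving band or
  # the tumour core; everything else (removed, exterior, off-grid) erodes
  interior_ok <- surviving | gtv$mask
  eroded <- surviving & !dilate26(!pad_false(interior_ok), dims)
  out <- binary_mask(eroded, band$spacing)
  if (!any(eroded)) {
    warning("corrected peritumoural band is empty; exclude patient from peritumour analysis")
    attr(out, "excluded") <- TRUE
  }
  out
}

# Treat off-grid neighbours as exterior: complement inside the grid already
# covers them because shift_array clips at edges, but edge voxels must see
# the outside world as not-interior. We emulate this by marking edge-adjacent
# exteriority explicitly.
pad_false <- function(mask) {
  dims <- dim(mask)
  edge <- array(FALSE, dims)
  edge[1, , ] <- TRUE; edge[dims[1], , ] <- TRUE
  edge[, 1, ] <- TRUE; edge[, dims[2], ] <- TRUE
  edge[, , 1] <- TRUE; edge[, , dims[3]] <- TRUE
  mask & !edge  # edge voxels count as having an exterior neighbour
}

#' Minimum-volume rule for texture analysis
#'
#' Masks below 64 voxels are considered too small for meaningful texture
#' features and are excluded.
#'
#' @param mask a [binary_mask].
#' @param min_voxels inclusive lower bound (default 64).
#' @return `TRUE` if the mask has at least `min_voxels` voxels.
#' @export
min_volume_check <- function(mask, min_voxels = 64) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$mask) >= min_voxels
}
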