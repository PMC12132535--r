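#' Pair of co-registered 3-D volumes
#'
#' Container for the two scalar fields compared by the overlap analysis: a
#' functional-contrast t-statistic map and a simulated electric-field
#' magnitude map, sharing one brain mask, voxel grid and voxel-to-world
#' (MNI mm) affine. The analysis is restricted to in-mask voxels.
#'
#' @param tmap,efield 3-D numeric arrays of identical dimensions.
#' @param mask 3-D logical array of the same dimensions (default: voxels
#'   where both fields are finite).
#' @param voxel_size Length-3 voxel edge lengths, mm. Default 2.5 mm
#'   isotropic.
#' @param affine 4 x 4 voxel-to-world transform; default a scaled identity
#'   centring the grid at the world origin.
#' @return An object of class \code{"volume_pair"}.
#' @export
volume_pair <- function(tmap, efield, mask = NULL,
                        voxel_size = c(2.5, 2.5, 2.5), affine = NULL) {
  stopifnot(is.array(tmap), is.array(efield), length(dim(tmap)) == 3L)
  if (!identical(dim(tmap), dim(efield)))
    stop("'tmap' and 'efield' must have identical dimensions",
         call. = FALSE)
  if (is.null(mask)) mask <- is.finite(tmap) & is.finite(efield)
  stopifnot(is.logical(mask))
  if (!identical(dim(mask), dim(tmap)))
    stop("'mask' dimensions must match the volumes", call. = FALSE)
  mask <- mask & is.finite(tmap) & is.finite(efield)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- -voxel_size * (dim(tmap) + 1) / 2
  }
  stopifnot(all(dim(affine) == c(4, 4)))
  structure(list(tmap = tmap, efield = efield, mask = mask,
                 voxel_size = voxel_size, affine = affine),
            class = "volume_pair")
}

#' @export
print.volume_pair <- function(x, ...) {
  cat(sprintf("Volume pair %s, %d in-mask voxels (%.3g x %.3g x %.3g mm)\n",
              paste(dim(x$tmap), collapse = " x "), sum(x$mask),
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

# squared distance of every voxel centre to a point, in voxel units
voxel_dist2 <- function(shape, centre) {
  ax <- (seq_len(shape[1]) - centre[1])^2
  ay <- (seq_len(shape[2]) - centre[2])^2
  az <- (seq_len(shape[3]) - centre[3])^2
  outer(outer(ax, ay, "+"), az, "+")
}

#' Generate a synthetic co-registered volume pair
#'
#' Produces a stand-in for one participant's functional t-map and simulated
#' e-field magnitude with a controllable degree of spatial co-localisation.
#' Inside an ellipsoidal "brain" mask, the t-map is a sum of Gaussian
#' activation blobs (one principal plus \code{n_blobs - 1} weaker
#' secondary blobs) over low-amplitude noise. The e-field is a smooth
#' exponential decay from a source point: at \code{overlap_strength = 1}
#' the source sits on the principal activation blob (strong
#' co-localisation), at 0 it sits at a mask-edge point drawn independently
#' of the blob layout, and intermediate values interpolate linearly, so
#' the expected rank-based mutual information between the two fields
#' increases with \code{overlap_strength}.
#'
#' @param shape Length-3 voxel dimensions, each at least 8.
#' @param overlap_strength Co-localisation dial in \eqn{[0, 1]}.
#' @param seed Integer seed.
#' @param n_blobs Number of activation blobs. Default 3.
#' @param noise_sd SD of additive t-map noise (breaks rank ties). Default
#'   0.1.
#' @return A [volume_pair()].
#' @examples
#' vp <- generate_volume_pair(c(16, 16, 16), overlap_strength = 1, seed = 2)
#' mutual_information_percent(vp)
#' @export
generate_volume_pair <- function(shape = c(24, 24, 24),
                                 overlap_strength = 0.5, seed = 1L,
                                 n_blobs = 3, noise_sd = 0.1) {
  stopifnot(length(shape) == 3L)
  shape <- as.integer(shape)
  if (any(shape < 8L))
    stop("each axis of 'shape' must be at least 8 voxels", call. = FALSE)
  if (overlap_strength < 0 || overlap_strength > 1)
    stop("'overlap_strength' must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  centre <- (shape + 1) / 2
  radii <- 0.45 * shape
  # ellipsoidal mask
  gx <- ((seq_len(shape[1]) - centre[1]) / radii[1])^2
  gy <- ((seq_len(shape[2]) - centre[2]) / radii[2])^2
  gz <- ((seq_len(shape[3]) - centre[3]) / radii[3])^2
  mask <- outer(outer(gx, gy, "+"), gz, "+") <= 1

  # principal blob well inside the mask; secondaries anywhere inside
  blob_centre <- function(frac) {
    repeat {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2)) * stats::runif(1)^(1 / 3)
      p <- centre + frac * radii * u
      if (mask[round(p[1]), round(p[2]), round(p[3])]) return(p)
    }
  }
  principal <- blob_centre(0.6)
  sigma <- 0.12 * min(shape)
  tmap <- 5 * exp(-voxel_dist2(shape, principal) / (2 * sigma^2))
  if (n_blobs > 1) {
    for (b in seq_len(n_blobs - 1)) {
      tmap <- tmap + stats::runif(1, 1, 2.5) *
        exp(-voxel_dist2(shape, blob_centre(0.9)) /
              (2 * (sigma * stats::runif(1, 0.6, 1.2))^2))
    }
  }
  tmap <- tmap + stats::rnorm(length(tmap), 0, noise_sd)

  # e-field source interpolates from an independently drawn mask-edge point
  # (no systematic geometric relation to the blob) to the principal blob
  u <- stats::rnorm(3)
  edge <- centre + u / sqrt(sum((u / radii)^2))
  src <- (1 - overlap_strength) * edge + overlap_strength * principal
  lambda <- 0.5 * mean(radii)
  efield <- exp(-sqrt(voxel_dist2(shape, src)) / lambda)

  dim(tmap) <- shape
  dim(efield) <- shape
  volume_pair(tmap, efield, mask)
}
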