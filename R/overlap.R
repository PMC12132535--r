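#' Rank-transform a volume within a mask
#'
#' Replaces each in-mask voxel value by its rank, ordered from highest to
#' lowest (the largest value receives rank 1); ties receive the average of
#' the ranks they span. Out-of-mask voxels are \code{NA}. Because only the
#' ordering enters, the transform -- and everything downstream of it -- is
#' invariant to any strictly monotone transformation of the input values.
#'
#' @param volume 3-D numeric array.
#' @param mask 3-D logical array of the same dimensions; at least 2 in-mask
#'   voxels.
#' @return A 3-D array of ranks (\code{NA} outside the mask).
#' @export
rank_transform <- function(volume, mask = NULL) {
  stopifnot(is.array(volume))
  if (is.null(mask)) mask <- is.finite(volume)
  stopifnot(is.logical(mask), identical(dim(mask), dim(volume)))
  vals <- volume[mask]
  if (length(vals) < 2L)
    stop("need at least 2 in-mask voxels", call. = FALSE)
  if (diff(range(vals)) == 0)
    stop("constant volume: no ordering to rank", call. = FALSE)
  out <- array(NA_real_, dim(volume))
  out[mask] <- rank(-vals, ties.method = "average")
  out
}

# equal-count discretisation of a rank vector into `bins` bins (1..bins)
bin_ranks <- function(r, bins) {
  pmin(bins, pmax(1L, ceiling(bins * r / length(r))))
}

# entropy (nats) of a count table
entropy_nats <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Rank-based mutual information between two volumes, as a percentage
#'
#' The overlap statistic: both volumes are rank-transformed within the
#' shared mask, the ranks are discretised into \code{bins} equal-count
#' bins per map, and the mutual information of the joint bin histogram is
#' computed in natural log units,
#' \deqn{I(A; B) = H(A) + H(B) - H(A, B).}
#' The result is normalised by the smaller marginal entropy
#' \eqn{\min(H(A), H(B))} -- the maximum mutual information attainable for
#' these marginals -- and expressed as a percentage, so identical maps give
#' 100\% and independent maps give values near 0. With equal-count bins
#' the normaliser equals \eqn{\log(\mathrm{bins})} in the absence of ties;
#' tie structure and the in-mask voxel count make the attainable maximum
#' specific to each volume pair.
#'
#' @param pair A [volume_pair()].
#' @param bins Number of rank bins per map, at least 2. Default 10.
#' @return An object of class \code{"overlap_result"}: list with
#'   \code{mi_percent}, \code{mi_nats}, \code{h_min} (the normaliser),
#'   \code{n_voxels}, \code{bins}.
#' @examples
#' vp <- generate_volume_pair(c(16, 16, 16), overlap_strength = 1, seed = 1)
#' mutual_information_percent(vp)
#' @export
mutual_information_percent <- function(pair, bins = 10) {
  stopifnot(inherits(pair, "volume_pair"))
  bins <- as.integer(bins)
  if (bins < 2L) stop("'bins' must be at least 2", call. = FALSE)
  n <- sum(pair$mask)
  if (n < 4L * bins)
    stop("too few in-mask voxels for the requested bin count",
         call. = FALSE)
  ra <- rank_transform(pair$tmap, pair$mask)[pair$mask]
  rb <- rank_transform(pair$efield, pair$mask)[pair$mask]
  ba <- bin_ranks(ra, bins)
  bb <- bin_ranks(rb, bins)
  joint <- table(ba, bb)
  ha <- entropy_nats(rowSums(joint))
  hb <- entropy_nats(colSums(joint))
  hab <- entropy_nats(joint)
  mi <- ha + hb - hab
  h_min <- min(ha, hb)
  structure(list(mi_percent = 100 * mi / h_min, mi_nats = mi,
                 h_min = h_min, n_voxels = n, bins = bins),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Rank-based mutual information: %.2f%% of maximum (%.4f / %.4f nats, %d voxels, %d bins)\n",
    x$mi_percent, x$mi_nats, x$h_min, x$n_voxels, x$bins))
  invisible(x)
}

#' Correlate per-participant overlap with behavioural modulation
#'
#' Pearson correlation (with two-sided p-value) between per-participant
#' mutual-information percentages and the ipsilateral-minus-contralateral
#' behavioural difference.
#'
#' @param mi_values Numeric vector of overlap percentages.
#' @param behavior Numeric vector of behavioural differences, same length
#'   (at least 3).
#' @return List with \code{r} and \code{p}.
#' @export
correlate_overlap_behavior <- function(mi_values, behavior) {
  if (length(mi_values) != length(behavior) || length(mi_values) < 3L)
    stop("need two equal-length vectors of at least 3 values",
         call. = FALSE)
  if (stats::sd(mi_values) == 0 || stats::sd(behavior) == 0)
    stop("zero variance input", call. = FALSE)
  ct <- stats::cor.test(mi_values, behavior, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Voxel-rank correlation between the two maps
#'
#' Pearson correlation of the two in-mask rank fields -- equivalently, a
#' rank (Spearman-type) correlation of the raw voxel values.
#'
#' @param pair A [volume_pair()].
#' @return Correlation in \eqn{[-1, 1]}.
#' @export
voxel_rank_correlation <- function(pair) {
  stopifnot(inherits(pair, "volume_pair"))
  ra <- rank_transform(pair$tmap, pair$mask)[pair$mask]
  rb <- rank_transform(pair$efield, pair$mask)[pair$mask]
  stats::cor(ra, rb)
}

#' Euclidean distance between two MNI coordinates
#'
#' @param a,b Length-3 numeric MNI coordinates, mm.
#' @return Distance in mm.
#' @examples
#' mni_distance(c(0, 0, 0), c(3, 4, 0))   # 5
#' @export
mni_distance <- function(a, b) {
  stopifnot(length(a) == 3L, length(b) == 3L,
            all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}
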