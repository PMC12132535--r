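#' Random-dot-kinematogram stimulus parameters
#'
#' Geometry and kinematics of the RDK stimulus: 150 white dots of 0.12 deg
#' diameter inside an 8-deg circular aperture (about 3 dots per square
#' degree), centred 12 deg left or right of fixation, drifting at
#' 13.3 deg/s. A dot survives for 47 ms of coherent travel or until it
#' reaches the aperture edge, after which it reappears at a random position
#' inside the aperture (keeping the dot count, and hence density,
#' constant). Each stimulus lasts 106 ms at a 60 Hz frame rate. Signal dots
#' move along one of the eight cardinal/diagonal trajectories (45 deg
#' steps); noise dots take a fresh random position every frame.
#'
#' @param n_dots Number of dots. Default 150.
#' @param dot_diameter Dot diameter, deg. Default 0.12.
#' @param aperture_diameter Aperture diameter, deg. Default 8.
#' @param eccentricity Aperture centre offset from fixation, deg (display
#'   offset only; dot coordinates are aperture-centred). Default 12.
#' @param speed Dot speed, deg/s. Default 13.3.
#' @param lifetime_ms Maximum coherent-travel lifetime, ms. Default 47.
#' @param duration_ms Stimulus duration, ms. Default 106.
#' @param frame_rate Display refresh, Hz. Default 60.
#' @param directions Allowed trajectory directions, deg (counter-clockwise
#'   from rightward). Default the eight 45-deg steps.
#' @return An object of class \code{"rdk_params"}. The implied dot density
#'   (dots per square degree) is stored as element \code{density}.
#' @export
rdk_params <- function(n_dots = 150, dot_diameter = 0.12,
                       aperture_diameter = 8, eccentricity = 12,
                       speed = 13.3, lifetime_ms = 47, duration_ms = 106,
                       frame_rate = 60, directions = seq(0, 315, by = 45)) {
  stopifnot(n_dots >= 1, aperture_diameter > 0, speed >= 0,
            lifetime_ms > 0, duration_ms > 0, frame_rate > 0)
  p <- list(n_dots = as.integer(n_dots), dot_diameter = dot_diameter,
            aperture_diameter = aperture_diameter,
            eccentricity = eccentricity, speed = speed,
            lifetime_ms = lifetime_ms, duration_ms = duration_ms,
            frame_rate = frame_rate, directions = directions)
  p$density <- n_dots / (pi * (aperture_diameter / 2)^2)
  p$n_frames <- as.integer(round(duration_ms / 1000 * frame_rate))
  # displacement steps a dot may take before forced replacement
  p$lifetime_steps <- as.integer(floor(lifetime_ms / (1000 / frame_rate)))
  p$step <- speed / frame_rate
  structure(p, class = "rdk_params")
}

#' @export
print.rdk_params <- function(x, ...) {
  cat(sprintf(
    "RDK: %d dots, %.3g deg aperture (%.2f dots/deg^2), %.3g deg/s\n",
    x$n_dots, x$aperture_diameter, x$density, x$speed))
  cat(sprintf(
    "  %d frames @ %g Hz (%.3g ms), lifetime %d steps of %.4g deg\n",
    x$n_frames, x$frame_rate, x$duration_ms, x$lifetime_steps, x$step))
  invisible(x)
}

# n uniform points in a disc of given radius
runif_disc <- function(n, radius) {
  r <- radius * sqrt(stats::runif(n))
  th <- 2 * pi * stats::runif(n)
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Generate an RDK frame stack
#'
#' Simulates the dot positions of one RDK presentation. On every frame each
#' dot is independently relabelled signal with probability
#' \code{coherence/100} (the default "different" rule: signal identity is
#' redrawn each frame rather than fixed per dot, which minimises motion
#' streaks). Signal dots displace by \code{speed/frame_rate} along the
#' trajectory direction; noise dots appear at a fresh random position.
#' A dot that completes its lifetime of coherent displacement steps, or
#' whose displacement would leave the circular aperture, is replaced at a
#' random position inside the aperture, so every frame contains exactly
#' \code{n_dots} dots. Dots start with uniformly staggered ages so
#' replacements are spread asynchronously across frames.
#'
#' @param coherence Nominal motion coherence, percent, in \eqn{[0, 100]}.
#' @param direction Trajectory direction in degrees; must be one of
#'   \code{params$directions}.
#' @param params An [rdk_params()] object.
#' @param seed Integer seed; the stack is a deterministic function of it.
#' @param signal_rule \code{"different"} (default): signal labels redrawn
#'   independently every frame. \code{"same"}: a fixed fraction of dots
#'   keeps the signal label for the whole presentation.
#' @return An object of class \code{"rdk_frames"}: a data frame with
#'   columns \code{frame}, \code{dot}, \code{x}, \code{y} (aperture-centred
#'   deg; x rightward, y upward) and \code{role} (\code{"signal"} or
#'   \code{"noise"}), with the parameters attached as attributes.
#' @examples
#' stack <- generate_rdk(50, direction = 90, seed = 1)
#' empirical_signal_fraction(stack)
#' @export
generate_rdk <- function(coherence, direction = 0, params = rdk_params(),
                         seed = 1L,
                         signal_rule = c("different", "same")) {
  signal_rule <- match.arg(signal_rule)
  stopifnot(inherits(params, "rdk_params"))
  if (!is.numeric(coherence) || length(coherence) != 1L ||
      coherence < 0 || coherence > 100)
    stop("'coherence' must lie in [0, 100]", call. = FALSE)
  if (!direction %in% params$directions)
    stop("'direction' must be one of the configured trajectories",
         call. = FALSE)
  set.seed(seed)
  n <- params$n_dots
  radius <- params$aperture_diameter / 2
  dx <- params$step * cos(direction * pi / 180)
  dy <- params$step * sin(direction * pi / 180)
  p_signal <- coherence / 100

  pos <- runif_disc(n, radius)
  # staggered ages: dots are part-way through their lifetime at onset
  age <- sample.int(params$lifetime_steps + 1L, n, replace = TRUE) - 1L
  fixed_signal <- if (signal_rule == "same")
    stats::runif(n) < p_signal else NULL

  frames <- vector("list", params$n_frames)
  for (f in seq_len(params$n_frames)) {
    role <- if (signal_rule == "same") fixed_signal else
      stats::runif(n) < p_signal
    if (f > 1L) {
      # signal dots translate; replace those that expire or exit
      idx_sig <- which(role)
      if (length(idx_sig)) {
        newx <- pos[idx_sig, 1] + dx
        newy <- pos[idx_sig, 2] + dy
        expired <- age[idx_sig] >= params$lifetime_steps |
          sqrt(newx^2 + newy^2) > radius
        keep <- idx_sig[!expired]
        pos[keep, 1] <- pos[keep, 1] + dx
        pos[keep, 2] <- pos[keep, 2] + dy
        age[keep] <- age[keep] + 1L
        rep_ <- idx_sig[expired]
        if (length(rep_)) {
          pos[rep_, ] <- runif_disc(length(rep_), radius)
          age[rep_] <- 0L
        }
      }
      # noise dots relocate uniformly every frame
      idx_noise <- which(!role)
      if (length(idx_noise)) {
        pos[idx_noise, ] <- runif_disc(length(idx_noise), radius)
        age[idx_noise] <- 0L
      }
    }
    frames[[f]] <- data.frame(frame = f, dot = seq_len(n),
                              x = pos[, 1], y = pos[, 2],
                              role = ifelse(role, "signal", "noise"),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, frames)
  attr(out, "params") <- params
  attr(out, "coherence") <- coherence
  attr(out, "direction") <- direction
  attr(out, "seed") <- seed
  class(out) <- c("rdk_frames", "data.frame")
  out
}

#' Realised signal fraction of a frame stack
#'
#' Mean over frames of the fraction of dots labelled signal; validates that
#' the generator realises the nominal coherence in the displayed dot
#' statistics (up to binomial sampling noise).
#'
#' @param stack An [generate_rdk()] frame stack.
#' @return Fraction in \eqn{[0, 1]}.
#' @export
empirical_signal_fraction <- function(stack) {
  stopifnot(inherits(stack, "rdk_frames"))
  if (nrow(stack) == 0L) stop("empty frame stack", call. = FALSE)
  per_frame <- tapply(stack$role == "signal", stack$frame, mean)
  mean(per_frame)
}

#' Export a frame stack to a columnar text file
#'
#' Writes the per-frame dot positions and role labels as tab-separated
#' text (columns frame, dot, x, y, role) for external visualisation.
#'
#' @param stack An [generate_rdk()] frame stack.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_rdk_frames <- function(stack, path) {
  stopifnot(inherits(stack, "rdk_frames"))
  utils::write.table(as.data.frame(stack), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
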