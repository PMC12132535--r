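#' Configuration of an adaptive thresholding session
#'
#' Bundles the parameters of one interleaved adaptive session: two hemifield
#' tracks run in parallel, each receiving \code{trials_per_hemifield} trials
#' split evenly across \code{blocks} blocks (the defaults give 160 trials
#' per hemifield over 5 blocks, i.e. 32 per hemifield per block). The next
#' stimulus is always placed at the \code{p_target}-accuracy level of the
#' currently selected hypothesis.
#'
#' @param trials_per_hemifield Trials per hemifield track; must be divisible
#'   by \code{blocks}. Default 160.
#' @param blocks Number of blocks. Default 5.
#' @param p_target Target accuracy for stimulus placement and threshold
#'   readout. Default 0.70.
#' @param initial_level Coherence of the first trial of each track, percent.
#'   Default 100 (a maximally visible first trial).
#' @param threshold_mode \code{"all-blocks"}: a single track per hemifield
#'   accumulates all trials and the threshold is read from the final
#'   selected hypothesis. \code{"per-block-average"}: the track is reset at
#'   each block boundary and the five per-block thresholds are averaged (the
#'   variant used by the earlier study this design replicates).
#' @param seed Integer seed; one session seed deterministically derives
#'   independent per-track response streams and the interleaving stream.
#' @return An object of class \code{"session_config"}.
#' @export
session_config <- function(trials_per_hemifield = 160, blocks = 5,
                           p_target = 0.70, initial_level = 100,
                           threshold_mode = c("all-blocks",
                                              "per-block-average"),
                           seed = 1L) {
  threshold_mode <- match.arg(threshold_mode)
  trials_per_hemifield <- as.integer(trials_per_hemifield)
  blocks <- as.integer(blocks)
  if (trials_per_hemifield < 1L || blocks < 1L)
    stop("'trials_per_hemifield' and 'blocks' must be positive",
         call. = FALSE)
  if (trials_per_hemifield %% blocks != 0L)
    stop("'trials_per_hemifield' must be divisible by 'blocks'",
         call. = FALSE)
  if (initial_level < 0 || initial_level > 100)
    stop("'initial_level' must lie in [0, 100]", call. = FALSE)
  if (p_target <= 0 || p_target >= 1)
    stop("'p_target' must lie in (0, 1)", call. = FALSE)
  structure(list(trials_per_hemifield = trials_per_hemifield,
                 blocks = blocks, p_target = p_target,
                 initial_level = initial_level,
                 threshold_mode = threshold_mode,
                 seed = as.integer(seed)),
            class = "session_config")
}

#' Create an empty adaptive track
#'
#' A track holds one hemifield's adaptive state: the hypothesis grid, the
#' trial history, the running per-hypothesis log-likelihoods, and the index
#' of the currently selected (maximum-likelihood) hypothesis.
#'
#' @param hemifield \code{"left"} or \code{"right"}.
#' @param grid A [hypothesis_grid()] object.
#' @return An object of class \code{"mlp_track"}.
#' @export
new_track <- function(hemifield = c("left", "right"),
                      grid = hypothesis_grid()) {
  hemifield <- match.arg(hemifield)
  stopifnot(inherits(grid, "hypothesis_grid"))
  structure(list(hemifield = hemifield, grid = grid,
                 history = NULL, loglik = numeric(grid$count),
                 mle_index = NA_integer_),
            class = "mlp_track")
}

#' Level to present on the next trial of a track
#'
#' On the first trial this is the configured initial level; afterwards it is
#' the \code{p_target}-accuracy level of the current maximum-likelihood
#' hypothesis, clipped to the presentable range \eqn{[0, 100]}.
#'
#' @param track An [new_track()] object.
#' @param config A [session_config()] object.
#' @return A coherence level in \eqn{[0, 100]}.
#' @export
next_level <- function(track, config = session_config()) {
  stopifnot(inherits(track, "mlp_track"))
  if (is.null(track$history) || nrow(track$history) == 0L)
    return(config$initial_level)
  pf <- grid_member(track$grid, track$mle_index)
  min(100, max(0, level_for_target(pf, config$p_target)))
}

#' Append one trial to a track and reselect the hypothesis
#'
#' Extends the track's history with one trial record and updates the
#' maximum-likelihood hypothesis. The per-hypothesis log-likelihoods are
#' accumulated incrementally (one additive term per trial), which is exactly
#' equivalent to [select_mle()] on the full history because the grid is
#' fixed and the trial log-likelihoods are additive.
#'
#' @param track An [new_track()] object.
#' @param record A one-row trial record (see [trial_record()]); its
#'   hemifield must match the track's.
#' @return The updated track.
#' @export
update_track <- function(track, record) {
  stopifnot(inherits(track, "mlp_track"))
  if (nrow(record) != 1L)
    stop("'record' must be a single trial", call. = FALSE)
  if (record$hemifield != track$hemifield)
    stop(sprintf("record hemifield '%s' does not match track '%s'",
                 record$hemifield, track$hemifield), call. = FALSE)
  track$history <- if (is.null(track$history)) record else
    rbind(track$history, record)
  track$loglik <- track$loglik +
    trial_loglik_increment(track$grid, record$level, record$correct)
  track$mle_index <- which.max(track$loglik)
  track
}

#' Threshold read-out of a track
#'
#' The estimated motion-coherence threshold: the \code{p_target} level of
#' the currently selected hypothesis, clipped to \eqn{[0, 100]}.
#'
#' @inheritParams next_level
#' @return Threshold in percent coherence, or \code{NA} before any trial.
#' @export
track_threshold <- function(track, config = session_config()) {
  stopifnot(inherits(track, "mlp_track"))
  if (is.na(track$mle_index)) return(NA_real_)
  pf <- grid_member(track$grid, track$mle_index)
  min(100, max(0, level_for_target(pf, config$p_target)))
}

#' Run an interleaved two-hemifield adaptive session
#'
#' Simulates one full thresholding session of the maximum-likelihood
#' procedure (MLP): two independent adaptive tracks, one per hemifield, are
#' interleaved in randomised order within each block. After every trial the
#' track's maximum-likelihood hypothesis is reselected over the fixed grid
#' and the next stimulus of that track is placed at its target-accuracy
#' level. With \code{threshold_mode = "all-blocks"} each hemifield's
#' threshold is the target level of the hypothesis selected after all
#' trials; with \code{"per-block-average"} the track restarts every block
#' and the per-block thresholds are averaged.
#'
#' A single session seed derives three independent streams (left responses,
#' right responses, interleaving order), so a track's response sequence --
#' and hence its entire maximum-likelihood trajectory -- does not depend on
#' how the two hemifields happen to be interleaved.
#'
#' @param observer_left,observer_right [sim_observer()] objects generating
#'   the responses for the two hemifield tracks.
#' @param config A [session_config()] object.
#' @param grid A [hypothesis_grid()] shared by both tracks; its
#'   \code{p_target} should match \code{config$p_target}.
#' @return An object of class \code{"mlp_session"}: list with
#'   \code{threshold_left}, \code{threshold_right}, \code{trial_log} (all
#'   trials in presentation order, with presented level, correctness,
#'   hemifield, block, within-track index, and the running threshold
#'   estimate), \code{final_level} per hemifield (the last presented
#'   level, logged alongside the hypothesis-based read-out),
#'   \code{block_thresholds} (per hemifield, in per-block-average mode),
#'   \code{config}, and \code{grid}.
#' @examples
#' obs <- sim_observer(psychfun(alpha = 40))
#' fit <- mlp_session(obs, obs, session_config(seed = 7))
#' coef(fit)
#' @export
mlp_session <- function(observer_left, observer_right,
                        config = session_config(),
                        grid = hypothesis_grid(p_target = config$p_target)) {
  stopifnot(inherits(observer_left, "sim_observer"),
            inherits(observer_right, "sim_observer"),
            inherits(config, "session_config"),
            inherits(grid, "hypothesis_grid"))
  per_block <- config$trials_per_hemifield %/% config$blocks

  # one session seed -> three independent streams
  set.seed(config$seed)
  stream_seeds <- sample.int(.Machine$integer.max, 3L)
  u <- list(left = with_seed(stream_seeds[1],
                             stats::runif(config$trials_per_hemifield)),
            right = with_seed(stream_seeds[2],
                              stats::runif(config$trials_per_hemifield)))
  order_per_block <- with_seed(stream_seeds[3], lapply(
    seq_len(config$blocks),
    function(b) sample(rep(c("left", "right"), per_block))))

  observers <- list(left = observer_left, right = observer_right)
  tracks <- list(left = new_track("left", grid),
                 right = new_track("right", grid))
  n_done <- c(left = 0L, right = 0L)
  reset_blocks <- config$threshold_mode == "per-block-average"
  block_thr <- list(left = numeric(0), right = numeric(0))
  log_rows <- vector("list", 2L * config$trials_per_hemifield)
  row_i <- 0L

  for (b in seq_len(config$blocks)) {
    if (reset_blocks && b > 1L) {
      tracks$left <- new_track("left", grid)
      tracks$right <- new_track("right", grid)
    }
    for (hf in order_per_block[[b]]) {
      lvl <- next_level(tracks[[hf]], config)
      n_done[hf] <- n_done[hf] + 1L
      correct <- respond(observers[[hf]], lvl, u = u[[hf]][n_done[hf]])
      rec <- trial_record(lvl, correct, hf, block_index = b,
                          trial_index = n_done[hf])
      tracks[[hf]] <- update_track(tracks[[hf]], rec)
      rec$threshold_est <- track_threshold(tracks[[hf]], config)
      row_i <- row_i + 1L
      log_rows[[row_i]] <- rec
    }
    if (reset_blocks) {
      block_thr$left <- c(block_thr$left,
                          track_threshold(tracks$left, config))
      block_thr$right <- c(block_thr$right,
                           track_threshold(tracks$right, config))
    }
  }

  trial_log <- do.call(rbind, log_rows)
  thr <- if (reset_blocks) {
    c(left = mean(block_thr$left), right = mean(block_thr$right))
  } else {
    c(left = track_threshold(tracks$left, config),
      right = track_threshold(tracks$right, config))
  }
  last_lvl <- vapply(c("left", "right"), function(hf) {
    x <- trial_log$level[trial_log$hemifield == hf]
    x[length(x)]
  }, 0)

  structure(list(threshold_left = unname(thr["left"]),
                 threshold_right = unname(thr["right"]),
                 trial_log = trial_log,
                 final_level = last_lvl,
                 block_thresholds = if (reset_blocks) block_thr else NULL,
                 tracks = tracks, config = config, grid = grid),
            class = "mlp_session")
}

# evaluate expr under a temporary seed without disturbing reproducibility
# of the surrounding derived-stream logic
with_seed <- function(seed, expr) {
  set.seed(seed)
  expr
}

#' Replay a response history through the hypothesis selector
#'
#' Computes the sequence of selected midpoints that the adaptive procedure
#' would produce for a fixed, already-recorded response history (the
#' selection after trial 1, 2, ..., n). Deterministic given the log; used to
#' verify that a logged session is exactly reproducible and that the two
#' hemifield tracks never mix.
#'
#' @param grid A [hypothesis_grid()] object.
#' @param history A trial history data frame (see [trial_record()]).
#' @return Numeric vector of selected midpoints, one per trial.
#' @export
replay_mle_sequence <- function(grid, history) {
  stopifnot(inherits(grid, "hypothesis_grid"))
  if (is.null(history) || nrow(history) == 0L)
    stop("'history' must contain at least one trial", call. = FALSE)
  ll <- numeric(grid$count)
  out <- numeric(nrow(history))
  for (i in seq_len(nrow(history))) {
    ll <- ll + trial_loglik_increment(grid, history$level[i],
                                      history$correct[i])
    out[i] <- grid$alphas[which.max(ll)]
  }
  out
}

#' @export
print.mlp_session <- function(x, ...) {
  cat("Adaptive MLP thresholding session\n")
  cat(sprintf("  %d trials per hemifield over %d blocks (mode: %s)\n",
              x$config$trials_per_hemifield, x$config$blocks,
              x$config$threshold_mode))
  cat(sprintf("  threshold (%.0f%% accuracy): left %.2f%%, right %.2f%% coherence\n",
              100 * x$config$p_target, x$threshold_left, x$threshold_right))
  invisible(x)
}

#' @export
coef.mlp_session <- function(object, ...) {
  c(left = object$threshold_left, right = object$threshold_right)
}

#' @export
summary.mlp_session <- function(object, ...) {
  log <- object$trial_log
  acc <- tapply(log$correct, log$hemifield, mean)
  out <- list(thresholds = coef(object), accuracy = acc,
              n_trials = table(log$hemifield),
              final_level = object$final_level,
              block_thresholds = object$block_thresholds,
              config = object$config)
  class(out) <- "summary.mlp_session"
  out
}

#' @export
print.summary.mlp_session <- function(x, ...) {
  cat("Adaptive MLP session summary\n")
  for (hf in c("left", "right")) {
    cat(sprintf("  %-5s: threshold %6.2f%%, observed accuracy %.3f over %d trials (last level %.2f%%)\n",
                hf, x$thresholds[hf], x$accuracy[hf], x$n_trials[hf],
                x$final_level[hf]))
  }
  if (!is.null(x$block_thresholds))
    cat("  per-block thresholds averaged (per-block-average mode)\n")
  invisible(x)
}

#' @export
plot.mlp_session <- function(x, ...) {
  log <- x$trial_log
  graphics::plot(NULL, xlim = c(1, x$config$trials_per_hemifield),
                 ylim = c(0, 100), xlab = "trial within hemifield",
                 ylab = "coherence (%)",
                 main = "Adaptive track: presented levels and running threshold")
  cols <- c(left = "steelblue", right = "firebrick")
  for (hf in c("left", "right")) {
    sub <- log[log$hemifield == hf, ]
    graphics::points(sub$trial_index, sub$level, col = cols[hf], pch = 20,
                     cex = 0.6)
    graphics::lines(sub$trial_index, sub$threshold_est, col = cols[hf])
  }
  graphics::legend("topright", legend = names(cols), col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}
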