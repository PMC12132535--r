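#' Logistic psychometric function
#'
#' Constructs a logistic psychometric function for an m-alternative
#' forced-choice task,
#' \deqn{p(x) = \gamma + \frac{1 - \gamma}{1 + e^{-\beta (x - \alpha)}},}
#' where \eqn{x} is the stimulus level (here, percent motion coherence on a
#' 0--100 scale), \eqn{\alpha} is the midpoint, \eqn{\beta > 0} the slope per
#' percentage point of coherence, and \eqn{\gamma \in [0, 1)} the lower
#' asymptote (the guess rate; 1/8 = 0.125 for an 8AFC task). The function
#' rises from \eqn{\gamma} at \eqn{x \to -\infty} to 1 at
#' \eqn{x \to +\infty} and equals \eqn{\gamma + (1-\gamma)/2} at
#' \eqn{x = \alpha}.
#'
#' @param alpha Midpoint on the coherence axis (percent coherence).
#' @param beta Slope, per percent coherence; must be positive.
#' @param gamma Guess rate (lower asymptote), in \eqn{[0, 1)}.
#' @return An object of class \code{"psychfun"}: a list with elements
#'   \code{alpha}, \code{beta}, \code{gamma}.
#' @seealso [prob_correct()], [level_for_target()], [hypothesis_grid()]
#' @examples
#' pf <- psychfun(alpha = 30)
#' prob_correct(30, pf)          # 0.5625 at the midpoint
#' level_for_target(pf, 0.70)    # coherence giving 70% accuracy
#' @export
psychfun <- function(alpha, beta = 0.5, gamma = 0.125) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a single positive number", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma >= 1)
    stop("'gamma' must be a single number in [0, 1)", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "psychfun")
}

#' @export
print.psychfun <- function(x, ...) {
  cat(sprintf(
    "Logistic psychometric function: alpha = %.4g, beta = %.4g, gamma = %.4g\n",
    x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Probability of a correct response
#'
#' Evaluates the psychometric function at stimulus level \code{x}. Strictly
#' increasing in \code{x}, strictly decreasing in the midpoint \code{alpha},
#' with limits \code{gamma} and 1.
#'
#' @param x Stimulus level(s), percent coherence; any real value is accepted.
#' @param pf A [psychfun()] object.
#' @return Probability of a correct response, in \code{(gamma, 1)};
#'   vectorised over \code{x}.
#' @export
prob_correct <- function(x, pf) {
  stopifnot(inherits(pf, "psychfun"))
  pf$gamma + (1 - pf$gamma) / (1 + exp(-pf$beta * (x - pf$alpha)))
}

#' Stimulus level for a target performance
#'
#' Closed-form inverse of [prob_correct()]: the level \eqn{x} at which the
#' psychometric function predicts accuracy \code{p_target},
#' \deqn{x = \alpha - \frac{1}{\beta}\,
#'   \ln\!\frac{1 - p}{p - \gamma}.}
#' In the adaptive procedure this is the "sweet point" at which the next
#' trial is placed (target accuracy 70% by default).
#'
#' @param pf A [psychfun()] object.
#' @param p_target Target probability correct, strictly between
#'   \code{pf$gamma} and 1.
#' @return Stimulus level in percent coherence (unclipped; may fall outside
#'   \eqn{[0, 100]} for extreme midpoints).
#' @export
level_for_target <- function(pf, p_target = 0.70) {
  stopifnot(inherits(pf, "psychfun"))
  if (!is.numeric(p_target) || length(p_target) != 1L ||
      p_target <= pf$gamma || p_target >= 1)
    stop(sprintf("'p_target' must lie strictly between gamma = %g and 1",
                 pf$gamma), call. = FALSE)
  pf$alpha - log((1 - p_target) / (p_target - pf$gamma)) / pf$beta
}

#' Hypothesis grid for the maximum-likelihood procedure
#'
#' Builds the fixed family of candidate psychometric functions over which the
#' adaptive procedure selects. All members share \code{beta} and
#' \code{gamma} and differ only in the midpoint \code{alpha}. Midpoints are
#' spaced linearly so that the \code{p_target}-performance levels of the
#' first and last hypotheses equal the bounds of \code{level_range}: with the
#' defaults, the 150 hypotheses allow any coherence in 0--100% to be the
#' presented 70%-accuracy level.
#'
#' @param count Number of hypotheses (at least 2); default 150.
#' @param beta,gamma Shared slope and guess rate, as in [psychfun()].
#' @param level_range Numeric length-2: range of presentable target levels,
#'   within \eqn{[0, 100]}.
#' @param p_target Target accuracy defining the presentable level of each
#'   hypothesis.
#' @return An object of class \code{"hypothesis_grid"}: list with
#'   \code{alphas} (strictly increasing midpoints), \code{beta},
#'   \code{gamma}, \code{p_target}, \code{count}.
#' @examples
#' g <- hypothesis_grid()
#' range(vapply(seq_len(g$count),
#'              function(i) level_for_target(grid_member(g, i)), 0))
#' @export
hypothesis_grid <- function(count = 150, beta = 0.5, gamma = 0.125,
                            level_range = c(0, 100), p_target = 0.70) {
  if (!is.numeric(count) || length(count) != 1L || count < 2)
    stop("'count' must be an integer >= 2", call. = FALSE)
  count <- as.integer(count)
  stopifnot(is.numeric(level_range), length(level_range) == 2L)
  if (diff(level_range) <= 0)
    stop("'level_range' must be a strictly increasing interval",
         call. = FALSE)
  if (level_range[1] < 0 || level_range[2] > 100)
    stop("'level_range' must lie within [0, 100]", call. = FALSE)
  # offset between a midpoint and its p_target level, shared by all members
  proto <- psychfun(0, beta, gamma)
  offset <- level_for_target(proto, p_target)
  alphas <- seq(level_range[1], level_range[2], length.out = count) - offset
  structure(list(alphas = alphas, beta = beta, gamma = gamma,
                 p_target = p_target, count = count),
            class = "hypothesis_grid")
}

#' @export
print.hypothesis_grid <- function(x, ...) {
  cat(sprintf(
    "Hypothesis grid: %d logistic functions, beta = %g, gamma = %g\n",
    x$count, x$beta, x$gamma))
  cat(sprintf("  midpoints %.4f .. %.4f (target p = %g spans levels %.4f .. %.4f)\n",
              min(x$alphas), max(x$alphas), x$p_target,
              min(x$alphas) + lft_offset(x), max(x$alphas) + lft_offset(x)))
  invisible(x)
}

# level offset x - alpha at the grid's target probability
lft_offset <- function(grid) {
  level_for_target(psychfun(0, grid$beta, grid$gamma), grid$p_target)
}

#' Extract one member of a hypothesis grid
#'
#' @param grid A [hypothesis_grid()] object.
#' @param i Index of the member, 1-based.
#' @return A [psychfun()] object.
#' @export
grid_member <- function(grid, i) {
  stopifnot(inherits(grid, "hypothesis_grid"))
  i <- as.integer(i)
  if (i < 1L || i > grid$count) stop("grid index out of range", call. = FALSE)
  psychfun(grid$alphas[i], grid$beta, grid$gamma)
}

#' Trial records
#'
#' Constructs a data frame of trial records for the adaptive procedure: one
#' row per trial with the presented coherence, response correctness,
#' hemifield, block and within-hemifield trial index.
#'
#' @param level Presented coherence, percent, in \eqn{[0, 100]}.
#' @param correct Logical response correctness.
#' @param hemifield \code{"left"} or \code{"right"}.
#' @param block_index Block number (1-based).
#' @param trial_index Trial number within hemifield (1-based).
#' @return A data frame with class \code{c("trial_log", "data.frame")}.
#' @export
trial_record <- function(level, correct, hemifield = "left",
                         block_index = 1L, trial_index = seq_along(level)) {
  stopifnot(is.numeric(level), is.logical(correct),
            length(level) == length(correct))
  if (any(level < 0 | level > 100))
    stop("trial levels must lie in [0, 100]", call. = FALSE)
  hemifield <- match.arg(hemifield, c("left", "right"))
  structure(
    data.frame(level = level, correct = correct,
               hemifield = rep_len(hemifield, length(level)),
               block_index = rep_len(as.integer(block_index), length(level)),
               trial_index = as.integer(trial_index),
               stringsAsFactors = FALSE),
    class = c("trial_log", "data.frame"))
}

#' Log-likelihood of a trial history under one psychometric function
#'
#' Bernoulli log-likelihood of a response history: the sum over trials of
#' \eqn{\log p(x_i)} for correct responses and \eqn{\log(1 - p(x_i))} for
#' incorrect ones, with \eqn{p} the candidate function evaluated at the
#' presented level. Finite for any candidate with \eqn{\gamma > 0} (a
#' correct response never has zero probability) and any level in
#' \eqn{[0, 100]}.
#'
#' @param history A data frame with columns \code{level} and \code{correct}
#'   (see [trial_record()]); must be non-empty.
#' @param pf A [psychfun()] object.
#' @return The log-likelihood (a single number).
#' @export
log_likelihood <- function(history, pf) {
  if (is.null(history) || nrow(history) == 0L)
    stop("'history' must contain at least one trial", call. = FALSE)
  p <- prob_correct(history$level, pf)
  sum(ifelse(history$correct, log(p), log1p(-p)))
}

#' Maximum-likelihood hypothesis selection
#'
#' Scans every member of the hypothesis grid and returns the one maximising
#' the log-likelihood of the trial history. The argmax is found by a full
#' scan (likelihood along the midpoint grid need not be unimodal); exact
#' ties are broken in favour of the lowest midpoint (the most sensitive
#' hypothesis), deterministically.
#'
#' @param grid A [hypothesis_grid()] object.
#' @param history Non-empty trial history (see [log_likelihood()]).
#' @return A [psychfun()] object, a member of \code{grid}, with attribute
#'   \code{"index"} giving its position in the grid.
#' @export
select_mle <- function(grid, history) {
  stopifnot(inherits(grid, "hypothesis_grid"))
  if (is.null(history) || nrow(history) == 0L)
    stop("'history' must contain at least one trial", call. = FALSE)
  ll <- grid_log_likelihoods(grid, history)
  k <- which.max(ll)  # first maximum = lowest alpha on ties
  out <- grid_member(grid, k)
  attr(out, "index") <- k
  out
}

# vector of log-likelihoods over all grid members; vectorised over the grid
grid_log_likelihoods <- function(grid, history) {
  ll <- numeric(grid$count)
  for (i in seq_len(nrow(history))) {
    p <- grid$gamma + (1 - grid$gamma) /
      (1 + exp(-grid$beta * (history$level[i] - grid$alphas)))
    ll <- ll + if (history$correct[i]) log(p) else log1p(-p)
  }
  ll
}

# single-trial log-likelihood increment over all grid members
trial_loglik_increment <- function(grid, level, correct) {
  p <- grid$gamma + (1 - grid$gamma) /
    (1 + exp(-grid$beta * (level - grid$alphas)))
  if (correct) log(p) else log1p(-p)
}
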