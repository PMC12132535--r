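#' Simulated observer
#'
#' A stochastic observer for validating the adaptive procedure. Responses
#' are Bernoulli draws from a lapse-mixed psychometric function: with
#' probability \code{1 - lapse} the observer responds according to its true
#' psychometric function, and with probability \code{lapse} it guesses
#' (probability correct \code{gamma}), i.e.
#' \deqn{P(\mathrm{correct} \mid x) =
#'   (1 - \lambda)\,p(x) + \lambda\,\gamma.}
#'
#' @param true_pf A [psychfun()] object: the observer's true function.
#' @param lapse Lapse probability in \eqn{[0, 1]}; default 0.
#' @return An object of class \code{"sim_observer"}.
#' @examples
#' obs <- sim_observer(psychfun(alpha = 40))
#' respond(obs, level = 41.3)
#' @export
sim_observer <- function(true_pf, lapse = 0) {
  stopifnot(inherits(true_pf, "psychfun"))
  if (!is.numeric(lapse) || length(lapse) != 1L || lapse < 0 || lapse > 1)
    stop("'lapse' must be a probability in [0, 1]", call. = FALSE)
  structure(list(true_pf = true_pf, lapse = lapse), class = "sim_observer")
}

#' @export
print.sim_observer <- function(x, ...) {
  cat(sprintf("Simulated observer (lapse = %g):\n  ", x$lapse))
  print(x$true_pf)
  invisible(x)
}

#' Simulate one response
#'
#' Draws a Bernoulli response from a simulated observer at a given stimulus
#' level. The draw consumes one uniform variate from the current RNG
#' stream (or from \code{u} if supplied, which makes response streams
#' reproducible independently of call order).
#'
#' @param observer A [sim_observer()] object.
#' @param level Stimulus level, percent coherence in \eqn{[0, 100]}.
#' @param u Optional uniform variate(s) in \eqn{[0, 1)} to compare against
#'   the response probability instead of drawing from the RNG.
#' @return Logical: was the response correct? Vectorised over
#'   \code{level}/\code{u}.
#' @export
respond <- function(observer, level, u = NULL) {
  stopifnot(inherits(observer, "sim_observer"))
  if (any(level < 0 | level > 100))
    stop("'level' must lie in [0, 100]", call. = FALSE)
  p <- (1 - observer$lapse) * prob_correct(level, observer$true_pf) +
    observer$lapse * observer$true_pf$gamma
  if (is.null(u)) u <- stats::runif(length(p))
  u < p
}
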