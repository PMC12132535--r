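#' Study conditions and hemifields
#'
#' The three within-subject stimulation conditions (active high-frequency
#' tRNS over left hMT+, sham over hMT+, active tRNS over the forehead) and
#' the two hemifields relative to the stimulated hemisphere.
#' @name design-levels
#' @keywords internal
NULL

trns_conditions <- c("hMT_active", "hMT_sham", "forehead_active")
trns_hemifields <- c("ipsilateral", "contralateral")

#' Cohort effect structure
#'
#' The generative model for a synthetic cohort of motion-coherence
#' thresholds with the study's within-subject design structure:
#' \deqn{y_{pch} = \mu + b_p + \delta\,(s_{pc} - 1) + \tau_{ch} +
#'   \varepsilon_{pch},}
#' with grand mean \eqn{\mu}, participant random effect
#' \eqn{b_p \sim N(0, \sigma_b^2)}, a linear learning drift \eqn{\delta}
#' per session over the counterbalanced session order \eqn{s_{pc}}, a fixed
#' condition-by-hemifield shift \eqn{\tau_{ch}}, and i.i.d. residual noise
#' \eqn{\varepsilon \sim N(0, \sigma_e^2)}. The default residual SD is
#' \eqn{14.8 / \sqrt{2} \approx 10.47}\%, so that the within-condition
#' ipsilateral-minus-contralateral difference score has SD 14.8\% -- the
#' standard deviation the sampling plan was powered on; the
#' between-participant SD defaults to the same value (an even split of
#' variance between participant and residual).
#'
#' @param n_participants Number of participants. Default 42.
#' @param grand_mean Grand-mean threshold, percent coherence. Default 71.
#' @param subject_sd Between-participant SD, percent. Default
#'   \code{14.8 / sqrt(2)}.
#' @param condition_hemifield_effect Fixed shifts \eqn{\tau_{ch}}: either a
#'   3 x 2 matrix (rows \code{hMT_active}, \code{hMT_sham},
#'   \code{forehead_active}; columns \code{ipsilateral},
#'   \code{contralateral}) or a single number applied to the
#'   \code{hMT_active}/\code{contralateral} cell (a negative value models
#'   contralateral facilitation by active stimulation). Default 0 (the
#'   null).
#' @param session_learning_slope Change in threshold per session, percent
#'   per session (negative = practice improves performance). Default -2.
#' @param residual_sd Residual SD, percent. Default \code{14.8 / sqrt(2)}.
#' @param seed Integer seed.
#' @return An object of class \code{"cohort_effects"}.
#' @export
cohort_effects <- function(n_participants = 42, grand_mean = 71,
                           subject_sd = 14.8 / sqrt(2),
                           condition_hemifield_effect = 0,
                           session_learning_slope = -2,
                           residual_sd = 14.8 / sqrt(2), seed = 1L) {
  if (subject_sd < 0 || residual_sd < 0)
    stop("standard deviations must be non-negative", call. = FALSE)
  if (n_participants < 1) stop("need at least one participant", call. = FALSE)
  eff <- matrix(0, 3, 2,
                dimnames = list(trns_conditions, trns_hemifields))
  if (is.matrix(condition_hemifield_effect)) {
    stopifnot(all(dim(condition_hemifield_effect) == c(3, 2)))
    eff[] <- condition_hemifield_effect[trns_conditions, trns_hemifields]
  } else {
    stopifnot(is.numeric(condition_hemifield_effect),
              length(condition_hemifield_effect) == 1L)
    eff["hMT_active", "contralateral"] <- condition_hemifield_effect
  }
  structure(list(n_participants = as.integer(n_participants),
                 grand_mean = grand_mean, subject_sd = subject_sd,
                 condition_hemifield_effect = eff,
                 session_learning_slope = session_learning_slope,
                 residual_sd = residual_sd, seed = as.integer(seed)),
            class = "cohort_effects")
}

# assign the 6 permutations of the 3 conditions as evenly as possible
counterbalance_orders <- function(n) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  idx <- rep(seq_len(6), length.out = ceiling(n / 6) * 6)[seq_len(n)]
  lapply(idx, function(i) perms[[i]])
}

#' Generate a synthetic cohort threshold table
#'
#' Draws a complete, balanced long-format table of per-participant,
#' per-condition, per-hemifield thresholds under the [cohort_effects()]
#' generative model. Condition order over the three sessions is
#' counterbalanced: each of the six permutations is assigned to
#' \code{n/6} participants when \code{n} is divisible by 6 (42 gives 7
#' each), otherwise to the nearest balanced assignment. Thresholds are
#' truncated to \eqn{[0, 100]} after noise; the number of truncated cells
#' is recorded in attribute \code{"n_truncated"}.
#'
#' @param effects A [cohort_effects()] object.
#' @return A \code{threshold_table}: a data frame with columns
#'   \code{participant}, \code{condition}, \code{hemifield},
#'   \code{session_order}, \code{threshold} (6 rows per participant).
#' @examples
#' tab <- generate_cohort(cohort_effects(n_participants = 12, seed = 3))
#' table(tab$condition, tab$hemifield)
#' @export
generate_cohort <- function(effects = cohort_effects()) {
  stopifnot(inherits(effects, "cohort_effects"))
  set.seed(effects$seed)
  n <- effects$n_participants
  orders <- counterbalance_orders(n)
  subj <- stats::rnorm(n, 0, effects$subject_sd)

  rows <- expand.grid(hemifield = trns_hemifields,
                      condition = trns_conditions,
                      participant = seq_len(n),
                      KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, c(3, 2, 1)]
  cond_idx <- match(rows$condition, trns_conditions)
  rows$session_order <- vapply(seq_len(nrow(rows)), function(i) {
    match(cond_idx[i], orders[[rows$participant[i]]])
  }, 0L)
  eff <- effects$condition_hemifield_effect[
    cbind(rows$condition, rows$hemifield)]
  y <- effects$grand_mean + subj[rows$participant] +
    effects$session_learning_slope * (rows$session_order - 1) +
    eff + stats::rnorm(nrow(rows), 0, effects$residual_sd)
  n_trunc <- sum(y < 0 | y > 100)
  rows$threshold <- pmin(100, pmax(0, y))
  out <- structure(rows, class = c("threshold_table", "data.frame"))
  attr(out, "n_truncated") <- n_trunc
  validate_threshold_table(out)
}

#' Validate a threshold table
#'
#' Checks that a long-format threshold table has the required columns, that
#' thresholds lie in \eqn{[0, 100]}, and that the design is complete (each
#' participant has every condition-by-hemifield cell exactly once).
#' Problems are reported as itemised errors.
#'
#' @param table A data frame with columns \code{participant},
#'   \code{condition}, \code{hemifield}, \code{session_order},
#'   \code{threshold}.
#' @return The table, classed as \code{threshold_table}, invisibly
#'   validated.
#' @export
validate_threshold_table <- function(table) {
  needed <- c("participant", "condition", "hemifield", "session_order",
              "threshold")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  problems <- character(0)
  bad_cond <- !table$condition %in% trns_conditions
  if (any(bad_cond))
    problems <- c(problems, paste0("unknown condition in rows: ",
                                   paste(which(bad_cond), collapse = ", ")))
  bad_hf <- !table$hemifield %in% trns_hemifields
  if (any(bad_hf))
    problems <- c(problems, paste0("unknown hemifield in rows: ",
                                   paste(which(bad_hf), collapse = ", ")))
  bad_thr <- !is.finite(table$threshold) | table$threshold < 0 |
    table$threshold > 100
  if (any(bad_thr))
    problems <- c(problems,
                  paste0("threshold outside [0, 100] in rows: ",
                         paste(which(bad_thr), collapse = ", ")))
  if (length(problems))
    stop(paste(problems, collapse = "\n"), call. = FALSE)
  cells <- table(table$participant,
                 paste(table$condition, table$hemifield))
  if (!all(cells == 1L)) {
    bad <- which(cells != 1L, arr.ind = TRUE)
    stop("incomplete design: ", nrow(bad),
         " participant x condition x hemifield cell(s) missing or duplicated",
         call. = FALSE)
  }
  if (!inherits(table, "threshold_table"))
    class(table) <- c("threshold_table", class(table))
  table
}
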