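#' Summarize one trial arm's WOMAC outcome
#'
#' Holds the pre- and post-intervention means of a WOMAC subscale for one
#' arm, together with the range of the reported scale, so scores reported on
#' different variants of the instrument can be standardized before
#' comparison.
#'
#' @param pre_mean,post_mean Arm means on the reported scale.
#' @param scale Numeric `c(min, max)` of the reported subscale range.
#' @return An object of class `womac_arm`.
#' @examples
#' womac_arm(12, 8, scale = c(0, 20))
#' @export
womac_arm <- function(pre_mean, post_mean, scale) {
  stopifnot(is.numeric(pre_mean), is.numeric(post_mean),
            is.numeric(scale), length(scale) == 2L)
  if (scale[1] >= scale[2]) stop("scale must satisfy min < max", call. = FALSE)
  for (v in c(pre_mean, post_mean)) {
    if (!is.finite(v) || v < scale[1] || v > scale[2]) {
      stop(sprintf("mean %g outside reported scale [%g, %g]",
                   v, scale[1], scale[2]), call. = FALSE)
    }
  }
  structure(list(pre_mean = pre_mean, post_mean = post_mean,
                 scale = unname(as.numeric(scale))), class = "womac_arm")
}

#' Standardized WOMAC subscale bounds
#'
#' The standardized ranges all outcomes are rescaled to before net changes
#' are compared across trials: 0-20 for the pain subscale and 0-68 for the
#' physical function subscale.
#'
#' @param subscale `"pain"` or `"function"`.
#' @return Numeric `c(min, max)`.
#' @export
womac_standard_scale <- function(subscale = c("pain", "function")) {
  subscale <- match.arg(subscale)
  switch(subscale, pain = c(0, 20), "function" = c(0, 68))
}

#' Rescale a WOMAC score between subscale ranges
#'
#' Linear map between scale ranges: endpoints map exactly to endpoints and
#' relative position is preserved. Used to bring trials that report WOMAC on
#' a 0-100 (or other) variant onto the standardized 0-20 pain / 0-68
#' function ranges.
#'
#' @param score Score on the source scale.
#' @param source_scale,target_scale Numeric `c(min, max)` pairs, `min < max`.
#' @return The rescaled score.
#' @examples
#' standardize_womac(34, c(0, 100), c(0, 68)) # 23.12
#' @export
standardize_womac <- function(score, source_scale, target_scale) {
  check_scale <- function(s, what) {
    if (!is.numeric(s) || length(s) != 2L || !all(is.finite(s)) || s[1] >= s[2])
      stop(what, " must be numeric c(min, max) with min < max", call. = FALSE)
  }
  check_scale(source_scale, "source_scale")
  check_scale(target_scale, "target_scale")
  if (any(score < source_scale[1] - 1e-9) || any(score > source_scale[2] + 1e-9)) {
    stop(sprintf("score outside source scale [%g, %g]",
                 source_scale[1], source_scale[2]), call. = FALSE)
  }
  target_scale[1] + (score - source_scale[1]) *
    diff(target_scale) / diff(source_scale)
}

#' Within-arm mean change
#'
#' Pre-intervention mean minus post-intervention mean. Lower WOMAC scores
#' are better, so a positive change is an improvement.
#'
#' @param arm A [womac_arm()].
#' @return The mean change (positive = improvement).
#' @export
mean_change <- function(arm) {
  stopifnot(inherits(arm, "womac_arm"))
  arm$pre_mean - arm$post_mean
}

#' Net change between exercise and control arms
#'
#' The net change is the exercise arm's mean change minus the control arm's
#' mean change, crediting the intervention only with improvement beyond what
#' the control condition achieved.
#'
#' @param exercise_change,control_change Finite mean changes.
#' @return `exercise_change - control_change`.
#' @export
net_change <- function(exercise_change, control_change) {
  stopifnot(is.finite(exercise_change), is.finite(control_change))
  exercise_change - control_change
}

#' Net change as a percentage of a reference level
#'
#' Expresses a net change relative to a positive reference value (by
#' default, the exercise arm's baseline mean on the standardized scale).
#'
#' @param net Net change.
#' @param reference Positive reference value (denominator).
#' @return `100 * net / reference`.
#' @export
percent_net_change <- function(net, reference) {
  if (!is.numeric(reference) || any(!is.finite(reference)) || any(reference <= 0)) {
    stop("`reference` must be positive and finite", call. = FALSE)
  }
  100 * net / reference
}
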