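# Permanganate footprint quantitation: region aggregates, reactive-region
# calling, bubble-fraction calibration, replicate fold-change testing and
# the fractional-occupancy bound.

#' Aggregate permanganate reactivity over a region
#'
#' Background-subtracted sum of band intensities over the thymine positions
#' of a lane region: `sum(max(0, intensity - mean(background)))` over T
#' positions in `region`. The background level is the mean intensity at the
#' supplied background offsets, which must be thymine positions outside the
#' region. Subtraction clamps at zero per position, and the aggregate is a
#' sum (not a mean), so longer bubbles score higher, matching gel-band
#' intuition.
#'
#' @param lane A [lane_profile()].
#' @param region Length-2 numeric, closed TSS-relative interval to
#'   quantify.
#' @param background_offsets Offsets (T positions outside `region`) that
#'   define the background level.
#' @return A single nonnegative aggregate reactivity.
#' @examples
#' lane <- lane_profile(1:10, c(rep(2, 5), rep(7, 3), 2, 2), rep(TRUE, 10))
#' quantify_region(lane, c(6, 8), background_offsets = 1:5)  # 3 x 5 = 15
#' @export
quantify_region <- function(lane, region, background_offsets) {
  if (!inherits(lane, "lane_profile")) {
    stop("`lane` must be a lane_profile", call. = FALSE)
  }
  if (length(region) != 2L || region[1] > region[2]) {
    stop("`region` must be c(a, b) with a <= b", call. = FALSE)
  }
  if (region[1] < min(lane$offset) || region[2] > max(lane$offset)) {
    stop("`region` must lie within the lane", call. = FALSE)
  }
  if (length(background_offsets) == 0L) {
    stop("`background_offsets` must be non-empty", call. = FALSE)
  }
  bg_idx <- match(background_offsets, lane$offset)
  if (anyNA(bg_idx)) stop("background offsets outside the lane", call. = FALSE)
  if (!all(lane$is_thymine[bg_idx])) {
    stop("background offsets must be thymine positions", call. = FALSE)
  }
  if (any(background_offsets >= region[1] & background_offsets <= region[2])) {
    stop("background offsets must lie outside the region", call. = FALSE)
  }
  in_region <- lane$offset >= region[1] & lane$offset <= region[2] &
    lane$is_thymine
  if (!any(in_region)) {
    stop("no thymine positions in the region", call. = FALSE)
  }
  bg <- mean(lane$intensity[bg_idx])
  sum(pmax(0, lane$intensity[in_region] - bg))
}

#' Call the reactive region of a lane
#'
#' Finds the longest run of consecutive thymine positions whose intensity
#' exceeds `background mean + z_threshold * background sd` and returns the
#' closed offset interval from its first to its last qualifying thymine.
#' When `background_offsets` is `NULL` the background statistics are taken
#' robustly from all thymine positions (median and MAD), which leaves a
#' flat lane with no qualifying position. Non-thymine positions between
#' qualifying thymines do not break a run (permanganate only reports on
#' Ts). Ties between equally long runs go to the most upstream one.
#'
#' @param lane A [lane_profile()].
#' @param z_threshold Number of background standard deviations a thymine
#'   must exceed the background mean by.
#' @param background_offsets Optional explicit background thymine offsets
#'   (>= 5 required); default `NULL` for the robust estimate.
#' @return A list of class `reactive_region`: `called`, and when called
#'   `region` (c(first, last) qualifying T offsets) and `n_thymines` in the
#'   run; `called = FALSE` when no position qualifies.
#' @export
call_reactive_region <- function(lane, z_threshold = 2.0,
                                 background_offsets = NULL) {
  if (!inherits(lane, "lane_profile")) {
    stop("`lane` must be a lane_profile", call. = FALSE)
  }
  t_idx <- which(lane$is_thymine)
  if (is.null(background_offsets)) {
    if (length(t_idx) < 5L) {
      stop("need at least 5 thymine positions for background estimation",
           call. = FALSE)
    }
    bg_mean <- median(lane$intensity[t_idx])
    bg_sd <- mad(lane$intensity[t_idx])
  } else {
    if (length(background_offsets) < 5L) {
      stop("need at least 5 background thymine positions", call. = FALSE)
    }
    bg_i <- match(background_offsets, lane$offset)
    if (anyNA(bg_i) || !all(lane$is_thymine[bg_i])) {
      stop("background offsets must be thymine positions in the lane",
           call. = FALSE)
    }
    bg_mean <- mean(lane$intensity[bg_i])
    bg_sd <- sd(lane$intensity[bg_i])
  }

  hot <- lane$intensity[t_idx] > bg_mean + z_threshold * bg_sd
  if (!any(hot)) {
    return(structure(list(called = FALSE, reason = "no reactive thymines"),
                     class = "reactive_region"))
  }
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])] # ties: first (upstream-most)
  first_t <- t_idx[starts[best]]
  last_t <- t_idx[ends[best]]
  structure(
    list(
      called = TRUE,
      region = c(lane$offset[first_t], lane$offset[last_t]),
      n_thymines = r$lengths[best]
    ),
    class = "reactive_region"
  )
}

#' Fit the bubble-fraction calibration line
#'
#' Ordinary least-squares fit of aggregate permanganate signal against the
#' fraction of bubble-containing template, the calibration that justifies
#' reading footprint intensity as fractional occupancy. The slope is the
#' gain per unit bubble fraction and the intercept the background signal.
#'
#' @param fractions Bubble fractions in \[0, 1\]; at least 3 distinct
#'   values.
#' @param signals Aggregate reactivities, one per fraction.
#' @return A list of class `calibration_fit`: `slope`, `intercept`,
#'   `r_squared` (0 for a constant-signal fit).
#' @examples
#' fit <- fit_calibration(c(0, .25, .5, .75, 1), 2 + 8 * c(0, .25, .5, .75, 1))
#' c(fit$slope, fit$intercept, fit$r_squared)  # 8 2 1
#' @export
fit_calibration <- function(fractions, signals) {
  if (length(fractions) != length(signals)) {
    stop("`fractions` and `signals` must have equal length", call. = FALSE)
  }
  if (length(unique(fractions)) < 3L) {
    stop("need at least 3 distinct fractions", call. = FALSE)
  }
  fit <- lm(signals ~ fractions)
  ss_tot <- sum((signals - mean(signals))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(fit$residuals^2) / ss_tot
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = min(1, max(0, r2))
    ),
    class = "calibration_fit"
  )
}

#' Fold change between replicate groups, with a t-test
#'
#' Fold change of treated over control aggregate reactivities, defined as
#' the ratio of group means, with a two-sided independent two-sample t-test
#' (pooled-variance Student's t by default; Welch optionally). The standard
#' deviation of the fold estimate is propagated to first order from the
#' groups' standard errors:
#' `fold * sqrt((se_t / mean_t)^2 + (se_c / mean_c)^2)`.
#'
#' When both groups have zero variance the t-statistic is undefined; the
#' result is flagged (`zero_variance = TRUE`) and the p-value is reported
#' as 1 for identical means, 0 otherwise.
#'
#' @param treated,control Numeric vectors of positive replicate aggregates,
#'   at least 2 each.
#' @param var_equal Pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @return A list of class `fold_change_result`: `fold`, `sd`, `p_value`,
#'   `t_statistic`, `df`, `n_per_group`, `zero_variance`.
#' @examples
#' res <- fold_change_test(c(2.0, 2.4, 1.6), c(1.0, 1.2, 0.8))
#' res$fold  # 2
#' @export
fold_change_test <- function(treated, control, var_equal = TRUE) {
  if (length(treated) < 2L || length(control) < 2L) {
    stop("need at least 2 replicates per group", call. = FALSE)
  }
  if (any(treated <= 0) || any(control <= 0)) {
    stop("aggregates must be positive", call. = FALSE)
  }
  m_t <- mean(treated)
  m_c <- mean(control)
  if (m_c == 0) stop("zero control mean", call. = FALSE)
  fold <- m_t / m_c
  se_t <- sd(treated) / sqrt(length(treated))
  se_c <- sd(control) / sqrt(length(control))
  fold_sd <- fold * sqrt((se_t / m_t)^2 + (se_c / m_c)^2)

  zero_var <- sd(treated) == 0 && sd(control) == 0
  if (zero_var) {
    p <- if (m_t == m_c) 1 else 0
    tt <- list(statistic = NA_real_, parameter = NA_real_)
  } else {
    tt <- stats::t.test(treated, control, var.equal = var_equal)
    p <- tt$p.value
  }
  structure(
    list(
      fold = fold, sd = fold_sd, p_value = p,
      t_statistic = unname(tt$statistic), df = unname(tt$parameter),
      n_per_group = c(treated = length(treated), control = length(control)),
      zero_variance = zero_var
    ),
    class = "fold_change_result"
  )
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("<fold_change_result> fold = %.4g (SD %.4g), p = %.4g%s\n",
              x$fold, x$sd, x$p_value,
              if (x$zero_variance) " [zero-variance groups]" else ""))
  invisible(x)
}

#' Upper bound on pre-activation fractional occupancy
#'
#' If the footprint signal is proportional to the fraction of gene copies
#' occupied by paused polymerase (as the linear bubble-fraction calibration
#' supports) and occupancy after activation cannot exceed 100%, a
#' `fold`-fold signal increase on activation bounds the pre-activation
#' occupancy at `100 / fold` percent. This is an upper bound, never an
#' estimate.
#'
#' @param fold Positive fold increase in pausing signal on activation.
#' @return Maximum pre-activation occupancy in percent, in (0, 100\];
#'   strictly decreasing in `fold`.
#' @examples
#' occupancy_bound(2.338)  # 42.77...%, i.e. ~40% occupancy at most
#' occupancy_bound(1)      # 100: no increase, no constraint
#' @export
occupancy_bound <- function(fold) {
  stopifnot_scalar_number(fold, "fold", positive = TRUE)
  min(100, 100 / fold)
}
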