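# Pause kinetics: normalization and log-linear half-life fitting of
# initiation-block decay series, and the two-state occupancy relation.

#' Normalize a decay series to its untreated point
#'
#' Divides every value by the mean reactivity at `t = 0`, so the untreated
#' sample is 1 and later time points are fractions of it. Idempotent.
#'
#' @param series A [decay_series()].
#' @return The normalized series (`attr(, "normalized")` is `TRUE`).
#' @examples
#' s <- decay_series(c(0, 10), c(1, 1), c(4, 2))
#' normalize_series(s)$value  # 1 0.5
#' @export
normalize_series <- function(series) {
  if (!inherits(series, "decay_series")) {
    stop("`series` must be a decay_series", call. = FALSE)
  }
  m0 <- mean(series$value[series$time == 0])
  if (m0 <= 0) stop("mean value at t = 0 must be > 0", call. = FALSE)
  decay_series(series$time, series$replicate, series$value / m0,
               normalized = TRUE)
}

#' Fit a pause half-life by log-linear regression
#'
#' Fits `ln(value) ~ time` by ordinary least squares across all replicate
#' points (replicates are not pre-averaged, so times with more replicates
#' carry more weight) and converts the slope to a half-life,
#' `t_half = log(2) / (-slope)`. Zero values are floored at `epsilon` with
#' a warning before taking logs. A nonlinear least-squares refinement of
#' the same single-exponential model is available with `method = "nls"`
#' (log-linear start values). A non-decaying series (slope >= 0) is an
#' error, not an estimate.
#'
#' @param series A normalized [decay_series()] (normalize first with
#'   [normalize_series()]) with at least 3 distinct time points.
#' @param method `"loglinear"` (default, closed form) or `"nls"`.
#' @param epsilon Floor applied to zero values before log-transform.
#' @return A list of class `half_life_estimate`: `t_half` (minutes),
#'   `decay_rate` (`log(2) / t_half`, per minute), `fit_r_squared`,
#'   `method`, `n_points`.
#' @examples
#' s <- decay_series(c(0, 10, 20), c(1, 1, 1), c(1, 0.5, 0.25),
#'                   normalized = TRUE)
#' fit_half_life(s)$t_half  # 10
#' @export
fit_half_life <- function(series, method = c("loglinear", "nls"),
                          epsilon = 1e-6) {
  method <- match.arg(method)
  if (!inherits(series, "decay_series")) {
    stop("`series` must be a decay_series", call. = FALSE)
  }
  if (!isTRUE(attr(series, "normalized"))) {
    stop("`series` must be normalized first (see normalize_series())",
         call. = FALSE)
  }
  if (length(unique(series$time)) < 3L) {
    stop("need at least 3 distinct time points", call. = FALSE)
  }
  v <- series$value
  if (any(v <= 0)) {
    warning(sum(v <= 0), " nonpositive value(s) floored at epsilon = ",
            epsilon)
    v <- pmax(v, epsilon)
  }
  fit <- lm(log(v) ~ series$time)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) {
    stop("series does not decay (log-linear slope = ",
         signif(slope, 4), " >= 0 per minute); cannot estimate a half-life",
         call. = FALSE)
  }
  ss_tot <- sum((log(v) - mean(log(v)))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  t_half <- log(2) / (-slope)

  if (method == "nls") {
    nfit <- tryCatch(
      stats::nls(value ~ a * 2^(-time / th), data = series,
                 start = list(a = exp(unname(coef(fit)[1])), th = t_half)),
      error = function(e) NULL
    )
    if (!is.null(nfit)) {
      th_nls <- unname(coef(nfit)["th"])
      if (th_nls > 0) {
        t_half <- th_nls
        pred <- stats::predict(nfit)
        sst <- sum((series$value - mean(series$value))^2)
        r2 <- if (sst == 0) 1 else 1 - sum((series$value - pred)^2) / sst
      }
    }
  }

  structure(
    list(
      t_half = t_half,
      decay_rate = log(2) / t_half,
      fit_r_squared = min(1, max(0, r2)),
      method = method,
      n_points = nrow(series)
    ),
    class = "half_life_estimate"
  )
}

#' @export
print.half_life_estimate <- function(x, ...) {
  cat(sprintf("<half_life_estimate> t1/2 = %.3g min (rate %.3g /min, R^2 %.3f, %s fit)\n",
              x$t_half, x$decay_rate, x$fit_r_squared, x$method))
  invisible(x)
}

#' Steady-state paused-gene occupancy
#'
#' In the two-state view of a promoter - unoccupied until an initiation
#' event (rate `k_init`) deposits a paused polymerase, which departs at the
#' pause-exit rate `log(2) / t_half` - the steady-state fraction of gene
#' copies bearing a paused polymerase is
#' `k_init / (k_init + log(2) / t_half)`. The same promoter signal can
#' therefore come from stable pausing of one polymerase or rapid turnover
#' of many; this relation makes the trade-off explicit.
#'
#' @param k_init Initiation rate per gene copy per minute (> 0).
#' @param t_half Pause half-life in minutes (> 0).
#' @return Fractional occupancy in (0, 1); strictly increasing in both
#'   arguments.
#' @examples
#' steady_state_occupancy(log(2) / 10, 10)  # exit rate == initiation rate: 0.5
#' @export
steady_state_occupancy <- function(k_init, t_half) {
  stopifnot_scalar_number(k_init, "k_init", positive = TRUE)
  stopifnot_scalar_number(t_half, "t_half", positive = TRUE)
  k_off <- log(2) / t_half
  k_init / (k_init + k_off)
}
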