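#' Wilson score interval for a binomial proportion
#'
#' Closed-form score interval obtained by inverting the normal test of the
#' proportion. Reported on the percent scale. The interval is
#' complement-symmetric: the interval for `n - x` successes is the
#' reflection of the interval for `x`.
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (> 0).
#' @param conf_level Two-sided confidence level, default 0.95.
#' @return Numeric length-2 `c(low, high)` in percent.
#' @examples
#' round(wilson_ci(82, 94), 1)  # 79.0 92.5
#' @export
wilson_ci <- function(x, n, conf_level = 0.95) {
  check_xn(x, n, conf_level)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  100 * c(max(0, centre - half), min(1, centre + half))
}

#' Clopper-Pearson exact interval for a binomial proportion
#'
#' The "exact" interval obtained by inverting the binomial tail
#' probabilities, computed through the beta-quantile representation.
#' `x = 0` pins the lower bound at 0; `x = n` pins the upper bound at 100.
#' Reported on the percent scale.
#'
#' @inheritParams wilson_ci
#' @return Numeric length-2 `c(low, high)` in percent.
#' @examples
#' round(clopper_pearson_ci(103, 104), 2)  # 94.76 99.98
#' @export
clopper_pearson_ci <- function(x, n, conf_level = 0.95) {
  check_xn(x, n, conf_level)
  alpha <- 1 - conf_level
  low <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  100 * c(low, high)
}

check_xn <- function(x, n, conf_level) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n <= 0 ||
      n != round(n))
    stop("n must be a single positive integer")
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > n ||
      x != round(x))
    stop("x must be an integer with 0 <= x <= n")
  if (!is.numeric(conf_level) || length(conf_level) != 1L ||
      conf_level <= 0 || conf_level >= 1)
    stop("conf_level must be in (0, 1)")
  invisible(TRUE)
}

#' Binomial proportion with confidence interval
#'
#' Container tying a count ratio to its point estimate and CI on the
#' percent scale; the building block for agreement statistics and response
#' rates. Internal values are kept at full precision; rounding happens only
#' in formatting.
#'
#' @param x Numerator count.
#' @param n Denominator count (> 0).
#' @param method `"wilson"` or `"clopper_pearson"`.
#' @param conf_level Two-sided confidence level, default 0.95.
#' @param label Optional label (e.g. `"ppa"`).
#' @return Object of class `prop_estimate`: list with `numerator`,
#'   `denominator`, `point`, `ci_low`, `ci_high` (percent), `method`,
#'   `conf_level`, `label`.
#' @export
proportion_estimate <- function(x, n,
                                method = c("wilson", "clopper_pearson"),
                                conf_level = 0.95, label = NULL) {
  method <- match.arg(method)
  ci <- switch(method,
               wilson = wilson_ci(x, n, conf_level),
               clopper_pearson = clopper_pearson_ci(x, n, conf_level))
  structure(list(numerator = as.integer(x), denominator = as.integer(n),
                 point = 100 * x / n, ci_low = ci[1], ci_high = ci[2],
                 method = method, conf_level = conf_level, label = label),
            class = "prop_estimate")
}

#' @export
print.prop_estimate <- function(x, digits = 1, ...) {
  cat(sprintf("%s%d/%d = %s%% (%g%% CI: %s; %s) [%s]\n",
              if (is.null(x$label)) "" else paste0(x$label, ": "),
              x$numerator, x$denominator,
              format(round(x$point, digits), nsmall = digits),
              100 * x$conf_level,
              format(round(x$ci_low, digits), nsmall = digits),
              format(round(x$ci_high, digits), nsmall = digits),
              x$method))
  invisible(x)
}

#' @export
as.data.frame.prop_estimate <- function(x, ...) {
  data.frame(statistic = if (is.null(x$label)) NA_character_ else x$label,
             numerator = x$numerator, denominator = x$denominator,
             point = x$point, ci_low = x$ci_low, ci_high = x$ci_high,
             method = x$method, stringsAsFactors = FALSE)
}
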