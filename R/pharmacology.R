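# Pharmacology curve fits: four-parameter logistic dose-response (EC50) and
# exponential plasma-stability decay (half-life).

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `bottom + (top - bottom) / (1 + (ec50/dose)^hill)`.
#' Internally parameterised on log10(dose) and log10(EC50) for conditioning,
#' with multi-start initialisation over a grid of hill slopes; the result is
#' canonicalised so `top >= bottom` (the model is invariant under swapping
#' bottom/top with `hill -> -hill`). Deterministic.
#'
#' @param data Tibble with dose and response columns; replicate rows are
#'   used as-is.
#' @param dose,response Column names (tidy-eval) holding molar doses (> 0)
#'   and responses. Defaults `dose_molar`, `response`.
#' @return An object of class `fit_4pl`: list with `bottom`, `top`, `ec50`
#'   (molar), `hill`, `rss`, `converged`, `data` and the underlying `nls`
#'   fit. Has `tidy()`, `glance()`, `predict()` and `autoplot()` methods.
#' @examples
#' d <- make_pharm_data("dose_response",
#'   params = list(ec50 = 1e-9, hill = 1, bottom = 0, top = 100),
#'   noise = 0, seed = 1
#' )
#' fit_4pl(d$data)
#' @export
fit_4pl <- function(data, dose = "dose_molar", response = "response") {
  d <- tibble(dose = data[[dose]], y = data[[response]])
  d <- filter(d, !is.na(.data$dose), !is.na(.data$y))
  if (any(d$dose <= 0)) abort("Doses must be positive molar concentrations")
  if (length(unique(d$dose)) < 5) abort("Need >= 5 dose levels")
  if (diff(range(log10(d$dose))) < 2) {
    abort("Doses must span >= 2 log units")
  }
  d$ld <- log10(d$dose)

  model <- y ~ bottom + (top - bottom) / (1 + 10^(hill * (lec50 - ld)))
  spanlo <- min(d$y)
  spanhi <- max(d$y)
  starts <- expand.grid(
    hill = c(0.5, 1, 2, -1),
    lec50 = quantile(d$ld, c(0.25, 0.5, 0.75))
  )
  best <- NULL
  best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        model, data = d,
        start = list(bottom = spanlo, top = spanhi,
                     lec50 = starts$lec50[i], hill = starts$hill[i]),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) {
        best <- fit
        best_rss <- rss
      }
    }
  }
  if (is.null(best)) {
    abort("4PL fit failed to converge from any start")
  }
  p <- as.list(coef(best))
  # canonicalise: top >= bottom (swap + flip hill leaves the curve unchanged)
  if (p$top < p$bottom) {
    tmp <- p$top
    p$top <- p$bottom
    p$bottom <- tmp
    p$hill <- -p$hill
  }
  structure(
    list(
      bottom = p$bottom, top = p$top, ec50 = 10^p$lec50, hill = p$hill,
      rss = best_rss, converged = TRUE, fit = best, data = d
    ),
    class = "fit_4pl"
  )
}

#' @export
print.fit_4pl <- function(x, ...) {
  cat(sprintf(
    "4PL dose-response fit: EC50 = %.4g M, hill = %.3f, bottom = %.4g, top = %.4g (RSS %.4g)\n",
    x$ec50, x$hill, x$bottom, x$top, x$rss
  ))
  invisible(x)
}

#' @export
predict.fit_4pl <- function(object, newdata = NULL, ...) {
  dose <- if (is.null(newdata)) object$data$dose else newdata$dose
  object$bottom + (object$top - object$bottom) /
    (1 + (object$ec50 / dose)^object$hill)
}

#' Fit an exponential decay and report the half-life
#'
#' Nonlinear least squares of `A * exp(-k * t)` on the raw scale (so
#' zero/near-zero late points carry honest weight), initialised from a
#' log-linear regression on the positive levels. Half-life is `ln(2) / k`.
#'
#' @param data Tibble with time and level columns.
#' @param time,level Column names; defaults `time_min` (minutes) and
#'   `level`.
#' @return Object of class `fit_decay`: `amplitude`, `k` (1/min), `t_half`
#'   (minutes), `rss`, `fit`, `data`. Has `tidy()`, `glance()`, `predict()`
#'   and `autoplot()` methods.
#' @examples
#' d <- tibble::tibble(time_min = c(0, 20, 40, 60),
#'                     level = 100 * 2^(-c(0, 20, 40, 60) / 8.5))
#' fit_decay(d)$t_half
#' @export
fit_decay <- function(data, time = "time_min", level = "level") {
  d <- tibble(t = data[[time]], y = data[[level]])
  d <- filter(d, !is.na(.data$t), !is.na(.data$y))
  if (nrow(d) < 3) abort("Need >= 3 time points")
  if (any(d$y < 0)) abort("Levels must be non-negative")
  if (all(d$y == 0)) abort("All-zero levels: nothing to fit")

  pos <- d$y > 0
  init <- if (sum(pos) >= 2) {
    ll <- lm(log(y) ~ t, data = d[pos, ])
    list(A = exp(unname(coef(ll)[1])), k = max(-unname(coef(ll)[2]), 1e-6))
  } else {
    list(A = max(d$y), k = 0.1)
  }
  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-k * t), data = d, start = init,
    lower = c(A = 0, k = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- as.list(coef(fit))
  structure(
    list(
      amplitude = p$A, k = p$k, t_half = log(2) / p$k,
      rss = sum(stats::residuals(fit)^2), fit = fit, data = d
    ),
    class = "fit_decay"
  )
}

#' @export
print.fit_decay <- function(x, ...) {
  cat(sprintf(
    "Exponential decay fit: t1/2 = %.3g min (k = %.4g /min, A = %.4g)\n",
    x$t_half, x$k, x$amplitude
  ))
  invisible(x)
}

#' @export
predict.fit_decay <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t else newdata$t
  object$amplitude * exp(-object$k * t)
}
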