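# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn fit_4pl One row per parameter (`term`, `estimate`).
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy fit_4pl
#' @export
tidy.fit_4pl <- function(x, ...) {
  tibble(
    term = c("bottom", "top", "ec50", "hill"),
    estimate = c(x$bottom, x$top, x$ec50, x$hill)
  )
}

#' @describeIn fit_4pl One-row model summary (`ec50`, `hill`, `rss`,
#'   `n`, `converged`).
#' @method glance fit_4pl
#' @export
glance.fit_4pl <- function(x, ...) {
  tibble(ec50 = x$ec50, hill = x$hill, rss = x$rss,
         n = nrow(x$data), converged = x$converged)
}

#' @describeIn fit_decay One row per parameter, including the derived
#'   half-life.
#' @param x A fitted object.
#' @param ... Unused.
#' @method tidy fit_decay
#' @export
tidy.fit_decay <- function(x, ...) {
  tibble(
    term = c("amplitude", "k", "t_half"),
    estimate = c(x$amplitude, x$k, x$t_half)
  )
}

#' @describeIn fit_decay One-row model summary.
#' @method glance fit_decay
#' @export
glance.fit_decay <- function(x, ...) {
  tibble(t_half = x$t_half, k = x$k, rss = x$rss, n = nrow(x$data))
}

#' @describeIn expression_zscore Long-format z-scores (`gene`, `tissue`,
#'   `z`), in clustered order.
#' @param x An `expression_zscore` object.
#' @param ... Unused.
#' @method tidy expression_zscore
#' @export
tidy.expression_zscore <- function(x, ...) {
  as_tibble(as.data.frame.table(x$zscore, stringsAsFactors = FALSE)) %>%
    setNames(c("gene", "tissue", "z")) %>%
    as_tibble()
}

#' @describeIn fit_standard_curve One row per coefficient.
#' @param x A `standard_curve` object.
#' @param ... Unused.
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @describeIn fit_standard_curve One-row fit summary.
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n = nrow(x$fit$model))
}
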