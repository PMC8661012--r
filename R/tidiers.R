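#' Tidiers for bimr result objects
#'
#' Broom-style accessors: `tidy()` returns the per-term/per-method table of
#' an object, `glance()` a one-row summary.
#'
#' @param x An object produced by this package.
#' @param ... Unused.
#' @name bimr_tidiers
NULL

#' @rdname bimr_tidiers
#' @export
tidy.mr_result <- function(x, ...) as_tibble(x)

#' @rdname bimr_tidiers
#' @export
glance.mr_result <- function(x, ...) {
  tb <- as_tibble(x)
  est <- tb[!tb$method %in% "(Intercept)", ]
  tibble(n_methods = nrow(est),
         n_instruments = est$n_instruments[1],
         n_significant = sum(est$p < 0.05, na.rm = TRUE))
}

#' @rdname bimr_tidiers
#' @export
tidy.mr_direction <- function(x, ...) {
  if (is.null(x$results)) {
    return(tibble(method = character(), estimate = numeric(), se = numeric(),
                  ci_lower = numeric(), ci_upper = numeric(), p = numeric(),
                  n_instruments = integer(), status = character()))
  }
  as_tibble(x$results)
}

#' @rdname bimr_tidiers
#' @export
glance.mr_direction <- function(x, ...) {
  tibble(exposure = x$exposure, outcome = x$outcome, status = x$status,
         n_instruments = if (is.null(x$instruments)) 0L else nrow(x$instruments),
         min_f = if (is.null(x$instruments)) NA_real_ else min(x$instruments$f_statistic))
}

#' @rdname bimr_tidiers
#' @export
tidy.study_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$forward),
                  direction = paste(x$forward$exposure, "->", x$forward$outcome),
                  .before = 1),
    dplyr::mutate(tidy(x$reverse),
                  direction = paste(x$reverse$exposure, "->", x$reverse$outcome),
                  .before = 1))
}

#' @rdname bimr_tidiers
#' @export
glance.study_report <- function(x, ...) {
  dplyr::bind_rows(glance(x$forward), glance(x$reverse))
}

#' @rdname bimr_tidiers
#' @export
tidy.instrument_set <- function(x, ...) as_tibble(x)
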