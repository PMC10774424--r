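#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy methods for fit objects
#'
#' `tidy()` returns one row per parameter; `glance()` returns a one-row
#' model summary (RSS, convergence, flags, n).
#'
#' @param x A fit object (`exp_recovery_fit`, `logistic_fit`, or
#'   `kinetics_fit`).
#' @param ... Unused.
#' @return A tibble.
#' @name omrkit-tidiers
NULL

#' @rdname omrkit-tidiers
#' @export
tidy.exp_recovery_fit <- function(x, ...) {
  tibble(term = c("r_inf", "t0", "tau_min"),
         estimate = c(x$r_inf, x$t0, x$tau_min))
}

#' @rdname omrkit-tidiers
#' @export
glance.exp_recovery_fit <- function(x, ...) {
  tibble(rss = x$rss, converged = x$converged, nobs = x$n)
}

#' @rdname omrkit-tidiers
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble(term = c("amplitude", "x0_min", "k_min"),
         estimate = c(x$amplitude, x$x0_min, x$k_min))
}

#' @rdname omrkit-tidiers
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(rss = x$rss, converged = x$converged,
         flags = paste(x$flags, collapse = ";"), nobs = x$n)
}

#' @rdname omrkit-tidiers
#' @export
tidy.kinetics_fit <- function(x, ...) {
  tibble(term = c("c_max_on", "tau_on_s", "c_max_off", "tau_off_s"),
         estimate = c(x$c_max_on, x$tau_on_s, x$c_max_off, x$tau_off_s))
}

#' @rdname omrkit-tidiers
#' @export
glance.kinetics_fit <- function(x, ...) {
  tibble(rss_on = x$rss_on, rss_off = x$rss_off, converged = x$converged,
         flags = paste(x$flags, collapse = ";"))
}
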