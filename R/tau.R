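tau_from_counts <- function(cts) {
  denom <- (cts[1L] + cts[2L] + cts[3L]) * (cts[1L] + cts[2L] + cts[4L])
  if (denom <= 0) return(NA_real_)
  (cts[1L] - cts[2L]) / sqrt(denom)
}

check_ranking <- function(v, arg) {
  if (!is.numeric(v)) abort(paste0(arg, " must be numeric"))
  if (anyNA(v)) abort(paste0(arg, " contains missing values"))
  v
}

#' Kendall's tau-b rank correlation with explicit pair counts
#'
#' Rank correlation robust to ties: with P concordant pairs, Q discordant
#' pairs, X0 pairs tied only in `x` and Y0 pairs tied only in `y` (pairs
#' tied in both contribute to no term),
#' tau-b = (P - Q) / sqrt((P + Q + X0) * (P + Q + Y0)).
#'
#' @param x,y Aligned numeric vectors (length >= 2, no missing values).
#' @return An object of class `tau_b`: a list with `tau`, `P`, `Q`, `X0`,
#'   `Y0`, `n`. Use [tidy()] / [glance()] for tibble output.
#' @examples
#' kendall_tau_b(c(1, 2, 2), c(1, 2, 3))
#' @export
kendall_tau_b <- function(x, y) {
  check_ranking(x, "x"); check_ranking(y, "y")
  n <- length(x)
  if (length(y) != n) abort("x and y must be aligned (same length)")
  if (n < 2L) abort("need at least 2 observations")
  cts <- tau_pair_counts(as.double(x), as.double(y))
  tau <- tau_from_counts(cts)
  if (is.na(tau)) {
    abort("tau-b undefined: one of the rankings is completely tied",
          class = "mwulex_degenerate")
  }
  structure(
    list(tau = tau, P = cts[1L], Q = cts[2L], X0 = cts[3L], Y0 = cts[4L],
         n = n),
    class = "tau_b"
  )
}

#' @export
print.tau_b <- function(x, ...) {
  cat(sprintf("Kendall tau-b = %.4f  (n = %d; P = %g, Q = %g, X0 = %g, Y0 = %g)\n",
              x$tau, x$n, x$P, x$Q, x$X0, x$Y0))
  invisible(x)
}

#' @export
tidy.tau_b <- function(x, ...) {
  tibble::tibble(estimate = x$tau, P = x$P, Q = x$Q, X0 = x$X0, Y0 = x$Y0,
                 n = x$n)
}

#' @export
glance.tau_b <- function(x, ...) {
  tibble::tibble(tau = x$tau, n = x$n)
}

partial_tau_from <- function(t_xy, t_fx, t_fy) {
  (t_xy - t_fx * t_fy) / sqrt((1 - t_fx^2) * (1 - t_fy^2))
}

#' Partial Kendall's tau-b
#'
#' Correlation between the rankings `x` and `y` with the contribution of a
#' third ranking `f` removed:
#' tau-b(xy.f) = (tau_xy - tau_fx * tau_fy) /
#'   sqrt((1 - tau_fx^2) * (1 - tau_fy^2)).
#' Undefined when either control correlation is +/-1.
#'
#' @param x,y,f Aligned numeric vectors.
#' @return An object of class `tau_b_partial`: `tau` plus the three
#'   component coefficients and `n`.
#' @examples
#' set.seed(1)
#' f <- rnorm(50); x <- f + rnorm(50); y <- f + rnorm(50)
#' partial_tau_b(x, y, f)
#' @export
partial_tau_b <- function(x, y, f) {
  t_xy <- kendall_tau_b(x, y)$tau
  t_fx <- kendall_tau_b(f, x)$tau
  t_fy <- kendall_tau_b(f, y)$tau
  if (abs(t_fx) >= 1 || abs(t_fy) >= 1) {
    abort("partial tau-b undefined: control ranking perfectly correlated with x or y",
          class = "mwulex_degenerate")
  }
  structure(
    list(tau = partial_tau_from(t_xy, t_fx, t_fy),
         tau_xy = t_xy, tau_fx = t_fx, tau_fy = t_fy, n = length(x)),
    class = "tau_b_partial"
  )
}

#' @export
print.tau_b_partial <- function(x, ...) {
  cat(sprintf(
    "Partial Kendall tau-b = %.4f  (tau_xy = %.4f, tau_fx = %.4f, tau_fy = %.4f, n = %d)\n",
    x$tau, x$tau_xy, x$tau_fx, x$tau_fy, x$n))
  invisible(x)
}

#' @export
tidy.tau_b_partial <- function(x, ...) {
  tibble::tibble(estimate = x$tau, tau_xy = x$tau_xy, tau_fx = x$tau_fx,
                 tau_fy = x$tau_fy, n = x$n)
}

#' @export
glance.tau_b_partial <- function(x, ...) {
  tibble::tibble(tau = x$tau, n = x$n)
}

#' Kendall tau-b between columns of a data frame
#'
#' Data-frame-first wrapper: full tau-b between columns `x` and `y`, or
#' partial tau-b given a `control` column.
#'
#' @param data A data frame of word-level measures.
#' @param x,y,control Column names (strings or bare names). `control = NULL`
#'   gives the full correlation.
#' @return A `tau_b` or `tau_b_partial` object.
#' @export
tau_cor <- function(data, x, y, control = NULL) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ctl <- rlang::enquo(control)
  if (rlang::quo_is_null(ctl)) {
    kendall_tau_b(xv, yv)
  } else {
    partial_tau_b(xv, yv, dplyr::pull(data, !!ctl))
  }
}
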