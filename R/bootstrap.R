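# Fast tau evaluators used inside bootstrap loops: return NA_real_ on
# degenerate resamples (completely tied ranking, |control tau| = 1) so the
# engine can redraw instead of erroring.
tau_stat_full <- function(xv, yv) {
  force(xv); force(yv)
  function(idx) tau_from_counts(tau_pair_counts(xv[idx], yv[idx]))
}

tau_stat_partial <- function(xv, yv, fv) {
  force(xv); force(yv); force(fv)
  function(idx) {
    t_xy <- tau_from_counts(tau_pair_counts(xv[idx], yv[idx]))
    t_fx <- tau_from_counts(tau_pair_counts(fv[idx], xv[idx]))
    t_fy <- tau_from_counts(tau_pair_counts(fv[idx], yv[idx]))
    if (is.na(t_xy) || is.na(t_fx) || is.na(t_fy) ||
        abs(t_fx) >= 1 || abs(t_fy) >= 1) {
      return(NA_real_)
    }
    partial_tau_from(t_xy, t_fx, t_fy)
  }
}

# Percentile bootstrap engine. stats is a named list of functions of a
# resample index vector; every replicate draws ONE index resample and
# evaluates all statistics on it (paired resampling). A resample on which
# any statistic is undefined (NA) is redrawn, up to 10 * reps total draws.
boot_percentile <- function(stats, n, reps, seed, level = 0.95) {
  stopifnot(n >= 2L, reps >= 1L)
  k <- length(stats)
  withr::with_seed(as.integer(seed), {
    out <- matrix(NA_real_, nrow = reps, ncol = k)
    drawn <- 0L
    kept <- 0L
    max_draws <- 10L * reps
    while (kept < reps) {
      if (drawn >= max_draws) {
        abort("bootstrap: too many degenerate resamples (cap 10 * reps)")
      }
      idx <- sample.int(n, n, replace = TRUE)
      drawn <- drawn + 1L
      vals <- vapply(stats, function(f) f(idx), numeric(1L))
      if (anyNA(vals)) next
      kept <- kept + 1L
      out[kept, ] <- vals
    }
    n_redrawn <- drawn - reps
    if (n_redrawn > 0L) {
      warn(paste0("bootstrap: ", n_redrawn, " degenerate resamples redrawn"))
    }
    list(replicates = out, n_redrawn = n_redrawn)
  })
}

percentile_interval <- function(v, level) {
  a <- (1 - level) / 2
  q <- quantile(v, c(a, 1 - a), type = 7, names = FALSE)
  c(lower = q[1L], upper = q[2L])
}

col_chr <- function(data, q) {
  if (rlang::quo_is_null(q)) return(NA_character_)
  rlang::as_name(q)
}

#' Bootstrap confidence interval for a (partial) Kendall tau-b
#'
#' Percentile bootstrap: `reps` resamples of the word rows with
#' replacement, sample size equal to the number of rows; the interval is
#' the (1-level)/2 and 1-(1-level)/2 quantiles of the resample
#' coefficients. Resamples on which the coefficient is undefined (a
#' completely tied ranking, or a control correlation of +/-1) are redrawn,
#' capped at 10 * `reps` draws. Deterministic given `seed`.
#'
#' @param data A data frame of word-level measures.
#' @param x,y,control Column names; `control = NULL` for the full
#'   correlation, otherwise the partial correlation given `control`.
#' @param reps Bootstrap resamples; default 1000.
#' @param seed Integer seed (required).
#' @param level Confidence level; default 0.95.
#' @return A one-row tibble: `x`, `y`, `control`, `tau` (point estimate on
#'   the full data), `lower`, `upper`, `level`, `reps`, `n`, `n_redrawn`.
#' @examples
#' d <- data.frame(a = rank(rnorm(40)), b = rank(rnorm(40)))
#' tau_ci(d, a, b, reps = 200, seed = 7)
#' @export
tau_ci <- function(data, x, y, control = NULL, reps = 1000L, seed = NULL,
                   level = 0.95) {
  if (is.null(seed)) abort("tau_ci requires a seed")
  xq <- rlang::enquo(x); yq <- rlang::enquo(y); cq <- rlang::enquo(control)
  xv <- as.double(dplyr::pull(data, !!xq))
  yv <- as.double(dplyr::pull(data, !!yq))
  partial <- !rlang::quo_is_null(cq)
  if (partial) {
    fv <- as.double(dplyr::pull(data, !!cq))
    point <- partial_tau_b(xv, yv, fv)$tau
    stat <- tau_stat_partial(xv, yv, fv)
  } else {
    point <- kendall_tau_b(xv, yv)$tau
    stat <- tau_stat_full(xv, yv)
  }
  bt <- boot_percentile(list(stat = stat), length(xv), reps, seed, level)
  ci <- percentile_interval(bt$replicates[, 1L], level)
  tibble::tibble(
    x = col_chr(data, xq), y = col_chr(data, yq), control = col_chr(data, cq),
    tau = point, lower = ci[["lower"]], upper = ci[["upper"]],
    level = level, reps = as.integer(reps), n = length(xv),
    n_redrawn = bt$n_redrawn
  )
}

#' Specify one correlation for a difference interval
#'
#' Captures the x/y/control columns of one (partial) tau-b so two such
#' specifications can be compared with [tau_diff_ci()].
#'
#' @param x,y,control Column names (bare or strings); `control = NULL` for
#'   a full correlation.
#' @return A `tau_spec` list of column-name strings.
#' @export
tau_spec <- function(x, y, control = NULL) {
  cq <- rlang::enquo(control)
  structure(
    list(x = rlang::as_name(rlang::enquo(x)),
         y = rlang::as_name(rlang::enquo(y)),
         control = if (rlang::quo_is_null(cq)) NA_character_ else rlang::as_name(cq)),
    class = "tau_spec"
  )
}

spec_stat <- function(data, spec) {
  xv <- as.double(data[[spec$x]])
  yv <- as.double(data[[spec$y]])
  if (is.na(spec$control)) {
    list(point = kendall_tau_b(xv, yv)$tau, stat = tau_stat_full(xv, yv))
  } else {
    fv <- as.double(data[[spec$control]])
    list(point = partial_tau_b(xv, yv, fv)$tau,
         stat = tau_stat_partial(xv, yv, fv))
  }
}

#' Paired-bootstrap interval for the difference between two coefficients
#'
#' Compares two (partial) tau-b coefficients computed over the same word
#' index. Each bootstrap replicate draws ONE resample of the rows and
#' evaluates both coefficients on it; the replicate value is
#' `|A| - |B|` when `absolute = TRUE` (the difference between magnitudes,
#' appropriate when both correlations are negative) or `A - B` otherwise.
#' The percentile interval over replicates is returned; the two
#' coefficients differ "significantly" at the given level when the interval
#' excludes zero.
#'
#' @param data A data frame of word-level measures.
#' @param spec_a,spec_b Two [tau_spec()] objects.
#' @param absolute Compare magnitudes (`|A| - |B|`)? Default `TRUE`.
#' @param reps,seed,level As in [tau_ci()].
#' @return A one-row tibble: the two specifications (as label strings),
#'   `estimate` (difference on the full data), `lower`, `upper`,
#'   `excludes_zero`, `absolute`, `level`, `reps`, `n`, `n_redrawn`.
#' @export
tau_diff_ci <- function(data, spec_a, spec_b, absolute = TRUE,
                        reps = 1000L, seed = NULL, level = 0.95) {
  if (is.null(seed)) abort("tau_diff_ci requires a seed")
  stopifnot(inherits(spec_a, "tau_spec"), inherits(spec_b, "tau_spec"))
  sa <- spec_stat(data, spec_a)
  sb <- spec_stat(data, spec_b)
  n <- nrow(data)
  combine <- if (absolute) function(u, v) abs(u) - abs(v) else `-`
  point <- combine(sa$point, sb$point)
  bt <- boot_percentile(list(a = sa$stat, b = sb$stat), n, reps, seed, level)
  d <- combine(bt$replicates[, 1L], bt$replicates[, 2L])
  ci <- percentile_interval(d, level)
  lab <- function(s) {
    if (is.na(s$control)) paste0("tau(", s$x, ", ", s$y, ")")
    else paste0("tau(", s$x, ", ", s$y, " | ", s$control, ")")
  }
  tibble::tibble(
    a = lab(spec_a), b = lab(spec_b),
    estimate = point,
    lower = ci[["lower"]], upper = ci[["upper"]],
    excludes_zero = ci[["lower"]] > 0 || ci[["upper"]] < 0,
    absolute = absolute, level = level, reps = as.integer(reps),
    n = n, n_redrawn = bt$n_redrawn
  )
}
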