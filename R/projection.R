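#' Deterministic population projection from an initial egg pulse
#'
#' Expected-value renewal recursion over the empirical age-stage schedules:
#' a cohort of newborn eggs is followed through the observed survival matrix
#' `s_xj`, and the eggs it lays seed new cohorts. Eggs laid by age-x parents
#' on day `t` are counted as age-0 births on day `t + 1`, so the recursion's
#' characteristic equation is exactly the Euler-Lotka equation with exponent
#' `-r(x+1)` used by [solve_intrinsic_rate()]:
#' \deqn{B(t) = \sum_{x=0}^{\min(t-1,\omega)} B(t-1-x)\, l_x m_x, \quad
#'       B(0) = \mathrm{initial\ eggs}}
#' \deqn{N_j(t) = \sum_{x=0}^{\min(t,\omega)} B(t-x)\, s_{xj}}
#' Counts are expected values and may be fractional; cohorts older than
#' \eqn{\omega} contribute nothing.
#'
#' @param schedules A `schedule_set` from [compute_schedules()].
#' @param initial_eggs Size of the newly-laid egg pulse at day 0 (must be
#'   positive).
#' @param horizon Number of days to project (>= 1).
#' @return A data frame of class `projection_series` with columns `day`
#'   (0..horizon), `births`, one column per stage, and `total`.
#' @export
project_population <- function(schedules, initial_eggs = 10, horizon = 60L) {
  stopifnot(inherits(schedules, "schedule_set"))
  if (initial_eggs <= 0) stop("initial_eggs must be positive")
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) stop("horizon must be at least 1 day")
  phi <- schedules$l_x * schedules$m_x
  s <- schedules$s_xj
  omega <- schedules$omega
  B <- numeric(horizon + 1L)
  B[1L] <- initial_eggs
  for (t in seq_len(horizon)) {
    xmax <- min(t - 1L, omega)
    B[t + 1L] <- sum(phi[1:(xmax + 1L)] * B[t - (0:xmax)])
  }
  k <- ncol(s)
  N <- matrix(0, horizon + 1L, k, dimnames = list(NULL, colnames(s)))
  for (t in 0:horizon) {
    xmax <- min(t, omega)
    ages <- 0:xmax
    N[t + 1L, ] <- colSums(s[ages + 1L, , drop = FALSE] * B[t - ages + 1L])
  }
  out <- data.frame(day = 0:horizon, births = B,
                    N, total = rowSums(N), check.names = FALSE)
  attr(out, "initial_eggs") <- initial_eggs
  attr(out, "omega") <- omega
  attr(out, "treatment") <- schedules$treatment
  class(out) <- c("projection_series", class(out))
  out
}

#' Realized daily growth rate of a projection
#'
#' Slope of `ln N(t)` versus `t` over the trailing `window` days. As the
#' horizon grows this converges to the intrinsic rate of increase solved
#' from the same schedules (the stable-age limit of the renewal recursion).
#'
#' @param series A `projection_series`.
#' @param window Number of trailing days to fit (>= 2).
#' @return Per-day growth rate, or `NA` with a warning if the population is
#'   extinct (non-positive) anywhere in the window.
#' @export
realized_growth_rate <- function(series, window = 20L) {
  stopifnot(inherits(series, "projection_series"), window >= 2L)
  n <- nrow(series)
  if (window > n) stop("window exceeds the projection horizon")
  tail_rows <- (n - window + 1L):n
  Nt <- series$total[tail_rows]
  if (any(Nt <= 0)) {
    warning("population non-positive inside the window; growth rate undefined")
    return(NA_real_)
  }
  day <- series$day[tail_rows]
  unname(stats::coef(stats::lm(log(Nt) ~ day))[2L])
}

#' @export
print.projection_series <- function(x, ...) {
  cat("Population projection ('", attr(x, "treatment") %||% "?", "'): ",
      attr(x, "initial_eggs"), " eggs over ", max(x$day), " days\n", sep = "")
  cat(sprintf("  final total %.1f individuals\n", x$total[nrow(x)]))
  invisible(x)
}
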