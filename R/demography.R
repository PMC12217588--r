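#' Net reproductive rate
#'
#' \eqn{R_0 = \sum_{x=0}^{\omega} l_x m_x}: the expected lifetime offspring
#' per newborn individual (both sexes in the denominator, female births in
#' the numerator), which for a cohort equals total eggs laid divided by n01.
#'
#' @param schedules A `schedule_set` from [compute_schedules()].
#' @return `R0` (offspring per individual).
#' @export
net_reproductive_rate <- function(schedules) {
  stopifnot(inherits(schedules, "schedule_set"))
  sum(schedules$l_x * schedules$m_x)
}

# Euler-Lotka residual: sum_x exp(-r (x+1)) phi_x - 1, with phi_x = l_x m_x
# and ages counted from 0 (an egg laid during day x recruits at the next
# daily census, hence the x+1 exponent).
euler_residual <- function(r, phi) {
  x <- seq_along(phi) - 1
  sum(exp(-r * (x + 1)) * phi) - 1
}

# bisection on the strictly decreasing Euler-Lotka residual
solve_r_bisect <- function(phi, bracket = c(-0.5, 1.5), tol = 1e-10,
                           max_iter = 200L) {
  if (sum(phi) <= 0)
    stop("R0 = 0: the Euler-Lotka equation has no root (no reproduction)",
         call. = FALSE)
  lo <- bracket[1]; hi <- bracket[2]
  flo <- euler_residual(lo, phi)
  fhi <- euler_residual(hi, phi)
  if (flo < 0 || fhi > 0)
    stop("bracket does not straddle the Euler-Lotka root: residual(",
         format(lo), ") = ", format(flo), ", residual(", format(hi),
         ") = ", format(fhi), call. = FALSE)
  it <- 0L
  mid <- (lo + hi) / 2
  fmid <- euler_residual(mid, phi)
  while (abs(fmid) > tol && it < max_iter) {
    if (fmid > 0) lo <- mid else hi <- mid
    mid <- (lo + hi) / 2
    fmid <- euler_residual(mid, phi)
    it <- it + 1L
  }
  list(r = mid, residual = fmid, iterations = it)
}

#' Solve the Euler-Lotka equation for the intrinsic rate of increase
#'
#' Finds the daily intrinsic rate of increase \eqn{r} satisfying
#' \deqn{\sum_{x=0}^{\omega} e^{-r(x+1)} l_x m_x = 1}
#' by iterative bisection. The left-hand side is strictly decreasing in
#' \eqn{r}, so bisection on a straddling bracket converges monotonically.
#' Also returns the finite rate of increase \eqn{\lambda = e^r} and the mean
#' generation time \eqn{T = \ln R_0 / r}.
#'
#' @param schedules A `schedule_set`.
#' @param bracket Length-2 numeric search interval for `r` (per day). The
#'   default `c(-0.5, 1.5)` covers all biologically plausible arthropod
#'   rates.
#' @param tol Residual tolerance; bisection stops when
#'   `|sum(exp(-r(x+1)) l_x m_x) - 1| <= tol`.
#' @param max_iter Maximum bisection iterations.
#' @return An object of class `demographic_params`: list with `R0`, `r`,
#'   `lambda`, `T`, `residual`, `iterations`, `bracket`.
#' @export
solve_intrinsic_rate <- function(schedules, bracket = c(-0.5, 1.5),
                                 tol = 1e-10, max_iter = 200L) {
  stopifnot(inherits(schedules, "schedule_set"))
  phi <- schedules$l_x * schedules$m_x
  R0 <- sum(phi)
  sol <- solve_r_bisect(phi, bracket, tol, max_iter)
  structure(
    list(R0 = R0, r = sol$r, lambda = exp(sol$r),
         T = generation_time(R0, sol$r),
         residual = sol$residual, iterations = sol$iterations,
         bracket = bracket, treatment = schedules$treatment),
    class = "demographic_params")
}

#' Finite rate of increase
#'
#' \eqn{\lambda = e^r}, the daily population multiplication factor.
#'
#' @param r Intrinsic rate of increase (per day).
#' @return `lambda` (per day).
#' @export
finite_rate <- function(r) exp(r)

#' Mean generation time
#'
#' \eqn{T = \ln R_0 / r}. Undefined (`NA` with a warning) when `r = 0`,
#' i.e. the replacement limit `R0 = 1`.
#'
#' @param R0 Net reproductive rate.
#' @param r Intrinsic rate of increase (per day).
#' @return `T` in days.
#' @export
generation_time <- function(R0, r) {
  if (r == 0) {
    warning("r = 0: mean generation time is undefined (R0 = 1 limit)")
    return(NA_real_)
  }
  log(R0) / r
}

#' @export
print.demographic_params <- function(x, ...) {
  cat("Demographic parameters",
      if (!is.null(x$treatment)) paste0(" ('", x$treatment, "')"), ":\n",
      sep = "")
  cat(sprintf("  R0 = %.4f offspring/individual\n", x$R0))
  cat(sprintf("  r  = %.6f /day   lambda = %.6f /day   T = %.4f days\n",
              x$r, x$lambda, x$T))
  cat(sprintf("  Euler-Lotka residual %.2e after %d bisection iterations\n",
              x$residual, x$iterations))
  invisible(x)
}

#' @export
as.data.frame.demographic_params <- function(x, ...) {
  data.frame(treatment = x$treatment %||% NA_character_,
             R0 = x$R0, r = x$r, lambda = x$lambda, T = x$T,
             residual = x$residual, iterations = x$iterations,
             stringsAsFactors = FALSE)
}
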