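#' Compute age-stage survival and fecundity schedules
#'
#' From a validated cohort computes the empirical age-stage schedules of the
#' two-sex life table:
#' \itemize{
#'   \item \eqn{s_{xj} = n_{xj} / n_{01}}: proportion of the starting cohort
#'     alive at age \eqn{x} (days) in stage \eqn{j};
#'   \item \eqn{l_x = \sum_j s_{xj}}: age-specific survival;
#'   \item \eqn{f_{xj} = E_{xj} / n_{xj}}: daily eggs per living female adult
#'     of age \eqn{x} (0 where \eqn{n_{xj} = 0});
#'   \item \eqn{m_x = \sum_j s_{xj} f_{xj} / \sum_j s_{xj}}: daily eggs per
#'     living individual of age \eqn{x}.
#' }
#' Ages run from 0 to \eqn{\omega}, the maximum death age in the cohort (the
#' final row is the first age at which the whole cohort is dead, so
#' \eqn{l_\omega = 0}); the day an egg is laid is age 0.
#'
#' @param cohort A [cohort_table()] with at least one non-excluded record.
#' @return A `schedule_set`: list with matrices `s_xj`, `f_xj`, `E_xj`,
#'   `n_xj` (rows ages `0:omega`, columns stages), vectors `l_x`, `m_x`,
#'   and scalars `omega`, `n01`.
#' @export
compute_schedules <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  idx <- included_idx(cohort)
  if (!length(idx)) stop("all individuals are excluded; nothing to analyse")
  schema <- cohort$schema
  n01 <- cohort$n01
  n_imm <- n_immature(schema)
  k <- length(schema$stages)
  rec <- cohort$records[idx, , drop = FALSE]
  ent <- cohort$entry[idx, , drop = FALSE]
  eggs <- cohort$eggs[idx, , drop = FALSE]
  omega <- max(rec$death_age)
  A <- omega + 1L
  dn <- list(age = 0:omega, stage = schema$stages)
  n_xj <- matrix(0, A, k, dimnames = dn)
  E_xj <- matrix(0, A, k, dimnames = dn)
  for (i in seq_len(nrow(rec))) {
    e <- ent[i, ]
    reached <- which(!is.na(e))
    last <- max(reached)
    for (s in reached) {
      from <- e[s]
      to <- if (s < last) e[s + 1L] - 1L else rec$death_age[i] - 1L
      if (to < from) next
      j <- if (s <= n_imm) s
           else if (rec$sex[i] == "F") schema$female_stage
           else schema$male_stage
      rows <- (from:to) + 1L
      n_xj[rows, j] <- n_xj[rows, j] + 1
    }
    if (rec$sex[i] == "F" && ncol(eggs)) {
      laid <- which(eggs[i, ] > 0L)
      if (length(laid))
        E_xj[laid, schema$female_stage] <-
          E_xj[laid, schema$female_stage] + eggs[i, laid]
    }
  }
  s_xj <- n_xj / n01
  l_x <- rowSums(s_xj)
  f_xj <- ifelse(n_xj > 0, E_xj / n_xj, 0)
  num <- rowSums(s_xj * f_xj)
  m_x <- ifelse(l_x > 0, num / l_x, 0)
  structure(
    list(s_xj = s_xj, l_x = l_x, f_xj = f_xj, m_x = m_x,
         E_xj = E_xj, n_xj = n_xj, omega = omega, n01 = n01,
         treatment = cohort$treatment, schema = schema),
    class = "schedule_set")
}

#' @export
print.schedule_set <- function(x, ...) {
  cat("Age-stage schedules for '", x$treatment, "' (n01 = ", x$n01,
      ", omega = ", x$omega, " d)\n", sep = "")
  cat("  R0 = sum(l_x m_x) = ", format(sum(x$l_x * x$m_x), digits = 4),
      " offspring/individual\n", sep = "")
  invisible(x)
}

#' Export schedules as tidy tables
#'
#' `schedules_long()` returns one row per (age, stage) with `s_xj` and
#' `f_xj`; `schedules_wide()` returns one row per age with `l_x`, `m_x` and
#' the net maternity `l_x * m_x` used by the projection and the Euler-Lotka
#' solver.
#'
#' @param schedules A `schedule_set` from [compute_schedules()].
#' @return A data frame.
#' @export
schedules_long <- function(schedules) {
  stopifnot(inherits(schedules, "schedule_set"))
  k <- ncol(schedules$s_xj)
  A <- nrow(schedules$s_xj)
  data.frame(
    age = rep(0:(A - 1L), times = k),
    stage = rep(colnames(schedules$s_xj), each = A),
    s_xj = as.vector(schedules$s_xj),
    f_xj = as.vector(schedules$f_xj),
    stringsAsFactors = FALSE)
}

#' @rdname schedules_long
#' @export
schedules_wide <- function(schedules) {
  stopifnot(inherits(schedules, "schedule_set"))
  data.frame(
    age = 0:schedules$omega,
    l_x = schedules$l_x,
    m_x = schedules$m_x,
    lxmx = schedules$l_x * schedules$m_x)
}
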