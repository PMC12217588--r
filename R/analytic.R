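#' Closed-form expected schedules for a deterministic-duration spec
#'
#' For a [treatment_spec()] in analytic mode (no duration jitter, integer
#' stage durations and APOP, zero-SD longevities) the life-history model has
#' finitely many outcomes: death in stage j on within-stage day u, or
#' adulthood as a female or male with fixed longevity. Enumerating these
#' outcomes with their probabilities yields the exact expected age-stage
#' schedules implied by the spec (with expected, possibly fractional, daily
#' fecundities), against which schedules computed from large generated
#' cohorts can be checked.
#'
#' @param spec A [treatment_spec()] in analytic mode.
#' @return A `schedule_set` with `n01 = 1` (per-newborn probabilities).
#' @export
expected_schedules <- function(spec) {
  stopifnot(inherits(spec, "treatment_spec"))
  if (spec$duration_jitter != 0 ||
      any(spec$duration_mean != round(spec$duration_mean)) ||
      spec$apop_mean != round(spec$apop_mean) ||
      length(spec$pmf_f$support) != 1L || length(spec$pmf_m$support) != 1L)
    stop("analytic mode requires deterministic durations, APOP and ",
         "longevities (no jitter, integer means, zero SDs)", call. = FALSE)
  schema <- spec$schema
  n_imm <- n_immature(schema)
  k <- length(schema$stages)
  d <- as.integer(spec$duration_mean)
  ent <- c(0L, cumsum(d))                # entries of stages 1..n_imm, adult
  Lf <- spec$pmf_f$support
  Lm <- spec$pmf_m$support
  A <- as.integer(spec$apop_mean)
  S <- cumprod(1 - spec$death_prob)      # P(survive through stage j)
  Sbefore <- c(1, S[-n_imm])             # P(alive entering stage j)
  omega <- max(ent[n_imm + 1L] + max(Lf, Lm),
               ent[seq_len(n_imm)] + d)  # latest possible death age
  nA <- omega + 1L
  dn <- list(age = 0:omega, stage = schema$stages)
  n_xj <- matrix(0, nA, k, dimnames = dn)
  E_xj <- matrix(0, nA, k, dimnames = dn)
  occupy <- function(j, from, to, p) {
    if (to >= from) n_xj[(from:to) + 1L, j] <<- n_xj[(from:to) + 1L, j] + p
  }
  # deaths within immature stage j, uniform over its d[j] days
  for (j in seq_len(n_imm)) {
    pdie <- Sbefore[j] * spec$death_prob[j]
    if (pdie == 0) next
    for (u in seq_len(d[j])) {
      p <- pdie / d[j]
      for (s in seq_len(j - 1L)) occupy(s, ent[s], ent[s + 1L] - 1L, p)
      occupy(j, ent[j], ent[j] + u - 1L, p)
    }
  }
  # survivors: immature path is certain, then sex and fixed adult life
  surv <- S[n_imm]
  for (sex in c("F", "M")) {
    p <- surv * if (sex == "F") spec$p_female else 1 - spec$p_female
    if (p == 0) next
    L <- if (sex == "F") Lf else Lm
    j_ad <- if (sex == "F") schema$female_stage else schema$male_stage
    for (s in seq_len(n_imm)) occupy(s, ent[s], ent[s + 1L] - 1L, p)
    occupy(j_ad, ent[n_imm + 1L], ent[n_imm + 1L] + L - 1L, p)
    if (sex == "F") {
      d_max <- min(spec$ovi_window, L - A)
      if (d_max >= 1L) {
        ages <- ent[n_imm + 1L] + A + seq_len(d_max) - 1L
        E_xj[ages + 1L, j_ad] <- E_xj[ages + 1L, j_ad] +
          p * spec$fec_daily[seq_len(d_max)]
      }
    }
  }
  s_xj <- n_xj                            # n01 = 1
  l_x <- rowSums(s_xj)
  f_xj <- ifelse(n_xj > 0, E_xj / n_xj, 0)
  m_x <- ifelse(l_x > 0, rowSums(s_xj * f_xj) / l_x, 0)
  structure(
    list(s_xj = s_xj, l_x = l_x, f_xj = f_xj, m_x = m_x,
         E_xj = E_xj, n_xj = n_xj, omega = omega, n01 = 1,
         treatment = spec$label, schema = schema),
    class = "schedule_set")
}

#' Spec-implied net reproductive rate
#'
#' Closed form `R0 = P(reach adulthood) * P(female) * expected fecundity`:
#' the generator calibrates the fecundity curve so that expected realised
#' lifetime eggs per female equals the spec's `fecundity` exactly, so this
#' holds for stochastic specs too.
#'
#' @param spec A [treatment_spec()].
#' @return Expected offspring per newborn individual.
#' @export
expected_r0 <- function(spec) {
  stopifnot(inherits(spec, "treatment_spec"))
  prod(1 - spec$death_prob) * spec$p_female * spec$fecundity
}
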