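#' Specify a synthetic cohort generator
#'
#' Defines the stochastic life-history model the generator draws from. Each
#' individual, independently:
#' \enumerate{
#'   \item draws an integer duration for each immature stage (mean-preserving
#'     discretisation: `floor(mean) + Bernoulli(frac)` plus an optional
#'     symmetric unit jitter with probability `duration_jitter`, clamped at 1
#'     day);
#'   \item survives each stage with probability `1 - death_prob[j]`; on
#'     failure, the death day is uniform over the days of that stage;
#'   \item on reaching adulthood is female with probability `p_female`;
#'   \item draws an adult longevity from a discretised gamma distribution
#'     (point mass at the rounded mean when `sd = 0`);
#'   \item if female, draws an adult pre-oviposition period (APOP) and then
#'     daily egg counts from a triangular rise-peak-decline fecundity curve,
#'     truncated at death (Poisson daily counts, or negative binomial when
#'     `fecundity_dispersion` is finite).
#' }
#' The fecundity curve scale is calibrated in closed form against the
#' longevity and APOP distributions so that the expected realised lifetime
#' fecundity per female equals `fecundity` exactly.
#'
#' @param label Treatment label.
#' @param n Cohort size (number of eggs started).
#' @param death_prob Per-immature-stage conditional death probabilities
#'   (length = number of immature stages).
#' @param duration_mean Per-immature-stage mean durations in days (>= 1).
#' @param duration_jitter Probability of a +/-1 day jitter on each duration.
#' @param p_female Probability an individual reaching adulthood is female.
#' @param apop_mean Mean adult pre-oviposition period in days (>= 1).
#' @param ovi_peak_day,ovi_window Peak day and length (days) of the
#'   triangular daily-fecundity curve, counted from the first oviposition
#'   day.
#' @param fecundity Target expected lifetime eggs per female.
#' @param fecundity_dispersion Negative-binomial size for daily egg counts;
#'   `Inf` (default) gives Poisson.
#' @param longevity_female,longevity_male Length-2 numeric `c(mean, sd)` of
#'   adult longevity in days by sex.
#' @param schema A [stage_schema()].
#' @return An object of class `treatment_spec`.
#' @export
treatment_spec <- function(label, n = 50L,
                           death_prob, duration_mean,
                           duration_jitter = 0.3,
                           p_female, apop_mean,
                           ovi_peak_day, ovi_window, fecundity,
                           fecundity_dispersion = Inf,
                           longevity_female, longevity_male,
                           schema = default_schema()) {
  n_imm <- n_immature(schema)
  stopifnot(length(death_prob) == n_imm, length(duration_mean) == n_imm,
            all(death_prob >= 0 & death_prob <= 1),
            all(duration_mean >= 1),
            duration_jitter >= 0, duration_jitter <= 1,
            p_female >= 0, p_female <= 1,
            apop_mean >= 1, ovi_window >= 1,
            ovi_peak_day >= 1, ovi_peak_day <= ovi_window,
            fecundity >= 0, fecundity_dispersion > 0,
            length(longevity_female) == 2L, length(longevity_male) == 2L,
            longevity_female[1] >= 1, longevity_male[1] >= 1,
            longevity_female[2] >= 0, longevity_male[2] >= 0)
  pmf_f <- longevity_pmf(longevity_female[1], longevity_female[2])
  pmf_m <- longevity_pmf(longevity_male[1], longevity_male[2])
  tri <- tri_curve(ovi_peak_day, ovi_window)
  # P(female lays on oviposition day d) = P(longevity - APOP >= d)
  a0 <- floor(apop_mean); fa <- apop_mean - a0
  surv_f <- rev(cumsum(rev(pmf_f$p)))                  # P(L >= l), l = support
  p_ge <- function(l) if (l <= pmf_f$support[1]) 1
                      else if (l > max(pmf_f$support)) 0
                      else surv_f[match(l, pmf_f$support)]
  lay_prob <- vapply(seq_len(ovi_window), function(d) {
    (1 - fa) * p_ge(a0 + d) + fa * p_ge(a0 + 1 + d)
  }, numeric(1))
  denom <- sum(tri * lay_prob)
  fec_daily <- if (fecundity == 0) rep(0, ovi_window)
               else {
                 if (denom <= 0)
                   stop("females never survive to oviposition under this spec")
                 fecundity * tri / denom
               }
  structure(
    list(label = label, n = as.integer(n),
         death_prob = death_prob, duration_mean = duration_mean,
         duration_jitter = duration_jitter,
         p_female = p_female, apop_mean = apop_mean,
         ovi_peak_day = ovi_peak_day, ovi_window = ovi_window,
         fecundity = fecundity, fecundity_dispersion = fecundity_dispersion,
         longevity_female = longevity_female, longevity_male = longevity_male,
         pmf_f = pmf_f, pmf_m = pmf_m, fec_daily = fec_daily,
         schema = schema),
    class = "treatment_spec")
}

# discretised gamma pmf on integer days >= 1 (point mass when sd = 0)
longevity_pmf <- function(mean, sd) {
  if (sd == 0) return(list(support = max(1L, round(mean)), p = 1))
  shape <- (mean / sd)^2
  rate <- mean / sd^2
  hi <- max(2L, ceiling(mean + 8 * sd))
  support <- 1:hi
  upper <- stats::pgamma(support + 0.5, shape, rate)
  lower <- stats::pgamma(support - 0.5, shape, rate)
  p <- upper - lower
  p[1] <- stats::pgamma(1.5, shape, rate)        # lump mass below 1 day
  p[hi] <- p[hi] + 1 - stats::pgamma(hi + 0.5, shape, rate)
  list(support = support, p = p / sum(p))
}

# triangular rise-peak-decline curve over oviposition days 1..w, peak at p
tri_curve <- function(p, w) {
  d <- seq_len(w)
  ifelse(d <= p, d / p, (w + 1 - d) / (w + 1 - p))
}

#' Packaged treatment presets
#'
#' Three presets mimicking the demographic structure of published
#' two-spotted spider mite cohorts on tomato reared on control plants and on
#' plants irrigated with two plasma-activated water doses: per-stage death
#' counts, stage-duration means, adult sex ratios, APOP, adult longevities
#' (means with SD back-computed from published standard errors), and
#' expected lifetime fecundities per female.
#'
#' @param preset One of `"control"`, `"paw1"`, `"paw2"`.
#' @param n Cohort size (default 50, the published design).
#' @return A [treatment_spec()].
#' @export
preset_spec <- function(preset = c("control", "paw1", "paw2"), n = 50L) {
  preset <- match.arg(preset)
  switch(preset,
    control = treatment_spec(
      label = "control", n = n,
      death_prob = c(1 / 50, 0, 1 / 49, 1 / 48),
      duration_mean = c(8.02, 3.12, 2.06, 3.06),
      p_female = 41 / 47, apop_mean = 1.48,
      ovi_peak_day = 6, ovi_window = 22, fecundity = 49.93,
      longevity_female = c(17.29, 6.66), longevity_male = c(14.16, 5.00)),
    paw1 = treatment_spec(
      label = "paw1", n = n,
      death_prob = c(10 / 50, 7 / 40, 0, 4 / 33),
      duration_mean = c(8.00, 3.12, 2.21, 3.44),
      p_female = 21 / 29, apop_mean = 1.57,
      ovi_peak_day = 5, ovi_window = 18, fecundity = 37.14,
      longevity_female = c(14.76, 4.81), longevity_male = c(9.12, 3.00)),
    paw2 = treatment_spec(
      label = "paw2", n = n,
      death_prob = c(6 / 50, 6 / 44, 1 / 38, 0),
      duration_mean = c(8.10, 3.10, 2.40, 3.24),
      p_female = 25 / 37, apop_mean = 1.66,
      ovi_peak_day = 4, ovi_window = 16, fecundity = 32.52,
      longevity_female = c(13.60, 5.90), longevity_male = c(8.00, 3.95)))
}

# mean-preserving integer draw: floor + Bernoulli(frac) + symmetric jitter
draw_duration <- function(n, mean, jitter) {
  base <- floor(mean)
  d <- base + stats::rbinom(n, 1L, mean - base)
  if (jitter > 0)
    d <- d + sample(c(-1L, 0L, 1L), n, replace = TRUE,
                    prob = c(jitter / 2, 1 - jitter, jitter / 2))
  as.integer(pmax(d, 1))
}

#' Generate a synthetic cohort
#'
#' Draws `spec$n` independent individual life histories from a
#' [treatment_spec()] and returns them as a validated [cohort_table()].
#' With a fixed seed the cohort is bit-for-bit reproducible.
#'
#' @param spec A [treatment_spec()].
#' @param seed Optional integer seed.
#' @param n Override of the spec's cohort size.
#' @return A [cohort_table()].
#' @export
generate_cohort <- function(spec, seed = NULL, n = spec$n) {
  stopifnot(inherits(spec, "treatment_spec"))
  with_local_seed(seed, {
    schema <- spec$schema
    n_imm <- n_immature(schema)
    dur <- vapply(seq_len(n_imm), function(j)
      draw_duration(n, spec$duration_mean[j], spec$duration_jitter),
      integer(n))
    if (n == 1L) dur <- matrix(dur, nrow = 1L)
    survives <- vapply(seq_len(n_imm), function(j)
      stats::runif(n) >= spec$death_prob[j], logical(n))
    if (n == 1L) survives <- matrix(survives, nrow = 1L)
    death_stage <- apply(survives, 1L, function(s) {
      w <- which(!s)
      if (length(w)) w[1L] else 0L
    })
    entry <- matrix(NA_integer_, n, n_imm + 1L)
    entry[, 1L] <- 0L
    cum <- t(apply(dur, 1L, cumsum))
    if (n == 1L) cum <- matrix(cum, nrow = 1L)
    for (j in seq_len(n_imm - 1L))
      entry[, j + 1L] <- cum[, j]
    entry[, n_imm + 1L] <- cum[, n_imm]
    sex <- character(n)
    death_age <- integer(n)
    adult <- death_stage == 0L
    sex[!adult] <- "N"
    sex[adult] <- ifelse(stats::runif(n)[adult] < spec$p_female, "F", "M")
    # death day uniform within the failed stage
    for (i in which(!adult)) {
      js <- death_stage[i]
      ent_i <- if (js == 1L) 0L else cum[i, js - 1L]
      death_age[i] <- ent_i + sample.int(dur[i, js], 1L)
      if (js < n_imm) entry[i, (js + 1L):(n_imm + 1L)] <- NA_integer_
      else entry[i, n_imm + 1L] <- NA_integer_
    }
    L <- integer(n)
    isF <- sex == "F"; isM <- sex == "M"
    draw_pmf <- function(pmf, m) {
      if (length(pmf$support) == 1L) rep(pmf$support, m)
      else sample(pmf$support, m, replace = TRUE, prob = pmf$p)
    }
    if (any(isF)) L[isF] <- draw_pmf(spec$pmf_f, sum(isF))
    if (any(isM)) L[isM] <- draw_pmf(spec$pmf_m, sum(isM))
    death_age[adult] <- entry[adult, n_imm + 1L] + L[adult]
    a0 <- floor(spec$apop_mean)
    apop <- a0 + stats::rbinom(n, 1L, spec$apop_mean - a0)
    W <- max(death_age)
    eggs <- matrix(0L, n, W)
    for (i in which(isF)) {
      first <- entry[i, n_imm + 1L] + apop[i]
      d_max <- min(spec$ovi_window, death_age[i] - first)
      if (d_max < 1L) next
      mu <- spec$fec_daily[seq_len(d_max)]
      counts <- if (is.finite(spec$fecundity_dispersion))
        stats::rnbinom(d_max, size = spec$fecundity_dispersion, mu = mu)
      else stats::rpois(d_max, mu)
      eggs[i, first + seq_len(d_max)] <- counts   # column x+1 = age x
    }
    records <- data.frame(
      id = sprintf("%s_%03d", spec$label, seq_len(n)),
      sex = sex,
      excluded = FALSE, censored = FALSE,
      death_age = death_age, stringsAsFactors = FALSE)
    cohort_table(records, entry, eggs, treatment = spec$label,
                 schema = schema)
  })
}
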