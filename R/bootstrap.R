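#' @title Bootstrap machinery for cohort life tables
#' @description Internal sufficient statistics: everything any supported
#'   parameter needs is a function of per-individual vectors (eggs-by-age
#'   rows, lifetime eggs, sex, adult entry, first-egg age, death age), so a
#'   bootstrap replicate never rebuilds the full cohort object. This is an
#'   exact algebraic shortcut: the net maternity schedule is
#'   l_x m_x = (column sums of eggs-by-age over sampled individuals) / n01.
#' @noRd
cohort_boot_stats <- function(cohort) {
  idx <- included_idx(cohort)
  rec <- cohort$records[idx, , drop = FALSE]
  ent <- cohort$entry[idx, , drop = FALSE]
  eggs <- cohort$eggs[idx, , drop = FALSE]
  if (any(rec$censored)) {
    warning("censored individuals are excluded from bootstrap resampling")
    keep <- !rec$censored
    rec <- rec[keep, , drop = FALSE]
    ent <- ent[keep, , drop = FALSE]
    eggs <- eggs[keep, , drop = FALSE]
  }
  n_imm <- n_immature(cohort$schema)
  adult_entry <- ent[, n_imm + 1L]
  first_egg <- apply(eggs, 1L, function(v) {
    w <- which(v > 0L)
    if (length(w)) w[1L] - 1L else NA_integer_
  })
  list(
    n = nrow(rec),
    eggs = eggs,
    lifetime = if (ncol(eggs)) rowSums(eggs) else rep(0, nrow(rec)),
    ovi_days = if (ncol(eggs)) rowSums(eggs > 0L) else rep(0, nrow(rec)),
    first_egg = as.numeric(first_egg),
    adult_entry = as.numeric(adult_entry),
    death_age = as.numeric(rec$death_age),
    isF = rec$sex == "F",
    isM = rec$sex == "M",
    reached_adult = !is.na(adult_entry))
}

boot_parameters <- c("R0", "r", "lambda", "T", "fecundity", "APOP", "TPOP",
                     "oviposition_days", "female_longevity", "male_longevity",
                     "sex_ratio", "immature_mortality")

# closure computing the requested parameters for a resample index vector;
# undefined parameters (no females drawn, R0 = 0, ...) come back NA
make_param_fun <- function(st, parameters, bracket, tol) {
  parameters <- match.arg(parameters, boot_parameters, several.ok = TRUE)
  need_r <- any(c("r", "lambda", "T") %in% parameters)
  function(idx) {
    n <- length(idx)
    out <- stats::setNames(rep(NA_real_, length(parameters)), parameters)
    lt <- st$lifetime[idx]
    R0 <- sum(lt) / n
    if ("R0" %in% parameters) out["R0"] <- R0
    if (need_r) {
      r <- NA_real_
      if (R0 > 0) {
        phi <- colSums(st$eggs[idx, , drop = FALSE]) / n
        sol <- tryCatch(solve_r_bisect(phi, bracket, tol), error = function(e) NULL)
        if (!is.null(sol)) r <- sol$r
      }
      if ("r" %in% parameters) out["r"] <- r
      if ("lambda" %in% parameters) out["lambda"] <- exp(r)
      if ("T" %in% parameters && !is.na(r) && r != 0) out["T"] <- log(R0) / r
    }
    f <- st$isF[idx]
    if ("fecundity" %in% parameters && any(f)) out["fecundity"] <- mean(lt[f])
    repro <- f & lt > 0
    if (any(repro)) {
      if ("APOP" %in% parameters)
        out["APOP"] <- mean(st$first_egg[idx][repro] - st$adult_entry[idx][repro])
      if ("TPOP" %in% parameters)
        out["TPOP"] <- mean(st$first_egg[idx][repro])
      if ("oviposition_days" %in% parameters)
        out["oviposition_days"] <- mean(st$ovi_days[idx][repro])
    }
    if ("female_longevity" %in% parameters && any(f))
      out["female_longevity"] <- mean(st$death_age[idx][f] - st$adult_entry[idx][f])
    m <- st$isM[idx]
    if ("male_longevity" %in% parameters && any(m))
      out["male_longevity"] <- mean(st$death_age[idx][m] - st$adult_entry[idx][m])
    if ("sex_ratio" %in% parameters) out["sex_ratio"] <- sum(f) / n
    if ("immature_mortality" %in% parameters)
      out["immature_mortality"] <- mean(!st$reached_adult[idx])
    out
  }
}

#' Bootstrap standard errors for life-table parameters
#'
#' Resamples `n01` individuals (whole life histories) with replacement `B`
#' times, recomputes every requested parameter per replicate, and reports the
#' bootstrap mean, standard error (SD over valid replicates), and percentile
#' confidence interval. Replicates where a parameter is undefined (e.g. no
#' females drawn for APOP, or R0 = 0 for r) are dropped from that parameter's
#' distribution; `B_valid` records how many replicates remained. With fewer
#' than two valid replicates the SE is 0 by convention and the result is
#' flagged degenerate.
#'
#' @param cohort A [cohort_table()].
#' @param B Number of bootstrap resamples.
#' @param seed Optional integer seed; with a fixed seed results are
#'   bit-reproducible.
#' @param parameters Character vector of parameter names, a subset of:
#'   R0, r, lambda, T, fecundity, APOP, TPOP, oviposition_days,
#'   female_longevity, male_longevity, sex_ratio, immature_mortality.
#' @param level Confidence level for the percentile interval.
#' @param bracket,tol Passed to the Euler-Lotka solver for per-replicate `r`.
#' @return A data frame of class `bootstrap_result` with columns `parameter`,
#'   `estimate`, `boot_mean`, `se`, `ci_lo`, `ci_hi`, `B`, `B_valid`,
#'   `degenerate`, `seed`.
#' @export
bootstrap_cohort <- function(cohort, B = 100000L, seed = NULL,
                             parameters = boot_parameters, level = 0.95,
                             bracket = c(-0.5, 1.5), tol = 1e-10) {
  stopifnot(inherits(cohort, "cohort_table"), B >= 1L, level > 0, level < 1)
  parameters <- match.arg(parameters, boot_parameters, several.ok = TRUE)
  st <- cohort_boot_stats(cohort)
  pf <- make_param_fun(st, parameters, bracket, tol)
  point <- pf(seq_len(st$n))
  reps <- with_local_seed(seed, {
    vapply(seq_len(B),
           function(b) pf(sample.int(st$n, st$n, replace = TRUE)),
           numeric(length(parameters)))
  })
  # vapply drops to a plain vector when a single parameter is requested
  reps <- if (length(parameters) == 1L) matrix(reps, ncol = 1L) else t(reps)
  alpha <- (1 - level) / 2
  out <- do.call(rbind, lapply(seq_along(parameters), function(j) {
    v <- reps[, j]
    v <- v[!is.na(v)]
    nv <- length(v)
    data.frame(
      parameter = parameters[j],
      estimate = point[j],
      boot_mean = if (nv) mean(v) else NA_real_,
      se = if (nv > 1L) stats::sd(v) else 0,
      ci_lo = if (nv) unname(stats::quantile(v, alpha)) else NA_real_,
      ci_hi = if (nv) unname(stats::quantile(v, 1 - alpha)) else NA_real_,
      B = B, B_valid = nv, degenerate = nv < 2L,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      stringsAsFactors = FALSE)
  }))
  class(out) <- c("bootstrap_result", class(out))
  out
}

#' Paired bootstrap test for a treatment difference
#'
#' For each replicate `b`, both cohorts are independently resampled (common
#' replicate index), the parameter is computed in each, and the difference
#' `A - B` recorded. The percentile interval of the `B` differences at the
#' stated level is the test: the difference is declared significant when the
#' interval excludes 0.
#'
#' @param cohort_a,cohort_b Two [cohort_table()] objects.
#' @param parameter A single parameter name (see [bootstrap_cohort()]).
#' @param B Number of paired resamples.
#' @param seed Optional integer seed.
#' @param level Confidence level (default 0.95).
#' @param bracket,tol Euler-Lotka solver controls.
#' @return A one-row data frame of class `paired_test` with the point
#'   difference, its percentile CI, the significance flag, and bookkeeping
#'   columns.
#' @export
paired_bootstrap_test <- function(cohort_a, cohort_b, parameter,
                                  B = 100000L, seed = NULL, level = 0.95,
                                  bracket = c(-0.5, 1.5), tol = 1e-10) {
  stopifnot(inherits(cohort_a, "cohort_table"),
            inherits(cohort_b, "cohort_table"),
            length(parameter) == 1L, B >= 1L, level > 0, level < 1)
  sa <- cohort_boot_stats(cohort_a)
  sb <- cohort_boot_stats(cohort_b)
  pa <- make_param_fun(sa, parameter, bracket, tol)
  pb <- make_param_fun(sb, parameter, bracket, tol)
  est_a <- unname(pa(seq_len(sa$n)))
  est_b <- unname(pb(seq_len(sb$n)))
  diffs <- with_local_seed(seed, {
    vapply(seq_len(B), function(b) {
      da <- pa(sample.int(sa$n, sa$n, replace = TRUE))
      db <- pb(sample.int(sb$n, sb$n, replace = TRUE))
      unname(da - db)
    }, numeric(1))
  })
  v <- diffs[!is.na(diffs)]
  alpha <- (1 - level) / 2
  ci <- if (length(v)) unname(stats::quantile(v, c(alpha, 1 - alpha)))
        else c(NA_real_, NA_real_)
  out <- data.frame(
    parameter = parameter,
    treatment_a = cohort_a$treatment, treatment_b = cohort_b$treatment,
    estimate_a = est_a, estimate_b = est_b,
    difference = est_a - est_b,
    ci_lo = ci[1], ci_hi = ci[2],
    significant = !anyNA(ci) && (ci[1] > 0 || ci[2] < 0),
    level = level, B = B, B_valid = length(v),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    stringsAsFactors = FALSE)
  class(out) <- c("paired_test", class(out))
  out
}
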