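#' Stage-level developmental summaries
#'
#' Per-stage duration means and standard errors, per-stage death counts, the
#' immature mortality proportion, pre-adult development time by sex, and sex
#' counts. A stage's duration for an individual is the entry age of the next
#' stage minus the entry age of this stage; the stage an individual dies in
#' contributes no duration. Immature mortality is
#' (n01 - number reaching any adult stage) / n01.
#'
#' @param cohort A [cohort_table()].
#' @return A list of class `stage_summary` with elements `durations`
#'   (data frame: stage, n, mean, se), `deaths` (data frame: stage, died),
#'   `immature_mortality`, `preadult` (data frame: sex, n, mean, se),
#'   `sex_counts` (named vector F/M/N), and `n01`. Censored individuals are
#'   dropped from all summaries with a warning.
#' @export
stage_summaries <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  idx <- included_idx(cohort)
  if (!length(idx)) stop("all individuals are excluded; nothing to analyse")
  rec <- cohort$records[idx, , drop = FALSE]
  ent <- cohort$entry[idx, , drop = FALSE]
  if (any(rec$censored)) {
    warning("censored individuals are excluded from stage summaries")
    keep <- !rec$censored
    rec <- rec[keep, , drop = FALSE]
    ent <- ent[keep, , drop = FALSE]
  }
  schema <- cohort$schema
  n_imm <- n_immature(schema)
  n01 <- cohort$n01
  se <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
  durations <- do.call(rbind, lapply(seq_len(n_imm), function(j) {
    d <- ent[, j + 1L] - ent[, j]
    d <- d[!is.na(d)]
    data.frame(stage = schema$stages[j], n = length(d),
               mean = if (length(d)) mean(d) else NA_real_,
               se = if (length(d)) se(d) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  # died in stage j: entered j, never entered j+1
  deaths <- do.call(rbind, lapply(seq_len(n_imm), function(j) {
    died <- sum(!is.na(ent[, j]) & is.na(ent[, j + 1L]))
    data.frame(stage = schema$stages[j], died = died, stringsAsFactors = FALSE)
  }))
  reached_adult <- !is.na(ent[, n_imm + 1L])
  preadult <- do.call(rbind, lapply(c("F", "M"), function(sx) {
    a <- ent[rec$sex == sx, n_imm + 1L]
    a <- a[!is.na(a)]
    data.frame(sex = sx, n = length(a),
               mean = if (length(a)) mean(a) else NA_real_,
               se = if (length(a)) se(a) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(
    list(durations = durations, deaths = deaths,
         immature_mortality = (n01 - sum(reached_adult)) / n01,
         preadult = preadult,
         sex_counts = c(F = sum(rec$sex == "F"), M = sum(rec$sex == "M"),
                        N = sum(rec$sex == "N")),
         n01 = n01, treatment = cohort$treatment),
    class = "stage_summary")
}

#' @export
print.stage_summary <- function(x, ...) {
  cat("Stage summary for '", x$treatment, "' (n01 = ", x$n01, ")\n", sep = "")
  cat("  immature mortality: ", format(x$immature_mortality, digits = 3),
      " (", paste(x$deaths$died, collapse = "/"), " deaths by stage)\n", sep = "")
  print(x$durations, row.names = FALSE)
  invisible(x)
}

#' Reproductive-period summaries
#'
#' Per-cohort reproductive statistics:
#' \itemize{
#'   \item APOP (adult pre-oviposition period): first-egg age minus adult
#'     entry age, per reproducing female;
#'   \item TPOP (total pre-oviposition period): first-egg age;
#'   \item oviposition days: number of ages with at least one egg laid;
#'   \item adult longevity by sex: death age minus adult entry age;
#'   \item sex ratio: females / n01 by default (`sex_ratio`), with the
#'     adults-only alternative females / (females + males) reported alongside
#'     (`sex_ratio_adults`);
#'   \item fecundity: lifetime eggs averaged over all females.
#' }
#' Statistics with an empty support (e.g. APOP in a cohort with no
#' reproducing female) are reported as `NA` and listed in `$undefined`,
#' never as zero.
#'
#' @param cohort A [cohort_table()].
#' @return A list of class `reproductive_summary` with `$table` (data frame:
#'   statistic, n, mean, se), `$undefined` (character vector), `$total_eggs`,
#'   and `$n01`.
#' @export
reproductive_summary <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  idx <- included_idx(cohort)
  if (!length(idx)) stop("all individuals are excluded; nothing to analyse")
  rec <- cohort$records[idx, , drop = FALSE]
  ent <- cohort$entry[idx, , drop = FALSE]
  eggs <- cohort$eggs[idx, , drop = FALSE]
  if (any(rec$censored)) {
    warning("censored individuals are excluded from reproductive summaries")
    keep <- !rec$censored
    rec <- rec[keep, , drop = FALSE]
    ent <- ent[keep, , drop = FALSE]
    eggs <- eggs[keep, , drop = FALSE]
  }
  n_imm <- n_immature(cohort$schema)
  n01 <- cohort$n01
  adult_entry <- ent[, n_imm + 1L]
  fem <- rec$sex == "F"
  mal <- rec$sex == "M"
  lifetime <- if (ncol(eggs)) rowSums(eggs) else rep(0L, nrow(rec))
  first_egg <- apply(eggs, 1L, function(v) {
    w <- which(v > 0L)
    if (length(w)) w[1L] - 1L else NA_integer_
  })
  ovi_days <- if (ncol(eggs)) rowSums(eggs > 0L) else rep(0L, nrow(rec))
  repro <- fem & lifetime > 0L
  se <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
  row <- function(name, v) {
    v <- v[!is.na(v)]
    data.frame(statistic = name, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               se = if (length(v)) se(v) else NA_real_,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(
    row("APOP", (first_egg - adult_entry)[repro]),
    row("TPOP", first_egg[repro]),
    row("oviposition_days", ovi_days[repro]),
    row("female_longevity", (rec$death_age - adult_entry)[fem]),
    row("male_longevity", (rec$death_age - adult_entry)[mal]),
    row("fecundity", lifetime[fem]))
  nF <- sum(fem); nM <- sum(mal)
  sr <- nF / n01
  sra <- if (nF + nM > 0L) nF / (nF + nM) else NA_real_
  tab <- rbind(tab,
    data.frame(statistic = "sex_ratio", n = n01, mean = sr,
               se = sqrt(sr * (1 - sr) / n01), stringsAsFactors = FALSE),
    data.frame(statistic = "sex_ratio_adults", n = nF + nM, mean = sra,
               se = if (is.na(sra)) NA_real_
                    else sqrt(sra * (1 - sra) / max(nF + nM, 1L)),
               stringsAsFactors = FALSE))
  structure(
    list(table = tab, undefined = tab$statistic[is.na(tab$mean)],
         total_eggs = sum(lifetime), n01 = n01, treatment = cohort$treatment),
    class = "reproductive_summary")
}

#' @export
print.reproductive_summary <- function(x, ...) {
  cat("Reproductive summary for '", x$treatment, "' (n01 = ", x$n01,
      ", total eggs = ", x$total_eggs, ")\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  if (length(x$undefined))
    cat("  undefined: ", paste(x$undefined, collapse = ", "), "\n", sep = "")
  invisible(x)
}
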