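#' Read a cohort CSV file
#'
#' The cohort CSV dialect is comma-separated UTF-8 with one row per
#' individual and columns: `id`, `treatment`, `excluded` (0/1), `censored`
#' (0/1, optional on input), `sex` (F/M/N), one `age_<stage>` column per
#' immature stage of the schema (egg entry always 0; blank means the stage
#' was never reached), `age_adult` (blank if died immature), `death_age`,
#' then `eggs_d0`, `eggs_d1`, ... daily egg counts by age (trailing zeros
#' omissible).
#'
#' Excluded individuals (e.g. escapees drowned on the cotton barrier) are
#' retained in the file but flagged and dropped from the cohort size `n01`.
#'
#' @param path Path to the CSV file.
#' @param schema A [stage_schema()]; defaults to [default_schema()].
#' @return A validated [cohort_table()].
#' @export
read_cohort <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  n_imm <- n_immature(schema)
  age_cols <- c(paste0("age_", schema$stages[seq_len(n_imm)]), "age_adult")
  need <- c("id", "treatment", "excluded", "sex", age_cols, "death_age")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("cohort file has a valid header but no individuals")
  to_int <- function(col) {
    v <- df[[col]]
    v[v %in% c("", "NA")] <- NA
    out <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop("malformed value in row ", bad[1], ", column '", col, "'")
    out
  }
  entry <- sapply(age_cols, to_int)
  if (nrow(df) == 1L) entry <- matrix(entry, nrow = 1L)
  egg_cols <- grep("^eggs_d[0-9]+$", names(df), value = TRUE)
  if (length(egg_cols)) {
    ages <- as.integer(sub("^eggs_d", "", egg_cols))
    eggs <- matrix(0L, nrow(df), max(ages) + 1L)
    for (j in seq_along(egg_cols)) {
      v <- to_int(egg_cols[j])
      v[is.na(v)] <- 0L
      eggs[, ages[j] + 1L] <- v
    }
  } else {
    eggs <- matrix(0L, nrow(df), 0L)
  }
  records <- data.frame(
    id = as.character(df$id),
    sex = as.character(df$sex),
    excluded = to_int("excluded") == 1L,
    censored = if ("censored" %in% names(df)) to_int("censored") == 1L
               else rep(FALSE, nrow(df)),
    death_age = to_int("death_age"),
    stringsAsFactors = FALSE)
  cohort <- cohort_table(records, entry, eggs,
                         treatment = df$treatment[1], schema = schema)
  if (cohort$n01 == 0L)
    stop("cohort has no non-excluded individuals (n01 = 0); nothing to analyse")
  if (any(records$censored))
    warning("cohort contains censored individuals; they count as alive ",
            "through last observation for survival schedules only")
  cohort
}

#' Write a cohort to CSV
#'
#' Writes the dialect documented in [read_cohort()]; a cohort written and
#' re-read round-trips field-for-field.
#'
#' @param cohort A [cohort_table()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  r <- cohort$records
  ent <- cohort$entry
  n_imm <- n_immature(cohort$schema)
  df <- data.frame(
    id = r$id,
    treatment = cohort$treatment,
    excluded = as.integer(r$excluded),
    censored = as.integer(r$censored),
    sex = r$sex,
    stringsAsFactors = FALSE)
  for (j in seq_len(n_imm))
    df[[paste0("age_", cohort$schema$stages[j])]] <- ent[, j]
  df$age_adult <- ent[, n_imm + 1L]
  df$death_age <- r$death_age
  if (ncol(cohort$eggs))
    df <- cbind(df, as.data.frame(cohort$eggs))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
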