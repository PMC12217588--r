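#' Assemble a validated cohort table
#'
#' A `cohort_table` holds one treatment's individual-level life histories:
#' per-individual stage entry ages (days, 0-based; the day an egg is laid is
#' age 0), sex, death age, daily egg counts, and exclusion/censoring flags.
#' `death_age` is the first daily census age at which the individual was
#' observed dead, so an individual is alive at ages `0 .. death_age - 1`.
#' For censored individuals `death_age` is the first unobserved age and the
#' individual counts as alive through its last observation.
#'
#' @param records Data frame with columns `id` (character, unique), `sex`
#'   (`"F"`, `"M"`, or `"N"` for died-immature), `excluded` (logical),
#'   `censored` (logical), `death_age` (integer).
#' @param entry Integer matrix, one row per record; columns are the immature
#'   stage names of `schema` followed by `"adult"`. `NA` means the stage was
#'   never reached. The egg column must be 0 everywhere.
#' @param eggs Integer matrix of daily egg counts, one row per record; column
#'   `x + 1` holds the eggs laid at age `x`. May have zero columns for a
#'   cohort that laid no eggs.
#' @param treatment Treatment label.
#' @param schema A [stage_schema()]; defaults to [default_schema()].
#' @return A `cohort_table` with cohort size `n01` = number of non-excluded
#'   records.
#' @export
cohort_table <- function(records, entry, eggs, treatment = "cohort",
                         schema = default_schema()) {
  stopifnot(inherits(schema, "stage_schema"))
  records <- as.data.frame(records)
  need <- c("id", "sex", "excluded", "censored", "death_age")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  records$id <- as.character(records$id)
  records$sex <- as.character(records$sex)
  records$excluded <- as.logical(records$excluded)
  records$censored <- as.logical(records$censored)
  records$death_age <- as.integer(records$death_age)
  entry <- as.matrix(entry)
  storage.mode(entry) <- "integer"
  eggs <- as.matrix(eggs)
  if (ncol(eggs)) storage.mode(eggs) <- "integer"
  # normalise egg matrix width to the last possible laying age (death - 1)
  W <- max(c(records$death_age, 0L), na.rm = TRUE)
  if (ncol(eggs) < W) {
    eggs <- cbind(eggs, matrix(0L, nrow(records), W - ncol(eggs)))
  } else if (ncol(eggs) > W) {
    if (any(eggs[, -seq_len(W), drop = FALSE] != 0L))
      stop("egg counts present beyond the last death age")
    eggs <- eggs[, seq_len(W), drop = FALSE]
  }
  colnames(eggs) <- if (W) paste0("eggs_d", 0:(W - 1L)) else character(0)
  n_imm <- n_immature(schema)
  expected_cols <- c(schema$stages[seq_len(n_imm)], "adult")
  if (ncol(entry) != length(expected_cols))
    stop("entry must have ", length(expected_cols), " columns (immature stages + adult)")
  colnames(entry) <- expected_cols
  if (nrow(entry) != nrow(records) || nrow(eggs) != nrow(records))
    stop("records, entry and eggs must have one row per individual")
  x <- structure(
    list(schema = schema, records = records, entry = entry, eggs = eggs,
         treatment = as.character(treatment)[1],
         n01 = sum(!records$excluded)),
    class = "cohort_table")
  validate_cohort(x)
  x
}

#' Validate a cohort table
#'
#' Checks every data-model invariant: unique ids, legal sex codes, egg entry
#' at age 0, strictly increasing entries along the traversed stage path with
#' no skipped stages, death after the last stage entry, died-immature
#' individuals without adult entry and without eggs, males without eggs, no
#' eggs before female adult entry or at/after death, nonnegative integer egg
#' counts.
#'
#' @param cohort A `cohort_table`.
#' @return Invisibly `TRUE`; otherwise an error naming the individual and the
#'   violated rule.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  r <- cohort$records
  ent <- cohort$entry
  eggs <- cohort$eggs
  fail <- function(id, rule) stop("individual '", id, "': ", rule, call. = FALSE)
  if (anyDuplicated(r$id)) stop("duplicate individual ids", call. = FALSE)
  n_imm <- n_immature(cohort$schema)
  for (i in seq_len(nrow(r))) {
    id <- r$id[i]
    if (!r$sex[i] %in% c("F", "M", "N")) fail(id, "sex must be F, M or N")
    e <- ent[i, ]
    if (is.na(e[1]) || e[1] != 0L) fail(id, "egg entry age must be 0")
    reached <- unname(which(!is.na(e)))
    if (!identical(reached, seq_len(max(reached))))
      fail(id, "stage entries skip a stage")
    if (any(diff(e[reached]) <= 0L))
      fail(id, "stage entry ages must strictly increase")
    has_adult <- !is.na(e[n_imm + 1L])
    if (has_adult && r$sex[i] == "N")
      fail(id, "died-immature individual has an adult entry")
    if (!has_adult && r$sex[i] != "N")
      fail(id, "sexed individual lacks an adult entry")
    if (is.na(r$death_age[i]) || r$death_age[i] <= max(e, na.rm = TRUE))
      fail(id, "death age must exceed the last stage entry age")
    ei <- if (ncol(eggs)) eggs[i, ] else integer(0)
    if (any(is.na(ei)) || any(ei < 0L)) fail(id, "egg counts must be nonnegative integers")
    tot <- sum(ei)
    if (r$sex[i] != "F" && tot > 0L) fail(id, "only females may have eggs")
    if (r$sex[i] == "F" && tot > 0L) {
      ages <- which(ei > 0L) - 1L
      if (any(ages < e[n_imm + 1L])) fail(id, "eggs laid before adult entry")
      if (any(ages >= r$death_age[i])) fail(id, "eggs laid at or after death age")
    }
  }
  invisible(TRUE)
}

# rows of the cohort that enter the analysis (non-excluded)
included_idx <- function(cohort) which(!cohort$records$excluded)

#' @export
print.cohort_table <- function(x, ...) {
  r <- x$records[!x$records$excluded, ]
  cat("Cohort '", x$treatment, "': n01 = ", x$n01,
      " (", sum(x$records$excluded), " excluded)\n", sep = "")
  cat("  females ", sum(r$sex == "F"), ", males ", sum(r$sex == "M"),
      ", died immature ", sum(r$sex == "N"),
      ", censored ", sum(r$censored), "\n", sep = "")
  cat("  max observed age ", max(r$death_age) - 1L, " d, total eggs ",
      if (ncol(x$eggs)) sum(x$eggs[!x$records$excluded, ]) else 0L, "\n", sep = "")
  invisible(x)
}
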