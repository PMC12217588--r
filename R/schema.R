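#' Stage schema for an age-stage, two-sex life table
#'
#' Defines the ordered developmental stages an individual can occupy, the
#' position of the first adult stage, and which adult stages correspond to
#' females and males. The default schema is the tetranychid mite life cycle:
#' egg, larva, protonymph, deutonymph, then adult-female / adult-male.
#'
#' @param stages Character vector of unique, ordered stage names, from egg to
#'   adult.
#' @param first_adult Integer index of the first adult stage within `stages`.
#' @param female_stage,male_stage Integer indices of the female-adult and
#'   male-adult stages; both must be `>= first_adult` and distinct.
#' @return An object of class `stage_schema`.
#' @examples
#' sc <- default_schema()
#' sc$stages
#' @export
stage_schema <- function(stages, first_adult, female_stage, male_stage) {
  stages <- as.character(stages)
  if (length(stages) < 2L || anyDuplicated(stages) || any(!nzchar(stages)))
    stop("stages must be at least two unique, nonempty names")
  first_adult <- as.integer(first_adult)
  female_stage <- as.integer(female_stage)
  male_stage <- as.integer(male_stage)
  k <- length(stages)
  if (first_adult < 2L || first_adult > k)
    stop("first_adult must index a stage after the egg stage")
  if (female_stage == male_stage)
    stop("female_stage and male_stage must be distinct")
  if (female_stage < first_adult || male_stage < first_adult)
    stop("adult sex stages must lie at or after first_adult")
  if (female_stage > k || male_stage > k)
    stop("adult sex stage index out of range")
  structure(
    list(stages = stages, first_adult = first_adult,
         female_stage = female_stage, male_stage = male_stage),
    class = "stage_schema")
}

#' @rdname stage_schema
#' @export
default_schema <- function() {
  stage_schema(
    stages = c("egg", "larva", "protonymph", "deutonymph",
               "adult_female", "adult_male"),
    first_adult = 5L, female_stage = 5L, male_stage = 6L)
}

#' Read a stage schema from a JSON descriptor
#'
#' The descriptor is a JSON object with fields `stages` (array of names),
#' `first_adult`, `female_stage`, `male_stage` (1-based indices).
#'
#' @param path Path to the JSON file.
#' @return A `stage_schema`.
#' @export
read_schema <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("stages", "first_adult", "female_stage", "male_stage"))
    if (is.null(x[[f]])) stop("schema descriptor missing field: ", f)
  stage_schema(x$stages, x$first_adult, x$female_stage, x$male_stage)
}

#' @export
print.stage_schema <- function(x, ...) {
  cat("Stage schema (", length(x$stages), " stages):\n", sep = "")
  lab <- x$stages
  lab[x$female_stage] <- paste0(lab[x$female_stage], " [female adult]")
  lab[x$male_stage] <- paste0(lab[x$male_stage], " [male adult]")
  cat(" ", paste(lab, collapse = " -> "), "\n")
  invisible(x)
}

# number of immature stages on the path to adulthood
n_immature <- function(schema) schema$first_adult - 1L
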