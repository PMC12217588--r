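# Compact builders for hand-written cohorts (default 6-stage schema).
# entries: numeric vector of stage entry ages in stage order, padded with NA
# for unreached stages (egg .. deutonymph, adult).
mk_ind <- function(id, sex, entries, death, eggs = NULL,
                   excluded = FALSE, censored = FALSE) {
  e <- rep(NA_integer_, 5L)
  e[seq_along(entries)] <- as.integer(entries)
  list(id = id, sex = sex, entry = e, death_age = as.integer(death),
       eggs = eggs, excluded = excluded, censored = censored)
}

mk_cohort <- function(inds, treatment = "test") {
  n <- length(inds)
  W <- max(vapply(inds, `[[`, integer(1), "death_age"))
  eggs <- matrix(0L, n, W)
  for (i in seq_len(n)) {
    ei <- inds[[i]]$eggs
    if (!is.null(ei)) {
      # eggs given as named vector: names are ages
      ages <- as.integer(names(ei))
      eggs[i, ages + 1L] <- as.integer(ei)
    }
  }
  records <- data.frame(
    id = vapply(inds, `[[`, character(1), "id"),
    sex = vapply(inds, `[[`, character(1), "sex"),
    excluded = vapply(inds, `[[`, logical(1), "excluded"),
    censored = vapply(inds, `[[`, logical(1), "censored"),
    death_age = vapply(inds, `[[`, integer(1), "death_age"),
    stringsAsFactors = FALSE)
  entry <- t(vapply(inds, `[[`, integer(5L), "entry"))
  cohort_table(records, entry, eggs, treatment = treatment)
}

# a simple reproducing female: adult at 16, first egg 17, dead at 33
mk_female <- function(id = "f1", total_eggs = 32, death = 33) {
  n_days <- death - 17L
  daily <- rep(total_eggs %/% n_days, n_days)
  r <- total_eggs %% n_days
  if (r) daily[seq_len(r)] <- daily[seq_len(r)] + 1L
  eggs <- stats::setNames(daily, 17:(death - 1L))
  mk_ind(id, "F", c(0, 8, 11, 13, 16), death, eggs = eggs)
}
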