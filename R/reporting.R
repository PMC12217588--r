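#' Compact letter display from pairwise bootstrap tests
#'
#' Assigns letters so that two treatments share a letter if and only if
#' their pairwise difference is not significant, using a greedy clique cover
#' of the "not significantly different" graph in treatment order. A
#' non-transitive significance pattern is still rendered (each treatment can
#' carry several letters) and flagged with a message.
#'
#' @param tests A data frame of [paired_bootstrap_test()] rows (stacked),
#'   all for the same parameter, covering every treatment pair.
#' @return Named character vector of letter strings, one per treatment, in
#'   first-appearance order.
#' @export
significance_letters <- function(tests) {
  stopifnot(is.data.frame(tests),
            all(c("treatment_a", "treatment_b", "significant") %in% names(tests)))
  trts <- unique(c(tests$treatment_a, tests$treatment_b))
  nt <- length(trts)
  same <- matrix(TRUE, nt, nt, dimnames = list(trts, trts))
  for (i in seq_len(nrow(tests))) {
    a <- tests$treatment_a[i]; b <- tests$treatment_b[i]
    same[a, b] <- same[b, a] <- !tests$significant[i]
  }
  # cover every "not different" edge with a clique, greedily extended in
  # treatment order, then add singletons for fully separated treatments
  groups <- list()
  in_common_group <- function(a, b)
    any(vapply(groups, function(g) all(c(a, b) %in% g), logical(1)))
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    a <- trts[i]; b <- trts[j]
    if (!same[a, b] || in_common_group(a, b)) next
    g <- c(a, b)
    for (t in trts) if (!(t %in% g) && all(same[t, g])) g <- c(g, t)
    groups[[length(groups) + 1L]] <- g
  }
  for (t in trts)
    if (!any(vapply(groups, function(g) t %in% g, logical(1))))
      groups[[length(groups) + 1L]] <- t
  groups <- groups[order(vapply(groups, function(g) min(match(g, trts)),
                                numeric(1)))]
  letters_out <- stats::setNames(rep("", nt), trts)
  for (g in seq_along(groups))
    for (t in groups[[g]])
      letters_out[t] <- paste0(letters_out[t], letters[g])
  if (any(nchar(letters_out) > 1L))
    message("non-transitive significance pattern: some treatments carry ",
            "multiple letters")
  letters_out
}

#' Run the full life-table analysis over one or more cohorts
#'
#' Orchestrates the pipeline: schedules, stage and reproductive summaries,
#' demographic parameters, bootstrap SEs, pairwise paired bootstrap tests
#' with compact letters (when more than one cohort is supplied), and the
#' population projection. Optionally writes the report tables as CSV, a JSON
#' parameter dump, and (flag-gated) schedule/projection plots, plus a plain
#' text run log recording seed, B and package version.
#'
#' @param cohorts Named list of [cohort_table()] objects (names = treatment
#'   labels) or a single cohort.
#' @param B Bootstrap replicates.
#' @param seed Integer master seed; per-cohort and per-test seeds are
#'   derived from it deterministically.
#' @param level Confidence level for bootstrap intervals and tests.
#' @param parameters Parameters to bootstrap and compare.
#' @param initial_eggs,horizon Projection settings.
#' @param outdir Optional output directory for CSV/JSON/log files; created
#'   if missing. On failure any files already written there by this run are
#'   removed.
#' @param plots If `TRUE` (and `outdir` given) writes schedule and
#'   projection PNG plots.
#' @param digits Rounding for the human-readable report tables; full
#'   precision always goes to the machine-readable sidecar.
#' @return A list of class `analysis_bundle` with `schedules`,
#'   `stage_tables`, `repro_tables`, `params` (per-treatment point estimates
#'   and SEs with letters), `tests`, `projections`, and `config`.
#' @export
run_full_analysis <- function(cohorts, B = 2000L, seed = 1L, level = 0.95,
                              parameters = c("R0", "r", "lambda", "T"),
                              initial_eggs = 10, horizon = 60L,
                              outdir = NULL, plots = FALSE, digits = 2L) {
  if (inherits(cohorts, "cohort_table")) cohorts <- list(cohorts)
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts))))
    names(cohorts) <- vapply(cohorts, `[[`, character(1), "treatment")
  written <- character(0)
  stage_wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("analysis stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  schedules <- stage_wrap("schedules", lapply(cohorts, compute_schedules))
  stage_tables <- stage_wrap("stage_summaries", lapply(cohorts, stage_summaries))
  repro_tables <- stage_wrap("reproductive_summary",
                             lapply(cohorts, reproductive_summary))
  boots <- stage_wrap("bootstrap", {
    lapply(seq_along(cohorts), function(i)
      bootstrap_cohort(cohorts[[i]], B = B, seed = seed + i,
                       parameters = parameters, level = level))
  })
  names(boots) <- names(cohorts)
  tests <- NULL
  letter_tab <- NULL
  if (length(cohorts) > 1L) {
    tests <- stage_wrap("paired_tests", {
      prs <- utils::combn(seq_along(cohorts), 2L, simplify = FALSE)
      do.call(rbind, lapply(parameters, function(p) {
        do.call(rbind, lapply(seq_along(prs), function(q) {
          i <- prs[[q]][1]; j <- prs[[q]][2]
          paired_bootstrap_test(cohorts[[i]], cohorts[[j]], parameter = p,
                                B = B, seed = seed + 100L * q +
                                  1000L * match(p, parameters),
                                level = level)
        }))
      }))
    })
    letter_tab <- do.call(rbind, lapply(parameters, function(p) {
      lt <- significance_letters(tests[tests$parameter == p, , drop = FALSE])
      data.frame(parameter = p, treatment = names(lt), letter = unname(lt),
                 stringsAsFactors = FALSE)
    }))
  }
  params <- do.call(rbind, lapply(names(cohorts), function(nm) {
    b <- boots[[nm]]
    df <- data.frame(treatment = nm, parameter = b$parameter,
                     estimate = b$estimate, boot_mean = b$boot_mean,
                     se = b$se, ci_lo = b$ci_lo, ci_hi = b$ci_hi,
                     B_valid = b$B_valid, stringsAsFactors = FALSE)
    if (!is.null(letter_tab))
      df$letter <- letter_tab$letter[match(paste(df$parameter, nm),
                                           paste(letter_tab$parameter,
                                                 letter_tab$treatment))]
    df
  }))
  projections <- stage_wrap("projection",
    lapply(schedules, project_population,
           initial_eggs = initial_eggs, horizon = horizon))
  bundle <- structure(
    list(schedules = schedules, stage_tables = stage_tables,
         repro_tables = repro_tables, params = params, tests = tests,
         projections = projections,
         config = list(B = B, seed = seed, level = level,
                       parameters = parameters, initial_eggs = initial_eggs,
                       horizon = horizon, digits = digits)),
    class = "analysis_bundle")
  if (!is.null(outdir)) {
    stage_wrap("write_outputs", {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      wr <- function(df, f) {
        p <- file.path(outdir, f)
        utils::write.csv(df, p, row.names = FALSE)
        written <<- c(written, p)
      }
      rounded <- params
      num <- vapply(rounded, is.numeric, logical(1))
      rounded[num] <- lapply(rounded[num], round, digits = digits)
      wr(rounded, "params_table.csv")
      wr(params, "params_full_precision.csv")
      if (!is.null(tests)) wr(tests, "paired_tests.csv")
      wr(do.call(rbind, lapply(names(stage_tables), function(nm)
        cbind(treatment = nm, stage_tables[[nm]]$durations,
              died = stage_tables[[nm]]$deaths$died))), "stage_table.csv")
      wr(do.call(rbind, lapply(names(repro_tables), function(nm)
        cbind(treatment = nm, repro_tables[[nm]]$table))), "repro_table.csv")
      for (nm in names(schedules))
        wr(schedules_wide(schedules[[nm]]),
           paste0("schedule_wide_", nm, ".csv"))
      for (nm in names(projections))
        wr(as.data.frame(projections[[nm]]), paste0("projection_", nm, ".csv"))
      pj <- file.path(outdir, "params.json")
      jsonlite::write_json(params, pj, auto_unbox = TRUE, digits = NA)
      written <<- c(written, pj)
      logp <- file.path(outdir, "run_log.txt")
      writeLines(c(
        paste("twosexlt", as.character(utils::packageVersion("twosexlt"))),
        paste("date:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
        paste("seed:", seed), paste("B:", B), paste("level:", level),
        paste("treatments:", paste(names(cohorts), collapse = ", ")),
        paste("parameters:", paste(parameters, collapse = ", "))), logp)
      written <<- c(written, logp)
      if (plots) {
        for (nm in names(schedules)) {
          p <- file.path(outdir, paste0("schedules_", nm, ".png"))
          grDevices::png(p, width = 900, height = 600)
          plot_schedules(schedules[[nm]])
          grDevices::dev.off()
          written <<- c(written, p)
        }
        p <- file.path(outdir, "projection.png")
        grDevices::png(p, width = 900, height = 600)
        plot_projections(projections)
        grDevices::dev.off()
        written <<- c(written, p)
      }
    })
  }
  bundle
}

#' Base-graphics schedule and projection plots
#'
#' @param schedules A `schedule_set`.
#' @return Invisibly `NULL`; draws on the current device.
#' @export
plot_schedules <- function(schedules) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  A <- 0:schedules$omega
  graphics::matplot(A, schedules$s_xj, type = "l", lty = 1,
                    xlab = "age (days)", ylab = "s_xj",
                    main = paste0("age-stage survival (",
                                  schedules$treatment, ")"))
  graphics::legend("topright", colnames(schedules$s_xj), lty = 1,
                   col = seq_len(ncol(schedules$s_xj)), cex = 0.7)
  graphics::plot(A, schedules$l_x, type = "l", ylim = c(0, 1),
                 xlab = "age (days)", ylab = "l_x (m_x scaled)",
                 main = "survival and fecundity")
  if (max(schedules$m_x) > 0)
    graphics::lines(A, schedules$m_x / max(schedules$m_x), lty = 2)
  invisible(NULL)
}

#' @param projections Named list of `projection_series`.
#' @rdname plot_schedules
#' @export
plot_projections <- function(projections) {
  tot <- sapply(projections, `[[`, "total")
  graphics::matplot(projections[[1]]$day, log10(pmax(tot, 1e-9)), type = "l",
                    lty = 1, xlab = "day", ylab = "log10 total individuals",
                    main = "population projection")
  graphics::legend("topleft", names(projections), lty = 1,
                   col = seq_along(projections), cex = 0.8)
  invisible(NULL)
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("Life-table analysis bundle:", length(x$schedules), "treatment(s), B =",
      x$config$B, ", seed =", x$config$seed, "\n")
  print(x$params, row.names = FALSE, digits = 4)
  invisible(x)
}
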