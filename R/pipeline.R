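#' Write a trial dataset to long-format CSV
#'
#' Native dialect: one row per trial, UTF-8, '.' decimal, header
#' `subject_id, beneficiary, audience, trial_index, xL, yL, pL, xR, yR,
#' pR, choice, obtained, counterfactual, rating`. Derived columns
#' (decision variables, experienced-emotion factors) are recomputed on
#' read and not written.
#'
#' @param data Dataset (from [simulate_dataset()] or [read_dataset()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  cols <- c("subject_id", "beneficiary", "audience", "trial_index",
            "xL", "yL", "pL", "xR", "yR", "pR",
            "choice", "obtained", "counterfactual", "rating")
  d <- as.data.frame(data)
  missing_cols <- setdiff(cols, names(d))
  if (length(missing_cols)) {
    stop("dataset lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  write.csv(d[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a long-format trial dataset
#'
#' Reads a trial CSV in the native dialect (see [write_dataset()]) or, for
#' external deposits with unknown schemas, in a `"mapped"` dialect where
#' `mapping` renames the file's columns onto the native ones. Rows
#' violating the lottery invariants (`x > y` on each side, `p` in (0, 1))
#' or missing a choice are dropped, with per-reason counts reported via
#' `message()` and stored in the `"dropped"` attribute. Decision
#' variables and experienced-emotion factors are recomputed from the raw
#' columns.
#'
#' @param path CSV file path.
#' @param dialect `"native"` or `"mapped"`.
#' @param mapping For `"mapped"`: named character vector,
#'   `c(native_column = "file_column", ...)`, covering at least the
#'   lottery columns, `subject_id`, condition labels and `choice`.
#' @return A validated data frame of class `"wof_dataset"`.
#' @export
read_dataset <- function(path, dialect = c("native", "mapped"), mapping = NULL) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop("unknown dialect '", dialect[1],
                                               "'; supported: native, mapped",
                                               call. = FALSE))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("empty dataset: ", path, call. = FALSE)
  if (dialect == "mapped") {
    if (is.null(mapping) || is.null(names(mapping))) {
      stop("mapped dialect requires a named column mapping", call. = FALSE)
    }
    missing_cols <- setdiff(unname(mapping), names(d))
    if (length(missing_cols)) {
      stop("mapped columns absent from file: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    for (native in names(mapping)) d[[native]] <- d[[mapping[[native]]]]
  }
  need <- c("subject_id", "beneficiary", "audience", "trial_index",
            "xL", "yL", "pL", "xR", "yR", "pR", "choice")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("dataset lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"rating" %in% names(d)) d$rating <- NA_real_

  bad_lottery <- with(d, !(xL > yL) | !(xR > yR) |
                        !(pL > 0 & pL < 1) | !(pR > 0 & pR < 1) |
                        !is.finite(xL) | !is.finite(yL) |
                        !is.finite(xR) | !is.finite(yR))
  bad_choice <- is.na(d$choice) | !(d$choice %in% c(0, 1))
  dropped <- c(invalid_lottery = sum(bad_lottery, na.rm = TRUE),
               missing_or_invalid_choice = sum(!bad_lottery & bad_choice,
                                               na.rm = TRUE))
  keep <- !bad_lottery & !bad_choice
  keep[is.na(keep)] <- FALSE
  if (any(!keep)) {
    message("read_dataset: dropped ", sum(!keep), " row(s) [",
            paste(names(dropped), dropped, sep = " = ", collapse = ", "), "]")
  }
  d <- d[keep, , drop = FALSE]
  if (nrow(d) == 0L) stop("no valid rows after validation", call. = FALSE)
  d <- add_decision_variables(d)
  if (all(c("obtained", "counterfactual") %in% names(d))) {
    d$regret <- d$counterfactual - d$obtained
    other <- ifelse(d$choice == 1L,
                    ifelse(d$obtained == d$xL, d$yL, d$xL),
                    ifelse(d$obtained == d$xR, d$yR, d$xR))
    d$disappointment <- other - d$obtained
  }
  rownames(d) <- NULL
  attr(d, "dropped") <- dropped
  class(d) <- c("wof_dataset", class(d))
  d
}

#' Read a pipeline configuration from YAML
#'
#' Builds a [simulation_config()] from a YAML file with top-level keys
#' matching the constructor's arguments (`n_subjects`,
#' `n_trials_per_condition`, `seed`, `alphabet`, `probability_grid`, ...)
#' and an optional `population` block with the offset vectors of
#' [population_spec()].
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pop_args <- y$population %||% list()
  pop_args <- lapply(pop_args, unlist)
  population <- do.call(population_spec, pop_args)
  args <- y[setdiff(names(y), "population")]
  args$population <- population
  do.call(simulation_config, args)
}

#' Run the full two-stage pipeline and collect a report
#'
#' Simulates (or ingests) a dataset, fits the four per-condition choice
#' and rating models, extracts per-subject coefficients, and runs the
#' five stage-2 ANOVAs (choice: `e`, `sd`, `r`; rating: `b_reg`,
#' `b_dis`). Deterministic given the configuration seed.
#'
#' @param config A [simulation_config()] (ignored when `data` is given).
#' @param data Optional pre-loaded dataset (e.g. from [read_dataset()]);
#'   when `NULL`, data are simulated from `config`.
#' @param method Stage-1 choice estimation method, see
#'   [fit_choice_condition()].
#' @return Object of class `"run_report"`: list with `choice_fits`,
#'   `rating_fits` (one per cell, named `"self.absent"` etc.),
#'   `subject_coefficients` (long data frame), `anovas` (named list of
#'   [rm_anova_2x2()] tables), and `provenance` (seed, design size,
#'   package version).
#' @export
run_full <- function(config = NULL, data = NULL,
                     method = c("laplace", "pirls")) {
  method <- match.arg(method)
  if (is.null(data)) {
    stopifnot(inherits(config, "simulation_config"))
    data <- simulate_dataset(config)
  }
  cells <- expand.grid(beneficiary = c("self", "partner"),
                       audience = c("absent", "present"),
                       stringsAsFactors = FALSE)
  cell_name <- function(i) paste(cells$beneficiary[i], cells$audience[i], sep = ".")

  choice_fits <- list(); rating_fits <- list(); coef_rows <- list()
  for (i in seq_len(nrow(cells))) {
    nm <- cell_name(i)
    cf <- fit_choice_condition(data, cells$beneficiary[i], cells$audience[i],
                               method = method)
    rf <- fit_rating_condition(data, cells$beneficiary[i], cells$audience[i])
    choice_fits[[nm]] <- cf
    rating_fits[[nm]] <- rf
    cc <- extract_subject_coefficients(cf)
    rc <- extract_rating_coefficients(rf)
    co <- merge(cc, rc, by = "subject_id", all = TRUE)
    co$beneficiary <- cells$beneficiary[i]
    co$audience <- cells$audience[i]
    coef_rows[[nm]] <- co
  }
  coefs <- do.call(rbind, coef_rows)
  rownames(coefs) <- NULL

  anovas <- lapply(setNames(nm = c("e", "sd", "r", "b_reg", "b_dis")),
                   function(cn) {
                     tab <- coefs[, c("subject_id", "beneficiary", "audience")]
                     tab$value <- coefs[[cn]]
                     rm_anova_2x2(tab)
                   })
  structure(list(choice_fits = choice_fits, rating_fits = rating_fits,
                 subject_coefficients = coefs, anovas = anovas,
                 provenance = list(
                   seed = if (!is.null(config)) config$seed else NA_integer_,
                   n_subjects = length(unique(data$subject_id)),
                   n_trials_per_condition =
                     max(table(data$subject_id, data$beneficiary, data$audience)),
                   method = method,
                   package_version = as.character(utils::packageVersion("regretwheel")))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Two-stage pipeline report\n")
  cat(sprintf("  %d subjects, %d trials/condition; stage-1 method: %s\n",
              x$provenance$n_subjects, x$provenance$n_trials_per_condition,
              x$provenance$method))
  for (nm in names(x$anovas)) {
    cat("\n== ANOVA on coefficient", nm, "==\n")
    print(x$anovas[[nm]])
  }
  invisible(x)
}

#' Serialise a run report to JSON
#'
#' Flattens a [run_full()] report (coefficients, Wald tests, ANOVA
#' tables, provenance) into a JSON file; model objects themselves are not
#' serialised.
#'
#' @param report A `"run_report"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  slim_choice <- lapply(report$choice_fits, function(f) {
    list(beta_hat = as.list(f$beta_hat), se = as.list(f$se),
         wald_z = as.list(f$wald_z), wald_p = as.list(f$wald_p),
         theta_hat = as.list(f$theta_hat), BIC = f$BIC,
         converged = f$converged, singular = f$singular,
         messages = f$messages)
  })
  slim_rating <- lapply(report$rating_fits, function(f) {
    list(beta_hat = as.list(f$beta_hat), se = as.list(f$se),
         df = as.list(f$df), p = as.list(f$p),
         residual_sd = f$residual_sd,
         factor_correlation = f$factor_correlation,
         converged = f$converged, fallback = f$fallback)
  })
  payload <- list(choice_models = slim_choice, rating_models = slim_rating,
                  subject_coefficients = report$subject_coefficients,
                  anovas = lapply(report$anovas, as.data.frame),
                  provenance = report$provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Draw a subject's random-trial bonus
#'
#' The task pays a bonus equal to the sum of the converted outcomes of two
#' randomly drawn trials, one from each audience condition. Uses the
#' global RNG stream.
#'
#' @param data Trial dataset.
#' @param subject Subject id present in `data`.
#' @return Bonus in GBP (between 0 and 5 by the anchor conversion).
#' @export
bonus_draw <- function(data, subject) {
  d <- as.data.frame(data)
  d <- d[d$subject_id == subject, , drop = FALSE]
  if (nrow(d) == 0L) stop("subject not found: ", subject, call. = FALSE)
  picks <- vapply(c("present", "absent"), function(aud) {
    rows <- d[d$audience == aud, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop("subject has no trials with audience ", aud, call. = FALSE)
    }
    rows$obtained[sample.int(nrow(rows), 1L)]
  }, numeric(1))
  sum(points_to_gbp(picks))
}
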