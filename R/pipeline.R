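#' Run the full Q-sort analysis pipeline
#'
#' Executes the five analysis stages in order on one dataset:
#' overall preference (ordered-probit Wald tests per variable and level
#' effects), overall dominance (per-participant weights, mean weights,
#' one-way ANOVA), by-person factor analysis (candidate comparison,
#' flagging, factor arrays), cluster x preference interaction (pooled
#' interaction model, per-variable Wald blocks, per-cluster level effects)
#' and cluster x dominance interaction (per-cluster mean-weight table,
#' two-way ANOVA). The interaction stages use flagged participants only;
#' they are skipped, with the reason recorded, when fewer than two factors
#' are available. The run is fully deterministic given the dataset and
#' options.
#'
#' @param dataset A [qsort_dataset()].
#' @param candidates Candidate factor counts compared by
#'   [choose_q_solution()].
#' @param crit Flagging significance quantile.
#' @param ref_levels Optional named vector of reference levels (see
#'   [encode_qsort_observations()]).
#' @param n_factors Optional fixed factor count, bypassing the automatic
#'   candidate rule.
#' @return An object of class `qmulti_report`: a list of sections
#'   (`overall_preference`, `overall_dominance`, `factor_solution`,
#'   `per_factor_preference`, `per_factor_dominance`), a named list
#'   `skipped` of stage -> reason, and `provenance`.
#' @export
#' @examples
#' ds <- simulate_qsorts(study_sim_config(), seed = 1)
#' rep <- run_qmulti(ds)
#' rep$overall_preference$wald
run_qmulti <- function(dataset, candidates = 1:4, crit = 1.96,
                       ref_levels = NULL, n_factors = NULL) {
  stopifnot(inherits(dataset, "qsort_dataset"))
  skipped <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      skipped[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  overall_preference <- run_stage("overall_preference", {
    fit <- fit_preference_model(dataset, ref_levels = ref_levels)
    list(
      wald = wald_preference_tests(fit),
      effects = preference_summary(fit, dataset$design),
      model = glance(fit)
    )
  })

  overall_dominance <- run_stage("overall_dominance", {
    w <- dominance_weights(dataset)
    list(
      weights = w,
      mean_weights = w |>
        dplyr::group_by(.data$variable) |>
        dplyr::summarise(mean_weight = mean(.data$weight), .groups = "drop"),
      anova = dominance_anova(w)
    )
  })

  selection <- run_stage("factor_solution", {
    if (is.null(n_factors)) {
      choose_q_solution(dataset, candidates = candidates, crit = crit)
    } else {
      sol <- q_factor_analysis(dataset, n_factors, crit = crit)
      structure(list(report = NULL, solution = sol,
                     n_factors_selected = as.integer(n_factors)),
                class = "qfactor_selection")
    }
  })
  solution <- selection$solution
  factor_solution <- if (!is.null(selection)) {
    list(
      candidates = selection$report,
      n_factors = selection$n_factors_selected,
      summary = if (!is.null(solution)) glance(solution),
      loadings = if (!is.null(solution)) tidy(solution),
      flags = if (!is.null(solution)) solution$flags,
      zscores = if (!is.null(solution)) solution$factor_zscores,
      arrays = if (!is.null(solution)) solution$factor_arrays
    )
  }

  labels <- NULL
  if (!is.null(solution)) {
    flagged <- dplyr::filter(solution$flags, !is.na(.data$factor))
    labels <- tibble::tibble(participant_id = flagged$participant_id,
                             cluster = flagged$factor)
  }
  enough_factors <- !is.null(labels) && dplyr::n_distinct(labels$cluster) >= 2

  per_factor_preference <- NULL
  per_factor_dominance <- NULL
  if (!enough_factors) {
    reason <- if (is.null(solution)) {
      "no factor solution selected"
    } else {
      "fewer than two factors with flagged participants"
    }
    skipped$per_factor_preference <- reason
    skipped$per_factor_dominance <- reason
  } else {
    per_factor_preference <- run_stage("per_factor_preference", {
      obs <- encode_qsort_observations(dataset, labels = labels,
                                       ref_levels = ref_levels)
      fit <- fit_ordered_probit(obs)
      per_factor_effects <- purrr::map(
        split(labels, labels$cluster),
        function(lab) {
          sub <- dplyr::semi_join(dataset$sorts, lab, by = "participant_id")
          f <- fit_ordered_probit(encode_qsort_observations(
            sub, dataset$design, dataset$grid, ref_levels = ref_levels))
          dplyr::mutate(preference_summary(f, dataset$design),
                        factor = lab$cluster[1], .before = 1)
        }) |>
        dplyr::bind_rows()
      list(
        interaction_wald = wald_interaction_tests(fit),
        effects = per_factor_effects,
        model = glance(fit)
      )
    })

    per_factor_dominance <- run_stage("per_factor_dominance", {
      w <- dominance_weights(dataset)
      list(
        table = factor_dominance_table(w, labels),
        anova = dominance_anova_by_factor(w, labels)
      )
    })
  }

  structure(
    list(
      overall_preference = overall_preference,
      overall_dominance = overall_dominance,
      factor_solution = factor_solution,
      per_factor_preference = per_factor_preference,
      per_factor_dominance = per_factor_dominance,
      skipped = skipped,
      provenance = list(
        package_version = as.character(utils::packageVersion("qmulti")),
        n_participants = length(participants(dataset)),
        n_stimuli = n_stimuli(dataset$design),
        candidates = as.integer(candidates),
        crit = crit
      )
    ),
    class = "qmulti_report"
  )
}

#' @export
print.qmulti_report <- function(x, ...) {
  cat("== Q-sort analysis report ==\n")
  cat(x$provenance$n_participants, "participants,",
      x$provenance$n_stimuli, "stimuli\n\n")
  if (!is.null(x$overall_preference)) {
    cat("-- Overall preference (Wald chi-square per variable) --\n")
    print(x$overall_preference$wald)
    cat("\n")
  }
  if (!is.null(x$overall_dominance)) {
    cat("-- Overall dominance (mean weights) --\n")
    print(x$overall_dominance$mean_weights)
    cat("\n-- Dominance ANOVA --\n")
    print(x$overall_dominance$anova)
    cat("\n")
  }
  if (!is.null(x$factor_solution)) {
    cat("-- Factor solution --\n")
    if (!is.null(x$factor_solution$summary)) print(x$factor_solution$summary)
    cat("\n")
  }
  if (!is.null(x$per_factor_preference)) {
    cat("-- Factor x preference interaction (Wald) --\n")
    print(x$per_factor_preference$interaction_wald)
    cat("\n")
  }
  if (!is.null(x$per_factor_dominance)) {
    cat("-- Per-factor dominance (mean weights) --\n")
    print(tidyr::pivot_wider(x$per_factor_dominance$table,
                             names_from = "cluster",
                             values_from = "mean_weight"))
    cat("\n-- Two-way dominance ANOVA --\n")
    print(x$per_factor_dominance$anova)
    cat("\n")
  }
  if (length(x$skipped)) {
    cat("-- Skipped stages --\n")
    for (nm in names(x$skipped)) cat(nm, ":", x$skipped[[nm]], "\n")
  }
  invisible(x)
}

# Recursively prepare a report for JSON: tibbles become data frames
# (serialized row-wise), everything else passes through.
report_to_jsonable <- function(x) {
  if (is.data.frame(x)) {
    as.data.frame(x)
  } else if (is.list(x)) {
    lapply(x, report_to_jsonable)
  } else {
    x
  }
}

report_from_json <- function(x) {
  if (is.data.frame(x)) {
    tibble::as_tibble(x)
  } else if (is.list(x)) {
    lapply(x, report_from_json)
  } else {
    x
  }
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (machine-readable, full numeric precision) and
#' `report.txt` (the human-readable rendering of [print.qmulti_report()])
#' into a directory.
#'
#' @param report A [run_qmulti()] report.
#' @param dir Output directory (created if absent).
#' @return The path of the JSON file, invisibly.
#' @export
write_qmulti_report <- function(report, dir) {
  stopifnot(inherits(report, "qmulti_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report_to_jsonable(unclass(report)), json_path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  txt_path <- file.path(dir, "report.txt")
  con <- file(txt_path, open = "wt")
  sink(con)
  on.exit({ sink(); close(con) })
  print(report)
  invisible(json_path)
}

#' Read a pipeline report back from its JSON serialization
#'
#' @param path Path to `report.json` (or the directory containing it).
#' @return A `qmulti_report` with all tables restored as tibbles.
#' @export
read_qmulti_report <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report.json")
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  structure(report_from_json(raw), class = "qmulti_report")
}
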