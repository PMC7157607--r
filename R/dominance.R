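#' Mean grid position of each level of each variable
#'
#' For every participant, variable and level: the mean of the grid column
#' values of all stimuli carrying that level. In a balanced full factorial a
#' two-level variable's level means are symmetric about the grid mean.
#'
#' @param sorts Long sorts tibble or [qsort_dataset()].
#' @param design A [stimulus_design()] (taken from the dataset when omitted).
#' @return A tibble (`participant_id`, `variable`, `level`, `n_stimuli`,
#'   `mean_rank`).
#' @export
level_positions <- function(sorts, design = NULL) {
  if (inherits(sorts, "qsort_dataset")) design <- design %||% sorts$design
  stopifnot(inherits(design, "stimulus_design"))
  tbl <- dplyr::inner_join(as_sorts_tibble(sorts), enumerate_stimuli(design),
                           by = "stimulus_id")
  purrr::map(variable_names(design), function(v) {
    tbl |>
      dplyr::group_by(.data$participant_id, level = .data[[v]]) |>
      dplyr::summarise(n_stimuli = dplyr::n(),
                       mean_rank = mean(.data$rank), .groups = "drop") |>
      dplyr::mutate(variable = v, .after = "participant_id")
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$participant_id)
}

#' Per-participant dominance weights of the design variables
#'
#' Dominance measures how strongly a variable drives a sort: the spread of
#' its levels' positions across the grid. For each variable the raw spread
#' is the count-weighted variance of its level mean positions about the grid
#' mean, `sum(n_level * (mean_level - grid_mean)^2) / n_stimuli`; weights
#' normalise the raw spreads to sum to 1 within each participant. A
#' participant whose sort is driven entirely by one variable concentrates
#' all weight on it; if every raw spread is 0 the weights are uniform.
#'
#' @param sorts Long sorts tibble or [qsort_dataset()].
#' @param design A [stimulus_design()] (from the dataset when omitted).
#' @param grid A [grid_spec()] (from the dataset when omitted); supplies the
#'   grand mean the spreads are measured about.
#' @return A tibble (`participant_id`, `variable`, `raw`, `weight`) with
#'   `sum(weight) == 1` within each participant.
#' @export
dominance_weights <- function(sorts, design = NULL, grid = NULL) {
  if (inherits(sorts, "qsort_dataset")) {
    design <- design %||% sorts$design
    grid <- grid %||% sorts$grid
  }
  stopifnot(inherits(design, "stimulus_design"), inherits(grid, "grid_spec"))
  gm <- grid_mean(grid)
  n_stim <- n_stimuli(design)
  level_positions(sorts, design) |>
    dplyr::group_by(.data$participant_id, .data$variable) |>
    dplyr::summarise(
      raw = sum(.data$n_stimuli * (.data$mean_rank - gm)^2) / n_stim,
      .groups = "drop_last"
    ) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      weight = if (sum(.data$raw) > 0) .data$raw / sum(.data$raw)
               else 1 / dplyr::n()
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(variable = factor(.data$variable,
                                    levels = variable_names(design))) |>
    dplyr::arrange(.data$participant_id, .data$variable) |>
    dplyr::mutate(variable = as.character(.data$variable))
}

tidy_aov <- function(fit) {
  tab <- summary(fit)[[1]]
  tibble::tibble(
    term = trimws(rownames(tab)),
    df = as.integer(tab$Df),
    sum_sq = tab$`Sum Sq`,
    mean_sq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p_value = tab$`Pr(>F)`
  )
}

#' One-way ANOVA of dominance weights across variables
#'
#' Tests whether the design variables differ in how much they dominate
#' participants' sorts: observations are the per-participant weights,
#' groups are the variables, so df = (variables - 1,
#' variables x (participants - 1)).
#'
#' @param weights Output of [dominance_weights()].
#' @return A tibble with rows `variable` and `Residuals`
#'   (`term`, `df`, `sum_sq`, `mean_sq`, `statistic`, `p_value`).
#' @export
dominance_anova <- function(weights) {
  weights <- tibble::as_tibble(weights)
  if (dplyr::n_distinct(weights$participant_id) < 2L) {
    abort("Dominance ANOVA needs at least two participants.")
  }
  if (all(abs(weights$weight - mean(weights$weight)) < 1e-12)) {
    warn("All dominance weights identical; F reported as 0.")
    nv <- dplyr::n_distinct(weights$variable)
    np <- dplyr::n_distinct(weights$participant_id)
    return(tibble::tibble(
      term = c("variable", "Residuals"),
      df = as.integer(c(nv - 1L, nv * (np - 1L))),
      sum_sq = c(0, 0), mean_sq = c(0, 0),
      statistic = c(0, NA_real_), p_value = c(1, NA_real_)
    ))
  }
  fit <- aov(weight ~ variable,
             data = transform(weights, variable = factor(variable)))
  tidy_aov(fit)
}

#' Two-way ANOVA of dominance weights by cluster and variable
#'
#' On cluster-labelled participants only: weight ~ factor + variable +
#' factor:variable. The interaction term asks whether clusters attend to
#' different variables; its df is (clusters - 1) x (variables - 1).
#'
#' @param weights Output of [dominance_weights()].
#' @param labels Tibble (`participant_id`, `cluster`); participants absent
#'   from `labels` are excluded.
#' @return A tibble with rows `factor`, `variable`, `factor:variable` and
#'   `Residuals`.
#' @export
dominance_anova_by_factor <- function(weights, labels) {
  labels <- tibble::as_tibble(labels)
  dat <- dplyr::inner_join(tibble::as_tibble(weights),
                           labels[c("participant_id", "cluster")],
                           by = "participant_id")
  if (!nrow(dat)) abort("No labelled participants in `weights`.")
  sizes <- dplyr::count(dplyr::distinct(dat, .data$participant_id,
                                        .data$cluster), .data$cluster)
  if (any(sizes$n < 1L) || nrow(sizes) < 2L) {
    abort("Each cluster needs at least one participant, and >= 2 clusters.")
  }
  dat <- transform(dat, f = factor(cluster), variable = factor(variable))
  fit <- aov(weight ~ f * variable, data = dat)
  out <- tidy_aov(fit)
  out$term <- sub("^f:variable$", "factor:variable",
                  sub("^f$", "factor", out$term))
  out
}

#' Mean dominance weights per cluster
#'
#' The per-cluster analogue of a dominance-weight table: the mean weight of
#' each variable over the labelled participants of each cluster. Columns sum
#' to 1 within each cluster.
#'
#' @param weights Output of [dominance_weights()].
#' @param labels Tibble (`participant_id`, `cluster`). When `NULL` a single
#'   overall column is produced.
#' @return A tibble (`cluster`, `variable`, `mean_weight`).
#' @export
factor_dominance_table <- function(weights, labels = NULL) {
  weights <- tibble::as_tibble(weights)
  if (is.null(labels)) {
    labels <- tibble::tibble(
      participant_id = unique(weights$participant_id), cluster = "Overall")
  }
  dplyr::inner_join(weights,
                    tibble::as_tibble(labels)[c("participant_id", "cluster")],
                    by = "participant_id") |>
    dplyr::group_by(.data$cluster, .data$variable) |>
    dplyr::summarise(mean_weight = mean(.data$weight), .groups = "drop")
}
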