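#' Validate Q-sorts against a design and grid
#'
#' Checks every participant's sort for the three ways a forced-distribution
#' sort can be malformed: stimuli missing from or extraneous to the design,
#' rank values outside the grid columns, and column counts that violate the
#' grid quotas. Nothing is thrown; the violations are the return value.
#'
#' @param sorts A data frame of long-format sorts with columns
#'   `participant_id`, `stimulus_id`, `rank`, or a [qsort_dataset()].
#' @param design A [stimulus_design()].
#' @param grid A [grid_spec()].
#' @return A tibble with columns `participant_id`, `issue`
#'   (`"missing_stimulus"`, `"unknown_stimulus"`, `"duplicate_stimulus"`,
#'   `"out_of_range"`, `"quota_violation"`) and `detail`. Zero rows iff all
#'   sorts are valid.
#' @export
validate_qsorts <- function(sorts, design, grid) {
  sorts <- as_sorts_tibble(sorts)
  ids <- enumerate_stimuli(design)$stimulus_id
  issue <- function(pid, what, detail) {
    tibble::tibble(participant_id = pid, issue = what, detail = detail)
  }
  per_participant <- function(tbl) {
    pid <- tbl$participant_id[1]
    out <- list()
    unknown <- setdiff(tbl$stimulus_id, ids)
    if (length(unknown)) {
      out <- c(out, list(issue(pid, "unknown_stimulus",
        paste("not in design:", paste(unknown, collapse = ", ")))))
    }
    dup <- unique(tbl$stimulus_id[duplicated(tbl$stimulus_id)])
    if (length(dup)) {
      out <- c(out, list(issue(pid, "duplicate_stimulus",
        paste("sorted more than once:", paste(dup, collapse = ", ")))))
    }
    missing <- setdiff(ids, tbl$stimulus_id)
    if (length(missing)) {
      out <- c(out, list(issue(pid, "missing_stimulus",
        paste("absent from sort:", paste(missing, collapse = ", ")))))
    }
    bad <- tbl$rank[!tbl$rank %in% grid$values]
    if (length(bad)) {
      out <- c(out, list(issue(pid, "out_of_range",
        paste("rank values outside grid columns:",
              paste(unique(bad), collapse = ", ")))))
    } else if (!length(unknown) && !length(dup) && !length(missing)) {
      counts <- table(factor(tbl$rank, levels = grid$values))
      off <- which(as.integer(counts) != grid$quotas)
      if (length(off)) {
        out <- c(out, list(issue(pid, "quota_violation",
          paste0("column ", grid$values[off], ": ", as.integer(counts)[off],
                 " stimuli, quota ", grid$quotas[off], collapse = "; "))))
      }
    }
    dplyr::bind_rows(out)
  }
  sorts |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_split() |>
    purrr::map(per_participant) |>
    dplyr::bind_rows()
}

#' Bundle sorts, design and grid into a dataset
#'
#' @param sorts Long-format tibble (`participant_id`, `stimulus_id`, `rank`).
#' @param design A [stimulus_design()].
#' @param grid A [grid_spec()].
#' @param labels Optional tibble (`participant_id`, `cluster`) of known
#'   cluster membership (e.g. planted labels from [simulate_qsorts()]).
#' @param validate Validate every sort on construction (default `TRUE`).
#' @return An object of class `qsort_dataset` with elements `sorts`,
#'   `design`, `grid` and (possibly `NULL`) `labels`.
#' @export
qsort_dataset <- function(sorts, design, grid, labels = NULL, validate = TRUE) {
  stopifnot(inherits(design, "stimulus_design"), inherits(grid, "grid_spec"))
  sorts <- as_sorts_tibble(sorts)
  if (grid_size(grid) != n_stimuli(design)) {
    abort("Grid cell count must equal the design's stimulus count.")
  }
  if (validate) {
    report <- validate_qsorts(sorts, design, grid)
    if (nrow(report)) {
      first <- report[1, ]
      abort(paste0("Invalid sorts (", nrow(report), " issue(s)); first: ",
                   first$participant_id, " [", first$issue, "] ",
                   first$detail))
    }
  }
  if (!is.null(labels)) {
    labels <- tibble::as_tibble(labels)
    stopifnot(all(c("participant_id", "cluster") %in% names(labels)))
  }
  structure(
    list(sorts = sorts, design = design, grid = grid, labels = labels),
    class = "qsort_dataset"
  )
}

#' @export
print.qsort_dataset <- function(x, ...) {
  cat("<qsort_dataset> ", dplyr::n_distinct(x$sorts$participant_id),
      " participants x ", n_stimuli(x$design), " stimuli\n", sep = "")
  print(x$design)
  print(x$grid)
  invisible(x)
}

#' Participant ids of a dataset
#' @param dataset A [qsort_dataset()].
#' @return Character vector in order of first appearance.
#' @export
participants <- function(dataset) {
  unique(as_sorts_tibble(dataset)$participant_id)
}

# Accept either a qsort_dataset or a long tibble of sorts.
as_sorts_tibble <- function(sorts) {
  if (inherits(sorts, "qsort_dataset")) {
    return(sorts$sorts)
  }
  sorts <- tibble::as_tibble(sorts)
  need <- c("participant_id", "stimulus_id", "rank")
  if (!all(need %in% names(sorts))) {
    abort(paste("Sorts need columns:", paste(need, collapse = ", ")))
  }
  sorts$participant_id <- as.character(sorts$participant_id)
  sorts$stimulus_id <- as.character(sorts$stimulus_id)
  sorts$rank <- as.integer(sorts$rank)
  sorts[c("participant_id", "stimulus_id", "rank")]
}
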