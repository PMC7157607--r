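#' Forced-distribution grid specification
#'
#' A Q-sorting grid is an ordered set of columns, each labelled with an
#' integer scale value and carrying a fixed quota of cells. Every completed
#' sort must place exactly `quotas[k]` stimuli in column `values[k]`, so the
#' marginal distribution of ranks is identical for all participants.
#'
#' @param values Integer vector of column scale values, strictly increasing
#'   (e.g. `-5:5` for an 11-column grid running from least to most preferred).
#' @param quotas Positive integer vector, same length as `values`: number of
#'   cells per column. `sum(quotas)` must equal the number of stimuli sorted.
#'
#' @return An object of class `grid_spec`.
#' @seealso [study_grid()] for the 32-cell, 11-column default.
#' @export
#' @examples
#' grid_spec(-2:2, c(1, 2, 3, 2, 1))
grid_spec <- function(values, quotas) {
  values <- as.integer(values)
  quotas <- as.integer(quotas)
  if (length(values) < 2L) {
    abort("A grid needs at least two columns.")
  }
  if (length(values) != length(quotas)) {
    abort("`values` and `quotas` must have the same length.")
  }
  if (any(diff(values) <= 0L)) {
    abort("Grid column `values` must be strictly increasing.")
  }
  if (anyNA(values) || anyNA(quotas) || any(quotas < 1L)) {
    abort("Grid `quotas` must be positive integers.")
  }
  structure(list(values = values, quotas = quotas), class = "grid_spec")
}

#' Default 11-column quasi-normal grid for 32 stimuli
#'
#' Columns run from -5 (least preferred) to +5 (most preferred) with
#' symmetric bell-shaped quotas `1,2,3,4,4,4,4,4,3,2,1`, accommodating the
#' 32 stimuli of the full factorial design in [io_design()].
#'
#' @return A `grid_spec`.
#' @export
study_grid <- function() {
  grid_spec(-5:5, c(1, 2, 3, 4, 4, 4, 4, 4, 3, 2, 1))
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", length(x$values), " columns, ", sum(x$quotas),
      " cells\n", sep = "")
  print(setNames(x$quotas, x$values))
  invisible(x)
}

#' Number of cells in a grid
#' @param grid A [grid_spec()].
#' @return Integer, `sum(quotas)`.
#' @export
grid_size <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  sum(grid$quotas)
}

#' Quota-weighted mean column value of a grid
#'
#' Every valid sort has this as its mean rank (0 for symmetric grids).
#' @param grid A [grid_spec()].
#' @return A number.
#' @export
grid_mean <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  sum(grid$values * grid$quotas) / sum(grid$quotas)
}

#' Factorial stimulus design
#'
#' Describes the design variables and their levels. The stimulus set is the
#' full Cartesian product of levels; each stimulus id concatenates one code
#' letter per variable, in variable order.
#'
#' @param variables Named list; each element is a named character vector
#'   mapping level name to its single code letter, e.g.
#'   `list(Size = c(Small = "S", Large = "L"))`. Level names and code letters
#'   must be unique within a variable.
#'
#' @return An object of class `stimulus_design`.
#' @seealso [io_design()], [enumerate_stimuli()]
#' @export
#' @examples
#' stimulus_design(list(
#'   Shape  = c(Round = "R", Angular = "A"),
#'   Colour = c(Red = "r", Green = "g", Blue = "b")
#' ))
stimulus_design <- function(variables) {
  if (!is.list(variables) || is.null(names(variables)) ||
      any(names(variables) == "") || anyDuplicated(names(variables))) {
    abort("`variables` must be a uniquely named list of level-code vectors.")
  }
  variables <- lapply(variables, function(v) {
    v <- vapply(v, as.character, character(1))
    if (length(v) < 1L || is.null(names(v)) || any(names(v) == "")) {
      abort("Each variable needs at least one named level.")
    }
    if (anyDuplicated(names(v))) {
      abort("Level names must be unique within a variable.")
    }
    if (any(nchar(v) != 1L) || anyDuplicated(v)) {
      abort("Level codes must be distinct single characters within a variable.")
    }
    v
  })
  structure(list(variables = variables), class = "stimulus_design")
}

#' The interactive-object study design
#'
#' Four variables in a 2 x 2 x 2 x 4 full factorial: Size (Small/Large),
#' Surface texture (Smooth/Rough), Contour (Round/Angular) and autonomous
#' Behaviour (Light/Sound/Vibrate/Quiescent), giving 32 stimuli. Stimulus
#' codes read Size, Texture, Contour, Behaviour: `"SSAL"` is the small smooth
#' angular object that lights up.
#'
#' @return A `stimulus_design`.
#' @export
io_design <- function() {
  stimulus_design(list(
    "Size"            = c(Small = "S", Large = "L"),
    "Surface texture" = c(Smooth = "S", Rough = "R"),
    "Contour"         = c(Round = "R", Angular = "A"),
    "Behaviour"       = c(Light = "L", Sound = "S", Vibrate = "V",
                          Quiescent = "Q")
  ))
}

#' @export
print.stimulus_design <- function(x, ...) {
  n <- prod(vapply(x$variables, length, integer(1)))
  cat("<stimulus_design> ", length(x$variables), " variables, ", n,
      " stimuli\n", sep = "")
  for (v in names(x$variables)) {
    lv <- x$variables[[v]]
    cat("  ", v, ": ",
        paste0(names(lv), " (", lv, ")", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

variable_names <- function(design) names(design$variables)

n_stimuli <- function(design) {
  prod(vapply(design$variables, length, integer(1)))
}

#' Enumerate the full factorial stimulus set
#'
#' Expands the Cartesian product of levels in deterministic lexicographic
#' order over level indices (first variable slowest) and builds stimulus ids
#' from the per-level code letters.
#'
#' @param design A [stimulus_design()].
#' @return A tibble with a `stimulus_id` column followed by one column per
#'   design variable holding the level name.
#' @export
#' @examples
#' enumerate_stimuli(io_design())
enumerate_stimuli <- function(design) {
  stopifnot(inherits(design, "stimulus_design"))
  levels <- lapply(design$variables, names)
  tbl <- rlang::exec(tidyr::expand_grid, !!!levels)
  codes <- purrr::imap(design$variables, function(lv, v) unname(lv[tbl[[v]]]))
  tbl <- dplyr::mutate(tbl,
    stimulus_id = rlang::exec(paste0, !!!unname(codes)),
    .before = 1
  )
  tbl
}
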