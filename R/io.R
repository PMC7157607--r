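#' Read a design/grid (and optional simulation) configuration
#'
#' The configuration is a single YAML or JSON file (chosen by extension) with
#' a `variables` block (variable -> level -> code letter), a `grid` block
#' (`values`, `quotas`) and, optionally, `clusters` and `seed` blocks
#' describing a synthetic-data scenario (see [cluster_spec()]).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `design` ([stimulus_design()]), `grid`
#'   ([grid_spec()]), and `clusters`/`seed` when present (`NULL` otherwise).
#' @export
read_design_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$variables) || is.null(cfg$grid)) {
    abort("Config must contain `variables` and `grid` blocks.")
  }
  design <- stimulus_design(lapply(cfg$variables, unlist))
  grid <- grid_spec(unlist(cfg$grid$values), unlist(cfg$grid$quotas))
  clusters <- NULL
  if (!is.null(cfg$clusters)) {
    clusters <- purrr::imap(cfg$clusters, function(cl, i) {
      cluster_spec(
        name = cl$name %||% paste0("C", i),
        size = cl$size,
        utilities = lapply(cl$utilities, unlist),
        noise_sd = cl$noise_sd %||% 0.3
      )
    })
  }
  list(design = design, grid = grid, clusters = clusters, seed = cfg$seed)
}

#' Write a design/grid configuration
#'
#' @param design A [stimulus_design()].
#' @param grid A [grid_spec()].
#' @param path Output path; `.json` writes JSON, anything else YAML.
#' @param clusters Optional list of [cluster_spec()] to embed.
#' @param seed Optional integer seed to embed.
#' @return `path`, invisibly.
#' @export
write_design_config <- function(design, grid, path, clusters = NULL,
                                seed = NULL) {
  cfg <- list(
    variables = lapply(design$variables, as.list),
    grid = list(values = grid$values, quotas = grid$quotas)
  )
  if (!is.null(clusters)) {
    cfg$clusters <- lapply(clusters, function(cl) {
      list(name = cl$name, size = cl$size, noise_sd = cl$noise_sd,
           utilities = lapply(cl$utilities, as.list))
    })
  }
  if (!is.null(seed)) cfg$seed <- seed
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Read a Q-sort dataset from a sort matrix and a design config
#'
#' The sort matrix is delimited text (comma for `.csv`, tab otherwise): one
#' row per participant, first column `participant_id`, remaining header cells
#' stimulus ids, body cells the grid column value each stimulus received.
#' Every sort is validated against the design and grid on read.
#'
#' @param sorts_path Path to the delimited sort matrix.
#' @param config_path Path to the design/grid config
#'   (see [read_design_config()]).
#' @return A [qsort_dataset()].
#' @export
read_qsort_dataset <- function(sorts_path, config_path) {
  cfg <- read_design_config(config_path)
  sep <- if (grepl("\\.csv$", sorts_path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(sorts_path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (names(raw)[1] != "participant_id") {
    abort("First column of the sort matrix must be `participant_id`.")
  }
  known <- enumerate_stimuli(cfg$design)$stimulus_id
  unknown <- setdiff(names(raw)[-1], known)
  if (length(unknown)) {
    abort(paste("Unknown stimulus id(s) in header:",
                paste(unknown, collapse = ", ")))
  }
  long <- tidyr::pivot_longer(tibble::as_tibble(raw), -"participant_id",
                              names_to = "stimulus_id", values_to = "cell")
  bad <- long[is.na(suppressWarnings(as.numeric(long$cell))), ]
  if (nrow(bad)) {
    abort(paste0("Malformed cell '", bad$cell[1], "' for participant ",
                 bad$participant_id[1], ", stimulus ", bad$stimulus_id[1]))
  }
  long$rank <- as.integer(round(as.numeric(long$cell)))
  qsort_dataset(long[c("participant_id", "stimulus_id", "rank")],
                cfg$design, cfg$grid)
}

#' Write a Q-sort dataset as a sort matrix (and optionally its config)
#'
#' @param dataset A [qsort_dataset()].
#' @param sorts_path Output path for the sort matrix (`.csv` comma,
#'   otherwise tab-delimited).
#' @param config_path Optional path; when given the design/grid config is
#'   written there too, so `read_qsort_dataset(sorts_path, config_path)`
#'   round-trips.
#' @return `sorts_path`, invisibly.
#' @export
write_qsort_dataset <- function(dataset, sorts_path, config_path = NULL) {
  stopifnot(inherits(dataset, "qsort_dataset"))
  ids <- enumerate_stimuli(dataset$design)$stimulus_id
  wide <- tidyr::pivot_wider(dataset$sorts, names_from = "stimulus_id",
                             values_from = "rank")
  wide <- wide[, c("participant_id", ids)]
  sep <- if (grepl("\\.csv$", sorts_path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(wide, sorts_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  if (!is.null(config_path)) {
    write_design_config(dataset$design, dataset$grid, config_path)
  }
  invisible(sorts_path)
}
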