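#' Cluster specification for the synthetic-sort generator
#'
#' A cluster is a group of participants sharing a latent utility profile over
#' stimulus levels. Each member's utility for a stimulus is the sum of the
#' utilities of its levels plus independent Gaussian noise; the member's sort
#' is the deterministic forced binning of those utilities
#' ([utilities_to_qsort()]). Within a variable only utility contrasts matter:
#' shifting all of a variable's level utilities by a constant shifts every
#' stimulus equally and leaves the sort unchanged.
#'
#' @param name Cluster label.
#' @param size Number of participants (>= 1).
#' @param utilities Named list: variable -> named numeric vector of level
#'   utilities. Variables or levels omitted contribute 0.
#' @param noise_sd Standard deviation of the per-stimulus Gaussian noise
#'   added to each participant's utilities (>= 0).
#' @return An object of class `cluster_spec`.
#' @export
cluster_spec <- function(name, size, utilities = list(), noise_sd = 0.3) {
  size <- as.integer(size)
  if (is.na(size) || size < 1L) abort("Cluster `size` must be >= 1.")
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  if (!is.list(utilities)) abort("`utilities` must be a named list.")
  structure(
    list(name = as.character(name), size = size,
         utilities = lapply(utilities, function(u) {
           u <- unlist(u)
           storage.mode(u) <- "double"
           u
         }),
         noise_sd = as.numeric(noise_sd)),
    class = "cluster_spec"
  )
}

#' Deterministic forced sorting of utilities into a grid
#'
#' Stimuli are ordered by descending utility (ties broken by lexicographic
#' stimulus id) and dealt into the grid from the top: the first
#' `quotas[K]` stimuli receive the highest column value, the next
#' `quotas[K-1]` the next, and so on.
#'
#' @param utilities Named numeric vector, one utility per stimulus id, or a
#'   data frame with columns `stimulus_id` and `utility`.
#' @param grid A [grid_spec()] whose cell count equals `length(utilities)`.
#' @return A tibble (`stimulus_id`, `rank`) in lexicographic stimulus order.
#' @export
#' @examples
#' g <- grid_spec(-1:1, c(1, 2, 1))
#' utilities_to_qsort(c(a = 3, b = 2, c = 1, d = 0), g)
utilities_to_qsort <- function(utilities, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.data.frame(utilities)) {
    utilities <- setNames(utilities$utility, utilities$stimulus_id)
  }
  if (is.null(names(utilities)) || anyDuplicated(names(utilities))) {
    abort("`utilities` must be uniquely named by stimulus id.")
  }
  if (length(utilities) != grid_size(grid)) {
    abort(paste0("Got ", length(utilities), " utilities for a grid of ",
                 grid_size(grid), " cells."))
  }
  ord <- order(-utilities, names(utilities))
  k <- length(grid$values)
  ranks_desc <- rep.int(grid$values[k:1], grid$quotas[k:1])
  out <- tibble::tibble(
    stimulus_id = names(utilities)[ord],
    rank = as.integer(ranks_desc)
  )
  dplyr::arrange(out, .data$stimulus_id)
}

#' Synthetic-study configuration
#'
#' @param design A [stimulus_design()].
#' @param grid A [grid_spec()] matching the design's stimulus count.
#' @param clusters List of [cluster_spec()]; total size is the number of
#'   participants generated.
#' @param seed Optional default integer seed used by [simulate_qsorts()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(design, grid, clusters, seed = NULL) {
  stopifnot(inherits(design, "stimulus_design"), inherits(grid, "grid_spec"))
  if (grid_size(grid) != n_stimuli(design)) {
    abort("Grid cell count must equal the design's stimulus count.")
  }
  if (!length(clusters) ||
      !all(vapply(clusters, inherits, logical(1), "cluster_spec"))) {
    abort("`clusters` must be a non-empty list of cluster_spec objects.")
  }
  vars <- variable_names(design)
  for (cl in clusters) {
    extra <- setdiff(names(cl$utilities), vars)
    if (length(extra)) {
      abort(paste("Cluster", cl$name, "names unknown variable(s):",
                  paste(extra, collapse = ", ")))
    }
    for (v in names(cl$utilities)) {
      bad <- setdiff(names(cl$utilities[[v]]), names(design$variables[[v]]))
      if (length(bad)) {
        abort(paste0("Cluster ", cl$name, ", variable ", v,
                     ": unknown level(s) ", paste(bad, collapse = ", ")))
      }
    }
  }
  structure(list(design = design, grid = grid, clusters = clusters,
                 seed = seed), class = "sim_config")
}

#' Default synthetic scenario mirroring the interactive-object study
#'
#' Eighteen participants sort the 32 stimuli of [io_design()] into
#' [study_grid()]: three latent clusters of sizes 8, 6 and 3 plus one
#' idiosyncratic participant with no shared viewpoint (zero utilities, noise
#' only), so that a by-person factor analysis should flag 8/6/3 exemplars
#' and leave one participant unflagged. The cluster utility profiles encode
#' three qualitatively distinct viewpoints: cluster C1 favours smooth,
#' lighting-up objects and strongly dislikes sound; C2 favours rough, round,
#' vibrating objects and dislikes sound; C3 attends almost exclusively to
#' behaviour, preferring vibration, then sound, with quiescent objects last.
#' Summed over the sample the planted contrasts give an overall preference
#' for rough texture, round contour and vibration, no size preference, and
#' behaviour as the most dominant variable.
#'
#' @param noise_sd Per-stimulus utility noise standard deviation shared by
#'   all clusters (default 0.3 latent units).
#' @param seed Default seed stored in the config.
#' @return A [sim_config()].
#' @export
study_sim_config <- function(noise_sd = 0.3, seed = NULL) {
  clusters <- list(
    cluster_spec("C1", 8, list(
      "Surface texture" = c(Smooth = 0.3, Rough = -0.3),
      "Contour"         = c(Round = 0.1, Angular = -0.1),
      "Behaviour"       = c(Light = 0.9, Sound = -1.2, Vibrate = 0.6,
                            Quiescent = -0.3)
    ), noise_sd = noise_sd),
    cluster_spec("C2", 6, list(
      "Surface texture" = c(Smooth = -0.8, Rough = 0.8),
      "Contour"         = c(Round = 0.4, Angular = -0.4),
      "Behaviour"       = c(Light = 0.7, Sound = -1.2, Vibrate = 1.0,
                            Quiescent = -0.5)
    ), noise_sd = noise_sd),
    cluster_spec("C3", 3, list(
      "Contour"   = c(Round = 0.2, Angular = -0.2),
      "Behaviour" = c(Light = 0.3, Sound = 0.4, Vibrate = 1.5,
                      Quiescent = -1.2)
    ), noise_sd = noise_sd),
    cluster_spec("none", 1, list(), noise_sd = noise_sd)
  )
  sim_config(io_design(), study_grid(), clusters, seed = seed)
}

#' Mean latent utility of each stimulus for each cluster
#'
#' @param config A [sim_config()].
#' @return A tibble (`cluster`, `stimulus_id`, `utility`) of noise-free
#'   utilities (sum of level contributions).
#' @export
cluster_utilities <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  stim <- enumerate_stimuli(config$design)
  purrr::map(config$clusters, function(cl) {
    u <- rep(0, nrow(stim))
    for (v in names(cl$utilities)) {
      contrib <- cl$utilities[[v]][stim[[v]]]
      contrib[is.na(contrib)] <- 0
      u <- u + contrib
    }
    tibble::tibble(cluster = cl$name, stimulus_id = stim$stimulus_id,
                   utility = u)
  }) |>
    dplyr::bind_rows()
}

#' Generate a synthetic Q-sort dataset with planted cluster structure
#'
#' For each participant the latent utility of every stimulus is the sum of
#' its levels' cluster utilities plus an independent `Normal(0, noise_sd)`
#' draw; the participant's sort is the deterministic forced binning of those
#' utilities. The run is fully reproducible from the seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to the seed stored in the config.
#' @return A [qsort_dataset()] whose `labels` element records the true
#'   cluster of every participant.
#' @export
#' @examples
#' ds <- simulate_qsorts(study_sim_config(), seed = 1)
#' ds$labels
simulate_qsorts <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) abort("A `seed` is required (in the config or as an argument).")
  base_util <- cluster_utilities(config)
  n_total <- sum(vapply(config$clusters, function(cl) cl$size, integer(1)))
  width <- max(2L, nchar(as.character(n_total)))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  p <- 0L
  sorts <- list()
  labels <- list()
  for (cl in config$clusters) {
    u0 <- base_util[base_util$cluster == cl$name, ]
    u0 <- setNames(u0$utility, u0$stimulus_id)
    for (i in seq_len(cl$size)) {
      p <- p + 1L
      pid <- sprintf(paste0("P%0", width, "d"), p)
      u <- u0 + stats::rnorm(length(u0), 0, cl$noise_sd)
      s <- utilities_to_qsort(u, config$grid)
      s$participant_id <- pid
      sorts[[p]] <- s[c("participant_id", "stimulus_id", "rank")]
      labels[[p]] <- tibble::tibble(participant_id = pid, cluster = cl$name)
    }
  }
  qsort_dataset(dplyr::bind_rows(sorts), config$design, config$grid,
                labels = dplyr::bind_rows(labels), validate = FALSE)
}
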