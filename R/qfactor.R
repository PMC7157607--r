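#' Correlations between participants' sorts
#'
#' The by-person correlation matrix at the heart of Q-factor analysis:
#' participants, not stimuli, are the variables being correlated. Because
#' every sort fills the same forced distribution, rank vectors always have
#' positive variance.
#'
#' @param sorts Long sorts tibble or [qsort_dataset()].
#' @return A symmetric participants x participants Pearson correlation
#'   matrix with unit diagonal, dimnames = participant ids.
#' @export
sort_correlations <- function(sorts) {
  tbl <- as_sorts_tibble(sorts)
  wide <- tidyr::pivot_wider(tbl, names_from = "participant_id",
                             values_from = "rank")
  wide <- dplyr::arrange(wide, .data$stimulus_id)
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (ncol(m) < 2L) abort("Need at least two participants.")
  cor(m)
}

#' Varimax simplicity criterion of a loading matrix
#'
#' Sum over factors of the variance of squared loadings; rows are first
#' scaled to unit communality when `normalize = TRUE` (Kaiser
#' normalization), matching the criterion [stats::varimax()] maximises.
#'
#' @param loadings Numeric matrix (participants x factors).
#' @param normalize Apply Kaiser row normalization first.
#' @return A single number; larger is simpler.
#' @export
varimax_criterion <- function(loadings, normalize = TRUE) {
  l <- as.matrix(loadings)
  if (normalize) {
    h <- sqrt(rowSums(l^2))
    h[h == 0] <- 1
    l <- l / h
  }
  sq <- l^2
  p <- nrow(l)
  sum(colSums(sq^2) / p - (colSums(sq) / p)^2)
}

#' Extract and rotate Q-factors from a sort correlation matrix
#'
#' Principal-component extraction (eigendecomposition of the correlation
#' matrix, loading = eigenvector x sqrt(eigenvalue)) of the leading
#' `n_factors` components, followed by varimax rotation with Kaiser
#' normalization. Per-factor eigenvalues are recomputed as column sums of
#' squared rotated loadings; columns are sign-fixed so each factor's
#' largest-magnitude loading is positive, and ordered by decreasing
#' eigenvalue.
#'
#' @param corr Participants x participants correlation matrix
#'   ([sort_correlations()]).
#' @param n_factors Number of factors, `1 <= n_factors < nrow(corr)`.
#' @return A list: `loadings` (participants x factors matrix, columns
#'   `F1..Fk`), `eigenvalues` (named numeric, from the rotated loadings) and
#'   `extraction_eigenvalues` (the leading unrotated eigenvalues of the
#'   correlation matrix, used by the Kaiser-Guttman retention rule).
#' @export
extract_and_rotate <- function(corr, n_factors) {
  corr <- as.matrix(corr)
  n <- nrow(corr)
  if (n_factors < 1L || n_factors >= n) {
    abort("`n_factors` must satisfy 1 <= n_factors < n_participants.")
  }
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8))) {
    abort("Correlation matrix must be symmetric.")
  }
  e <- eigen((corr + t(corr)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values))) {
    abort("Correlation matrix is not positive semi-definite.")
  }
  lam <- pmax(e$values[seq_len(n_factors)], 0)
  l <- e$vectors[, seq_len(n_factors), drop = FALSE] %*% diag(sqrt(lam),
                                                              n_factors)
  if (n_factors > 1L) {
    rot <- stats::varimax(l, normalize = TRUE, eps = 1e-10)
    l <- l %*% rot$rotmat
  }
  ev <- colSums(l^2)
  ord <- order(ev, decreasing = TRUE)
  l <- l[, ord, drop = FALSE]
  ev <- ev[ord]
  for (j in seq_len(ncol(l))) {
    s <- sign(l[which.max(abs(l[, j])), j])
    if (s < 0) l[, j] <- -l[, j]
  }
  dimnames(l) <- list(rownames(corr), paste0("F", seq_len(n_factors)))
  list(loadings = l, eigenvalues = setNames(ev, colnames(l)),
       extraction_eigenvalues = lam)
}

#' Flag factor exemplars from a rotated loading matrix
#'
#' A participant is flagged on factor f iff (i) the loading exceeds the
#' significance threshold `crit / sqrt(n_stimuli)` (1.96 for p < .05 on a
#' loading standard error of `1/sqrt(n_stimuli)`), and (ii) the squared
#' loading exceeds half the participant's communality, so the factor holds a
#' strict majority of the participant's common variance. Rule (ii) makes a
#' double flag impossible.
#'
#' @param loadings Rotated loading matrix from [extract_and_rotate()].
#' @param n_stimuli Number of stimuli each sort ranks.
#' @param crit Normal quantile of the significance rule (default 1.96).
#' @return A tibble (`participant_id`, `factor` — `NA` when unflagged,
#'   `loading`, `communality`).
#' @export
flag_participants <- function(loadings, n_stimuli, crit = 1.96) {
  l <- as.matrix(loadings)
  thr <- crit / sqrt(n_stimuli)
  h2 <- rowSums(l^2)
  pick <- purrr::map(seq_len(nrow(l)), function(i) {
    ok <- which(l[i, ] > thr & l[i, ]^2 > h2[i] / 2)
    if (length(ok)) {
      tibble::tibble(factor = colnames(l)[ok[1]], loading = l[i, ok[1]])
    } else {
      tibble::tibble(factor = NA_character_, loading = NA_real_)
    }
  })
  dplyr::bind_rows(pick) |>
    dplyr::mutate(
      participant_id = rownames(l) %||% as.character(seq_len(nrow(l))),
      communality = unname(h2), .before = 1
    ) |>
    dplyr::relocate("participant_id", "factor", "loading", "communality")
}

#' Factor z-scores and idealized factor arrays
#'
#' Each factor's idealized sort is built from its flagged exemplars: sorts
#' are weighted by `w = loading / (1 - loading^2)` (more reliable exemplars
#' count more), the weighted mean rank of every stimulus is standardized to
#' a z-score across stimuli, and the z-scores are force-sorted back into the
#' grid with [utilities_to_qsort()].
#'
#' @param sorts Long sorts tibble or [qsort_dataset()].
#' @param loadings Rotated loadings ([extract_and_rotate()]).
#' @param flags Flag table ([flag_participants()]).
#' @param grid A [grid_spec()] (from the dataset when omitted).
#' @return A list of tibbles: `zscores` (`stimulus_id`, `factor`, `zscore`)
#'   and `arrays` (`stimulus_id`, `factor`, `rank`), each array a valid sort.
#' @export
factor_scores_and_arrays <- function(sorts, loadings, flags, grid = NULL) {
  if (inherits(sorts, "qsort_dataset")) grid <- grid %||% sorts$grid
  stopifnot(inherits(grid, "grid_spec"))
  tbl <- as_sorts_tibble(sorts)
  factors <- colnames(as.matrix(loadings))
  zs <- list()
  arrays <- list()
  for (f in factors) {
    ex <- dplyr::filter(flags, !is.na(.data$factor), .data$factor == f)
    if (!nrow(ex)) {
      abort(paste0("Factor ", f, " has no flagged exemplars."))
    }
    w <- setNames(ex$loading / (1 - ex$loading^2), ex$participant_id)
    sub <- dplyr::filter(tbl, .data$participant_id %in% ex$participant_id)
    m <- sub |>
      dplyr::mutate(w = w[.data$participant_id]) |>
      dplyr::group_by(.data$stimulus_id) |>
      dplyr::summarise(m = sum(.data$w * .data$rank) / sum(.data$w),
                       .groups = "drop")
    s <- stats::sd(m$m)
    z <- if (is.na(s) || s == 0) rep(0, nrow(m)) else (m$m - mean(m$m)) / s
    zs[[f]] <- tibble::tibble(stimulus_id = m$stimulus_id, factor = f,
                              zscore = z)
    arr <- utilities_to_qsort(setNames(z, m$stimulus_id), grid)
    arrays[[f]] <- tibble::tibble(stimulus_id = arr$stimulus_id, factor = f,
                                  rank = arr$rank)
  }
  list(zscores = dplyr::bind_rows(zs), arrays = dplyr::bind_rows(arrays))
}

#' By-person Q-factor analysis of a dataset
#'
#' Runs the full chain — sort correlations, PCA extraction, varimax
#' rotation, exemplar flagging, factor z-scores and idealized arrays — for a
#' fixed number of factors.
#'
#' @param dataset A [qsort_dataset()].
#' @param n_factors Number of factors to extract.
#' @param crit Flagging significance quantile (see [flag_participants()]).
#' @param compute_arrays Also compute z-scores and factor arrays (requires
#'   every factor to have at least one exemplar).
#' @return An object of class `qfactor_solution`: `n_factors`, `loadings`,
#'   `flags`, `eigenvalues`, `explained_variance_pct`
#'   (`100 * eigenvalue / n_participants`), `factor_zscores`,
#'   `factor_arrays`, `n_participants`, `n_stimuli`.
#' @export
q_factor_analysis <- function(dataset, n_factors, crit = 1.96,
                              compute_arrays = TRUE) {
  stopifnot(inherits(dataset, "qsort_dataset"))
  corr <- sort_correlations(dataset)
  ext <- extract_and_rotate(corr, n_factors)
  ns <- n_stimuli(dataset$design)
  flags <- flag_participants(ext$loadings, ns, crit = crit)
  scores <- NULL
  if (compute_arrays) {
    scores <- factor_scores_and_arrays(dataset, ext$loadings, flags,
                                       dataset$grid)
  }
  structure(
    list(
      n_factors = as.integer(n_factors),
      loadings = ext$loadings,
      flags = flags,
      eigenvalues = ext$eigenvalues,
      extraction_eigenvalues = ext$extraction_eigenvalues,
      explained_variance_pct = 100 * ext$eigenvalues / nrow(corr),
      factor_zscores = scores$zscores,
      factor_arrays = scores$arrays,
      n_participants = nrow(corr),
      n_stimuli = ns
    ),
    class = "qfactor_solution"
  )
}

#' @export
print.qfactor_solution <- function(x, ...) {
  cat("<qfactor_solution> ", x$n_factors, " factors, ", x$n_participants,
      " participants\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @rdname q_factor_analysis
#' @param x,object A `qfactor_solution`.
#' @param ... Unused.
#' @method tidy qfactor_solution
#' @export
tidy.qfactor_solution <- function(x, ...) {
  l <- x$loadings
  tibble::tibble(
    participant_id = rep(rownames(l), ncol(l)),
    factor = rep(colnames(l), each = nrow(l)),
    loading = as.vector(l)
  ) |>
    dplyr::left_join(x$flags[c("participant_id", "factor")] |>
                       dplyr::mutate(flagged = TRUE),
                     by = c("participant_id", "factor")) |>
    dplyr::mutate(flagged = !is.na(.data$flagged))
}

#' @rdname q_factor_analysis
#' @method glance qfactor_solution
#' @export
glance.qfactor_solution <- function(x, ...) {
  flagged <- table(factor(x$flags$factor, levels = names(x$eigenvalues)))
  tibble::tibble(
    factor = names(x$eigenvalues),
    eigenvalue = unname(x$eigenvalues),
    explained_variance_pct = unname(x$explained_variance_pct),
    n_flagged = as.integer(flagged)
  )
}

#' Compare candidate factor counts and pick a solution
#'
#' Computes a solution for each candidate factor count and reports, per
#' candidate, the eigenvalues, total explained variance and flagged counts.
#' The selected solution is the largest candidate all of whose factors pass
#' the Kaiser-Guttman bound (unrotated extraction eigenvalue greater than
#' `eigenvalue_min`; varimax redistributes variance, so rotated eigenvalues
#' would overstate weak factors) and have at least `min_flagged` flagged
#' exemplars; `force` overrides the rule.
#'
#' @param dataset A [qsort_dataset()].
#' @param candidates Integer vector of factor counts to compare (silently
#'   clipped to the valid range `1..n_participants - 1`).
#' @param eigenvalue_min Minimum per-factor eigenvalue (default 1, the
#'   Kaiser-Guttman bound).
#' @param min_flagged Minimum exemplars per factor (default 2).
#' @param crit Flagging quantile, passed to [flag_participants()].
#' @param force Optional factor count to select regardless of the rule.
#' @return A list of class `qfactor_selection`: `report` (one row per
#'   candidate: `n_factors`, `min_eigenvalue`, `total_variance_pct`,
#'   `min_flagged`, `admissible`), `solution` (the selected
#'   `qfactor_solution`, or `NULL` with a warning when no candidate is
#'   admissible), `n_factors_selected`.
#' @export
choose_q_solution <- function(dataset, candidates = 1:4, eigenvalue_min = 1,
                              min_flagged = 2L, crit = 1.96, force = NULL) {
  stopifnot(inherits(dataset, "qsort_dataset"))
  np <- length(participants(dataset))
  candidates <- sort(unique(candidates[candidates >= 1 & candidates < np]))
  if (!length(candidates)) abort("No valid candidate factor counts.")
  need_flagged <- min_flagged
  sols <- lapply(candidates, function(k) {
    q_factor_analysis(dataset, k, crit = crit, compute_arrays = FALSE)
  })
  report <- purrr::map2(sols, candidates, function(s, k) {
    flagged <- table(factor(s$flags$factor, levels = names(s$eigenvalues)))
    fewest <- as.integer(min(flagged))
    adm <- min(s$extraction_eigenvalues) > eigenvalue_min &&
      fewest >= need_flagged
    tibble::tibble(
      n_factors = as.integer(k),
      min_eigenvalue = min(s$extraction_eigenvalues),
      total_variance_pct = sum(s$explained_variance_pct),
      min_flagged = fewest,
      admissible = adm
    )
  }) |>
    dplyr::bind_rows()
  chosen <- if (!is.null(force)) {
    if (!force %in% candidates) abort("`force` must be one of the candidates.")
    force
  } else if (any(report$admissible)) {
    max(report$n_factors[report$admissible])
  } else {
    NA_integer_
  }
  solution <- NULL
  if (!is.na(chosen)) {
    solution <- q_factor_analysis(dataset, chosen, crit = crit,
                                  compute_arrays = TRUE)
  } else {
    warn("No candidate factor count is admissible; no solution selected.")
  }
  structure(list(report = report, solution = solution,
                 n_factors_selected = chosen),
            class = "qfactor_selection")
}

#' @export
print.qfactor_selection <- function(x, ...) {
  cat("<qfactor_selection> selected:",
      if (is.na(x$n_factors_selected)) "none" else x$n_factors_selected,
      "factors\n")
  print(x$report)
  invisible(x)
}

#' Lay a factor array out as a grid table
#'
#' Renders one factor's idealized sort in grid layout: one column per grid
#' value, stimulus codes stacked in each column (most preferred column
#' rightmost).
#'
#' @param arrays `arrays` tibble from [factor_scores_and_arrays()] (or the
#'   `factor_arrays` element of a solution).
#' @param factor_id Which factor to render (e.g. `"F1"`).
#' @return A tibble with one list-free character column per grid value.
#' @export
factor_array_grid <- function(arrays, factor_id) {
  arr <- dplyr::filter(tibble::as_tibble(arrays),
                       .data$factor == factor_id) |>
    dplyr::arrange(.data$rank, .data$stimulus_id)
  if (!nrow(arr)) abort(paste("No array for factor", factor_id))
  cols <- split(arr$stimulus_id, arr$rank)
  depth <- max(lengths(cols))
  tibble::as_tibble(lapply(cols, function(v) c(v, rep("", depth - length(v)))),
                    .name_repair = "minimal")
}
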