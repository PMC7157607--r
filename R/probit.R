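#' Build the ordinal observation table for preference modelling
#'
#' Expands a dataset into one observation per (participant, stimulus). The
#' outcome is the 1-based index of the grid column the stimulus was sorted
#' into; the predictors are dummy indicators for every non-reference level of
#' every design variable, plus, when cluster labels are supplied, dummies for
#' each non-reference cluster and all cluster x level products.
#'
#' @param sorts Long sorts tibble or [qsort_dataset()].
#' @param design A [stimulus_design()] (taken from the dataset when omitted).
#' @param grid A [grid_spec()] (taken from the dataset when omitted).
#' @param labels Optional tibble (`participant_id`, `cluster`). Participants
#'   absent from `labels` are dropped (e.g. unflagged participants in
#'   per-cluster analyses).
#' @param ref_levels Optional named character vector, variable -> reference
#'   level. Defaults to the first level of each variable.
#' @return An object of class `qsort_observations`: list with the outcome
#'   vector `y` (category index), model matrix `x`, a `terms` tibble
#'   describing each column (`term`, `type`, `variable`, `level`, `cluster`),
#'   `n_categories` and the source `grid`.
#' @export
encode_qsort_observations <- function(sorts, design = NULL, grid = NULL,
                                      labels = NULL, ref_levels = NULL) {
  if (inherits(sorts, "qsort_dataset")) {
    design <- design %||% sorts$design
    grid <- grid %||% sorts$grid
  }
  stopifnot(inherits(design, "stimulus_design"), inherits(grid, "grid_spec"))
  tbl <- as_sorts_tibble(sorts)
  if (!is.null(labels)) {
    labels <- tibble::as_tibble(labels)
    tbl <- dplyr::inner_join(tbl, labels[c("participant_id", "cluster")],
                             by = "participant_id")
    if (!nrow(tbl)) abort("No participants remain after applying `labels`.")
  }
  stim <- enumerate_stimuli(design)
  tbl <- dplyr::inner_join(tbl, stim, by = "stimulus_id")
  y <- match(tbl$rank, grid$values)
  if (anyNA(y)) abort("Found ranks outside the grid columns.")

  refs <- default_ref_levels(design, ref_levels)
  cols <- list()
  terms <- list()
  for (v in variable_names(design)) {
    for (l in setdiff(names(design$variables[[v]]), refs[[v]])) {
      nm <- paste0(v, "=", l)
      cols[[nm]] <- as.numeric(tbl[[v]] == l)
      terms[[nm]] <- tibble::tibble(term = nm, type = "level", variable = v,
                                    level = l, cluster = NA_character_)
    }
  }
  if (!is.null(labels)) {
    clusters <- unique(labels$cluster)
    if (length(clusters) < 2L) {
      abort("Interaction encoding needs at least two clusters in `labels`.")
    }
    level_terms <- names(cols)
    for (cl in clusters[-1]) {
      nm <- paste0("Factor=", cl)
      cols[[nm]] <- as.numeric(tbl$cluster == cl)
      terms[[nm]] <- tibble::tibble(term = nm, type = "factor",
                                    variable = "Factor", level = NA_character_,
                                    cluster = cl)
    }
    for (cl in clusters[-1]) {
      fdum <- as.numeric(tbl$cluster == cl)
      for (lt in level_terms) {
        nm <- paste0("Factor=", cl, ":", lt)
        cols[[nm]] <- fdum * cols[[lt]]
        terms[[nm]] <- tibble::tibble(
          term = nm, type = "interaction",
          variable = terms[[lt]]$variable, level = terms[[lt]]$level,
          cluster = cl)
      }
    }
  }
  x <- do.call(cbind, cols)
  structure(
    list(y = as.integer(y), x = x, terms = dplyr::bind_rows(terms),
         n_categories = length(grid$values), grid = grid,
         participant_id = tbl$participant_id, stimulus_id = tbl$stimulus_id),
    class = "qsort_observations"
  )
}

default_ref_levels <- function(design, ref_levels = NULL) {
  refs <- lapply(design$variables, function(lv) names(lv)[1])
  if (!is.null(ref_levels)) {
    for (v in names(ref_levels)) {
      if (!v %in% names(refs)) abort(paste("Unknown variable:", v))
      if (!ref_levels[[v]] %in% names(design$variables[[v]])) {
        abort(paste0("Unknown reference level for ", v, ": ", ref_levels[[v]]))
      }
      refs[[v]] <- ref_levels[[v]]
    }
  }
  refs
}

# Negative log-likelihood and analytic score of the cumulative probit model
# in the natural parameterisation (beta, tau). Thresholds tau must be
# increasing; category k has P = pnorm(tau_k - eta) - pnorm(tau_{k-1} - eta).
probit_nll_parts <- function(beta, tau, y, x, k) {
  eta <- if (length(beta)) drop(x %*% beta) else rep(0, length(y))
  tau_ext <- c(-Inf, tau, Inf)
  a_hi <- tau_ext[y + 1L] - eta
  a_lo <- tau_ext[y] - eta
  p <- pmax(pnorm(a_hi) - pnorm(a_lo), 1e-300)
  phi_hi <- ifelse(is.finite(a_hi), dnorm(a_hi), 0)
  phi_lo <- ifelse(is.finite(a_lo), dnorm(a_lo), 0)
  d_eta <- (phi_hi - phi_lo) / p
  g_beta <- if (length(beta)) drop(crossprod(x, d_eta)) else numeric(0)
  g_tau <- vapply(seq_len(k - 1L), function(j) {
    -sum(phi_hi[y == j] / p[y == j]) + sum(phi_lo[y == j + 1L] / p[y == j + 1L])
  }, numeric(1))
  list(nll = -sum(log(p)), g = c(g_beta, g_tau))
}

#' Fit an ordered-probit (cumulative probit) model by maximum likelihood
#'
#' The latent-response model is `y* = x'beta + e`, `e ~ N(0, 1)`, with the
#' observed category `k` whenever `tau_{k-1} < y* <= tau_k`; equivalently
#' `P(category <= k) = pnorm(tau_k - x'beta)`. Estimation maximises the
#' likelihood by BFGS with an analytic score; the cutpoints are
#' reparameterised as the first cutpoint plus log-scaled increments, so the
#' increasing-threshold constraint holds at every iterate. The reported
#' covariance is the inverse observed information at the optimum, over all
#' free parameters (slopes then cutpoints).
#'
#' @param observations A [encode_qsort_observations()] object, or a list with
#'   integer outcome `y` (1..K), model matrix `x` and `n_categories`.
#' @param maxit Maximum BFGS iterations.
#' @param reltol Relative convergence tolerance passed to [stats::optim()].
#' @return An object of class `ordered_probit` with elements `coefficients`,
#'   `thresholds`, `vcov`, `log_likelihood`, `null_log_likelihood`, `n_obs`,
#'   `n_categories`, `convergence` and the `terms` tibble (when available).
#' @export
fit_ordered_probit <- function(observations, maxit = 500L, reltol = 1e-12) {
  y <- observations$y
  x <- observations$x
  k <- observations$n_categories
  if (is.null(x)) x <- matrix(numeric(0), nrow = length(y), ncol = 0)
  stopifnot(length(y) > 0L, all(y >= 1L), all(y <= k))
  counts <- tabulate(y, nbins = k)
  if (sum(counts > 0L) < 2L) {
    abort("Need observations in at least two outcome categories.")
  }
  if (any(counts == 0L)) {
    abort(paste("Empty outcome categories:",
                paste(which(counts == 0L), collapse = ", "),
                "- use a grid matching the observed columns."))
  }
  p <- ncol(x)

  # start: null-model cutpoints (closed form), zero slopes
  tau0 <- qnorm(cumsum(counts[-k]) / length(y))
  theta0 <- c(rep(0, p), tau0[1], if (k > 2L) log(diff(tau0)))

  unpack <- function(theta) {
    beta <- theta[seq_len(p)]
    t1 <- theta[p + 1L]
    tau <- if (k > 2L) t1 + c(0, cumsum(exp(theta[(p + 2L):(p + k - 1L)])))
           else t1
    list(beta = beta, tau = tau)
  }
  fn <- function(theta) {
    par <- unpack(theta)
    probit_nll_parts(par$beta, par$tau, y, x, k)$nll
  }
  gr <- function(theta) {
    par <- unpack(theta)
    g <- probit_nll_parts(par$beta, par$tau, y, x, k)$g
    g_beta <- g[seq_len(p)]
    g_tau <- g[p + seq_len(k - 1L)]
    g_t1 <- sum(g_tau)
    g_s <- if (k > 2L) {
      exp(theta[(p + 2L):(p + k - 1L)]) *
        rev(cumsum(rev(g_tau)))[-1]
    }
    c(g_beta, g_t1, g_s)
  }
  opt <- optim(theta0, fn, gr, method = "BFGS",
               control = list(maxit = maxit, reltol = reltol))
  par <- unpack(opt$par)
  final_grad <- probit_nll_parts(par$beta, par$tau, y, x, k)$g

  # observed information in the natural parameterisation
  score_nat <- function(w) {
    probit_nll_parts(w[seq_len(p)], w[p + seq_len(k - 1L)], y, x, k)$g
  }
  info <- pracma::jacobian(score_nat, c(par$beta, par$tau))
  info <- (info + t(info)) / 2
  vcov <- tryCatch(solve(info), error = function(e) {
    warn("Observed information is singular; covariance unavailable.")
    matrix(NA_real_, nrow(info), ncol(info))
  })
  vcov <- (vcov + t(vcov)) / 2
  nms <- c(colnames(x), paste0("tau_", seq_len(k - 1L)))
  dimnames(vcov) <- list(nms, nms)

  if (p > 0L && any(abs(par$beta) > 10)) {
    warn("Very large coefficient estimates; possible complete separation.")
  }
  if (opt$convergence != 0L) {
    abort(paste0("Ordered-probit fit did not converge (optim code ",
                 opt$convergence, ", final nll ", signif(opt$value, 8), ")."))
  }
  structure(
    list(
      coefficients = setNames(par$beta, colnames(x)),
      thresholds = setNames(par$tau, paste0("tau_", seq_len(k - 1L))),
      vcov = vcov,
      log_likelihood = -opt$value,
      null_log_likelihood = -probit_nll_parts(numeric(0), tau0, y,
        matrix(numeric(0), length(y), 0), k)$nll,
      n_obs = length(y),
      n_categories = k,
      convergence = list(code = opt$convergence,
                         max_abs_score = max(abs(final_grad)),
                         counts = opt$counts),
      terms = observations$terms %||% NULL
    ),
    class = "ordered_probit"
  )
}

#' @export
print.ordered_probit <- function(x, ...) {
  cat("<ordered_probit> ", x$n_obs, " obs, ", x$n_categories,
      " categories, logLik ", format(x$log_likelihood), "\n", sep = "")
  if (length(x$coefficients)) {
    print(round(x$coefficients, 4))
  }
  invisible(x)
}

#' @rdname fit_ordered_probit
#' @param x,object An `ordered_probit` fit.
#' @param ... Unused.
#' @method tidy ordered_probit
#' @export
tidy.ordered_probit <- function(x, ...) {
  est <- c(x$coefficients, x$thresholds)
  se <- sqrt(pmax(diag(x$vcov), 0))
  tibble::tibble(
    term = names(est),
    type = rep(c("coefficient", "threshold"),
               c(length(x$coefficients), length(x$thresholds))),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se)))
  )
}

#' @rdname fit_ordered_probit
#' @method glance ordered_probit
#' @export
glance.ordered_probit <- function(x, ...) {
  npar <- length(x$coefficients) + length(x$thresholds)
  tibble::tibble(
    logLik = x$log_likelihood,
    null_logLik = x$null_log_likelihood,
    AIC = 2 * npar - 2 * x$log_likelihood,
    df = npar,
    nobs = x$n_obs,
    n_categories = x$n_categories,
    converged = x$convergence$code == 0L
  )
}

#' Wald chi-square test that a block of coefficients is jointly zero
#'
#' Computes `b' V^-1 b` for the named coefficient block `b` with `V` the
#' corresponding sub-block of the fit covariance; the statistic is referred
#' to the chi-square distribution with df equal to the block size.
#'
#' @param fit An [fit_ordered_probit()] result.
#' @param terms Character vector of coefficient names forming the block.
#' @param label Label reported in the `variable` column (defaults to the
#'   collapsed term names).
#' @return A one-row tibble (`variable`, `chi_square`, `df`, `p_value`).
#' @export
wald_test <- function(fit, terms, label = NULL) {
  missing <- setdiff(terms, names(fit$coefficients))
  if (length(missing)) {
    abort(paste("Coefficients not in fit:", paste(missing, collapse = ", ")))
  }
  b <- fit$coefficients[terms]
  v <- fit$vcov[terms, terms, drop = FALSE]
  vinv <- tryCatch(solve(v), error = function(e) {
    abort("Singular covariance block; Wald test unavailable.")
  })
  stat <- drop(t(b) %*% vinv %*% b)
  df <- length(terms)
  tibble::tibble(
    variable = label %||% paste(terms, collapse = "+"),
    chi_square = stat,
    df = as.integer(df),
    p_value = pchisq(stat, df, lower.tail = FALSE)
  )
}

#' Per-variable Wald tests of the main-effect blocks
#'
#' One Wald block test per design variable: the block collects the dummy
#' coefficients of all its non-reference levels, so df = levels - 1.
#'
#' @param fit An [fit_ordered_probit()] result carrying a `terms` tibble.
#' @return A tibble with one row per variable
#'   (`variable`, `chi_square`, `df`, `p_value`).
#' @export
wald_preference_tests <- function(fit) {
  stopifnot(!is.null(fit$terms))
  lev <- dplyr::filter(fit$terms, .data$type == "level")
  purrr::map(split(lev, factor(lev$variable, unique(lev$variable))),
             function(tt) wald_test(fit, tt$term, label = tt$variable[1])) |>
    dplyr::bind_rows()
}

#' Per-variable Wald tests of the cluster x variable interaction blocks
#'
#' For each design variable, tests that all cluster x level product
#' coefficients are jointly zero: df = (clusters - 1) x (levels - 1).
#'
#' @param fit A fit of an interaction-encoded observation table
#'   ([encode_qsort_observations()] with `labels`).
#' @return A tibble with one row per variable, `variable` labelled
#'   `"Factor * <variable>"`.
#' @export
wald_interaction_tests <- function(fit) {
  stopifnot(!is.null(fit$terms))
  int <- dplyr::filter(fit$terms, .data$type == "interaction")
  if (!nrow(int)) abort("Fit contains no interaction terms.")
  purrr::map(split(int, factor(int$variable, unique(int$variable))),
             function(tt) {
               wald_test(fit, tt$term,
                         label = paste("Factor *", tt$variable[1]))
             }) |>
    dplyr::bind_rows()
}

#' Per-level preference effects on the latent scale
#'
#' Reports every level of every design variable with its latent-scale
#' effect relative to the variable's reference level (effect 0 by
#' construction): a positive estimate means the level is preferred over the
#' reference.
#'
#' @param fit An [fit_ordered_probit()] result with a `terms` tibble.
#' @param design The [stimulus_design()] the fit was encoded from.
#' @return A tibble (`variable`, `level`, `estimate`, `std_error`,
#'   `reference`).
#' @export
preference_summary <- function(fit, design) {
  stopifnot(!is.null(fit$terms), inherits(design, "stimulus_design"))
  se <- sqrt(pmax(diag(fit$vcov), 0))
  rows <- list()
  for (v in variable_names(design)) {
    for (l in names(design$variables[[v]])) {
      nm <- paste0(v, "=", l)
      hit <- nm %in% names(fit$coefficients)
      rows[[nm]] <- tibble::tibble(
        variable = v, level = l,
        estimate = if (hit) unname(fit$coefficients[nm]) else 0,
        std_error = if (hit) unname(se[nm]) else NA_real_,
        reference = !hit
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Fit the overall (or interaction) preference model for a dataset
#'
#' Convenience wrapper: encodes the observation table and fits the
#' ordered-probit model in one call.
#'
#' @inheritParams encode_qsort_observations
#' @param dataset A [qsort_dataset()].
#' @return An `ordered_probit` fit.
#' @export
fit_preference_model <- function(dataset, labels = NULL, ref_levels = NULL) {
  stopifnot(inherits(dataset, "qsort_dataset"))
  obs <- encode_qsort_observations(dataset, labels = labels,
                                   ref_levels = ref_levels)
  fit_ordered_probit(obs)
}
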