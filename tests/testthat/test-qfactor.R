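test_that("sort correlations behave like by-person Pearson correlations", {
  d <- io_design()
  g <- study_grid()
  set.seed(51)
  a <- random_sort(d, g, "A")
  b <- a
  b$participant_id <- "B"
  b$rank <- -b$rank   # grid reflection
  c_ <- random_sort(d, g, "C")
  corr <- sort_correlations(dplyr::bind_rows(a, b, c_))

  expect_equal(diag(corr), c(A = 1, B = 1, C = 1))
  expect_equal(corr["A", "B"], -1)
  expect_equal(corr, t(corr))

  # null distribution of r between independent forced sorts is narrow
  set.seed(52)
  rs <- vapply(1:200, function(i) {
    s1 <- random_sort(d, g, "x")
    s2 <- random_sort(d, g, "y")
    cor(s1$rank[order(s1$stimulus_id)], s2$rank[order(s2$stimulus_id)])
  }, numeric(1))
  expect_lte(mean(abs(rs) >= 0.6), 0.01)
})

test_that("extraction and rotation preserve structure and simplify loadings", {
  # rank-1 structure: identical participants
  ones <- matrix(1, 6, 6, dimnames = list(paste0("P", 1:6), paste0("P", 1:6)))
  ext1 <- extract_and_rotate(ones, 1)
  expect_equal(unname(ext1$eigenvalues), 6, tolerance = 1e-10)
  expect_equal(unname(ext1$loadings[, 1]), rep(1, 6), tolerance = 1e-10)

  ds <- simulate_qsorts(study_sim_config(), seed = 14)
  corr <- sort_correlations(ds)
  e <- eigen(corr, symmetric = TRUE, only.values = TRUE)
  # eigenvalues of the full decomposition sum to the participant count
  expect_equal(sum(e$values), 18, tolerance = 1e-10)

  ext <- extract_and_rotate(corr, 3)
  # rotation is orthogonal: communalities match the unrotated extraction
  lam <- e$values[1:3]
  v <- eigen(corr, symmetric = TRUE)$vectors[, 1:3]
  unrot <- v %*% diag(sqrt(lam))
  expect_equal(rowSums(ext$loadings^2), unname(rowSums(unrot^2)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # eigenvalues = column sums of squared loadings, descending
  expect_equal(unname(ext$eigenvalues), unname(colSums(ext$loadings^2)))
  expect_true(all(diff(ext$eigenvalues) <= 0))
  # sign convention: dominant loading positive
  for (j in 1:3) {
    expect_gt(ext$loadings[which.max(abs(ext$loadings[, j])), j], 0)
  }
  expect_error(extract_and_rotate(corr, 18), "n_factors")

  # varimax criterion beats random orthogonal rotations
  set.seed(53)
  crit <- varimax_criterion(ext$loadings)
  rand <- vapply(1:1000, function(i) {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    varimax_criterion(ext$loadings %*% q)
  }, numeric(1))
  expect_true(all(crit >= rand - 1e-10))
})

test_that("flagging applies the significance and majority-of-variance rules", {
  expect_equal(1.96 / sqrt(32), 0.34648, tolerance = 1e-4)

  l <- rbind(
    strong   = c(0.9, 0.1, 0.1),    # flagged on F1
    split    = c(0.5, 0.5, 0.0),    # no majority of common variance
    weak     = c(0.2, 0.1, 0.0),    # below threshold
    moderate = c(0.6, 0.3, 0.1)     # flagged on F1
  )
  colnames(l) <- paste0("F", 1:3)
  fl <- flag_participants(l, n_stimuli = 32)
  expect_equal(fl$factor, c("F1", NA, NA, "F1"))
  expect_equal(fl$loading[1], 0.9)
  # each participant flagged on at most one factor (one row each)
  expect_equal(nrow(fl), 4L)
})

test_that("factor arrays are exemplar-weighted idealized sorts", {
  d <- io_design()
  g <- study_grid()
  set.seed(54)
  s1 <- random_sort(d, g, "P1")
  s2 <- random_sort(d, g, "P2")
  sorts <- dplyr::bind_rows(s1, s2)

  # single exemplar: the array is that participant's sort
  l <- matrix(c(0.8, 0.1), ncol = 1, dimnames = list(c("P1", "P2"), "F1"))
  fl <- tibble::tibble(participant_id = c("P1", "P2"),
                       factor = c("F1", NA), loading = c(0.8, NA),
                       communality = c(0.64, 0.01))
  fa <- factor_scores_and_arrays(sorts, l, fl, g)
  arr <- fa$arrays[order(fa$arrays$stimulus_id), ]
  expect_equal(arr$rank, s1$rank[order(s1$stimulus_id)])
  expect_equal(nrow(validate_qsorts(
    dplyr::mutate(arr, participant_id = "F1")[c("participant_id",
                                                "stimulus_id", "rank")],
    d, g)), 0L)

  # two exemplars: weighted means use w = loading / (1 - loading^2)
  l2 <- matrix(c(0.5, 0.8), ncol = 1, dimnames = list(c("P1", "P2"), "F1"))
  fl2 <- tibble::tibble(participant_id = c("P1", "P2"),
                        factor = c("F1", "F1"), loading = c(0.5, 0.8),
                        communality = c(0.25, 0.64))
  w1 <- 0.5 / (1 - 0.25)
  expect_equal(w1, 2 / 3)
  w2 <- 0.8 / (1 - 0.64)
  fa2 <- factor_scores_and_arrays(sorts, l2, fl2, g)
  m <- (w1 * s1$rank[order(s1$stimulus_id)] +
          w2 * s2$rank[order(s2$stimulus_id)]) / (w1 + w2)
  z <- (m - mean(m)) / sd(m)
  zs <- fa2$zscores[order(fa2$zscores$stimulus_id), ]
  expect_equal(zs$zscore, z, tolerance = 1e-12)

  # a factor without exemplars errors by name
  expect_error(factor_scores_and_arrays(sorts, l, fl[2, ], g), "F1")
})

test_that("planted clusters are recovered exactly at zero noise", {
  cfg <- sim_config(io_design(), study_grid(), list(
    cluster_spec("A", 3, list(Behaviour = c(Vibrate = 1.5, Quiescent = -1.5)),
                 noise_sd = 0),
    cluster_spec("B", 3, list("Surface texture" = c(Rough = 1.5,
                                                    Smooth = -1.5)),
                 noise_sd = 0),
    cluster_spec("C", 2, list(Contour = c(Round = 1.5, Angular = -1.5)),
                 noise_sd = 0)
  ))
  ds <- simulate_qsorts(cfg, seed = 1)
  sol <- q_factor_analysis(ds, 3)

  # every factor array reproduces its cluster's common (noise-free) sort
  flagged <- dplyr::inner_join(sol$flags, ds$labels, by = "participant_id")
  expect_true(all(!is.na(flagged$factor)))
  expect_equal(dplyr::n_distinct(paste(flagged$cluster, flagged$factor)), 3L)
  for (f in unique(flagged$factor)) {
    pid <- flagged$participant_id[flagged$factor == f][1]
    own <- ds$sorts[ds$sorts$participant_id == pid, ]
    arr <- sol$factor_arrays[sol$factor_arrays$factor == f, ]
    expect_equal(arr$rank[order(arr$stimulus_id)],
                 own$rank[order(own$stimulus_id)])
  }
})

test_that("uncorrelated clusters are recovered perfectly across replicates", {
  # viewpoints built on disjoint variables: between-cluster utility
  # correlation is zero
  cfg <- sim_config(io_design(), study_grid(), list(
    cluster_spec("beh", 5, list(Behaviour = c(Vibrate = 1.2,
                                              Quiescent = -1.2)),
                 noise_sd = 0.3),
    cluster_spec("tex", 5, list("Surface texture" = c(Rough = 1.2,
                                                      Smooth = -1.2)),
                 noise_sd = 0.3)
  ))
  aris <- vapply(1:10, function(s) {
    ds <- simulate_qsorts(cfg, seed = s)
    sol <- q_factor_analysis(ds, 2, compute_arrays = FALSE)
    cluster_recovery_ari(sol$flags, ds$labels)
  }, numeric(1))
  expect_true(all(aris == 1))
})

test_that("solution choice follows the eigenvalue and flagged-count rule", {
  ds <- simulate_qsorts(study_sim_config(), seed = 16)
  sel <- choose_q_solution(ds, candidates = 1:4)
  expect_equal(sel$n_factors_selected, 3L)
  expect_equal(cluster_recovery_ari(sel$solution$flags, ds$labels), 1)
  # report identity: variance always 100 * eigenvalue / n
  gl <- glance(sel$solution)
  expect_equal(gl$explained_variance_pct, 100 * gl$eigenvalue / 18)

  # homogeneous single-cluster data -> one factor
  cfg1 <- sim_config(io_design(), study_grid(), list(
    cluster_spec("only", 8, list(Behaviour = c(Vibrate = 1.2,
                                               Quiescent = -1.2)),
                 noise_sd = 0.3)
  ))
  ds1 <- simulate_qsorts(cfg1, seed = 2)
  sel1 <- choose_q_solution(ds1, candidates = 1:4)
  expect_equal(sel1$n_factors_selected, 1L)

  # factor arrays of the selected solution satisfy the grid quotas
  arr <- sel$solution$factor_arrays
  for (f in unique(arr$factor)) {
    a <- arr[arr$factor == f, ]
    counts <- table(factor(a$rank, levels = ds$grid$values))
    expect_equal(as.integer(counts), ds$grid$quotas)
  }
})
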