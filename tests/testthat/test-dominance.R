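test_that("level positions average the grid columns occupied by each level", {
  d <- io_design()
  g <- study_grid()
  # put all 16 Rough stimuli in the 16 highest cells
  stim <- enumerate_stimuli(d)
  u <- setNames(ifelse(stim$`Surface texture` == "Rough", 1, 0),
                stim$stimulus_id)
  s <- utilities_to_qsort(u, g)
  s$participant_id <- "P1"
  lp <- level_positions(s, d)
  tex <- lp[lp$variable == "Surface texture", ]

  # oracle: quota-weighted mean of the top/bottom 16 cells
  cells <- rep(g$values, g$quotas)
  top16 <- mean(sort(cells, decreasing = TRUE)[1:16])
  expect_equal(top16, 2.125)
  expect_equal(tex$mean_rank[tex$level == "Rough"], top16)
  expect_equal(tex$mean_rank[tex$level == "Smooth"], -top16)

  # any valid sort: 2-level variables symmetric about the grid mean
  set.seed(41)
  s2 <- random_sort(d, g)
  lp2 <- level_positions(s2, d)
  for (v in c("Size", "Surface texture", "Contour")) {
    m <- lp2$mean_rank[lp2$variable == v]
    expect_equal(sum(m), 2 * grid_mean(g))
  }
})

test_that("dominance weights normalise to one and isolate the driving variable", {
  d <- io_design()
  g <- study_grid()
  stim <- enumerate_stimuli(d)

  # texture perfectly splits the grid halves; within each half the other
  # variables are balanced by the id tie-break
  u <- setNames(ifelse(stim$`Surface texture` == "Rough", 1, 0),
                stim$stimulus_id)
  s <- utilities_to_qsort(u, g)
  s$participant_id <- "P1"
  w <- dominance_weights(s, d, g)
  expect_equal(sum(w$weight), 1)
  # the lexicographic tie-break within each half leaks a little spread to
  # the other variables; texture still dominates by a wide margin
  expect_gt(w$weight[w$variable == "Surface texture"], 0.6)
  expect_equal(w$variable[which.max(w$weight)], "Surface texture")

  # every valid random sort sums to 1
  set.seed(42)
  for (i in 1:10) {
    w <- dominance_weights(random_sort(d, g), d, g)
    expect_equal(sum(w$weight), 1)
    expect_true(all(w$weight >= 0))
  }

  # one variable splits the halves while the other is perfectly balanced:
  # all weight concentrates on the splitting variable
  d3 <- stimulus_design(list(A = c(lo = "l", hi = "h"),
                             B = c(lo = "L", hi = "H")))
  g3 <- grid_spec(c(-2, -1, 1, 2), c(1, 1, 1, 1))
  s3 <- tibble::tibble(
    participant_id = "P1",
    stimulus_id = c("lL", "lH", "hL", "hH"),
    rank = c(-2L, -1L, 2L, 1L)
  )
  w3 <- dominance_weights(s3, d3, g3)
  expect_equal(w3$weight[w3$variable == "A"], 1)
  expect_equal(w3$weight[w3$variable == "B"], 0)

  # identical spreads for all variables -> uniform weights: rank = a + b
  # makes both variables' level means coincide
  d2 <- stimulus_design(list(A = c(lo = "l", hi = "h"),
                             B = c(lo = "L", hi = "H")))
  g2 <- grid_spec(-1:1, c(1, 2, 1))
  s2 <- tibble::tibble(
    participant_id = "P1",
    stimulus_id = c("lL", "lH", "hL", "hH"),
    rank = c(-1L, 0L, 0L, 1L)
  )
  w2 <- dominance_weights(s2, d2, g2)
  expect_equal(w2$weight, c(0.5, 0.5))
})

test_that("dominance weights are invariant to grid reflection and level relabeling", {
  d <- io_design()
  g <- study_grid()
  set.seed(43)
  s <- random_sort(d, g)
  w <- dominance_weights(s, d, g)

  refl <- s
  refl$rank <- -refl$rank
  w_refl <- dominance_weights(refl, d, g)
  expect_equal(w$weight, w_refl$weight)

  # relabeling levels (swapping names within a variable) permutes nothing
  # in the weights
  d_swap <- stimulus_design(list(
    "Size"            = c(Large = "S", Small = "L"),
    "Surface texture" = c(Smooth = "S", Rough = "R"),
    "Contour"         = c(Round = "R", Angular = "A"),
    "Behaviour"       = c(Light = "L", Sound = "S", Vibrate = "V",
                          Quiescent = "Q")
  ))
  w_swap <- dominance_weights(s, d_swap, g)
  expect_equal(w$weight, w_swap$weight)
})

test_that("greater level-mean separation strictly increases a variable's weight", {
  d <- io_design()
  g <- study_grid()
  stim <- enumerate_stimuli(d)
  base <- setNames(ifelse(stim$Behaviour == "Vibrate", 1, 0) +
                     0.45 * ifelse(stim$Contour == "Round", 1, 0),
                   stim$stimulus_id)
  weights_at <- function(beta_tex) {
    u <- base + beta_tex * (stim$`Surface texture` == "Rough")
    s <- utilities_to_qsort(setNames(u, stim$stimulus_id), g)
    s$participant_id <- "P1"
    w <- dominance_weights(s, d, g)
    w$weight[w$variable == "Surface texture"]
  }
  w_seq <- vapply(c(0.1, 0.5, 0.8, 1.2, 1.6), weights_at, numeric(1))
  expect_true(all(diff(w_seq) > 0))
})

test_that("one-way dominance ANOVA matches hand-computed sums of squares", {
  ds <- simulate_qsorts(study_sim_config(), seed = 9)
  w <- dominance_weights(ds)
  out <- dominance_anova(w)
  oracle <- oracle_oneway_anova(w$weight, w$variable)

  expect_equal(out$statistic[1], oracle$F, tolerance = 1e-10)
  expect_equal(out$df, c(oracle$df1, oracle$df2))
  expect_equal(out$df, c(3L, 68L))  # 18 participants x 4 variables
  expect_equal(out$p_value[1], oracle$p, tolerance = 1e-10)

  # uniform weights -> degenerate data, F = 0
  uni <- tidyr::expand_grid(participant_id = c("a", "b", "c"),
                            variable = c("V1", "V2")) |>
    dplyr::mutate(raw = 0, weight = 0.5)
  expect_warning(out0 <- dominance_anova(uni), "identical")
  expect_equal(out0$statistic[1], 0)
})

test_that("two-way dominance ANOVA has the cluster-design df structure", {
  ds <- simulate_qsorts(study_sim_config(), seed = 10)
  w <- dominance_weights(ds)
  labels <- ds$labels[ds$labels$cluster != "none", ]
  out <- dominance_anova_by_factor(w, labels)

  expect_equal(out$term,
               c("factor", "variable", "factor:variable", "Residuals"))
  # 3 clusters (8/6/3), 4 variables: interaction df 6, error df 56
  expect_equal(out$df, c(2L, 3L, 6L, 56L))

  # identical weight profiles in all clusters -> interaction F ~ 0
  flat <- tidyr::expand_grid(participant_id = sprintf("P%02d", 1:9),
                             variable = c("A", "B", "C")) |>
    dplyr::mutate(weight = rep(c(0.5, 0.3, 0.2), 9), raw = weight)
  lab <- tibble::tibble(participant_id = sprintf("P%02d", 1:9),
                        cluster = rep(c("X", "Y", "Z"), each = 3))
  out_flat <- dominance_anova_by_factor(flat, lab)
  # residual variance is exactly zero here, so test the interaction SS
  expect_lt(out_flat$sum_sq[out_flat$term == "factor:variable"], 1e-20)
})

test_that("clusters planted with different dominance profiles interact detectably", {
  # Behaviour-only vs Texture+Behaviour clusters
  cfg <- sim_config(io_design(), study_grid(), list(
    cluster_spec("beh", 8, list(
      Behaviour = c(Light = 0.5, Sound = -1, Vibrate = 1.2, Quiescent = -0.7)
    ), noise_sd = 0.3),
    cluster_spec("tex", 8, list(
      "Surface texture" = c(Smooth = -0.9, Rough = 0.9),
      Behaviour = c(Light = 0.4, Sound = -0.6, Vibrate = 0.6,
                    Quiescent = -0.4)
    ), noise_sd = 0.3)
  ))
  pvals <- vapply(1:25, function(s) {
    ds <- simulate_qsorts(cfg, seed = s)
    w <- dominance_weights(ds)
    out <- dominance_anova_by_factor(w, ds$labels)
    out$p_value[out$term == "factor:variable"]
  }, numeric(1))
  expect_true(all(pvals < 0.01))
})

test_that("per-cluster mean weights reproduce the planted dominance ordering", {
  ds <- simulate_qsorts(study_sim_config(), seed = 13)
  w <- dominance_weights(ds)
  tab <- factor_dominance_table(w, ds$labels)
  for (cl in c("C1", "C2", "C3")) {
    sub <- tab[tab$cluster == cl, ]
    expect_equal(sub$variable[which.max(sub$mean_weight)], "Behaviour")
    # columns sum to one
    expect_equal(sum(sub$mean_weight), 1)
  }
  # the behaviour-only cluster is the most behaviour-dominated
  beh <- tab[tab$variable == "Behaviour", ]
  expect_equal(beh$cluster[which.max(beh$mean_weight)], "C3")
})
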