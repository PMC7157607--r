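# Small designs/grids and independent oracles shared across test files.

tiny_design <- function() {
  stimulus_design(list(
    Shape  = c(Round = "R", Angular = "A"),
    Colour = c(Red = "r", Green = "g", Blue = "b")
  ))
}

tiny_grid <- function() grid_spec(-2:2, c(1, 1, 2, 1, 1))

# A deterministic valid sort: stimuli in lexicographic order get ranks from
# the top of the grid downwards.
lexicographic_sort <- function(design, grid, participant_id = "P1") {
  ids <- sort(enumerate_stimuli(design)$stimulus_id)
  k <- length(grid$values)
  tibble::tibble(
    participant_id = participant_id,
    stimulus_id = ids,
    rank = as.integer(rep(grid$values[k:1], grid$quotas[k:1]))
  )
}

# Random valid sort via random utilities (fixed RNG state of the caller).
random_sort <- function(design, grid, participant_id = "P1") {
  ids <- enumerate_stimuli(design)$stimulus_id
  s <- utilities_to_qsort(stats::setNames(stats::runif(length(ids)), ids),
                          grid)
  s$participant_id <- participant_id
  s[c("participant_id", "stimulus_id", "rank")]
}

# Independent sort-then-bin oracle for forced sorting: explicit loop, no
# shared code with utilities_to_qsort().
oracle_forced_sort <- function(utilities, grid) {
  ids <- names(utilities)
  ord <- ids[order(-utilities, ids)]
  out <- integer(length(ids))
  names(out) <- ord
  pos <- 1L
  for (col in rev(seq_along(grid$values))) {
    for (q in seq_len(grid$quotas[col])) {
      out[pos] <- grid$values[col]
      pos <- pos + 1L
    }
  }
  out[sort(names(out))]
}

# Textbook one-way ANOVA from sums of squares.
oracle_oneway_anova <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  ss_between <- 0
  ss_within <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ss_between <- ss_between + length(v) * (mean(v) - grand)^2
    ss_within <- ss_within + sum((v - mean(v))^2)
  }
  df1 <- length(unique(groups)) - 1
  df2 <- length(values) - length(unique(groups))
  f <- (ss_between / df1) / (ss_within / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Adjusted Rand index between planted labels and recovered flags, over the
# participants that carry a planted cluster (unflagged participants form
# their own recovered group).
cluster_recovery_ari <- function(flags, labels) {
  m <- dplyr::inner_join(flags, labels, by = "participant_id")
  m <- m[m$cluster != "none", ]
  mclust::adjustedRandIndex(
    m$cluster, ifelse(is.na(m$factor), "unflagged", m$factor))
}
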