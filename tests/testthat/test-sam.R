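test_that("pooled denominator matches the hand computation", {
  # SS1 = SS2 = 2, pooled variance 1, s = sqrt(2/3)
  pd <- pooled_denominator(c(1, 2, 3), c(4, 5, 6))
  expect_equal(pd$mean_diff, -3)
  expect_equal(pd$s, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(pd$s, 4), 0.8165)

  same <- pooled_denominator(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff, 0)

  sw <- pooled_denominator(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sw$mean_diff, 3)
  expect_equal(sw$s, pd$s)

  expect_error(pooled_denominator(1, c(1, 2)), "at least 2")
})

test_that("fixed-percentile s0 hits its quantile boundaries", {
  s <- 1:10
  d <- rnorm(10)
  expect_equal(estimate_s0(d, s, "fixed_percentile", fixed_q = 0), 1)
  expect_equal(estimate_s0(d, s, "fixed_percentile", fixed_q = 1), 10)
  expect_error(estimate_s0(d, rep(0, 10), "fixed_percentile"), "zero")
})

test_that("percentile-grid s0 equals an independent transcription of the recipe", {
  # oracle: plain-loop transcription of the percentile-grid procedure
  s0_oracle <- function(diffs, s) {
    alphas <- seq(0, 1, by = 0.05)
    cand <- as.numeric(quantile(s, alphas))
    breaks <- unique(quantile(s, seq(0, 1, by = 0.01)))
    win <- cut(s, breaks, include.lowest = TRUE)
    best <- Inf
    best_s0 <- NA_real_
    for (s0 in cand) {
      d <- diffs / (s + s0)
      mads <- c()
      for (w in levels(win)) {
        dw <- d[win == w]
        if (length(dw)) mads <- c(mads, mad(dw))
      }
      cv <- sd(mads) / mean(mads)
      if (cv < best) { best <- cv; best_s0 <- s0 }
    }
    best_s0
  }
  set.seed(1)
  n_genes <- 1000L
  g1 <- matrix(rnorm(n_genes * 20), n_genes)
  g2 <- matrix(rnorm(n_genes * 20), n_genes)
  diffs <- rowMeans(g1) - rowMeans(g2)
  ss <- rowSums((g1 - rowMeans(g1))^2) + rowSums((g2 - rowMeans(g2))^2)
  s <- sqrt((1 / 20 + 1 / 20) * ss / 38)
  expect_equal(estimate_s0(diffs, s, "percentile_grid"),
               s0_oracle(diffs, s), tolerance = 1e-12)
  expect_error(estimate_s0(diffs[1:50], s[1:50], "percentile_grid"),
               "at least 100")
})

make_assignment <- function(ds, labels) {
  cluster_assignment(ds$name, "kmeans", max(labels),
                     setNames(labels, samples(ds)), 1L, 0)
}

test_that("the printed hand fixture yields d = -3.674 with s0 = 0", {
  values <- matrix(c(1, 2, 3, 4, 5, 6,
                     2, 3, 2, 5, 6, 5,
                     1, 1, 2, 2, 1, 1), 3, 6, byrow = TRUE,
                   dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:6)))
  ds <- expression_dataset("hand", values)
  tm <- moderated_t_matrix(ds, make_assignment(ds, c(1, 1, 1, 2, 2, 2)),
                           s0 = 0)
  expect_equal(round(tm$scores["g1", 1L], 3), -3.674)
  expect_equal(tm$scores["g1", 1L], -3 / sqrt(2 / 3), tolerance = 1e-12)
})

test_that("k = 2 score columns are exact negations of each other", {
  sim <- small_sim()
  ds <- sim$datasets[[1L]]
  a <- kmeans_partition(ds, genes(ds), 2L, n_init = 3L, seed = 1L)
  tm <- moderated_t_matrix(ds, a)
  expect_equal(tm$scores[, 1L], -tm$scores[, 2L], ignore_attr = TRUE)
  expect_equal(tm$s0[1L], tm$s0[2L])
})

test_that("moderated t is invariant to constant gene shifts and zero for flat genes", {
  sim <- small_sim()
  ds <- sim$datasets[[1L]]
  a <- kmeans_partition(ds, genes(ds), 3L, n_init = 3L, seed = 2L)
  tm <- moderated_t_matrix(ds, a)

  shifted <- ds$values
  shifted["g0001", ] <- shifted["g0001", ] + 1000
  tm2 <- moderated_t_matrix(expression_dataset(ds$name, shifted,
                                               ds$annotations), a)
  expect_equal(tm2$scores["g0001", ], tm$scores["g0001", ], tolerance = 1e-6)

  flat <- ds$values
  flat["g0002", ] <- 7
  tm3 <- moderated_t_matrix(expression_dataset(ds$name, flat,
                                               ds$annotations), a)
  expect_equal(unname(tm3$scores["g0002", ]), rep(0, 3))
  expect_true(all(is.finite(tm3$scores)))
})

test_that("permuting samples within clusters changes nothing", {
  sim <- small_sim()
  ds <- sim$datasets[[1L]]
  a <- kmeans_partition(ds, genes(ds), 3L, n_init = 3L, seed = 3L)
  tm <- moderated_t_matrix(ds, a)
  perm <- sample(samples(ds))
  ds_p <- subset_dataset(ds, samples = perm)
  a_p <- cluster_assignment(ds$name, a$algorithm, a$k, a$labels[perm],
                            a$seed, a$objective)
  expect_equal(moderated_t_matrix(ds_p, a_p)$scores, tm$scores)
})

test_that("undersized clusters are rejected", {
  ds <- toy_dataset()
  expect_error(moderated_t_matrix(ds, make_assignment(ds, c(1, 2, 2, 2, 2)),
                                  s0 = 0),
               "at least 2 samples")
})
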