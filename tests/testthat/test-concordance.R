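test_that("pearson correlation honors its identities and preconditions", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  # textbook formula evaluated directly
  y <- c(1, 2, 3, 10)
  oracle <- (sum(x * y) - 4 * mean(x) * mean(y)) /
    sqrt((sum(x^2) - 4 * mean(x)^2) * (sum(y^2) - 4 * mean(y)^2))
  expect_equal(pearson_correlation(x, y), oracle, tolerance = 1e-12)
  expect_error(pearson_correlation(x, c(1, 2)), "equal length")
  expect_error(pearson_correlation(c(1, 1, 1), x[1:3]), "zero-variance")
})

fake_tscores <- function(scores, name = "A", k = ncol(scores)) {
  structure(list(dataset_name = name, algorithm = "kmeans", k = k,
                 scores = scores, s0 = rep(0, k)), class = "tscore_matrix")
}

test_that("cross-dataset correlations expose antisymmetry and permutations", {
  set.seed(1)
  v <- rnorm(200)
  tA <- fake_tscores(matrix(c(v, -v), ncol = 2,
                            dimnames = list(paste0("g", 1:200), NULL)))
  self <- cross_dataset_correlations(tA, tA)
  expect_equal(self, matrix(c(1, -1, -1, 1), 2, 2), ignore_attr = TRUE)

  m <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(paste0("g", 1:200), NULL))
  tB <- fake_tscores(m, "B")
  tC <- fake_tscores(m[, c(2, 3, 1)], "C")
  corr <- cross_dataset_correlations(tB, tC)
  expect_equal(apply(corr, 1L, which.max), c(3L, 1L, 2L))

  tD <- fake_tscores(m[sample(200), ], "D")
  expect_error(cross_dataset_correlations(tB, tD), "gene universes")
})

test_that("gene-order permutations applied to both matrices change nothing", {
  set.seed(2)
  m1 <- matrix(rnorm(300), 100, 3, dimnames = list(paste0("g", 1:100), NULL))
  m2 <- matrix(rnorm(300), 100, 3, dimnames = list(paste0("g", 1:100), NULL))
  perm <- sample(100)
  c1 <- cross_dataset_correlations(fake_tscores(m1), fake_tscores(m2, "B"))
  c2 <- cross_dataset_correlations(fake_tscores(m1[perm, ]),
                                   fake_tscores(m2[perm, ], "B"))
  expect_equal(c1, c2)
})

test_that("optimal matching equals brute-force search on random matrices", {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  all_perms <- perms(1:4)
  set.seed(99)
  for (rep in 1:100) {
    corr <- matrix(runif(16, -1, 1), 4, 4)
    got <- match_clusters(corr)
    expect_true(all(sort(got) == 1:4))
    totals <- vapply(all_perms, function(p) sum(corr[cbind(1:4, p)]),
                     numeric(1L))
    expect_equal(sum(corr[cbind(1:4, got)]), max(totals), tolerance = 1e-9)
  }
})

test_that("matching recovers dominant diagonals, permutations, and breaks ties low", {
  dom <- matrix(0.1, 3, 3); diag(dom) <- 0.9
  expect_equal(match_clusters(dom), 1:3)
  # permuting columns by p makes row a's best column the inverse image of a
  perm <- dom[, c(3, 1, 2)]
  expect_equal(match_clusters(perm), c(2L, 3L, 1L))
  # all-equal matrix: every bijection optimal; lexicographically smallest wins
  expect_equal(match_clusters(matrix(0.5, 3, 3)), 1:3)
  expect_error(match_clusters(matrix(1, 2, 3)), "square")
})

test_that("matching is symmetric between the two orientations of a pair", {
  set.seed(3)
  m1 <- matrix(rnorm(400), 100, 4, dimnames = list(paste0("g", 1:100), NULL))
  m2 <- matrix(rnorm(400), 100, 4, dimnames = list(paste0("g", 1:100), NULL))
  ab <- match_clusters(cross_dataset_correlations(fake_tscores(m1, "A"),
                                                  fake_tscores(m2, "B")))
  ba <- match_clusters(cross_dataset_correlations(fake_tscores(m2, "B"),
                                                  fake_tscores(m1, "A")))
  inv <- integer(4); inv[ab] <- 1:4
  expect_equal(ba, inv)
})

test_that("reference labels propagate through the bijection", {
  set.seed(4)
  base <- matrix(rnorm(600), 200, 3, dimnames = list(paste0("g", 1:200), NULL))
  tRef <- fake_tscores(base, "ref")
  tSwp <- fake_tscores(base[, c(2, 1, 3)] + rnorm(600, sd = 0.05), "other")
  labs <- assign_reference_labels(list(tRef, tSwp), "ref",
                                  c("mesenchymal-like", "proliferative-like",
                                    "immunoreactive-like"))
  ref_rows <- labs[labs$dataset == "ref", ]
  expect_equal(ref_rows$label[ref_rows$cluster == 1L], "mesenchymal-like")
  oth <- labs[labs$dataset == "other", ]
  expect_equal(oth$label[oth$cluster == 1L], "proliferative-like")
  expect_equal(oth$label[oth$cluster == 2L], "mesenchymal-like")

  solo <- assign_reference_labels(list(tRef), "ref", c("a", "b", "c"))
  expect_equal(solo$label, c("a", "b", "c"))
  expect_error(assign_reference_labels(list(tRef), "missing", c("a", "b", "c")),
               "not present")
})

test_that("concordance summary ranges and exclusions behave as tabulated", {
  set.seed(5)
  shared <- matrix(rnorm(1500), 500, 3,
                   dimnames = list(paste0("g", 1:500), NULL))
  noisy <- function(name, sd = 0.4)
    fake_tscores(shared + rnorm(1500, sd = sd), name)
  # one deliberately decorrelated study with independent signatures
  indep <- fake_tscores(matrix(rnorm(1500), 500, 3,
                               dimnames = list(paste0("g", 1:500), NULL)),
                        "indep")
  conc <- concordance(list(noisy("A"), noisy("B"), noisy("C"), indep))
  expect_s3_class(conc, "concordance_result")
  for (p in conc$pairs) {
    expect_true(all(p$corr >= -1 & p$corr <= 1))
    expect_equal(sort(p$matching), 1:3)
    expect_equal(p$matched_correlations, p$corr[cbind(1:3, p$matching)])
  }
  expect_equal(flag_nonconcordant(conc, threshold = 0.3), "indep")

  summ <- concordance_summary(conc, exclude = "indep")
  retained <- summ[summ$block == "retained", ]
  expect_equal(nrow(retained), 3L)
  expect_true(all(retained$min > 0.6))
  expect_true(all(retained$n_pairs == 3L))       # 3 retained pairs
  excl <- summ[summ$block == "indep", ]
  expect_true(all(excl$n_pairs == 3L))           # indep vs each retained
  expect_true(min(excl$min) < 0.3)               # straddles low values

  # singleton range: two studies only
  conc2 <- concordance(list(noisy("A"), noisy("B")))
  s2 <- concordance_summary(conc2)
  expect_equal(s2$min, s2$max)
})

test_that("cross-tabulation against original labels counts correctly", {
  sim <- small_sim()
  ds <- sim$datasets[[1L]]
  truth <- sim$truth$labels[[1L]]
  a <- kmeans_partition(ds, genes(ds), 3L, n_init = 5L, seed = 6L)
  tab <- crosstab_assignments(a, truth)
  expect_equal(sum(tab), ncol(ds$values))
  # diagonal fraction after optimal row/col matching equals accuracy
  acc <- max(vapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                         c(3, 1, 2), c(3, 2, 1)), function(p)
    sum(tab[cbind(1:3, p)]), numeric(1L))) / sum(tab)
  expect_gte(acc, 0.9)

  # identity case: assignments equal to original labels give a diagonal table
  lab_named <- setNames(paste0("subtype", a$labels), names(a$labels))
  tab_id <- crosstab_assignments(a, lab_named)
  expect_equal(sum(diag(tab_id)), sum(tab_id))

  # all samples unlabeled
  tab_na <- crosstab_assignments(a, setNames(rep(NA_character_,
                                                 length(a$labels)),
                                             names(a$labels)))
  expect_equal(colnames(tab_na), "NC/NA")
  expect_equal(sum(tab_na), length(a$labels))
})
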