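test_that("replicate means collapse tracks to one value per replicate", {
  d <- tibble::tibble(
    g = "a", rep = c(1, 1, 1, 2, 2), v = c(1, 2, 3, 4, 6)
  )
  rm <- replicate_means(d, v, g, rep)
  expect_equal(rm$mean, c(2.0, 5.0))
  # 162 tracks over 6 replicates enter the test as exactly 6 values
  d2 <- tibble::tibble(
    g = "dynein",
    rep = rep(1:6, length.out = 162),
    v = rnorm(162, 1.76, 0.3)
  )
  expect_equal(nrow(replicate_means(d2, v, g, rep)), 6)
  single <- replicate_means(
    tibble::tibble(g = "a", rep = 1, v = 7), v, g, rep
  )
  expect_equal(single$mean, 7)
})

test_that("identical groups give a null result near 1", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 3), v = rep(1:3, 2))
  res <- omnibus_test(d, v, g)
  expect_gte(res$p_value, 0.99)
})

test_that("rank-branch omnibus statistic equals longhand rank arithmetic", {
  groups <- list(
    a = c(0.1, 0.2, 0.3, 8), b = c(0.2, 0.4, 0.5, 12), c = c(3, 5, 6, 40)
  )
  d <- tibble::tibble(
    g = rep(names(groups), lengths(groups)), v = unlist(groups)
  )
  res <- omnibus_test(d, v, g)
  expect_equal(res$branch, "rank")
  expect_equal(res$test, "kruskal-wallis")
  expect_equal(res$statistic, manual_kruskal_h(groups), tolerance = 1e-10)
  # toy groups from first principles as well
  toy <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(10, 11, 12))
  dt <- tibble::tibble(g = rep(names(toy), each = 3), v = unlist(toy))
  expect_equal(
    unname(stats::kruskal.test(dt$v, factor(dt$g))$statistic),
    manual_kruskal_h(toy),
    tolerance = 1e-10
  )
})

test_that("Dunn z statistics match manual computation on 3x3 data", {
  groups <- list(a = c(1, 2, 3), b = c(2.5, 3.5, 4.5), c = c(10, 11, 12))
  d <- tibble::tibble(
    g = rep(names(groups), each = 3), v = unlist(groups)
  )
  dz <- dunn_posthoc(d, v, g, adjustment = "none")
  oracle <- manual_dunn(groups)
  expect_equal(dz$statistic, oracle$z, tolerance = 1e-10)
  expect_equal(dz$p_value, 2 * pnorm(-abs(oracle$z)), tolerance = 1e-10)

  same <- tibble::tibble(g = rep(c("a", "b", "c"), each = 3), v = rep(1:3, 3))
  expect_true(all(dunn_posthoc(same, v, g)$p_value > 0.9))
})

test_that("Holm adjustment is monotone above raw p values", {
  set.seed(2)
  d <- tibble::tibble(
    g = rep(letters[1:4], each = 5), v = rnorm(20) + rep(c(0, 0, 1, 3), each = 5)
  )
  raw <- dunn_posthoc(d, v, g, adjustment = "none")
  holm <- dunn_posthoc(d, v, g, adjustment = "holm")
  expect_true(all(holm$p_adjusted >= raw$p_value - 1e-12))
  expect_true(all(holm$p_adjusted >= holm$p_value - 1e-12))
  expect_true(all(holm$p_adjusted <= 1) && all(holm$p_adjusted >= 0))
})

test_that("normal data take the parametric branch with Tukey pairs", {
  base <- qnorm(ppoints(8)) # perfectly normal-scoring within-group shape
  d <- tibble::tibble(
    g = rep(c("a", "b", "c"), each = 8),
    v = c(base, base + 0.5, base + 3)
  )
  res <- omnibus_test(d, v, g)
  expect_equal(res$branch, "parametric")
  expect_equal(res$test, "anova")
  expect_equal(nrow(res$pairwise), 3)
  ref <- summary(aov(v ~ g, data = d))[[1]]
  expect_equal(res$statistic, ref[1, "F value"], tolerance = 1e-10)
})

test_that("group relabeling permutes the pairwise table consistently", {
  set.seed(6)
  d <- tibble::tibble(
    g = rep(c("a", "b", "c"), each = 6), v = rnorm(18, rep(c(0, 1, 5), each = 6))
  )
  res1 <- omnibus_test(d, v, g)
  relabel <- c(a = "z", b = "a", c = "b")
  d2 <- dplyr::mutate(d, g = unname(relabel[g]))
  res2 <- omnibus_test(d2, v, g)
  expect_equal(res1$p_value, res2$p_value)
  key1 <- with(
    res1$pairwise,
    paste(pmin(relabel[group1], relabel[group2]),
          pmax(relabel[group1], relabel[group2]))
  )
  key2 <- with(res2$pairwise, paste(pmin(group1, group2), pmax(group1, group2)))
  expect_setequal(key1, key2)
})

test_that("constant data reports a degenerate-variance status, not an error", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 4), v = 1)
  res <- omnibus_test(d, v, g)
  expect_equal(res$status, "degenerate-variance")
})

test_that("the replicate-mean pathway feeds the omnibus test", {
  set.seed(8)
  d <- tibble::tibble(
    g = rep(c("a", "b", "c"), each = 30),
    rep = rep(rep(1:5, each = 6), 3),
    v = rnorm(90, rep(c(1, 1.2, 3), each = 30), 0.4)
  )
  res <- omnibus_test(d, v, g, rep)
  expect_equal(nrow(res$data), 15) # 3 groups x 5 replicate means
  expect_s3_class(res$pairwise, "tbl_df")
})
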