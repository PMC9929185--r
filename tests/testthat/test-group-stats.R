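test_that("group summaries report median, mean and sample SD", {
  df <- data.frame(condition = "a", pcc = c(1, 2, 3))
  s <- summarizeGroups(df)
  expect_equal(s$median, 2)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$n, 3L)

  one <- summarizeGroups(data.frame(condition = "a", pcc = 0.5))
  expect_true(is.na(one$sd))

  two <- summarizeGroups(data.frame(condition = rep(c("a", "b"), each = 3),
                                    pcc = rep(c(1, 2, 3), 2)))
  expect_equal(two$median[1], two$median[2])
  expect_equal(two$sd[1], two$sd[2])

  withNA <- summarizeGroups(data.frame(condition = "a",
                                       pcc = c(1, NA, 3)))
  expect_equal(withNA$n, 2L)
  expect_equal(withNA$nExcluded, 1L)

  expect_error(summarizeGroups(df, statistic = "nope"),
               class = "SynapseColoc_invalidParameter")
})

test_that("two-group comparisons behave like a rank-sum test should", {
  expect_equal(as.numeric(compareTwo(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_lt(compareTwo(1:10, 101:110), 0.01)
  expect_identical(as.numeric(compareTwo(1:8, c(4:9, 30, 40))),
                   as.numeric(compareTwo(c(4:9, 30, 40), 1:8)))
  expect_warning(p <- compareTwo(c(5, 5, 5), c(5, 5, 5)),
                 class = "SynapseColoc_degenerateData")
  expect_equal(as.numeric(p), 1)
  expect_error(compareTwo(1:2, 1:5),
               class = "SynapseColoc_invalidParameter")
})

test_that("omnibus and post-hoc tests resolve which groups differ", {
  expect_warning(res0 <- compareMany(list(a = rep(1, 5), b = rep(1, 5),
                                          c = rep(1, 5))),
                 class = "SynapseColoc_degenerateData")
  expect_equal(res0$omnibusP, 1)

  withr::local_seed(10)
  g <- list(a = rnorm(15), b = rnorm(15), c = rnorm(15, 10))
  res <- compareMany(g)
  expect_lt(res$omnibusP, 0.01)
  pw <- res$pairwise
  key <- paste(pw$group1, pw$group2)
  expect_lt(pw$pAdj[key == "a c"], 0.05)
  expect_lt(pw$pAdj[key == "b c"], 0.05)
  expect_gt(pw$pAdj[key == "a b"], 0.05)

  expect_error(compareMany(list(a = 1:5, b = 1:5)),
               class = "SynapseColoc_invalidParameter")
  expect_error(compareMany(list(a = 1:5, b = 1:5, c = 1:2)),
               class = "SynapseColoc_invalidParameter")
})

test_that("the post-hoc z statistics match a hand-worked example", {
  # groups (1,2,3), (4,5,6), (7,8,9): pooled ranks 1..9, mean ranks 2, 5, 8;
  # sigma = sqrt(N(N+1)/12 * (1/3 + 1/3)) = sqrt(5); z_ac = -6 / sqrt(5)
  res <- compareMany(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
  pw <- res$pairwise
  zac <- pw$z[pw$group1 == "a" & pw$group2 == "c"]
  expect_equal(zac, -6 / sqrt(5), tolerance = 1e-12)
  expect_equal(pw$p[pw$group1 == "a" & pw$group2 == "c"],
               2 * pnorm(-6 / sqrt(5)), tolerance = 1e-12)
  expect_equal(pw$pAdj, pmin(1, pw$p * 3), tolerance = 1e-12)
})

test_that("plate-assay viability and cytotoxicity follow the OD formula", {
  r <- cytotoxicityFromOD(0.8, 0.2, 1.2, 0.2)
  expect_equal(r$viability, 60)
  expect_equal(r$cytotoxicity, 40)
  expect_false(r$clamped)

  full <- cytotoxicityFromOD(1.2, 0.2, 1.2, 0.2)
  expect_equal(full$viability, 100)
  expect_equal(full$cytotoxicity, 0)

  none <- cytotoxicityFromOD(0.3, 0.3, 1.2, 0.2)
  expect_equal(none$viability, 0)
  expect_equal(none$cytotoxicity, 100)

  over <- cytotoxicityFromOD(2.0, 0.1, 1.2, 0.2)
  expect_true(over$clamped)
  expect_equal(over$viability, 100)
  expect_equal(attr(over, "viabilityRaw") + attr(over, "cytotoxicityRaw"),
               100)

  expect_error(cytotoxicityFromOD(0.8, 0.2, 0.2, 0.2),
               class = "SynapseColoc_invalidParameter")
})
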