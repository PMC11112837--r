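test_that("contingency tables cross-tabulate grades correctly", {
  t2 <- contingency_table(c(0L, 0L, 1L), c(0L, 1L, 1L), k = 2L)
  expect_equal(unclass(t2)[1:2, 1:2],
               matrix(c(1L, 0L, 1L, 1L), 2, 2), ignore_attr = TRUE)

  g <- filter_gradable(oslo_fixture())
  t4 <- contingency_table(g$manual_grade, g$ai_grade)
  expect_equal(sum(t4), 64L)
  expect_equal(unname(diag(unclass(t4))), c(52L, 2L, 5L, 3L))
  off <- unclass(t4); diag(off) <- 0L
  expect_equal(sum(off), 2L)
  expect_equal(off[3, 2], 2L)  # manual moderate, AI mild

  # a vector against itself is purely diagonal
  v <- c(0L, 1L, 2L, 3L, 2L, 1L)
  ts <- contingency_table(v, v)
  expect_equal(sum(unclass(ts)) - sum(diag(unclass(ts))), 0L)

  expect_error(contingency_table(0:2, 0:1), "equal length")
  expect_error(contingency_table(c(0L, 4L), c(0L, 1L), k = 4L), "0..3")
  expect_error(contingency_table(c(0L, NA), c(0L, 1L)), "filter_gradable")
})

test_that("Cohen's kappa matches hand-derived values on small tables", {
  expect_equal(cohen_kappa(matrix(c(5, 0, 0, 5), 2))$kappa, 1.0)
  # Po = 0.9, Pe = 0.5 -> kappa = 0.8
  expect_equal(cohen_kappa(matrix(c(45, 5, 5, 45), 2))$kappa, 0.8)
  # perfect binary any-DR agreement in the fixture
  g <- filter_gradable(oslo_fixture())
  tb <- contingency_table(as.integer(g$manual_grade >= 1),
                          as.integer(g$ai_grade >= 1), k = 2L)
  expect_equal(cohen_kappa(tb)$kappa, 1.0)
  # degenerate table: all mass on one category pair
  expect_error(cohen_kappa(matrix(c(0, 0, 0, 5), 2)), "undefined")
})

test_that("weighted kappa reproduces the published 4-level agreement", {
  g <- filter_gradable(oslo_fixture())
  t4 <- contingency_table(g$manual_grade, g$ai_grade)
  wk <- weighted_kappa(t4, "linear")
  expect_equal(round(wk$kappa, 2), 0.95)
  expect_equal(wk$band, "very good")
  expect_lt(wk$p_value, 0.001)
  # any diagonal table has perfect weighted agreement under any scheme
  d <- diag(c(3, 1, 4, 1))
  for (s in c("identity", "linear", "quadratic"))
    expect_equal(weighted_kappa(d, s)$kappa, 1.0)
})

test_that("kappa properties hold over random tables", {
  set.seed(20260923)
  for (rep in 1:50) {
    m <- random_table()
    wl <- weighted_kappa(m, "linear")
    expect_gte(wl$kappa, -1); expect_lte(wl$kappa, 1)
    expect_equal(wl$kappa, (wl$po - wl$pe) / (1 - wl$pe))
    # identity-weight equivalence
    expect_equal(weighted_kappa(m, "identity")$kappa, cohen_kappa(m)$kappa,
                 tolerance = 1e-12)
    # brute-force double-loop oracle
    w <- kappa_weights("linear", k = 4L)
    expect_equal(wl$kappa, brute_kappa(m, w), tolerance = 1e-12)
    # invariance under simultaneous row/column permutation with permuted weights
    perm <- sample(4L)
    expect_equal(weighted_kappa(m[perm, perm],
                                kappa_weights("custom", 4L, w[perm, perm]))$kappa,
                 wl$kappa, tolerance = 1e-12)
    # scale invariance: counts are proportions in disguise
    expect_equal(weighted_kappa(m * 7L, "linear")$kappa, wl$kappa,
                 tolerance = 1e-12)
  }
})

test_that("2x2 kappa agrees with direct enumeration of (Po-Pe)/(1-Pe)", {
  set.seed(5)
  for (rep in 1:25) {
    m <- matrix(sample(0:30, 4, TRUE), 2)
    if (sum(m) == 0) next
    n <- sum(m)
    po <- (m[1, 1] + m[2, 2]) / n
    pe <- (sum(m[1, ]) * sum(m[, 1]) + sum(m[2, ]) * sum(m[, 2])) / n^2
    if (pe > 0.999) next
    expect_equal(cohen_kappa(m)$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
  }
})

test_that("rank correlation matches a brute-force average-rank oracle", {
  expect_equal(spearman_rho(c(0, 1, 2, 3, 1), c(0, 1, 2, 3, 1))$rho, 1.0)
  expect_equal(spearman_rho(0:4, 4:0)$rho, -1.0)
  g <- filter_gradable(oslo_fixture())
  sp <- spearman_rho(g$manual_grade, g$ai_grade)
  expect_gt(sp$rho, 0.9); expect_lte(sp$rho, 1.0)
  expect_equal(sp$rho, brute_spearman(g$manual_grade, g$ai_grade),
               tolerance = 1e-10)
  expect_lt(sp$p_value, 0.001)
  expect_error(spearman_rho(c(1, 1, 1), c(0, 1, 2)), "zero variance")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
})

test_that("Landis-Koch bands use upper-inclusive printed ranges", {
  expect_equal(landis_koch_band(0.95), "very good")
  expect_equal(landis_koch_band(0.20), "poor")
  expect_equal(landis_koch_band(0.61), "good")
  expect_equal(landis_koch_band(c(0.40, 0.60, 0.80, 0.81)),
               c("fair", "moderate", "good", "very good"))
  expect_equal(landis_koch_band(-1), "poor")
  expect_error(landis_koch_band(1.5), "\\[-1, 1\\]")
})

test_that("agreement results serialize to the documented JSON shape", {
  wk <- weighted_kappa(matrix(c(45, 5, 5, 45), 2), "identity")
  parsed <- jsonlite::fromJSON(agreement_json(wk, statistic = "cohen_kappa"))
  expect_equal(parsed$kappa, 0.8)
  expect_named(parsed, c("statistic", "scheme", "kappa", "po", "pe", "se",
                         "p_value", "band", "n"))
})
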