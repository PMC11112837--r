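bs <- baseline_strategies()

test_that("one-way sweeps over the AI fee reproduce closed-form differences", {
  grid <- parameter_grid("ai", "screening_cost", c(33, 64, 113, 164))
  sw <- one_way_sweep(bs$manual, bs$ai, grid)
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 4L)
  expect_equal(sw$total_a, rep(273, 4))
  expect_equal(sw$difference, c(143, 112, 63, 12))  # 273 - (v + 73 + 24)

  single <- one_way_sweep(bs$manual, bs$ai,
                          parameter_grid("ai", "screening_cost", 33))
  expect_equal(single$difference, 143)

  const <- one_way_sweep(bs$manual, bs$ai,
                         parameter_grid("ai", "screening_cost", rep(50, 5)))
  expect_equal(length(unique(const$difference)), 1L)
  # bases never mutated
  expect_equal(bs$ai$screening_cost, 33)
})

test_that("sweep differences are affine in the swept parameter", {
  for (par in c("screening_cost", "patient_time_hours", "time_cost_per_hour")) {
    sw <- one_way_sweep(bs$manual, bs$ai,
                        grid_seq("ai", par, 0, 10, steps = 9L))
    expect_lt(max(abs(diff(diff(sw$difference)))), 1e-9)
    sw2 <- one_way_sweep(bs$manual, bs$ai,
                         grid_seq("manual", par, 0, 10, steps = 9L))
    expect_lt(max(abs(diff(diff(sw2$difference)))), 1e-9)
  }
})

test_that("two-way sweeps evaluate the full cartesian product", {
  g1 <- parameter_grid("manual", "patient_time_hours", c(0.5, 1, 1.5, 2))
  g2 <- parameter_grid("ai", "screening_cost", c(33, 164))
  sw <- two_way_sweep(bs$manual, bs$ai, g1, g2)
  expect_equal(dim(sw$difference), c(4L, 2L))
  expect_equal(sw$difference[3, 1], 143)       # baseline cell (1.5 h, $33)
  expect_equal(sw$difference[1, 2], -12)       # (0.5 h, $164): 249 - 261
  # restricting one axis reproduces the one-way sweep
  ai164 <- bs$ai; ai164$screening_cost <- 164
  expect_equal(unname(sw$difference[, 2]),
               one_way_sweep(bs$manual, ai164, g1)$difference)

  one <- two_way_sweep(bs$manual, bs$ai,
                       parameter_grid("manual", "patient_time_hours", 1.5),
                       parameter_grid("ai", "screening_cost", 33))
  expect_equal(as.numeric(one$difference), cost_difference(bs$manual, bs$ai))
  expect_error(two_way_sweep(bs$manual, bs$ai, g2, g2), "distinct")
})

test_that("break-even values solve the affine cost model in closed form", {
  expect_equal(break_even(bs$manual, bs$ai, "ai", "screening_cost", c(0, 500)),
               176)  # 164 + (1.5 - 1) * 24
  ai164 <- bs$ai; ai164$screening_cost <- 164
  expect_equal(break_even(bs$manual, ai164, "ai", "patient_time_hours",
                          c(0, 5)), 1.5)
  # no root in the bracket for a constant nonzero difference
  expect_true(is.na(break_even(bs$manual, bs$ai, "manual",
                               "transport_cost_round_trip", c(0, 10))))
  expect_error(break_even(bs$manual, bs$ai, "ai", "screening_cost", c(5, 5)),
               "bracket")
})

test_that("closed-form break-even agrees with bisection on random instances", {
  set.seed(71)
  for (rep in 1:20) {
    a <- screening_strategy("a", runif(1, 50, 300), runif(1, 0, 100),
                            runif(1, 0.5, 3), runif(1, 10, 50))
    b <- screening_strategy("b", runif(1, 0, 100), runif(1, 0, 100),
                            runif(1, 0.2, 2), runif(1, 10, 50))
    cf <- break_even(a, b, "b", "screening_cost", c(0, 1000))
    bi <- break_even(a, b, "b", "screening_cost", c(0, 1000),
                     method = "bisection")
    expect_false(is.na(cf))
    expect_equal(cf, bi, tolerance = 1e-6)
    # the sign of the difference flips across the root
    g <- parameter_grid("b", "screening_cost", c(cf - 1, cf + 1))
    d <- one_way_sweep(a, b, g)$difference
    expect_lt(d[1] * d[2], 0)
  }
})

test_that("sweep results export to long-format CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  sw <- one_way_sweep(bs$manual, bs$ai,
                      parameter_grid("ai", "screening_cost", c(33, 64)))
  write_sweep_csv(sw, path)
  back <- utils::read.csv(path)
  expect_equal(back$ai.screening_cost, c(33, 64))
  expect_equal(back$difference, c(143, 112))

  sw2 <- two_way_sweep(bs$manual, bs$ai,
                       parameter_grid("manual", "patient_time_hours", c(0.5, 1.5)),
                       parameter_grid("ai", "screening_cost", c(33, 164)))
  write_sweep_csv(sw2, path)
  back2 <- utils::read.csv(path)
  expect_equal(nrow(back2), 4L)
  expect_equal(back2$difference[back2$manual.patient_time_hours == 1.5 &
                                  back2$ai.screening_cost == 33], 143)
})

test_that("unknown sweep targets are rejected", {
  expect_error(parameter_grid("ai", "no_such_parameter", 1), "unknown parameter")
  expect_error(one_way_sweep(bs$manual, bs$ai,
                             parameter_grid("other", "screening_cost", 1)),
               "matches neither")
})
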