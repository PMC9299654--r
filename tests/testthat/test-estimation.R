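test_that("gradient regression recovers the analytic gradients", {
  st <- population_state(0, 10, 4)
  tab <- make_contest_table(5e4, st, base_params(), weak_honesty_G(), seed = 201)
  td <- tidy(estimate_gradients(tab))
  truth <- selection_gradients(base_params(), st)
  expected <- c(betaNS = truth$betaN[["S"]], betaNB = 0,
                betaNA = truth$betaN[["A"]], betaSS = 0,
                betaSB = truth$betaS[["B"]], betaSA = truth$betaS[["A"]])
  for (term in names(expected)) {
    row <- td[td$term == term, ]
    expect_lt(abs(row$estimate - expected[[term]]), 3 * row$std.error)
  }
  # betaSB specifically targets -cB * meanA = -0.8
  expect_lt(abs(td$estimate[td$term == "betaSB"] + 0.8),
            3 * td$std.error[td$term == "betaSB"])
  gl <- glance(estimate_gradients(tab))
  expect_equal(gl$nobs, 5e4)
  expect_gt(gl$r.squared, 0)
  expect_lt(gl$condition_number, 100)
})

test_that("with all costs and benefits zero every gradient vanishes", {
  p0 <- contest_params(bA = 0, cA = 0, cB = 0, cS = 0, deltaAS = 0.4, w0 = 1)
  tab <- make_contest_table(2e4, origin_state(), p0, weak_honesty_G(), seed = 202,
                            calibrate = FALSE)
  td <- tidy(estimate_gradients(tab))
  expect_true(all(abs(td$estimate) < 3 * td$std.error))
})

test_that("betaNB and betaSS are zero within error for any parameterisation", {
  set.seed(203)
  for (i in 1:3) {
    p <- random_params()
    st <- population_state(runif(1, -2, 2), runif(1, -2, 2),
                           aggression_equilibrium(p))
    tab <- make_contest_table(2e4, st, p, weak_honesty_G(), seed = 300 + i)
    td <- tidy(estimate_gradients(tab))
    for (term in c("betaNB", "betaSS")) {
      row <- td[td$term == term, ]
      expect_lt(abs(row$estimate), 3 * row$std.error)
    }
  }
})

test_that("estimator error shrinks as the sample grows", {
  st <- population_state(0, 10, 4)
  err <- purrr::map_dbl(c(1e3, 1e4, 1e5), function(n) {
    tab <- make_contest_table(n, st, base_params(), weak_honesty_G(), seed = 204)
    td <- tidy(estimate_gradients(tab))
    se <- td$std.error[td$term == "betaSB"]
    expect_lt(abs(td$estimate[td$term == "betaSB"] + 0.8), 4 * se)
    se
  })
  expect_true(all(diff(err) < 0))
})

test_that("responsiveness is recovered at both reference strengths", {
  for (d in c(0.4, 0.8)) {
    tab <- make_contest_table(1e4, origin_state(), base_params(deltaAS = d),
                              weak_honesty_G(), seed = 205)
    td <- tidy(estimate_responsiveness(tab))
    expect_lt(abs(td$estimate - d), 3 * td$std.error)
  }
})

test_that("cost coefficients invert from gradients at known states", {
  p <- base_params()
  # cB from betaSB at meanA = 4
  st1 <- population_state(0, 10, 4)
  fit1 <- estimate_gradients(make_contest_table(5e4, st1, p, weak_honesty_G(),
                                                seed = 206))
  rc1 <- recover_costs(fit1, st1)
  row <- rc1[rc1$term == "cB", ]
  expect_lt(abs(row$estimate - 0.2), 3 * row$std.error)

  # cS from betaNS with the mean signal displaced one unit above the optimum
  st2 <- population_state(1, 0, 4)
  fit2 <- estimate_gradients(make_contest_table(5e4, st2, p, weak_honesty_G(),
                                                seed = 207))
  rc2 <- recover_costs(fit2, st2)
  row <- rc2[rc2$term == "cS", ]
  expect_lt(abs(row$estimate - 0.05), 3 * row$std.error)

  # bA and cA from betaNA at two distinct aggression means
  st3 <- population_state(0, 0, 2)
  fit3 <- estimate_gradients(make_contest_table(5e4, st3, p, weak_honesty_G(),
                                                seed = 208))
  rc3 <- recover_costs(fit1, st1, fit2 = fit3, state2 = st3)
  expect_lt(abs(rc3$estimate[rc3$term == "bA"] - 0.2),
            3 * rc3$std.error[rc3$term == "bA"])
  expect_lt(abs(rc3$estimate[rc3$term == "cA"] - 0.05),
            3 * rc3$std.error[rc3$term == "cA"])
})

test_that("degenerate estimation inputs fail loudly", {
  p <- base_params()
  small <- make_contest_table(40, origin_state(), p, weak_honesty_G(), seed = 209)
  expect_error(estimate_gradients(small), "50")
  expect_error(estimate_responsiveness(small), "50")

  # no signal variance: responsiveness unidentifiable
  G0 <- genetic_architecture(GSS = 0, GBB = 1, GAA = 1, GSB = 0, ESS = 0)
  tab0 <- make_contest_table(200, origin_state(), p, G0, seed = 210)
  expect_error(estimate_responsiveness(tab0), "variance")

  # aggression with no intrinsic variance is collinear with the signals
  Gc <- genetic_architecture(GSS = 1, GBB = 1, GAA = 0, GSB = 0, EAA = 0)
  tabc <- make_contest_table(500, origin_state(), p, Gc, seed = 211)
  expect_error(estimate_gradients(tabc), "collinear")

  # cost inversion at a zero mean is refused with advice
  st0 <- origin_state()
  fit <- estimate_gradients(make_contest_table(200, population_state(0, 0, 4),
                                               p, weak_honesty_G(), seed = 212))
  expect_error(recover_costs(fit, st0), "nonzero mean aggression")
  expect_error(recover_costs(fit, population_state(0, 0, 4), fit2 = fit,
                             state2 = population_state(5, 5, 4)),
               "distinct mean aggression")
})

test_that("estimation results serialise to JSON", {
  tab <- make_contest_table(500, origin_state(), base_params(), weak_honesty_G(),
                            seed = 213)
  path <- withr::local_tempfile(fileext = ".json")
  write_estimation(estimate_gradients(tab), path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_setequal(back$coefficients$term,
                  c("betaNS", "betaNB", "betaNA", "betaSS", "betaSB",
                    "betaSA"))
  expect_true(all(back$coefficients$std.error > 0))
  expect_true(all(is.finite(back$coefficients$estimate)))
})
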