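test_that("benchmark problems evaluate their references correctly", {
  # constant RHS with c = Gamma(beta+1): exact solution u0 + t^beta
  for (beta in c(0.5, 0.8)) {
    bp <- make_benchmark("constant_rhs", c = gamma(beta + 1), beta = beta)
    expect_equal(bp$reference(2), 1 + 2^beta)
  }
  expect_equal(make_benchmark("linear_decay_beta1")$reference(1), exp(-1))
  # Mittag-Leffler reference collapses to the exponential at beta = 1
  cl <- make_benchmark("caputo_linear", beta = 1)
  tt <- c(0.3, 1, 2)
  expect_equal(cl$reference(tt[1]), exp(-tt[1]), tolerance = 1e-12)
  expect_equal(vapply(tt, cl$reference, numeric(1)), exp(-tt),
               tolerance = 1e-12)
  expect_error(make_benchmark("lorenz"))
})

test_that("first-step exactness holds for constant RHS at every order", {
  for (beta in c(0.5, 0.75, 0.9, 1)) {
    for (h in c(0.05, 0.1, 0.2)) {
      bp <- make_benchmark("constant_rhs", c = 2.5, beta = beta, u0 = 0.7)
      for (method in c("fem", "modified")) {
        tr <- solve_crisp(bp$rhs, bp$u0, bp$v0,
                          time_grid(h = h, steps = 1), beta1 = beta,
                          method = method)
        expect_equal(tr$u[2], bp$reference(h), tolerance = 1e-15)
      }
    }
  }
})

test_that("empirical convergence orders at beta = 1 are 1 (FEM) and 2 (modified)", {
  bp <- make_benchmark("linear_decay_beta1")
  h_list <- c(0.1, 0.05, 0.025, 0.0125)
  fem <- convergence_order("fem", problem = bp, h_list = h_list, horizon = 1)
  expect_gt(fem$slope, 0.8); expect_lt(fem$slope, 1.2)
  mod <- convergence_order("modified", "corrected", bp, h_list, horizon = 1)
  expect_gt(mod$slope, 1.8); expect_lt(mod$slope, 2.2)
  # also on the smooth nonlinear benchmark
  lvb <- make_benchmark("lv_beta1")
  h_lv <- c(0.05, 0.025, 0.0125, 0.00625)   # asymptotic regime for the
  fem2 <- convergence_order("fem", problem = lvb, h_list = h_lv,  # fast LV
                            horizon = 1)                          # transient
  expect_gt(fem2$slope, 0.8); expect_lt(fem2$slope, 1.2)
  mod2 <- convergence_order("modified", "corrected", lvb, h_lv,
                            horizon = 1)
  expect_gt(mod2$slope, 1.8); expect_lt(mod2$slope, 2.2)
  # order estimation refuses beta < 1 problems (no trustworthy limit)
  expect_error(convergence_order("fem",
                                 problem = make_benchmark("caputo_linear",
                                                          beta = 0.5),
                                 h_list = h_list),
               "beta = 1")
  expect_error(convergence_order("fem", problem = bp, h_list = c(0.1, 0.05)),
               "3 step sizes")
})

test_that("the modified scheme improves on FEM at beta = 1", {
  # on the fppm presets from the fuzzy cores, terminal error vs a fine-grid
  # reference is strictly smaller for the corrected modified scheme at h=0.1
  for (case in 1:2) {
    rhs <- make_case_rhs(case)
    ref <- solve_crisp(rhs, 1.3, 0.6, time_grid(h = 0.001, horizon = 2),
                       beta1 = 1, method = "modified")
    ref_u <- ref$u[nrow(ref)]
    err <- vapply(c(fem = "fem", modified = "modified"), function(m) {
      tr <- solve_crisp(rhs, 1.3, 0.6, time_grid(h = 0.1, horizon = 2),
                        beta1 = 1, method = m)
      abs(tr$u[nrow(tr)] - ref_u)
    }, numeric(1))
    expect_lt(err[["modified"]], err[["fem"]])
  }
})

test_that("modified beats FEM nodewise on a smooth beta = 1 problem", {
  bp <- make_benchmark("linear_decay_beta1")
  g <- time_grid(h = 0.1, horizon = 2)
  fem <- solve_crisp(bp$rhs, 1, 0, g, beta1 = 1, method = "fem")
  mod <- solve_crisp(bp$rhs, 1, 0, g, beta1 = 1, method = "modified")
  exact <- exp(-g$times)
  beyond <- -1  # drop node 0 where both are exact
  expect_true(all(abs(mod$u - exact)[beyond] <= abs(fem$u - exact)[beyond]))
})

test_that("Lotka-Volterra preset moves in the right direction at t0", {
  # f1(0.25, 0.2) > 0 and f2(0.25, 0.2) < 0: prey rises, predator falls
  tr <- solve_crisp(make_lv_rhs(5, 1, 2), 0.25, 0.2,
                    time_grid(h = 0.1, horizon = 5), beta1 = 1)
  expect_gt(tr$u[2], tr$u[1])
  expect_lt(tr$v[2], tr$v[1])
  expect_true(all(is.finite(tr$u)) && all(is.finite(tr$v)))
})

test_that("compare_methods tabulates envelopes and differences", {
  # constant RHS: the two methods coincide, all difference columns zero
  bp <- make_benchmark("constant_rhs", c = 1.5, beta = 0.8)
  cmp <- compare_methods(bp, beta1 = 0.8, h = 0.1, horizon = 1)
  for (b in c("u_lower", "u_upper", "v_lower", "v_upper")) {
    expect_equal(cmp$table[[paste0(b, "_diff")]],
                 rep(0, nrow(cmp$table)))
  }
  # fuzzy preset comparison: structure of the figure-analogue table
  cf <- suppressWarnings(compare_methods("fppm_case1", r = 0.9,
                                         beta1 = 0.9, h = 0.1, horizon = 1))
  expect_identical(nrow(cf$table), 11L)
  expect_true(all(c("t", "u_lower_fem", "u_lower_mod", "u_lower_diff",
                    "v_upper_fem", "v_upper_mod", "v_upper_diff")
                  %in% names(cf$table)))
  expect_output(print(cf), "Method comparison")
})
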