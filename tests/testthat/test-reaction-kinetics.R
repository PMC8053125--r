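test_that("build_ode applies the mass-action law", {
  f1 <- build_ode(scheme_preset("model1"), c(k1 = 1, k_m1 = 0))
  d <- f1(0, c(R = 1, L = 1, B = 0))
  expect_equal(unname(d["B"]), 1)
  expect_equal(unname(d["R"]), -1)
  expect_equal(unname(d["L"]), -1)

  # all rates zero: quiescent system
  f0 <- build_ode(scheme_preset("model4"),
                  c(k1 = 0, k_m1 = 0, k2 = 0, k_m2 = 0))
  expect_equal(unname(f0(0, c(R = 2, L = 4, I = 1, B = 1))), rep(0, 4))

  # two-step association flux at the mixing state
  fA <- build_ode(scheme_preset("model4"),
                  c(k1 = 10, k_m1 = 1.6, k2 = 4, k_m2 = 2.3))
  d <- fA(0, c(R = 2, L = 4, I = 0, B = 0))
  expect_equal(unname(d["I"]), 80)  # 10 * 2 * 4

  expect_error(build_ode(scheme_preset("model1"), c(k1 = 1)), "k_m1")
  expect_error(build_ode(scheme_preset("model1"), c(k1 = -1, k_m1 = 0)),
               ">= 0")
})

test_that("compiled and R right-hand sides agree", {
  sch <- scheme_preset("model4")
  rates <- c(k1 = 10, k_m1 = 1.6, k2 = 4, k_m2 = 2.3)
  f <- build_ode(sch, rates)
  tg <- seq(0, 1, length.out = 50)
  traj <- simulate_scheme(sch, rates, c(R = 2, L = 8), tg)
  # integrate the same system with the plain-R RHS as an independent path
  sol <- deSolve::lsoda(c(R = 2, L = 8, I = 0, B = 0), tg,
                        function(t, y, p) list(f(t, y)), parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  expect_lt(max(abs(traj$conc - sol[, -1])), 1e-6)
})

test_that("mass is conserved along every preset trajectory", {
  rates <- list(
    model1 = c(k1 = 7.78, k_m1 = 0.33),
    model2 = c(k_pre = 2, k_unpre = 3, k_on = 5, k_off = 0.5),
    model3 = c(k1 = 5, k2 = 8),
    model4 = c(k1 = 10, k_m1 = 1.6, k2 = 4, k_m2 = 2.3),
    model5 = c(k1 = 7.62, k_m1 = 2.9, k2 = 23))
  tg <- c(0, exp(seq(log(1e-3), log(5), length.out = 80)))
  for (id in names(rates)) {
    sch <- scheme_preset(id)
    y0 <- initial_state(sch, rates[[id]], R0 = 2, L0 = 8)
    traj <- simulate_scheme(sch, rates[[id]], y0, tg)
    ct <- conserved_totals(traj)
    expect_lt(max(abs(ct$ligand_total - 8)), 1e-6)
    expect_lt(max(abs(ct$receptor_total - 2)), 1e-6)
  }
})

test_that("simulate matches the pseudo-first-order closed form", {
  tg <- seq(0, 1, length.out = 200)
  sch <- scheme_preset("model1")
  # irreversible limit: R(t) = R0 exp(-k1 L0 t)
  tr <- simulate_scheme(sch, c(k1 = 1, k_m1 = 0), c(R = 0.001, L = 10), tg)
  expect_equal(tr$conc[, "R"], 0.001 * exp(-10 * tg), tolerance = 1e-4)

  # reversible: bound fraction at equilibrium equals L0/(L0 + KD)
  tg2 <- seq(0, 60, length.out = 100)
  tr2 <- simulate_scheme(sch, c(k1 = 7.78, k_m1 = 0.33),
                         c(R = 0.01, L = 4), tg2)
  frac <- tr2$conc[nrow(tr2$conc), "B"] / 0.01
  expect_equal(unname(frac), 4 / (4 + 0.33 / 7.78), tolerance = 1e-4)

  # full transient: discrepancy is dominated by the ligand-depletion error
  # of the closed form, O(R0/L0), and shrinks proportionally with it
  err_at <- function(R0) {
    cf <- closed_form_model1_pfo(7.78, 0.33, L0 = 4, R0 = R0, time_grid = tg)
    tr <- simulate_scheme(sch, c(k1 = 7.78, k_m1 = 0.33),
                          c(R = R0, L = 4), tg)
    max(abs(cf$bound - tr$conc[, "B"])) / R0
  }
  e1 <- err_at(0.04)                     # R0 = 0.01 * L0
  e2 <- err_at(0.004)                    # 10x more ligand excess
  expect_lt(e1, 2.5e-3)
  expect_lt(e2, 0.15 * e1)               # error ~ proportional to R0/L0
})

test_that("closed form reports k_obs = k1*L0 + k-1 and guards its domain", {
  cf <- closed_form_model1_pfo(7.78, 0.33, L0 = 4, R0 = 0.1,
                               time_grid = c(0, 1))
  expect_equal(cf$k_obs, 31.45)
  # complete binding when the off-rate vanishes
  cf0 <- closed_form_model1_pfo(5, 0, L0 = 10, R0 = 0.5, time_grid = c(0, 1))
  expect_equal(cf0$B_eq, 0.5)
  expect_error(closed_form_model1_pfo(0, 0.3, 4, 0.1, c(0, 1)), "k1")
  expect_error(closed_form_model1_pfo(5, 0.3, 1, 0.9, c(0, 1)), "L0 >= 2")
  expect_warning(closed_form_model1_pfo(5, 0.3, 4, 1.5, c(0, 1)), "marginal")
})

test_that("apparent K_D follows equilibrium algebra", {
  expect_equal(apparent_kd(scheme_preset("model1"),
                           c(k1 = 7.78, k_m1 = 0.33)), 0.33 / 7.78)
  # vanishing off-rate: K_D -> 0
  expect_lt(apparent_kd(scheme_preset("model1"),
                        c(k1 = 5.21, k_m1 = 1e-7)), 1e-6)
  expect_equal(apparent_kd(scheme_preset("model4"),
                           c(k1 = 10, k_m1 = 1.6, k2 = 4, k_m2 = 2.3)),
               0.16 * (2.3 / 6.3))
  expect_equal(apparent_kd(scheme_preset("model5"),
                           c(k1 = 7.62, k_m1 = 2.9, k2 = 23)), 0)
  expect_equal(apparent_kd(scheme_preset("model3"), c(k1 = 5, k2 = 8)), 0)
  expect_error(apparent_kd(scheme_preset("model2"),
                           c(k_pre = 1, k_unpre = 1, k_on = 1, k_off = 1)),
               "model2")
})

test_that("model4 satisfies detailed balance at equilibrium", {
  sch <- scheme_preset("model4")
  rates <- c(k1 = 10, k_m1 = 1.6, k2 = 4, k_m2 = 2.3)
  tg <- c(0, exp(seq(log(0.01), log(200), length.out = 120)))
  traj <- simulate_scheme(sch, rates, c(R = 2, L = 4), tg)
  eq <- traj$conc[nrow(traj$conc), ]
  expect_equal(rates[["k1"]] * eq[["R"]] * eq[["L"]] / eq[["I"]],
               rates[["k_m1"]], tolerance = 0.01)
  expect_equal(rates[["k2"]] * eq[["I"]] / eq[["B"]],
               rates[["k_m2"]], tolerance = 0.01)
})

test_that("irreversible locking gives a non-decreasing bound complex", {
  sch <- scheme_preset("model5")
  tg <- c(0, exp(seq(log(1e-3), log(5), length.out = 150)))
  traj <- simulate_scheme(sch, c(k1 = 7.62, k_m1 = 0, k2 = 23),
                          c(R = 2, L = 4), tg)
  expect_true(all(diff(traj$conc[, "B"]) >= -1e-10))
})

test_that("trajectories export as time + species CSV", {
  sch <- scheme_preset("model1")
  traj <- simulate_scheme(sch, c(k1 = 1, k_m1 = 0.1), c(R = 1, L = 2),
                          seq(0, 1, length.out = 20))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  df <- read.csv(path)
  expect_identical(names(df), c("time_s", "R", "L", "B"))
  expect_equal(df$B, unname(traj$conc[, "B"]), tolerance = 1e-10)
  unlink(path)
})

test_that("simulate validates its inputs", {
  sch <- scheme_preset("model1")
  expect_error(simulate_scheme(sch, c(k1 = 1, k_m1 = 0), c(R = 1, L = 1),
                               c(0.5, 1)), "start at 0")
  expect_error(simulate_scheme(sch, c(k1 = 1, k_m1 = 0), c(R = -1, L = 1),
                               c(0, 1)), "non-negative")
  expect_error(simulate_scheme(sch, c(k1 = 1, k_m1 = 0), c(X = 1),
                               c(0, 1)), "unknown")
})
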