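test_that("generation is deterministic given the seed", {
  des <- small_sf_design(n_points = 80L)
  s1 <- gen_stopped_flow("A-model4", design = des,
                         noise = noise_spec("gaussian", sigma = 0.01, seed = 7))
  s2 <- gen_stopped_flow("A-model4", design = des,
                         noise = noise_spec("gaussian", sigma = 0.01, seed = 7))
  expect_identical(s1, s2)
  s3 <- gen_stopped_flow("A-model4", design = des,
                         noise = noise_spec("gaussian", sigma = 0.01, seed = 8))
  expect_false(identical(s1$traces[[1]]$signal, s3$traces[[1]]$signal))

  h1 <- gen_tcspc("CFX", noise = noise_spec("poisson", total_counts = 1e5,
                                            seed = 9))
  h2 <- gen_tcspc("CFX", noise = noise_spec("poisson", total_counts = 1e5,
                                            seed = 9))
  expect_identical(h1$counts, h2$counts)

  # byte-identical on disk
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_trace_csv(s1$traces[[1]], p1)
  write_trace_csv(s2$traces[[1]], p2)
  expect_identical(readLines(p1), readLines(p2))
  unlink(c(p1, p2))
})

test_that("noise-free generation equals the model prediction", {
  ser <- gen_stopped_flow("RS-model5",
                          noise = noise_spec("gaussian", sigma = 0, seed = 1))
  p <- preset_rates("RS-model5")
  for (tr in ser$traces) {
    pred <- predict_signal(p$scheme, p$rates, observable_map(), tr$time_s,
                           tr$ligand_conc_uM, tr$receptor_conc_uM)
    expect_equal(tr$signal, pred, tolerance = 1e-10)
  }
})

test_that("paper-design equilibration times order A < RS < preRS at 2 eq", {
  eq <- vapply(c("A-model4", "RS-model5", "preRS-model5"), function(p) {
    ser <- gen_stopped_flow(p, noise = noise_spec("gaussian", sigma = 0,
                                                  seed = 1))
    equilibration_time(ser$traces[[1]])  # first trace = 4 uM = 2 eq
  }, numeric(1))
  expect_lt(eq[["A-model4"]], eq[["RS-model5"]])
  expect_lt(eq[["RS-model5"]], eq[["preRS-model5"]])
  # the fast binder is visually equilibrated within a few hundred ms
  expect_lt(eq[["A-model4"]], 0.3)
  expect_lt(eq[["preRS-model5"]], 1.0)
})

test_that("TCSPC log-counts decay linearly for a single component", {
  h <- gen_tcspc(data.frame(tau_ns = 2, amplitude_pct = 100),
                 design = tcspc_design(n_channels = 512,
                                       channel_width_ns = 0.02),
                 noise = noise_spec("poisson", total_counts = 5e6, seed = 3))
  t <- h$channel_time_ns
  keep <- h$counts > 100  # Poisson-dominated region
  slope <- coef(lm(log(h$counts[keep]) ~ t[keep]))[2]
  expect_equal(unname(slope), -1 / 2, tolerance = 0.02)
  # empty late channels are legal at low count totals
  hlow <- gen_tcspc(data.frame(tau_ns = 0.5, amplitude_pct = 100),
                    noise = noise_spec("poisson", total_counts = 2e4,
                                       seed = 4))
  expect_true(any(hlow$counts == 0))
  expect_s3_class(hlow, "decay_histogram")
})

test_that("titration generation warns when K_D falls off the grid", {
  expect_warning(gen_titration(list(K_D = 5000, h = 1, B_max = 1),
                               noise = noise_spec("gaussian", sigma = 0,
                                                  seed = 1)),
                 "outside")
  cur <- gen_titration(list(K_D = 13, h = 1, B_max = 1),
                       noise = noise_spec("gaussian", sigma = 0, seed = 1))
  expect_equal(cur$response,
               hill_model(cur$titrant_conc, 13, 1, 1), tolerance = 1e-12)
})

test_that("reported standard errors are calibrated (z-scores over replicates)", {
  z <- vapply(1:200, function(i) {
    cur <- gen_titration(list(K_D = 13, h = 1, B_max = 1),
                         noise = noise_spec("gaussian", sigma = 0.01,
                                            seed = 3000 + i))
    f <- fit_hill(cur)
    (f$K_D - 13) / f$se[["K_D"]]
  }, numeric(1))
  expect_lt(abs(mean(z)), 0.2)
  expect_gt(sd(z), 0.7)
  expect_lt(sd(z), 1.4)
})

test_that("presets carry the published rate and lifetime values", {
  p <- preset_rates("preRS-model4")
  expect_identical(p$scheme$id, "model4")
  expect_equal(unname(p$rates["k2"] / p$rates["k_m2"]), 220)
  expect_error(preset_rates("nope"), "unknown preset")
  expect_identical(nrow(decay_preset("CFX@RS")), 3L)
  expect_error(decay_preset("nope"), "unknown")
  expect_error(noise_spec("gaussian", sigma = 0.01), "seed")
})
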