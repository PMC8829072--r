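test_that("peak_diffuser picks the earliest maximum of S + V", {
  tr <- new_trajectory(data.frame(t = 0:2, I = 0, S = c(0.25, 0.25, 0.25),
                                  V = 0, O = 0, R = 0.75))
  expect_equal(peak_diffuser(tr), c(value = 0.25, time = 0))
  tr2 <- new_trajectory(data.frame(t = 0:2, I = 0, S = c(0, 0.3, 0.1),
                                   V = c(0, 0.2, 0.1), O = 0, R = 0))
  expect_equal(peak_diffuser(tr2), c(value = 0.5, time = 1))
})

test_that("a one-value sweep equals a plain ensemble", {
  spec <- network_spec("ws", n = 150, k = 4, p = 0.2)
  cfg <- abm_config(isvor_params(), t_max = 50)
  sw <- run_sweep(spec, cfg, "mu2", 0.5, reps = 5, seed = 3)
  e <- abm_ensemble(spec, cfg, reps = 5, seed = 3)
  expect_equal(as.data.frame(sw$means[[1]]), as.data.frame(e$mean),
               ignore_attr = TRUE)
  # the summary statistic is the mean of per-replicate peaks
  expect_equal(sw$summary$peak_diffuser, mean(e$summaries$peak_diffuser),
               tolerance = 1e-12)
})

test_that("sweeps validate their inputs", {
  spec <- network_spec("ws", n = 50, k = 4, p = 0.2)
  cfg <- abm_config(isvor_params(), t_max = 10)
  expect_error(run_sweep(spec, cfg, "nonsense", 0.5, reps = 2, seed = 1),
               "unknown sweep parameter")
  expect_error(run_sweep(spec, cfg, "mu2", c(0.1, 1.5), reps = 2, seed = 1),
               "probabilities")
})

test_that("common random numbers couple replicates across grid values", {
  spec <- network_spec("ba", n = 120, m = 3)
  cfg <- abm_config(isvor_params(), t_max = 40)
  sw <- run_sweep(spec, cfg, "mu2", c(0.1, 0.5), reps = 4, seed = 7,
                  keep_long = TRUE)
  # same derived seeds for every grid value
  expect_identical(sw$seeds, isvor:::derive_seeds(7, 4))
  # identical graphs and initial conditions: densities at t = 0 agree
  t0 <- sw$long[sw$long$t == 0, ]
  for (r in unique(t0$rep))
    expect_equal(t0[t0$rep == r & t0$param_value == 0.1, c("I", "S")],
                 t0[t0$rep == r & t0$param_value == 0.5, c("I", "S")],
                 ignore_attr = TRUE)
})

test_that("sweep summaries are recomputable from the stored runs", {
  spec <- network_spec("ws", n = 100, k = 4, p = 0.2)
  cfg <- abm_config(isvor_params(), t_max = 30)
  sw <- run_sweep(spec, cfg, "xi2", c(0.2, 0.6), reps = 3, seed = 5,
                  keep_long = TRUE)
  for (v in sw$grid) {
    rows <- sw$per_rep[sw$per_rep$param_value == v, ]
    for (r in rows$rep) {
      d <- sw$long[sw$long$param_value == v & sw$long$rep == r, ]
      expect_equal(max(d$S + d$V), rows$peak_diffuser[rows$rep == r])
    }
  }
})

test_that("interventions with no effect produce zero deltas", {
  spec <- network_spec("ws", n = 100, k = 4, p = 0.2)
  # identical grid values: the two runs are the same realization
  cfg <- abm_config(isvor_params(), t_max = 30)
  ic <- intervention_comparison(spec, cfg, grid = c(0.3, 0.3), reps = 3,
                                seed = 2, n_boot = 50)
  expect_equal(ic$delta_peak, c(0, 0))
  # no variation is ever created: mu2 and xi2 act on nothing
  cfg0 <- abm_config(rates_only(alpha = 0.5, mu1 = 0.5, xi1 = 0.5,
                                theta = 0.25, beta1 = 0.1), t_max = 30)
  ic0 <- intervention_comparison(spec, cfg0, grid = c(0.1, 0.5), reps = 3,
                                 seed = 2, n_boot = 50)
  expect_equal(ic0$delta_peak, c(0, 0))
})

test_that("figure experiments write their outputs and manifest", {
  out <- withr::local_tempdir()
  man <- reproduce_figure("fig3", out, scale = "ci", seed = 4)
  expect_equal(man$n_nodes, 300L)
  expect_equal(man$reps, 10L)
  for (f in man$files) expect_true(file.exists(file.path(out, f)))
  ws <- utils::read.csv(file.path(out, "fig3_ws.csv"))
  expect_identical(names(ws), c("t", "I", "S", "V", "O", "R"))
  j <- jsonlite::read_json(file.path(out, "fig3_manifest.json"))
  expect_equal(j$params$alpha, 0.5)
  expect_error(reproduce_figure("fig99", out), "arg")
})
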