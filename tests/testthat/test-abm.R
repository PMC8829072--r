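test_that("initialization places the requested spreaders", {
  g <- generate_ws(20, 4, 0.2, seed = 1)
  set.seed(7)
  r <- abm_init(g, abm_config(init_spreaders = 1))
  expect_equal(sum(r == 1L), 1L)
  expect_equal(sum(r == 0L), 19L)
  r2 <- abm_init(g, abm_config(init_nodes = c(0L, 3L)))
  expect_identical(which(r2 == 1L), c(1L, 4L))
  expect_error(abm_init(g, abm_config(init_spreaders = 20)), "< n_nodes")
  set.seed(5); a <- abm_init(g, abm_config(init_spreaders = 3))
  set.seed(5); b <- abm_init(g, abm_config(init_spreaders = 3))
  expect_identical(a, b)
})

test_that("deterministic single-step cases behave as specified", {
  # I-S edge with alpha = 1: infection is certain, the spreader stays
  g <- isvor_graph(2, rbind(c(0, 1)))
  cfg <- abm_config(rates_only(alpha = 1))
  set.seed(1)
  out <- abm_step(g, c(0L, 1L), cfg)
  expect_identical(out$roles, c(1L, 1L))
  expect_equal(out$transitions[["I->S"]], 1L)

  # all-recovered assignment is a fixed point with an empty log
  set.seed(1)
  outR <- abm_step(g, c(4L, 4L), abm_config(isvor_params()))
  expect_identical(outR$roles, c(4L, 4L))
  expect_true(all(outR$transitions == 0L))
})

test_that("isolated-node transition probabilities follow the trial order", {
  one <- isvor_graph(1, NULL)
  # spreader: gamma then xi1 (contact trials vacuous)
  dS <- exact_one_step(one, 1L,
                       abm_config(rates_only(gamma = 0.3, xi1 = 0.5)))
  pS <- setNames(dS$probs, role_labels(dS$assignments[, 1]))
  expect_equal(pS[["V"]], 0.3)
  expect_equal(pS[["O"]], 0.35)
  expect_equal(pS[["S"]], 0.35)
  # oyster: theta, then beta1, then beta2
  dO <- exact_one_step(one, 3L,
                       abm_config(rates_only(theta = 0.25, beta1 = 0.1,
                                             beta2 = 0.1)))
  pO <- setNames(dO$probs, role_labels(dO$assignments[, 1]))
  expect_equal(pO[["R"]], 0.25)
  expect_equal(pO[["S"]], 0.075)
  expect_equal(pO[["V"]], 0.0675)
  expect_equal(pO[["O"]], 0.6075)
})

test_that("exact enumeration is a proper, correct distribution", {
  g <- isvor_graph(2, rbind(c(0, 1)))
  d <- exact_one_step(g, c(0L, 1L), abm_config(rates_only(alpha = 0.5)))
  keys <- apply(d$assignments, 1, paste, collapse = "")
  expect_setequal(keys, c("01", "11"))
  expect_equal(sort(d$probs), c(0.5, 0.5))

  dR <- exact_one_step(g, c(4L, 4L), abm_config(isvor_params()))
  expect_equal(dR$probs, 1)

  # full parameter set on a 3-path: probabilities still sum to one
  p3 <- exact_one_step(path_graph(3), c(0L, 1L, 2L),
                       abm_config(isvor_params(epsilon = 0.2),
                                  include_epsilon = TRUE))
  expect_lt(abs(sum(p3$probs) - 1), 1e-12)
  expect_error(exact_one_step(generate_ws(10, 2, 0), integer(10),
                              abm_config(isvor_params())), "<= 8 nodes")
})

test_that("Monte-Carlo one-step frequencies match the exact oracle", {
  trials <- 20000
  fixtures <- list(
    list(g = isvor_graph(1, NULL), roles = 3L,
         cfg = abm_config(isvor_params())),
    list(g = path_graph(3), roles = c(0L, 1L, 2L),
         cfg = abm_config(isvor_params())),
    # per-contact mode: the center spreader faces two non-ignorant
    # neighbours, so trial counts differ from per-step mode
    list(g = path_graph(3), roles = c(4L, 1L, 2L),
         cfg = abm_config(isvor_params(), contact_mode = "per_contact")))
  for (fx in fixtures) {
    d <- exact_one_step(fx$g, fx$roles, fx$cfg)
    keys <- apply(d$assignments, 1, paste, collapse = "")
    set.seed(99)
    freq <- mc_onestep_freq(fx$g, fx$roles, fx$cfg, trials)
    for (i in seq_along(keys)) {
      p <- d$probs[i]
      se <- sqrt(p * (1 - p) / trials)
      obs <- if (keys[i] %in% names(freq)) freq[[keys[i]]] else 0
      expect_lt(abs(obs - p), 5 * se + 1e-12)
    }
  }
})

test_that("runs conserve counts and respect the absorbing structure", {
  g <- generate_ws(300, 6, 0.2, seed = 3)
  cfg <- abm_config(isvor_params(), t_max = 200)
  run <- abm_run(g, cfg, seed = 11)
  expect_true(all(rowSums(run$counts) == 300L))
  expect_true(all(diff(run$counts[, "R"]) >= 0))
  expect_true(all(diff(run$counts[, "I"]) <= 0))
  # absorbing: after S = V = O = 0, nothing changes (run stops there)
  last <- run$counts[nrow(run$counts), ]
  expect_equal(sum(last[c("S", "V", "O")]), 0L)
  expect_false(is.na(run$absorbed_at))

  # per-step transition flows balance the role-count deltas exactly
  flows <- run$transitions
  deltas <- diff(run$counts)
  from <- substr(colnames(flows), 1, 1)
  to <- substr(colnames(flows), 4, 4)
  for (role in c("I", "S", "V", "O", "R")) {
    net <- as.integer(flows %*% ((to == role) - (from == role)))
    expect_identical(net, unname(deltas[, role]))
  }
})

test_that("no infection path leaves the ignorant untouched", {
  g <- generate_ws(100, 4, 0.2, seed = 2)
  cfg <- abm_config(isvor_params(alpha = 0, lambda = 0), t_max = 300)
  run <- abm_run(g, cfg, seed = 5)
  expect_true(all(run$counts[, "I"] == 99L))
  # the single seeded spreader eventually reaches recovery
  expect_equal(unname(run$counts[nrow(run$counts), "R"]), 1L)
})

test_that("identical graph, config and seed give bit-identical runs", {
  g <- generate_ba(200, 3, seed = 4)
  cfg <- abm_config(isvor_params(), t_max = 80)
  a <- abm_run(g, cfg, seed = 123)
  b <- abm_run(g, cfg, seed = 123)
  expect_identical(a$counts, b$counts)
  expect_identical(a$transitions, b$transitions)
  expect_identical(a$final_roles, b$final_roles)
})

test_that("ensembles average runs and pad absorbed replicates", {
  spec <- network_spec("ws", n = 150, k = 4, p = 0.2)
  cfg <- abm_config(isvor_params(), t_max = 60)
  e1 <- abm_ensemble(spec, cfg, reps = 1, seed = 9)
  seeds <- isvor:::derive_seeds(9, 1)
  g <- graph_from_spec(spec, seeds[1, "graph"])
  single <- abm_run(g, cfg, seed = seeds[1, "run"])
  m <- as.matrix(single$trajectory[, c("I", "S", "V", "O", "R")])
  expect_equal(unname(as.matrix(e1$mean[seq_len(nrow(m)), -1])), unname(m))
  # padded tail equals the absorbing state
  expect_true(all(e1$mean$R[nrow(m):nrow(e1$mean)] == m[nrow(m), "R"]))

  e <- abm_ensemble(spec, cfg, reps = 10, seed = 9)
  expect_equal(e$mean$I + e$mean$S + e$mean$V + e$mean$O + e$mean$R,
               rep(1, nrow(e$mean)), tolerance = 1e-12)
  expect_equal(mean(e$summaries$final_I + e$summaries$final_R), 1,
               tolerance = 1e-12)
})

test_that("stronger infection raises the ensemble diffuser peak", {
  spec <- network_spec("ba", n = 300, m = 5)
  hi <- abm_ensemble(spec, abm_config(isvor_params(alpha = 0.5),
                                      t_max = 60), reps = 10, seed = 13)
  lo <- abm_ensemble(spec, abm_config(isvor_params(alpha = 0.1),
                                      t_max = 60), reps = 10, seed = 13)
  expect_gt(peak_diffuser(hi$mean)[["value"]],
            peak_diffuser(lo$mean)[["value"]])
})

test_that("on a complete graph the ABM tracks the conserving mean field", {
  # per-step contact probabilities scaled by h * k / (n - 1) and
  # spontaneous ones by h, so one ABM step corresponds to ODE time h
  n <- 500L; h <- 0.02; init <- 25L; steps <- 750L; k_ode <- 10
  base <- isvor_params()
  sc <- function(r) r * h * k_ode / (n - 1)
  sp <- function(r) r * h
  p <- isvor_params(alpha = sc(base$alpha), lambda = sc(base$lambda),
                    mu1 = sc(base$mu1), mu2 = sc(base$mu2),
                    eta = sc(base$eta), gamma = sp(base$gamma),
                    xi1 = sp(base$xi1), xi2 = sp(base$xi2),
                    theta = sp(base$theta), beta1 = sp(base$beta1),
                    beta2 = sp(base$beta2))
  g <- complete_graph(n)
  e <- abm_ensemble(g, abm_config(p, init_spreaders = init, t_max = steps,
                                  contact_mode = "per_contact"),
                    reps = 10, seed = 2)
  ode <- isvor_meanfield(base, c(1 - init / n, init / n, 0, 0, 0),
                         t_max = steps * h, variant = "conserving", dt = h)
  sup <- max(abs(as.matrix(e$mean[, 2:6]) - as.matrix(ode[, 2:6])))
  expect_lt(sup, 0.05)
})

test_that("alternative contact semantics are honoured", {
  # lambda as a fraction of infections: V contacts cannot convert I
  gIV <- isvor_graph(2, rbind(c(0, 1)))
  cfg_frac <- abm_config(rates_only(alpha = 0.4, lambda = 0.25),
                         lambda_mode = "fraction_of_infections")
  d <- exact_one_step(gIV, c(0L, 2L), cfg_frac)
  expect_equal(d$probs, 1)               # single outcome: nothing happens
  expect_identical(d$assignments[1, ], c(0L, 2L))
  # under an I-S edge the infection splits alpha*(lambda : 1-lambda)
  dIS <- exact_one_step(gIV, c(0L, 1L), cfg_frac)
  pIS <- setNames(dIS$probs, role_labels(dIS$assignments[, 1]))
  expect_equal(pIS[["S"]], 0.4 * 0.75)
  expect_equal(pIS[["V"]], 0.4 * 0.25)

  # contact-mode forgetting: one theta trial per non-ignorant neighbour
  gO <- path_graph(3)
  cfgc <- abm_config(rates_only(theta = 0.5), theta_mode = "contact")
  dO <- exact_one_step(gO, c(3L, 4L, 4L), cfgc)  # O with one R neighbour
  pO <- dO$probs[apply(dO$assignments, 1, function(r) r[1] == 4L)]
  expect_equal(sum(pO), 0.5)

  # epsilon rule: I-S edge, epsilon tried before alpha
  cfge <- abm_config(rates_only(alpha = 0.5, epsilon = 0.2),
                     include_epsilon = TRUE)
  de <- exact_one_step(gIV, c(0L, 1L), cfge)
  pe <- setNames(de$probs, role_labels(de$assignments[, 1]))
  expect_equal(pe[["R"]], 0.2)
  expect_equal(pe[["S"]], 0.8 * 0.5)
  expect_equal(pe[["I"]], 0.4)
})
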