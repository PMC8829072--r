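test_that("the right-hand side matches hand-evaluated values", {
  p <- isvor_params()
  # all-ignorant state is a rest point of the E1 family
  expect_equal(unname(isvor_rhs(c(1, 0, 0, 0, 0), p)), rep(0, 5))
  # pure-spreader state: dS = -mu1*k - (xi1 + gamma)
  expect_equal(isvor_rhs(c(0, 1, 0, 0, 0), p)[["S"]], -5.8)
  # conservation defect of the printed system at (I=.5, O=.5)
  expect_equal(sum(isvor_rhs(c(.5, 0, 0, .5, 0), p, "as_printed")), 0.0625)
  expect_equal(sum(isvor_rhs(c(.5, 0, 0, .5, 0), p, "conserving")), 0)
  expect_error(isvor_rhs(c(1, 0, 0, 0, 0), p, "bogus"))
})

test_that("printed-system leak equals theta*O*I on the simplex", {
  set.seed(11)
  p <- isvor_params()
  for (i in 1:200) {
    s <- rsimplex()
    expect_lt(abs(sum(isvor_rhs(s, p, "as_printed")) -
                    p$theta * s[4] * s[1]), 1e-12)
    expect_lt(abs(sum(isvor_rhs(s, p, "conserving"))), 1e-12)
  }
})

test_that("every rumor-free state is an equilibrium of both variants", {
  p <- isvor_params()
  for (I1 in seq(0, 1, length.out = 23)) {
    e1 <- c(I1, 0, 0, 0, 1 - I1)
    expect_equal(max(abs(isvor_rhs(e1, p, "as_printed"))), 0)
    expect_equal(max(abs(isvor_rhs(e1, p, "conserving"))), 0)
  }
})

test_that("integration preserves the simplex and reaches the plateau", {
  p <- isvor_params()
  # equilibrium initial condition stays constant
  tr0 <- isvor_meanfield(p, c(1, 0, 0, 0, 0), t_max = 10)
  expect_lt(max(abs(as.matrix(tr0[, -1]) -
                      rep(c(1, 0, 0, 0, 0), each = nrow(tr0)))), 1e-9)
  # epidemic-style initial condition: active compartments die out
  init <- isvor_state(I = 1 - 1 / 2000, S = 1 / 2000)
  tr <- isvor_meanfield(p, init, t_max = 100, variant = "conserving")
  last <- tr[nrow(tr), ]
  expect_lt(last$S + last$V + last$O, 1e-3)
  expect_lt(max(abs(rowSums(tr[, -1]) - 1)), 1e-6)
  expect_gt(min(as.matrix(tr[, -1])), -1e-9)
  # the two variants differ only through theta
  p0 <- isvor_params(theta = 0)
  a <- isvor_meanfield(p0, init, t_max = 20, variant = "as_printed")
  b <- isvor_meanfield(p0, init, t_max = 20, variant = "conserving")
  expect_lt(max(abs(as.matrix(a[, -1]) - as.matrix(b[, -1]))), 1e-7)
})

test_that("fixed-step Euler mirrors the adaptive solution at small dt", {
  p <- isvor_params()
  init <- isvor_state(I = 0.999, S = 0.001)
  a <- isvor_meanfield(p, init, t_max = 10, method = "rk_adaptive", dt = 1)
  e <- isvor_meanfield(p, init, t_max = 10, method = "euler_dt", dt = 0.001)
  at <- as.matrix(a[a$t %in% 0:10, -1])
  et <- as.matrix(e[e$t %in% 0:10, -1])
  expect_lt(max(abs(at - et)), 5e-3)
})

test_that("equilibrium enumeration flags the infeasible families", {
  eq <- isvor_equilibria(isvor_params())
  expect_true(eq$E1$feasible)
  expect_false(eq$E2$feasible)
  expect_false(eq$E3$feasible)
  expect_false(eq$degenerate)
  expect_equal(unname(isvor_rhs(eq$E1$family(0.3), isvor_params())),
               rep(0, 5))
  expect_true(isvor_equilibria(rates_only())$degenerate)
})

test_that("the reduced Jacobian matches its closed-form entries", {
  p <- isvor_params()
  expect_equal(isvor_jacobian(p, 1)[1, 1], p$alpha * p$k - p$xi1 - p$gamma)
  expect_equal(isvor_jacobian(p, 1)[1, 1], 4.2)
  expect_equal(unname(isvor_jacobian(rates_only(), 0.5)),
               matrix(0, 3, 3))
  set.seed(4)
  for (i in 1:20) {
    q <- isvor_params(alpha = runif(1), lambda = runif(1), mu1 = runif(1),
                      mu2 = runif(1), gamma = runif(1), xi1 = runif(1),
                      xi2 = runif(1), theta = runif(1), beta1 = runif(1),
                      beta2 = runif(1))
    expect_identical(isvor_jacobian(q, runif(1))[1, 2], 0)
  }
  expect_error(isvor_jacobian(p, 1.2), "\\[0, 1\\]")
})

test_that("stability report: crossings, verdict, and Hurwitz concordance", {
  p <- isvor_params()
  # U1 = 0 at (mu1 k + xi1 + gamma)/(mu1 k + alpha k) = 0.58
  u1_cross <- uniroot(function(i) stability_report(p, i)$U1, c(0, 1),
                      tol = 1e-12)$root
  expect_equal(u1_cross, 0.58, tolerance = 1e-10)
  # B = 0 at (beta1 + beta2)/theta = 0.8
  b_cross <- uniroot(function(i) stability_report(p, i)$B, c(0, 1),
                     tol = 1e-12)$root
  expect_equal(b_cross, 0.8, tolerance = 1e-10)
  expect_equal(stability_report(p, 0.58)$U1, 0, tolerance = 1e-12)

  # degenerate parameters: all eigenvalues zero, verdict marginal
  expect_identical(stability_report(rates_only(), 0.4)$verdict, "marginal")

  # verdict always matches the sign of the leading eigenvalue real part;
  # Hurwitz discordances are recorded, not hidden
  set.seed(21)
  discordant <- 0L
  for (i in 1:300) {
    q <- isvor_params(alpha = runif(1), lambda = runif(1), mu1 = runif(1),
                      mu2 = runif(1), gamma = runif(1), eta = runif(1),
                      xi1 = runif(1), xi2 = runif(1), theta = runif(1),
                      beta1 = runif(1), beta2 = runif(1))
    rep_ <- stability_report(q, runif(1))
    expect_identical(rep_$verdict == "stable", rep_$max_re < -1e-8)
    if (rep_$hurwitz_stable && !rep_$hurwitz_concordant)
      discordant <- discordant + 1L
  }
  expect_gte(discordant, 0L)
})

test_that("stability interval reports the closed-form candidate bounds", {
  p <- isvor_params()
  si <- stability_interval(p)
  expect_equal(si$candidate_bounds[["u1_zero"]], 0.58, tolerance = 1e-12)
  expect_equal(si$candidate_bounds[["b_zero"]], 0.8, tolerance = 1e-12)
  expect_equal(si$candidate_bounds[["u2_zero"]], 5.5 / 7,
               tolerance = 1e-12)
  # the published second bound differs from the U2 root (xi1+gamma vs xi2)
  expect_equal(si$candidate_bounds[["printed_u2_bound"]], 5.8 / 7,
               tolerance = 1e-12)

  # symmetric rates: the two U-bounds coincide
  q <- isvor_params(mu1 = 0.4, mu2 = 0.4, alpha = 0.3, lambda = 0.3,
                    xi1 = 0.2, gamma = 0.1, xi2 = 0.3)
  sq <- stability_interval(q)
  expect_equal(sq$candidate_bounds[["u1_zero"]],
               sq$candidate_bounds[["u2_zero"]], tolerance = 1e-12)

  # theta = 0: B = -(beta1+beta2) < 0 for all I1; scan still works
  s0 <- stability_interval(isvor_params(theta = 0))
  expect_identical(s0$candidate_bounds[["b_zero"]], Inf)
  expect_true(is.matrix(s0$intervals))

  expect_true(stability_interval(rates_only())$degenerate)

  # boundaries agree with the eigenvalue sign on either side
  if (nrow(si$intervals) > 0) {
    for (r in seq_len(nrow(si$intervals))) {
      lo <- si$intervals[r, 1]; hi <- si$intervals[r, 2]
      mid <- (lo + hi) / 2
      expect_lt(stability_report(p, mid)$max_re, 0)
    }
  }
})

test_that("zeroing the variation/oyster channels reduces to an I/S/R flow", {
  p <- rates_only(alpha = 0.5, mu1 = 0.5)
  init <- c(0.99, 0.01, 0, 0, 0)
  tr <- isvor_meanfield(p, init, t_max = 30, variant = "conserving")
  expect_equal(max(abs(tr$V)), 0)
  expect_equal(max(abs(tr$O)), 0)
  # independently coded 3-compartment reference
  f <- function(t, y, parms) list(isr_rhs(y, 0.5, 0.5, 10))
  ref <- deSolve::ode(c(0.99, 0.01, 0), times = tr$t, func = f,
                      parms = NULL, method = "ode45",
                      rtol = 1e-8, atol = 1e-10)
  expect_lt(max(abs(as.matrix(tr[, c("I", "S", "R")]) - ref[, 2:4])), 1e-6)
})

test_that("epsilon terms enter only on request", {
  p <- isvor_params(epsilon = 0.3)
  s <- c(0.5, 0.3, 0.1, 0.05, 0.05)
  off <- isvor_rhs(s, p)
  on <- isvor_rhs(s, p, include_epsilon = TRUE)
  shift <- p$k * p$epsilon * s[1] * s[2]
  expect_equal(on[["I"]], off[["I"]] - shift)
  expect_equal(on[["R"]], off[["R"]] + shift)
  expect_equal(on[c("S", "V", "O")], off[c("S", "V", "O")])
})
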