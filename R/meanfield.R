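#' Mean-field right-hand side of the ISVOR system
#'
#' Evaluates the time derivative of the five compartment densities under
#' the degree-\code{k} mass-action approximation.  Two variants are
#' provided:
#' \describe{
#'   \item{\code{as_printed}}{the published equation system verbatim.  Its
#'     components do not sum to zero: on the unit simplex the sum equals
#'     \eqn{\theta O I}, because the oyster-forgetting outflow is written
#'     as contact-driven (\eqn{-\theta O (S+V+O+R)}) while the matching
#'     recovery inflow is spontaneous (\eqn{+\theta O}).}
#'   \item{\code{conserving}}{identical except the forgetting outflow is
#'     spontaneous (\eqn{-\theta O}), matching its inflow, so the
#'     components sum to zero identically.  This is the default for
#'     experiments.}
#' }
#' The two variants coincide when \eqn{\theta = 0}.
#'
#' @param state numeric length-5 density vector in order
#'   \code{(I, S, V, O, R)} (see \code{\link{isvor_state}}).
#' @param params an \code{\link{isvor_params}} object.
#' @param variant \code{"conserving"} (default) or \code{"as_printed"}.
#' @param include_epsilon if \code{TRUE}, adds the verbal
#'   ignorant-to-recovered contact rule as \eqn{-k\epsilon I S} in
#'   \eqn{dI/dt} and \eqn{+k\epsilon I S} in \eqn{dR/dt} (absent from the
#'   published equations; off by default).
#' @return numeric length-5 derivative vector named \code{(I, S, V, O, R)}.
#' @examples
#' p <- isvor_params()
#' isvor_rhs(isvor_state(I = 1), p)                 # all-ignorant: rest point
#' isvor_rhs(c(0, 1, 0, 0, 0), p)["S"]             # -mu1*k - (xi1 + gamma)
#' @export
isvor_rhs <- function(state, params, variant = c("conserving", "as_printed"),
                      include_epsilon = FALSE) {
  variant <- match.arg(variant)
  stopifnot(length(state) == 5L)
  I <- state[[1L]]; S <- state[[2L]]; V <- state[[3L]]
  O <- state[[4L]]; R <- state[[5L]]
  p <- params
  k <- p$k
  Q <- S + V + O + R   # all non-ignorant compartments
  dI <- -k * p$alpha * I * S - k * p$lambda * I * V
  dS <- -p$mu1 * k * S * Q - (p$xi1 + p$gamma) * S + p$alpha * k * I * S +
    p$beta1 * O - p$eta * k * S * V
  dV <- -p$mu2 * k * V * Q - p$xi2 * V + p$gamma * S + k * p$lambda * I * V +
    p$eta * k * S * V + p$beta2 * O
  dO <- -(p$beta1 + p$beta2) * O + p$xi1 * S + p$xi2 * V -
    if (variant == "as_printed") p$theta * O * Q else p$theta * O
  dR <- p$theta * O + p$mu1 * k * S * Q + p$mu2 * k * V * Q
  if (include_epsilon) {
    dI <- dI - k * p$epsilon * I * S
    dR <- dR + k * p$epsilon * I * S
  }
  c(I = dI, S = dS, V = dV, O = dO, R = dR)
}

#' Integrate the mean-field ISVOR system
#'
#' Numerically integrates \code{\link{isvor_rhs}} from an initial density
#' state.  The default integrator is adaptive Runge-Kutta
#' (\code{deSolve::ode}, method \code{"ode45"}) with relative/absolute
#' tolerances \code{1e-8}/\code{1e-10}; a fixed-step forward-Euler mode
#' (\code{dt = 1} by default) is provided to mirror the discrete-time
#' probability semantics of the agent-based simulator.
#'
#' @inheritParams isvor_rhs
#' @param init initial state (length-5 density vector summing to 1).
#' @param t_max final time (> 0).
#' @param method \code{"rk_adaptive"} or \code{"euler_dt"}.
#' @param dt output interval (and Euler step for \code{method =
#'   "euler_dt"}).
#' @return an \code{\link{isvor_trajectory}}: a data frame with columns
#'   \code{t, I, S, V, O, R} plus metadata attributes.
#' @examples
#' tr <- isvor_meanfield(isvor_params(), isvor_state(I = 0.9995, S = 5e-4),
#'                       t_max = 30)
#' tail(tr, 1)
#' @export
isvor_meanfield <- function(params, init, t_max,
                            variant = c("conserving", "as_printed"),
                            method = c("rk_adaptive", "euler_dt"),
                            dt = 1, include_epsilon = FALSE) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  stopifnot(is.numeric(t_max), t_max > 0, dt > 0)
  init <- isvor_state(init[[1L]], init[[2L]], init[[3L]], init[[4L]],
                      init[[5L]], tol = 1e-9)
  times <- seq(0, t_max, by = dt)
  if (times[length(times)] < t_max) times <- c(times, t_max)
  if (method == "rk_adaptive") {
    f <- function(t, y, parms)
      list(isvor_rhs(y, params, variant, include_epsilon))
    # the step ceiling keeps the dense-output interpolant from
    # undershooting zero near the absorbing plateau
    sol <- deSolve::ode(y = init, times = times, func = f, parms = NULL,
                        method = "ode45", rtol = 1e-8, atol = 1e-10,
                        hmax = 0.5)
    istate <- attr(sol, "istate")
    if (!is.null(istate) && istate[1L] < 0)
      stop("mean-field integration failed: ",
           paste(utils::capture.output(deSolve::diagnostics(sol)),
                 collapse = "\n"), call. = FALSE)
    out <- as.data.frame(unclass(sol))
    names(out) <- c("t", "I", "S", "V", "O", "R")
  } else {
    y <- init
    out <- matrix(NA_real_, length(times), 6L)
    out[1L, ] <- c(0, y)
    for (i in seq_along(times)[-1L]) {
      h <- times[i] - times[i - 1L]
      y <- y + h * isvor_rhs(y, params, variant, include_epsilon)
      out[i, ] <- c(times[i], y)
    }
    out <- as.data.frame(out)
    names(out) <- c("t", "I", "S", "V", "O", "R")
  }
  if (variant == "conserving") {
    defect <- max(abs(rowSums(out[, 2:6]) - 1))
    if (defect > 1e-6)
      warning("conserving trajectory drifted off the simplex by ",
              format(defect, digits = 3))
  }
  new_trajectory(out, metadata = list(
    kind = "meanfield", variant = variant, method = method, dt = dt,
    include_epsilon = include_epsilon, params = unclass(params)))
}

#' Enumerate equilibrium candidates
#'
#' The mean-field system admits a one-parameter rumor-free family
#' \eqn{E_1 = (I_1, 0, 0, 0, 1 - I_1)}, which is an equilibrium for every
#' \eqn{I_1 \in [0, 1]}.  Candidates with active compartments are
#' infeasible: an \eqn{E_2}-type state (\eqn{I = 0}, some of
#' \eqn{S, V, O > 0}) would require \eqn{\mu_1 k S + \mu_2 k V + \theta O
#' = 0}, forcing the positive components to vanish, and an
#' \eqn{E_3}-type state (all positive) would require
#' \eqn{\alpha k I S + \lambda k I V = 0}, a contradiction.
#'
#' @param params an \code{\link{isvor_params}}.
#' @return a list with elements \code{E1}, \code{E2}, \code{E3}, each a
#'   list with \code{feasible} flag and a \code{reason}; plus
#'   \code{degenerate} (\code{TRUE} when all rates are zero so every state
#'   is an equilibrium).
#' @examples
#' isvor_equilibria(isvor_params())
#' @export
isvor_equilibria <- function(params) {
  p <- params
  rates <- unlist(p[PROB_FIELDS])
  degenerate <- all(rates == 0)
  list(
    E1 = list(feasible = TRUE,
              family = function(I1) c(I = I1, S = 0, V = 0, O = 0, R = 1 - I1),
              reason = "rumor-free family (I1, 0, 0, 0, 1 - I1), I1 in [0,1]"),
    E2 = list(feasible = FALSE,
              reason = paste("requires mu1*k*S + mu2*k*V + theta*O = 0 with",
                             "positive S, V, O: contradiction")),
    E3 = list(feasible = FALSE,
              reason = paste("requires alpha*k*I*S + lambda*k*I*V = 0 with",
                             "all compartments positive: contradiction")),
    degenerate = degenerate)
}

#' Reduced Jacobian at the rumor-free equilibrium
#'
#' The linearization around \eqn{E_1 = (I_1, 0, 0, 0, 1 - I_1)} reduces to
#' a 3x3 matrix in the active coordinates \eqn{(S, V, O)}:
#' \deqn{J = \pmatrix{U_1 & 0 & \beta_1 \cr \gamma & U_2 & \beta_2 \cr
#'   \xi_1 & \xi_2 & B}}
#' with \eqn{U_1 = \mu_1 k I_1 - \mu_1 k - \xi_1 - \gamma + \alpha k I_1},
#' \eqn{U_2 = \mu_2 k I_1 - \mu_2 k - \xi_2 + \lambda k I_1}.  The (3,3)
#' entry has two conventions: the published matrix uses \eqn{B = \theta
#' I_1 - (\beta_1 + \beta_2)} (\code{entry33 = "as_printed"}, the
#' default), while direct linearization of the contact-driven forgetting
#' term gives \eqn{\theta I_1 - \theta - (\beta_1 + \beta_2)}
#' (\code{entry33 = "linearized"}).
#'
#' @param params an \code{\link{isvor_params}}.
#' @param I1 ignorant density of the equilibrium, in \code{[0, 1]}.
#' @param entry33 which (3,3) convention to use.
#' @return a 3x3 numeric matrix.
#' @examples
#' isvor_jacobian(isvor_params(), I1 = 1)[1, 1]   # alpha*k - xi1 - gamma
#' @export
isvor_jacobian <- function(params, I1,
                           entry33 = c("as_printed", "linearized")) {
  entry33 <- match.arg(entry33)
  if (!is.numeric(I1) || length(I1) != 1L || is.na(I1) || I1 < 0 || I1 > 1)
    stop("I1 must be a density in [0, 1]", call. = FALSE)
  p <- params; k <- p$k
  U1 <- p$mu1 * k * I1 - p$mu1 * k - p$xi1 - p$gamma + p$alpha * k * I1
  U2 <- p$mu2 * k * I1 - p$mu2 * k - p$xi2 + p$lambda * k * I1
  B <- p$theta * I1 - (p$beta1 + p$beta2)
  if (entry33 == "linearized") B <- B - p$theta
  matrix(c(U1,      0,      p$beta1,
           p$gamma, U2,     p$beta2,
           p$xi1,   p$xi2,  B),
         nrow = 3L, byrow = TRUE,
         dimnames = list(c("S", "V", "O"), c("S", "V", "O")))
}

#' Linear stability report at the rumor-free equilibrium
#'
#' Computes the diagonal quantities \eqn{U_1, U_2, B}, the Hurwitz
#' determinants of the factored characteristic polynomial
#' \eqn{(\chi - U_1)(\chi - U_2)(\chi - B) = 0}
#' (\eqn{\Delta_1 = -(U_1+U_2+B)},
#' \eqn{\Delta_2 = -(U_1+U_2+B)[(U_1+U_2)B + U_1 U_2] - U_1 U_2 B},
#' \eqn{\Delta_3 = -U_1 U_2 B}), and the numerical eigenvalues of the
#' reduced Jacobian.  The verdict (\code{stable} / \code{unstable} /
#' \code{marginal}) follows the eigenvalue real parts, which are
#' authoritative; a \code{hurwitz_concordant} flag records whether the
#' Hurwitz sign conditions agree with them (they need not: the factored
#' polynomial ignores the Jacobian's off-diagonal coupling
#' \eqn{\gamma, \beta_1, \beta_2, \xi_1, \xi_2}).
#'
#' @inheritParams isvor_jacobian
#' @param tol eigenvalue real parts within \code{tol} of zero give the
#'   verdict \code{"marginal"}.
#' @return an object of class \code{"isvor_stability"}: a list with
#'   \code{I1}, \code{U1}, \code{U2}, \code{B}, \code{delta1..3},
#'   \code{eigenvalues}, \code{verdict}, \code{hurwitz_stable},
#'   \code{hurwitz_concordant}, \code{B_linearized} and
#'   \code{entry33_sign_agrees}.
#' @examples
#' stability_report(isvor_params(), I1 = 0.3)
#' @export
stability_report <- function(params, I1, tol = 1e-8) {
  J <- isvor_jacobian(params, I1, entry33 = "as_printed")
  p <- params; k <- p$k
  U1 <- J[1L, 1L]; U2 <- J[2L, 2L]; B <- J[3L, 3L]
  s <- U1 + U2 + B
  delta1 <- -s
  delta2 <- -s * ((U1 + U2) * B + U1 * U2) - U1 * U2 * B
  delta3 <- -U1 * U2 * B
  ev <- eigen(J, only.values = TRUE)$values
  mx <- max(Re(ev))
  verdict <- if (mx < -tol) "stable" else if (mx > tol) "unstable"
             else "marginal"
  hurwitz_stable <- delta1 > 0 && delta2 > 0 && delta3 > 0
  B_lin <- B - p$theta
  structure(list(
    I1 = I1, U1 = U1, U2 = U2, B = B,
    delta1 = delta1, delta2 = delta2, delta3 = delta3,
    eigenvalues = ev, max_re = mx, verdict = verdict,
    hurwitz_stable = hurwitz_stable,
    hurwitz_concordant = identical(hurwitz_stable, verdict == "stable"),
    B_linearized = B_lin,
    entry33_sign_agrees = sign(B) == sign(B_lin)),
    class = "isvor_stability")
}

#' @rdname stability_report
#' @param x report to print.
#' @param ... ignored.
#' @export
print.isvor_stability <- function(x, ...) {
  cat(sprintf("Rumor-free equilibrium E1 = (%.4g, 0, 0, 0, %.4g)\n",
              x$I1, 1 - x$I1))
  cat(sprintf("  U1 = %.6g, U2 = %.6g, B = %.6g\n", x$U1, x$U2, x$B))
  cat(sprintf("  Hurwitz: D1 = %.6g, D2 = %.6g, D3 = %.6g (%s)\n",
              x$delta1, x$delta2, x$delta3,
              if (x$hurwitz_stable) "all positive" else "not all positive"))
  cat("  eigenvalues:",
      paste(format(x$eigenvalues, digits = 6), collapse = ", "), "\n")
  cat("  verdict (eigenvalues authoritative):", x$verdict,
      if (!x$hurwitz_concordant) "[discordant with Hurwitz signs]" else "",
      "\n")
  invisible(x)
}

#' Stable range of the rumor-free ignorant density
#'
#' Scans \eqn{I_1 \in [0, 1]} on a fine grid, classifies each point by the
#' numerical eigenvalue verdict of \code{\link{stability_report}}, and
#' refines the stability boundaries by bisection.  Also reports the
#' closed-form candidate bounds obtained from the diagonal sign changes:
#' \eqn{U_1 = 0} at \eqn{(\mu_1 k + \xi_1 + \gamma)/(\mu_1 k + \alpha k)},
#' \eqn{U_2 = 0} at \eqn{(\mu_2 k + \xi_2)/(\mu_2 k + \lambda k)},
#' \eqn{B = 0} at \eqn{(\beta_1 + \beta_2)/\theta}, together with the
#' published second bound \eqn{(\mu_2 k + \xi_1 + \gamma)/(\mu_2 k +
#' \lambda k)} for comparison (solving \eqn{U_2 = 0} gives \eqn{\xi_2} in
#' the numerator, not \eqn{\xi_1 + \gamma}).
#'
#' @param params an \code{\link{isvor_params}}.
#' @param grid_n number of grid points on \code{[0, 1]}.
#' @param tol bisection tolerance on the boundary location.
#' @return a list with \code{intervals} (two-column matrix of stable
#'   \code{I1} ranges, possibly zero rows), \code{candidate_bounds}
#'   (named vector: \code{u1_zero}, \code{u2_zero}, \code{b_zero},
#'   \code{printed_u2_bound}), and \code{degenerate}.
#' @examples
#' stability_interval(isvor_params())$candidate_bounds
#' @export
stability_interval <- function(params, grid_n = 1001L, tol = 1e-10) {
  p <- params; k <- p$k
  rates <- unlist(p[PROB_FIELDS])
  if (all(rates == 0))
    return(list(intervals = matrix(numeric(0), ncol = 2L),
                candidate_bounds = c(u1_zero = NA_real_, u2_zero = NA_real_,
                                     b_zero = NA_real_,
                                     printed_u2_bound = NA_real_),
                degenerate = TRUE))
  cand <- c(
    u1_zero = (p$mu1 * k + p$xi1 + p$gamma) / (p$mu1 * k + p$alpha * k),
    u2_zero = (p$mu2 * k + p$xi2) / (p$mu2 * k + p$lambda * k),
    b_zero = if (p$theta > 0) (p$beta1 + p$beta2) / p$theta else Inf,
    printed_u2_bound = (p$mu2 * k + p$xi1 + p$gamma) /
      (p$mu2 * k + p$lambda * k))
  maxre <- function(i1)
    max(Re(eigen(isvor_jacobian(p, i1), only.values = TRUE)$values))
  grid <- seq(0, 1, length.out = grid_n)
  vals <- vapply(grid, maxre, 0)
  stable <- vals < 0
  # boundary refinement by bisection on max Re(eigenvalue)
  refine <- function(lo, hi) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if ((maxre(mid) < 0) == (maxre(lo) < 0)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  runs <- rle(stable)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ivs <- NULL
  for (j in which(runs$values)) {
    lo <- grid[starts[j]]; hi <- grid[ends[j]]
    if (starts[j] > 1L) lo <- refine(grid[starts[j] - 1L], grid[starts[j]])
    if (ends[j] < grid_n) hi <- refine(grid[ends[j] + 1L], grid[ends[j]])
    ivs <- rbind(ivs, c(lo, hi))
  }
  if (is.null(ivs)) ivs <- matrix(numeric(0), ncol = 2L)
  colnames(ivs) <- c("lower", "upper")
  list(intervals = ivs, candidate_bounds = cand, degenerate = FALSE)
}
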