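# shared fixtures and independent reference implementations

path_graph <- function(n)
  isvor_graph(n, cbind(0:(n - 2L), 1:(n - 1L)))

complete_graph <- function(n)
  isvor_graph(n, t(utils::combn(n, 2L)) - 1L)

# parameters with every rate zero except those supplied
rates_only <- function(...) {
  z <- list(alpha = 0, epsilon = 0, lambda = 0, mu1 = 0, mu2 = 0,
            gamma = 0, eta = 0, xi1 = 0, xi2 = 0, theta = 0,
            beta1 = 0, beta2 = 0, k = 10)
  z[names(list(...))] <- list(...)
  do.call(isvor_params, z)
}

# independently coded reduced ignorant/spreader/recovered flow, for the
# reduction property of the mean-field system
isr_rhs <- function(state, alpha, mu1, k) {
  I <- state[1L]; S <- state[2L]; R <- state[3L]
  Q <- S + R
  c(-k * alpha * I * S,
    -mu1 * k * S * Q + alpha * k * I * S,
    mu1 * k * S * Q)
}

# empirical one-step outcome frequencies of the compiled simulator
mc_onestep_freq <- function(g, roles, cfg, trials) {
  keys <- character(trials)
  for (i in seq_len(trials)) {
    nxt <- abm_step(g, roles, cfg)$roles
    keys[i] <- paste(nxt, collapse = "")
  }
  table(keys) / trials
}

# random point on the unit 5-simplex
rsimplex <- function() {
  x <- -log(runif(5))
  x / sum(x)
}

# tolerant unimodality: rises to its max then falls, with deviations from
# the running envelope bounded by tol (absorbs residual ensemble noise)
is_unimodal <- function(x, tol) {
  i <- which.max(x)
  up <- x[seq_len(i)]
  down <- x[i:length(x)]
  max(cummax(up) - up) <= tol &&      # non-decreasing before the peak
    max(down - cummin(down)) <= tol   # non-increasing after it
}
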