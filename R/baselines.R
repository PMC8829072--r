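#' Baseline comparator parameters
#'
#' Parameter bundle for the three comparator rumor models run on the same
#' network substrates as the ISVOR simulator:
#' \describe{
#'   \item{SIR}{susceptibles are infected per spreader contact with
#'     probability \code{alpha}; infected recover spontaneously with
#'     probability \code{mu1}.}
#'   \item{SEIR}{as SIR, but contact first produces an exposed
#'     (hesitating) state that becomes infectious spontaneously with
#'     probability \code{incubation}.}
#'   \item{Twin-SIR}{two competing spreader types: the rumor spreader
#'     S1 and the rumor dispeller S2, which converts both susceptibles
#'     and S1 nodes on contact with probability \code{dispel}; dispellers
#'     retire with probability \code{dispel_recovery}; \code{n_dispellers}
#'     dispellers are seeded among susceptibles after
#'     \code{dispel_delay} steps.}
#' }
#' Only the SIR mapping (\code{alpha}, \code{mu1}) is prescribed by the
#' reference experiments; the SEIR and Twin-SIR rates are standard
#' reconstructions, not reference values.
#'
#' @param alpha infection probability per spreader contact.
#' @param mu1 spontaneous recovery probability of an infected/spreader.
#' @param incubation SEIR exposed-to-infectious probability.
#' @param dispel Twin-SIR dispeller conversion probability (defaults to
#'   \code{alpha}).
#' @param dispel_recovery Twin-SIR dispeller retirement probability
#'   (defaults to \code{mu1}).
#' @param dispel_delay steps before dispellers are introduced.
#' @param n_dispellers how many dispellers are seeded.
#' @return an object of class \code{"baseline_params"}.
#' @export
baseline_params <- function(alpha = 0.5, mu1 = 0.5, incubation = 0.5,
                            dispel = alpha, dispel_recovery = mu1,
                            dispel_delay = 5L, n_dispellers = 1L) {
  for (v in c(alpha, mu1, incubation, dispel, dispel_recovery))
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1)
      stop("baseline probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(alpha = alpha, mu1 = mu1, incubation = incubation,
                 dispel = dispel, dispel_recovery = dispel_recovery,
                 dispel_delay = as.integer(dispel_delay),
                 n_dispellers = as.integer(n_dispellers)),
            class = "baseline_params")
}

baseline_init <- function(g, init, n_states) {
  n <- g$n_nodes
  roles <- integer(n)
  if (length(init) == 1L && init < n) {
    roles[sample.int(n, init)] <- 1L
  } else {
    stop("init must be a count of initial spreaders < n_nodes",
         call. = FALSE)
  }
  roles
}

baseline_traj <- function(counts, labels, n, kind, seed, t_max) {
  colnames(counts) <- labels
  dens <- as.data.frame(counts / n)
  new_trajectory(cbind(t = seq_len(nrow(dens)) - 1L, dens),
                 metadata = list(kind = kind, n = n, seed = seed,
                                 t_max = t_max))
}

#' Run the baseline comparator models
#'
#' Seeded synchronous network simulations with the same per-contact
#' Bernoulli semantics as the ISVOR ABM.  Each returns an
#' \code{\link{isvor_trajectory}} of role densities (columns named after
#' the model's own roles).
#'
#' @param g an \code{\link{isvor_graph}}.
#' @param p a \code{\link{baseline_params}}.
#' @param init number of initially infected/spreading nodes.
#' @param contact_mode contact semantics, as in
#'   \code{\link{abm_config}}: under \code{"maki_thompson"} (default)
#'   and \code{"per_contact"} susceptibles receive one infection trial
#'   per spreading neighbour, under \code{"per_step"} a single
#'   conditional trial; in Twin-SIR the rumor spreader's
#'   dispeller-conversion uses one sampled partner under
#'   \code{"maki_thompson"}.
#' @param t_max maximum steps (runs stop when no active role remains).
#' @param seed optional integer seed.
#' @return an \code{\link{isvor_trajectory}} with densities per step:
#'   \code{S, I, R} (SIR), \code{S, E, I, R} (SEIR), or
#'   \code{S, S1, S2, R} (Twin-SIR).
#' @examples
#' g <- generate_ba(300, 5, seed = 1)
#' tr <- run_sir(g, baseline_params(), init = 1, t_max = 50, seed = 2)
#' peak_diffuser(tr, cols = "I")
#' @export
run_sir <- function(g, p = baseline_params(), init = 1L, t_max = 100L,
                    seed = NULL,
                    contact_mode = c("maki_thompson", "per_step",
                                     "per_contact")) {
  stopifnot(is_isvor_graph(g), inherits(p, "baseline_params"))
  contact_mode <- match.arg(contact_mode)
  if (!is.null(seed)) set.seed(seed)
  csr <- adjacency_csr(g)
  roles <- baseline_init(g, init, 3L)
  res <- sir_run_cpp(roles, csr$off, csr$nb, p$alpha, p$mu1,
                     as.integer(t_max), contact_mode == "per_step")
  baseline_traj(res$counts, c("S", "I", "R"), g$n_nodes, "sir", seed, t_max)
}

#' @rdname run_sir
#' @export
run_seir <- function(g, p = baseline_params(), init = 1L, t_max = 100L,
                     seed = NULL,
                     contact_mode = c("maki_thompson", "per_step",
                                      "per_contact")) {
  stopifnot(is_isvor_graph(g), inherits(p, "baseline_params"))
  contact_mode <- match.arg(contact_mode)
  if (!is.null(seed)) set.seed(seed)
  csr <- adjacency_csr(g)
  roles <- baseline_init(g, init, 4L)
  roles[roles == 1L] <- 2L               # initial actives are infectious
  res <- seir_run_cpp(roles, csr$off, csr$nb, p$alpha, p$incubation, p$mu1,
                      as.integer(t_max), contact_mode == "per_step")
  baseline_traj(res$counts, c("S", "E", "I", "R"), g$n_nodes, "seir", seed,
                t_max)
}

#' @rdname run_sir
#' @export
run_twin_sir <- function(g, p = baseline_params(), init = 1L,
                         t_max = 100L, seed = NULL,
                         contact_mode = c("maki_thompson", "per_step",
                                          "per_contact")) {
  stopifnot(is_isvor_graph(g), inherits(p, "baseline_params"))
  contact_mode <- match.arg(contact_mode)
  if (!is.null(seed)) set.seed(seed)
  csr <- adjacency_csr(g)
  roles <- baseline_init(g, init, 4L)
  res <- twinsir_run_cpp(roles, csr$off, csr$nb, p$alpha, p$mu1, p$dispel,
                         p$dispel_recovery, p$dispel_delay, p$n_dispellers,
                         as.integer(t_max),
                         match(contact_mode,
                               c("maki_thompson", "per_step",
                                 "per_contact")) - 1L)
  baseline_traj(res$counts, c("S", "S1", "S2", "R"), g$n_nodes, "twin_sir",
                seed, t_max)
}

#' Ensemble mean of a baseline model
#'
#' @param model one of \code{"sir"}, \code{"seir"}, \code{"twin_sir"}.
#' @param spec an \code{\link{isvor_graph}} or \code{\link{network_spec}}
#'   (fresh graph per replicate).
#' @param p a \code{\link{baseline_params}}.
#' @param init,t_max as in \code{\link{run_sir}}.
#' @param reps replicates.
#' @param seed root seed (replicate seeds derived as in
#'   \code{\link{abm_ensemble}}).
#' @return an \code{\link{isvor_trajectory}} of ensemble-mean densities.
#' @export
baseline_ensemble <- function(model = c("sir", "seir", "twin_sir"), spec,
                              p = baseline_params(), init = 1L,
                              t_max = 100L, reps = 50L, seed = 1L,
                              contact_mode = c("maki_thompson", "per_step",
                                               "per_contact")) {
  model <- match.arg(model)
  contact_mode <- match.arg(contact_mode)
  runner <- switch(model, sir = run_sir, seir = run_seir,
                   twin_sir = run_twin_sir)
  seeds <- derive_seeds(seed, reps)
  acc <- NULL
  for (r in seq_len(reps)) {
    g <- if (is_isvor_graph(spec)) spec
         else graph_from_spec(spec, seeds[r, "graph"])
    tr <- runner(g, p, init = init, t_max = t_max, seed = seeds[r, "run"],
                 contact_mode = contact_mode)
    d <- as.matrix(tr[, setdiff(names(tr), "t")])
    full <- t_max + 1L
    if (nrow(d) < full)
      d <- rbind(d, d[rep(nrow(d), full - nrow(d)), , drop = FALSE])
    acc <- if (is.null(acc)) d else acc + d
  }
  m <- acc / reps
  new_trajectory(data.frame(t = 0:t_max, m),
                 metadata = list(kind = paste0(model, "_ensemble"),
                                 reps = reps, seed = seed))
}
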