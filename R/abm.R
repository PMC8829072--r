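#' Agent-based simulation configuration
#'
#' Settings for the discrete-time Monte-Carlo simulator.  Each step is a
#' synchronous update: every node's next role is computed from the
#' current configuration, with independent Bernoulli trials evaluated
#' sequentially (first success wins, contact-driven trials before
#' spontaneous ones; competing contact types are visited in randomized
#' order).  The mean-field degree \code{k} in \code{params} is ignored
#' here -- contacts come from the graph.
#'
#' @param params an \code{\link{isvor_params}} object.
#' @param init_spreaders number of initial spreaders, placed uniformly at
#'   random (ignored when \code{init_nodes} is given).
#' @param init_nodes optional explicit 0-based node ids to start as
#'   spreaders.
#' @param include_epsilon include the verbal ignorant-to-recovered contact
#'   rule (probability \code{epsilon} per spreader contact, tried before
#'   the infection trial).
#' @param contact_mode how contact-driven probabilities are applied.
#'   \code{"maki_thompson"} (default): ignorant nodes receive one
#'   independent infection trial per spreading neighbour, while each
#'   active node (spreader, variation, and oyster under contact-driven
#'   forgetting) keys its own contact-driven transitions on one uniformly
#'   sampled discussion partner per step, as in classic Maki-Thompson
#'   rumor dynamics.  \code{"per_step"}: one Bernoulli trial per contact
#'   class, conditional on at least one neighbour of that class being
#'   present (per-step conditional probabilities; no degree saturation).
#'   \code{"per_contact"}: one independent trial per neighbour of the
#'   class, the discrete counterpart of the degree-multiplied mass-action
#'   terms of the mean-field system.
#' @param theta_mode \code{"spontaneous"} (one forgetting trial per step,
#'   matching the verbal definition; default) or \code{"contact"} (one
#'   trial per non-ignorant neighbour, matching the printed
#'   \eqn{-\theta O (S+V+O+R)} term).
#' @param lambda_mode \code{"contact_with_V"} (an ignorant can be
#'   converted directly by variation neighbours, matching the
#'   \eqn{k \lambda I V} mass-action term; default) or
#'   \code{"fraction_of_infections"} (each new infection is redirected to
#'   the variation role with probability \code{lambda}, matching the
#'   verbal rule).
#' @param t_max maximum number of steps (runs stop earlier once no
#'   spreader, variation or oyster remains).
#' @param seed optional integer seed for \code{\link{abm_run}}.
#' @return an object of class \code{"abm_config"}.
#' @examples
#' cfg <- abm_config(isvor_params(), init_spreaders = 1, t_max = 100)
#' @export
abm_config <- function(params = isvor_params(), init_spreaders = 1L,
                       init_nodes = NULL, include_epsilon = FALSE,
                       contact_mode = c("maki_thompson", "per_step",
                                        "per_contact"),
                       theta_mode = c("spontaneous", "contact"),
                       lambda_mode = c("contact_with_V",
                                       "fraction_of_infections"),
                       t_max = 100L, seed = NULL) {
  stopifnot(is_isvor_params(params))
  contact_mode <- match.arg(contact_mode)
  theta_mode <- match.arg(theta_mode)
  lambda_mode <- match.arg(lambda_mode)
  init_spreaders <- as.integer(init_spreaders)
  t_max <- as.integer(t_max)
  if (is.na(init_spreaders) || init_spreaders < 1L)
    stop("init_spreaders must be >= 1", call. = FALSE)
  if (is.na(t_max) || t_max < 1L) stop("t_max must be >= 1", call. = FALSE)
  structure(list(params = params, init_spreaders = init_spreaders,
                 init_nodes = init_nodes,
                 include_epsilon = isTRUE(include_epsilon),
                 contact_mode = contact_mode,
                 theta_mode = theta_mode, lambda_mode = lambda_mode,
                 t_max = t_max, seed = seed),
            class = "abm_config")
}

par_vector <- function(p)
  c(p$alpha, p$epsilon, p$lambda, p$mu1, p$mu2, p$gamma, p$eta,
    p$xi1, p$xi2, p$theta, p$beta1, p$beta2)

flag_vector <- function(cfg)
  as.integer(c(cfg$include_epsilon, cfg$theta_mode == "contact",
               cfg$lambda_mode == "fraction_of_infections",
               match(cfg$contact_mode,
                     c("maki_thompson", "per_step", "per_contact")) - 1L))

#' Initial role assignment
#'
#' Places the configured spreaders (uniformly chosen distinct nodes, or
#' the explicit \code{init_nodes}); all other nodes start ignorant.
#'
#' @param g an \code{\link{isvor_graph}}.
#' @param cfg an \code{\link{abm_config}}.
#' @return integer role vector over nodes, coded \code{0=I, 1=S, 2=V,
#'   3=O, 4=R} (labels in \code{\link{role_labels}}).
#' @examples
#' set.seed(7)
#' abm_init(generate_ws(10, 2, 0), abm_config())
#' @export
abm_init <- function(g, cfg) {
  stopifnot(is_isvor_graph(g), inherits(cfg, "abm_config"))
  n <- g$n_nodes
  roles <- integer(n)                      # all ignorant
  if (!is.null(cfg$init_nodes)) {
    ids <- as.integer(cfg$init_nodes)
    if (any(is.na(ids)) || any(ids < 0L) || any(ids >= n) ||
        anyDuplicated(ids))
      stop("init_nodes must be distinct 0-based node ids", call. = FALSE)
    roles[ids + 1L] <- 1L
  } else {
    if (cfg$init_spreaders >= n)
      stop("init_spreaders must be < n_nodes", call. = FALSE)
    roles[sample.int(n, cfg$init_spreaders)] <- 1L
  }
  roles
}

#' @rdname abm_init
#' @param roles integer role codes.
#' @export
role_labels <- function(roles) ROLE_LEVELS[roles + 1L]

#' One synchronous ABM step
#'
#' @param g graph.
#' @param roles integer role vector (codes \code{0=I..4=R}).
#' @param cfg an \code{\link{abm_config}}.
#' @param csr optional precomputed adjacency (internal use).
#' @return a list with the next \code{roles} and the named
#'   \code{transitions} count vector of the realized flows.
#' @export
abm_step <- function(g, roles, cfg, csr = NULL) {
  if (is.null(csr)) csr <- adjacency_csr(g)
  res <- isvor_step_cpp(as.integer(roles), csr$off, csr$nb,
                        par_vector(cfg$params), flag_vector(cfg))
  names(res$transitions) <- TRANSITION_TYPES
  res
}

TRANSITION_TYPES <- c("I->S", "I->V", "I->R", "S->V", "S->O", "S->R",
                      "V->O", "V->R", "O->S", "O->V", "O->R")

#' Run one seeded ABM realization
#'
#' Runs the synchronous chain until \code{t_max} or until the state is
#' absorbing (no spreader, variation or oyster left).  Fully reproducible
#' from \code{(g, cfg)} when \code{cfg$seed} (or \code{seed}) is set.
#'
#' @param g an \code{\link{isvor_graph}}.
#' @param cfg an \code{\link{abm_config}}.
#' @param seed overrides \code{cfg$seed}.
#' @return a list of class \code{"isvor_abm"}: \code{trajectory}
#'   (densities, an \code{\link{isvor_trajectory}}), \code{counts}
#'   (integer role counts per step), \code{transitions} (per-step realized
#'   flow counts), \code{absorbed_at} (step index or \code{NA}), and
#'   \code{final_roles}.
#' @examples
#' g <- generate_ws(200, 4, 0.1, seed = 1)
#' r <- abm_run(g, abm_config(t_max = 50), seed = 42)
#' tail(r$trajectory, 1)
#' @export
abm_run <- function(g, cfg, seed = cfg$seed) {
  stopifnot(is_isvor_graph(g), inherits(cfg, "abm_config"))
  if (!is.null(seed)) set.seed(seed)
  csr <- adjacency_csr(g)
  roles <- abm_init(g, cfg)
  res <- isvor_run_cpp(roles, csr$off, csr$nb, par_vector(cfg$params),
                       flag_vector(cfg), cfg$t_max)
  counts <- res$counts
  colnames(counts) <- ROLE_LEVELS
  colnames(res$transitions) <- TRANSITION_TYPES
  dens <- as.data.frame(counts / g$n_nodes)
  traj <- new_trajectory(
    cbind(t = seq_len(nrow(dens)) - 1L, dens),
    metadata = list(kind = "abm", n = g$n_nodes, seed = seed,
                    t_max = cfg$t_max,
                    contact_mode = cfg$contact_mode,
                    theta_mode = cfg$theta_mode,
                    lambda_mode = cfg$lambda_mode,
                    params = unclass(cfg$params)))
  structure(list(trajectory = traj, counts = counts,
                 transitions = res$transitions,
                 absorbed_at = if (res$absorbed_at < 0) NA_integer_
                               else res$absorbed_at,
                 final_roles = res$final_roles,
                 n = g$n_nodes),
            class = "isvor_abm")
}

#' @rdname abm_run
#' @param x run to print.
#' @param ... ignored.
#' @export
print.isvor_abm <- function(x, ...) {
  cat("ABM run on", x$n, "nodes:", nrow(x$counts) - 1L, "steps",
      if (!is.na(x$absorbed_at)) paste0("(absorbed at t=", x$absorbed_at, ")"),
      "\n")
  print(x$trajectory)
  invisible(x)
}

# derive independent per-replicate seed pairs (graph, run) from one root
# seed; documented splitting rule so replicates are reproducible
derive_seeds <- function(seed, reps) {
  set.seed(seed)
  matrix(sample.int(2147483646L, 2L * reps), nrow = reps,
         dimnames = list(NULL, c("graph", "run")))
}

#' Ensemble of ABM runs
#'
#' Averages \code{reps} independent runs.  When \code{x} is a
#' \code{\link{network_spec}}, a fresh graph is generated per replicate
#' (pass a fixed \code{isvor_graph} to pin the substrate).  Runs that hit
#' the absorbing state early are padded with their absorbing values so
#' all replicates share the time grid \code{0..t_max}.
#'
#' @param x an \code{\link{isvor_graph}} or \code{\link{network_spec}}.
#' @param cfg an \code{\link{abm_config}}.
#' @param reps number of replicates (>= 1).
#' @param seed root seed; per-replicate seeds are derived from it.
#' @param keep_runs keep each replicate's padded density matrix.
#' @return an object of class \code{"isvor_ensemble"}: \code{mean} (an
#'   \code{\link{isvor_trajectory}} of ensemble means), \code{se}
#'   (pointwise standard errors), \code{summaries} (per-replicate peak
#'   and final statistics), \code{reps}, and optionally \code{runs}.
#' @examples
#' e <- abm_ensemble(network_spec("ws", n = 200, k = 4, p = 0.1),
#'                   abm_config(t_max = 50), reps = 5, seed = 1)
#' peak_diffuser(e$mean)
#' @export
abm_ensemble <- function(x, cfg, reps = 50L, seed = 1L, keep_runs = FALSE) {
  stopifnot(reps >= 1L)
  seeds <- derive_seeds(seed, reps)
  tgrid <- 0:cfg$t_max
  arr <- array(NA_real_, c(length(tgrid), 5L, reps))
  summ <- vector("list", reps)
  for (r in seq_len(reps)) {
    g <- if (is_isvor_graph(x)) x else graph_from_spec(x, seeds[r, "graph"])
    run <- abm_run(g, cfg, seed = seeds[r, "run"])
    d <- as.matrix(run$trajectory[, ROLE_LEVELS])
    if (nrow(d) < length(tgrid))   # pad with the absorbing state
      d <- rbind(d, d[rep(nrow(d), length(tgrid) - nrow(d)), , drop = FALSE])
    arr[, , r] <- d
    pk <- peak_diffuser(run$trajectory)
    pv <- peak_diffuser(run$trajectory, cols = "V")
    po <- peak_diffuser(run$trajectory, cols = "O")
    summ[[r]] <- data.frame(
      rep = r, peak_diffuser = pk[["value"]], peak_time = pk[["time"]],
      peak_V = pv[["value"]], peak_V_time = pv[["time"]],
      peak_O = po[["value"]],
      final_R = d[nrow(d), "R"], final_I = d[nrow(d), "I"],
      absorbed_at = run$absorbed_at)
  }
  m <- apply(arr, c(1L, 2L), mean)
  s <- apply(arr, c(1L, 2L), stats::sd) / sqrt(reps)
  colnames(m) <- colnames(s) <- ROLE_LEVELS
  mean_traj <- new_trajectory(
    data.frame(t = tgrid, m),
    metadata = list(kind = "abm_ensemble", reps = reps, seed = seed,
                    params = unclass(cfg$params)))
  structure(list(mean = mean_traj, se = data.frame(t = tgrid, s),
                 summaries = do.call(rbind, summ), reps = reps,
                 seed = seed, seeds = seeds,
                 runs = if (keep_runs) arr else NULL),
            class = "isvor_ensemble")
}

#' @rdname abm_ensemble
#' @export
print.isvor_ensemble <- function(x, ...) {
  cat("ABM ensemble:", x$reps, "replicates\n")
  pk <- peak_diffuser(x$mean)
  cat(sprintf("  mean peak diffuser S+V = %.4f at t = %d\n",
              pk[["value"]], as.integer(pk[["time"]])))
  cat(sprintf("  mean final R = %.4f, final I = %.4f\n",
              x$mean$R[nrow(x$mean)], x$mean$I[nrow(x$mean)]))
  invisible(x)
}
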