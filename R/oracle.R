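#' Exact one-step transition distribution on a tiny graph
#'
#' Enumerates the exact probability distribution over next-step role
#' assignments for the synchronous ABM update.  Because the update is
#' synchronous, nodes transition independently given the current
#' configuration, so the joint distribution is the product of per-node
#' distributions; each per-node distribution is obtained by enumerating
#' the sequential Bernoulli-trial rule analytically (including the
#' randomized interleaving of competing contact types for ignorant
#' nodes).  Used as the independent test oracle for the compiled
#' simulator.
#'
#' @param g an \code{\link{isvor_graph}} with at most 8 nodes.
#' @param roles integer role codes (\code{0=I..4=R}) over nodes.
#' @param cfg an \code{\link{abm_config}}.
#' @param prune drop outcomes with probability below this threshold.
#' @return a list with \code{assignments} (matrix, one row per reachable
#'   next assignment, role codes) and \code{probs} (summing to 1).
#' @examples
#' g <- isvor_graph(2, rbind(c(0, 1)))
#' cfg <- abm_config(isvor_params(alpha = 0.5, epsilon = 0, lambda = 0,
#'                                mu1 = 0, mu2 = 0, gamma = 0, eta = 0,
#'                                xi1 = 0, xi2 = 0, theta = 0,
#'                                beta1 = 0, beta2 = 0))
#' exact_one_step(g, c(0L, 1L), cfg)   # {(S,S): 0.5, (I,S): 0.5}
#' @export
exact_one_step <- function(g, roles, cfg, prune = 0) {
  stopifnot(is_isvor_graph(g), inherits(cfg, "abm_config"))
  n <- g$n_nodes
  if (n > 8L) stop("exact enumeration is limited to graphs with <= 8 nodes",
                   call. = FALSE)
  stopifnot(length(roles) == n)
  csr <- adjacency_csr(g)
  dists <- lapply(seq_len(n), function(v) {
    nbr <- if (csr$off[v + 1L] > csr$off[v])
      csr$nb[(csr$off[v] + 1L):csr$off[v + 1L]] else integer(0)
    node_next_dist(roles[v], roles[nbr + 1L], cfg)
  })
  states <- matrix(integer(0), nrow = 1L, ncol = 0L)
  probs <- 1
  for (v in seq_len(n)) {
    d <- dists[[v]]
    nz <- which(d > 0)
    states <- states[rep(seq_len(nrow(states)), times = length(nz)), ,
                     drop = FALSE]
    states <- cbind(states, rep(nz - 1L, each = length(probs)))
    probs <- as.vector(outer(probs, d[nz]))
    if (prune > 0) {
      keep <- probs >= prune
      states <- states[keep, , drop = FALSE]
      probs <- probs[keep]
    }
  }
  colnames(states) <- NULL
  list(assignments = states, probs = probs)
}

# per-node next-role distribution (probability vector over I,S,V,O,R);
# in per_step contact mode every contact count is clamped to one trial;
# in maki_thompson mode active nodes mix over one sampled partner
node_next_dist <- function(role, nbr_roles, cfg) {
  p <- cfg$params
  mode <- cfg$contact_mode
  clamp <- if (mode == "per_step") function(x) min(x, 1L) else identity
  sampled <- mode == "maki_thompson"
  d <- length(nbr_roles)
  out <- numeric(5L)
  names(out) <- ROLE_LEVELS
  if (role == 4L) { out["R"] <- 1; return(out) }
  nNonI <- clamp(sum(nbr_roles != 0L))
  if (role == 0L) {                          # ignorant
    eps <- if (cfg$include_epsilon) p$epsilon else 0
    nS <- clamp(sum(nbr_roles == 1L))
    nV <- if (cfg$lambda_mode == "contact_with_V")
      clamp(sum(nbr_roles == 2L)) else 0L
    cS <- (1 - eps) * (1 - p$alpha)          # continue past an S contact
    cV <- 1 - p$lambda                       # continue past a V contact
    if (cfg$lambda_mode == "fraction_of_infections") {
      stay <- cS^nS
      unit <- eps + (1 - eps) * p$alpha      # per-contact success prob
      pany <- 1 - stay
      if (unit > 0) {
        out["R"] <- pany * eps / unit
        win <- pany * (1 - eps) * p$alpha / unit
        out["V"] <- win * p$lambda
        out["S"] <- win * (1 - p$lambda)
      }
      out["I"] <- stay
      return(out)
    }
    d <- nS + nV
    if (d == 0L) { out["I"] <- 1; return(out) }
    accS <- accV <- accR <- 0
    if (nS == 0L || nV == 0L) {
      arrangements <- matrix(c(rep(1L, nS), rep(2L, nV)), nrow = 1L)
      w <- 1
    } else {
      pos <- utils::combn(d, nS)
      arrangements <- t(apply(pos, 2L, function(ix) {
        a <- rep(2L, d); a[ix] <- 1L; a
      }))
      w <- 1 / ncol(pos)
    }
    for (r in seq_len(nrow(arrangements))) {
      cont <- 1
      for (type in arrangements[r, ]) {
        if (type == 1L) {
          accR <- accR + w * cont * eps
          accS <- accS + w * cont * (1 - eps) * p$alpha
          cont <- cont * cS
        } else {
          accV <- accV + w * cont * p$lambda
          cont <- cont * cV
        }
      }
    }
    out["S"] <- accS; out["V"] <- accV; out["R"] <- accR
    out["I"] <- cS^nS * cV^nV
  } else if (role == 1L) {                   # spreader
    if (sampled) {
      fNonI <- if (d > 0) sum(nbr_roles != 0L) / d else 0
      fV <- if (d > 0) sum(nbr_roles == 2L) / d else 0
      pmu <- fNonI * p$mu1                   # partner informed, mu1 wins
      peta <- fV * (1 - p$mu1) * p$eta       # partner is V, mu1 failed
      out["R"] <- pmu
      out["V"] <- peta + (1 - pmu - peta) * p$gamma
      out["O"] <- (1 - pmu - peta) * (1 - p$gamma) * p$xi1
    } else {
      nV <- clamp(sum(nbr_roles == 2L))
      pmu <- 1 - (1 - p$mu1)^nNonI
      peta <- 1 - (1 - p$eta)^nV
      out["R"] <- pmu
      out["V"] <- (1 - pmu) * (peta + (1 - peta) * p$gamma)
      out["O"] <- (1 - pmu) * (1 - peta) * (1 - p$gamma) * p$xi1
    }
    out["S"] <- 1 - sum(out)
  } else if (role == 2L) {                   # variation
    pmu <- if (sampled) {
      (if (d > 0) sum(nbr_roles != 0L) / d else 0) * p$mu2
    } else 1 - (1 - p$mu2)^nNonI
    out["R"] <- pmu
    out["O"] <- (1 - pmu) * p$xi2
    out["V"] <- 1 - sum(out)
  } else {                                   # oyster
    pth <- if (cfg$theta_mode != "contact") p$theta
           else if (sampled)
             (if (d > 0) sum(nbr_roles != 0L) / d else 0) * p$theta
           else 1 - (1 - p$theta)^nNonI
    out["R"] <- pth
    out["S"] <- (1 - pth) * p$beta1
    out["V"] <- (1 - pth) * (1 - p$beta1) * p$beta2
    out["O"] <- 1 - sum(out)
  }
  out
}
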