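#' Transition probabilities of the ISVOR model
#'
#' Bundles the twelve per-step transition probabilities of the
#' Ignorance-Spreader-Variation-Oyster-Recovery model together with the
#' mean contact degree \code{k} used by the mean-field equations.  The
#' defaults are the reference parameter set used throughout the
#' simulation experiments: \eqn{\alpha = 0.5}, \eqn{\beta_1 = \beta_2 =
#' 0.1}, \eqn{\lambda = 0.2}, \eqn{\eta = 0.5}, \eqn{\xi_1 = \xi_2 =
#' 0.5}, \eqn{\gamma = 0.3}, \eqn{\theta = 0.25}, \eqn{\mu_1 = \mu_2 =
#' 0.5}, with \eqn{k = 10}.
#'
#' @param alpha probability that an ignorant becomes a spreader on contact
#'   with a spreader (\eqn{\alpha}).
#' @param epsilon probability that an ignorant becomes recovered on contact
#'   with a spreader (\eqn{\epsilon}).  Defined verbally in the model but
#'   absent from the mean-field equations; defaults to 0 and only enters
#'   when explicitly enabled (see \code{include_epsilon} arguments).
#' @param lambda probability that an ignorant becomes a variation on
#'   contact with a variation (\eqn{\lambda}).
#' @param mu1 probability that a spreader becomes recovered per contact
#'   with a non-ignorant (\eqn{\mu_1}, spreader immunity).
#' @param mu2 probability that a variation becomes recovered per contact
#'   with a non-ignorant (\eqn{\mu_2}, variation immunity).
#' @param gamma probability that a spreader spontaneously becomes a
#'   variation (\eqn{\gamma}).
#' @param eta probability that a spreader becomes a variation per contact
#'   with a variation (\eqn{\eta}).
#' @param xi1 probability that a spreader falls silent, becoming an oyster
#'   (\eqn{\xi_1}).
#' @param xi2 probability that a variation falls silent, becoming an
#'   oyster (\eqn{\xi_2}).
#' @param theta probability that an oyster forgets the rumor and becomes
#'   recovered (\eqn{\theta}).
#' @param beta1 probability that an oyster is resuscitated as a spreader
#'   (\eqn{\beta_1}).
#' @param beta2 probability that an oyster is resuscitated as a variation
#'   (\eqn{\beta_2}).
#' @param k mean contact degree entering the mean-field mass-action terms
#'   (positive real; ignored by the agent-based simulator, where contacts
#'   come from the graph).
#'
#' @return An object of class \code{"isvor_params"}: a named list of the
#'   thirteen values.
#' @examples
#' p <- isvor_params()
#' p$alpha
#' isvor_params(mu2 = 0.1)
#' @export
isvor_params <- function(alpha = 0.5, epsilon = 0, lambda = 0.2,
                         mu1 = 0.5, mu2 = 0.5, gamma = 0.3, eta = 0.5,
                         xi1 = 0.5, xi2 = 0.5, theta = 0.25,
                         beta1 = 0.1, beta2 = 0.1, k = 10) {
  p <- list(alpha = alpha, epsilon = epsilon, lambda = lambda,
            mu1 = mu1, mu2 = mu2, gamma = gamma, eta = eta,
            xi1 = xi1, xi2 = xi2, theta = theta,
            beta1 = beta1, beta2 = beta2, k = k)
  validate_isvor_params(p)
  structure(p, class = "isvor_params")
}

#' @rdname isvor_params
#' @param x object to test or print.
#' @export
is_isvor_params <- function(x) inherits(x, "isvor_params")

validate_isvor_params <- function(p) {
  probs <- setdiff(names(p), "k")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("parameter '", nm, "' must be a single probability in [0, 1], got ",
           deparse(v), call. = FALSE)
  }
  if (!is.numeric(p$k) || length(p$k) != 1L || is.na(p$k) || p$k <= 0)
    stop("parameter 'k' must be a single positive number", call. = FALSE)
  invisible(p)
}

#' @rdname isvor_params
#' @param ... ignored.
#' @export
print.isvor_params <- function(x, ...) {
  cat("ISVOR transition probabilities (mean degree k =", x$k, ")\n")
  v <- unlist(x[setdiff(names(x), "k")])
  print(v)
  invisible(x)
}

#' A compartment density state
#'
#' Constructs and validates a five-compartment density vector
#' \code{(I, S, V, O, R)} on the unit simplex.
#'
#' @param I,S,V,O,R densities in \code{[0, 1]}.
#' @param tol tolerance on \code{I + S + V + O + R = 1}.
#' @return A named numeric vector of length 5.
#' @examples
#' isvor_state(I = 0.9995, S = 0.0005)
#' @export
isvor_state <- function(I = 1, S = 0, V = 0, O = 0, R = 0, tol = 1e-9) {
  s <- c(I = I, S = S, V = V, O = O, R = R)
  if (any(!is.finite(s)) || any(s < 0))
    stop("state densities must be finite and non-negative", call. = FALSE)
  if (abs(sum(s) - 1) > tol)
    stop("state densities must sum to 1 (got ", format(sum(s), digits = 12),
         ")", call. = FALSE)
  s
}

# role coding shared by the ABM and the baselines
ROLE_LEVELS <- c("I", "S", "V", "O", "R")

# canonical order of the sweep-able probability fields
PROB_FIELDS <- c("alpha", "epsilon", "lambda", "mu1", "mu2", "gamma", "eta",
                 "xi1", "xi2", "theta", "beta1", "beta2")
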