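#' Run configuration files
#'
#' Reproducible runs are described by a YAML configuration with four
#' blocks (\code{network}, \code{params}, \code{abm}, \code{output}) plus
#' a \code{schema_version}.  Missing keys are filled from the defaults
#' (the reference simulation settings: \code{N = 2000}, \eqn{\alpha=0.5,
#' \beta_1=\beta_2=0.1, \lambda=0.2, \eta=0.5, \xi_1=\xi_2=0.5,
#' \gamma=0.3, \theta=0.25, \mu_1=\mu_2=0.5}); unknown keys are rejected;
#' constraint violations name the offending key.  \code{load_config}
#' of a saved configuration reproduces it exactly.
#'
#' @return \code{default_config} and \code{load_config} return a named
#'   list of class \code{"isvor_config"}.
#' @examples
#' cfg <- default_config()
#' cfg$params$alpha
#' @export
default_config <- function() {
  structure(list(
    schema_version = 1L,
    network = list(family = "ws", n = 2000L, k = 10L, p = 0.4, m = 5L),
    params = c(as.list(unclass(isvor_params()))),
    abm = list(init_spreaders = 1L, include_epsilon = FALSE,
               contact_mode = "maki_thompson",
               theta_mode = "spontaneous", lambda_mode = "contact_with_V",
               t_max = 100L, reps = 50L, seed = 1L),
    output = list(dir = "results")),
    class = "isvor_config")
}

#' @rdname default_config
#' @param path YAML file to read or write.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  base <- default_config()
  merged <- merge_config(unclass(base), user, key = "")
  cfg <- structure(merged, class = "isvor_config")
  validate_config(cfg)
  cfg
}

#' @rdname default_config
#' @param cfg configuration to save.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

merge_config <- function(base, user, key) {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown config key", if (length(unknown) > 1L) "s", ": ",
         paste0(sub("^\\.", "", paste0(key, ".", unknown)), collapse = ", "),
         call. = FALSE)
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]))
      merge_config(base[[nm]], user[[nm]], paste0(key, ".", nm))
    else user[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  for (nm in PROB_FIELDS) {
    v <- cfg$params[[nm]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1)
      stop("config constraint violated: params.", nm,
           " must be a probability in [0, 1] (got ", v, ")", call. = FALSE)
  }
  if (!is.numeric(cfg$params$k) || cfg$params$k <= 0)
    stop("config constraint violated: params.k must be positive",
         call. = FALSE)
  if (cfg$network$n < 2)
    stop("config constraint violated: network.n must be >= 2",
         call. = FALSE)
  if (!cfg$network$family %in% c("ws", "ba", "edgelist", "fixture"))
    stop("config constraint violated: network.family", call. = FALSE)
  if (cfg$abm$t_max < 1)
    stop("config constraint violated: abm.t_max must be >= 1",
         call. = FALSE)
  if (!cfg$abm$contact_mode %in% c("maki_thompson", "per_step",
                                   "per_contact"))
    stop("config constraint violated: abm.contact_mode", call. = FALSE)
  invisible(cfg)
}

#' Trajectory CSV serialization
#'
#' Trajectories are stored as CSV with a header row \code{t,I,S,V,O,R}
#' (mean-field and ABM trajectories share the schema) at full float
#' precision, so \code{read_trajectory(write_trajectory(x))} reproduces
#' \code{x} exactly.  Densities are validated on read.
#'
#' @param traj trajectory to write (columns \code{t, I, S, V, O, R}).
#' @param path CSV path.
#' @return \code{read_trajectory} returns an
#'   \code{\link{isvor_trajectory}}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' tr <- isvor_meanfield(isvor_params(), isvor_state(I = 0.999, S = 0.001),
#'                       t_max = 5)
#' write_trajectory(tr, f)
#' all.equal(as.data.frame(read_trajectory(f)), as.data.frame(tr))
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("t", "I", "S", "V", "O", "R")
  if (!all(cols %in% names(traj)))
    stop("trajectory must have columns ", paste(cols, collapse = ","),
         call. = FALSE)
  m <- as.matrix(traj[, cols])
  txt <- apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(paste(cols, collapse = ","), txt), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  cols <- c("t", "I", "S", "V", "O", "R")
  if (!identical(names(df), cols))
    stop("trajectory file schema mismatch: expected header ",
         paste(cols, collapse = ","), call. = FALSE)
  dens <- as.matrix(df[, -1L])
  if (any(!is.finite(dens)) || any(dens < -1e-9) || any(dens > 1 + 1e-9))
    stop("invalid trajectory: densities must lie in [0, 1]", call. = FALSE)
  new_trajectory(df, metadata = list(kind = "file", path = path))
}

#' Write a reproducibility manifest
#'
#' Records everything needed to re-run a computation bit-identically:
#' the full configuration, the root seed and the package version.
#'
#' @param path JSON path.
#' @param config configuration list.
#' @param seed root seed.
#' @param extra optional extra fields.
#' @export
write_run_manifest <- function(path, config, seed, extra = list()) {
  manifest <- c(list(config = unclass(config), seed = seed,
                     package_version = as.character(
                       utils::packageVersion("isvor"))),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
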