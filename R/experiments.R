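#' Parameter sweep with common random numbers
#'
#' Runs an ensemble for each value of one ISVOR probability on a grid,
#' reusing identical per-replicate seeds (same graph instance and initial
#' spreaders) across grid values so that the parameter effect is not
#' confounded by sampling noise.  A fresh network is generated per
#' replicate unless \code{pin_graph = TRUE}.
#'
#' @param spec a \code{\link{network_spec}} (or \code{isvor_graph}).
#' @param cfg an \code{\link{abm_config}} providing the base parameters.
#' @param param name of the swept probability (one of the twelve ISVOR
#'   rates, e.g. \code{"mu2"}).
#' @param grid numeric vector of probability values.
#' @param reps replicates per grid value.
#' @param seed root seed.
#' @param pin_graph reuse one network instance for all replicates.
#' @param keep_long keep the tidy long-format table of every run.
#' @return an object of class \code{"isvor_sweep"}: \code{summary} (one
#'   row per grid value: means and standard errors of the peak-diffuser
#'   density \code{max S(t)+V(t)}, its time, the variation and oyster
#'   peaks, and final R and I), \code{per_rep} (per-replicate statistics,
#'   for paired comparisons), \code{long} (optional tidy table
#'   \code{param_value, rep, t, I, S, V, O, R}), plus the sweep metadata.
#' @examples
#' sw <- run_sweep(network_spec("ws", n = 200, k = 4, p = 0.1),
#'                 abm_config(t_max = 40), "mu2", c(0.1, 0.5),
#'                 reps = 3, seed = 1)
#' sw$summary
#' @export
run_sweep <- function(spec, cfg, param, grid, reps = 50L, seed = 1L,
                      pin_graph = FALSE, keep_long = FALSE) {
  if (!param %in% PROB_FIELDS)
    stop("unknown sweep parameter '", param, "'; must be one of: ",
         paste(PROB_FIELDS, collapse = ", "), call. = FALSE)
  if (any(grid < 0 | grid > 1))
    stop("grid values must be probabilities in [0, 1]", call. = FALSE)
  seeds <- derive_seeds(seed, reps)          # shared across grid values
  graphs <- NULL
  if (pin_graph && !is_isvor_graph(spec))
    spec <- graph_from_spec(spec, seeds[1L, "graph"])
  per_rep <- NULL
  long <- NULL
  means <- list()
  for (gi in seq_along(grid)) {
    p <- cfg$params
    p[[param]] <- grid[gi]
    class(p) <- "isvor_params"
    cfg_i <- cfg
    cfg_i$params <- p
    tgrid <- 0:cfg$t_max
    acc <- matrix(0, length(tgrid), 5L)
    for (r in seq_len(reps)) {
      g <- if (is_isvor_graph(spec)) spec
           else graph_from_spec(spec, seeds[r, "graph"])
      run <- abm_run(g, cfg_i, seed = seeds[r, "run"])
      d <- as.matrix(run$trajectory[, ROLE_LEVELS])
      if (nrow(d) < length(tgrid))
        d <- rbind(d, d[rep(nrow(d), length(tgrid) - nrow(d)), ,
                        drop = FALSE])
      acc <- acc + d
      pk <- peak_diffuser(run$trajectory)
      pv <- peak_diffuser(run$trajectory, cols = "V")
      po <- peak_diffuser(run$trajectory, cols = "O")
      per_rep <- rbind(per_rep, data.frame(
        param_value = grid[gi], rep = r,
        peak_diffuser = pk[["value"]], peak_time = pk[["time"]],
        peak_V = pv[["value"]], peak_V_time = pv[["time"]],
        peak_O = po[["value"]],
        final_R = d[nrow(d), "R"], final_I = d[nrow(d), "I"]))
      if (keep_long)
        long <- rbind(long, data.frame(param_value = grid[gi], rep = r,
                                       t = tgrid, d))
    }
    m <- acc / reps
    colnames(m) <- ROLE_LEVELS
    means[[gi]] <- new_trajectory(
      data.frame(t = tgrid, m),
      metadata = list(kind = "sweep_mean", param = param,
                      param_value = grid[gi], reps = reps))
  }
  agg <- do.call(rbind, lapply(seq_along(grid), function(gi) {
    s <- per_rep[per_rep$param_value == grid[gi], ]
    data.frame(param_value = grid[gi],
               peak_diffuser = mean(s$peak_diffuser),
               peak_diffuser_se = stats::sd(s$peak_diffuser) / sqrt(reps),
               peak_time = mean(s$peak_time),
               peak_V = mean(s$peak_V),
               peak_V_time = mean(s$peak_V_time),
               peak_O = mean(s$peak_O),
               peak_O_se = stats::sd(s$peak_O) / sqrt(reps),
               final_R = mean(s$final_R),
               final_R_se = stats::sd(s$final_R) / sqrt(reps),
               final_I = mean(s$final_I))
  }))
  structure(list(param = param, grid = grid, summary = agg,
                 per_rep = per_rep, means = means, long = long,
                 reps = reps, seed = seed, seeds = seeds),
            class = "isvor_sweep")
}

#' @rdname run_sweep
#' @param x sweep to print.
#' @param ... ignored.
#' @export
print.isvor_sweep <- function(x, ...) {
  cat("parameter sweep over", x$param, "(", x$reps,
      "replicates per value, common random numbers )\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Paired one-sided comparison of peak statistics between grid values
#'
#' With common-random-number coupling, replicate r of one grid value is
#' directly comparable to replicate r of another; a paired t-test on the
#' per-replicate peaks then tests monotonicity of the parameter effect.
#'
#' @param sweep an \code{\link{run_sweep}} result.
#' @param stat which per-replicate column to compare.
#' @param alternative passed to \code{\link[stats]{t.test}}; the default
#'   \code{"greater"} tests that the statistic decreases along the grid.
#' @return data frame of consecutive-pair comparisons with p-values.
#' @export
sweep_pairwise_test <- function(sweep, stat = "peak_diffuser",
                                alternative = "greater") {
  g <- sweep$grid
  out <- NULL
  for (i in seq_len(length(g) - 1L)) {
    a <- sweep$per_rep[sweep$per_rep$param_value == g[i], stat]
    b <- sweep$per_rep[sweep$per_rep$param_value == g[i + 1L], stat]
    tt <- stats::t.test(a, b, paired = TRUE, alternative = alternative)
    out <- rbind(out, data.frame(from = g[i], to = g[i + 1L],
                                 mean_diff = mean(a - b),
                                 p_value = tt$p.value))
  }
  out
}

#' Compare silencing against immunization of the variation
#'
#' Sweeps the variation's silent probability \eqn{\xi_2} and immune
#' probability \eqn{\mu_2} over the same grid with identical seeds and
#' reports the drop in the ensemble-mean peak diffuser density from the
#' lowest to the highest grid value, with bootstrap confidence intervals
#' over replicates.
#'
#' @inheritParams run_sweep
#' @param grid probability grid applied to both parameters.
#' @param n_boot bootstrap resamples for the CI of each delta.
#' @return data frame with one row per parameter: \code{delta_peak}
#'   (mean peak at lowest minus at highest grid value), bootstrap
#'   \code{ci_lo}/\code{ci_hi}, and a \code{winner} attribute naming the
#'   intervention with the larger drop.
#' @export
intervention_comparison <- function(spec, cfg, grid = c(0.1, 0.5),
                                    reps = 50L, seed = 1L, n_boot = 1000L) {
  res <- lapply(c("mu2", "xi2"), function(par) {
    sw <- run_sweep(spec, cfg, par, range(grid), reps = reps, seed = seed)
    lo <- sw$per_rep[sw$per_rep$param_value == min(grid), "peak_diffuser"]
    hi <- sw$per_rep[sw$per_rep$param_value == max(grid), "peak_diffuser"]
    d <- lo - hi                       # per-replicate paired drop
    boot <- replicate(n_boot, mean(sample(d, replace = TRUE)))
    data.frame(param = par, delta_peak = mean(d),
               ci_lo = stats::quantile(boot, 0.025, names = FALSE),
               ci_hi = stats::quantile(boot, 0.975, names = FALSE))
  })
  out <- do.call(rbind, res)
  attr(out, "winner") <- out$param[which.max(out$delta_peak)]
  out
}

#' Reproduce the packaged figure-level experiments
#'
#' Scripted versions of the five simulation experiments: role-density
#' curves on both network families (\code{fig3}), the SIR/SEIR/Twin-SIR/
#' ISVOR comparison on the scale-free network (\code{fig4}), the
#' \eqn{\mu_2} sweep (\code{fig5_7}), the \eqn{\xi_2} sweep
#' (\code{fig8_10}) and the \eqn{\alpha} sweep on the scale-free network
#' (\code{fig11}).  At \code{scale = "full"} the study conditions are
#' \code{N = 2000} nodes (WS: \code{k = 10}, \code{p = 0.4}; BA:
#' \code{m = 5}), default rates and 50 replicates; \code{scale = "ci"}
#' runs \code{N = 300} and 10 replicates.
#'
#' @param figure experiment id.
#' @param out_dir directory for CSV output and the JSON manifest.
#' @param scale \code{"full"} or \code{"ci"}.
#' @param seed root seed.
#' @param plots also write PNG plots.
#' @return (invisibly) the manifest list, including the written file
#'   paths and every configuration value needed to re-run.
#' @export
reproduce_figure <- function(figure = c("fig3", "fig4", "fig5_7", "fig8_10",
                                        "fig11"),
                             out_dir, scale = c("full", "ci"), seed = 1L,
                             plots = FALSE) {
  figure <- match.arg(figure)
  scale <- match.arg(scale)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- if (scale == "full") 2000L else 300L
  reps <- if (scale == "full") 50L else 10L
  ws <- network_spec("ws", n = n, k = 10, p = 0.4)
  ba <- network_spec("ba", n = n, m = 5)
  cfg <- abm_config(isvor_params(), t_max = 100L)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  if (figure == "fig3") {
    for (fam in c("ws", "ba")) {
      e <- abm_ensemble(if (fam == "ws") ws else ba, cfg, reps = reps,
                        seed = seed)
      emit(as.data.frame(e$mean), paste0("fig3_", fam))
      if (plots) plot_png(e$mean, file.path(out_dir,
                                            paste0("fig3_", fam, ".png")))
    }
  } else if (figure == "fig4") {
    bp <- baseline_params(alpha = 0.5, mu1 = 0.5)
    emit(as.data.frame(baseline_ensemble("sir", ba, bp, reps = reps,
                                         seed = seed)), "fig4_sir")
    emit(as.data.frame(baseline_ensemble("seir", ba, bp, reps = reps,
                                         seed = seed)), "fig4_seir")
    emit(as.data.frame(baseline_ensemble("twin_sir", ba, bp, reps = reps,
                                         seed = seed)), "fig4_twin_sir")
    e <- abm_ensemble(ba, cfg, reps = reps, seed = seed)
    emit(as.data.frame(e$mean), "fig4_isvor")
  } else if (figure %in% c("fig5_7", "fig8_10")) {
    par <- if (figure == "fig5_7") "mu2" else "xi2"
    for (fam in c("ws", "ba")) {
      sw <- run_sweep(if (fam == "ws") ws else ba, cfg, par,
                      c(0.1, 0.3, 0.5), reps = reps, seed = seed)
      emit(sw$summary, paste0(figure, "_", fam, "_summary"))
      for (gi in seq_along(sw$grid))
        emit(as.data.frame(sw$means[[gi]]),
             sprintf("%s_%s_%s_%s", figure, fam, par, sw$grid[gi]))
    }
  } else {                               # fig11: alpha sweep, BA only
    sw <- run_sweep(ba, cfg, "alpha", c(0.1, 0.3, 0.5), reps = reps,
                    seed = seed)
    emit(sw$summary, "fig11_ba_summary")
    for (gi in seq_along(sw$grid))
      emit(as.data.frame(sw$means[[gi]]),
           sprintf("fig11_ba_alpha_%s", sw$grid[gi]))
  }
  manifest <- list(figure = figure, scale = scale, seed = seed,
                   n_nodes = n, reps = reps, t_max = cfg$t_max,
                   params = unclass(cfg$params),
                   ws = list(k = 10, p = 0.4), ba = list(m = 5),
                   files = basename(files),
                   package_version = as.character(
                     utils::packageVersion("isvor")))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(figure, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

plot_png <- function(traj, path) {
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  plot(traj)
}
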