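#' Experiment configuration
#'
#' Describes a (possibly swept) simulation experiment: scalar defaults for
#' every model parameter, an optional `sweep` list of values for any of
#' `temptation`, `M`, `beta`, `K` (the run grid is their Cartesian
#' product), a replicate count (replicate r uses seed `seed + r - 1`), the
#' averaging window used for steady-state means, and an optional output
#' directory for CSVs and snapshots.
#'
#' @param L lattice side length.
#' @param p_c initial cooperation probability.
#' @param M,beta,temptation,K scalar defaults for any axis not swept.
#' @param steps Monte Carlo steps per run.
#' @param record_every observable recording interval (MCS).
#' @param update_scheme,boundary,stability_of,reset_threshold see
#'   [run_simulation()].
#' @param sweep named list of numeric vectors over a subset of
#'   `c("temptation", "M", "beta", "K")`; every entry must be non-empty.
#' @param replicates independent runs per grid point (>= 1).
#' @param seed base RNG seed.
#' @param averaging_window number of final recorded steps averaged for the
#'   steady-state cooperation rate; default 10% of the recorded series.
#' @param snapshot_times absolute `t` values at which lattices are saved.
#' @param output_dir directory for per-run CSVs, snapshots, the resolved
#'   config and the summary table; `NULL` keeps everything in memory.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(L = 200, p_c = 0.5, M = 0, beta = 0.5,
                              temptation = 1.05, K = 0.1, steps = 10000,
                              record_every = 1L,
                              update_scheme = "asynchronous",
                              boundary = "periodic",
                              stability_of = "self",
                              reset_threshold = 0.5,
                              sweep = list(), replicates = 5, seed = 1,
                              averaging_window = NULL,
                              snapshot_times = integer(0),
                              output_dir = NULL) {
  if (!is.list(sweep))
    stop("sweep must be a named list", call. = FALSE)
  allowed <- c("temptation", "M", "beta", "K")
  if (length(sweep)) {
    if (is.null(names(sweep)) || !all(names(sweep) %in% allowed))
      stop("sweep axes must be among: ", paste(allowed, collapse = ", "),
           call. = FALSE)
    if (any(lengths(sweep) == 0))
      stop("every swept list must be non-empty", call. = FALSE)
  }
  if (!is.numeric(replicates) || replicates < 1)
    stop("replicates must be >= 1", call. = FALSE)
  nrec <- floor(steps / record_every)
  if (is.null(averaging_window))
    averaging_window <- max(1L, floor(0.1 * nrec))
  if (averaging_window > nrec)
    stop("averaging window cannot exceed the recorded steps", call. = FALSE)
  structure(list(L = L, p_c = p_c, M = M, beta = beta,
                 temptation = temptation, K = K, steps = steps,
                 record_every = as.integer(record_every),
                 update_scheme = update_scheme, boundary = boundary,
                 stability_of = stability_of,
                 reset_threshold = reset_threshold, sweep = sweep,
                 replicates = as.integer(replicates), seed = seed,
                 averaging_window = as.integer(averaging_window),
                 snapshot_times = as.integer(snapshot_times),
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Canonical configurations for the standard experiment layouts
#'
#' Pre-registered sweep configurations matching the study's figure-style
#' experiments: cooperation rate versus temptation under several memory
#' lengths (`fig1`), versus memory length under several (T, K)
#' combinations (`fig2`), cooperation-rate time series (`fig3`),
#' steady-state snapshots across M (`fig4`), and stability / retention
#' time series (`fig7`, `fig8`). `"full"` scale uses L = 200 and 10^4 MCS;
#' `"desk"` scale uses L = 50 (sweeps) or L = 100 (time series and
#' snapshots) and 2 x 10^3 MCS with the same parameter grids, sized to run
#' on one core in minutes.
#'
#' @param name one of `"fig1"`, `"fig2"`, `"fig3"`, `"fig4"`, `"fig7"`,
#'   `"fig8"`.
#' @param scale `"desk"` (default) or `"full"`.
#' @param output_dir optional output directory, passed through.
#' @return An [experiment_config()].
#' @export
figure_recipes <- function(name = c("fig1", "fig2", "fig3", "fig4", "fig7",
                                    "fig8"),
                           scale = c("desk", "full"), output_dir = NULL) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  full <- scale == "full"
  steps <- if (full) 10000L else 2000L
  L_sweep <- if (full) 200L else 50L
  L_series <- if (full) 200L else 100L
  base <- list(beta = 0.5, K = 0.1, steps = steps, replicates = 5,
               output_dir = output_dir)
  cfg <- switch(name,
    fig1 = c(base, list(
      L = L_sweep,
      sweep = list(temptation = if (full) seq(1.02, 2, by = 0.02)
                                else c(1.05, seq(1.1, 2, by = 0.1)),
                   M = c(0, 1, 3, 5, 7, 9)),
      record_every = 10L)),
    fig2 = c(base, list(
      L = L_sweep,
      sweep = list(temptation = c(1.04, 1.05, 1.06),
                   K = c(0.1, 0.2, 0.3),
                   M = if (full) c(1:10, seq(15, 100, by = 5))
                       else c(1:5, 7, 10, 15, 20, 30, 50, 70, 100)),
      record_every = 10L)),
    fig3 = c(base, list(
      L = L_series, temptation = 1.05,
      sweep = list(M = c(0, 1, 3, 5, 7, 9)))),
    fig4 = c(base, list(
      L = L_series, temptation = 1.05,
      sweep = list(M = c(0, 1, 2, 5, 8, 10, 20, 30, 50, 80, 100, 200)),
      snapshot_times = steps, record_every = 10L)),
    fig7 = c(base, list(
      L = L_series, temptation = 1.05,
      sweep = list(M = c(3, 5, 7, 9)))),
    fig8 = c(base, list(
      L = L_series, temptation = 1.05,
      sweep = list(M = c(3, 5, 7, 9))))
  )
  do.call(experiment_config, cfg)
}

#' Run a (swept) experiment
#'
#' Runs one simulation per grid point and replicate (replicate r uses seed
#' `config$seed + r - 1`) and returns a summary data frame with one row
#' per run: the parameter point, seed, steady-state cooperation rate
#' (mean over the final averaging window), final mean stability, final
#' cooperation rate, and the first recorded time at which the cooperator
#' retention reaches the defector retention (`NA` if never). When
#' `output_dir` is set, each run's time series CSV, requested snapshots, a
#' resolved copy of the configuration (YAML) and the summary CSV are
#' written there; reruns with the same config and seed reproduce every
#' file byte for byte.
#'
#' @param config an [experiment_config()].
#' @return Summary data frame (invisibly also written to
#'   `output_dir/summary.csv` if configured).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  axes <- list(temptation = config$temptation, M = config$M,
               beta = config$beta, K = config$K)
  for (ax in names(config$sweep)) axes[[ax]] <- config$sweep[[ax]]
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)

  out_dir <- config$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    resolved <- unclass(config)
    resolved$output_dir <- NULL  # implicit: the directory the copy sits in
    resolved$sweep <- lapply(resolved$sweep, as.numeric)
    yaml::write_yaml(resolved, file.path(out_dir, "config.yml"))
  }

  rows <- vector("list", nrow(grid) * config$replicates)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    for (r in seq_len(config$replicates)) {
      run_seed <- config$seed + r - 1L
      sim <- run_simulation(
        L = config$L, M = grid$M[g], beta = grid$beta[g],
        temptation = grid$temptation[g], K = grid$K[g],
        steps = config$steps, seed = run_seed, p_c = config$p_c,
        update_scheme = config$update_scheme, boundary = config$boundary,
        stability_of = config$stability_of,
        reset_threshold = config$reset_threshold,
        record_every = config$record_every,
        snapshot_times = config$snapshot_times)
      s <- sim$series
      w <- config$averaging_window
      pc_steady <- mean(utils::tail(s$pc, w))
      defined <- !is.na(s$pcc) & !is.na(s$pdd)
      cross <- which(defined & s$pcc >= s$pdd)
      t_cross <- if (length(cross)) s$t[cross[1]] else NA_real_
      tag <- sprintf("T%.3f_M%d_beta%.2f_K%.2f_rep%d", grid$temptation[g],
                     as.integer(grid$M[g]), grid$beta[g], grid$K[g], r)
      if (!is.null(out_dir)) {
        write_timeseries(s, file.path(out_dir, paste0("ts_", tag, ".csv")))
        for (nm in names(sim$snapshots))
          write_snapshot(sim$snapshots[[nm]],
                         file.path(out_dir,
                                   paste0("snap_", tag, "_t", nm, ".txt")))
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        temptation = grid$temptation[g], M = grid$M[g], beta = grid$beta[g],
        K = grid$K[g], replicate = r, seed = run_seed,
        pc_steady = pc_steady, pc_final = s$pc[nrow(s)],
        rho_final = s$rho[nrow(s)], t_cross = t_cross)
    }
  }
  summary <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE, na = "")
  summary
}
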