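# Configuration files, fixtures and run outputs.
#
# Configurations are YAML with a strict schema (unknown keys are rejected);
# every run writes a manifest sufficient to reproduce it bit-identically.

config_schema <- list(
  "spiking-network" = c("kind", "coupling", "coupling_file", "input",
                        "input_breaks", "input_values", "duration", "dt",
                        "tau_s", "k", "seed", "outdir"),
  "phase-network"   = c("kind", "coupling", "coupling_file", "period",
                        "duration", "tau_c", "seed", "outdir"),
  "composed"        = c("kind", "counts", "skeleton_file", "pulse_amp",
                        "pulses", "duration", "dt", "seed", "outdir")
)

#' Load and validate a run configuration
#'
#' @param path YAML file.
#' @param base_dir directory against which relative file references are
#'   resolved (defaults to the configuration file's directory).
#' @return validated configuration (list, class `run_config`) with defaults
#'   filled in.
#' @export
load_config <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg, base_dir = base_dir)
}

#' @rdname load_config
#' @param cfg configuration list.
#' @export
validate_config <- function(cfg, base_dir = ".") {
  if (is.null(cfg$kind)) cfg$kind <- "spiking-network"
  if (!cfg$kind %in% names(config_schema)) {
    stop("unknown config kind: ", cfg$kind, call. = FALSE)
  }
  allowed <- config_schema[[cfg$kind]]
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # defaults
  if (is.null(cfg[["dt"]]) && cfg$kind != "phase-network") cfg$dt <- 0.05
  if (is.null(cfg[["tau_s"]]) && cfg$kind == "spiking-network") cfg$tau_s <- 20
  if (is.null(cfg[["tau_c"]]) && cfg$kind == "phase-network") cfg$tau_c <- 2
  if (is.null(cfg[["k"]]) && cfg$kind == "spiking-network") cfg$k <- K_DEFAULT
  if (is.null(cfg[["seed"]])) cfg$seed <- 1L
  # checks, naming the offending key
  chk_pos <- function(key) {
    v <- cfg[[key]]
    if (!is.null(v) && (!is.numeric(v) || any(v <= 0))) {
      stop("config key '", key, "' must be positive", call. = FALSE)
    }
  }
  chk_pos("tau_s"); chk_pos("dt"); chk_pos("period"); chk_pos("tau_c")
  if (is.null(cfg$duration) || cfg$duration < 0) {
    stop("config key 'duration' must be a nonnegative number",
         call. = FALSE)
  }
  if (!is.null(cfg[["coupling_file"]])) {
    f <- cfg[["coupling_file"]]
    if (!file.exists(f)) f <- file.path(base_dir, cfg[["coupling_file"]])
    if (!file.exists(f)) stop("config key 'coupling_file': file not found: ",
                              cfg[["coupling_file"]], call. = FALSE)
    cfg$coupling <- read_coupling(f)
  }
  if (!is.null(cfg[["coupling"]]) && !is.matrix(cfg[["coupling"]])) {
    cfg$coupling <- do.call(rbind, cfg[["coupling"]])
  }
  if (cfg$kind != "composed" && is.null(cfg[["coupling"]])) {
    stop("config needs 'coupling' or 'coupling_file'", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Save a configuration as YAML
#' @param cfg a `run_config` (or plain list).
#' @param path output file.
#' @export
save_config <- function(cfg, path) {
  cfg <- unclass(cfg)
  if (!is.null(cfg[["coupling"]]) && is.matrix(cfg[["coupling"]])) {
    cfg$coupling <- apply(cfg[["coupling"]], 1, as.numeric, simplify = FALSE)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Execute a validated configuration
#'
#' @param cfg a `run_config`.
#' @return the simulation result of the kind the configuration describes.
#' @export
run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  switch(cfg$kind,
    "spiking-network" = {
      p <- network_params(cfg[["coupling"]], tau_s = cfg[["tau_s"]], k = cfg[["k"]])
      inp <- if (!is.null(cfg[["input_breaks"]])) {
        input_schedule(cfg[["input_breaks"]],
                       do.call(rbind, cfg[["input_values"]]))
      } else if (!is.null(cfg[["input"]])) cfg[["input"]] else 0
      simulate_network(p, inp, duration = cfg$duration, dt = cfg$dt,
                       seed = cfg$seed)
    },
    "phase-network" = {
      net <- phase_network(2 * pi / cfg[["period"]], cfg[["coupling"]],
                           tau_c = cfg[["tau_c"]])
      simulate_phase_coupled(net, cfg$duration, seed = cfg$seed)
    },
    "composed" = {
      skel <- if (!is.null(cfg[["skeleton_file"]])) {
        mode_skeleton(read_coupling(cfg[["skeleton_file"]]),
                      as.integer(cfg$counts))
      } else canonical_skeleton(as.integer(cfg$counts))
      net <- build_multifunctional(skel)
      sch <- canonical_schedule(pulse_amp = cfg[["pulse_amp"]] %||% 12,
                                pulses = isTRUE(cfg[["pulses"]] %||% TRUE))
      run_schedule(net, sch, seed = cfg$seed, dt = cfg$dt)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the canonical experiment fixtures
#'
#' Emits the inputs (coupling matrix files plus a validated configuration)
#' of the package's reference experiments, so that each one can be rerun
#' from files alone.
#'
#' @param name one of `"two-node-fixed-point"`, `"two-node-limit-cycle"`,
#'   `"two-node-bistable"`, `"two-node-monostable"`, `"heteroclinic"`,
#'   `"sync"`, `"timing"`, `"composed"`.
#' @param dir output directory (created if needed).
#' @return the validated `run_config`, invisibly; files are written under
#'   `dir`.
#' @export
make_fixture <- function(name, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  two_node <- c("two-node-fixed-point", "two-node-limit-cycle",
                "two-node-bistable", "two-node-monostable")
  cfg <- if (name %in% two_node) {
    kind <- sub("two-node-", "", name)
    par <- canonical_two_node(kind)
    write_coupling(par$coupling, file.path(dir, "coupling.txt"))
    list(kind = "spiking-network", coupling_file = "coupling.txt",
         input = par$input, duration = 1000, seed = 1L)
  } else if (name == "heteroclinic") {
    write_coupling(heteroclinic_matrix(1, 0.3, 0.5),
                   file.path(dir, "coupling.txt"))
    list(kind = "spiking-network", coupling_file = "coupling.txt",
         input = c(1, 1, 1), duration = 1000, seed = 1L)
  } else if (name == "sync") {
    net <- canonical_sync_network(0.5)
    write_coupling(net$coupling, file.path(dir, "coupling.txt"))
    list(kind = "phase-network", coupling_file = "coupling.txt",
         period = 20, duration = 2000, seed = 3L)
  } else if (name == "timing") {
    net <- canonical_timing_network("synchrony")
    write_coupling(net$coupling, file.path(dir, "coupling.txt"))
    list(kind = "phase-network", coupling_file = "coupling.txt",
         period = 20, duration = 2000, seed = 1L)
  } else if (name == "composed") {
    skel <- canonical_skeleton()
    write_coupling(skel$coupling, file.path(dir, "skeleton.txt"))
    list(kind = "composed", skeleton_file = "skeleton.txt",
         counts = skel$counts, duration = 1800, seed = 1L)
  } else {
    stop("unknown fixture name: ", name, call. = FALSE)
  }
  cfg <- validate_config(cfg, base_dir = dir)
  save_config(cfg[names(cfg) != "coupling"], file.path(dir, "config.yaml"))
  invisible(cfg)
}

#' Write simulation outputs as delimited text
#'
#' Trajectories go to `trajectory.csv` (header
#' `t, theta_0..theta_{n-1}, omega_0..omega_{n-1}`, times in ms), spikes to
#' `spikes.csv` (two columns `t_ms, neuron_index`, zero-based, sorted by
#' time), and a manifest with the configuration, seed and package version
#' to `manifest.yaml`.
#'
#' @param sim a [simulate_network()] result.
#' @param dir output directory (created if needed).
#' @param cfg optional `run_config` recorded in the manifest.
#' @return character vector of the files written.
#' @export
write_outputs <- function(sim, dir, cfg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(sim$theta)
  traj_path <- file.path(dir, "trajectory.csv")
  header <- paste(c("t", paste0("theta_", seq_len(n) - 1),
                    paste0("omega_", seq_len(n) - 1)), collapse = ",")
  rows <- if (length(sim$time)) {
    df <- cbind(sim$time, t(sim$theta), t(sim$omega))
    apply(df, 1, function(r) paste(format(r, digits = 15, trim = TRUE),
                                   collapse = ","))
  } else character(0)
  writeLines(c(header, rows), traj_path)

  spk_path <- file.path(dir, "spikes.csv")
  spk <- sim$spikes[order(sim$spikes$t), , drop = FALSE]
  writeLines(c("t_ms,neuron_index",
               if (nrow(spk)) paste(format(spk$t, digits = 15, trim = TRUE),
                                    spk$neuron - 1L, sep = ",")),
             spk_path)

  man_path <- file.path(dir, "manifest.yaml")
  man <- list(
    package = "sfmnet",
    version = as.character(utils::packageVersion("sfmnet")),
    seed = sim$seed, dt = sim$dt,
    config = if (!is.null(cfg)) unclass(cfg))
  if (!is.null(man$config$coupling) && is.matrix(man$config$coupling)) {
    man$config$coupling <- apply(man$config$coupling, 1, as.numeric,
                                 simplify = FALSE)
  }
  yaml::write_yaml(man, man_path)
  c(traj_path, spk_path, man_path)
}

#' Read back a trajectory file
#' @param path `trajectory.csv` as written by [write_outputs()].
#' @return data frame.
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Read back a spikes file
#' @param path `spikes.csv` as written by [write_outputs()].
#' @return data frame with columns `t_ms`, `neuron_index`.
#' @export
read_spikes <- function(path) {
  utils::read.csv(path)
}

#' Serialise a flow report as structured text
#'
#' @param report a `flow_report`.
#' @param path output file, or `NULL` to return the lines.
#' @return the lines, invisibly when written.
#' @export
write_flow_report <- function(report, path = NULL) {
  fp <- report$fixed_points
  lines <- c(
    paste("classification:", report$classification),
    paste("oscillatory:", isTRUE(report$oscillatory)),
    paste("n_fixed_points:", nrow(fp)),
    if (nrow(fp)) {
      c("fixed_points:",
        apply(fp, 1, function(r) {
          paste0("  - ", paste(names(fp), format(unname(r), digits = 8),
                               sep = "=", collapse = " "))
        }))
    },
    if (length(report$protocol)) {
      c(paste("large_kick_amplification:",
              format(report$protocol$large$amplification, digits = 6)),
        paste("large_kick_returned:", report$protocol$large$returned))
    }
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
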