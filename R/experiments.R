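## Config-driven experiment runner and figure-style scenario presets.

preset_table <- function() list(
  fig3A = list(module = "invasion",
               drive = list(n_daisy = 2, delta = 0.95, s_d = 0.1, R = 0.5),
               valley = list(s_t = 0.9, s_p = 0.2, r = 0.5),
               grid = list(s_p = seq(0, 0.6, by = 0.02),
                           s_t = c(0.1, 0.5, 0.9))),
  fig3B = list(module = "single", generations = 100,
               drive = list(n_daisy = 2, delta = 0.95, s_d = 0.1, R = 0.5),
               valley = list(s_t = 0, s_p = 0.2, r = 0.5,
                             valley_mode = "cargo_only"),
               release = list(f0 = 0.1, gamete = "ABCd")),
  fig3C = list(module = "single", generations = 100,
               drive = list(n_daisy = 2, delta = 0.95, s_d = 0.1, R = 0.5),
               valley = list(s_t = 0.9, s_p = 0.2, r = 0.5),
               release = list(f0 = 0.1, gamete = "full")),
  fig3D = list(module = "single", generations = 100,
               drive = list(n_daisy = 2, delta = 0.95, s_d = 0.1, R = 0.5),
               valley = list(s_t = 0, s_p = 0.2, r = 0.5,
                             valley_mode = "cargo_only"),
               release = list(f0 = 0.03, gamete = "ABCd")),
  fig3E = list(module = "single", generations = 100,
               drive = list(n_daisy = 2, delta = 0.95, s_d = 0.1, R = 0.5),
               valley = list(s_t = 0.9, s_p = 0.2, r = 0.5),
               release = list(f0 = 0.03, gamete = "full")),
  fig4A = list(module = "valley_crossing", generations = 100,
               drive = list(n_daisy = 2, delta = 0.8, s_d = 0.1, R = 0.5),
               valley = list(s_t = 0.9, s_p = 0.2, r = 0.5),
               release = list(f0 = 0.05, gamete = "full"),
               grid = list(s_p = seq(0.02, 0.5, by = 0.04),
                           s_t = seq(0.1, 0.9, by = 0.1))),
  fig4B = list(module = "valley_crossing", generations = 100,
               drive = list(n_daisy = 2, delta = 0.95, s_d = 0.1, R = 0.5),
               valley = list(s_t = 0.9, s_p = 0.2, r = 0.5),
               release = list(f0 = 0.05, gamete = "full"),
               grid = list(s_p = seq(0.02, 0.5, by = 0.04),
                           s_t = seq(0.1, 0.9, by = 0.1))),
  fig5A = list(module = "metapop", generations = 1000,
               drive = list(n_daisy = 2, delta = 0.9, s_d = 0.02, R = 0.5),
               valley = list(s_t = 0.9, s_p = 0.1, r = 0.5),
               metapop = list(M = 101, m = 0.025),
               release = list(f0 = 0.05, gamete = "full")),
  fig5B = list(module = "metapop", generations = 1000,
               drive = list(n_daisy = 2, delta = 0.9, s_d = 0.02, R = 0.5),
               valley = list(s_t = 0.9, s_p = 0.1, r = 0.5),
               metapop = list(M = 101, m = 0.00005),
               release = list(f0 = 0.05, gamete = "full")),
  fig5C = list(module = "migration_sweep", generations = 1000,
               drive = list(n_daisy = 2, delta = 0.9, s_d = 0.02, R = 0.5),
               valley = list(s_t = 0.9, s_p = 0.1, r = 0.5),
               metapop = list(M = 101, m = 0.01),
               release = list(f0 = 0.05, gamete = "full"),
               m_grid = c(0.00005, 0.0005, 0.005, 0.02, 0.05, 0.08, 0.12)),
  fig7 = list(module = "continuous", Tgen = 1200,
              drive = list(n_daisy = 2, delta = 0.9, s_d = 0.02, R = 0.5),
              valley = list(s_t = 0.9, s_p = 0.35, r = 0.5),
              landscape = list(L = 200, dx = 0.25, D = 0.2, dt = 0.1,
                               boundaries = 400),
              release = list(f0 = 1, gamete = "full")),
  s7 = list(module = "stochastic", generations = 150,
            drive = list(n_daisy = 2, delta = 0.9, s_d = 0.02, R = 0.5),
            valley = list(s_t = 0.9, s_p = 0.1, r = 0.5),
            demography = list(K = 10000, F = 1.2, m = 0.05, replicates = 50),
            metapop = list(M = 5, m = 0.05),
            release = list(f0 = 0.05, gamete = "full")),
  s8 = list(module = "stochastic", generations = 150,
            drive = list(n_daisy = 2, delta = 0.9, s_d = 0.02, R = 0.5),
            valley = list(s_t = 0.9, s_p = 0.1, r = 0.5),
            demography = list(K = 10000, F = 1.05, m = 0.05, replicates = 50),
            metapop = list(M = 5, m = 0.05),
            release = list(f0 = 0.05, gamete = "full")),
  s11 = list(module = "patchiness", Tgen = 400,
             drive = list(n_daisy = 2, delta = 0.9, s_d = 0.02, R = 0.5),
             valley = list(s_t = 0.9, s_p = 0.1, r = 0.5),
             step_sizes = c(0.25, 0.5, 1, 2, 3),
             s_p_values = c(0.1, 0.2, 0.35))
)

#' Figure-style scenario presets
#'
#' Returns a ready-made experiment configuration for the named scenario
#' (single-population trajectories, valley-crossing grids, stepping-stone
#' runs and sweeps, the continuous-space comparison, stochastic
#' modification/suppression, and the patchiness sweep), with the parameter
#' values of the corresponding published scenario.
#'
#' @param name Preset name; call \code{dqd_preset()} with no argument to
#'   list the available names.
#' @param seed Seed stored in the configuration (default 1).
#' @return An experiment configuration list (class
#'   \code{"dqd_experiment_config"}).
#' @examples
#' dqd_preset()
#' cfg <- dqd_preset("fig5B")
#' @export
dqd_preset <- function(name = NULL, seed = 1L) {
  tab <- preset_table()
  if (is.null(name)) return(names(tab))
  if (!name %in% names(tab))
    stop("unknown preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  cfg <- tab[[name]]
  cfg$scenario <- name
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "dqd_experiment_config")
}

config_keys <- c("scenario", "module", "seed", "generations", "Tgen",
                 "drive", "valley", "release", "metapop", "landscape",
                 "demography", "grid", "m_grid", "step_sizes", "s_p_values",
                 "out_dir")

#' Read / write experiment configurations
#'
#' Configurations are stored as YAML; unknown keys are rejected with an
#' error naming the offending key, so typos do not silently change an
#' experiment.
#'
#' @param cfg An experiment configuration list.
#' @param path File path.
#' @return \code{read_config()} returns the configuration;
#'   \code{write_config()} returns \code{path} invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  structure(cfg, class = "dqd_experiment_config")
}

validate_config <- function(cfg) {
  bad <- setdiff(names(cfg), config_keys)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$module)) stop("configuration lacks a 'module'", call. = FALSE)
  invisible(cfg)
}

cfg_model <- function(cfg) {
  drive <- if (!is.null(cfg$drive)) do.call(drive_params, cfg$drive)
  valley <- do.call(valley_params, cfg$valley)
  daisy_quorum_model(drive, valley)
}

#' Run a configured experiment
#'
#' Executes the scenario described by an experiment configuration (a
#' [dqd_preset()] or a configuration read with [read_config()]), writes the
#' outputs as long-format CSV files, and writes a JSON manifest recording
#' the configuration, seed, package version and wall time, sufficient to
#' re-run the experiment exactly.
#'
#' @param cfg Experiment configuration (or a preset name).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the output \code{files} and the
#'   \code{manifest} path.
#' @examples
#' \donttest{
#' res <- run_experiment(dqd_preset("fig3C"), out_dir = tempfile())
#' }
#' @export
run_experiment <- function(cfg, out_dir = ".") {
  if (is.character(cfg)) cfg <- dqd_preset(cfg)
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed %||% 1L)
  t0 <- Sys.time()
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(cfg$scenario %||% cfg$module, "_", name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  switch(cfg$module,
    single = {
      model <- cfg_model(cfg)
      rel <- release_spec(cfg$release$f0, cfg$release$gamete %||% "full")
      tr <- simulate_population(model, rel, cfg$generations)
      emit(as.data.frame(tr), "gametes")
      af <- allele_trajectory(tr)
      long <- data.frame(generation = rep(af$generation, ncol(af) - 1),
                         allele = rep(names(af)[-1], each = nrow(af)),
                         frequency = unlist(af[-1], use.names = FALSE))
      emit(long, "alleles")
    },
    invasion = {
      g <- expand.grid(s_p = cfg$grid$s_p, s_t = cfg$grid$s_t)
      g$delta_c_star <- mapply(function(sp, st)
        critical_drive_force(valley_params(s_t = st, s_p = sp,
                                           r = cfg$valley$r %||% 0.5)),
        g$s_p, g$s_t)
      emit(g, "critical_drive")
    },
    valley_crossing = {
      g <- expand.grid(s_p = cfg$grid$s_p, s_t = cfg$grid$s_t)
      g$final_C <- mapply(function(sp, st) {
        v <- cfg$valley; v$s_p <- sp; v$s_t <- st
        cfg2 <- cfg; cfg2$valley <- v
        model <- cfg_model(cfg2)
        tr <- simulate_population(model, cfg$release$f0, cfg$generations)
        af <- allele_trajectory(tr)
        af$C[nrow(af)]
      }, g$s_p, g$s_t)
      emit(g, "final_C")
    },
    metapop = {
      model <- cfg_model(cfg)
      mp <- do.call(metapop_config, c(cfg$metapop,
                                      list(release = cfg$release$f0)))
      sp <- run_spread(model, mp, cfg$generations)
      df <- data.frame(generation = rep(sp$times, each = mp$M),
                       patch = rep(seq_len(mp$M), length(sp$times)),
                       payload_frequency = as.vector(sp$payload))
      emit(df, "payload_field")
    },
    migration_sweep = {
      model <- cfg_model(cfg)
      mp <- do.call(metapop_config, c(cfg$metapop,
                                      list(release = cfg$release$f0)))
      emit(migration_sweep(model, cfg$m_grid, mp, cfg$generations), "sweep")
    },
    continuous = {
      model <- cfg_model(cfg)
      ls_args <- cfg$landscape
      bnd <- ls_args$boundaries; ls_args$boundaries <- NULL
      land_h <- do.call(build_landscape, ls_args)
      fld <- run_reaction_diffusion(model, land_h, cfg$Tgen)
      ws <- asymptotic_wave_speed(fld)
      land_het <- do.call(build_landscape,
                          c(ls_args, list(boundaries = bnd, seed = cfg$seed)))
      fld2 <- run_reaction_diffusion(model, land_het, cfg$Tgen)
      ws2 <- asymptotic_wave_speed(fld2)
      emit(data.frame(time = c(fld$times, fld2$times),
                      landscape = rep(c("homogeneous", "heterogeneous"),
                                      c(length(fld$times), length(fld2$times))),
                      front_left = c(fld$front_left, fld2$front_left)),
           "fronts")
      emit(data.frame(landscape = c("homogeneous", "heterogeneous"),
                      speed = c(ws$speed, ws2$speed)), "speeds")
    },
    stochastic = {
      model <- cfg_model(cfg)
      demo <- do.call(demography_params, c(cfg$demography,
                                           list(seed = cfg$seed %||% 1L)))
      emit(run_replicates(model, demo, M = cfg$metapop$M %||% 1,
                          f0 = cfg$release$f0,
                          generations = cfg$generations), "replicates")
    },
    patchiness = {
      base_valley <- cfg$valley
      drv <- cfg$drive
      model_for <- function(sp) {
        v <- base_valley; v$s_p <- sp
        daisy_quorum_model(do.call(drive_params, drv), do.call(valley_params, v))
      }
      emit(patchiness_sweep(model_for, cfg$step_sizes, cfg$s_p_values,
                            Tgen = cfg$Tgen), "speeds")
    },
    stop("unknown module '", cfg$module, "'", call. = FALSE)
  )
  manifest <- list(scenario = cfg$scenario, config = unclass(cfg),
                   seed = cfg$seed %||% 1L,
                   package_version = as.character(utils::packageVersion("daisyquorum")),
                   wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                   files = files)
  mpath <- file.path(out_dir, paste0(cfg$scenario %||% cfg$module, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(files = files, manifest = mpath))
}

#' Random fixtures for property-based testing
#'
#' Generates random valid gamete-frequency states and random parameter sets
#' within their documented ranges, together with the published parameter
#' presets, for use by the test suite.
#'
#' @param seed Integer seed.
#' @param n_states Number of random states per architecture.
#' @return A list with \code{states} (for 2- and 4-locus systems),
#'   \code{params} (random drive/valley parameter sets), and
#'   \code{presets}.
#' @export
generate_fixtures <- function(seed = 1L, n_states = 20) {
  set.seed(seed)
  rstate <- function(G) {
    x <- stats::rexp(G)
    x / sum(x)
  }
  rparams <- function() list(
    drive = drive_params(n_daisy = sample(1:3, 1), delta = stats::runif(1),
                         s_d = stats::runif(1, 0, 0.5), R = stats::runif(1, 0, 0.5)),
    valley = valley_params(s_t = stats::runif(1), s_p = stats::runif(1, 0, 0.8),
                           r = stats::runif(1, 0, 0.5)))
  list(states = list(valley = replicate(n_states, rstate(4), simplify = FALSE),
                     four_locus = replicate(n_states, rstate(16), simplify = FALSE)),
       params = replicate(n_states, rparams(), simplify = FALSE),
       presets = list(
         fig3 = list(drive = drive_params(2, 0.95, 0.1, 0.5),
                     valley = valley_params(0.9, 0.2, 0.5)),
         fig5 = list(drive = drive_params(2, 0.9, 0.02, 0.5),
                     valley = valley_params(0.9, 0.1, 0.5))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
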