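#' Read a pipeline configuration
#'
#' Accepts a YAML or JSON file (by extension) or a ready-made list. The
#' configuration may contain a `seed`, a `network` block mirroring
#' [network_params()] field names, a `protocol` block mirroring
#' [stimulus_protocol()], `generator` blocks passed to
#' [generator_config()], and a `stages` character vector.
#'
#' @param config path or list.
#' @return validated configuration list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config error: file not found: ", config, call. = FALSE)
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      yaml = , yml = yaml::read_yaml(config),
      json = jsonlite::read_json(config, simplifyVector = TRUE),
      stop("config error: unsupported config format '.", ext, "'", call. = FALSE))
  }
  if (!is.list(config)) stop("config error: not a list", call. = FALSE)
  if (is.null(config$seed)) stop("config error: field 'seed' is required",
                                 call. = FALSE)
  known <- c("seed", "network", "protocol", "generator", "stages")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("config error: unknown field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (is.null(config$stages)) config$stages <- c("network", "whisker", "spatial")
  bad <- setdiff(config$stages, c("network", "whisker", "spatial"))
  if (length(bad))
    stop("config error: unknown stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  config
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages (network model, whisker-overlap geometry,
#' spatial statistics) on synthetic inputs, writes all outputs as CSV/JSON
#' under `out_dir`, and emits a run manifest. All randomness flows from the
#' configured seed; re-running with the same configuration reproduces the
#' outputs bit-identically.
#'
#' @param config list or config-file path (see [read_pipeline_config()]).
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return the manifest (invisibly), also written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  outputs <- character(0)
  wr <- function(obj, name) {
    path <- file.path(out_dir, name)
    if (grepl("\\.csv$", name)) {
      utils::write.csv(obj, path, row.names = FALSE)
    } else {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
    }
    outputs <<- c(outputs, name)
    path
  }

  params <- do.call(network_params, as.list(cfg$network %||% list()))
  protocol <- do.call(stimulus_protocol, as.list(cfg$protocol %||% list()))
  gcfg <- do.call(generator_config,
                  c(list(seed = cfg$seed), as.list(cfg$generator %||% list())))

  if ("network" %in% cfg$stages) {
    say("[network] simulating default protocol (seed %s)", cfg$seed)
    tr <- simulate_network(params, protocol, keep_every = 100L)
    wr(data.frame(time = tr$times, A_P = tr$A_P, A_F = tr$A_F),
       "network_trajectory.csv")
    ss <- steady_states_from_simulation(tr)
    reg <- classify_regime(params)
    sup <- suppression_analytic(params)
    wr(list(steady_state_v = as.list(ss$v), steady_state_vw = as.list(ss$vw),
            suppression = list(dA_P = sup[["dA_P"]], dA_F = sup[["dA_F"]],
                               valid = attr(sup, "valid")),
            regime = unclass(reg)),
       "network_summary.json")
    say("[network] sweeping I_cm, theta_P, alpha and the gain plane")
    wr(sweep_network(params, "I_cm", seq(0, 1.2, by = 0.05)), "sweep_I_cm.csv")
    wr(sweep_network(params, "theta_P", seq(0.3, 0.9, by = 0.025)),
       "sweep_theta_P.csv")
    wr(sweep_network(params, "alpha", seq(1, 4, by = 0.125)), "sweep_alpha.csv")
    wr(sweep_network(params, "G_P", seq(0.25, 2.5, by = 0.25),
                     "G_F", seq(0.5, 8, by = 0.5)), "sweep_gains.csv")
  }

  if ("whisker" %in% cfg$stages) {
    say("[whisker] posing synthetic array and measuring overlap")
    arr <- gen_whisker_array(gcfg)
    map <- gen_visual_space(gcfg, dilation = 20)
    scen <- list(retraction = -40, intermediate = 0, protraction = 40)
    overlap <- lapply(scen, function(a)
      tips_in_space(pose_array(arr, a), map)$fraction)
    wr(overlap, "whisker_overlap.json")
    unc <- lapply(arr$whiskers, propagate_tip_uncertainty)
    wr(data.frame(id = vapply(unc, `[[`, character(1), "id"),
                  sphere_radius = vapply(unc, `[[`, numeric(1), "sphere_radius")),
       "tip_uncertainty.csv")
    wr(arc_summary(pose_array(arr, 40)), "arc_summary_protraction.csv")
  }

  if ("spatial" %in% cfg$stages) {
    say("[spatial] PCA parcellation, density map, barrel test")
    cloud <- gen_cell_cloud(gcfg)
    axes <- pca_axes(as.matrix(cloud[, c("x", "y")]))
    parc <- parcellate(as.matrix(cloud[, c("x", "y")]), axes)
    wr(parc$parcels, "parcels.csv")
    dm <- density_map(as.matrix(cloud[, c("x", "y")]))
    wr(list(argmax = as.list(dm$argmax),
            explained = axes$explained), "spatial_summary.json")
    bg <- gen_barrel_map(gcfg)
    pt <- barrel_permutation_test(bg$cells, bg$map, seed = cfg$seed + 1)
    wr(data.frame(barrel = rownames(pt$fr_obs), pt$fr_obs, p = pt$p,
                  check.names = FALSE), "barrel_test.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tactovis")),
    seed = cfg$seed,
    stages = cfg$stages,
    config = cfg,
    config_hash = config_hash(cfg),
    out_dir = normalizePath(out_dir),
    outputs = outputs,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("pipeline done: %d output files in %s", length(outputs), out_dir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# order-stable polynomial checksum of the canonical JSON serialization
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
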