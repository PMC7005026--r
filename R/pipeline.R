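# Orchestration: a single structured config drives any subset of the
# stages (synthetic or file-based inputs), producing a machine-readable
# report with full provenance. A failing stage is recorded and isolated;
# it never silently zero-fills results or takes down the other stages.

# tiny polynomial content hash for provenance (hex string)
.config_hash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                      force = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}

.stage <- function(report, name, expr) {
  res <- tryCatch(expr, error = function(e)
    structure(list(message = conditionMessage(e)), class = "stage_error"))
  if (inherits(res, "stage_error")) {
    report$errors[[name]] <- res$message
  } else {
    report[[name]] <- res
  }
  report
}

.get_traj <- function(cmp, default_seed) {
  if (!is.null(cmp$trajectory)) {
    read_trajectory(cmp$trajectory, cmp$topology, label = cmp$label)
  } else {
    gen <- cmp$generator
    stop_if(is.null(gen), paste0("composition '", cmp$label,
                                 "' has neither a trajectory nor a generator"))
    if (is.null(gen$seed)) gen$seed <- default_seed
    spec <- do.call(bilayer_gen_spec, gen)
    generate_bilayer(spec, n_frames = cmp$n_frames %||% 5,
                     label = cmp$label)
  }
}

#' Run the composition-comparison pipeline
#'
#' Executes the stages named in a structured config -- bilayer density
#' maps and band statistics per composition with difference maps against a
#' reference, bilayer descriptors, rotamer-state populations, the
#' spectroscopy reductions, and the liposome molarity model -- in
#' dependency order, deterministically under the configured seeds. See the
#' package vignette for the config schema; \code{\link{demo_config}}
#' returns a complete synthetic example.
#'
#' @param config a named list, or the path to a YAML file with the same
#'   structure.
#' @return an \code{analysis_report}: nested list with one entry per
#'   executed stage, a \code{provenance} block (package version, seed,
#'   config hash), and an \code{errors} block naming any failed stages.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  report <- list(
    provenance = list(
      package = "memprofiler",
      version = as.character(utils::packageVersion("memprofiler")),
      seed = seed,
      config_hash = .config_hash(config)),
    errors = list())

  if (!is.null(config$compositions)) {
    report <- .stage(report, "compositions", {
      band <- config$density$band %||% c(3, 10)
      ve <- config$density$voxel_edge %||% 1
      conv <- config$props$order_convention %||% "segment"
      maps <- list(); out <- list()
      for (cmp in config$compositions) {
        traj <- center_and_wrap(.get_traj(cmp, seed))
        map <- voxel_density(traj, voxel_edge = ve)
        maps[[cmp$label]] <- map
        bs <- band_statistic(map, band[1], band[2])
        apl <- area_per_lipid(traj)
        th <- thickness(traj)
        op <- order_parameters(traj, conv)
        out[[cmp$label]] <- list(
          band_density_mean_A3 = bs$mean, band_density_sd_A3 = bs$sd,
          area_per_lipid_A2 = apl$mean, area_per_lipid_sd_A2 = apl$sd,
          thickness_A = th$mean, thickness_sd_A = th$sd,
          order_S_mean = mean(op$S))
      }
      ref <- config$density$reference %||% names(maps)[1]
      stop_if(!ref %in% names(maps),
              paste0("reference composition '", ref, "' not found"))
      for (lbl in setdiff(names(maps), ref)) {
        dm <- difference_map(maps[[lbl]], maps[[ref]])
        bs <- band_statistic(dm, band[1], band[2])
        out[[lbl]]$band_difference_vs_reference_A3 <- bs$mean
      }
      attr(out, "reference") <- ref
      out
    })
  }

  if (!is.null(config$rotamer)) {
    report <- .stage(report, "rotamer", {
      rc <- config$rotamer
      dtraj <- if (!is.null(rc$pdb))
        read_dimer_pdb(rc$pdb, rc$sensor_index %||% 15)
      else {
        gen <- rc$generator
        stop_if(is.null(gen), "rotamer stage needs a pdb or a generator")
        if (is.null(gen$seed)) gen$seed <- seed
        gen$state_weights <- as.numeric(gen$state_weights)
        generate_dimer(do.call(dimer_gen_spec, gen))
      }
      series <- analyze_dimer(dtraj,
                              facing_threshold = rc$facing_threshold %||% 60)
      pops <- state_populations(series, n_boot = rc$n_boot %||% 500,
                                seed = seed)
      list(populations = pops, n_frames = nrow(series),
           n_flagged = sum(series$flagged))
    })
  }

  sp <- config$spectroscopy
  if (!is.null(sp)) {
    if (!is.null(sp$gp)) report <- .stage(report, "gp", {
      spec <- if (!is.null(sp$gp$file)) read_emission_csv(sp$gp$file)
      else generate_emission_spectrum(sp$gp$bands,
                                      noise_sd = sp$gp$noise_sd %||% 0,
                                      seed = seed)
      list(gp = gp(spec))
    })
    if (!is.null(sp$fret)) report <- .stage(report, "fret", {
      spec <- if (!is.null(sp$fret$file)) read_emission_csv(sp$fret$file)
      else generate_emission_spectrum(sp$fret$bands,
                                      grid = seq(500, 700, by = 1),
                                      noise_sd = sp$fret$noise_sd %||% 0,
                                      seed = seed, excitation = 488)
      if (!is.null(sp$fret$acceptor_file))
        spec <- acceptor_normalize(spec,
                                   read_emission_csv(sp$fret$acceptor_file))
      list(e_rel = fret_erel(spec))
    })
    if (!is.null(sp$fcs)) report <- .stage(report, "fcs", {
      curve <- if (!is.null(sp$fcs$file)) read_fcs_csv(sp$fcs$file)
      else generate_fcs_curve(N = sp$fcs$N %||% 10,
                              tau_D = sp$fcs$tau_D %||% 1e-3,
                              T = sp$fcs$T %||% 0.2,
                              tau_T = sp$fcs$tau_T %||% 5e-6,
                              noise_sd = sp$fcs$noise_sd %||% 0.01,
                              seed = seed)
      fit <- fit_fcs(curve)
      out <- list(converged = fit$converged,
                  N = unname(fit$estimate[["N"]]),
                  tau_D_s = unname(fit$estimate[["tau_D"]]),
                  T = unname(fit$estimate[["T"]]),
                  tau_T_s = unname(fit$estimate[["tau_T"]]))
      if (!is.null(sp$fcs$beam_waist_um))
        out$D_um2_s <- diffusion_coefficient(out$tau_D_s,
                                             sp$fcs$beam_waist_um)
      out
    })
    if (!is.null(sp$epr)) report <- .stage(report, "epr", {
      spec <- if (!is.null(sp$epr$file)) read_epr_csv(sp$epr$file)
      else generate_epr_spectrum(
        broadening = sp$epr$broadening %||% 0,
        amplitudes = as.numeric(sp$epr$amplitudes %||% c(0.8, 1.0, 0.6)),
        noise_sd = sp$epr$noise_sd %||% 0, seed = seed)
      list(proximity_index = epr_proximity_index(spec))
    })
  }

  if (!is.null(config$liposome)) {
    report <- .stage(report, "liposome", {
      lc <- config$liposome
      comp <- if (is.data.frame(lc$composition)) lc$composition
      else do.call(rbind, lapply(lc$composition, as.data.frame))
      spec <- liposome_spec(
        diameter_nm = lc$diameter_nm %||% 200,
        thickness_nm = lc$thickness_nm %||% 4,
        area_per_lipid_nm2 = lc$area_per_lipid_nm2 %||% 0.65,
        composition = comp,
        lipid_count = lc$lipid_count,
        membrane_volume_l = lc$membrane_volume_l)
      list(membrane_volume_l = membrane_volume(spec),
           lipid_count = lipid_count(spec),
           unsaturated_chain_molarity_M = unsaturated_chain_molarity(spec))
    })
  }

  class(report) <- c("analysis_report", "list")
  report
}

#' Write an analysis report as JSON
#'
#' @param report an \code{analysis_report}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' A complete synthetic demo configuration
#'
#' Three bilayer compositions (cis-analog reference, saturated/trans
#' analog, PE analog), a three-state dimer mixture, one of each
#' spectroscopy input, and the canonical 200 nm liposome -- all generated,
#' nothing read from disk.
#'
#' @param seed master seed recorded in the report.
#' @param lipids_per_leaflet system size of the synthetic bilayers.
#' @param n_frames frames per bilayer trajectory.
#' @return a config list for \code{\link{run_pipeline}}.
#' @export
demo_config <- function(seed = 1L, lipids_per_leaflet = 49, n_frames = 4) {
  base <- list(lipids_per_leaflet = lipids_per_leaflet,
               area_per_lipid = 64, seed = seed)
  pe <- base; pe$headgroup_atom_count <- 5; pe$area_per_lipid <- 60
  list(
    seed = seed,
    compositions = list(
      list(label = "cis_analog",
           generator = c(base, fraction_kinked_chains = 1),
           n_frames = n_frames),
      list(label = "saturated_analog",
           generator = c(base, fraction_kinked_chains = 0),
           n_frames = n_frames),
      list(label = "pe_analog",
           generator = c(pe, fraction_kinked_chains = 1),
           n_frames = n_frames)),
    density = list(voxel_edge = 1, band = c(3, 10),
                   reference = "cis_analog"),
    props = list(order_convention = "segment"),
    rotamer = list(generator = list(state_weights = c(0.5, 0.3, 0.2),
                                    n_frames = 2000, seed = seed),
                   n_boot = 200),
    spectroscopy = list(
      gp = list(bands = list(c(430, 12, 1), c(500, 14, 0.6))),
      fret = list(bands = list(c(525, 12, 1), c(614, 14, 0.5))),
      fcs = list(N = 10, tau_D = 1e-3, T = 0.2, tau_T = 5e-6,
                 noise_sd = 0.01),
      epr = list(broadening = 0.3, amplitudes = c(0.8, 1.0, 0.6))),
    liposome = list(diameter_nm = 200, composition = data.frame(
      species = c("DOPC", "POPC"), mol_fraction = c(0.5, 0.5),
      chains = c(2, 2), unsat_chains = c(2, 1))))
}
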