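## Study orchestration: configuration handling and the four-arm
## plaque/no-plaque x Newtonian/generalized-power-law study.

.all_arms <- c("plaque_newtonian", "plaque_gpl",
               "noplaque_newtonian", "noplaque_gpl")

#' Default study configuration
#'
#' The full four-arm study at the default geometry, plaques, waveform and
#' solver schedule.
#'
#' @param out_dir Output directory.
#' @return A \code{study_config} object.
#' @export
default_study_config <- function(out_dir = "coroflow_out") {
  structure(list(
    geometry = vessel_spec(),
    plaques = default_plaques(),
    waveform = list(source = "default", harmonics = 8,
                    peak_inlet_velocity = 0.017, csv = NULL),
    solver = solver_config(),
    rheology = list(newtonian = newtonian_model(), gpl = gpl_model()),
    mesh = list(h = 0.15, seed = 1L),
    arms = .all_arms,
    report_times = c(0.4, 0.7),
    output = list(dir = out_dir, fields = "reporting")),
    class = "study_config")
}

#' Validate and load a study configuration file
#'
#' Reads a YAML configuration, fills defaults for absent keys, and checks
#' every invariant (positive dimensions, stenosis fraction in [0,1), the
#' timestep schedule dt * steps_per_cycle = waveform period, known arm
#' names, referenced files existing). All violations are reported together.
#'
#' @param path YAML file (see the packaged
#'   \code{extdata/default_study.yaml} for the schema), or NULL for pure
#'   defaults.
#' @return A \code{study_config}.
#' @export
validate_config <- function(path = NULL) {
  cfg <- default_study_config()
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  if (!is.null(raw$geometry)) {
    gargs <- raw$geometry
    known <- names(formals(vessel_spec))
    bad <- setdiff(names(gargs), known)
    if (length(bad)) note(paste0("geometry: unknown key(s) ", paste(bad, collapse = ", ")))
    sp <- try(do.call(vessel_spec, gargs[intersect(names(gargs), known)]),
              silent = TRUE)
    if (inherits(sp, "try-error")) {
      note(paste0("geometry: ", attr(sp, "condition")$message))
    } else cfg$geometry <- sp
  }
  if (!is.null(raw$plaques)) {
    pls <- list()
    for (i in seq_along(raw$plaques)) {
      p <- raw$plaques[[i]]
      pl <- try(plaque_spec(branch = p$branch, center_s = p$center_s,
                            length = if (is.null(p$length)) 4 else p$length,
                            stenosis_fraction = if (is.null(p$stenosis_fraction)) 0.6
                                                else p$stenosis_fraction,
                            eccentric = isTRUE(p$eccentric)), silent = TRUE)
      if (inherits(pl, "try-error")) {
        note(sprintf("plaques[%d]: %s", i, attr(pl, "condition")$message))
      } else pls[[length(pls) + 1]] <- pl
    }
    if (!length(errs)) cfg$plaques <- pls
  }
  if (!is.null(raw$waveform)) {
    for (k in c("source", "harmonics", "peak_inlet_velocity", "csv"))
      if (!is.null(raw$waveform[[k]])) cfg$waveform[[k]] <- raw$waveform[[k]]
    if (identical(cfg$waveform$source, "csv") &&
        (is.null(cfg$waveform$csv) || !file.exists(cfg$waveform$csv)))
      note("waveform: source 'csv' but the csv file does not exist")
  }
  if (!is.null(raw$solver)) {
    sargs <- raw$solver
    known <- names(formals(solver_config))
    bad <- setdiff(names(sargs), known)
    if (length(bad)) note(paste0("solver: unknown key(s) ", paste(bad, collapse = ", ")))
    sc <- try(do.call(solver_config, sargs[intersect(names(sargs), known)]),
              silent = TRUE)
    if (inherits(sc, "try-error")) {
      note(paste0("solver: ", attr(sc, "condition")$message))
    } else cfg$solver <- sc
  }
  if (!is.null(raw$mesh)) {
    if (!is.null(raw$mesh$h)) cfg$mesh$h <- raw$mesh$h
    if (!is.null(raw$mesh$seed)) cfg$mesh$seed <- as.integer(raw$mesh$seed)
    if (cfg$mesh$h <= 0) note("mesh: h must be > 0")
  }
  if (!is.null(raw$arms)) {
    bad <- setdiff(unlist(raw$arms), .all_arms)
    if (length(bad)) {
      note(paste0("arms: unknown arm(s) ", paste(bad, collapse = ", "),
                  " (choose from ", paste(.all_arms, collapse = ", "), ")"))
    } else cfg$arms <- unlist(raw$arms)
    if (!length(cfg$arms)) note("arms: the arms list must be non-empty")
  }
  if (!is.null(raw$report_times)) cfg$report_times <- as.numeric(unlist(raw$report_times))
  if (!is.null(raw$output)) {
    if (!is.null(raw$output$dir)) cfg$output$dir <- raw$output$dir
    if (!is.null(raw$output$fields)) {
      if (!raw$output$fields %in% c("none", "reporting", "all"))
        note("output: fields must be one of none, reporting, all")
      else cfg$output$fields <- raw$output$fields
    }
  }

  wf <- try(.study_waveform(cfg), silent = TRUE)
  if (inherits(wf, "try-error")) {
    note(paste0("waveform: ", attr(wf, "condition")$message))
  } else {
    sc <- cfg$solver
    if (abs(sc$dt * sc$steps_per_cycle - wf$period) > 1e-9)
      note(sprintf(
        "solver: dt * steps_per_cycle = %g s must equal the waveform period %g s",
        sc$dt * sc$steps_per_cycle, wf$period))
    ks <- round(cfg$report_times / sc$dt)
    if (any(abs(ks * sc$dt - cfg$report_times) > 1e-9))
      note("report_times must be multiples of the solver timestep")
  }
  if (length(errs)) {
    stop("invalid study configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  cfg
}

.study_waveform <- function(cfg) {
  w <- cfg$waveform
  if (identical(w$source, "csv")) {
    read_waveform_csv(w$csv, K = w$harmonics)
  } else {
    default_waveform(K = w$harmonics, peak_inlet_velocity = w$peak_inlet_velocity)
  }
}

#' Run the full hemodynamic study
#'
#' Builds the bifurcation with and without plaques, meshes both, solves
#' every requested arm over the configured cycles, post-processes, and
#' writes the output tree: \code{report.json} and per-table CSVs,
#' per-arm residual logs, section profile CSVs and (optionally) VTK flow
#' fields at the reporting phases, plus STL surfaces of both geometries.
#' Deterministic: identical configuration gives an identical report.
#'
#' @param config A \code{study_config} from [validate_config()] /
#'   [default_study_config()].
#' @param write_outputs Write the artifact tree (otherwise just return the
#'   report and histories).
#' @param verbose Progress messages.
#' @return List with \code{report} (a \code{summary_report}),
#'   \code{histories}, \code{meshes}, \code{outlines} and \code{out_dir}.
#' @export
run_study <- function(config = default_study_config(), write_outputs = TRUE,
                      verbose = interactive()) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  inflow <- .study_waveform(config)
  need <- unique(vapply(strsplit(config$arms, "_"), `[`, "", 1))

  outlines <- list()
  meshes <- list()
  say("building geometry and meshes (h = %g mm)", config$mesh$h)
  base <- build_bifurcation(config$geometry)
  if ("noplaque" %in% need) {
    outlines$noplaque <- base
    meshes$noplaque <- generate_mesh(base, h = config$mesh$h,
                                     seed = config$mesh$seed)
  }
  if ("plaque" %in% need) {
    ol <- base
    for (pl in config$plaques) ol <- apply_plaque(ol, pl)
    assert_simple_outline(ol)
    outlines$plaque <- ol
    meshes$plaque <- generate_mesh(ol, h = config$mesh$h,
                                   seed = config$mesh$seed)
  }

  histories <- list()
  for (arm in config$arms) {
    parts <- strsplit(arm, "_")[[1]]
    geom <- parts[1]
    rheol <- config$rheology[[parts[2]]]
    say("solving arm %s (%d cycles x %d steps)", arm, config$solver$cycles,
        config$solver$steps_per_cycle)
    histories[[arm]] <- run_cycles(meshes[[geom]], config$solver, inflow,
                                   rheol, verbose = verbose)
  }

  plq <- if (length(config$plaques)) config$plaques else
    list(plaque_spec("lms", 5), plaque_spec("lad", 5.5))
  report <- summarize_study(histories, outlines, plaques = plq,
                            times = config$report_times,
                            require_all = setequal(config$arms, .all_arms))

  out_dir <- config$output$dir
  if (write_outputs) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report_to_json(report, file.path(out_dir, "report.json"))
    write_report_csv(report, file.path(out_dir, "tables"))
    write_waveform_csv(inflow, file.path(out_dir, "inlet_waveform.csv"))
    for (geom in names(meshes)) {
      export_stl(meshes[[geom]], file.path(out_dir, paste0("lumen_", geom, ".stl")))
    }
    for (arm in names(histories)) {
      hist <- histories[[arm]]
      adir <- file.path(out_dir, arm)
      dir.create(adir, showWarnings = FALSE)
      utils::write.csv(hist$log, file.path(adir, "residuals.csv"),
                       row.names = FALSE)
      geom <- strsplit(arm, "_")[[1]][1]
      secs <- define_sections(outlines[[geom]], plaques = plq)
      for (tm in config$report_times) {
        st <- state_at(hist, tm)
        if (config$output$fields %in% c("reporting", "all")) {
          export_vtk(st, hist$mesh,
                     file.path(adir, sprintf("fields_t%04.0fms.vtk", tm * 1000)))
        }
        for (i in seq_len(nrow(secs))) {
          pr <- sample_section(st, hist$mesh, secs[i, ])
          write_profile_csv(pr, file.path(
            adir, sprintf("section_%s_t%04.0fms.csv", secs$label[i], tm * 1000)))
        }
      }
      if (config$output$fields == "all") {
        for (k in seq_along(hist$states)) {
          if (!is.null(hist$states[[k]]))
            export_vtk(hist$states[[k]], hist$mesh,
                       file.path(adir, sprintf("fields_step%03d.vtk", k)))
        }
      }
    }
    say("outputs written to %s", out_dir)
  }
  list(report = report, histories = histories, meshes = meshes,
       outlines = outlines, out_dir = out_dir)
}
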