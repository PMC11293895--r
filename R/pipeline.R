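#' Run the full regulatory-metabolic coupling pipeline
#'
#' End-to-end workflow: parse the CellDesigner map, infer the Boolean model
#' (optionally restricted to a seeded subnetwork and/or forcefully
#' initialized), compute its minimal trap spaces, derive zero-flux
#' constraints for components proven asymptotically inactive, and run the
#' control and contextualized FBA (or FVA). Writes six files into `out_dir`,
#' in order:
#'
#' 1. `components.csv` — component names, logic formulae, aliases;
#' 2. `model_qual.sbml` — the Boolean model in SBML-qual;
#' 3. `model.bnet` — the Boolean model in BNET;
#' 4. `trap_spaces.csv` — all computed minimal trap spaces;
#' 5. `control_<mode>.csv` — control flux results;
#' 6. `specific_<mode>.csv` — cell-/disease-specific flux results;
#'
#' and prints both ATP-ratio summaries.
#'
#' @param map Path to a CellDesigner XML map.
#' @param metabolism Path to the metabolic SBML model.
#' @param init_csv Optional initial-conditions CSV (`component,value`).
#' @param seeds Optional seed components for subnetwork extraction.
#' @param direction Direction for the extraction (`"both"`, `"upstream"`,
#'   `"downstream"`).
#' @param mode `"fba"` (default) or `"fva"`.
#' @param out_dir Output directory, created if needed.
#' @param classification `flx_classification` for the ATP pathway split.
#' @param synonyms Optional synonym table (see [match_components()]).
#' @param objective Optional objective override passed to [fba()]/[fva()].
#' @param fraction_of_optimum FVA fraction (default 1).
#' @param quiet Suppress progress logging.
#' @return Invisibly, a list (class `flx_run`) with the network, trap
#'   spaces, mapping, constraints, both flux results and both ATP reports.
#' @export
run_pipeline <- function(map, metabolism, init_csv = NULL, seeds = NULL,
                         direction = "both", mode = c("fba", "fva"),
                         out_dir = ".",
                         classification = default_atp_classification(),
                         synonyms = NULL, objective = NULL,
                         fraction_of_optimum = 1, quiet = FALSE) {
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[fluxlogic] ", ...)

  say("parsing map: ", map)
  pd <- parse_celldesigner(map)
  say("  ", nrow(pd$species), " species, ", length(pd$reactions), " reactions")
  net <- infer_boolean(pd)
  if (!is.null(seeds)) {
    say("extracting ", direction, " subnetwork from ",
        paste(seeds, collapse = ", "))
    net <- extract_subnetwork(net, seeds, direction)
  }
  say("Boolean model: ", length(net$variables), " components")
  readr::write_csv(components_table(net, pd),
                   file.path(out_dir, "components.csv"))
  write_sbml_qual(net, file.path(out_dir, "model_qual.sbml"))
  write_bnet(net, file.path(out_dir, "model.bnet"))

  net_ic <- net
  if (!is.null(init_csv)) {
    ic <- read_initial_conditions(init_csv)
    say("applying ", length(ic), " initial condition(s)")
    net_ic <- apply_initial_conditions(net, ic)
  }
  say("computing minimal trap spaces")
  traps <- minimal_trap_spaces(net_ic)
  say("  ", nrow(traps), " minimal trap space(s)")
  write_trap_spaces(traps, file.path(out_dir, "trap_spaces.csv"))

  say("reading metabolic model: ", metabolism)
  model <- read_sbml_fbc(metabolism)
  say("  ", nrow(model$metabolites), " metabolites, ",
      nrow(model$reactions), " reactions")
  mapping <- match_components(net_ic, model, synonyms = synonyms)
  say("matched ", length(unique(mapping$component)),
      " component(s) to reactions")
  proj <- project_max(traps, unique(mapping$component))
  constraints <- extract_constraints(mapping, proj, model)
  say(nrow(constraints), " reaction(s) constrained to zero flux")
  specific_model <- apply_constraints(model, constraints)

  analyse <- function(mod) {
    if (mode == "fba") fba(mod, objective = objective)
    else fva(mod, fraction_of_optimum = fraction_of_optimum,
             objective = objective)
  }
  flux_for_ratio <- function(mod, res) {
    if (mode == "fba") list(fluxes = res, envelope = NULL)
    else list(fluxes = fba(mod, objective = objective), envelope = res)
  }
  say("control ", mode)
  control_res <- analyse(model)
  say("specific ", mode)
  specific_res <- analyse(specific_model)
  write_flux_csv(control_res,
                 file.path(out_dir, paste0("control_", mode, ".csv")))
  write_flux_csv(specific_res,
                 file.path(out_dir, paste0("specific_", mode, ".csv")))

  ctl <- flux_for_ratio(model, control_res)
  spc <- flux_for_ratio(specific_model, specific_res)
  control_atp <- atp_ratio(ctl$fluxes, model, classification,
                           envelope = ctl$envelope)
  specific_atp <- atp_ratio(spc$fluxes, specific_model, classification,
                            envelope = spc$envelope)
  cat(report_atp(control_atp, specific_atp), sep = "\n")

  invisible(structure(
    list(network = net, network_initialized = net_ic, trap_spaces = traps,
         mapping = mapping, projection = proj, constraints = constraints,
         control = control_res, specific = specific_res,
         control_atp = control_atp, specific_atp = specific_atp,
         mode = mode, out_dir = out_dir),
    class = "flx_run"))
}

#' Format the paired ATP-ratio summary
#'
#' Deterministic line-oriented text with 4-decimal ratios, one block per
#' condition; zero total production is flagged explicitly.
#'
#' @param control,specific `flx_atp_report` rows from [atp_ratio()].
#' @return Character vector of lines.
#' @export
report_atp <- function(control, specific) {
  block <- function(label, r) {
    if (r$zero_production) {
      return(c(paste0(label, ": zero ATP production")))
    }
    lines <- c(
      paste0(label, ": total_atp=", sprintf("%.4f", r$total_atp)),
      paste0(label, ": glycolytic_ratio=", sprintf("%.4f", r$ratio_glycolytic)),
      paste0(label, ": oxidative_ratio=", sprintf("%.4f", r$ratio_oxidative))
    )
    if (r$solution_dependent) {
      lines <- c(lines, paste0(label, ": ratio is solution-dependent ",
                               "(ATP producers vary across the optimal face)"))
    }
    lines
  }
  c(block("control", control), block("specific", specific))
}

#' @export
print.flx_run <- function(x, ...) {
  cat("<flx_run> mode=", x$mode, ", ", length(x$network$variables),
      " components, ", nrow(x$trap_spaces), " trap space(s), ",
      nrow(x$constraints), " constrained reaction(s)\n", sep = "")
  cat(report_atp(x$control_atp, x$specific_atp), sep = "\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.flx_run <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$network$variables),
    n_trap_spaces = nrow(x$trap_spaces),
    n_constrained = nrow(x$constraints),
    control_objective = attr(x$control, "objective_value") %||%
      NA_real_,
    specific_objective = attr(x$specific, "objective_value") %||%
      NA_real_,
    control_glycolytic_ratio = x$control_atp$ratio_glycolytic,
    specific_glycolytic_ratio = x$specific_atp$ratio_glycolytic
  )
}
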