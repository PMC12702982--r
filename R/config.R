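#' Default run configuration
#'
#' The full default configuration document, sectioned by pipeline stage.
#' Every parameter a run uses appears here (and is echoed into the run log),
#' so an empty YAML file yields a fully specified run.
#'
#' @return A nested list with sections `phantom`, `mechanics`, `cytokines`,
#'   `cells`, `engine`, `morphometry`, `stats`.
#' @export
default_config <- function() {
  list(
    phantom = list(dims = c(64L, 64L, 64L), spacing = 14, target_bvtv = 0.131,
                   archetype_mix = 0.7, strut_thickness = 110, seed = 1L),
    mechanics = list(E_max = 10000, nu = 0.3, target_peak = 2500,
                     rtol = 1e-5),
    cytokines = list(dose_peak_pM = 40000, species = list()),
    cells = list(annual_loss = 0.006, rate_limit = 0.05,
                 seeding_mode = "remodelling", overrides = list()),
    engine = list(P_A = 1L, P_B = 1L, P_C = 1L, P_D = 1L,
                  treatment_months = 24, followup_months = 24,
                  cell_dt = 1, fe_interval_days = 10, fe_change_frac = 0.01,
                  n_subregions = 1000, record_interval_days = 30,
                  spin_up_days = 30, burn_in_days = 270,
                  output_months = c(1, 6, 12, 24, 30, 36, 42, 48),
                  seed = 1L),
    morphometry = list(rho_cal = 1.2),
    stats = list(windows = list(all = c(0, 48), dmab = c(0, 24),
                                dis = c(24, 36), end = c(36, 48))))
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    here <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", here)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        !key %in% c("species", "overrides", "windows")) {
      if (!is.list(user[[key]]))
        stop("configuration key ", here, " must be a section")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], here)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate and normalize a YAML run configuration
#'
#' Reads the YAML (an empty or absent document means all defaults), rejects
#' unknown keys with their full path, checks value sanity, and attaches the
#' canonical Greek run label implied by the four mechanism flags.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A `run_config`: the normalized nested list, with attributes
#'   `label` (Greek run label) and `provenance` (`"default"` or the path).
#' @export
validate_config <- function(path = NULL) {
  user <- list()
  provenance <- "default"
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    provenance <- path
  }
  cfg <- merge_config(default_config(), user)
  if (cfg$engine$cell_dt <= 0)
    stop("schema error at engine.cell_dt: timestep must be positive")
  if (cfg$phantom$target_bvtv <= 0 || cfg$phantom$target_bvtv >= 1)
    stop("schema error at phantom.target_bvtv: must be in (0, 1)")
  for (f in c("P_A", "P_B", "P_C", "P_D"))
    if (!cfg$engine[[f]] %in% c(0L, 1L))
      stop("schema error at engine.", f, ": flags are binary")
  flags <- hypothesis_flags(cfg$engine$P_A == 1, cfg$engine$P_B == 1,
                            cfg$engine$P_C == 1, cfg$engine$P_D == 1)
  structure(cfg, label = run_label(flags), provenance = provenance,
            class = c("run_config", "list"))
}

#' Build a simulation configuration from a run config
#'
#' @param cfg a [validate_config()] result.
#' @return A [simulation_config()].
#' @export
config_to_simulation <- function(cfg) {
  species <- species_defaults()
  for (nm in names(cfg$cytokines$species)) {
    row <- which(species$species == nm)
    if (length(row) == 0L) stop("unknown species in config: ", nm)
    for (f in names(cfg$cytokines$species[[nm]]))
      species[row, f] <- cfg$cytokines$species[[nm]][[f]]
  }
  params <- do.call(rate_params, cfg$cells$overrides)
  params$rate_limit <- cfg$cells$rate_limit
  simulation_config(
    flags = hypothesis_flags(cfg$engine$P_A == 1, cfg$engine$P_B == 1,
                             cfg$engine$P_C == 1, cfg$engine$P_D == 1),
    treatment_months = cfg$engine$treatment_months,
    followup_months = cfg$engine$followup_months,
    dose_peak_pM = cfg$cytokines$dose_peak_pM,
    cell_dt = cfg$engine$cell_dt,
    fe_interval_days = cfg$engine$fe_interval_days,
    fe_change_frac = cfg$engine$fe_change_frac,
    fe_rtol = cfg$mechanics$rtol,
    E_max = cfg$mechanics$E_max, nu = cfg$mechanics$nu,
    target_peak = cfg$mechanics$target_peak,
    annual_loss = cfg$cells$annual_loss,
    n_subregions = cfg$engine$n_subregions,
    seeding_mode = cfg$cells$seeding_mode,
    record_interval_days = cfg$engine$record_interval_days,
    spin_up_days = cfg$engine$spin_up_days,
    burn_in_days = cfg$engine$burn_in_days,
    output_months = cfg$engine$output_months,
    seed = cfg$engine$seed, params = params, species = species)
}

#' Write a reproducible run bundle
#'
#' Deterministic layout: `config.yaml`, `table.csv`, `states/` snapshots,
#' `log.jsonl`, and `manifest.json` listing every emitted file with an MD5
#' content hash, so re-running the same inputs reproduces identical hashes.
#'
#' @param outdir output directory (created).
#' @param run a `sim_result` from [run_simulation()].
#' @param config the `run_config` (or any list) echoed to `config.yaml`.
#' @param log a list of log records appended as JSON lines.
#' @return The manifest as a list, invisibly.
#' @export
write_run_bundle <- function(outdir, run, config = NULL, log = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config %||% list(), file.path(outdir, "config.yaml"))
  tab <- as.data.frame(run$table)
  write.csv(tab, file.path(outdir, "table.csv"), row.names = FALSE)
  save_state_snapshot(run$tissue, file.path(outdir, "states"), "final",
                      time_days = max(run$table$time_days))
  con <- file(file.path(outdir, "log.jsonl"), "w")
  for (rec in log)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  close(con)
  files <- setdiff(list.files(outdir, recursive = TRUE), "manifest.json")
  manifest <- list(
    algorithm = "md5",
    files = lapply(files, function(f) list(
      path = f, md5 = unname(tools::md5sum(file.path(outdir, f))))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
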