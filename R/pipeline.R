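# Manifest-driven orchestration: inputs -> concentration series -> ledger
# -> tidy reports.  Manifests are JSON (fields below); all stages are
# deterministic given the manifest and its seed.
#
# Manifest fields:
#   mode            "tables" (a prebuilt series CSV) or "trajectories"
#   temperature     K
#   rho_cond        mg/mL
#   dS_P            conformational entropy change, J mol^-1 K^-1 (optional)
#   include_mix     logical (optional)
#   seed            integer
#   series_csv      tables mode: path to a concentration-series CSV
#   systems         trajectories mode: array of records with rho,
#                   replicate, is_bulk, n_chains, structure,
#                   velocity_trajectory, energy_tables {PP, PW, WW}
# Relative paths are resolved against the manifest's directory.

.resolve_path <- function(p, base) {
  if (is.null(p) || p == "") return(NULL)
  if (file.exists(p)) return(p)
  fp <- file.path(base, p)
  fp
}

#' Validate a run manifest
#'
#' Checks the structural invariants of a manifest: at least two distinct
#' concentrations including the condensate row, a bulk-water (dilute
#' phase) reference entry -- the released/retained budget and the
#' solvation entropy changes are undefined without them -- and that every
#' referenced path resolves.  Problems are collected rather than thrown.
#'
#' @param manifest manifest list or path to a JSON manifest.
#' @param base_dir directory against which relative paths resolve
#'   (defaults to the manifest's directory).
#' @return list with `valid` (logical), `errors`, `warnings`, and the
#'   parsed `manifest` (with `base_dir` attached).
#' @export
validate_manifest <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    base_dir <- base_dir %||% dirname(manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  }
  base_dir <- base_dir %||% "."
  errors <- character(0); warnings <- character(0)
  mode <- manifest$mode %||% "tables"
  if (!mode %in% c("tables", "trajectories"))
    errors <- c(errors, paste0("unknown mode: ", mode))
  if (is.null(manifest$rho_cond))
    errors <- c(errors, "rho_cond missing")
  if (is.null(manifest$temperature))
    errors <- c(errors, "temperature missing")
  if (mode == "tables") {
    p <- .resolve_path(manifest$series_csv, base_dir)
    if (is.null(p) || !file.exists(p)) {
      errors <- c(errors, paste0("series_csv not found: ",
                                 manifest$series_csv %||% "<missing>"))
    } else {
      df <- utils::read.csv(p)
      rho_sys <- unique(df$rho[!df$is_bulk])
      if (!any(df$is_bulk))
        errors <- c(errors, paste0(
          "no bulk (dilute-phase) row: the released-water entropy change ",
          "needs the bulk reference S(rho_dil)"))
      if (!is.null(manifest$rho_cond) &&
          !any(abs(rho_sys - manifest$rho_cond) < 1e-9))
        errors <- c(errors, paste0(
          "condensate row rho_cond = ", manifest$rho_cond, " missing: the ",
          "released-water budget is defined relative to N_W(rho_cond)"))
      if (length(rho_sys) < 2L)
        errors <- c(errors, "need at least 2 distinct concentrations")
    }
  } else {
    if (length(manifest$systems %||% list()) == 0L) {
      errors <- c(errors, "trajectories mode needs a systems array")
    } else {
      rho <- vapply(manifest$systems, function(s) s$rho %||% NA_real_, 0)
      is_bulk <- vapply(manifest$systems, function(s) isTRUE(s$is_bulk), TRUE)
      if (!any(is_bulk))
        errors <- c(errors, paste0(
          "no bulk (dilute-phase) system: the released-water entropy ",
          "change needs the bulk reference S(rho_dil)"))
      if (!any(abs(rho[!is_bulk] - (manifest$rho_cond %||% -1)) < 1e-9))
        errors <- c(errors, paste0(
          "condensate system at rho_cond missing: the released-water ",
          "budget is defined relative to N_W(rho_cond)"))
      reps <- table(rho[!is_bulk])
      if (length(reps) && any(reps != max(reps)))
        warnings <- c(warnings, "unequal replicate counts across concentrations")
      for (s in manifest$systems) {
        for (p in c(s$structure, s$velocity_trajectory,
                    unlist(s$energy_tables))) {
          rp <- .resolve_path(p, base_dir)
          if (!is.null(rp) && !file.exists(rp))
            errors <- c(errors, paste0("dangling path: ", p))
        }
      }
    }
  }
  attr(manifest, "base_dir") <- base_dir
  list(valid = length(errors) == 0L, errors = errors, warnings = warnings,
       manifest = manifest)
}

# build one series row from a trajectories-mode system record
.series_row_from_system <- function(s, base_dir, T) {
  st <- read_structure(.resolve_path(s$structure, base_dir))
  n_chains <- s$n_chains %||% length(st$topology$chains)
  n_waters <- st$topology$n_waters
  ent <- list(S_tot = NA_real_, S_tr = NA_real_, S_rot = NA_real_)
  if (!is.null(s$velocity_trajectory)) {
    vs <- read_velocity_trajectory(.resolve_path(s$velocity_trajectory, base_dir),
                                   st$topology, temperature = T)
    e <- entropy_pipeline(vs, T = T)
    ent <- list(S_tot = e$S_tot, S_tr = e$S_tr, S_rot = e$S_rot)
  }
  emeans <- list(PP = 0, PW = 0, WW = 0)
  for (lab in names(s$energy_tables %||% list())) {
    es <- read_energy_table(.resolve_path(s$energy_tables[[lab]], base_dir), lab)
    emeans[[lab]] <- mean(es$values)
  }
  data.frame(
    rho = s$rho, replicate = s$replicate %||% 1L,
    n_chains = if (isTRUE(s$is_bulk)) 0L else n_chains,
    n_waters = n_waters,
    S_tot = ent$S_tot, S_tr = ent$S_tr, S_rot = ent$S_rot,
    E_PP = if (isTRUE(s$is_bulk)) 0 else emeans$PP / max(n_chains, 1L),
    E_PW = emeans$PW / max(n_waters, 1L),
    E_WW = emeans$WW / max(n_waters, 1L),
    is_bulk = isTRUE(s$is_bulk))
}

#' Run the full pipeline from a manifest
#'
#' Builds (or loads) the concentration series, assembles the thermodynamic
#' ledger, and writes a tidy report bundle to `out_dir`: `series.csv`,
#' `ledger.csv`, `ledger.json` and `qc.json` (the QC report records every
#' convention and default actually used).  Fully deterministic given the
#' manifest and seed.
#'
#' @param manifest manifest list or JSON path (see [validate_manifest()]).
#' @param out_dir output directory (created if needed).
#' @return the `ct_ledger`, invisibly; the report paths are attached as
#'   attribute `files`.
#' @export
run_pipeline <- function(manifest, out_dir = ".") {
  val <- validate_manifest(manifest)
  if (!val$valid)
    stop("invalid manifest:\n  - ", paste(val$errors, collapse = "\n  - "),
         call. = FALSE)
  for (w in val$warnings) warning(w, call. = FALSE)
  m <- val$manifest
  base_dir <- attr(m, "base_dir")
  T <- m$temperature
  if (!is.null(m$seed)) set.seed(m$seed)
  if ((m$mode %||% "tables") == "tables") {
    df <- utils::read.csv(.resolve_path(m$series_csv, base_dir))
  } else {
    rows <- lapply(m$systems, function(s) {
      tryCatch(.series_row_from_system(s, base_dir, T),
               error = function(e) stop("stage 'series' failed at rho = ",
                                        s$rho %||% "?", ": ",
                                        conditionMessage(e), call. = FALSE))
    })
    df <- do.call(rbind, rows)
  }
  series <- concentration_series(df)
  led <- tryCatch(
    assemble_ledger(series, rho_cond = m$rho_cond,
                    dS_P = m$dS_P %||% 0, T = T,
                    include_mix = isTRUE(m$include_mix)),
    error = function(e) stop("stage 'ledger' failed: ", conditionMessage(e),
                             call. = FALSE))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f_series <- file.path(out_dir, "series.csv")
  f_ledger <- file.path(out_dir, "ledger.csv")
  f_json <- file.path(out_dir, "ledger.json")
  f_qc <- file.path(out_dir, "qc.json")
  utils::write.csv(as.data.frame(series), f_series, row.names = FALSE)
  utils::write.csv(led$table, f_ledger, row.names = FALSE)
  jsonlite::write_json(list(rho_cond = led$rho_cond, temperature = led$T,
                            table = led$table, sd = led$sd),
                       f_json, digits = NA, auto_unbox = TRUE)
  qc <- list(mode = m$mode %||% "tables", seed = m$seed,
             conventions = led$conventions,
             hb_criterion = list(dist_cutoff = 0.35, angle_cutoff = 30),
             phl_cutoff = 0.3,
             dos = list(window = "none", zero_pad = 2,
                        note = "max_lag = duration/2 unless overridden"))
  jsonlite::write_json(qc, f_qc, auto_unbox = TRUE, pretty = TRUE)
  attr(led, "files") <- c(series = f_series, ledger = f_ledger,
                          json = f_json, qc = f_qc)
  invisible(led)
}
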