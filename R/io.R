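.UCAL_J <- .J_PER_CAL * 1e-6   # joules per microcalorie

.fmt17 <- function(x) formatC(x, format = "g", digits = 17)

#' Write an isotherm to CSV (with a YAML sidecar)
#'
#' Columns: `injection_index`, `inj_volume_uL`, `heat_ucal`, `molar_ratio`
#' (ASCII headers; heats in microcalories), plus a `heat_J` column holding
#' the unconverted joule values. Values are printed with 17 significant
#' digits, and the reader prefers `heat_J`, so a write/read round trip
#' reproduces the doubles bit-for-bit. The titration configuration is written to
#' `<path>.yaml` (`v_cell_mL`, `cell_uM`, `syringe_uM`, `temp_C`,
#' `dilution_heat_ucal`, plus any isotherm metadata).
#'
#' @param iso An isotherm.
#' @param path Output CSV path.
#' @param sidecar Write the YAML configuration sidecar.
#' @return `path`, invisibly.
#' @export
write_isotherm_csv <- function(iso, path, sidecar = TRUE) {
  stopifnot(inherits(iso, "isotherm"))
  df <- data.frame(
    injection_index = seq_along(iso$heats),
    inj_volume_uL = .fmt17(iso$config$schedule$volumes * 1e6),
    heat_ucal = .fmt17(iso$heats / .UCAL_J),
    molar_ratio = .fmt17(iso$molar_ratio),
    heat_J = .fmt17(iso$heats),  # unconverted: guarantees exact round trips
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    cfg <- list(
      v_cell_mL = iso$config$v_cell * 1e3,
      cell_uM = iso$config$m_cell_0 * 1e6,
      syringe_uM = iso$config$x_syringe * 1e6,
      temp_C = iso$config$temperature - 273.15,
      dilution_heat_ucal = iso$config$dilution_heat / .UCAL_J,
      occupancy = iso$occupancy
    )
    meta <- iso$meta[!vapply(iso$meta, is.null, logical(1))]
    yaml::write_yaml(c(cfg, meta), paste0(path, ".yaml"))
  }
  invisible(path)
}

#' Read an isotherm from CSV
#'
#' Accepts the layout written by [write_isotherm_csv()]. Heats may be given
#' as `heat_J` (preferred when present), `heat_ucal` (microcalories per
#' injection), or
#' `heat_kcal_per_mol` (kcal per mole of injectant; converted using the
#' syringe concentration). A missing `molar_ratio` column is recomputed
#' from the configuration. Malformed rows raise errors naming the row.
#'
#' @param path CSV path.
#' @param config A [titration_config()]; if `NULL`, the `<path>.yaml`
#'   sidecar is read.
#' @return An isotherm (heats in J).
#' @export
read_isotherm_csv <- function(path, config = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("isotherm file '", path, "' has no data rows")
  meta <- list()
  occupancy <- 1
  if (is.null(config)) {
    side <- paste0(path, ".yaml")
    if (!file.exists(side)) {
      stop("no titration config given and no sidecar found at '", side, "'")
    }
    sc <- yaml::read_yaml(side)
    need <- c("v_cell_mL", "cell_uM", "syringe_uM")
    miss <- setdiff(need, names(sc))
    if (length(miss)) stop("sidecar lacks field(s): ",
                           paste(miss, collapse = ", "))
    vol_col <- df$inj_volume_uL
    if (is.null(vol_col)) stop("isotherm file lacks an inj_volume_uL column")
    vols <- suppressWarnings(as.numeric(vol_col))
    bad <- which(!is.finite(vols))
    if (length(bad)) stop("non-numeric injection volume in row ", bad[1L])
    if (any(vols <= 0)) {
      stop("non-positive injection volume in row ", which(vols <= 0)[1L])
    }
    config <- titration_config(
      v_cell = sc$v_cell_mL * 1e-3,
      m_cell_0 = sc$cell_uM * 1e-6,
      x_syringe = sc$syringe_uM * 1e-6,
      temperature = (sc$temp_C %||% 25) + 273.15,
      schedule = injection_schedule(vols * 1e-6),
      dilution_heat = (sc$dilution_heat_ucal %||% 0) * .UCAL_J
    )
    occupancy <- sc$occupancy %||% 1
    meta <- sc[setdiff(names(sc),
                       c("v_cell_mL", "cell_uM", "syringe_uM", "temp_C",
                         "dilution_heat_ucal", "occupancy"))]
  }
  n <- length(config$schedule$volumes)
  if (nrow(df) != n) {
    stop(sprintf("isotherm file has %d rows but the schedule has %d injections",
                 nrow(df), n))
  }
  heats <- if (!is.null(df$heat_J)) {
    suppressWarnings(as.numeric(df$heat_J))
  } else if (!is.null(df$heat_ucal)) {
    suppressWarnings(as.numeric(df$heat_ucal)) * .UCAL_J
  } else if (!is.null(df$heat_kcal_per_mol)) {
    mol_inj <- config$x_syringe * config$schedule$volumes
    suppressWarnings(as.numeric(df$heat_kcal_per_mol)) * 1e3 * .J_PER_CAL *
      mol_inj
  } else {
    stop("isotherm file lacks a heat column ",
         "(heat_ucal, heat_J or heat_kcal_per_mol)")
  }
  bad <- which(!is.finite(heats))
  if (length(bad)) stop("missing or non-numeric heat in row ", bad[1L])
  mr <- if (!is.null(df$molar_ratio)) {
    suppressWarnings(as.numeric(df$molar_ratio))
  } else {
    dilution_trajectory(config)$molar_ratio
  }
  structure(list(config = config, heats = heats, molar_ratio = mr,
                 occupancy = occupancy, Q = NULL, meta = meta),
            class = "isotherm")
}

#' Normalised heats in kcal per mole of injectant
#'
#' The conventional y-axis of ITC figures: each injection heat divided by
#' the moles of ligand delivered by that injection.
#'
#' @param iso An isotherm.
#' @return Numeric vector (kcal/mol of injectant).
#' @export
normalized_heats <- function(iso) {
  stopifnot(inherits(iso, "isotherm"))
  mol_inj <- iso$config$x_syringe * iso$config$schedule$volumes
  iso$heats / (mol_inj * 1e3 * .J_PER_CAL)
}

#' Write / read umbrella-window samples as two-column text
#'
#' Plain whitespace-separated text with columns time and CV value, the
#' interchange format for biased window time series.
#'
#' @param window A [bias_window()].
#' @param path Output path.
#' @param dt Time spacing between samples (first column).
#' @return `path` (write) or a [bias_window()] (read).
#' @export
write_window_samples <- function(window, path, dt = 1) {
  stopifnot(inherits(window, "bias_window"))
  df <- data.frame(time = .fmt17(seq_along(window$samples) * dt),
                   cv_value = .fmt17(window$samples))
  utils::write.table(df, path, row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_window_samples
#' @param center,k_force Window parameters to attach on read.
#' @export
read_window_samples <- function(path, center, k_force) {
  df <- utils::read.table(path, header = TRUE)
  bias_window(center, k_force, as.numeric(df[[2L]]))
}

#' Export a free-energy profile as CSV
#'
#' @param profile A `"free_energy_profile"`.
#' @param path Output path; columns `bin_center`, `delta_g_kT`.
#' @return `path`, invisibly.
#' @export
export_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "free_energy_profile"))
  write.csv(data.frame(bin_center = profile$bins,
                       delta_g_kT = profile$delta_g),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a panel manifest
#'
#' The manifest is a YAML file listing the isotherm CSVs of a panel with
#' per-isotherm metadata, plus the shared model:
#' \preformatted{
#' model:
#'   classes:
#'     - {n: 1, k: 2.9e5, dh: -18000}
#'     - {n: 2, k: 2.5e4, dh: -8000}
#' entries:
#'   - {csv: iso_wt_0.csv, condition: 0, arm: WT}
#'   - ...
#' outdir: results
#' }
#'
#' @param path Manifest path.
#' @return List with `model` (a [binding_model()]), `entries`, `outdir`;
#'   relative CSV paths are resolved against the manifest's directory.
#' @export
read_panel_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  if (is.null(man$entries) || !length(man$entries)) {
    stop("panel manifest lists no entries")
  }
  if (is.null(man$model$classes)) stop("panel manifest lacks model classes")
  base <- dirname(path)
  for (i in seq_along(man$entries)) {
    csv <- man$entries[[i]]$csv
    if (is.null(csv)) stop("manifest entry ", i, " lacks a csv path")
    if (!grepl("^(/|[A-Za-z]:)", csv)) {
      man$entries[[i]]$csv <- file.path(base, csv)
    }
    if (!file.exists(man$entries[[i]]$csv)) {
      stop("isotherm file not found: ", man$entries[[i]]$csv)
    }
  }
  labels <- vapply(man$entries, function(e)
    paste(e$arm %||% "", e$condition %||% "", sep = "/"), character(1))
  if (anyDuplicated(labels)) {
    stop("condition labels are not unique within arms")
  }
  model <- binding_model(lapply(man$model$classes, function(cl)
    site_class(cl$n, cl$k, cl$dh)))
  list(model = model, entries = man$entries,
       outdir = man$outdir %||% ".")
}

#' Run the occupancy-analysis pipeline on a panel manifest
#'
#' Reads every isotherm listed in the manifest, performs the global
#' shared-thermodynamics fit, tabulates occupancy against condition, and
#' writes `occupancy.csv`, a machine-readable `report.json` (seed, input
#' checksums, package version, shared parameters, goodness of fit, numeric
#' warnings) and a residual/fit plot `fit.pdf` to the output directory.
#'
#' @param manifest Path to a manifest file, or the list returned by
#'   [read_panel_manifest()].
#' @param seed Integer seed recorded in all outputs and used for any
#'   stochastic fitting options.
#' @param outdir Output directory (default: the manifest's `outdir`).
#' @param n_starts Optimiser starts for the global fit.
#' @param make_plots Write the PDF fit plot.
#' @return Invisibly, a list with `fit`, `occupancy`, `report`.
#' @export
run_pipeline <- function(manifest, seed = 1L, outdir = NULL, n_starts = 1L,
                         make_plots = TRUE) {
  man <- if (is.character(manifest)) read_panel_manifest(manifest) else manifest
  stopifnot(length(man$entries) >= 1L)
  outdir <- outdir %||% man$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  panel <- lapply(man$entries, function(e) {
    iso <- read_isotherm_csv(e$csv)
    iso$meta$condition <- e$condition %||% iso$meta$condition
    iso$meta$arm <- e$arm %||% iso$meta$arm
    iso
  })
  fit <- fit_global(panel, man$model, n_starts = n_starts, seed = seed)
  if (!fit$converged) stop("pipeline aborted at stage [globalfit]: ",
                           "optimiser did not converge (info = ", fit$info, ")")
  occ <- occupancy_vs_condition(fit,
                                file = file.path(outdir, "occupancy.csv"))
  warnings_out <- character()
  if (isTRUE(fit$high_correlation)) {
    warnings_out <- c(warnings_out,
                      "parameter correlations exceed |r| = 0.95")
  }
  near <- occ$theta > 1.45
  if (any(near)) {
    warnings_out <- c(warnings_out, paste0(
      "occupancy at upper bound for isotherm(s) ",
      paste(which(near), collapse = ", ")))
  }
  files <- vapply(man$entries, `[[`, character(1), "csv")
  report <- list(
    seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("alloitc")),
    inputs = lapply(seq_along(files), function(i)
      list(csv = files[i], md5 = unname(tools::md5sum(files[i])))),
    shared_parameters = fit$shared,
    chi2 = fit$chi2, chi2_reduced = fit$chi2_reduced,
    converged = fit$converged,
    warnings = warnings_out
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (make_plots) {
    pdf(file.path(outdir, "fit.pdf"), width = 7, height = 5)
    on.exit(dev.off(), add = TRUE)
    for (i in seq_along(panel)) {
      iso <- panel[[i]]
      obs <- normalized_heats(iso)
      pred_iso <- iso
      pred_iso$heats <- iso$heats + fit$residuals[[i]]  # resid = pred - obs
      plot(iso$molar_ratio, obs, pch = 16, cex = 0.7,
           xlab = "molar ratio [X]t/[M]t",
           ylab = "kcal / mol of injectant",
           main = sprintf("isotherm %d (%s, condition %s): Theta = %.2f",
                          i, fit$theta$arm[i],
                          format(fit$theta$condition[i]),
                          fit$theta$theta[i]))
      lines(iso$molar_ratio, normalized_heats(pred_iso), col = "red3")
    }
  }
  invisible(list(fit = fit, occupancy = occ, report = report))
}
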