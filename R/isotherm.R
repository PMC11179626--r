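#' Injection schedule
#'
#' @param volumes Injected volumes in litres, one per injection, each > 0.
#' @return An object of class `"injection_schedule"`.
#' @seealso [vp_itc_schedule()] for the default VP-ITC style schedule.
#' @export
injection_schedule <- function(volumes) {
  stopifnot(is.numeric(volumes), length(volumes) >= 0L,
            all(is.finite(volumes)), all(volumes > 0))
  structure(list(volumes = as.numeric(volumes)), class = "injection_schedule")
}

#' VP-ITC style injection schedule
#'
#' The schedule used throughout the package's worked examples: a small first
#' injection (commonly discarded in ITC practice) followed by a train of
#' equal larger injections. Defaults give 35 injections: 2 uL then 34 x 8 uL.
#'
#' @param first_uL Volume of the first injection (microlitres).
#' @param n_following Number of subsequent injections.
#' @param following_uL Volume of each subsequent injection (microlitres).
#' @return An [injection_schedule()].
#' @export
vp_itc_schedule <- function(first_uL = 2, n_following = 34, following_uL = 8) {
  injection_schedule(c(first_uL, rep(following_uL, n_following)) * 1e-6)
}

#' Titration configuration
#'
#' Everything fixed about one titration: cell volume, starting cell
#' concentration of the macromolecule, syringe concentration of the ligand,
#' temperature, the injection schedule, and a constant per-injection heat of
#' dilution (the residual offset after blank subtraction; default 0).
#'
#' Cumulative injected volume beyond half the cell volume triggers a warning
#' (the perfusion approximation degrades); beyond the cell volume, an error.
#'
#' @param v_cell Cell volume (L). Default 1.4 mL, the nominal VP-ITC cell.
#' @param m_cell_0 Macromolecule concentration in the cell at the start (mol/L).
#' @param x_syringe Ligand concentration in the syringe (mol/L).
#' @param temperature Temperature (K).
#' @param schedule An [injection_schedule()].
#' @param dilution_heat Constant heat of dilution per injection (J).
#' @return An object of class `"titration_config"`.
#' @export
titration_config <- function(v_cell = 1.4e-3, m_cell_0, x_syringe,
                             temperature = 298.15,
                             schedule = vp_itc_schedule(),
                             dilution_heat = 0) {
  stopifnot(is.numeric(v_cell), v_cell > 0,
            is.numeric(m_cell_0), m_cell_0 >= 0,
            is.numeric(x_syringe), x_syringe >= 0,
            is.numeric(temperature), temperature > 0,
            inherits(schedule, "injection_schedule"),
            is.numeric(dilution_heat), is.finite(dilution_heat))
  cum <- sum(schedule$volumes)
  if (cum > v_cell) {
    stop("cumulative injected volume exceeds the cell volume")
  }
  if (cum > 0.5 * v_cell) {
    warning("cumulative injected volume exceeds half the cell volume; ",
            "the perfusion-cell dilution model becomes inaccurate")
  }
  structure(list(v_cell = v_cell, m_cell_0 = m_cell_0, x_syringe = x_syringe,
                 temperature = temperature, schedule = schedule,
                 dilution_heat = dilution_heat),
            class = "titration_config")
}

#' Zn2+-into-albumin titration configuration
#'
#' 1.5 mM ligand titrated into 50 uM macromolecule at 25 C, 35 injections
#' (2 uL then 34 x 8 uL) into a 1.4 mL cell — the Zn2+/albumin design used
#' for all the package's synthetic zinc-binding panels.
#'
#' @param ... Overrides passed to [titration_config()].
#' @return A `"titration_config"`.
#' @export
zn_titration_config <- function(...) {
  defaults <- list(v_cell = 1.4e-3, m_cell_0 = 50e-6, x_syringe = 1.5e-3,
                   temperature = 298.15)
  do.call(titration_config, modifyList(defaults, list(...)))
}

#' Myristate-into-albumin titration configuration
#'
#' 500 uM fatty acid titrated into 12.5 uM albumin, same 35-injection
#' schedule and temperature as [zn_titration_config()].
#'
#' @param ... Overrides passed to [titration_config()].
#' @return A `"titration_config"`.
#' @export
myristate_titration_config <- function(...) {
  defaults <- list(v_cell = 1.4e-3, m_cell_0 = 12.5e-6, x_syringe = 500e-6,
                   temperature = 298.15)
  do.call(titration_config, modifyList(defaults, list(...)))
}

#' Two-class Zn2+/albumin binding model
#'
#' One high-affinity site (site A; K = 2.9e5 M^-1) and a set of two weaker
#' sites (K = 2.5e4 M^-1), the model used for global fits of zinc-binding
#' panels. Enthalpies are representative exothermic values in J/mol.
#'
#' @return A [binding_model()] with two site classes.
#' @export
hsa_zn_model <- function() {
  binding_model(site_class(1, 2.9e5, -18e3),
                site_class(2, 2.5e4, -8e3))
}

#' Three-class myristate/albumin binding model
#'
#' Three sets of sites with stoichiometries 2/1/4 and association constants
#' 1.76e6, 3.91e5 and 3.11e4 M^-1 (highest, medium, lowest affinity), the
#' model used for fatty-acid titrations of wild-type albumin.
#'
#' @return A [binding_model()] with three site classes.
#' @export
hsa_myristate_model <- function() {
  binding_model(site_class(2, 1.76e6, -25e3),
                site_class(1, 3.91e5, -15e3),
                site_class(4, 3.11e4, -6e3))
}

#' Per-injection cell concentrations under perfusion dilution
#'
#' A perfusion (constant-volume) calorimeter cell displaces liquid as it is
#' injected into. After cumulative injected volume `dV`, the standard
#' Origin-style bookkeeping gives
#' `m_total = m0 * (1 - dV/(2 v)) / (1 + dV/(2 v))` and
#' `x_total = x_syr * (dV/v) / (1 + dV/(2 v))`.
#'
#' @param config A [titration_config()].
#' @return A data frame with one row per injection: `injection`, `volume`
#'   (L), `cum_volume` (L), `m_total`, `x_total` (mol/L) and `molar_ratio`
#'   (`x_total / m_total`).
#' @export
dilution_trajectory <- function(config) {
  stopifnot(inherits(config, "titration_config"))
  vols <- config$schedule$volumes
  if (!length(vols)) {
    return(data.frame(injection = integer(), volume = numeric(),
                      cum_volume = numeric(), m_total = numeric(),
                      x_total = numeric(), molar_ratio = numeric()))
  }
  cum <- cumsum(vols)
  r <- cum / (2 * config$v_cell)
  m <- config$m_cell_0 * (1 - r) / (1 + r)
  x <- config$x_syringe * (cum / config$v_cell) / (1 + r)
  data.frame(injection = seq_along(vols), volume = vols, cum_volume = cum,
             m_total = m, x_total = x, molar_ratio = x / m)
}

#' Forward-simulate a titration isotherm
#'
#' Computes the per-injection heats of the independent sets-of-sites model
#' for a given titration. The heat of injection k is
#' `q_k = Q_k - Q_(k-1) + (dV_k / v_cell) * (Q_k + Q_(k-1)) / 2 +
#' dilution_heat`, where `Q` is the cell heat content ([heat_content()]) at
#' the diluted concentrations and the middle term accounts for heat carried
#' out with the displaced volume.
#'
#' @param model A [binding_model()] (canonical order: class 1 has the
#'   highest affinity).
#' @param config A [titration_config()].
#' @param occupancy Occupancy scaling (Theta) of the first site class only
#'   (>= 0, default 1). `occupancy = 0` removes the high-affinity class,
#'   emulating a macromolecule whose high-affinity site is fully blocked.
#' @return An object of class `"isotherm"`: a list with `config`, `heats`
#'   (J, one per injection), `molar_ratio`, `occupancy`, `Q` (cumulative
#'   heat content after each injection, J) and a `meta` list.
#' @export
#' @examples
#' iso <- simulate_isotherm(hsa_zn_model(), zn_titration_config())
#' round(iso$heats[1:3] / 4.184e-6)  # first heats in ucal
simulate_isotherm <- function(model, config, occupancy = 1) {
  stopifnot(inherits(model, "binding_model"),
            inherits(config, "titration_config"),
            is.numeric(occupancy), length(occupancy) == 1L, occupancy >= 0)
  mats <- .model_mats(model)
  n <- mats$n
  n[1L] <- n[1L] * occupancy
  traj <- dilution_trajectory(config)
  k <- nrow(traj)
  if (!k) {
    return(structure(list(config = config, heats = numeric(),
                          molar_ratio = numeric(), occupancy = occupancy,
                          Q = numeric(), meta = list()),
                     class = "isotherm"))
  }
  nm <- matrix(n, k, length(n), byrow = TRUE)
  Km <- matrix(mats$K, k, length(n), byrow = TRUE)
  sol <- .free_ligand_core(nm, Km, traj$m_total, traj$x_total)
  Q <- config$v_cell * traj$m_total *
    as.numeric(sol$theta %*% (n * mats$dH))
  Qprev <- c(0, Q[-k])  # pre-injection cell holds no ligand: Q_0 = 0
  q <- Q - Qprev + (traj$volume / config$v_cell) * (Q + Qprev) / 2 +
    config$dilution_heat
  structure(list(config = config, heats = q, molar_ratio = traj$molar_ratio,
                 occupancy = occupancy, Q = Q, meta = list()),
            class = "isotherm")
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf("ITC isotherm: %d injections, molar ratio %.3g-%.3g\n",
              length(x$heats),
              if (length(x$molar_ratio)) min(x$molar_ratio) else NA,
              if (length(x$molar_ratio)) max(x$molar_ratio) else NA))
  if (length(x$heats)) {
    cat(sprintf("  heats: %.3g to %.3g ucal; occupancy Theta = %.3g\n",
                min(x$heats) / (.J_PER_CAL * 1e-6),
                max(x$heats) / (.J_PER_CAL * 1e-6), x$occupancy))
  }
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Generate a panel of synthetic isotherms with per-isotherm occupancy
#'
#' Simulates one isotherm per element of `theta_schedule`, all sharing a
#' single binding model and titration configuration, then adds i.i.d.
#' Gaussian noise to the heats. This is the package's stand-in for a
#' fatty-acid loading series: the occupancy Theta of the high-affinity class
#' declines along one arm while a knockout-like arm stays at 1.
#'
#' @param theta_schedule Numeric vector of occupancies, one per isotherm.
#' @param model Shared [binding_model()].
#' @param config Shared [titration_config()].
#' @param noise_sd Standard deviation of additive Gaussian heat noise (J).
#'   Default (`NULL`) is 1% of the largest absolute noiseless heat in the
#'   panel.
#' @param seed Integer seed; a fixed seed makes the panel bit-reproducible.
#' @param conditions Per-isotherm condition values (e.g. fatty acid mol.
#'   eq.); stored in each isotherm's `meta`. Default `0, 1, 2, ...`.
#' @param arm Optional per-isotherm arm labels (e.g. `"WT"` / `"KO"`).
#' @return A list of [simulate_isotherm()] objects with populated `meta`
#'   (`condition`, `arm`, `theta_true`, `noise_sd`).
#' @export
make_synthetic_panel <- function(theta_schedule, model = hsa_zn_model(),
                                 config = zn_titration_config(),
                                 noise_sd = NULL, seed = NULL,
                                 conditions = seq_along(theta_schedule) - 1,
                                 arm = NULL) {
  stopifnot(is.numeric(theta_schedule), length(theta_schedule) >= 1L,
            all(theta_schedule >= 0),
            length(conditions) == length(theta_schedule),
            is.null(noise_sd) || (is.numeric(noise_sd) && noise_sd >= 0))
  if (!is.null(arm)) arm <- rep_len(arm, length(theta_schedule))
  base <- lapply(theta_schedule, function(th)
    simulate_isotherm(model, config, occupancy = th))
  if (is.null(noise_sd)) {
    noise_sd <- 0.01 * max(abs(unlist(lapply(base, `[[`, "heats"))))
  }
  with_seed(seed, {
    for (i in seq_along(base)) {
      n <- length(base[[i]]$heats)
      if (noise_sd > 0) {
        base[[i]]$heats <- base[[i]]$heats + rnorm(n, 0, noise_sd)
      }
      base[[i]]$meta <- list(condition = conditions[[i]],
                             arm = if (is.null(arm)) NA_character_ else arm[[i]],
                             theta_true = theta_schedule[[i]],
                             noise_sd = noise_sd)
    }
    base
  })
}

#' Twelve-isotherm palmitate-loading panel
#'
#' The package's reference study design: two arms of six zinc titrations at
#' 0-5 mol. eq. fatty acid. In the wild-type-like arm the occupancy of the
#' high-affinity site declines from 1 to 0.1 with fatty-acid load; in the
#' knockout-like arm it stays at 1 throughout.
#'
#' @param seed Integer seed for the heat noise.
#' @param noise_sd Heat noise SD (J); default 1% of the largest heat.
#' @param theta_wt Occupancy schedule of the wild-type-like arm.
#' @return List of 12 isotherms (6 per arm) with `meta$arm` in
#'   `c("WT", "FA2-KO")` and `meta$condition` = mol. eq. 0-5.
#' @export
palmitate_panel <- function(seed = NULL, noise_sd = NULL,
                            theta_wt = c(1, 0.85, 0.65, 0.45, 0.25, 0.10)) {
  stopifnot(length(theta_wt) == 6L)
  make_synthetic_panel(
    theta_schedule = c(theta_wt, rep(1, 6)),
    model = hsa_zn_model(), config = zn_titration_config(),
    noise_sd = noise_sd, seed = seed,
    conditions = rep(0:5, 2),
    arm = rep(c("WT", "FA2-KO"), each = 6)
  )
}
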