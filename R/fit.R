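#' Declare one fit parameter
#'
#' @param name Parameter name. Model parameters are named `N1`, `K1`, `H1`,
#'   `N2`, ... (stoichiometry, association constant in M^-1, enthalpy in
#'   J/mol per class) plus `Qdil` (constant heat of dilution per injection,
#'   J).
#' @param value Initial (and, if `fixed`, final) value.
#' @param fixed If `TRUE` the parameter never moves during fitting.
#' @param lower,upper Box bounds; must satisfy `lower <= value <= upper`.
#' @param shared In global fits, `TRUE` means one value across all isotherms
#'   (all non-occupancy parameters in this package's global model).
#' @return A one-row data frame; combine rows with `rbind()`.
#' @export
param_spec <- function(name, value, fixed = FALSE, lower = -Inf, upper = Inf,
                       shared = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(value), is.finite(value),
            lower <= value, value <= upper)
  data.frame(name = name, value = as.numeric(value), fixed = fixed,
             lower = as.numeric(lower), upper = as.numeric(upper),
             shared = shared, stringsAsFactors = FALSE)
}

#' Default parameter table for a single-isotherm fit
#'
#' Builds one `N`, `K`, `H` row per site class of `model`, initialised at
#' the model's values, with wide default bounds; optionally a `Qdil` row.
#'
#' @param model A [binding_model()] providing starting values.
#' @param fix Character vector of parameter names to hold fixed.
#' @param dilution_heat If non-`NULL`, adds a `Qdil` parameter at this value
#'   (J per injection); otherwise the isotherm's configured dilution heat is
#'   used unchanged.
#' @param fit_dilution Free the `Qdil` parameter (requires `dilution_heat`).
#' @param n_upper,k_lower,k_upper,h_abs Default bounds for stoichiometries,
#'   association constants (M^-1) and |enthalpies| (J/mol).
#' @return A parameter data frame as built by [param_spec()].
#' @export
fit_specs <- function(model, fix = character(), dilution_heat = NULL,
                      fit_dilution = FALSE, n_upper = 20,
                      k_lower = 1e-2, k_upper = 1e15, h_abs = 1e6) {
  mats <- .model_mats(model)
  rows <- list()
  for (i in seq_along(mats$n)) {
    rows[[length(rows) + 1L]] <-
      param_spec(paste0("N", i), mats$n[i], lower = 0, upper = n_upper)
    rows[[length(rows) + 1L]] <-
      param_spec(paste0("K", i), mats$K[i], lower = k_lower, upper = k_upper)
    rows[[length(rows) + 1L]] <-
      param_spec(paste0("H", i), mats$dH[i], lower = -h_abs, upper = h_abs)
  }
  if (!is.null(dilution_heat)) {
    rows[[length(rows) + 1L]] <-
      param_spec("Qdil", dilution_heat, fixed = !fit_dilution,
                 lower = -1e-3, upper = 1e-3)
  }
  tab <- do.call(rbind, rows)
  if (length(fix)) {
    bad <- setdiff(fix, tab$name)
    if (length(bad)) stop("unknown parameter name(s): ",
                          paste(bad, collapse = ", "))
    tab$fixed[tab$name %in% fix] <- TRUE
  }
  tab
}

#' Default parameter table for a global fit
#'
#' Shared-thermodynamics global model: all `K` and `H` values are shared
#' across isotherms and free; stoichiometries are fixed at the model's
#' values (the per-isotherm occupancy Theta of class 1 carries all
#' between-isotherm variation).
#'
#' @inheritParams fit_specs
#' @param free Character vector of additional parameter names to free.
#' @return A parameter data frame.
#' @export
global_fit_specs <- function(model, fix = character(), free = character(),
                             dilution_heat = NULL, fit_dilution = FALSE) {
  tab <- fit_specs(model, dilution_heat = dilution_heat,
                   fit_dilution = fit_dilution)
  tab$fixed[grepl("^N", tab$name)] <- TRUE
  tab$shared <- !grepl("^N", tab$name)
  if (length(fix)) tab$fixed[tab$name %in% fix] <- TRUE
  if (length(free)) tab$fixed[tab$name %in% free] <- FALSE
  tab
}

.spec_validate <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("name", "value", "fixed", "lower", "upper") %in% names(tab)),
            !anyDuplicated(tab$name),
            all(tab$lower <= tab$value), all(tab$value <= tab$upper))
  if (is.null(tab$shared)) tab$shared <- FALSE
  tab
}

# Natural <-> internal parameter scale. Association constants are fitted as
# log10(K) for conditioning; everything else is fitted as-is.
.is_logged <- function(names, log_k) log_k & grepl("^K", names)

.to_internal <- function(v, names, log_k) {
  lg <- .is_logged(names, log_k)
  v[lg] <- log10(pmax(v[lg], 1e-300))
  v
}

.from_internal <- function(v, names, log_k) {
  lg <- .is_logged(names, log_k)
  v[lg] <- 10^v[lg]
  v
}

# Fill the full natural-scale named parameter vector from the free subset.
.fill_params <- function(tab, pfree, log_k) {
  full <- setNames(tab$value, tab$name)
  free <- !tab$fixed
  full[free] <- .from_internal(pfree, tab$name[free], log_k)
  full
}

.model_from_vec <- function(v, n_classes) {
  classes <- lapply(seq_len(n_classes), function(i)
    site_class(v[[paste0("N", i)]], v[[paste0("K", i)]], v[[paste0("H", i)]]))
  binding_model(classes, canonicalize = FALSE)
}

.predict_heats <- function(v, n_classes, config, occupancy = 1) {
  model <- .model_from_vec(v, n_classes)
  cfg <- config
  if ("Qdil" %in% names(v)) cfg$dilution_heat <- v[["Qdil"]]
  simulate_isotherm(model, cfg, occupancy = occupancy)$heats
}

# One Levenberg-Marquardt run plus optional seeded multi-start.
.lm_multistart <- function(resid_fn, start, lower, upper, n_starts, seed,
                           control) {
  ctrl <- do.call(nls.lm.control,
                  modifyList(list(maxiter = 500, ftol = 1e-15, ptol = 1e-15,
                                  gtol = 0, maxfev = 100000),
                             control %||% list()))
  run1 <- function(p0) {
    tryCatch(nls.lm(par = p0, lower = lower, upper = upper, fn = resid_fn,
                    control = ctrl),
             error = function(e) NULL)
  }
  fits <- list(run1(start))
  if (n_starts > 1L) {
    with_seed(seed, {
      for (s in seq_len(n_starts - 1L)) {
        p0 <- start + runif(length(start), -0.3, 0.3) * pmax(abs(start), 0.5)
        p0 <- pmin(pmax(p0, lower + 1e-12), upper - 1e-12)
        fits[[length(fits) + 1L]] <- run1(p0)
      }
    })
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("all optimiser starts failed")
  ssr <- vapply(fits, function(f) f$deviance, numeric(1))
  list(best = fits[[which.min(ssr)]], ssr_starts = ssr)
}

# Standard errors, correlation matrix and identifiability flag from the
# Gauss-Newton Hessian approximation at the optimum.
.fit_uncertainty <- function(fit, tab, log_k, n_obs) {
  free <- !tab$fixed
  p <- sum(free)
  sigma2 <- if (n_obs > p) fit$deviance / (n_obs - p) else NA_real_
  covu <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  se_nat <- rep(NA_real_, nrow(tab))
  cor <- NULL
  high_cor <- FALSE
  if (is.null(covu) || any(!is.finite(diag(covu)))) {
    high_cor <- TRUE  # singular information matrix: not identifiable
  } else {
    se_int <- sqrt(pmax(diag(covu), 0) * sigma2)
    vals <- .from_internal(fit$par, tab$name[free], log_k)
    se <- se_int
    lg <- .is_logged(tab$name[free], log_k)
    se[lg] <- log(10) * vals[lg] * se_int[lg]
    se_nat[free] <- se
    cor <- tryCatch(cov2cor(covu), error = function(e) NULL)
    if (!is.null(cor)) {
      dimnames(cor) <- list(tab$name[free], tab$name[free])
      off <- abs(cor[upper.tri(cor)])
      high_cor <- any(off > 0.95, na.rm = TRUE)
    }
  }
  list(se = se_nat, cor = cor, sigma2 = sigma2, high_correlation = high_cor)
}

#' Fit one ITC isotherm with the independent sets-of-sites model
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) on the per-injection
#' heats. Association constants are fitted internally on a log10 scale for
#' conditioning; fixed parameters never move; an optional seeded multi-start
#' returns the best of several perturbed starts. Standard errors come from
#' the Jacobian at the optimum; a warning flag is raised when any pair of
#' free parameters has |correlation| > 0.95 (poorly identifiable fit).
#'
#' @param iso An [simulate_isotherm()] / [read_isotherm_csv()] isotherm.
#' @param model0 A [binding_model()] defining the class structure and
#'   default starting values.
#' @param specs Parameter table from [fit_specs()] (default built from
#'   `model0`); at least one parameter must be free.
#' @param log_k Fit association constants as log10(K) internally.
#' @param n_starts Number of optimiser starts (first start is `specs$value`).
#' @param seed Seed for the multi-start perturbations.
#' @param exclude_first Drop the first injection from the residuals (common
#'   ITC practice for the small first injection).
#' @param control List of overrides for [minpack.lm::nls.lm.control()].
#' @return An object of class `"itc_fit"`: `params` (data frame of name,
#'   value, se, fixed), `chi2` (sum of squared residuals, J^2),
#'   `chi2_reduced`, `residuals`, `converged`, `high_correlation`, `cor`,
#'   `n_obs`, `n_free`, `ssr_starts`.
#' @export
fit_single_isotherm <- function(iso, model0, specs = NULL, log_k = TRUE,
                                n_starts = 1L, seed = NULL,
                                exclude_first = FALSE, control = NULL) {
  stopifnot(inherits(iso, "isotherm"), inherits(model0, "binding_model"),
            all(is.finite(iso$heats)))
  tab <- .spec_validate(specs %||% fit_specs(model0))
  if (!any(!tab$fixed)) stop("all parameters are fixed; nothing to fit")
  n_classes <- length(model0$site_classes)
  keep <- if (exclude_first) -1L else seq_along(iso$heats)
  obs <- iso$heats[keep]
  free <- !tab$fixed
  resid_fn <- function(pfree) {
    full <- .fill_params(tab, pfree, log_k)
    .predict_heats(full, n_classes, iso$config)[keep] - obs
  }
  start <- .to_internal(tab$value[free], tab$name[free], log_k)
  lower <- .to_internal(pmax(tab$lower[free],
                             ifelse(.is_logged(tab$name[free], log_k),
                                    1e-300, -Inf)),
                        tab$name[free], log_k)
  upper <- .to_internal(tab$upper[free], tab$name[free], log_k)
  ms <- .lm_multistart(resid_fn, start, lower, upper, n_starts, seed, control)
  fit <- ms$best
  full <- .fill_params(tab, fit$par, log_k)
  unc <- .fit_uncertainty(fit, tab, log_k, length(obs))
  params <- data.frame(name = tab$name, value = as.numeric(full[tab$name]),
                       se = unc$se, fixed = tab$fixed,
                       stringsAsFactors = FALSE)
  n_free <- sum(free)
  structure(list(params = params, chi2 = fit$deviance,
                 chi2_reduced = fit$deviance / max(length(obs) - n_free, 1L),
                 residuals = as.numeric(fit$fvec),
                 fitted = obs + as.numeric(fit$fvec),
                 converged = fit$info %in% c(1L, 2L, 3L),
                 info = fit$info, message = fit$message,
                 high_correlation = unc$high_correlation, cor = unc$cor,
                 n_obs = length(obs), n_free = n_free,
                 ssr_starts = ms$ssr_starts),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("Sets-of-sites ITC fit: SSR = %.4g, reduced = %.4g, %s\n",
              x$chi2, x$chi2_reduced,
              if (x$converged) "converged" else "NOT converged"))
  p <- x$params
  disp <- p$value
  cat(sprintf("  %-6s %12s %12s %s\n", "param", "value", "se", ""))
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-6s %12.5g %12.4g %s\n", p$name[i], disp[i], p$se[i],
                if (p$fixed[i]) "(fixed)" else ""))
  }
  if (isTRUE(x$high_correlation)) {
    cat("  warning: parameter correlations exceed |r| = 0.95;",
        "estimates are poorly identifiable\n")
  }
  invisible(x)
}

#' Global fit of an isotherm panel with shared thermodynamics
#'
#' Fits all isotherms of a panel simultaneously with one joint residual
#' vector. All shared parameters (by default every `K` and `H`) take a
#' single value across isotherms; stoichiometries are fixed; one occupancy
#' parameter `Theta_i` per isotherm scales the stoichiometry of the first
#' (highest-affinity) site class. Theta is bounded on `[0, 1.5]` by default:
#' values above 1 are allowed so that model misfit shows up in the estimate
#' rather than being clamped at the physical ceiling.
#'
#' @param panel List of isotherms sharing the injection schedule length.
#' @param model0 A [binding_model()] with the shared class structure.
#' @param specs Parameter table from [global_fit_specs()].
#' @param theta_start Starting value for every occupancy.
#' @param theta_bounds Length-2 bounds for the occupancies.
#' @inheritParams fit_single_isotherm
#' @return An object of class `"global_itc_fit"`: `shared` (parameter data
#'   frame), `theta` (data frame with per-isotherm `theta`, `se`,
#'   `condition`, `arm`, and `theta_true` when the panel is synthetic),
#'   `chi2`, `chi2_reduced`, `per_isotherm_ssr`, `residuals` (list),
#'   `converged`, `high_correlation`, `cor`, `meta`.
#' @export
fit_global <- function(panel, model0, specs = NULL, theta_start = 1,
                       theta_bounds = c(0, 1.5), log_k = TRUE,
                       n_starts = 1L, seed = NULL, control = NULL) {
  stopifnot(is.list(panel), length(panel) >= 1L,
            all(vapply(panel, inherits, logical(1), "isotherm")))
  tab <- .spec_validate(specs %||% global_fit_specs(model0))
  if (length(panel) < 2L || !any(tab$shared & !tab$fixed)) {
    warning("fewer than 2 isotherms (or no free shared parameters); ",
            "falling back to a single-isotherm fit")
    return(fit_single_isotherm(panel[[1L]], model0, specs = tab,
                               log_k = log_k, n_starts = n_starts,
                               seed = seed, control = control))
  }
  n_inj <- vapply(panel, function(p) length(p$heats), integer(1))
  if (length(unique(n_inj)) != 1L) {
    stop("all isotherms in a global fit must share the injection count")
  }
  n_classes <- length(model0$site_classes)
  m <- length(panel)
  free <- !tab$fixed
  n_shared_free <- sum(free)
  obs <- lapply(panel, `[[`, "heats")
  resid_fn <- function(p) {
    pshared <- p[seq_len(n_shared_free)]
    theta <- p[n_shared_free + seq_len(m)]
    full <- .fill_params(tab, pshared, log_k)
    unlist(lapply(seq_len(m), function(i) {
      .predict_heats(full, n_classes, panel[[i]]$config,
                     occupancy = theta[i]) - obs[[i]]
    }))
  }
  start <- c(.to_internal(tab$value[free], tab$name[free], log_k),
             rep(theta_start, m))
  lower <- c(.to_internal(pmax(tab$lower[free],
                               ifelse(.is_logged(tab$name[free], log_k),
                                      1e-300, -Inf)),
                          tab$name[free], log_k),
             rep(theta_bounds[1], m))
  upper <- c(.to_internal(tab$upper[free], tab$name[free], log_k),
             rep(theta_bounds[2], m))
  ms <- .lm_multistart(resid_fn, start, lower, upper, n_starts, seed, control)
  fit <- ms$best
  n_obs <- sum(n_inj)
  # Uncertainty on the joint parameter vector (shared block + thetas).
  joint_tab <- rbind(tab[free, , drop = FALSE],
                     do.call(rbind, lapply(seq_len(m), function(i)
                       param_spec(paste0("Theta_", i), theta_start,
                                  lower = theta_bounds[1],
                                  upper = theta_bounds[2]))))
  joint_tab$fixed <- FALSE
  unc <- .fit_uncertainty(fit, joint_tab, log_k, n_obs)
  pshared <- fit$par[seq_len(n_shared_free)]
  full <- .fill_params(tab, pshared, log_k)
  shared <- data.frame(name = tab$name, value = as.numeric(full[tab$name]),
                       se = NA_real_, fixed = tab$fixed, shared = tab$shared,
                       stringsAsFactors = FALSE)
  shared$se[free] <- unc$se[seq_len(n_shared_free)]
  theta_hat <- fit$par[n_shared_free + seq_len(m)]
  meta <- lapply(panel, `[[`, "meta")
  theta_df <- data.frame(
    isotherm = seq_len(m),
    condition = vapply(meta, function(x) {
      v <- x$condition
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1)),
    arm = vapply(meta, function(x) {
      v <- x$arm
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1)),
    theta = theta_hat,
    se = unc$se[n_shared_free + seq_len(m)],
    theta_true = vapply(meta, function(x) {
      v <- x$theta_true
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  resid_list <- split(as.numeric(fit$fvec), rep(seq_len(m), n_inj))
  per_ssr <- vapply(resid_list, function(r) sum(r^2), numeric(1))
  n_free_total <- n_shared_free + m
  structure(list(shared = shared, theta = theta_df, chi2 = fit$deviance,
                 chi2_reduced = fit$deviance / max(n_obs - n_free_total, 1L),
                 per_isotherm_ssr = as.numeric(per_ssr),
                 residuals = resid_list,
                 converged = fit$info %in% c(1L, 2L, 3L), info = fit$info,
                 message = fit$message,
                 high_correlation = unc$high_correlation, cor = unc$cor,
                 n_obs = n_obs, n_free = n_free_total, meta = meta,
                 ssr_starts = ms$ssr_starts),
            class = "global_itc_fit")
}

#' @export
print.global_itc_fit <- function(x, ...) {
  cat(sprintf(
    "Global sets-of-sites fit: %d isotherms, SSR = %.4g (reduced %.4g), %s\n",
    nrow(x$theta), x$chi2, x$chi2_reduced,
    if (x$converged) "converged" else "NOT converged"))
  cat("Shared parameters:\n")
  s <- x$shared
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-6s %12.5g %12.4g %s%s\n", s$name[i], s$value[i], s$se[i],
                if (s$fixed[i]) "(fixed) " else "",
                if (s$shared[i]) "(shared)" else ""))
  }
  cat("Occupancy (Theta) per isotherm:\n")
  print(x$theta, row.names = FALSE)
  if (isTRUE(x$high_correlation)) {
    cat("  warning: parameter correlations exceed |r| = 0.95\n")
  }
  invisible(x)
}

#' Tabulate fitted occupancy against an experimental condition
#'
#' Extracts the per-isotherm occupancy estimates of a [fit_global()] result
#' and joins them to a metadata key stored on each isotherm (typically the
#' fatty-acid mol. eq.), sorted by arm and condition — the read-out used to
#' display how the high-affinity site's availability declines with ligand
#' load.
#'
#' @param fit A `"global_itc_fit"`.
#' @param key Metadata key to report as the condition (default
#'   `"condition"`); every isotherm's `meta` must contain it.
#' @param file Optional path: write the table as CSV.
#' @return Data frame with columns `condition`, `arm`, `theta`, `se`.
#' @export
occupancy_vs_condition <- function(fit, key = "condition", file = NULL) {
  stopifnot(inherits(fit, "global_itc_fit"))
  if (!fit$converged) warning("global fit did not converge; table is tentative")
  has <- vapply(fit$meta, function(x) !is.null(x[[key]]), logical(1))
  if (!all(has)) {
    stop("metadata key '", key, "' missing for isotherm(s) ",
         paste(which(!has), collapse = ", "))
  }
  out <- data.frame(
    condition = vapply(fit$meta, function(x) as.numeric(x[[key]]), numeric(1)),
    arm = fit$theta$arm, theta = fit$theta$theta, se = fit$theta$se,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$arm, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
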