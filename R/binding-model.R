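#' One class of independent, identical binding sites
#'
#' A site class is the elementary unit of the independent sets-of-sites
#' model: `n_sites` identical and independent sites per macromolecule, each
#' with association constant `k_assoc` and molar binding enthalpy `d_h`.
#'
#' @param n_sites Stoichiometry per macromolecule (dimensionless, >= 0). A
#'   class with `n_sites = 0` contributes nothing to any output.
#' @param k_assoc Association constant in 1/(mol/L) (> 0), i.e. the
#'   concentration-based apparent constant as reported by ITC software;
#'   activity corrections are not applied.
#' @param d_h Molar binding enthalpy in J per mol of sites (any sign).
#' @return An object of class `"site_class"`.
#' @seealso [binding_model()]
#' @export
#' @examples
#' site_class(n_sites = 1, k_assoc = 2.9e5, d_h = -18e3)
site_class <- function(n_sites, k_assoc, d_h) {
  stopifnot(
    is.numeric(n_sites), length(n_sites) == 1L, is.finite(n_sites), n_sites >= 0,
    is.numeric(k_assoc), length(k_assoc) == 1L, is.finite(k_assoc), k_assoc > 0,
    is.numeric(d_h), length(d_h) == 1L, is.finite(d_h)
  )
  structure(list(n_sites = as.numeric(n_sites),
                 k_assoc = as.numeric(k_assoc),
                 d_h = as.numeric(d_h)),
            class = "site_class")
}

#' Independent sets-of-sites binding model
#'
#' Combines one or more [site_class()] objects into the "sets of sites"
#' equilibrium model: the binding polynomial is the product of the per-class
#' polynomials, so each class binds independently of the others.
#'
#' @param ... `site_class` objects, or a single list of them.
#' @param canonicalize Reorder classes by decreasing `k_assoc` (the canonical
#'   reporting order, so class 1 is always the highest-affinity set). Fitting
#'   code disables this to preserve class identity across iterations.
#' @return An object of class `"binding_model"` with element `site_classes`.
#' @export
#' @examples
#' m <- binding_model(site_class(2, 2.5e4, -8e3), site_class(1, 2.9e5, -18e3))
#' vapply(m$site_classes, `[[`, numeric(1), "k_assoc")  # decreasing
binding_model <- function(..., canonicalize = TRUE) {
  classes <- list(...)
  if (length(classes) == 1L && is.list(classes[[1L]]) &&
      !inherits(classes[[1L]], "site_class")) {
    classes <- classes[[1L]]
  }
  if (!length(classes) ||
      !all(vapply(classes, inherits, logical(1), what = "site_class"))) {
    stop("binding_model() takes one or more site_class objects")
  }
  if (canonicalize) {
    classes <- classes[order(-vapply(classes, `[[`, numeric(1), "k_assoc"))]
  }
  structure(list(site_classes = classes), class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("Independent sets-of-sites model: %d class(es)\n",
              length(x$site_classes)))
  for (i in seq_along(x$site_classes)) {
    cl <- x$site_classes[[i]]
    cat(sprintf("  class %d: N = %.4g, K = %.4g M^-1, dH = %.4g kJ/mol\n",
                i, cl$n_sites, cl$k_assoc, cl$d_h / 1e3))
  }
  invisible(x)
}

# Extract (n, K, dH) vectors from a binding_model.
.model_mats <- function(model) {
  stopifnot(inherits(model, "binding_model"))
  list(
    n  = vapply(model$site_classes, `[[`, numeric(1), "n_sites"),
    K  = vapply(model$site_classes, `[[`, numeric(1), "k_assoc"),
    dH = vapply(model$site_classes, `[[`, numeric(1), "d_h")
  )
}

#' Total binding capacity of a model
#'
#' @param model A [binding_model()].
#' @return Sum of the per-class stoichiometries (sites per macromolecule).
#' @export
binding_capacity <- function(model) sum(.model_mats(model)$n)

# Vectorised free-ligand solver shared by solve_free_ligand() and the
# isotherm simulator. Each row of nmat/Kmat together with m_total[i],
# x_total[i] defines one independent mass-balance problem
#   f(x) = x + m * sum_i n_i K_i x / (1 + K_i x) - x_total = 0.
# f is strictly increasing with f(0) <= 0 <= f(x_total), so a bracketed
# Newton iteration (bisection fallback) is globally convergent.
.free_ligand_core <- function(nmat, Kmat, m_total, x_total,
                              rel_tol = 1e-12, max_iter = 300L) {
  len <- length(x_total)
  stopifnot(length(m_total) == len, nrow(nmat) == len, nrow(Kmat) == len)
  lo <- numeric(len)
  hi <- x_total
  x <- 0.5 * x_total
  tol <- rel_tol * pmax(x_total, .Machine$double.xmin)
  # Trivial cases: no ligand, no macromolecule, or zero capacity.
  trivial <- x_total <= 0 | m_total <= 0 | rowSums(nmat) == 0
  x[trivial] <- x_total[trivial]
  x[x_total <= 0] <- 0
  done <- trivial
  for (it in seq_len(max_iter)) {
    if (all(done)) break
    Kx <- Kmat * x
    fx <- x + m_total * rowSums(nmat * Kx / (1 + Kx)) - x_total
    dfx <- 1 + m_total * rowSums(nmat * Kmat / (1 + Kx)^2)
    pos <- !done & fx > 0
    neg <- !done & fx <= 0
    hi[pos] <- x[pos]
    lo[neg] <- x[neg]
    done <- done | abs(fx) <= tol
    if (all(done)) break
    step <- x - fx / dfx
    bad <- !is.finite(step) | step <= lo | step >= hi
    step[bad] <- 0.5 * (lo[bad] + hi[bad])
    x[!done] <- step[!done]
  }
  if (all(done)) {
    # Two Newton polish steps: the f-based stopping rule bounds the mass
    # balance, but when x_free << x_total the root itself needs sharpening
    # (quadratic convergence makes the residual error negligible).
    for (polish in 1:2) {
      Kx <- Kmat * x
      fx <- x + m_total * rowSums(nmat * Kx / (1 + Kx)) - x_total
      dfx <- 1 + m_total * rowSums(nmat * Kmat / (1 + Kx)^2)
      step <- x - fx / dfx
      ok <- is.finite(step) & step >= 0 & step <= x_total & !trivial
      x[ok] <- step[ok]
    }
  }
  if (!all(done)) {
    i <- which(!done)[1L]
    cond <- structure(
      class = c("alloitc_solver_failure", "error", "condition"),
      list(message = sprintf(
             "free-ligand solver did not converge (last bracket [%.6e, %.6e])",
             lo[i], hi[i]),
           call = sys.call(-1), bracket = c(lo[i], hi[i]))
    )
    stop(cond)
  }
  theta <- Kmat * x / (1 + Kmat * x)
  list(x_free = x, theta = theta)
}

#' Solve the cell equilibrium for the free-ligand concentration
#'
#' Given total macromolecule and total ligand concentrations, solves the
#' mass-balance equation of the independent sets-of-sites model for the free
#' ligand concentration and the per-class fractional saturations
#' `theta_i = K_i x / (1 + K_i x)`.
#'
#' The mass-balance function is strictly increasing in the free ligand, so
#' the solver brackets the root on `[0, x_total]` and takes safeguarded
#' Newton steps, falling back to bisection whenever a step would leave the
#' bracket; this is globally convergent.
#'
#' @param model A [binding_model()].
#' @param m_total Total macromolecule concentration in the cell (mol/L, >= 0).
#' @param x_total Total ligand concentration in the cell (mol/L, >= 0).
#' @param rel_tol Relative tolerance on the mass balance (default `1e-12`);
#'   convergence requires `|x_free + bound - x_total| <= rel_tol * x_total`.
#' @return An object of class `"cell_state"`: a list with `m_total`,
#'   `x_total`, `x_free` and `theta` (per-class saturation, same order as
#'   `model$site_classes`).
#' @export
#' @examples
#' m <- binding_model(site_class(1, 1e6, -20e3))
#' st <- solve_free_ligand(m, m_total = 5e-5, x_total = 2.5e-5)
#' st$x_free + st$m_total * st$theta  # mass balance: equals x_total
solve_free_ligand <- function(model, m_total, x_total, rel_tol = 1e-12) {
  stopifnot(is.numeric(m_total), length(m_total) == 1L, m_total >= 0,
            is.numeric(x_total), length(x_total) == 1L, x_total >= 0,
            is.numeric(rel_tol), rel_tol > 0)
  mats <- .model_mats(model)
  sol <- .free_ligand_core(matrix(mats$n, 1L), matrix(mats$K, 1L),
                           m_total, x_total, rel_tol = rel_tol)
  structure(list(m_total = m_total, x_total = x_total,
                 x_free = sol$x_free, theta = as.numeric(sol$theta)),
            class = "cell_state")
}

#' Total heat content of the calorimeter cell
#'
#' The cumulative heat evolved if the cell contents were assembled from free
#' components: `Q = v_cell * m_total * sum_i n_i * theta_i * dH_i`. Injection
#' heats are finite differences of this quantity (plus displacement terms).
#'
#' @param state A `"cell_state"` from [solve_free_ligand()].
#' @param model The [binding_model()] the state was solved under (same class
#'   count and order).
#' @param v_cell Cell volume in litres.
#' @return Heat content in joules.
#' @export
heat_content <- function(state, model, v_cell) {
  stopifnot(inherits(state, "cell_state"), v_cell > 0)
  mats <- .model_mats(model)
  if (length(state$theta) != length(mats$n)) {
    stop("cell_state and binding_model disagree on the number of site classes")
  }
  v_cell * state$m_total * sum(mats$n * state$theta * mats$dH)
}
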