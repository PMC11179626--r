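#' Analytic one-dimensional energy landscape
#'
#' Toy landscapes stand in for a molecular force field so that the full
#' steering -> window selection -> biased sampling -> WHAM protocol can be
#' validated against closed forms on a desk. Energies are in units of kT
#' unless stated otherwise.
#'
#' @param f Potential energy function of one coordinate.
#' @param grad Its derivative.
#' @param domain Length-2 vector; trajectories leaving it abort with an
#'   unstable-step error.
#' @param label Identifier.
#' @return An object of class `"landscape"`.
#' @export
landscape <- function(f, grad, domain = c(-Inf, Inf), label = "") {
  stopifnot(is.function(f), is.function(grad), length(domain) == 2L,
            domain[1] < domain[2])
  structure(list(f = f, grad = grad, domain = domain,
                 label = as.character(label)),
            class = "landscape")
}

#' Harmonic well landscape, U(x) = kappa (x - center)^2 / 2
#'
#' @param kappa Force constant (energy per unit^2).
#' @param center Position of the minimum.
#' @param domain Allowed coordinate range.
#' @return A [landscape()].
#' @export
harmonic_landscape <- function(kappa = 1, center = 0, domain = c(-Inf, Inf)) {
  stopifnot(kappa > 0)
  landscape(function(x) 0.5 * kappa * (x - center)^2,
            function(x) kappa * (x - center),
            domain = domain, label = sprintf("harmonic(kappa=%g)", kappa))
}

#' Symmetric double-well landscape
#'
#' `U(x) = height * ((x / halfwidth)^2 - 1)^2`: minima at `x = +/-
#' halfwidth` and a barrier of exactly `height` at `x = 0`.
#'
#' @param height Barrier height (energy units, typically kT).
#' @param halfwidth Position of the minima.
#' @param domain Allowed coordinate range.
#' @return A [landscape()].
#' @export
double_well_landscape <- function(height = 5, halfwidth = 1,
                                  domain = c(-4, 4)) {
  stopifnot(height > 0, halfwidth > 0)
  a2 <- halfwidth^2
  landscape(function(x) height * (x^2 / a2 - 1)^2,
            function(x) 4 * height * x * (x^2 / a2 - 1) / a2,
            domain = domain,
            label = sprintf("double_well(h=%g)", height))
}

.unstable_stop <- function(x, step) {
  cond <- structure(
    class = c("alloitc_unstable_step", "error", "condition"),
    list(message = sprintf(
      "trajectory left the landscape domain at step %d (x = %.4g); try a smaller dt",
      step, x), call = sys.call(-1))
  )
  stop(cond)
}

#' Overdamped Langevin dynamics on a landscape
#'
#' Euler-Maruyama integration of the overdamped Langevin equation
#' `dx = -U'(x)/friction dt + sqrt(2 kT dt / friction) xi`. Optionally a
#' static harmonic bias `bias_k/2 (x - bias_center)^2` is added — this is
#' how umbrella-sampling windows are generated. Trajectories are
#' bit-reproducible for a fixed seed.
#'
#' @param landscape A [landscape()].
#' @param start Starting coordinate.
#' @param n_steps Number of integration steps.
#' @param dt Time step.
#' @param kT Thermal energy (>= 0; 0 gives deterministic gradient descent).
#' @param friction Friction coefficient (> 0).
#' @param seed Optional integer seed.
#' @param bias_center,bias_k Optional static harmonic restraint.
#' @param thin Keep every `thin`-th position.
#' @return Numeric vector of sampled positions (after each kept step).
#' @export
langevin_simulate <- function(landscape, start, n_steps, dt, kT = 1,
                              friction = 1, seed = NULL,
                              bias_center = NA_real_, bias_k = 0,
                              thin = 1L) {
  stopifnot(inherits(landscape, "landscape"), is.finite(start),
            n_steps >= 1L, dt > 0, kT >= 0, friction > 0, thin >= 1L,
            bias_k >= 0)
  grad <- landscape$grad
  dom <- landscape$domain
  biased <- bias_k > 0
  with_seed(seed, {
    noise <- if (kT > 0) rnorm(n_steps, 0, sqrt(2 * kT * dt / friction))
             else numeric(n_steps)
    out <- numeric(n_steps %/% thin)
    x <- start
    j <- 0L
    for (i in seq_len(n_steps)) {
      g <- grad(x)
      if (biased) g <- g + bias_k * (x - bias_center)
      x <- x - dt * g / friction + noise[i]
      if (!is.finite(x) || x < dom[1] || x > dom[2]) .unstable_stop(x, i)
      if (i %% thin == 0L) {
        j <- j + 1L
        out[j] <- x
      }
    }
    out
  })
}

#' Steered pulling along a coordinate
#'
#' A harmonic restraint of stiffness `k_force` whose centre moves along
#' `centers` drags the system across the landscape; the accumulated
#' external work is `W = sum k_force (center_t - x_t) * delta_center`. The
#' end-point trajectory provides starting configurations for umbrella
#' windows.
#'
#' @param landscape A [landscape()].
#' @param k_force Restraint stiffness (> 0).
#' @param from,to,n_steps Linear pulling schedule from `from` to `to` in
#'   `n_steps` steps (ignored when `centers` is given).
#' @param centers Explicit monotone schedule of restraint centres, one per
#'   step.
#' @param start Starting coordinate (default: first centre).
#' @inheritParams langevin_simulate
#' @return An object of class `"smd_trajectory"`: list with `x` (positions),
#'   `centers`, `work` (cumulative, same length), `total_work`, `k_force`.
#' @export
steered_pull <- function(landscape, k_force, from = NULL, to = NULL,
                         n_steps = NULL, centers = NULL, start = NULL,
                         dt = 1e-3, kT = 1, friction = 1, seed = NULL) {
  stopifnot(inherits(landscape, "landscape"), k_force > 0, dt > 0, kT >= 0,
            friction > 0)
  if (is.null(centers)) {
    stopifnot(is.numeric(from), is.numeric(to), n_steps >= 2L)
    centers <- seq(from, to, length.out = n_steps)
  }
  dc <- diff(centers)
  if (length(dc) && !(all(dc >= 0) || all(dc <= 0))) {
    stop("the pulling schedule must be monotone")
  }
  n <- length(centers)
  if (is.null(start)) start <- centers[1]
  grad <- landscape$grad
  dom <- landscape$domain
  with_seed(seed, {
    noise <- if (kT > 0) rnorm(n, 0, sqrt(2 * kT * dt / friction))
             else numeric(n)
    x <- numeric(n)
    w <- numeric(n)
    xi <- start
    acc <- 0
    for (i in seq_len(n)) {
      ci <- centers[i]
      if (i > 1L) acc <- acc + k_force * (ci - xi) * (ci - centers[i - 1L])
      g <- grad(xi) + k_force * (xi - ci)
      xi <- xi - dt * g / friction + noise[i]
      if (!is.finite(xi) || xi < dom[1] || xi > dom[2]) .unstable_stop(xi, i)
      x[i] <- xi
      w[i] <- acc
    }
    structure(list(x = x, centers = centers, work = w,
                   total_work = acc, k_force = k_force, dt = dt, kT = kT),
              class = "smd_trajectory")
  })
}

#' Umbrella-sampling bias window
#'
#' @param center Restraint centre (CV units).
#' @param k_force Harmonic constant (energy per CV-unit^2; 0 means an
#'   unbiased window).
#' @param samples Time series of CV values sampled under the bias.
#' @return An object of class `"bias_window"`.
#' @export
bias_window <- function(center, k_force, samples = numeric()) {
  stopifnot(is.numeric(center), length(center) == 1L, is.finite(center),
            is.numeric(k_force), length(k_force) == 1L, k_force >= 0,
            is.numeric(samples))
  structure(list(center = center, k_force = k_force,
                 samples = as.numeric(samples)),
            class = "bias_window")
}

# Histogram-intersection overlap between two sample sets on a common grid.
.hist_overlap <- function(a, b, n_bins = 30L) {
  if (!length(a) || !length(b)) return(0)
  rng <- range(c(a, b))
  if (rng[1] == rng[2]) return(1)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  pa <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), n_bins) / length(a)
  pb <- tabulate(findInterval(b, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), n_bins) / length(b)
  sum(pmin(pa, pb))
}

#' Select umbrella windows along a steered trajectory with overlap control
#'
#' Places between `n_min` and `n_max` harmonic windows spanning the CV range
#' visited by a steered pull. Each candidate window is equilibrated briefly
#' and sampled; adjacent windows must overlap (histogram intersection of
#' their samples) by at least `overlap_target`. Starting from `n_min`
#' uniformly spaced centres, extra windows are inserted midway across the
#' worst-overlapping gap until every adjacent pair satisfies the target, so
#' the spacing adapts to the local stiffness of the landscape.
#'
#' @param smd An `"smd_trajectory"` from [steered_pull()] (or any list with
#'   an `x` component spanning the CV range).
#' @param landscape The [landscape()] sampled in each window.
#' @param k_force Window stiffness; defaults to the pull stiffness.
#' @param n_min,n_max Window-count range (defaults 28 and 39).
#' @param overlap_target Minimum adjacent histogram overlap in `[0, 1]`;
#'   `0` accepts any spacing.
#' @param equil_steps,sample_steps Integration steps discarded as
#'   equilibration and kept as samples for the overlap check.
#' @inheritParams langevin_simulate
#' @return List of [bias_window()] objects (samples filled with the
#'   equilibration-run samples) with attributes `overlaps` (adjacent
#'   overlaps) and `n_windows`.
#' @export
select_windows <- function(smd, landscape, k_force = NULL, n_min = 28L,
                           n_max = 39L, overlap_target = 0.1,
                           equil_steps = 1000L, sample_steps = 2000L,
                           dt = 1e-3, kT = 1, friction = 1, thin = 2L,
                           seed = NULL) {
  stopifnot(n_min >= 1L, n_min <= n_max, overlap_target >= 0,
            overlap_target <= 1)
  k_force <- k_force %||% smd$k_force
  stopifnot(is.numeric(k_force), k_force > 0)
  rng <- range(smd$x)
  if (diff(rng) <= 0) stop("steered trajectory does not span a CV range")
  sample_window <- function(center, wseed) {
    x0 <- smd$x[which.min(abs(smd$x - center))]
    traj <- langevin_simulate(landscape, start = x0,
                              n_steps = equil_steps + sample_steps, dt = dt,
                              kT = kT, friction = friction, seed = wseed,
                              bias_center = center, bias_k = k_force,
                              thin = 1L)
    traj[-seq_len(equil_steps)][seq(1L, sample_steps, by = thin)]
  }
  centers <- seq(rng[1], rng[2], length.out = n_min)
  cache <- new.env(parent = emptyenv())
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  get_samples <- function(center) {
    key <- sprintf("%.15g", center)
    if (is.null(cache[[key]])) {
      wseed <- if (is.null(base_seed)) NULL
               else (base_seed + length(ls(cache))) %% .Machine$integer.max
      cache[[key]] <- sample_window(center, wseed)
    }
    cache[[key]]
  }
  repeat {
    samples <- lapply(centers, get_samples)
    n <- length(centers)
    overlaps <- vapply(seq_len(n - 1L), function(i)
      .hist_overlap(samples[[i]], samples[[i + 1L]]), numeric(1))
    if (overlap_target <= 0 || all(overlaps >= overlap_target)) break
    if (n >= n_max) {
      k_sugg <- k_force * max(min(overlaps) / overlap_target, 1e-3)^2
      stop(sprintf(paste0(
        "cannot reach adjacent overlap %.2f with %d windows ",
        "(worst overlap %.3f); consider a softer window stiffness, ",
        "e.g. k_force ~ %.3g"), overlap_target, n_max, min(overlaps),
        k_sugg))
    }
    worst <- which.min(overlaps)
    centers <- sort(c(centers, (centers[worst] + centers[worst + 1L]) / 2))
  }
  windows <- lapply(seq_along(centers), function(i)
    bias_window(centers[i], k_force, samples[[i]]))
  attr(windows, "overlaps") <- overlaps
  attr(windows, "n_windows") <- length(centers)
  windows
}

#' Sample all umbrella windows for production
#'
#' Runs a longer biased simulation in every window (starting from the
#' window's selection-stage samples) and returns windows whose `samples`
#' are ready for [wham_1d()].
#'
#' @param windows List of [bias_window()] from [select_windows()].
#' @param landscape The [landscape()] to sample.
#' @param n_steps Production steps per window.
#' @param equil_steps Steps discarded before recording.
#' @inheritParams langevin_simulate
#' @return The windows with `samples` replaced by the production samples.
#' @export
sample_windows <- function(windows, landscape, n_steps = 20000L,
                           equil_steps = 1000L, dt = 1e-3, kT = 1,
                           friction = 1, thin = 5L, seed = NULL) {
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    x0 <- if (length(w$samples)) w$samples[length(w$samples)] else w$center
    wseed <- if (is.null(base_seed)) NULL
             else (base_seed + i) %% .Machine$integer.max
    traj <- langevin_simulate(landscape, start = x0,
                              n_steps = equil_steps + n_steps, dt = dt,
                              kT = kT, friction = friction, seed = wseed,
                              bias_center = w$center, bias_k = w$k_force,
                              thin = 1L)
    bias_window(w$center, w$k_force,
                traj[-seq_len(equil_steps)][seq(1L, n_steps, by = thin)])
  })
}
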