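#' Weighted histogram analysis of umbrella-sampling windows
#'
#' Iterates the WHAM self-consistent equations over a common bin grid:
#' unnormalised `P(b) = sum_w n_w(b) / sum_w N_w exp((f_w - U_w(b)) / kT)`
#' and `f_w = -kT log sum_b P(b) exp(-U_w(b) / kT)`, where `U_w(b)` is the
#' harmonic bias of window `w` evaluated at bin centre `b`, until the
#' largest change in any `f_w` falls below `tol`. The free-energy profile
#' is `dG(b) = -kT log P(b)`, shifted so its minimum is zero. Window free
#' energies are anchored by `f_1 = 0`.
#'
#' Bins with no counts are reported as gaps (`NA`), never interpolated.
#'
#' @param windows List of [bias_window()] objects; at least one must carry
#'   samples. A window with zero `k_force` is unbiased.
#' @param n_bins Number of histogram bins (default 200).
#' @param kT Thermal energy unit of the output (default 1: profiles in kT).
#' @param tol Convergence tolerance on `max |delta f_w|` (kT units).
#' @param max_iter Iteration cap; non-convergence returns the profile with
#'   `converged = FALSE`, a warning and the tail of the `f` history.
#' @param range Optional length-2 binning range (default: the sample range).
#'   Samples outside it are dropped.
#' @return An object of class `"free_energy_profile"`: `bins` (centres),
#'   `delta_g` (kT), `counts`, `f` (window free energies), `converged`,
#'   `n_iter`, `kT`, `breaks`.
#' @export
wham_1d <- function(windows, n_bins = 200L, kT = 1, tol = 1e-8,
                    max_iter = 1e5, range = NULL) {
  stopifnot(is.list(windows), length(windows) >= 1L,
            all(vapply(windows, inherits, logical(1), "bias_window")),
            n_bins >= 2L, kT > 0, tol > 0, max_iter >= 1)
  samp <- lapply(windows, `[[`, "samples")
  if (!any(lengths(samp) > 0)) stop("no window carries samples")
  if (is.null(range)) range <- base::range(unlist(samp))
  stopifnot(length(range) == 2L, range[1] < range[2])
  breaks <- seq(range[1], range[2], length.out = n_bins + 1L)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  W <- length(windows)
  counts <- vapply(samp, function(s) {
    idx <- findInterval(s, breaks, rightmost.closed = TRUE)
    tabulate(idx[idx >= 1L & idx <= n_bins], n_bins)
  }, integer(n_bins))
  counts <- matrix(counts, nrow = n_bins, ncol = W)
  Nw <- colSums(counts)
  ctot <- rowSums(counts)
  centers <- vapply(windows, `[[`, numeric(1), "center")
  kf <- vapply(windows, `[[`, numeric(1), "k_force")
  U <- 0.5 * outer(mids, centers, `-`)^2 %*% diag(kf, W)   # B x W bias matrix
  M <- exp(-U / kT)
  f <- numeric(W)
  f_hist <- NULL
  converged <- FALSE
  iter <- 0L
  P <- ctot
  for (iter in seq_len(max_iter)) {
    a <- Nw * exp(f / kT)
    denom <- as.numeric(M %*% a)
    P <- ctot / denom
    fnew <- -kT * log(as.numeric(crossprod(M, P)))
    fnew <- fnew - fnew[1L]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (iter %% 100L == 0L || delta < tol) {
      f_hist <- rbind(utils::tail(f_hist, 9L), f)
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  G <- -kT * log(P)
  G[ctot == 0L] <- NA_real_
  G <- G - min(G, na.rm = TRUE)
  if (!converged) {
    warning(sprintf("WHAM did not converge in %d iterations (last delta f = %.3g)",
                    as.integer(max_iter), delta))
  }
  structure(list(bins = mids, delta_g = as.numeric(G), counts = ctot, f = f,
                 converged = converged, n_iter = iter, kT = kT,
                 breaks = breaks,
                 f_history = if (!converged) f_hist else NULL),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  gaps <- sum(is.na(x$delta_g))
  cat(sprintf(
    "Free-energy profile: %d bins on [%.4g, %.4g], max dG = %.3g kT%s\n",
    length(x$bins), min(x$breaks), max(x$breaks),
    max(x$delta_g, na.rm = TRUE),
    if (gaps) sprintf(" (%d empty bins)", gaps) else ""))
  if (!x$converged) cat("  WHAM iteration did NOT converge\n")
  invisible(x)
}

#' Read a free-energy profile at a target CV value
#'
#' Linear interpolation of the profile at `target`; used to extract the
#' free-energy cost of reaching a reference (e.g. closed-state) CV value.
#' Targets outside the binned range are refused rather than extrapolated.
#'
#' @param profile A `"free_energy_profile"` from [wham_1d()].
#' @param target CV value at which to read the profile.
#' @return Interpolated free energy (kT units).
#' @export
delta_g_at_target <- function(profile, target) {
  stopifnot(inherits(profile, "free_energy_profile"),
            is.numeric(target), length(target) == 1L, is.finite(target))
  ok <- is.finite(profile$delta_g)
  xs <- profile$bins[ok]
  if (target < min(xs) || target > max(xs)) {
    stop(sprintf(
      "target %.4g lies outside the sampled profile range [%.4g, %.4g]; refusing to extrapolate",
      target, min(xs), max(xs)))
  }
  approx(xs, profile$delta_g[ok], xout = target)$y
}

#' Free-energy difference between two systems at a target CV value
#'
#' Computes `dG_profile(target) - dG_reference(target)`: the extra
#' free-energy cost, relative to a named reference system, of bringing the
#' CV to its target (closed-state) value. Summing such differences over a
#' set of CVs gives the cumulative relative cost of the transition.
#'
#' @param profile,reference `"free_energy_profile"` objects for the system
#'   of interest and the reference system.
#' @param target CV value at which both profiles are read.
#' @return Relative free energy (kT units).
#' @export
profile_diff <- function(profile, reference, target) {
  delta_g_at_target(profile, target) - delta_g_at_target(reference, target)
}
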