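# Waveform optimisation: maximise noise-free TDR over
# (delta1, Delta1, delta2, Delta2) at fixed b under hardware constraints,
# with G solved from b for each shell. Because
# TDR = 1 - S1_mean/S2_mean and each shell's spherical mean depends only on
# its own timings, the 4-D problem decouples into minimising the mean
# signal for shell 1 and maximising it for shell 2 over the same feasible
# (delta, Delta) region; the exhaustive grid plus Nelder-Mead polish below
# exploits this.

.feasible_timings <- function(delta, Delta, constraints, b, min_gap) {
  if (delta <= 0 || Delta < delta + min_gap) return(FALSE)
  if (delta + Delta > constraints$T_max) return(FALSE)
  G <- gradient_for_b(b, delta, Delta)
  G <= constraints$G_max
}

.mean_signal_at <- function(delta, Delta, sub, b, dirs, n_bins) {
  w <- sde_waveform(delta, Delta, b = b)
  spherical_mean(substrate_shell(sub, w, dirs, n_bins = n_bins))
}

#' Noise-free TDR objective over the 4-D timing space
#'
#' Evaluates `TDR = (S2 - S1)/S2` from 60-direction spherical means, where
#' shell 1 is built from `(delta1, Delta1)` and shell 2 from
#' `(delta2, Delta2)`, each with G solved from the common b-value.
#'
#' @param params Numeric vector `c(delta1, Delta1, delta2, Delta2)` in ms.
#' @param sub A [substrate()].
#' @param constraints A [scanner_constraints()].
#' @param b Common b-value, ms/um^2.
#' @param dirs Gradient direction matrix (default: 60 repulsion directions).
#' @param min_gap Minimum `Delta - delta`, ms. The default of 2 ms reserves
#'   room for the refocusing pulse between the two gradient lobes, matching
#'   practical spin-echo implementations.
#' @param n_bins Diameter bins for the substrate discretisation.
#' @param penalty Value returned for infeasible parameters (set to `NA` to
#'   propagate instead).
#' @return TDR (dimensionless), or `penalty` when infeasible.
#' @export
tdr_objective <- function(params, sub, constraints, b = 8, dirs = NULL,
                          min_gap = 2, n_bins = 50, penalty = -1e6) {
  if (is.null(dirs)) dirs <- generate_directions(60)
  ok1 <- .feasible_timings(params[1], params[2], constraints, b, min_gap)
  ok2 <- .feasible_timings(params[3], params[4], constraints, b, min_gap)
  if (!ok1 || !ok2) return(penalty)
  s1 <- .mean_signal_at(params[1], params[2], sub, b, dirs, n_bins)
  s2 <- .mean_signal_at(params[3], params[4], sub, b, dirs, n_bins)
  (s2 - s1) / s2
}

# grid of feasible (delta, Delta) with mean signals; shared by both shells
.signal_grid <- function(sub, constraints, b, dirs, n_grid, min_gap, n_bins,
                         delta_min = 0.5) {
  d_hi <- (constraints$T_max - min_gap) / 2
  deltas <- seq(delta_min, d_hi, length.out = n_grid)
  rows <- list()
  for (de in deltas) {
    Dl <- seq(de + min_gap, constraints$T_max - de, length.out = n_grid)
    G <- sqrt(b / (de^2 * (Dl - de / 3))) / .gamma_eff
    keep <- G <= constraints$G_max & Dl >= de + min_gap
    if (!any(keep)) next
    s <- vapply(Dl[keep], function(De)
      .mean_signal_at(de, De, sub, b, dirs, n_bins), numeric(1))
    rows[[length(rows) + 1L]] <-
      data.frame(delta = de, Delta = Dl[keep], G = G[keep], signal = s)
  }
  if (!length(rows)) stop("empty feasible region", call. = FALSE)
  do.call(rbind, rows)
}

# Nelder-Mead polish of one shell's timings
.polish_shell <- function(start, sub, constraints, b, dirs, min_gap, n_bins,
                          maximise) {
  sgn <- if (maximise) -1 else 1
  fn <- function(p) {
    if (!.feasible_timings(p[1], p[2], constraints, b, min_gap)) return(1e6)
    sgn * .mean_signal_at(p[1], p[2], sub, b, dirs, n_bins)
  }
  fit <- stats::optim(start, fn, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-8))
  fit$par
}

#' Optimise the TDR waveform pair under hardware constraints
#'
#' Exhaustive coarse grid over feasible `(delta, Delta)` pairs (G solved
#' from the fixed b-value) followed by a derivative-free local polish.
#' Shell 1 minimises and shell 2 maximises the substrate's spherical-mean
#' signal; their combination maximises TDR.
#'
#' @inheritParams tdr_objective
#' @param n_grid Grid density per timing axis (default 40).
#' @param refine Run the Nelder-Mead polish after the grid stage.
#' @return An object of class `tdr_optimisation`: waveforms `shell1` and
#'   `shell2`, `tdr_opt`, spherical means `s1_mean` / `s2_mean`, their
#'   difference `signal_diff`, the grid `trace`, and the inputs.
#' @examples
#' \donttest{
#' sub <- preset_substrates()$large_cylinders
#' opt <- optimise_tdr(sub, scanner_constraints(600, 45), b = 8, n_grid = 20)
#' opt$shell2$Delta  # ~31 ms
#' }
#' @export
optimise_tdr <- function(sub, constraints, b = 8, dirs = NULL, n_grid = 40,
                         refine = TRUE, min_gap = 2, n_bins = 50) {
  stopifnot(inherits(sub, "substrate"), inherits(constraints, "scanner_constraints"))
  if (is.null(dirs)) dirs <- generate_directions(60)
  grid <- .signal_grid(sub, constraints, b, dirs, n_grid, min_gap, n_bins)
  p1 <- unlist(grid[which.min(grid$signal), c("delta", "Delta")])
  p2 <- unlist(grid[which.max(grid$signal), c("delta", "Delta")])
  if (refine) {
    p1 <- .polish_shell(p1, sub, constraints, b, dirs, min_gap, n_bins, FALSE)
    p2 <- .polish_shell(p2, sub, constraints, b, dirs, min_gap, n_bins, TRUE)
  }
  shell1 <- sde_waveform(unname(p1[1]), unname(p1[2]), b = b)
  shell2 <- sde_waveform(unname(p2[1]), unname(p2[2]), b = b)
  s1 <- .mean_signal_at(shell1$delta, shell1$Delta, sub, b, dirs, n_bins)
  s2 <- .mean_signal_at(shell2$delta, shell2$Delta, sub, b, dirs, n_bins)
  structure(list(shell1 = shell1, shell2 = shell2,
                 tdr_opt = (s2 - s1) / s2,
                 s1_mean = s1, s2_mean = s2, signal_diff = s2 - s1,
                 trace = grid, constraints = constraints, b = b,
                 min_gap = min_gap,
                 substrate = if (is.null(sub$label)) "substrate" else sub$label),
            class = "tdr_optimisation")
}

#' @export
print.tdr_optimisation <- function(x, ...) {
  cat(sprintf("TDR optimisation (%s, b = %g ms/um^2, G <= %g mT/m, T <= %g ms)\n",
              x$substrate, x$b, x$constraints$G_max, x$constraints$T_max))
  cat(sprintf("  shell1: delta = %.2f, Delta = %.2f ms, G = %.1f mT/m\n",
              x$shell1$delta, x$shell1$Delta, x$shell1$G))
  cat(sprintf("  shell2: delta = %.2f, Delta = %.2f ms, G = %.1f mT/m\n",
              x$shell2$delta, x$shell2$Delta, x$shell2$G))
  cat(sprintf("  TDR = %.4f (S1 = %.4f, S2 = %.4f, S2 - S1 = %.4f)\n",
              x$tdr_opt, x$s1_mean, x$s2_mean, x$signal_diff))
  invisible(x)
}

#' Optimise across the four reference hardware constraint sets
#'
#' Runs [optimise_tdr()] for a typical pre-clinical scanner (600 mT/m,
#' 45 ms), a high-gradient pre-clinical system (2700 mT/m, 45 ms), a
#' Connectome-class human scanner (300 mT/m, 80 ms) and a high-performance
#' clinical scanner (80 mT/m, 80 ms).
#'
#' @inheritParams optimise_tdr
#' @return A list of `tdr_optimisation` results named by
#'   `"G<g>_T<t>"`, plus a summary data.frame in attribute `"summary"`.
#' @export
hardware_sweep <- function(sub, b = 8, dirs = NULL, n_grid = 40,
                           refine = TRUE, min_gap = 2, n_bins = 50) {
  sets <- list(c(600, 45), c(2700, 45), c(300, 80), c(80, 80))
  if (is.null(dirs)) dirs <- generate_directions(60)
  out <- lapply(sets, function(gt)
    optimise_tdr(sub, scanner_constraints(gt[1], gt[2]), b = b, dirs = dirs,
                 n_grid = n_grid, refine = refine, min_gap = min_gap,
                 n_bins = n_bins))
  names(out) <- vapply(sets, function(gt) sprintf("G%d_T%d", gt[1], gt[2]), "")
  attr(out, "summary") <- data.frame(
    G_max = vapply(sets, `[`, numeric(1), 1),
    T_max = vapply(sets, `[`, numeric(1), 2),
    delta1 = vapply(out, function(r) r$shell1$delta, numeric(1)),
    Delta1 = vapply(out, function(r) r$shell1$Delta, numeric(1)),
    delta2 = vapply(out, function(r) r$shell2$delta, numeric(1)),
    Delta2 = vapply(out, function(r) r$shell2$Delta, numeric(1)),
    tdr = vapply(out, function(r) r$tdr_opt, numeric(1)),
    signal_diff = vapply(out, function(r) r$signal_diff, numeric(1)))
  out
}

#' Non-optimised waveform pair for a constraint set
#'
#' The original TDR strategy: both shells share the shortest gradient
#' duration achievable at `G_max` and only the diffusion time changes --
#' shell 1 takes the minimum `Delta`, shell 2 the maximum allowed by
#' `T_max`. Used as the comparison baseline for [optimise_tdr()].
#'
#' @inheritParams optimise_tdr
#' @return A list with [sde_waveform()] elements `shell1` and `shell2`.
#' @examples
#' non_optimised_pair(scanner_constraints(600, 45), b = 8)  # ~ (6.9, 8.9/38.1)
#' @export
non_optimised_pair <- function(constraints, b = 8, min_gap = 2) {
  stopifnot(inherits(constraints, "scanner_constraints"))
  # smallest delta whose minimum-Delta waveform still reaches b at G_max
  f <- function(de) bvalue(de, de + min_gap, constraints$G_max) - b
  hi <- (constraints$T_max - min_gap) / 2
  if (f(hi) < 0) stop("empty feasible region", call. = FALSE)
  de <- stats::uniroot(f, c(1e-3, hi), tol = 1e-10)$root
  list(shell1 = sde_waveform(de, de + min_gap, b = b),
       shell2 = sde_waveform(de, constraints$T_max - de, b = b))
}
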