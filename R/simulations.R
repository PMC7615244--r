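# Desk-scale experiment runners mirroring the three simulation studies:
# waveform optimisation, TDR over size-distribution grids, and subset-TDR
# under Rician noise.

#' Simulation 1: waveform optimisation with signal maps
#'
#' Runs the constrained TDR optimisation for one substrate and constraint
#' set, and returns the optimum together with the full (delta, Delta)
#' spherical-mean signal map explored by the grid stage.
#'
#' @inheritParams optimise_tdr
#' @return A list with `optimum` (a `tdr_optimisation`) and `signal_map`
#'   (data.frame of `delta`, `Delta`, `G`, `signal`).
#' @export
run_sim1 <- function(sub, constraints, b = 8, dirs = NULL, n_grid = 40,
                     refine = TRUE, min_gap = 2, n_bins = 50) {
  opt <- optimise_tdr(sub, constraints, b = b, dirs = dirs, n_grid = n_grid,
                      refine = refine, min_gap = min_gap, n_bins = n_bins)
  list(optimum = opt, signal_map = opt$trace)
}

#' Simulation 2: TDR over a grid of size distributions
#'
#' Computes the noise-free TDR for a fixed waveform pair across a grid of
#' diameter-distribution parameters (mean along one axis, standard
#' deviation along the other). Gamma (cylinder) cells where the 20 um
#' truncation shifts the mean by more than 10% are marked inadmissible and
#' their TDR is `NA`.
#'
#' @param shell1,shell2 [sde_waveform()] objects with equal b.
#' @param geometry `"cylinder"` (gamma distributions, single bundle) or
#'   `"sphere"` (normal distributions).
#' @param means,sds Grid axes in um. Defaults: cylinders mean 0.5-10 um by
#'   sd 0.1-4 um (20 x 20); spheres mean 2-20 um by sd 0.1-3 um.
#' @param dirs Direction matrix (default 60 repulsion directions).
#' @param n_bins Diameter bins per cell.
#' @return Data.frame with columns `mean`, `sd`, `admissible`, `tdr`.
#' @export
run_sim2 <- function(shell1, shell2, geometry = c("cylinder", "sphere"),
                     means = NULL, sds = NULL, dirs = NULL, n_bins = 50) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(shell1, "sde_waveform"), inherits(shell2, "sde_waveform"))
  if (abs(shell1$b - shell2$b) > 1e-6 * max(shell1$b, 1))
    stop("shells must share the same b-value", call. = FALSE)
  if (is.null(means))
    means <- if (geometry == "cylinder") seq(0.5, 10, length.out = 20)
             else seq(2, 20, length.out = 20)
  if (is.null(sds))
    sds <- if (geometry == "cylinder") seq(0.1, 4, length.out = 20)
           else seq(0.1, 3, length.out = 20)
  if (is.null(dirs)) dirs <- generate_directions(60)
  family <- if (geometry == "cylinder") "gamma" else "normal"
  grid <- expand.grid(mean = means, sd = sds)
  grid$admissible <- TRUE
  grid$tdr <- NA_real_
  for (i in seq_len(nrow(grid))) {
    dist <- diameter_distribution(family, grid$mean[i], grid$sd[i])
    if (!truncation_admissible(dist)) {
      grid$admissible[i] <- FALSE
      next
    }
    sub <- substrate(geometry, dist)
    s1 <- spherical_mean(substrate_shell(sub, shell1, dirs, n_bins = n_bins))
    s2 <- spherical_mean(substrate_shell(sub, shell2, dirs, n_bins = n_bins))
    grid$tdr[i] <- (s2 - s1) / s2
  }
  grid
}

#' Simulation 3: subset-TDR curves under Rician noise
#'
#' For one, two and three orthogonal bundles of the large-cylinder
#' distribution plus a sphere substrate, simulates the given waveform pair,
#' runs the Rician noise ensemble, and returns the `TDR_M` accuracy /
#' precision curves together with the cross-configuration coefficient of
#' variation over the bundle substrates.
#'
#' @param shell1,shell2 [sde_waveform()] objects with equal b.
#' @param spec A [noise_spec()].
#' @param dirs Direction matrix (default 60 repulsion directions).
#' @param cylinder_dist,sphere_dist Diameter distributions for the bundle
#'   and sphere substrates (defaults: gamma mean 5.33 / sd 3.00 um and
#'   normal mean 7 / sd 0.5 um).
#' @param n_bins Diameter bins.
#' @return A list with `curves` (data.frame of `config`, `M`,
#'   `noise_free`, `ensemble_mean`, `ensemble_sd`), `cov` (data.frame `M`,
#'   `cov` across the bundle configurations) and `M_min`.
#' @export
run_sim3 <- function(shell1, shell2, spec, dirs = NULL,
                     cylinder_dist = diameter_distribution("gamma", 5.33, 3.00),
                     sphere_dist = diameter_distribution("normal", 7, 0.5),
                     n_bins = 50) {
  stopifnot(inherits(spec, "noise_spec"))
  if (is.null(dirs)) dirs <- generate_directions(60)
  configs <- list(
    bundles1 = substrate("cylinder", cylinder_dist,
                         bundle_axes = fibre_configuration(1)),
    bundles2 = substrate("cylinder", cylinder_dist,
                         bundle_axes = fibre_configuration(2)),
    bundles3 = substrate("cylinder", cylinder_dist,
                         bundle_axes = fibre_configuration(3)),
    spheres = substrate("sphere", sphere_dist))
  pairs <- lapply(configs, function(sub) list(
    s1 = substrate_shell(sub, shell1, dirs, n_bins = n_bins),
    s2 = substrate_shell(sub, shell2, dirs, n_bins = n_bins)))
  curves <- do.call(rbind, lapply(names(pairs), function(nm) {
    r <- tdr_noise_ensemble(pairs[[nm]]$s1, pairs[[nm]]$s2, spec)
    data.frame(config = nm, M = r$M, noise_free = r$noise_free,
               ensemble_mean = r$ensemble_mean, ensemble_sd = r$ensemble_sd)
  }))
  cov <- cov_across_configs(pairs[c("bundles1", "bundles2", "bundles3")], spec)
  list(curves = curves, cov = cov$curve, M_min = cov$M_min)
}
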