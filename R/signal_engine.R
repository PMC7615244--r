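# Gaussian phase distribution (GPD) series for restricted diffusion in
# impermeable cylinders and spheres under a rectangular SDE pulse pair.
# Attenuation for a pore of radius R transverse to a gradient of amplitude
# G is
#   -ln S = 2 (gamma G)^2 sum_m B_m(delta, Delta; D alpha_m^2)
#                         / (D^2 alpha_m^6 (beta_m^2 - c)),
#   B_m = 2 D a^2 delta - 2 + 2 e^{-D a^2 delta} + 2 e^{-D a^2 Delta}
#         - e^{-D a^2 (Delta - delta)} - e^{-D a^2 (Delta + delta)},
# where alpha_m = beta_m / R, beta_m the m-th positive root of J1'(x) = 0
# (cylinder, c = 1) or of the derivative of the first spherical Bessel
# function j1'(x) = 0 (sphere, c = 2).

.engine_cache <- new.env(parent = emptyenv())

# roots of J1'(x) = 0; J1'(x) = J0(x) - J1(x)/x
.bessel_roots_cylinder <- function(n = 60L) {
  key <- paste0("cyl", n)
  if (!is.null(.engine_cache[[key]])) return(.engine_cache[[key]])
  f <- function(x) besselJ(x, 0) - besselJ(x, 1) / x
  r <- vapply(seq_len(n), function(m) {
    stats::uniroot(f, c(max((m - 0.75) * pi, 0.5), (m + 0.35) * pi),
                   tol = 1e-13)$root
  }, numeric(1))
  .engine_cache[[key]] <- r
  r
}

# roots of j1'(x) = 0, i.e. of 2 x cos x + (x^2 - 2) sin x = 0
.bessel_roots_sphere <- function(n = 60L) {
  key <- paste0("sph", n)
  if (!is.null(.engine_cache[[key]])) return(.engine_cache[[key]])
  f <- function(x) 2 * x * cos(x) + (x^2 - 2) * sin(x)
  r <- vapply(seq_len(n), function(m) {
    stats::uniroot(f, c((m - 0.5) * pi + 1e-9, (m + 0.5) * pi - 1e-9),
                   tol = 1e-13)$root
  }, numeric(1))
  .engine_cache[[key]] <- r
  r
}

# C(d) such that -ln S = (gamma_eff * G_perp)^2 * C(d), vectorised over
# diameters. Roots are added (in blocks) until the last block contributes
# less than rel_tol of the running sum for every diameter; at least
# min_roots are always used.
.gpd_coefficient <- function(diameters, delta, Delta, D,
                             geometry = c("cylinder", "sphere"),
                             rel_tol = 1e-8, min_roots = 20L,
                             max_roots = 240L) {
  geometry <- match.arg(geometry)
  R <- diameters / 2
  total <- numeric(length(R))
  m0 <- 0L
  block <- min_roots
  repeat {
    n_need <- m0 + block
    beta <- if (geometry == "cylinder") .bessel_roots_cylinder(max(60L, n_need))
            else .bessel_roots_sphere(max(60L, n_need))
    if (n_need > length(beta)) stop("truncation-failure: GPD series did not converge",
                                    call. = FALSE)
    idx <- (m0 + 1L):n_need
    bi <- beta[idx]
    cfac <- if (geometry == "cylinder") bi^2 - 1 else bi^2 - 2
    # alpha = beta / R: outer over (roots, diameters)
    a2 <- outer(bi^2, 1 / R^2)           # alpha^2
    Da2 <- D * a2
    brack <- 2 * Da2 * delta - 2 +
      2 * exp(-Da2 * delta) + 2 * exp(-Da2 * Delta) -
      exp(-Da2 * (Delta - delta)) - exp(-Da2 * (Delta + delta))
    a6 <- a2^3
    contrib <- colSums(brack / (D^2 * a6 * cfac))
    total <- total + 2 * contrib
    m0 <- n_need
    done <- all(abs(contrib) <= rel_tol * pmax(abs(total), .Machine$double.eps))
    if (done) break
    if (m0 >= max_roots)
      stop("truncation-failure: GPD series did not converge within ",
           max_roots, " roots", call. = FALSE)
    block <- 20L
  }
  total
}

#' Transverse restricted-diffusion attenuation in a cylinder
#'
#' GPD-series signal fraction for spins inside an impermeable cylinder of
#' the given diameter with the gradient perpendicular to its axis.
#'
#' @param diameter Cylinder diameter, um (> 0). Vectorised.
#' @param w An [sde_waveform()].
#' @param D Intrinsic diffusivity, um^2/ms.
#' @return Signal fraction(s) in (0, 1].
#' @examples
#' w <- sde_waveform(6.9, 9, b = 8)
#' cylinder_perp_attenuation(5, w)
#' @export
cylinder_perp_attenuation <- function(diameter, w, D = 2) {
  stopifnot(inherits(w, "sde_waveform"), all(diameter > 0), D > 0)
  C <- .gpd_coefficient(diameter, w$delta, w$Delta, D, "cylinder")
  exp(-(.gamma_eff * w$G)^2 * C)
}

#' Restricted-diffusion attenuation in a sphere
#'
#' GPD-series signal fraction for spins inside an impermeable sphere;
#' independent of gradient direction.
#'
#' @inheritParams cylinder_perp_attenuation
#' @return Signal fraction(s) in (0, 1].
#' @export
sphere_attenuation <- function(diameter, w, D = 2) {
  stopifnot(inherits(w, "sde_waveform"), all(diameter > 0), D > 0)
  C <- .gpd_coefficient(diameter, w$delta, w$Delta, D, "sphere")
  exp(-(.gamma_eff * w$G)^2 * C)
}

#' Signal from a cylinder at arbitrary gradient orientation
#'
#' Composes free diffusion along the cylinder axis with GPD-restricted
#' diffusion transverse to it:
#' \eqn{S = e^{-b D \cos^2\theta} \, S_\perp(G \sin\theta)} with
#' \eqn{\cos\theta} the axis / gradient-direction dot product.
#'
#' @param diameter Cylinder diameter, um.
#' @param axis Unit 3-vector, cylinder axis.
#' @param g_dir Unit 3-vector, gradient direction.
#' @inheritParams cylinder_perp_attenuation
#' @return Signal fraction in (0, 1].
#' @export
cylinder_signal <- function(diameter, axis, g_dir, w, D = 2) {
  axis <- axis / sqrt(sum(axis^2))
  g_dir <- g_dir / sqrt(sum(g_dir^2))
  ct <- sum(axis * g_dir)
  st2 <- max(0, 1 - ct^2)
  C <- .gpd_coefficient(diameter, w$delta, w$Delta, D, "cylinder")
  exp(-w$b * D * ct^2) * exp(-(.gamma_eff * w$G)^2 * st2 * C)
}

#' Per-direction shell signals
#'
#' Container pairing one waveform with a direction set and the normalised
#' signal measured along each direction.
#'
#' @param waveform An [sde_waveform()].
#' @param directions `N x 3` matrix of unit gradient directions.
#' @param signals Length-`N` vector of signal fractions in `[0, 1]`.
#' @return An object of class `shell_signals`.
#' @export
shell_signals <- function(waveform, directions, signals) {
  stopifnot(inherits(waveform, "sde_waveform"))
  directions <- as.matrix(directions)
  if (ncol(directions) != 3) stop("directions must be N x 3", call. = FALSE)
  if (nrow(directions) != length(signals))
    stop("signals length must match direction count", call. = FALSE)
  nn <- sqrt(rowSums(directions^2))
  if (any(abs(nn - 1) > 1e-6))
    stop("directions must be unit vectors", call. = FALSE)
  structure(list(waveform = waveform, directions = directions,
                 signals = as.numeric(signals)),
            class = "shell_signals")
}

#' @export
print.shell_signals <- function(x, ...) {
  cat(sprintf("Shell of %d directions, b = %.4g ms/um^2, mean signal %.4f\n",
              length(x$signals), x$waveform$b, mean(x$signals)))
  invisible(x)
}

# per-direction signals for a cylinder substrate given axis set (orientation
# matrix K x 3 with weights); vectorised over directions and diameters
.cylinder_dir_signals <- function(dirs, axes, axis_weights, wd, w, D) {
  C <- .gpd_coefficient(wd$diameters, w$delta, w$Delta, D, "cylinder")
  acc <- numeric(nrow(dirs))
  for (k in seq_len(nrow(axes))) {
    ct <- as.vector(dirs %*% axes[k, ])
    st2 <- pmax(0, 1 - ct^2)
    lnS_perp <- -(.gamma_eff * w$G)^2 * outer(st2, C)
    S <- exp(-w$b * D * ct^2) * exp(lnS_perp)   # N x n_diam
    acc <- acc + axis_weights[k] * as.vector(S %*% wd$weights)
  }
  acc
}

#' Simulate one shell for a substrate
#'
#' Computes the normalised signal along each gradient direction for a
#' substrate (mixture over bundles, diameter bins and, when `kappa` is set,
#' a Watson orientation grid). Sphere substrates are orientation
#' independent and return a constant signal across directions.
#'
#' @param sub A [substrate()].
#' @param w An [sde_waveform()].
#' @param dirs `N x 3` matrix of unit gradient directions.
#' @param n_bins Diameter bins used to discretise the size distribution.
#' @param n_watson Orientation grid size when the substrate is dispersed.
#' @return A [shell_signals()] object.
#' @examples
#' dirs <- generate_directions(30, seed = 1)
#' sub <- preset_substrates()$large_cylinders
#' s <- substrate_shell(sub, sde_waveform(6.9, 9, b = 8), dirs)
#' @export
substrate_shell <- function(sub, w, dirs, n_bins = 50, n_watson = 200) {
  stopifnot(inherits(sub, "substrate"), inherits(w, "sde_waveform"))
  dirs <- as.matrix(dirs)
  wd <- discretise(sub$distribution, sub$geometry, n_bins)
  D <- sub$diffusivity
  if (sub$geometry == "sphere") {
    s <- sum(sphere_attenuation(wd$diameters, w, D) * wd$weights)
    return(shell_signals(w, dirs, rep(s, nrow(dirs))))
  }
  acc <- numeric(nrow(dirs))
  for (i in seq_along(sub$bundle_axes)) {
    ax <- sub$bundle_axes[[i]]
    if (is.null(sub$kappa)) {
      axes <- matrix(ax, 1, 3)
      aw <- 1
    } else {
      wo <- watson_orientations(sub$kappa, mean_axis = ax, n_samples = n_watson)
      axes <- wo$orientations
      aw <- wo$weights
    }
    acc <- acc + sub$fractions[i] *
      .cylinder_dir_signals(dirs, axes, aw, wd, w, D)
  }
  shell_signals(w, dirs, acc)
}

#' Random-walk Monte Carlo oracle for a single pore
#'
#' Brute-force validation of the GPD engine: spins perform a Gaussian
#' random walk with elastic (radial) reflection inside a single cylinder
#' cross-section (2-D disc, gradient transverse to the axis) or sphere,
#' accumulating phase under the rectangular pulse pair. Returns the
#' magnitude of the ensemble-average transverse magnetisation.
#'
#' @param geometry `"cylinder"`, `"sphere"`, or `"free"` (no boundary;
#'   closed-form Gaussian check).
#' @param diameter Pore diameter, um (ignored for `"free"`).
#' @param w An [sde_waveform()].
#' @param D Intrinsic diffusivity, um^2/ms.
#' @param n_walkers Number of spins.
#' @param dt Time step, ms; defaults to the largest step satisfying
#'   `sqrt(2 D dt) <= diameter / 10`, capped at 0.05 ms.
#' @param seed RNG seed (local to this call).
#' @return A list with `signal`, its Monte-Carlo standard error `se`, and
#'   the step count.
#' @export
mc_oracle <- function(geometry = c("cylinder", "sphere", "free"), diameter,
                      w, D = 2, n_walkers = 10000, dt = NULL, seed = 1) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(w, "sde_waveform"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  if (geometry == "free") diameter <- Inf
  if (is.null(dt)) dt <- min(0.05, (diameter / 10)^2 / (2 * D))
  if (sqrt(2 * D * dt) > diameter / 10 + 1e-12)
    stop("resolution-too-coarse: step length exceeds diameter/10", call. = FALSE)
  Ttot <- w$Delta + w$delta
  n_steps <- ceiling(Ttot / dt)
  dt <- Ttot / n_steps
  sig <- sqrt(2 * D * dt)
  R <- diameter / 2
  ndim <- if (geometry == "sphere") 3L else 2L
  # initial positions uniform in the pore (or at the origin for free diffusion)
  if (is.finite(R)) {
    pos <- matrix(stats::rnorm(n_walkers * ndim), n_walkers, ndim)
    rad <- sqrt(rowSums(pos^2))
    u <- stats::runif(n_walkers)^(1 / ndim)
    pos <- pos / rad * (R * u)
  } else {
    pos <- matrix(0, n_walkers, ndim)
  }
  phi <- numeric(n_walkers)
  for (k in seq_len(n_steps)) {
    newpos <- pos + matrix(stats::rnorm(n_walkers * ndim, sd = sig),
                           n_walkers, ndim)
    if (is.finite(R)) {
      rn <- sqrt(rowSums(newpos^2))
      out <- rn > R
      if (any(out)) {  # reflect radially about the boundary: r -> 2R - r
        sc <- (2 * R - rn[out]) / rn[out]
        newpos[out, ] <- newpos[out, , drop = FALSE] * sc
      }
    }
    pos <- newpos
    tm <- (k - 0.5) * dt
    g <- if (tm < w$delta) w$G else if (tm >= w$Delta) -w$G else 0
    if (g != 0) phi <- phi + .gamma_eff * g * pos[, 1] * dt
  }
  z <- mean(exp(1i * phi))
  list(signal = Mod(z),
       se = stats::sd(cos(phi - Arg(z))) / sqrt(n_walkers),
       n_steps = n_steps)
}
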