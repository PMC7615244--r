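#' Pore diameter distribution
#'
#' Describes the distribution of pore diameters in a substrate. Gamma
#' distributions (parameterised by mean and standard deviation, truncated at
#' an upper bound) are the conventional model for axon diameters; normal
#' distributions are used for cell-soma sizes; `delta` is a point mass for
#' single-diameter substrates.
#'
#' @param family `"gamma"`, `"normal"` or `"delta"`.
#' @param mean Mean diameter, um (> 0).
#' @param sd Standard deviation, um (>= 0; ignored for `"delta"`).
#' @param truncation Upper support bound in um, applied to the gamma family
#'   (default 20 um, a realistic ceiling for axon diameters).
#' @return An object of class `diameter_distribution`.
#' @examples
#' diameter_distribution("gamma", mean = 5.33, sd = 3)
#' @export
diameter_distribution <- function(family = c("gamma", "normal", "delta"),
                                  mean, sd = 0, truncation = 20) {
  family <- match.arg(family)
  if (mean <= 0) stop("mean must be > 0", call. = FALSE)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (family == "delta") sd <- 0
  if (family != "delta" && sd == 0) family <- "delta"
  structure(list(family = family, mean = mean, sd = sd,
                 truncation = truncation),
            class = "diameter_distribution")
}

# shape/scale of the gamma family recovered exactly from (mean, sd)
.gamma_pars <- function(dist) {
  list(shape = (dist$mean / dist$sd)^2, scale = dist$sd^2 / dist$mean)
}

#' Substrate: a pore population for signal synthesis
#'
#' @param geometry `"cylinder"` or `"sphere"`.
#' @param distribution A [diameter_distribution()].
#' @param bundle_axes For cylinders, a list of unit 3-vectors giving the
#'   fibre-bundle orientations (equal volume fractions unless `fractions` is
#'   given). Ignored for spheres.
#' @param fractions Optional bundle volume fractions (summing to 1).
#' @param kappa Optional Watson concentration parameter; when set, each
#'   bundle axis is replaced by a Watson-dispersed orientation set.
#' @param diffusivity Intrinsic diffusivity, um^2/ms (default 2, typical for
#'   tissue at 37 C).
#' @param label Optional name used in result tables.
#' @return An object of class `substrate`.
#' @examples
#' substrate("cylinder", diameter_distribution("gamma", 5.33, 3))
#' @export
substrate <- function(geometry = c("cylinder", "sphere"), distribution,
                      bundle_axes = list(c(1, 0, 0)), fractions = NULL,
                      kappa = NULL, diffusivity = 2, label = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(distribution, "diameter_distribution"))
  if (diffusivity <= 0) stop("diffusivity must be > 0", call. = FALSE)
  if (geometry == "sphere") {
    bundle_axes <- NULL
    fractions <- NULL
    kappa <- NULL
  } else {
    bundle_axes <- lapply(bundle_axes, function(a) {
      a <- as.numeric(a)
      n <- sqrt(sum(a^2))
      if (abs(n - 1) > 1e-6) stop("bundle axes must be unit vectors", call. = FALSE)
      a / n
    })
    if (is.null(fractions)) {
      fractions <- rep(1 / length(bundle_axes), length(bundle_axes))
    } else if (abs(sum(fractions) - 1) > 1e-9 ||
               length(fractions) != length(bundle_axes)) {
      stop("fractions must match bundle_axes and sum to 1", call. = FALSE)
    }
    if (!is.null(kappa) && kappa <= 0)
      stop("kappa must be > 0", call. = FALSE)
  }
  structure(list(geometry = geometry, distribution = distribution,
                 bundle_axes = bundle_axes, fractions = fractions,
                 kappa = kappa, diffusivity = diffusivity, label = label),
            class = "substrate")
}

#' @export
print.substrate <- function(x, ...) {
  d <- x$distribution
  cat(sprintf("Substrate%s: %s, %s(mean %.3g, sd %.3g um), D = %g um^2/ms",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$geometry, d$family, d$mean, d$sd, x$diffusivity))
  if (!is.null(x$bundle_axes))
    cat(sprintf(", %d bundle(s)%s", length(x$bundle_axes),
                if (is.null(x$kappa)) "" else sprintf(", Watson kappa = %g", x$kappa)))
  cat("\n")
  invisible(x)
}

#' Reference substrates
#'
#' Four canonical pore populations: gamma-distributed parallel cylinders
#' mimicking spinal-cord axons (`large_cylinders`: mean 5.33, sd 3.00 um)
#' and corpus-callosum axons (`small_cylinders`: mean 1.93, sd 0.81 um),
#' and normally distributed spheres mimicking cell somas
#' (`small_spheres`: mean 7, sd 0.5 um; `large_spheres`: mean 15,
#' sd 0.5 um). All use intrinsic diffusivity 2 um^2/ms.
#'
#' @return A named list of [substrate()] objects.
#' @export
preset_substrates <- function() {
  list(
    small_cylinders = substrate("cylinder",
      diameter_distribution("gamma", 1.93, 0.81), label = "small_cylinders"),
    large_cylinders = substrate("cylinder",
      diameter_distribution("gamma", 5.33, 3.00), label = "large_cylinders"),
    small_spheres = substrate("sphere",
      diameter_distribution("normal", 7, 0.5), label = "small_spheres"),
    large_spheres = substrate("sphere",
      diameter_distribution("normal", 15, 0.5), label = "large_spheres"))
}

#' Discretise a diameter distribution into signal-weighted bins
#'
#' Bin-centre diameters on the truncated support with weights proportional
#' to pdf(d) times pore volume -- d^2 for cylinders (cross-section per unit
#' length), d^3 for spheres -- normalised to sum to one. The volume
#' weighting reflects that each pore contributes signal in proportion to
#' the spins it contains.
#'
#' @param dist A [diameter_distribution()].
#' @param geometry `"cylinder"` or `"sphere"`.
#' @param n_bins Number of bins (default 50).
#' @return A list with numeric vectors `diameters` (um) and `weights`.
#' @examples
#' wd <- discretise(diameter_distribution("gamma", 5.33, 3), "cylinder")
#' sum(wd$weights)  # 1
#' @export
discretise <- function(dist, geometry = c("cylinder", "sphere"), n_bins = 50) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(dist, "diameter_distribution"), n_bins >= 1)
  if (dist$family == "delta" || dist$sd == 0)
    return(list(diameters = dist$mean, weights = 1))
  vol_pow <- if (geometry == "cylinder") 2 else 3
  if (dist$family == "gamma") {
    gp <- .gamma_pars(dist)
    lo <- max(1e-3, dist$mean - 4 * dist$sd)
    hi <- dist$truncation
    pdf <- function(d) stats::dgamma(d, shape = gp$shape, scale = gp$scale)
  } else {
    lo <- max(1e-3, dist$mean - 4 * dist$sd)
    hi <- dist$mean + 4 * dist$sd
    pdf <- function(d) stats::dnorm(d, dist$mean, dist$sd)
  }
  if (hi <= lo) stop("empty support after truncation", call. = FALSE)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  d <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w <- pdf(d) * d^vol_pow
  s <- sum(w)
  if (s <= 0) stop("distribution has no mass on the support", call. = FALSE)
  list(diameters = d, weights = w / s)
}

#' Does truncation leave the distribution admissible?
#'
#' Gamma diameter distributions are truncated at an upper bound; parameter
#' combinations where truncation shifts the (number-weighted) mean by more
#' than `max_shift` (default 10%) are excluded from size-grid analyses.
#'
#' @param dist A [diameter_distribution()].
#' @param max_shift Maximum tolerated relative change of the mean.
#' @return Logical.
#' @export
truncation_admissible <- function(dist, max_shift = 0.1) {
  stopifnot(inherits(dist, "diameter_distribution"))
  if (dist$family != "gamma") return(TRUE)
  gp <- .gamma_pars(dist)
  tr <- dist$truncation
  p_in <- stats::pgamma(tr, shape = gp$shape, scale = gp$scale)
  if (p_in <= 0) return(FALSE)
  # E[d | d <= tr] via the shape+1 identity for the gamma first moment
  m_in <- dist$mean * stats::pgamma(tr, shape = gp$shape + 1, scale = gp$scale) / p_in
  abs(m_in - dist$mean) / dist$mean <= max_shift
}

#' Mutually orthogonal fibre-bundle axes
#'
#' @param n_bundles 1, 2 or 3 bundles crossing at right angles.
#' @return A list of unit axes along x, then y, then z.
#' @examples
#' fibre_configuration(3)
#' @export
fibre_configuration <- function(n_bundles) {
  if (!n_bundles %in% 1:3)
    stop("unsupported bundle count; use 1, 2 or 3", call. = FALSE)
  axes <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  axes[seq_len(n_bundles)]
}

#' Watson-distributed orientation set
#'
#' Returns unit vectors with weights representing the antipodally
#' symmetric Watson density \eqn{\exp(\kappa (\mu \cdot u)^2)}. The
#' default scheme is a deterministic product quadrature -- polar-angle
#' nodes at equal quantiles of the Watson marginal about the mean axis
#' crossed with uniform azimuths, all with equal weight -- which resolves
#' arbitrarily high concentrations and makes downstream signal synthesis
#' reproducible without a seed; seeded rejection sampling is retained as
#' an alternative.
#'
#' @param kappa Concentration parameter (> 0); larger values concentrate
#'   orientations around `mean_axis`.
#' @param mean_axis Unit 3-vector, the mean orientation.
#' @param n_samples Approximate number of grid points or exact number of
#'   samples (default 200).
#' @param method `"grid"` (deterministic) or `"sample"`.
#' @param seed Seed for `method = "sample"`.
#' @return A list with an `n x 3` matrix `orientations` and a vector
#'   `weights` summing to one.
#' @export
watson_orientations <- function(kappa, mean_axis = c(0, 0, 1),
                                n_samples = 200,
                                method = c("grid", "sample"), seed = NULL) {
  method <- match.arg(method)
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  mu <- as.numeric(mean_axis)
  mu <- mu / sqrt(sum(mu^2))
  if (method == "grid") {
    n_phi <- max(4L, min(16L, as.integer(floor(sqrt(n_samples)))))
    n_theta <- max(1L, as.integer(round(n_samples / n_phi)))
    # polar nodes: equal quantiles of the marginal density ~ exp(kappa u^2)
    # on u = cos(theta) in [0, 1] (one hemisphere; antipodally symmetric)
    ug <- seq(0, 1, length.out = 4096)
    dens <- exp(kappa * (ug^2 - 1))  # -1: overflow guard
    cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(ug)))
    cdf <- cdf / cdf[length(cdf)]
    q <- (seq_len(n_theta) - 0.5) / n_theta
    u <- stats::approx(cdf, ug, xout = q, ties = "ordered")$y
    st <- sqrt(pmax(0, 1 - u^2))
    phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
    # orthonormal frame about the mean axis
    ref <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * mu) * mu
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
            mu[3] * e1[1] - mu[1] * e1[3],
            mu[1] * e1[2] - mu[2] * e1[1])
    loc <- cbind(rep(st, each = n_phi) * cos(phi),
                 rep(st, each = n_phi) * sin(phi),
                 rep(u, each = n_phi))
    pts <- loc[, 1] %o% e1 + loc[, 2] %o% e2 + loc[, 3] %o% mu
    return(list(orientations = pts,
                weights = rep(1 / nrow(pts), nrow(pts))))
  }
  # rejection sampling from the Watson density, envelope = uniform sphere
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  out <- matrix(0, n_samples, 3)
  got <- 0L
  while (got < n_samples) {
    m <- 2L * (n_samples - got)
    z <- stats::rnorm(m); x <- stats::rnorm(m); y <- stats::rnorm(m)
    u <- cbind(x, y, z)
    u <- u / sqrt(rowSums(u^2))
    acc <- stats::runif(m) < exp(kappa * (as.vector(u %*% mu)^2 - 1))
    take <- which(acc)[seq_len(min(sum(acc), n_samples - got))]
    if (length(take)) {
      out[got + seq_along(take), ] <- u[take, , drop = FALSE]
      got <- got + length(take)
    }
  }
  list(orientations = out, weights = rep(1 / n_samples, n_samples))
}
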