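#' Generate a uniform gradient direction set by electrostatic repulsion
#'
#' Minimises the antipodally symmetric Coulomb energy
#' \eqn{\sum_{i<j} 1/\|u_i - u_j\| + 1/\|u_i + u_j\|}
#' over unit vectors, starting from a seeded random configuration, using
#' BFGS with an analytic gradient in spherical coordinates. Deterministic
#' given the seed.
#'
#' @param N Number of directions (>= 1).
#' @param seed RNG seed for the starting configuration (local to this call).
#' @param max_iter Maximum optimiser iterations.
#' @return An `N x 3` matrix of unit vectors with attribute
#'   `scheme = "repulsion"`.
#' @examples
#' dirs <- generate_directions(30, seed = 1)
#' range(sqrt(rowSums(dirs^2)))  # all 1
#' @export
generate_directions <- function(N, seed = 1234, max_iter = 400) {
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  if (N == 1) {
    u <- stats::rnorm(3)
    out <- matrix(u / sqrt(sum(u^2)), 1, 3)
    attr(out, "scheme") <- "repulsion"
    return(out)
  }
  u0 <- matrix(stats::rnorm(3 * N), N, 3)
  u0 <- u0 / sqrt(rowSums(u0^2))
  theta0 <- acos(pmin(1, pmax(-1, u0[, 3])))
  phi0 <- atan2(u0[, 2], u0[, 1])

  unpack <- function(p) {
    th <- p[1:N]; ph <- p[(N + 1):(2 * N)]
    cbind(cos(ph) * sin(th), sin(ph) * sin(th), cos(th))
  }
  energy <- function(p) {
    U <- unpack(p)
    G <- tcrossprod(U)
    G[G > 1 - 1e-12] <- 1 - 1e-12
    G[G < -1 + 1e-12] <- -1 + 1e-12
    Em <- 1 / sqrt(2 - 2 * G); Ep <- 1 / sqrt(2 + 2 * G)
    diag(Em) <- 0; diag(Ep) <- 0
    sum(Em + Ep) / 2
  }
  gradient <- function(p) {
    th <- p[1:N]; ph <- p[(N + 1):(2 * N)]
    U <- unpack(p)
    G <- tcrossprod(U)
    G[G > 1 - 1e-12] <- 1 - 1e-12
    G[G < -1 + 1e-12] <- -1 + 1e-12
    Am <- (2 - 2 * G)^(-1.5); Ap <- (2 + 2 * G)^(-1.5)
    diag(Am) <- 0; diag(Ap) <- 0
    # dE/dU_i = -sum_j Am_ij (u_i - u_j) - sum_j Ap_ij (u_i + u_j)
    dU <- -(rowSums(Am) + rowSums(Ap)) * U + (Am - Ap) %*% U
    dth <- cbind(cos(ph) * cos(th), sin(ph) * cos(th), -sin(th))
    dph <- cbind(-sin(ph) * sin(th), cos(ph) * sin(th), 0)
    c(rowSums(dU * dth), rowSums(dU * dph))
  }
  fit <- stats::optim(c(theta0, phi0), energy, gradient, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  out <- unpack(fit$par)
  out <- out / sqrt(rowSums(out^2))
  # canonical hemisphere (antipodal pairs are equivalent)
  flip <- out[, 3] < 0 | (out[, 3] == 0 & out[, 2] < 0)
  out[flip, ] <- -out[flip, , drop = FALSE]
  attr(out, "scheme") <- "repulsion"
  out
}

#' Minimum pairwise angle of an antipodally symmetric direction set
#'
#' @param dirs `N x 3` matrix of unit vectors.
#' @return Smallest inter-direction angle in degrees, treating `u` and `-u`
#'   as the same direction.
#' @export
min_pairwise_angle <- function(dirs) {
  G <- abs(tcrossprod(as.matrix(dirs)))
  diag(G) <- 0
  acos(pmin(1, max(G))) * 180 / pi
}
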