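# Unit system used throughout: time in ms, length in um, gradient amplitude
# in mT/m, b-value in ms/um^2, diffusivity in um^2/ms.

#' Proton gyromagnetic ratio in package units
#'
#' 2.6752218744e8 rad s^-1 T^-1 expressed as rad ms^-1 um^-1 per (mT/m), so
#' that \eqn{b = (\gamma G)^2 \delta^2 (\Delta - \delta/3)} comes out in
#' ms/um^2 when timings are in ms and G in mT/m.
#' @keywords internal
.gamma_eff <- 2.6752218744e-4

#' Single diffusion encoding (SDE) waveform
#'
#' A rectangular-pulse pair described by gradient duration `delta` (ms),
#' pulse separation `Delta` (ms, the diffusion time) and amplitude `G`
#' (mT/m). Exactly one of `G` or `b` must be given; the other is derived
#' through the Stejskal-Tanner relation.
#'
#' @param delta Gradient pulse duration, ms. Must be > 0.
#' @param Delta Pulse separation, ms. Must satisfy `Delta >= delta`.
#' @param G Gradient amplitude, mT/m (>= 0). Mutually exclusive with `b`.
#' @param b Diffusion weighting, ms/um^2 (>= 0). Mutually exclusive with `G`.
#' @return An object of class `sde_waveform`: a list with fields `delta`,
#'   `Delta`, `G` and `b`.
#' @examples
#' w <- sde_waveform(delta = 6.9, Delta = 9, b = 8)
#' w$G  # ~592 mT/m
#' @export
sde_waveform <- function(delta, Delta, G = NULL, b = NULL) {
  .check_timings(delta, Delta)
  if (is.null(G) == is.null(b))
    stop("supply exactly one of 'G' or 'b'", call. = FALSE)
  if (is.null(G)) {
    G <- gradient_for_b(b, delta, Delta)
  } else {
    if (G < 0) stop("invalid waveform: G must be >= 0", call. = FALSE)
    b <- bvalue(delta, Delta, G)
  }
  structure(list(delta = delta, Delta = Delta, G = G, b = b),
            class = "sde_waveform")
}

#' @export
print.sde_waveform <- function(x, ...) {
  cat(sprintf(
    "SDE waveform: delta = %.4g ms, Delta = %.4g ms, G = %.5g mT/m, b = %.5g ms/um^2\n",
    x$delta, x$Delta, x$G, x$b))
  invisible(x)
}

.check_timings <- function(delta, Delta) {
  if (!is.numeric(delta) || !is.numeric(Delta) || length(delta) != 1L ||
      length(Delta) != 1L || !is.finite(delta) || !is.finite(Delta))
    stop("invalid waveform: timings must be finite scalars", call. = FALSE)
  if (delta <= 0)
    stop("invalid waveform: delta must be > 0", call. = FALSE)
  if (Delta < delta)
    stop("invalid waveform: Delta must be >= delta", call. = FALSE)
  invisible(TRUE)
}

#' b-value of a rectangular SDE waveform
#'
#' Computes \eqn{b = \gamma^2 G^2 \delta^2 (\Delta - \delta/3)} in ms/um^2.
#'
#' @inheritParams sde_waveform
#' @param G Gradient amplitude, mT/m.
#' @return b-value in ms/um^2.
#' @examples
#' bvalue(6.9, 9, 592)  # ~8
#' @export
bvalue <- function(delta, Delta, G) {
  .check_timings(delta, Delta)
  if (any(G < 0)) stop("invalid waveform: G must be >= 0", call. = FALSE)
  (.gamma_eff * G)^2 * delta^2 * (Delta - delta / 3)
}

#' Gradient amplitude required for a target b-value
#'
#' Inverts the Stejskal-Tanner relation at fixed timings; the unique
#' non-negative solution.
#'
#' @param b Target b-value, ms/um^2 (>= 0).
#' @inheritParams sde_waveform
#' @return Gradient amplitude in mT/m.
#' @examples
#' gradient_for_b(8, 6.9, 9)  # ~592 mT/m
#' @export
gradient_for_b <- function(b, delta, Delta) {
  .check_timings(delta, Delta)
  if (any(b < 0)) stop("b must be >= 0", call. = FALSE)
  sqrt(b / (delta^2 * (Delta - delta / 3))) / .gamma_eff
}

#' Scanner hardware constraint set
#'
#' @param G_max Maximum gradient amplitude, mT/m (> 0).
#' @param T_max Upper bound on `Delta + delta`, ms (> 0).
#' @return An object of class `scanner_constraints`.
#' @examples
#' scanner_constraints(600, 45)
#' @export
scanner_constraints <- function(G_max, T_max) {
  if (!is.numeric(G_max) || G_max <= 0 || !is.numeric(T_max) || T_max <= 0)
    stop("G_max and T_max must be strictly positive", call. = FALSE)
  structure(list(G_max = G_max, T_max = T_max), class = "scanner_constraints")
}

#' @export
print.scanner_constraints <- function(x, ...) {
  cat(sprintf("Scanner constraints: G <= %g mT/m, Delta + delta <= %g ms\n",
              x$G_max, x$T_max))
  invisible(x)
}

#' Check a waveform against a constraint set
#'
#' Reports, rather than raises, every violated bound.
#'
#' @param w An [sde_waveform()].
#' @param constraints A [scanner_constraints()].
#' @return A list with logical `feasible` and a character vector `violations`
#'   (empty when feasible).
#' @export
check_constraints <- function(w, constraints) {
  stopifnot(inherits(w, "sde_waveform"), inherits(constraints, "scanner_constraints"))
  v <- character()
  if (w$G > constraints$G_max)
    v <- c(v, sprintf("G = %.4g exceeds G_max = %g mT/m", w$G, constraints$G_max))
  if (w$delta + w$Delta > constraints$T_max)
    v <- c(v, sprintf("Delta + delta = %.4g exceeds T_max = %g ms",
                      w$delta + w$Delta, constraints$T_max))
  if (w$Delta < w$delta)
    v <- c(v, "Delta < delta")
  list(feasible = length(v) == 0L, violations = v)
}

# printed shell timings of the ex-vivo protocols: label x b x G_max context
.preset_table <- function() {
  tab <- rbind(
    data.frame(label = "shell1",  b = 8,  G_max = 600,  delta = 6.9, Delta = 9),
    data.frame(label = "shell2n", b = 8,  G_max = 600,  delta = 6.9, Delta = 34.6),
    data.frame(label = "shell2o", b = 8,  G_max = 600,  delta = 14,  Delta = 27.5),
    data.frame(label = "shell1",  b = 8,  G_max = 2500, delta = 2.2, Delta = 4.5),
    data.frame(label = "shell2n", b = 8,  G_max = 2500, delta = 2.2, Delta = 39),
    data.frame(label = "shell2o", b = 8,  G_max = 2500, delta = 15,  Delta = 26.5),
    data.frame(label = "shell1",  b = 20, G_max = 600,  delta = 9.7, Delta = 11.7),
    data.frame(label = "shell2n", b = 20, G_max = 600,  delta = 9.7, Delta = 32),
    data.frame(label = "shell2o", b = 20, G_max = 600,  delta = 15,  Delta = 26.5),
    data.frame(label = "shell1",  b = 20, G_max = 2500, delta = 3.2, Delta = 5.2),
    data.frame(label = "shell2n", b = 20, G_max = 2500, delta = 3.2, Delta = 38.5),
    data.frame(label = "shell2o", b = 20, G_max = 2500, delta = 15,  Delta = 26.5))
  tab
}

#' Protocol presets for the non-optimised and optimised shell pairs
#'
#' The twelve shell definitions used in the ex-vivo demonstration:
#' `shell1` (short duration, short diffusion time), `shell2n` (short
#' duration, long diffusion time; the original non-optimised contrast) and
#' `shell2o` (long duration, long diffusion time; the optimised contrast),
#' for b in \{8, 20\} ms/um^2 and maximum gradient context in \{600, 2500\}
#' mT/m. `G` is solved from the shell's b-value and timings.
#'
#' @return A data.frame with columns `label`, `b`, `G_max`, `delta`, `Delta`
#'   and `G` (mT/m).
#' @examples
#' protocol_presets()
#' @export
protocol_presets <- function() {
  tab <- .preset_table()
  tab$G <- mapply(gradient_for_b, tab$b, tab$delta, tab$Delta)
  tab
}

#' Retrieve one protocol preset as a waveform
#'
#' @param label One of `"shell1"`, `"shell2n"`, `"shell2o"`.
#' @param b Shell b-value, 8 or 20 ms/um^2.
#' @param G_max Gradient context, 600 or 2500 mT/m.
#' @return An [sde_waveform()].
#' @examples
#' preset_waveform("shell2o", b = 8, G_max = 600)
#' @export
preset_waveform <- function(label, b = 8, G_max = 600) {
  tab <- .preset_table()
  hit <- tab$label == label & tab$b == b & tab$G_max == G_max
  if (!any(hit))
    stop(sprintf("no preset '%s' for b = %g, G_max = %g", label, b, G_max),
         call. = FALSE)
  row <- tab[hit, ]
  sde_waveform(delta = row$delta, Delta = row$Delta, b = row$b)
}

#' Write / read a protocol description as YAML
#'
#' Serialises a list of waveforms with keys `label`, `delta_ms`, `Delta_ms`,
#' `b` and `G_mT_per_m`.
#'
#' @param waveforms Named list of [sde_waveform()] objects (names become labels).
#' @param path File path.
#' @return `read_protocol_yaml` returns a named list of waveforms.
#' @export
write_protocol_yaml <- function(waveforms, path) {
  stopifnot(is.list(waveforms), length(waveforms) > 0)
  labs <- names(waveforms)
  if (is.null(labs)) labs <- sprintf("shell%d", seq_along(waveforms))
  entries <- mapply(function(w, lab) {
    list(label = lab, delta_ms = w$delta, Delta_ms = w$Delta,
         b = w$b, G_mT_per_m = w$G)
  }, waveforms, labs, SIMPLIFY = FALSE)
  yaml::write_yaml(unname(entries), path)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  entries <- yaml::read_yaml(path)
  out <- lapply(entries, function(e)
    sde_waveform(delta = e$delta_ms, Delta = e$Delta_ms, b = e$b))
  names(out) <- vapply(entries, `[[`, "", "label")
  out
}
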