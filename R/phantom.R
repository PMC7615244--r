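# Synthetic voxel phantom: a labelled 2-D slab whose voxels carry the
# per-direction signals of their substrate plus seeded Rician noise. A
# desk-scale stand-in for real multi-shell maps; the voxelwise subset-TDR
# map applies the same statistic the scanner pipeline would.

#' Generate a synthetic TDR phantom
#'
#' @param labels Character matrix (any dimensions); each entry names a
#'   substrate in `substrates`, or `NA` for background.
#' @param substrates Named list of [substrate()] objects.
#' @param shell1,shell2 [sde_waveform()] objects with equal b.
#' @param dirs Direction matrix shared by both shells.
#' @param snr Rician SNR on the b0 signal; `Inf` for noise-free.
#' @param seed RNG seed; each voxel uses an independent draw from one
#'   seeded stream.
#' @param n_bins Diameter bins per substrate.
#' @return An object of class `tdr_phantom`: `labels`, signal arrays `s1`
#'   and `s2` of dimension `c(dim(labels), N)`, `dirs`, the waveforms,
#'   `snr` and `seed`.
#' @export
generate_phantom <- function(labels, substrates, shell1, shell2, dirs,
                             snr = Inf, seed = 1234, n_bins = 50) {
  labels <- as.matrix(labels)
  stopifnot(is.list(substrates), length(substrates) > 0)
  used <- unique(stats::na.omit(as.vector(labels)))
  missing <- setdiff(used, names(substrates))
  if (length(missing))
    stop("labels reference undefined substrates: ",
         paste(missing, collapse = ", "), call. = FALSE)
  N <- nrow(as.matrix(dirs))
  base <- lapply(substrates[used], function(sub) list(
    s1 = substrate_shell(sub, shell1, dirs, n_bins = n_bins)$signals,
    s2 = substrate_shell(sub, shell2, dirs, n_bins = n_bins)$signals))
  dims <- dim(labels)
  s1 <- array(NA_real_, c(dims, N))
  s2 <- array(NA_real_, c(dims, N))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sigma <- if (is.infinite(snr)) 0 else 1 / snr
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    lab <- labels[i, j]
    if (is.na(lab)) next
    v1 <- base[[lab]]$s1
    v2 <- base[[lab]]$s2
    if (sigma > 0) {
      v1 <- sqrt((v1 + stats::rnorm(N, 0, sigma))^2 + stats::rnorm(N, 0, sigma)^2)
      v2 <- sqrt((v2 + stats::rnorm(N, 0, sigma))^2 + stats::rnorm(N, 0, sigma)^2)
    }
    s1[i, j, ] <- v1
    s2[i, j, ] <- v2
  }
  structure(list(labels = labels, s1 = s1, s2 = s2, dirs = as.matrix(dirs),
                 shell1 = shell1, shell2 = shell2, snr = snr, seed = seed),
            class = "tdr_phantom")
}

#' Voxelwise sorted-subset TDR map
#'
#' Applies [tdr_subset()] independently in every voxel of a phantom, with
#' the per-voxel direction ordering determined by the voxel's own mean
#' signal.
#'
#' @param phantom A [generate_phantom()] result.
#' @param M Subset size (default: all directions).
#' @return A numeric matrix of per-voxel TDR values (`NA` for background).
#' @export
tdr_map <- function(phantom, M = NULL) {
  stopifnot(inherits(phantom, "tdr_phantom"))
  dims <- dim(phantom$labels)
  N <- dim(phantom$s1)[3]
  if (is.null(M)) M <- N
  out <- matrix(NA_real_, dims[1], dims[2])
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    if (is.na(phantom$labels[i, j])) next
    out[i, j] <- tdr_subset(phantom$s1[i, j, ], phantom$s2[i, j, ], M)
  }
  out
}
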