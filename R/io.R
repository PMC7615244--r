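# Readers and writers for the standard acquisition-description dialects.
# Package-internal b-values are in ms/um^2; FSL .bval files carry s/mm^2
# (1 ms/um^2 = 1000 s/mm^2) and Camino scheme files carry SI units.

#' FSL bval / bvec files
#'
#' `write_bval` writes one whitespace-separated row of b-values in s/mm^2
#' (converted from ms/um^2); `read_bval` converts back. `write_bvec`
#' writes a 3 x N table of unit direction columns; `read_bvec` validates
#' shape and unit norm.
#'
#' @param b Numeric vector of b-values in ms/um^2.
#' @param dirs `N x 3` matrix of unit directions.
#' @param path File path.
#' @param tol Unit-norm tolerance on read.
#' @return Readers return b-values in ms/um^2 / an `N x 3` matrix.
#' @export
write_bval <- function(b, path) {
  writeLines(paste(format(b * 1000, trim = TRUE, digits = 15), collapse = " "),
             path)
  invisible(path)
}

#' @rdname write_bval
#' @export
read_bval <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) != 1)
    stop("malformed bval file: expected a single row, got ", length(ln),
         " (line ", length(ln), ")", call. = FALSE)
  v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
  if (anyNA(v)) stop("malformed bval file: non-numeric entry on line 1",
                     call. = FALSE)
  v / 1000
}

#' @rdname write_bval
#' @export
write_bvec <- function(dirs, path) {
  dirs <- as.matrix(dirs)
  stopifnot(ncol(dirs) == 3)
  rows <- apply(t(dirs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " "))
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_bval
#' @export
read_bvec <- function(path, tol = 1e-4) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) != 3)
    stop("malformed bvec file: expected 3 rows, got ", length(ln), call. = FALSE)
  rows <- lapply(seq_along(ln), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln[i]), "\\s+")[[1]]))
    if (anyNA(v)) stop("malformed bvec file: non-numeric entry on line ", i,
                       call. = FALSE)
    v
  })
  if (length(unique(lengths(rows))) != 1)
    stop("malformed bvec file: rows have different lengths", call. = FALSE)
  dirs <- t(do.call(rbind, rows))
  nn <- sqrt(rowSums(dirs^2))
  bad <- which(abs(nn - 1) > tol)
  if (length(bad))
    stop("malformed bvec file: non-unit vector in column ", bad[1], call. = FALSE)
  dirs
}

#' Camino scheme files (STEJSKALTANNER)
#'
#' Each measurement row holds `x y z |G| Delta delta TE` in SI units
#' (T/m and s). The package converts from / to its ms, mT/m convention.
#'
#' @param waveforms List of [sde_waveform()], one per shell.
#' @param dirs_list List of `N x 3` direction matrices, parallel to
#'   `waveforms` (a single matrix is recycled).
#' @param path File path.
#' @param TE Echo time in ms written to the file (default
#'   `max(Delta + delta) + 5`).
#' @return `read_scheme` returns a data.frame with columns `x, y, z, G`
#'   (mT/m), `Delta`, `delta`, `TE` (ms) and `b` (ms/um^2).
#' @export
write_scheme <- function(waveforms, dirs_list, path, TE = NULL) {
  if (inherits(waveforms, "sde_waveform")) waveforms <- list(waveforms)
  if (is.matrix(dirs_list)) dirs_list <- rep(list(dirs_list), length(waveforms))
  stopifnot(length(dirs_list) == length(waveforms))
  if (is.null(TE))
    TE <- max(vapply(waveforms, function(w) w$Delta + w$delta, numeric(1))) + 5
  lines <- c("VERSION: STEJSKALTANNER")
  for (k in seq_along(waveforms)) {
    w <- waveforms[[k]]
    d <- as.matrix(dirs_list[[k]])
    for (i in seq_len(nrow(d))) {
      lines <- c(lines, paste(format(
        c(d[i, ], w$G * 1e-3, w$Delta * 1e-3, w$delta * 1e-3, TE * 1e-3),
        trim = TRUE, digits = 15), collapse = " "))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  if (!grepl("STEJSKALTANNER", ln[1]))
    stop("malformed scheme file: missing STEJSKALTANNER header (line 1)",
         call. = FALSE)
  rows <- lapply(seq_along(ln[-1]), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln[i + 1]), "\\s+")[[1]]))
    if (anyNA(v) || length(v) != 7)
      stop("malformed scheme file: bad row on line ", i + 1, call. = FALSE)
    v
  })
  m <- do.call(rbind, rows)
  out <- data.frame(x = m[, 1], y = m[, 2], z = m[, 3],
                    G = m[, 4] * 1e3, Delta = m[, 5] * 1e3,
                    delta = m[, 6] * 1e3, TE = m[, 7] * 1e3)
  out$b <- bvalue_vec(out$delta, out$Delta, out$G)
  out
}

# vectorised b-value without the scalar-waveform checks
bvalue_vec <- function(delta, Delta, G) {
  (.gamma_eff * G)^2 * delta^2 * (Delta - delta / 3)
}

#' Per-shell signal tables
#'
#' Long-format CSV/TSV with columns `shell`, `dir_index`, `signal`.
#'
#' @param shells Named list of [shell_signals()] objects.
#' @param path File path; extension `.tsv` selects tab separation.
#' @return `read_signal_table` returns the data.frame.
#' @export
write_signal_table <- function(shells, path) {
  stopifnot(is.list(shells), length(shells) > 0)
  labs <- names(shells)
  if (is.null(labs)) labs <- sprintf("shell%d", seq_along(shells))
  df <- do.call(rbind, lapply(seq_along(shells), function(k)
    data.frame(shell = labs[k],
               dir_index = seq_along(shells[[k]]$signals),
               signal = shells[[k]]$signals)))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signal_table
#' @export
read_signal_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("shell", "dir_index", "signal")
  if (!all(need %in% names(df)))
    stop("malformed signal table: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}
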