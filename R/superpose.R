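#' Optimal rigid superposition of paired Calpha atoms
#'
#' Kabsch least-squares superposition via SVD with reflection
#' correction: finds the proper rotation `R` (det +1) and translation
#' `t` minimising the RMSD between `R %*% mobile + t` and `fixed`, and
#' reports `RMSD = sqrt(mean(d_i^2))` over the `N` aligned pairs.
#'
#' @param fixed,mobile numeric N x 3 matrices of paired coordinates
#'   (Angstrom), N >= 3, not all collinear.
#' @return An object of class `superposition_result` with fields
#'   `rotation` (3 x 3, proper orthonormal), `translation` (length-3),
#'   `rmsd` (Angstrom) and `n_pairs`.
#' @export
kabsch_superpose <- function(fixed, mobile) {
  fixed <- as.matrix(fixed); mobile <- as.matrix(mobile)
  stopifnot(ncol(fixed) == 3L, ncol(mobile) == 3L)
  n <- nrow(fixed)
  if (n != nrow(mobile) || n < 3L) stop("insufficient pairs")
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  Fc <- sweep(fixed, 2L, cf); Mc <- sweep(mobile, 2L, cm)
  scale <- max(sqrt(rowSums(Fc^2)), sqrt(rowSums(Mc^2)))
  if (scale == 0 ||
      svd(Fc, nu = 0, nv = 0)$d[2] < 1e-8 * scale ||
      svd(Mc, nu = 0, nv = 0)$d[2] < 1e-8 * scale)
    stop("degenerate geometry")
  H <- crossprod(Mc, Fc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tvec <- cf - as.vector(R %*% cm)
  moved <- t(R %*% t(mobile)) + matrix(tvec, n, 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  structure(list(rotation = R, translation = tvec, rmsd = rmsd,
                 n_pairs = n),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition_result> RMSD %.4f A over %d CA pairs\n",
              x$rmsd, x$n_pairs))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sup a [kabsch_superpose()] result.
#' @param coords N x 3 matrix to transform.
#' @return Transformed N x 3 matrix.
#' @export
apply_superposition <- function(sup, coords) {
  stopifnot(inherits(sup, "superposition_result"))
  coords <- as.matrix(coords)
  t(sup$rotation %*% t(coords)) +
    matrix(sup$translation, nrow(coords), 3L, byrow = TRUE)
}

#' Superpose the Calpha pairs of an alignment path
#'
#' Gathers the coordinates of the non-gap pairs of a residue-level
#' alignment and delegates to [kabsch_superpose()] (query fixed,
#' database chain mobile).
#'
#' @param path an `alignment_path` from [phase2_align()]/[backtrack()].
#' @param trace_q,trace_d the [calpha_trace] objects the aligned chains
#'   were built from.
#' @return A `superposition_result`.
#' @export
rmsd_of_path <- function(path, trace_q, trace_d) {
  stopifnot(inherits(trace_q, "calpha_trace"), inherits(trace_d, "calpha_trace"))
  keep <- !is.na(path$q) & !is.na(path$d)
  if (sum(keep) < 3L) stop("insufficient pairs")
  kabsch_superpose(trace_q$coords[path$q[keep], , drop = FALSE],
                   trace_d$coords[path$d[keep], , drop = FALSE])
}
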