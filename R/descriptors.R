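#' @title Structure representations for the two alignment phases
#' @description Phase 2 works on *molecular residue descriptors*: per
#' residue, the vector `<|C_i|, gamma_i, SSE_i, r_i>` holding the length
#' of the vector between consecutive Calpha atoms, the angle between
#' successive such vectors, the secondary-structure code and the
#' amino-acid type. Phase 1 works on *reduced chains of secondary
#' structures*: the run-length encoding of the per-residue SSE sequence
#' into SE regions `[SSE_i, L_i]`.
#' @name representations
NULL

#' Construct a descriptor chain
#'
#' Column-oriented container of molecular residue descriptors. All
#' vectors must have equal length; `c_len` must be non-negative and
#' `gamma` must lie in `[0, pi]` (radians).
#'
#' @param id chain identifier.
#' @param c_len numeric vector, inter-Calpha vector lengths (Angstrom).
#' @param gamma numeric vector, inter-vector angles (radians).
#' @param sse character vector of codes in `{H, E, L}`.
#' @param residues character vector of one-letter amino-acid codes.
#' @return An object of class `descriptor_chain`.
#' @export
new_descriptor_chain <- function(id, c_len, gamma, sse, residues) {
  q <- length(c_len)
  if (q < 1L) stop("empty trace")
  stopifnot(length(gamma) == q, length(sse) == q, length(residues) == q)
  if (any(c_len < 0)) stop("c_len must be non-negative")
  if (any(gamma < -1e-12 | gamma > pi + 1e-12))
    stop("gamma must lie in [0, pi] radians")
  structure(list(id = as.character(id)[1], c_len = as.numeric(c_len),
                 gamma = pmin(pmax(as.numeric(gamma), 0), pi),
                 sse = as.character(sse), residues = as.character(residues)),
            class = "descriptor_chain")
}

#' @export
length.descriptor_chain <- function(x) length(x$c_len)

#' @export
print.descriptor_chain <- function(x, ...) {
  cat(sprintf("<descriptor_chain> %s: %d residues\n", x$id, length(x)))
  invisible(x)
}

#' Build the molecular residue descriptor chain of a trace
#'
#' For a trace of `q` residues (0-based position `i`): `c_len[i]` is the
#' Euclidean distance between Calpha `i` and `i+1` (zero for the last
#' residue); `gamma[i]` is the angle, in radians, between the backbone
#' vectors `C_i` and `C_{i+1}` (zero for the last two residues).
#' Secondary structure and residue type are copied from the trace.
#' Terminal positions where a feature is undefined are zero-filled.
#'
#' @param trace a [calpha_trace].
#' @return A [new_descriptor_chain()] of the same length as the trace.
#' @export
build_descriptor_chain <- function(trace) {
  stopifnot(inherits(trace, "calpha_trace"))
  q <- length(trace)
  xyz <- trace$coords
  c_len <- numeric(q)
  gamma <- numeric(q)
  if (q >= 2L) {
    v <- xyz[-1L, , drop = FALSE] - xyz[-q, , drop = FALSE]  # C_i, i=1..q-1
    vn <- sqrt(rowSums(v * v))
    c_len[seq_len(q - 1L)] <- vn
    if (q >= 3L) {
      a <- v[-(q - 1L), , drop = FALSE]
      b <- v[-1L, , drop = FALSE]
      dot <- rowSums(a * b)
      den <- vn[-(q - 1L)] * vn[-1L]
      cosang <- ifelse(den > 0, pmin(pmax(dot / den, -1), 1), 1)
      gamma[seq_len(q - 2L)] <- acos(cosang)
    }
  }
  new_descriptor_chain(trace$structure_id, c_len, gamma,
                       trace$sse, trace$residues)
}

#' Construct a reduced chain of secondary structures
#'
#' @param id chain identifier.
#' @param sse character vector of region codes; adjacent codes must
#'   differ (maximal runs).
#' @param lengths positive integer vector of region lengths (residues).
#' @return An object of class `reduced_chain`.
#' @export
new_reduced_chain <- function(id, sse, lengths) {
  n <- length(sse)
  if (n < 1L) stop("empty chain")
  stopifnot(length(lengths) == n)
  lengths <- as.integer(lengths)
  if (any(lengths < 1L)) stop("region lengths must be >= 1")
  if (n > 1L && any(sse[-1L] == sse[-n]))
    stop("adjacent regions must have different sse codes")
  structure(list(id = as.character(id)[1], sse = as.character(sse),
                 lengths = lengths),
            class = "reduced_chain")
}

#' @export
length.reduced_chain <- function(x) length(x$sse)

#' @export
print.reduced_chain <- function(x, ...) {
  cat(sprintf("<reduced_chain> %s: %d regions (%s)\n", x$id, length(x),
              paste0(x$sse, x$lengths, collapse = " ")))
  invisible(x)
}

#' Reduce a chain to its secondary-structure regions
#'
#' Run-length encodes the per-residue SSE sequence into SE regions
#' `[type, length]`, preserving order. Region lengths always sum to the
#' chain length, and the number of regions is at most the number of
#' residues.
#'
#' @param chain a [descriptor_chain][new_descriptor_chain] or
#'   [calpha_trace] (its `sse` field is used).
#' @return A [reduced_chain][new_reduced_chain].
#' @export
reduce_chain <- function(chain) {
  sse <- chain$sse
  if (length(sse) == 0L) stop("empty chain")
  r <- rle(sse)
  id <- if (!is.null(chain$id)) chain$id else chain$structure_id
  new_reduced_chain(id, r$values, r$lengths)
}

#' Expand a reduced chain back to a per-residue SSE sequence
#'
#' Inverse of [reduce_chain()] on the `sse` field.
#'
#' @param reduced a [reduced_chain][new_reduced_chain].
#' @return Character vector of per-residue codes.
#' @export
expand_regions <- function(reduced) {
  rep(reduced$sse, times = reduced$lengths)
}
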