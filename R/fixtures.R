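#' Specification of a synthetic test structure
#'
#' Describes a deterministic synthetic Calpha trace: a secondary-
#' structure layout (ordered regions with types and lengths) built with
#' idealised backbone geometry, reproducible from a seed. These
#' generators exist so that alignment, filtering and superposition can
#' be exercised without downloading real PDB entries; the traces have
#' realistic local geometry (consecutive Calpha spacing near 3.8
#' Angstrom, helical rise/twist) but are not physically packed folds.
#'
#' @param seed integer seed; all randomness (loop walks, region
#'   orientations, residue identities) derives from it.
#' @param layout ordered region layout: character vector of types in
#'   `{H, E, L}` with integer lengths, e.g.
#'   `c(H = 8, L = 3, E = 5)`. Repeated names are allowed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, layout = c(H = 8, L = 3, E = 5)) {
  types <- names(layout)
  lens <- as.integer(layout)
  if (is.null(types) || !all(types %in% c("H", "E", "L")))
    stop("layout names must be H, E or L")
  if (any(lens < 1L)) stop("layout lengths must be >= 1")
  structure(list(seed = as.integer(seed), types = types, lengths = lens,
                 n_residues = sum(lens)),
            class = "fixture_spec")
}

# Random unit vector / rotation from the current RNG stream.
.runit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}
.rrot <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Ideal local coordinates of one region, first atom at the origin.
.region_coords <- function(type, len) {
  k <- seq_len(len) - 1
  local <- switch(type,
    H = cbind(2.3 * cos(k * 100 * pi / 180),
              2.3 * sin(k * 100 * pi / 180), 1.5 * k),
    E = cbind(3.4 * k, 0.85 * (-1)^k, 0),
    L = {
      steps <- t(vapply(seq_len(len), function(i) 3.8 * .runit(),
                        numeric(3)))
      apply(rbind(0, steps[-len, , drop = FALSE]), 2, cumsum)
    })
  local <- matrix(local, nrow = len)
  sweep(local, 2, local[1, ])
}

#' Generate a synthetic Calpha trace
#'
#' Builds idealised backbone geometry region by region: alpha-helices
#' with 1.5 Angstrom rise, 2.3 Angstrom radius and 100 degrees per
#' residue; near-linear beta-strands with 3.4 Angstrom rise and a small
#' alternating pleat; loops as seeded random walks with 3.8 Angstrom
#' steps. Each region is given a random (seeded) orientation and starts
#' 3.8 Angstrom from the previous region's end. Residue identities are
#' drawn uniformly from the 20 standard amino acids. The result is a
#' pure function of the spec.
#'
#' @param spec a [fixture_spec()].
#' @return A [calpha_trace] with `sse` set from the layout.
#' @export
make_trace <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    coords <- matrix(numeric(0), 0, 3)
    cur <- c(0, 0, 0)
    first <- TRUE
    for (r in seq_along(spec$types)) {
      local <- .region_coords(spec$types[r], spec$lengths[r])
      placed <- local %*% t(.rrot())
      start <- if (first) cur else cur + 3.8 * .runit()
      placed <- sweep(placed, 2, start, `+`)
      coords <- rbind(coords, placed)
      cur <- placed[nrow(placed), ]
      first <- FALSE
    }
    residues <- sample(.AA20, spec$n_residues, replace = TRUE)
    new_calpha_trace(structure_id = sprintf("synthetic_%d", spec$seed),
                     chain_id = "A", coords = coords, residues = residues,
                     sse = rep(spec$types, spec$lengths))
  })
}

#' Write a Calpha trace as PDB text
#'
#' Emits ATOM records (Calpha only, chain as stored on the trace) plus
#' HELIX/SHEET records covering the maximal `H`/`E` runs of the trace's
#' SSE labels, in standard PDB v3.3 columns, so that
#' [parse_structure()] + [assign_sse()] recover the trace.
#'
#' @param trace a [calpha_trace].
#' @param path optional file path; when given the text is also written
#'   there.
#' @return Character vector of PDB lines, invisibly when `path` is set.
#' @export
write_pdb <- function(trace, path = NULL) {
  stopifnot(inherits(trace, "calpha_trace"))
  q <- length(trace)
  res3 <- vapply(trace$residues, function(a) {
    if (a %in% .AA20) bio3d::aa123(a) else "UNK"
  }, character(1))
  ch <- substr(trace$chain_id, 1, 1)
  runs <- rle(trace$sse)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  header <- character(0)
  nh <- 0L; ns <- 0L
  for (r in seq_along(runs$values)) {
    i1 <- starts[r]; i2 <- ends[r]
    if (runs$values[r] == "H") {
      nh <- nh + 1L
      header <- c(header, sprintf(
        "HELIX  %3d %3d %3s %1s %4d  %3s %1s %4d  1%30s %5d",
        nh, nh, res3[i1], ch, trace$seq_ids[i1],
        res3[i2], ch, trace$seq_ids[i2], "", i2 - i1 + 1L))
    } else if (runs$values[r] == "E") {
      ns <- ns + 1L
      header <- c(header, sprintf(
        "SHEET  %3d %3s%2d %3s %1s%4d  %3s %1s%4d  0",
        ns, sprintf("%d", ns), 1L, res3[i1], ch, trace$seq_ids[i1],
        res3[i2], ch, trace$seq_ids[i2]))
    }
  }
  atoms <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(q), res3, ch, trace$seq_ids,
    trace$coords[, 1], trace$coords[, 2], trace$coords[, 3])
  lines <- c(header, atoms, "TER", "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Add seeded Gaussian noise to a descriptor chain
#'
#' Perturbs `c_len` (clamped at zero) and `gamma` (clamped to
#' `[0, pi]`) with independent Gaussian noise; SSE codes and residues
#' are unchanged. Zero noise is the identity; results are reproducible
#' per seed.
#'
#' @param chain a [descriptor_chain][new_descriptor_chain].
#' @param noise_c standard deviation of the `c_len` noise (Angstrom).
#' @param noise_gamma standard deviation of the `gamma` noise (radians).
#' @param seed integer seed.
#' @return A perturbed `descriptor_chain`.
#' @export
perturb <- function(chain, noise_c = 0.05, noise_gamma = 0.05, seed = 1L) {
  stopifnot(inherits(chain, "descriptor_chain"),
            noise_c >= 0, noise_gamma >= 0)
  q <- length(chain)
  with_seed(seed, {
    chain$c_len <- pmax(chain$c_len + rnorm(q, sd = noise_c), 0)
    chain$gamma <- pmin(pmax(chain$gamma + rnorm(q, sd = noise_gamma), 0), pi)
  })
  chain
}
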