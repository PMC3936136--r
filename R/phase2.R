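#' Phase-2 component weights
#'
#' Participation weights of the four components of the residue-level
#' similarity reward: vector length (`w_c`), inter-vector angle
#' (`w_gamma`), secondary structure (`w_sse`) and amino-acid type
#' (`w_r`). All default to 1; setting `w_r = 0` disables the sequence
#' component, e.g. when hunting structural similarity without sequence
#' similarity.
#'
#' @param w_c,w_gamma,w_sse,w_r non-negative weights.
#' @return An object of class `phase2_weights`.
#' @export
phase2_weights <- function(w_c = 1, w_gamma = 1, w_sse = 1, w_r = 1) {
  w <- c(w_c = w_c, w_gamma = w_gamma, w_sse = w_sse, w_r = w_r)
  if (any(w < 0)) stop("weights must be non-negative")
  structure(as.list(w), class = "phase2_weights")
}

.pkg_cache <- new.env(parent = emptyenv())

#' Min-max normalised BLOSUM62 substitution table
#'
#' The standard 20x20 integer BLOSUM62 matrix rescaled globally to
#' `[0, 1]` by `(v - min) / (max - min)` (min −4, max 11, attained at
#' W-W). An `X` row and column of zeros is appended for non-standard
#' residues: an unknown residue carries no evidence of similarity.
#'
#' @return Symmetric 21 x 21 numeric matrix with entries in `[0, 1]`,
#'   dimnames the 20 standard one-letter codes plus `"X"`.
#' @export
normalize_blosum62 <- function() {
  if (!is.null(.pkg_cache$blosum)) return(.pkg_cache$blosum)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  raw <- e$BLOSUM62[.AA20, .AA20]
  if (min(raw) != -4 || max(raw) != 11)
    stop("unexpected BLOSUM62 range")
  norm <- (raw - min(raw)) / (max(raw) - min(raw))
  norm <- rbind(cbind(norm, X = 0), X = 0)
  colnames(norm)[21] <- "X"
  .pkg_cache$blosum <- norm
  norm
}

#' Gaussian similarity of inter-Calpha vector lengths
#'
#' `exp(-(c_q - c_d)^2)` for lengths in Angstrom: 1 at equality,
#' decaying with the squared difference.
#'
#' @param c_q,c_d non-negative vector lengths (Angstrom).
#' @return Numeric in `(0, 1]`.
#' @export
sigma_c <- function(c_q, c_d) exp(-(c_q - c_d)^2)

#' Gaussian similarity of inter-vector angles
#'
#' `exp(-(g_q - g_d)^2)` for angles in radians.
#'
#' @param g_q,g_d angles in `[0, pi]` radians.
#' @return Numeric in `(0, 1]`.
#' @export
sigma_gamma <- function(g_q, g_d) exp(-(g_q - g_d)^2)

#' Residue-level similarity reward
#'
#' The phase-2 reward for one pair of molecular residue descriptors:
#' `ss = w_c * sigma_c + w_gamma * sigma_gamma + w_sse * sigma_sse +
#' w_r * sigma_r`, with the secondary-structure component from
#' [sse_sigma()] and the sequence component from the normalised BLOSUM62
#' table. A pure reward: every component is non-negative, so divergence
#' is penalised only through gaps and the local-alignment clamp at zero.
#'
#' @param c_q,gamma_q,sse_q,res_q features of the query residue.
#' @param c_d,gamma_d,sse_d,res_d features of the database residue.
#' @param w a [phase2_weights()] object.
#' @param sub substitution table from [normalize_blosum62()].
#' @return Numeric reward in `[0, w_c + w_gamma + w_sse + w_r]`.
#' @export
residue_reward <- function(c_q, gamma_q, sse_q, res_q,
                           c_d, gamma_d, sse_d, res_d,
                           w = phase2_weights(), sub = normalize_blosum62()) {
  rq <- ifelse(res_q %in% rownames(sub), res_q, "X")
  rd <- ifelse(res_d %in% rownames(sub), res_d, "X")
  w$w_c * sigma_c(c_q, c_d) + w$w_gamma * sigma_gamma(gamma_q, gamma_d) +
    w$w_sse * sse_sigma(sse_q, sse_d) + w$w_r * sub[cbind(rq, rd)]
}

# Dense phase-2 reward matrix (query rows, database columns), vectorised.
.phase2_reward <- function(query, db, w, sub = normalize_blosum62()) {
  sc <- exp(-outer(query$c_len, db$c_len, `-`)^2)
  sg <- exp(-outer(query$gamma, db$gamma, `-`)^2)
  ss <- outer(query$sse, db$sse, sse_sigma)
  rq <- ifelse(query$residues %in% rownames(sub), query$residues, "X")
  rd <- ifelse(db$residues %in% rownames(sub), db$residues, "X")
  sr <- sub[rq, rd, drop = FALSE]
  w$w_c * sc + w$w_gamma * sg + w$w_sse * ss + w$w_r * sr
}

#' Phase-2 score of a database chain against a query
#'
#' High-resolution local alignment of two descriptor chains: the
#' region-level reward of phase 1 is replaced by [residue_reward()] over
#' molecular residue descriptors, and the score is the affine-gap local
#' alignment maximum. This score ranks the qualified database chains.
#'
#' @param query,db [descriptor_chain][new_descriptor_chain] objects.
#' @param gaps [gap_penalties()]; defaults to open 2.0, extend 0.2.
#' @param w a [phase2_weights()] object.
#' @return A `score_result` (see [local_affine_score()]).
#' @export
phase2_score <- function(query, db, gaps = gap_penalties(2.0, 0.2),
                         w = phase2_weights()) {
  stopifnot(inherits(query, "descriptor_chain"),
            inherits(db, "descriptor_chain"))
  local_affine_score(.phase2_reward(query, db, w), gaps = gaps)
}

#' Residue-level alignment path between two descriptor chains
#'
#' Computes the full phase-2 similarity matrix and backtracks from its
#' maximum, yielding the residue-level local alignment. The path score
#' equals [phase2_score()]. Intended for the small number of top-ranked
#' hits, not for whole-database scans.
#'
#' @inheritParams phase2_score
#' @return An `alignment_path` (see [backtrack()]).
#' @export
phase2_align <- function(query, db, gaps = gap_penalties(2.0, 0.2),
                         w = phase2_weights()) {
  stopifnot(inherits(query, "descriptor_chain"),
            inherits(db, "descriptor_chain"))
  dp <- local_affine_matrix(.phase2_reward(query, db, w), gaps = gaps)
  backtrack(dp)
}
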