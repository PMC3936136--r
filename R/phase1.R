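#' Secondary-structure similarity coefficient
#'
#' The three-valued coefficient `sigma` between two SE region types:
#' 1 when both regions are the same regular structure (both helix or
#' both strand); 0.5 when at least one is a loop/turn/coil/undetermined
#' region; 0 when one is a helix and the other a strand. Any code
#' outside `{H, E, L}` is treated as a neutral padding element with
#' coefficient 0.
#'
#' @param a,b character vectors of SSE codes (recycled to equal length).
#' @return Numeric vector with values in `{0, 0.5, 1}`.
#' @export
sse_sigma <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  out <- numeric(n)
  reg <- c("H", "E")
  out[(a %in% reg & b == "L") | (a == "L" & b %in% reg) |
        (a == "L" & b == "L")] <- 0.5
  out[a %in% reg & b %in% reg & a == b] <- 1
  out
}

#' Length-damped region similarity reward
#'
#' The phase-1 reward for aligning two SE regions:
#' `delta = sigma * (1 - |L_d - L_q| / (L_d + L_q))`, so identical types
#' of identical length score `sigma` and the reward decays with relative
#' length difference. Always in `[0, sigma]`.
#'
#' @param sse_q,sse_d SSE codes of the query and database regions.
#' @param len_q,len_d region lengths in residues (positive integers).
#' @return Numeric vector of rewards in `[0, 1]`.
#' @export
region_delta <- function(sse_q, len_q, sse_d, len_d) {
  sig <- sse_sigma(sse_q, sse_d)
  tot <- len_q + len_d
  damp <- ifelse(tot > 0, 1 - abs(len_d - len_q) / tot, 0)
  sig * damp
}

#' Encode / decode phase-1 similarity coefficients
#'
#' The query profile stores coefficients as 1-byte integers:
#' 0 -> 0, 1 -> 1, 0.5 -> 2.
#'
#' @param sigma numeric vector with values in `{0, 0.5, 1}`.
#' @return `encode_sigma`: integer codes; `decode_sigma`: numeric
#'   coefficients.
#' @export
encode_sigma <- function(sigma) {
  code <- integer(length(sigma))
  code[sigma == 1] <- 1L
  code[sigma == 0.5] <- 2L
  if (!all(sigma %in% c(0, 0.5, 1))) stop("sigma must be 0, 0.5 or 1")
  code
}

#' @rdname encode_sigma
#' @param code integer vector with values in `{0, 1, 2}`.
#' @export
decode_sigma <- function(code) {
  if (!all(code %in% 0:2)) stop("codes must be 0, 1 or 2")
  c(0, 1, 0.5)[code + 1L]
}

#' Build the phase-1 query profile
#'
#' Precomputes, for every SE region of the query, the encoded similarity
#' coefficient against each possible database region type (`H`, `E`,
#' `L`) plus a neutral element `0` whose column is all zeros. During a
#' database scan the reward is a profile lookup instead of a pairwise
#' rule evaluation.
#'
#' @param query a [reduced_chain][new_reduced_chain].
#' @return A `phase1_profile`: integer code matrix (regions x 4 with
#'   columns `H`, `E`, `L`, `0`) plus the region lengths.
#' @export
build_phase1_profile <- function(query) {
  stopifnot(inherits(query, "reduced_chain"))
  types <- c("H", "E", "L")
  codes <- vapply(types, function(t) encode_sigma(sse_sigma(query$sse, t)),
                  integer(length(query)))
  codes <- cbind(matrix(codes, ncol = 3L,
                        dimnames = list(NULL, types)), `0` = 0L)
  structure(list(codes = codes, lengths = query$lengths, sse = query$sse),
            class = "phase1_profile")
}

# Phase-1 reward matrix via the decoded query profile.
.phase1_reward <- function(profile, db) {
  col <- match(db$sse, colnames(profile$codes))
  col[is.na(col)] <- 4L                     # neutral padding elements
  sig <- matrix(decode_sigma(profile$codes[, col, drop = FALSE]),
                nrow = nrow(profile$codes))
  lq <- profile$lengths
  ld <- db$lengths
  tot <- outer(lq, ld, `+`)
  damp <- ifelse(tot > 0, 1 - abs(outer(lq, ld, `-`)) / tot, 0)
  sig * damp
}

#' Phase-1 score of a database chain against a query
#'
#' Low-resolution local alignment of two reduced chains of secondary
#' structures: the reward for pairing query region `i` with database
#' region `j` is [region_delta()], evaluated through the decoded query
#' profile, and the score is the affine-gap local alignment maximum.
#'
#' @param query,db [reduced_chain][new_reduced_chain] objects (or a
#'   prebuilt [build_phase1_profile()] for `query`).
#' @param gaps [gap_penalties()]; defaults to open 1.0, extend 0.1.
#' @return A `score_result` (see [local_affine_score()]).
#' @export
phase1_score <- function(query, db, gaps = gap_penalties(1.0, 0.1)) {
  profile <- if (inherits(query, "phase1_profile")) query
             else build_phase1_profile(query)
  stopifnot(inherits(db, "reduced_chain"))
  local_affine_score(.phase1_reward(profile, db), gaps = gaps)
}

#' Phase-1 self-score of the query
#'
#' The maximum phase-1 score the query can achieve: its score against
#' itself. Because every region's best partner is itself (identical type
#' and length), this equals the number of helix/strand regions plus half
#' the number of loop regions.
#'
#' @inheritParams phase1_score
#' @return Numeric scalar.
#' @export
phase1_self_score <- function(query, gaps = gap_penalties(1.0, 0.1)) {
  stopifnot(inherits(query, "reduced_chain"))
  phase1_score(query, query, gaps = gaps)$score
}
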