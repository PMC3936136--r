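#' Affine gap penalties
#'
#' Opening a gap costs `open` (g_O); each extension costs `extend` (g_E).
#' Both are non-negative and `open >= extend`.
#'
#' @param open non-negative gap-open penalty.
#' @param extend non-negative gap-extension penalty.
#' @return An object of class `gap_penalties`.
#' @export
gap_penalties <- function(open = 1.0, extend = 0.1) {
  open <- as.numeric(open); extend <- as.numeric(extend)
  if (!(open >= extend && extend >= 0))
    stop("gap penalties must satisfy open >= extend >= 0")
  structure(list(open = open, extend = extend), class = "gap_penalties")
}

# Coerce a reward function (i, j) -> real to a dense matrix.
.reward_matrix <- function(reward, n_query, n_db) {
  if (is.matrix(reward)) {
    storage.mode(reward) <- "double"
    return(reward)
  }
  if (!is.function(reward)) stop("reward must be a matrix or a function")
  m <- matrix(0, n_query, n_db)
  for (i in seq_len(n_query)) for (j in seq_len(n_db)) m[i, j] <- reward(i, j)
  m
}

#' Local alignment score with affine gaps, linear space
#'
#' Smith-Waterman-style local alignment over an arbitrary reward.
#' Matrix cells follow
#' `M[i,j] = max(M[i-1,j-1] + reward(i,j), E[i,j], F[i,j], 0)` with
#' boundary row/column zero, where `E` and `F` are the horizontal and
#' vertical affine gap vectors
#' (`E[i,j] = max(E[i,j-1] - g_E, M[i,j-1] - g_O)` and symmetrically for
#' `F`). The score is the maximum cell; only two rows are kept, so memory
#' is linear in `n_db`. Argmax ties break to the smallest `i`, then the
#' smallest `j`.
#'
#' @param reward either an `n_query x n_db` numeric matrix or a function
#'   `(i, j) -> numeric` over 1-based indices.
#' @param n_query,n_db dimensions; inferred when `reward` is a matrix.
#' @param gaps a [gap_penalties()] object.
#' @return A list of class `score_result` with elements `score`
#'   (non-negative) and `pos` (1-based `(i, j)` argmax; `c(0, 0)` when the
#'   score is zero).
#' @export
local_affine_score <- function(reward, n_query = nrow(reward),
                               n_db = ncol(reward), gaps = gap_penalties()) {
  stopifnot(inherits(gaps, "gap_penalties"))
  if (n_query < 1L || n_db < 1L)
    return(structure(list(score = 0, pos = c(0L, 0L)), class = "score_result"))
  m <- .reward_matrix(reward, n_query, n_db)
  r <- .dp_score(m, gaps$open, gaps$extend)
  structure(list(score = r$score, pos = c(r$i, r$j)), class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result> score %.4f at (%d, %d)\n",
              x$score, x$pos[1], x$pos[2]))
  invisible(x)
}

#' Full similarity matrix with gap vectors
#'
#' Quadratic-space companion of [local_affine_score()]: materialises the
#' complete matrices `M`, `E`, `F` (including the zero boundary row and
#' column) for backtracking. The maximum cell is identical to the
#' linear-space score.
#'
#' @inheritParams local_affine_score
#' @return List with `(n_query+1) x (n_db+1)` matrices `M`, `E`, `F`, the
#'   `score`, its position `pos`, the reward matrix and the penalties.
#' @export
local_affine_matrix <- function(reward, n_query = nrow(reward),
                                n_db = ncol(reward), gaps = gap_penalties()) {
  stopifnot(inherits(gaps, "gap_penalties"), n_query >= 1L, n_db >= 1L)
  m <- .reward_matrix(reward, n_query, n_db)
  r <- .dp_matrix(m, gaps$open, gaps$extend)
  list(M = r$M, E = r$E, F = r$F, score = r$score, pos = c(r$i, r$j),
       reward = m, gaps = gaps)
}

#' Backtrack a local alignment path
#'
#' Traces the alignment from a positive cell of the full matrix down to
#' the first zero cell. At each step the move consistent with the
#' recurrence is chosen with priority diagonal, then vertical gap (query
#' residue vs gap), then horizontal gap.
#'
#' @param dp result of [local_affine_matrix()].
#' @param start 1-based `(i, j)` start cell; defaults to the argmax.
#' @return An `alignment_path`: data frame with columns `q` and `d`
#'   (1-based indices, `NA` for a gap) ordered from the start of the local
#'   alignment, with attribute `score`. An empty path if the start cell is
#'   not positive.
#' @export
backtrack <- function(dp, start = dp$pos) {
  M <- dp$M; E <- dp$E; F <- dp$F
  rw <- dp$reward; go <- dp$gaps$open; ge <- dp$gaps$extend
  eps <- 1e-9
  i <- start[1]; j <- start[2]
  qs <- integer(0); ds <- integer(0)
  score <- if (i >= 1L && j >= 1L) M[i + 1L, j + 1L] else 0
  if (!(i >= 1L && j >= 1L) || score <= 0) {
    out <- data.frame(q = integer(0), d = integer(0))
    attr(out, "score") <- 0
    class(out) <- c("alignment_path", class(out))
    return(out)
  }
  state <- "M"
  repeat {
    if (state == "M") {
      v <- M[i + 1L, j + 1L]
      if (v <= eps) break
      if (abs(v - (M[i, j] + rw[i, j])) <= eps) {
        qs <- c(qs, i); ds <- c(ds, j); i <- i - 1L; j <- j - 1L
      } else if (abs(v - F[i + 1L, j + 1L]) <= eps) {
        state <- "F"
      } else if (abs(v - E[i + 1L, j + 1L]) <= eps) {
        state <- "E"
      } else stop("inconsistent matrices during backtracking")
    } else if (state == "F") {        # vertical gap: consume query residue
      v <- F[i + 1L, j + 1L]
      qs <- c(qs, i); ds <- c(ds, NA_integer_)
      if (abs(v - (M[i, j + 1L] - go)) <= eps) state <- "M"
      else if (abs(v - (F[i, j + 1L] - ge)) <= eps) state <- "F"
      else stop("inconsistent F vector during backtracking")
      i <- i - 1L
    } else {                          # horizontal gap: consume db residue
      v <- E[i + 1L, j + 1L]
      qs <- c(qs, NA_integer_); ds <- c(ds, j)
      if (abs(v - (M[i + 1L, j] - go)) <= eps) state <- "M"
      else if (abs(v - (E[i + 1L, j] - ge)) <= eps) state <- "E"
      else stop("inconsistent E vector during backtracking")
      j <- j - 1L
    }
  }
  out <- data.frame(q = rev(qs), d = rev(ds))
  attr(out, "score") <- score
  class(out) <- c("alignment_path", class(out))
  out
}
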