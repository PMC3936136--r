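# Independent reference implementations used only as test oracles.

# Full-matrix local affine-gap alignment in plain R, written directly
# from the recurrences; returns the maximum cell.
ref_local_affine <- function(reward, go, ge) {
  n <- nrow(reward); m <- ncol(reward)
  M <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(E[i, j - 1] - ge, M[i, j - 1] - go)
      F[i, j] <- max(F[i - 1, j] - ge, M[i - 1, j] - go)
      M[i, j] <- max(M[i - 1, j - 1] + reward[i - 1, j - 1],
                     E[i, j], F[i, j], 0)
    }
  }
  max(M)
}

# Exhaustive local-alignment oracle for tiny instances: enumerates every
# chain of matched pairs with strictly increasing indices, scoring
# rewards minus affine costs for the index jumps between consecutive
# pairs. Returns the best score and one best pair chain.
enum_local_paths <- function(reward, go, ge) {
  n <- nrow(reward); m <- ncol(reward)
  gapcost <- function(k) if (k <= 0) 0 else go + (k - 1) * ge
  best <- list(score = 0, pairs = matrix(integer(0), 0, 2))
  extend <- function(pairs, score) {
    if (score > best$score) best <<- list(score = score, pairs = pairs)
    last <- pairs[nrow(pairs), ]
    for (i in seq_len(n)) for (j in seq_len(m)) {
      if (i > last[1] && j > last[2]) {
        add <- reward[i, j] - gapcost(i - last[1] - 1) -
          gapcost(j - last[2] - 1)
        extend(rbind(pairs, c(i, j)), score + add)
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m))
    extend(matrix(c(i, j), 1, 2), reward[i, j])
  best
}

# Horn's quaternion method for optimal rigid superposition: an
# SVD-free route to the same minimum RMSD.
quaternion_superpose_rmsd <- function(fixed, mobile) {
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  S <- crossprod(A, B)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  e <- eigen(K, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  moved <- A %*% t(R)
  sqrt(mean(rowSums((moved - B)^2)))
}

# Random helpers for property-style tests.
random_reduced_chain <- function(n_regions, id = "rnd") {
  repeat {
    sse <- sample(c("H", "E", "L"), n_regions, replace = TRUE)
    if (n_regions == 1L || all(sse[-1] != sse[-n_regions])) break
  }
  new_reduced_chain(id, sse, sample(1:12, n_regions, replace = TRUE))
}

random_descriptor_chain <- function(q, id = "rnd") {
  new_descriptor_chain(id,
                       c_len = c(runif(q - 1, 3.4, 4.0), 0)[seq_len(q)],
                       gamma = c(runif(max(q - 2, 0), 0, pi),
                                 numeric(min(q, 2)))[seq_len(q)],
                       sse = sample(c("H", "E", "L"), q, replace = TRUE),
                       residues = sample(LETTERS[c(1, 3:9, 11:14,
                                                   16:20, 22, 23, 25)],
                                         q, replace = TRUE))
}

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
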