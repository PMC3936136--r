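test_that("normalised BLOSUM62 is a symmetric [0,1] table with unit W-W", {
  sub <- normalize_blosum62()
  expect_equal(dim(sub), c(21L, 21L))
  expect_equal(min(sub), 0)
  expect_equal(max(sub), 1)
  expect_equal(sub["W", "W"], 1)      # raw 11, the global maximum
  expect_true(all(sub >= 0 & sub <= 1))
  expect_equal(sub, t(sub))
  expect_true(all(sub["X", ] == 0) && all(sub[, "X"] == 0))
})

test_that("Gaussian feature similarities match direct evaluation", {
  expect_equal(sigma_c(3.8, 3.8), 1)
  expect_equal(sigma_c(3.8, 2.8), exp(-1))
  expect_equal(sigma_gamma(1.2, 1.2), 1)
  expect_equal(sigma_gamma(pi / 2, 0), exp(-(pi / 2)^2))
  expect_equal(sigma_gamma(0.3, 1.1), sigma_gamma(1.1, 0.3))
  # strictly decreasing in the absolute difference
  d <- sigma_c(3.8, 3.8 + seq(0, 2, by = 0.1))
  expect_true(all(diff(d) < 0))
})

test_that("residue_reward combines the four weighted components", {
  w0r <- phase2_weights(w_r = 0)
  expect_equal(residue_reward(3.8, 1.0, "H", "A", 3.8, 1.0, "H", "A", w0r), 3)
  expect_equal(residue_reward(3.8, 1.0, "L", "W", 3.8, 1.0, "L", "W"), 3.5)
  expect_equal(residue_reward(1, 1, "H", "A", 2, 2, "E", "C",
                              phase2_weights(0, 0, 0, 0)), 0)
  # unknown residues carry no sequence evidence
  expect_equal(residue_reward(3.8, 1, "H", "X", 3.8, 1, "H", "X"), 3)
  # bounded by the weight sum, attained only at full identity on H/E
  expect_lte(residue_reward(3.7, 0.9, "E", "W", 3.7, 0.9, "E", "W"), 4)
  expect_equal(residue_reward(3.7, 0.9, "E", "W", 3.7, 0.9, "E", "W"), 4)
  expect_lt(residue_reward(3.7, 0.9, "L", "W", 3.7, 0.9, "L", "W"), 4)
})

test_that("phase-2 self-score equals the diagonal reward sum", {
  withr::local_seed(31)
  g <- gap_penalties(2, 0.2)
  for (k in 1:100) {
    d <- random_descriptor_chain(sample(2:12, 1))
    diag_sum <- sum(residue_reward(d$c_len, d$gamma, d$sse, d$residues,
                                   d$c_len, d$gamma, d$sse, d$residues))
    expect_equal(phase2_score(d, d, g)$score, diag_sum, tolerance = 1e-9)
  }
})

test_that("phase-2 score is symmetric, non-negative, zero at zero weights", {
  withr::local_seed(32)
  g <- gap_penalties(2, 0.2)
  w0 <- phase2_weights(0, 0, 0, 0)
  for (k in 1:20) {
    a <- random_descriptor_chain(sample(2:8, 1), "a")
    b <- random_descriptor_chain(sample(2:8, 1), "b")
    expect_equal(phase2_score(a, b, g)$score, phase2_score(b, a, g)$score,
                 tolerance = 1e-12)
    expect_gte(phase2_score(a, b, g)$score, 0)
    expect_equal(phase2_score(a, b, g, w = w0)$score, 0)
  }
})

test_that("phase-2 DP agrees with the plain-R oracle on random pairs", {
  withr::local_seed(33)
  sub <- normalize_blosum62()
  for (k in 1:50) {
    a <- random_descriptor_chain(sample(2:8, 1), "a")
    b <- random_descriptor_chain(sample(2:8, 1), "b")
    rw <- outer(seq_along(a$c_len), seq_along(b$c_len), function(i, j)
      residue_reward(a$c_len[i], a$gamma[i], a$sse[i], a$residues[i],
                     b$c_len[j], b$gamma[j], b$sse[j], b$residues[j],
                     sub = sub))
    go <- runif(1, 0.5, 3); ge <- runif(1, 0, 0.5)
    expect_equal(phase2_score(a, b, gap_penalties(go, ge))$score,
                 ref_local_affine(rw, go, ge), tolerance = 1e-9)
  }
})

test_that("identical chains align gaplessly; path score equals the score", {
  d <- random_descriptor_chain(6, "a")
  p <- phase2_align(d, d)
  expect_identical(p$q, 1:6)
  expect_identical(p$d, 1:6)
  expect_equal(attr(p, "score"), phase2_score(d, d)$score, tolerance = 1e-9)
})

test_that("deleting two residues from a copy is bridged by one gap run", {
  withr::local_seed(34)
  d <- random_descriptor_chain(8, "a")
  keep <- setdiff(1:8, 4:5)
  cut <- new_descriptor_chain("cut", d$c_len[keep], d$gamma[keep],
                              d$sse[keep], d$residues[keep])
  p <- phase2_align(d, cut)
  gaps <- which(is.na(p$d))
  expect_identical(p$q[gaps], 4:5)                  # deleted query positions
  expect_identical(p$q[!is.na(p$d)], setdiff(1:8, 4:5))
  expect_identical(p$d[!is.na(p$d)], 1:6)
})

test_that("path score equals phase2_score on random pairs", {
  withr::local_seed(35)
  for (k in 1:50) {
    a <- random_descriptor_chain(sample(3:10, 1), "a")
    b <- random_descriptor_chain(sample(3:10, 1), "b")
    p <- phase2_align(a, b)
    expect_equal(attr(p, "score"), phase2_score(a, b)$score, tolerance = 1e-9)
  }
})

test_that("a planted noisy fragment is recovered by the phase-2 path", {
  withr::local_seed(36)
  frag <- random_descriptor_chain(20, "frag")
  flank <- function(q, id) random_descriptor_chain(q, id)
  a_pre <- flank(15, "ap"); a_post <- flank(12, "as")
  b_pre <- flank(9, "bp"); b_post <- flank(18, "bs")
  glue <- function(id, parts) {
    new_descriptor_chain(id,
                         unlist(lapply(parts, `[[`, "c_len")),
                         unlist(lapply(parts, `[[`, "gamma")),
                         unlist(lapply(parts, `[[`, "sse")),
                         unlist(lapply(parts, `[[`, "residues")))
  }
  frag_b <- perturb(frag, noise_c = 0.05, noise_gamma = 0.05, seed = 99)
  a <- glue("a", list(a_pre, frag, a_post))
  b <- glue("b", list(b_pre, frag_b, b_post))
  p <- phase2_align(a, b)
  got <- paste(p$q, p$d)
  planted <- paste(15 + 1:20, 9 + 1:20)
  expect_gte(mean(planted %in% got), 0.95)
})
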