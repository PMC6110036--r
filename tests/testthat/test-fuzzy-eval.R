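test_that("eval_matrix validates shape, directions and weights", {
  m <- rbind(a = c(1, 2), b = c(3, 4))
  em <- eval_matrix(m, criteria = c("HRIA", "HRIT"))
  expect_equal(em$weights, c(0.5, 0.5))
  expect_equal(em$directions, c("cost", "cost"))
  expect_error(eval_matrix(m[1, , drop = FALSE]), "2 groups")
  expect_error(eval_matrix(rbind(c(1, NA), c(2, 3))), "finite")
  expect_error(eval_matrix(m, directions = "up"), "cost")
  expect_error(eval_matrix(m, weights = c(-1, 2)), "weights")
  # weights normalized
  expect_equal(eval_matrix(m, weights = c(2, 6))$weights, c(0.25, 0.75))
})

test_that("vector normalization divides by the column Euclidean norm", {
  em <- eval_matrix(cbind(c(3, 4)), criteria = "c1",
                    groups = c("a", "b"))
  nm <- topsis_normalize(em, "vector")
  expect_equal(unname(nm$values[, 1]), c(0.6, 0.8))
  z <- eval_matrix(cbind(c(0, 0), c(1, 2)))
  expect_error(topsis_normalize(z, "vector"), "zero-norm")
})

test_that("minmax normalization is direction-aware", {
  em <- eval_matrix(cbind(c(10, 50)), directions = "cost")
  nm <- topsis_normalize(em, "minmax")
  expect_equal(unname(nm$values[, 1]), c(1, 0))  # lower cost is better
  expect_equal(nm$directions, "benefit")
  emb <- eval_matrix(cbind(c(10, 50)), directions = "benefit")
  expect_equal(unname(topsis_normalize(emb, "minmax")$values[, 1]), c(0, 1))
  const <- eval_matrix(cbind(c(2, 2), c(1, 3)))
  expect_warning(nc <- topsis_normalize(const, "minmax"), "constant")
  expect_equal(unname(nc$values[, 1]), c(0, 0))
})

test_that("scheme 'none' is the identity", {
  em <- eval_matrix(rbind(c(1, 9), c(4, 2)))
  expect_equal(topsis_normalize(em, "none")$values, em$values)
})

test_that("ideal points pick the best/worst per direction", {
  ip <- ideal_points(cbind(c(0.2, 0.5, 0.9)), "cost")
  expect_equal(ip$ideal, 0.2)
  expect_equal(ip$anti_ideal, 0.9)
  ip2 <- ideal_points(cbind(c(0.2, 0.9)), "benefit")
  expect_equal(ip2$ideal, 0.9)
  ip3 <- ideal_points(cbind(c(1, 2), c(5, 3)), c("cost", "benefit"))
  expect_length(ip3$ideal, 2)
  expect_equal(ip3$ideal, c(1, 5))
  expect_equal(ip3$anti_ideal, c(2, 3))
})

test_that("closeness reproduces the published distance pairs", {
  expect_equal(round(closeness(0.045, 0.465), 3), 0.912)
  expect_equal(closeness(0.502, 0), 0)
  expect_equal(closeness(0.33, 0.33), 0.5)
  expect_error(closeness(-0.1, 0.2), "nonnegative")
  expect_warning(c0 <- closeness(0, 0), "zero")
  expect_equal(c0, 1)
})

test_that("dense ranking ties share a rank with no gap after", {
  expect_equal(dense_rank_desc(c(1, 0.9, 0.3, 0.3, 0)), c(1, 2, 3, 3, 4))
  expect_equal(dense_rank_desc(c(5, 5, 5)), c(1, 1, 1))
})

test_that("evaluate: 3 groups on 2 equal cost criteria give C = 1, 0.5, 0", {
  em <- eval_matrix(rbind(a = c(1, 1), b = c(2, 2), c = c(3, 3)),
                    criteria = c("HRIA", "HRIT"))
  r <- topsis_evaluate(em, scheme = "vector")
  expect_equal(r$closeness, c(1, 0.5, 0))
  expect_equal(r$rank, c(1L, 2L, 3L))
  expect_equal(r$group, c("a", "b", "c"))
})

test_that("group at the per-criterion ideal gets C = 1 and rank 1; worst gets 0", {
  set.seed(31)
  m <- matrix(runif(12, 1, 9), 4, 3)
  m[2, ] <- apply(m, 2, min) - 0.1  # dominates on all cost criteria
  m[4, ] <- apply(m, 2, max) + 0.1  # dominated everywhere
  r <- topsis_evaluate(eval_matrix(m), scheme = "vector")
  expect_equal(r$closeness[2], 1)
  expect_equal(r$rank[2], 1L)
  expect_equal(r$closeness[4], 0)
  expect_true(all(r$closeness >= 0 & r$closeness <= 1))
})

test_that("identical rows tie and the next distinct C takes the next rank", {
  em <- eval_matrix(rbind(best = c(1, 1), t1 = c(2.5, 2.5),
                          t2 = c(2.5, 2.5), worst = c(4, 4)))
  r <- topsis_evaluate(em)
  expect_equal(r$rank, c(1L, 2L, 2L, 3L))
  expect_equal(r$closeness[2], r$closeness[3])
})

test_that("permuting group rows permutes the results identically", {
  set.seed(41)
  m <- matrix(runif(10), 5, 2, dimnames = list(letters[1:5], NULL))
  r <- topsis_evaluate(eval_matrix(m), scheme = "vector")
  perm <- c(3, 1, 5, 2, 4)
  rp <- topsis_evaluate(eval_matrix(m[perm, ]), scheme = "vector")
  expect_equal(rp$closeness, r$closeness[perm])
  expect_equal(rp$rank, r$rank[perm])
})

test_that("minmax monotonicity: worsening a non-extreme cost value lowers C", {
  m <- rbind(a = c(1, 1), b = c(2, 2), c = c(4, 4))
  base <- topsis_evaluate(eval_matrix(m), scheme = "minmax")
  m2 <- m; m2["b", 1] <- 3  # worse on criterion 1, extremes unchanged
  worse <- topsis_evaluate(eval_matrix(m2), scheme = "minmax")
  expect_lte(worse$closeness[2], base$closeness[2])
})

test_that("evaluate matches the brute-force oracle on random matrices", {
  set.seed(53)
  for (i in 1:50) {
    g <- sample(2:5, 1); k <- sample(1:3, 1)
    m <- matrix(runif(g * k, 1, 100), g, k)
    dirs <- sample(c("cost", "benefit"), k, replace = TRUE)
    w <- runif(k, 0.1, 1)
    for (scheme in c("vector", "minmax")) {
      r <- topsis_evaluate(eval_matrix(m, directions = dirs, weights = w),
                           scheme = scheme)
      o <- topsis_oracle(m, dirs, w, scheme)
      expect_lt(max(abs(r$closeness - o$closeness)), 1e-12)
      expect_equal(r$rank, o$rank)
    }
  }
})

test_that("the bundled reference table is well-formed", {
  ref <- efficacy_reference()
  expect_equal(nrow(ref), 9)
  expect_true(all(c("d_plus", "d_minus", "c_published",
                    "rank_published") %in% names(ref)))
  expect_true(all(ref$d_plus >= 0 & ref$d_minus >= 0))
})
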