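# Shared fixtures and independent oracles.

# regular n-gon approximating a circle (vertices on the circle)
circle_polygon <- function(r, n = 128L, center = c(0, 0)) {
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(x = center[1] + r * cos(theta), y = center[2] + r * sin(theta))
}

# exact area of a regular n-gon with circumradius r
ngon_area <- function(r, n) n / 2 * r^2 * sin(2 * pi / n)

# noise-free concentric-circle section with given ring radii
concentric_section <- function(r_lumen, r_iel, r_eel, n = 128L,
                               group = "g", animal = 1L, slice = 1L) {
  list(group = group, animal = animal, slice = slice,
       contours = list(eel = circle_polygon(r_eel, n),
                       iel = circle_polygon(r_iel, n),
                       lumen = circle_polygon(r_lumen, n)))
}

# Independent brute-force TOPSIS: explicit loops, no shared code with the
# package implementation. Returns closeness and dense ranks.
topsis_oracle <- function(values, directions, weights, scheme) {
  m <- as.matrix(values)
  G <- nrow(m); K <- ncol(m)
  w <- weights / sum(weights)
  nm <- matrix(NA_real_, G, K)
  dir2 <- directions
  for (j in seq_len(K)) {
    col <- m[, j]
    if (scheme == "vector") {
      nm[, j] <- col / sqrt(sum(col * col))
    } else if (scheme == "minmax") {
      if (directions[j] == "cost") {
        nm[, j] <- (max(col) - col) / (max(col) - min(col))
      } else {
        nm[, j] <- (col - min(col)) / (max(col) - min(col))
      }
      dir2[j] <- "benefit"
    } else {
      nm[, j] <- col
    }
    nm[, j] <- nm[, j] * w[j]
  }
  ideal <- anti <- numeric(K)
  for (j in seq_len(K)) {
    if (dir2[j] == "cost") {
      ideal[j] <- min(nm[, j]); anti[j] <- max(nm[, j])
    } else {
      ideal[j] <- max(nm[, j]); anti[j] <- min(nm[, j])
    }
  }
  dp <- dm <- cc <- numeric(G)
  for (i in seq_len(G)) {
    dp[i] <- sqrt(sum((nm[i, ] - ideal)^2))
    dm[i] <- sqrt(sum((nm[i, ] - anti)^2))
    cc[i] <- if (dp[i] + dm[i] > 0) dm[i] / (dp[i] + dm[i]) else 1
  }
  rk <- integer(G)
  for (i in seq_len(G)) {
    bigger <- 0L
    for (u in unique(cc)) if (u > cc[i]) bigger <- bigger + 1L
    rk[i] <- bigger + 1L
  }
  list(d_plus = dp, d_minus = dm, closeness = cc, rank = rk)
}

# configured efficacy order of the default cohort, best first (by
# increasing intimal-thickness effect; the truth sidecar carries it)
configured_efficacy_order <- function(cohort) {
  truth <- cohort$truth
  injured <- truth[names(truth) != "normal"]
  it <- vapply(injured, `[[`, 0, "intima_thickness_mean")
  names(sort(it))
}
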