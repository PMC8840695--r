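# Independent oracles used across the suite. These never call the package's
# quadrature path: the grid oracle integrates the random-effect integral by
# Simpson's rule on a dense 2-D grid, and the 2x2 chi-square uses the
# N(ad-bc)^2 closed form.

bern_ll_vec <- function(eta, y) y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0)

# Simpson weights for an odd number of points
simpson_w <- function(n) {
  stopifnot(n %% 2 == 1)
  c(1, rep(c(4, 2), length.out = n - 2), 1) / 3
}

# brute-force marginal log-likelihood: dense Simpson grid over
# [-6*sigma_max, 6*sigma_max]^2 per cluster
grid_oracle_ll <- function(design, th1, th2, Sigma, n_grid = 1201) {
  Q <- solve(Sigma)
  ld <- as.numeric(determinant(Sigma)$modulus)
  total <- 0
  for (c in seq_len(design$n_clusters) - 1L) {
    r1 <- which(design$cl1 == c)
    r2 <- which(design$cl2 == c)
    s <- 6 * sqrt(max(diag(Sigma)))
    u <- seq(-s, s, length.out = n_grid)
    h <- u[2] - u[1]
    w <- simpson_w(n_grid) * h
    e1 <- drop(design$X1[r1, , drop = FALSE] %*% th1)
    e2 <- drop(design$X2[r2, , drop = FALSE] %*% th2)
    G <- matrix(0, n_grid, n_grid)
    for (k in seq_along(r1)) G <- G + bern_ll_vec(e1[k] + u, design$y1[r1[k]])
    for (k in seq_along(r2)) {
      G <- G + matrix(bern_ll_vec(e2[k] + u, design$y2[r2[k]]),
                      n_grid, n_grid, byrow = TRUE)
    }
    U1 <- matrix(u, n_grid, n_grid)
    U2 <- t(U1)
    G <- G - 0.5 * (Q[1, 1] * U1^2 + 2 * Q[1, 2] * U1 * U2 + Q[2, 2] * U2^2) -
      0.5 * ld - log(2 * pi)
    total <- total + log(drop(t(w) %*% exp(G) %*% w))
  }
  total
}

# closed-form Pearson chi-square for a 2x2 table
chi2_2x2_closed <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  N <- a + b + c + d
  N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# expand a levels x 2 count table into one record per unit
records_from_counts <- function(counts, variable, outcome,
                                cluster_id = "EA0001") {
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    for (j in 1:2) {
      n <- counts[i, j]
      if (n > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          level = rownames(counts)[i], y = ifelse(j == 1, 1L, 0L),
          count = n, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  out <- tab[rep(seq_len(nrow(tab)), tab$count), c("level", "y")]
  df <- data.frame(
    child_id = sprintf("ch%05d", seq_len(nrow(out))),
    cluster_id = cluster_id, household_id = "h1", weight = 1,
    stringsAsFactors = FALSE)
  df[[variable]] <- out$level
  df[[outcome]] <- out$y
  df
}
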