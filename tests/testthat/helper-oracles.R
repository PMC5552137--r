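# Independent brute-force oracles and small fixture generators.
# These deliberately avoid the package's vectorised/log-space code paths.

random_window_string <- function(k = 41L) {
  paste(sample(AA_LETTERS, k, replace = TRUE), collapse = "")
}

random_grid <- function(n, lo = 0L, hi = 20L) {
  matrix(sample(lo:hi, n * n, replace = TRUE), n, n)
}

# direct double-loop raw moment
oracle_raw_moment <- function(grid, i, j) {
  n <- nrow(grid)
  s <- 0
  for (p in 1:n) for (q in 1:n) s <- s + p^i * q^j * grid[p, q]
  s
}

oracle_central_moment <- function(grid, i, j) {
  m00 <- oracle_raw_moment(grid, 0, 0)
  xb <- oracle_raw_moment(grid, 1, 0) / m00
  yb <- oracle_raw_moment(grid, 0, 1) / m00
  n <- nrow(grid)
  s <- 0
  for (p in 1:n) for (q in 1:n) s <- s + (p - xb)^i * (q - yb)^j * grid[p, q]
  s
}

# plain-product Pochhammer and term-by-term Hahn polynomial (no logs)
oracle_poch <- function(a, k) if (k == 0) 1 else prod(a + 0:(k - 1))

oracle_hahn <- function(n, r, N, u = 0, v = 0) {
  s <- 0
  for (k in 0:n) {
    s <- s + oracle_poch(-n, k) * oracle_poch(n + u + v + 1, k) *
      oracle_poch(-r, k) /
      (oracle_poch(v + 1, k) * oracle_poch(1 - N, k) * factorial(k))
  }
  s
}

oracle_hahn_weight <- function(r, N, u = 0, v = 0) {
  gamma(N + u - r) * gamma(v + 1 + r) / (gamma(r + 1) * gamma(N - r))
}

# table of normalised basis values h~_n(r) for n in 0..maxord
oracle_hahn_tilde <- function(N, maxord, u = 0, v = 0) {
  r <- 0:(N - 1)
  rho <- sapply(r, oracle_hahn_weight, N = N, u = u, v = v)
  t(sapply(0:maxord, function(n) {
    h <- sapply(r, function(ri) oracle_hahn(n, ri, N, u, v))
    h * sqrt(rho / sum(rho * h^2))
  }))
}

oracle_hahn_moment <- function(grid, i, j, tilde) {
  N <- nrow(grid)
  s <- 0
  for (p in 1:N) for (q in 1:N) {
    s <- s + grid[p, q] * tilde[i + 1, q] * tilde[j + 1, p]
  }
  s
}

# double-loop PRIM
oracle_prim <- function(codes) {
  A <- matrix(0, 20, 20)
  pos <- which(codes >= 1)
  for (i in 1:20) {
    fi <- pos[codes[pos] == i][1]
    if (is.na(fi)) next
    for (j in 1:20) {
      pj <- pos[codes[pos] == j]
      if (length(pj)) A[i, j] <- sum(pj - fi)
    }
  }
  A
}

# AUC as the pairwise rank statistic (Mann-Whitney U / (n_pos * n_neg))
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# small configs that keep protocol-level tests fast
quick_config <- function(...) {
  train_config(hidden = 5L, max_epochs = 60L, seed = 42L, ...)
}

quick_dataset <- function(n_per = 30L, seed = 7L, ...) {
  generate_dataset(sim_config(n_pos = n_per, n_neg = n_per,
                              seed = seed, ...))
}
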