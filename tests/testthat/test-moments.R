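test_that("reshape_to_grid fills row-major into the smallest square", {
  g <- reshape_to_grid(c(1, 2, 3, 4))
  expect_identical(g, matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  expect_identical(reshape_to_grid(5), matrix(5, 1, 1))
  g41 <- reshape_to_grid(rep(1, 41))
  expect_identical(dim(g41), c(7L, 7L))
  expect_identical(sum(g41 == 0), 8L)           # 49 - 41 trailing zeros
  expect_identical(as.vector(t(g41))[42:49], rep(0, 8))
  expect_error(reshape_to_grid(numeric(0)), "empty")
  # mass conservation
  set.seed(1)
  codes <- sample(0:20, 41, replace = TRUE)
  expect_equal(sum(reshape_to_grid(codes)), sum(codes))
})

test_that("raw moments match hand values and the double-loop oracle", {
  ones <- matrix(1, 7, 7)
  m <- raw_moments(ones)
  expect_equal(m[["m00"]], 49)
  expect_equal(m[["m10"]], 196)    # 7 * (1 + ... + 7)
  expect_equal(unname(raw_moments(matrix(0, 7, 7))), rep(0, 8))
  set.seed(11)
  for (n in c(7L, 20L)) {
    for (rep in 1:10) {
      g <- random_grid(n)
      m <- raw_moments(g)
      for (k in seq_len(nrow(MOMENT_ORDERS))) {
        expect_equal(m[[k]],
                     oracle_raw_moment(g, MOMENT_ORDERS[k, 1],
                                       MOMENT_ORDERS[k, 2]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("centroid is M10/M00, M01/M00 and fails on zero mass", {
  expect_equal(centroid(matrix(1, 7, 7)), c(x = 4, y = 4))
  pt <- matrix(0, 5, 5); pt[2, 3] <- 9
  expect_equal(centroid(pt), c(x = 2, y = 3))
  expect_error(centroid(matrix(0, 7, 7)), "zero total mass")
})

test_that("central moments: first order vanishes, point mass degenerates", {
  set.seed(2)
  g <- random_grid(7)
  cm <- central_moments(g)
  expect_equal(cm[["c10"]], 0, tolerance = 1e-9)
  expect_equal(cm[["c01"]], 0, tolerance = 1e-9)
  expect_equal(cm[["c00"]], raw_moments(g)[["m00"]])
  expect_equal(central_moments(matrix(1, 7, 7))[["c11"]], 0,
               tolerance = 1e-9)
  pt <- matrix(0, 6, 6); pt[4, 2] <- 5
  cpt <- central_moments(pt)
  expect_equal(unname(cpt[-1]), rep(0, 7), tolerance = 1e-9)
  expect_error(central_moments(matrix(0, 3, 3)), "zero total mass")
})

test_that("central moments are invariant to translating the pattern", {
  pat <- matrix(c(3, 1, 0, 2), 2, 2)
  emb <- function(dr, dc) {
    g <- matrix(0, 9, 9)
    g[dr + 1:2, dc + 1:2] <- pat
    g
  }
  base <- central_moments(emb(0, 0))
  for (sh in list(c(3, 0), c(0, 4), c(5, 6))) {
    expect_equal(central_moments(emb(sh[1], sh[2])), base,
                 tolerance = 1e-9)
  }
})

test_that("central moments against the double-loop oracle", {
  set.seed(13)
  for (n in c(7L, 20L)) {
    g <- random_grid(n, lo = 1L)
    cm <- central_moments(g)
    for (k in seq_len(nrow(MOMENT_ORDERS))) {
      expect_equal(cm[[k]],
                   oracle_central_moment(g, MOMENT_ORDERS[k, 1],
                                         MOMENT_ORDERS[k, 2]),
                   tolerance = 1e-9)
    }
  }
})

test_that("hahn_polynomial: order 0 is constant, matches term oracle", {
  expect_equal(hahn_polynomial(0, 0:6, 7), rep(1, 7))
  for (n in 0:4) {
    expect_equal(hahn_polynomial(n, 0:6, 7),
                 sapply(0:6, function(r) oracle_hahn(n, r, 7)),
                 tolerance = 1e-9)
  }
  # non-default shape parameters and the larger support
  expect_equal(hahn_polynomial(3, 0:19, 20, u = 1.5, v = 0.5),
               sapply(0:19, function(r) oracle_hahn(3, r, 20, 1.5, 0.5)),
               tolerance = 1e-9)
  expect_error(hahn_polynomial(7, 0, 7), "0..N-1")
  expect_error(hahn_polynomial(1, 9, 7), "0..N-1")
})

test_that("weighted Hahn basis is orthonormal", {
  for (uv in list(c(0, 0), c(1, 2))) {
    phi <- hahn_basis(7, u = uv[1], v = uv[2])
    expect_lt(max(abs(phi %*% t(phi) - diag(7))), 1e-8)
  }
  phi20 <- hahn_basis(20, orders = 0:3)
  expect_lt(max(abs(phi20 %*% t(phi20) - diag(4))), 1e-8)
  # raw-polynomial weighted orthogonality, m != n
  rho <- hahn_weight(0:6, 7)
  for (m in 0:3) for (n in 0:3) {
    if (m == n) next
    s <- sum(rho * hahn_polynomial(m, 0:6, 7) * hahn_polynomial(n, 0:6, 7))
    expect_lt(abs(s), 1e-8)
  }
})

test_that("full-order Hahn transform reconstructs the grid", {
  set.seed(5)
  for (n in c(7L, 9L)) {
    g <- random_grid(n)
    H <- hahn_transform(g)
    expect_lt(max(abs(inverse_hahn_transform(H) - g)), 1e-6)
  }
})

test_that("hahn_moments equal the brute-force double sum with oracle basis", {
  set.seed(23)
  for (n in c(7L, 20L)) {
    tilde <- oracle_hahn_tilde(n, maxord = 3)
    for (rep in 1:3) {
      g <- random_grid(n)
      hm <- hahn_moments(g)
      for (k in seq_len(nrow(MOMENT_ORDERS))) {
        ref <- oracle_hahn_moment(g, MOMENT_ORDERS[k, 1],
                                  MOMENT_ORDERS[k, 2], tilde)
        expect_equal(hm[[k]], ref,
                     tolerance = 1e-9 * max(1, abs(ref)))
      }
    }
  }
  expect_equal(unname(hahn_moments(matrix(0, 7, 7))), rep(0, 8))
})

test_that("all three families are sensitive to residue order", {
  set.seed(31)
  w <- encode_residue(random_window_string(41))
  # swap two positions holding different residues
  i <- 3L; j <- which(w != w[3])[1]
  w2 <- w; w2[i] <- w[j]; w2[j] <- w[i]
  g1 <- reshape_to_grid(w); g2 <- reshape_to_grid(w2)
  expect_false(isTRUE(all.equal(raw_moments(g1), raw_moments(g2))))
  expect_false(isTRUE(all.equal(hahn_moments(g1), hahn_moments(g2))))
})
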