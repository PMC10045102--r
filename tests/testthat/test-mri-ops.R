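# Linear operators: centered FFT, sampling masks, forward/adjoint pair,
# normalization, and the CG data-consistency solve.

test_that("centered orthonormal FFT is unitary and self-consistent", {
  set.seed(11)
  for (d in list(c(32L, 32L), c(16L, 48L), c(15L, 9L))) {
    x <- rand_cplx(d[1], d[2])
    expect_lt(max(Mod(ifft2c(fft2c(x)) - x)), 1e-12)
    expect_equal(sum(Mod(fft2c(x))^2), sum(Mod(x)^2), tolerance = 1e-12)
  }
})

test_that("mask honours line budget, ACS placement and determinism", {
  m <- make_mask(100, 4, 0.08, seed = 5)
  expect_equal(sum(m$pe_flags), 25)            # round(100 / 4)
  expect_equal(m$acs_width, 8L)                # round(0.08 * 100)
  expect_true(all(diff(m$acs_lines) == 1L))    # contiguous
  expect_true(all(m$pe_flags[m$acs_lines] == 1L))
  expect_lt(abs(mean(m$acs_lines) - 50.5), 1.01)  # centered
  expect_identical(m$pe_flags, make_mask(100, 4, 0.08, seed = 5)$pe_flags)
  expect_false(identical(m$pe_flags, make_mask(100, 4, 0.08, seed = 6)$pe_flags))
  expect_equal(sum(make_mask(64, 1, 0.08, seed = 1)$pe_flags), 64)
  expect_error(make_mask(100, 50, 0.25, seed = 1), "infeasible")
  # cardinality / ACS invariants across settings
  for (np in c(32L, 64L, 100L)) {
    for (R in c(2, 4)) {
      mm <- make_mask(np, R, 0.08, seed = np + R)
      expect_equal(sum(mm$pe_flags), round(np / R))
      expect_true(all(mm$pe_flags[mm$acs_lines] == 1L))
    }
  }
})

test_that("forward and adjoint satisfy the inner-product identity", {
  set.seed(21)
  maps <- gen_coil_maps(4, 32, 32, seed = 2)
  op <- forward_operator(maps, make_mask(32, 4, 0.08, seed = 3))
  for (i in 1:20) {
    u <- rand_cplx(32, 32)
    v <- array(rand_cplx(32 * 32 * 4), c(32, 32, 4))
    ip1 <- sum(Conj(v) * apply_A(u, op))
    ip2 <- sum(Conj(apply_AH(v, op)) * u)
    expect_lt(Mod(ip1 - ip2) / Mod(ip1), 1e-10)
  }
  expect_equal(max(Mod(apply_A(matrix(0i, 32, 32), op))), 0)
  expect_equal(max(Mod(apply_AH(array(0i, c(32, 32, 4)), op))), 0)
})

test_that("normal operator is Hermitian positive semidefinite (dense 8x8)", {
  maps <- gen_coil_maps(2, 8, 8, seed = 5)
  op <- forward_operator(maps, make_mask(8, 2, 0.25, seed = 6))
  M <- dense_gram(op)
  expect_lt(max(Mod(M - Conj(t(M)))), 1e-12)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
  # A^H A on a delta image equals the dense column
  e <- matrix(0i, 8, 8); e[19] <- 1
  expect_lt(max(Mod(as.vector(apply_AH(apply_A(e, op), op)) - M[, 19])), 1e-12)
})

test_that("single fully-sampled unit-magnitude coil makes A^H A the identity", {
  maps <- array(exp(1i * 0.7) + 0i, c(8, 8, 1))
  op <- forward_operator(maps, rep(1L, 8))
  set.seed(3)
  u <- rand_cplx(8, 8)
  expect_lt(max(Mod(apply_AH(apply_A(u, op), op) - u)), 1e-12)
  # and plain S = 1 gives the orthonormal FFT
  op1 <- forward_operator(array(1 + 0i, c(8, 8, 1)), rep(1L, 8))
  expect_lt(max(Mod(apply_A(u, op1)[, , 1] - fft2c(u))), 1e-12)
})

test_that("root-sum-of-squares combines coils pixelwise", {
  x <- array(0i, c(2, 2, 2))
  x[1, 1, ] <- c(3, 4)
  r <- rss(x)
  expect_equal(r[1, 1], 5)
  expect_true(all(r >= 0))
  one <- matrix(complex(real = -1, imaginary = 2), 2, 2)
  expect_equal(rss(one), Mod(one))
})

test_that("ACS normalization is homogeneous, idempotent, and matches full-ACS RSS", {
  s <- tiny_sample(seed = 31)
  nc <- acs_rss_norm(s$kspace, s$mask)
  expect_gt(nc, 0)
  expect_equal(acs_rss_norm(s$kspace * 3.7, s$mask), 3.7 * nc, tolerance = 1e-12)
  expect_equal(acs_rss_norm(s$kspace / nc, s$mask), 1, tolerance = 1e-12)
  # all-ACS "mask": equals the max of the direct RSS reconstruction
  full <- tiny_sample(seed = 32, accel_R = 1)
  imgs <- array(0i, dim(full$kspace))
  for (c in 1:dim(imgs)[3]) imgs[, , c] <- ifft2c(full$kspace[, , c])
  expect_equal(acs_rss_norm(full$kspace, seq_len(32)), max(rss(imgs)),
               tolerance = 1e-12)
  expect_error(acs_rss_norm(array(0i, c(8, 8, 1)), 3:6), "degenerate")
})

test_that("CG matches the closed form when A^H A is the identity", {
  maps <- array(exp(1i * 0.3) + 0i, c(8, 8, 1))
  op <- forward_operator(maps, rep(1L, 8))
  set.seed(41)
  u <- rand_cplx(8, 8)
  y <- apply_A(u, op)
  xn <- rand_cplx(8, 8)
  lam <- 0.3
  z <- cg_data_consistency(xn, y, op, lam, n_iter = 2)
  z_exact <- (apply_AH(y, op) + lam * xn) / (1 + lam)
  expect_lt(max(Mod(z - z_exact)), 1e-8)
})

test_that("CG matches a dense direct solve on an 8x8 two-coil R=2 system", {
  set.seed(43)
  for (trial in 1:3) {
    maps <- gen_coil_maps(2, 8, 8, seed = trial)
    op <- forward_operator(maps, make_mask(8, 2, 0.25, seed = trial + 10))
    M <- dense_gram(op)
    lam <- 0.1
    u <- rand_cplx(8, 8)
    xn <- rand_cplx(8, 8)
    y <- apply_A(u, op)
    rhs <- as.vector(apply_AH(y, op) + lam * xn)
    z_direct <- solve(M + lam * diag(64), rhs)
    z_cg <- as.vector(cg_data_consistency(xn, y, op, lam, n_iter = 64))
    expect_lt(sqrt(sum(Mod(z_cg - z_direct)^2)) / sqrt(sum(Mod(z_direct)^2)),
              1e-6)
  }
})

test_that("large lambda pins the CG solution to the current iterate", {
  s <- normalize_sample(tiny_sample(seed = 47))
  op <- forward_operator(s$sens_maps, s$mask)
  set.seed(48)
  xn <- rand_cplx(32, 32)
  z <- cg_data_consistency(xn, s$kspace, op, lam = 1e6, n_iter = 4)
  expect_lt(max(Mod(z - xn)) / max(Mod(xn)), 1e-3)
})

test_that("CG residual norm is non-increasing over iterations", {
  s <- normalize_sample(tiny_sample(seed = 49))
  op <- forward_operator(s$sens_maps, s$mask)
  lam <- 0.05
  xn <- apply_AH(s$kspace, op)
  rhs <- apply_AH(s$kspace, op) + lam * xn
  res <- sapply(1:8, function(k) {
    z <- cg_data_consistency(xn, s$kspace, op, lam, n_iter = k)
    r <- rhs - (apply_AH(apply_A(z, op), op) + lam * z)
    sqrt(sum(Mod(r)^2))
  })
  expect_true(all(diff(res) <= 1e-10))
  expect_error(cg_data_consistency(xn, s$kspace, op, -1, 4), "positive")
  expect_error(cg_data_consistency(xn, s$kspace, op, 0.05, 0), "n_iter")
})
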