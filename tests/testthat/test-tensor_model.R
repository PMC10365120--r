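test_that("design matrix rows follow the Stejskal-Tanner linearization", {
  gt <- gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  X <- build_design_matrix(gt)
  expect_equal(dim(X), c(2L, 7L))
  expect_equal(X[1, ], c(0, 0, 0, 0, 0, 0, 1))        # b = 0 frame
  expect_equal(X[2, ], c(-1000, 0, 0, 0, 0, 0, 1))    # b = 1000, g = x
  # the 64-direction scheme spans a full rank-7 design
  expect_identical(qr(build_design_matrix(default_gtab()))$rank, 7L)
})

test_that("noiseless signals from known tensors are recovered exactly", {
  gt <- default_gtab()
  # isotropic tensor
  A_iso <- diag(3) * 0.7e-3
  # prolate tensor aligned with x
  A_pro <- diag(c(1.7, 0.3, 0.3) * 1e-3)
  for (A in list(A_iso, A_pro)) {
    sig <- array(forward_signal(A, gt, s0 = 800),
                 dim = c(1L, 1L, 1L, length(gt)))
    dwi <- dwi_dataset(sig, diag(4), gt)
    tf <- fit_tensor(dwi)
    expect_lt(max(abs(tf$coeffs[1, 1, 1, ] - tensor_to_coeffs(A))), 1e-10)
    expect_lt(abs(tf$s0[1, 1, 1] - 800), 1e-6)
  }
  sig <- array(forward_signal(A_pro, gt), dim = c(1L, 1L, 1L, length(gt)))
  tf <- fit_tensor(dwi_dataset(sig, diag(4), gt))
  expect_lt(max(abs(sort(tf$eigvals[1, 1, 1, ], decreasing = TRUE) -
                      c(1.7, 0.3, 0.3) * 1e-3)), 1e-10)
  e1 <- tf$eigvecs[1, 1, 1, , 1]
  expect_lt(min(sum((e1 - c(1, 0, 0))^2), sum((e1 + c(1, 0, 0))^2)), 1e-12)
  maps <- compute_scalar_maps(tf)
  expect_equal(maps$fa[1, 1, 1], metric_oracle(A_pro)[["fa"]],
               tolerance = 1e-9)
})

test_that("random-tensor refits agree with the forward-simulation oracle", {
  gt <- default_gtab()
  set.seed(11)
  n <- 200L
  tensors <- replicate(n, random_spd_tensor(), simplify = FALSE)
  sig <- t(vapply(tensors, forward_signal, numeric(length(gt)), gtab = gt))
  dwi <- dwi_dataset(array(sig, dim = c(n, 1L, 1L, length(gt))), diag(4), gt)
  tf <- fit_tensor(dwi)
  C <- matrix(tf$coeffs, ncol = 6L)
  truth <- t(vapply(tensors, tensor_to_coeffs, numeric(6L)))
  rel <- max(abs(C - truth)) / max(abs(truth))
  expect_lt(rel, 1e-9)
  maps <- compute_scalar_maps(tf)
  om <- t(vapply(tensors, metric_oracle, numeric(4L)))
  expect_lt(max(abs(as.vector(maps$fa) - om[, "fa"])), 1e-12)
  expect_lt(max(abs(as.vector(maps$md) - om[, "md"])), 1e-12)
  expect_lt(max(abs(as.vector(maps$ad) - om[, "ad"])), 1e-12)
  expect_lt(max(abs(as.vector(maps$rd) - om[, "rd"])), 1e-12)
})

test_that("scalar map identities hold: FA limits, MD decomposition, rotation invariance", {
  # analytic limit cases via the eigen-pair constructor
  d <- 1e-3
  tf_iso <- manual_field(c(2L, 2L, 2L),
                         lam_fun = function(w) matrix(d, nrow(w), 3L))
  m <- compute_scalar_maps(tf_iso)
  expect_equal(as.vector(m$fa), rep(0, 8))
  expect_equal(as.vector(m$md), rep(d, 8))
  expect_equal(as.vector(m$ad), rep(d, 8))
  expect_equal(as.vector(m$rd), rep(d, 8))

  tf_rank1 <- manual_field(c(2L, 2L, 2L),
                           lam_fun = function(w)
                             matrix(c(d, 0, 0), nrow(w), 3L, byrow = TRUE))
  expect_equal(as.vector(compute_scalar_maps(tf_rank1)$fa), rep(1, 8))

  # zero tensor: FA defined as 0
  tf0 <- manual_field(c(2L, 2L, 2L),
                      lam_fun = function(w) matrix(0, nrow(w), 3L))
  expect_equal(as.vector(compute_scalar_maps(tf0)$fa), rep(0, 8))

  # MD == (AD + 2 RD) / 3 at machine precision on fitted noisy data
  gt <- default_gtab()
  A <- diag(c(1.5, 0.5, 0.2) * 1e-3)
  sig <- array(rep(forward_signal(A, gt, 500), each = 27) *
                 runif(27 * length(gt), 0.9, 1.1),
               dim = c(3L, 3L, 3L, length(gt)))
  maps <- compute_scalar_maps(fit_tensor(dwi_dataset(sig, diag(4), gt)))
  expect_lt(max(abs(maps$md - (maps$ad + 2 * maps$rd) / 3)), 1e-12)
  expect_true(all(maps$fa >= 0 & maps$fa <= 1))

  # FA is rotation invariant
  A <- diag(c(1.7, 0.3, 0.3) * 1e-3)
  fa0 <- metric_oracle(A)[["fa"]]
  set.seed(5)
  for (i in 1:10) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    Ar <- Q %*% A %*% t(Q)
    sig <- array(forward_signal(Ar, gt), dim = c(1L, 1L, 1L, length(gt)))
    m <- compute_scalar_maps(fit_tensor(dwi_dataset(sig, diag(4), gt)))
    expect_lt(abs(m$fa[1, 1, 1] - fa0), 1e-9)
  }
})

test_that("all-zero voxels give NaN, negative eigenvalues are clamped and counted", {
  gt <- default_gtab()
  A <- diag(c(1.7, 0.3, 0.3) * 1e-3)
  sig <- array(forward_signal(A, gt, 500), dim = c(1L, 2L, 1L, length(gt)))
  sig[1, 2, 1, ] <- 0
  tf <- fit_tensor(dwi_dataset(sig, diag(4), gt))
  expect_true(all(is.nan(tf$eigvals[1, 2, 1, ])))
  expect_false(anyNA(tf$eigvals[1, 1, 1, ]))

  # very noisy isotropic background produces clamped negative eigenvalues
  pf <- manual_field(c(8L, 8L, 8L),
                     lam_fun = function(w) matrix(0.1e-3, nrow(w), 3L))
  dwi <- simulate_dwi(pf, gt, s0 = 100, snr = 2, rng_seed = 3)
  tf <- fit_tensor(dwi)
  expect_gt(tf$n_clamped, 0L)
  maps <- compute_scalar_maps(tf)
  expect_true(all(maps$fa <= 1 + 1e-12, na.rm = TRUE))
  # rank-deficient design is fatal
  gt2 <- gradient_table(c(0, rep(1000, 6)),
                        rbind(0, matrix(rep(c(1, 0, 0), 6), ncol = 3,
                                        byrow = TRUE)))
  sig2 <- array(500, dim = c(1L, 1L, 1L, 7L))
  expect_error(fit_tensor(dwi_dataset(sig2, diag(4), gt2)),
               "design_rank_error")
})

test_that("tensor fits stay accurate under Rician noise at protocol SNR", {
  gt <- default_gtab()
  pf <- manual_field(c(6L, 6L, 6L))   # uniform prolate bundle-like block
  fa_true <- metric_oracle(diag(c(1.7, 0.3, 0.3) * 1e-3))[["fa"]]
  errs <- vapply(1:10, function(seed) {
    dwi <- simulate_dwi(pf, gt, s0 = 1000, snr = 30, rng_seed = seed)
    m <- compute_scalar_maps(fit_tensor(dwi))
    stats::median(abs(m$fa - fa_true))
  }, numeric(1L))
  expect_lt(stats::median(errs), 0.03)
})

test_that("fitted eigen-decompositions reconstruct the tensor and stay orthonormal", {
  gt <- default_gtab()
  set.seed(21)
  n <- 100L
  tensors <- replicate(n, random_spd_tensor(), simplify = FALSE)
  sig <- t(vapply(tensors, forward_signal, numeric(length(gt)), gtab = gt))
  dwi <- dwi_dataset(array(sig * runif(length(sig), 0.95, 1.05),
                           dim = c(n, 1L, 1L, length(gt))), diag(4), gt)
  tf <- fit_tensor(dwi)
  V <- matrix(tf$eigvecs, ncol = 9L)
  L <- matrix(tf$eigvals, ncol = 3L)
  C <- matrix(tf$coeffs, ncol = 6L)
  for (i in seq_len(n)) {
    Vi <- matrix(V[i, ], 3L, 3L)
    expect_lt(max(abs(crossprod(Vi) - diag(3))), 1e-6)
    R <- Vi %*% diag(L[i, ]) %*% t(Vi)
    # clamped eigenvalues may deviate; reconstruct with unclamped via oracle
    Ai <- matrix(C[i, c(1, 4, 5, 4, 2, 6, 5, 6, 3)], 3L)
    eo <- eigen(Ai, symmetric = TRUE)
    if (all(eo$values >= 0))
      expect_lt(max(abs(R - Ai)), 1e-9)
    expect_lt(max(abs(sort(pmax(eo$values, 0), decreasing = TRUE) -
                        L[i, ])), 1e-12)
  }
})
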