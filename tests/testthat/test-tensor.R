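test_that("predict_signal matches the monoexponential model", {
  sch <- test_scheme(12)
  # isotropic tensor: g' D g = 1e-3 for every unit g
  s <- predict_signal(diag(3) * 1e-3, sch, s0 = 100)
  expect_equal(s[1], 100)                               # b = 0 row
  expect_equal(s[-1], rep(100 * exp(-1), 12), tolerance = 1e-12)
  # single-direction hand evaluation: exp(-1000 * 1.7e-3)
  sch1 <- acquisition_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  s1 <- predict_signal(diag(c(1.7e-3, 0.3e-3, 0.3e-3)), sch1, s0 = 1)
  expect_equal(s1[2], 0.182683524053, tolerance = 1e-10)
})

test_that("predict_signal rejects non-symmetric tensors and bad s0", {
  sch <- test_scheme(8)
  D <- diag(3) * 1e-3; D[1, 2] <- 5e-4
  expect_error(predict_signal(D, sch), "symmetric")
  expect_error(predict_signal(diag(3) * 1e-3, sch, s0 = 0), "positive")
})

test_that("signal is monotone decreasing in b for positive-definite tensors", {
  g <- c(1, 2, 2) / 3
  bs <- c(0, 250, 500, 1000, 2000)
  sch <- acquisition_scheme(bs, rbind(c(0, 0, 0),
                                      matrix(rep(g, 4), 4, 3, byrow = TRUE)))
  set.seed(42)
  for (i in 1:5) {
    s <- predict_signal(random_spd_tensor(), sch, s0 = 10)
    expect_true(all(diff(s) < 0))
  }
})

test_that("noise-free tensor fits recover the generating tensor", {
  sch <- test_scheme(32)
  s <- predict_signal(diag(c(1.2e-3, 0.8e-3, 0.6e-3)), sch, s0 = 500)
  fit <- fit_tensor(s, sch)
  expect_true(fit$ok)
  expect_rel_equal(diag(fit$tensor), c(1.2e-3, 0.8e-3, 0.6e-3), 1e-10)
  expect_rel_equal(fit$s0, 500, 1e-10)
  # property: any SPD tensor, any fittable scheme
  set.seed(7)
  for (i in 1:20) {
    D <- random_spd_tensor()
    sch_i <- test_scheme(sample(c(7, 15, 32, 64), 1))
    fit_i <- fit_tensor(predict_signal(D, sch_i, s0 = 100), sch_i)
    expect_rel_equal(fit_i$tensor, D, 1e-10)
  }
})

test_that("fitting is rotation equivariant on noise-free data", {
  set.seed(11)
  D <- random_spd_tensor()
  sch <- test_scheme(32)
  s <- predict_signal(D, sch, s0 = 100)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  # claiming the gradients were R g while the signal came from g means the
  # fitted tensor must be R D R'
  sch_rot <- acquisition_scheme(sch$bvals, sch$bvecs %*% t(R))
  fit <- fit_tensor(s, sch_rot)
  expect_lt(max(abs(fit$tensor - R %*% D %*% t(R))), 1e-8 * max(abs(D)))
})

test_that("mean fitted Dxx is unbiased within 5% under Rician noise at SNR 30", {
  sch <- test_scheme(32)
  D <- diag(c(1.2e-3, 0.8e-3, 0.6e-3))
  s0 <- 500; sigma <- s0 / 30
  clean <- predict_signal(D, sch, s0 = s0)
  set.seed(123)
  dxx <- replicate(500, {
    noisy <- sqrt((clean + rnorm(length(clean), 0, sigma))^2 +
                    rnorm(length(clean), 0, sigma)^2)
    fit_tensor(noisy, sch)$tensor[1, 1]
  })
  expect_lt(abs(mean(dxx) - 1.2e-3) / 1.2e-3, 0.05)
})

test_that("degenerate signals are handled: drops, failures, zero tensors", {
  sch <- test_scheme(32)
  s <- predict_signal(diag(3) * 1e-3, sch, s0 = 100)
  s_bad <- s; s_bad[5] <- 0
  expect_warning(fit <- fit_tensor(s_bad, sch), "dropped")
  expect_true(fit$ok)
  expect_equal(fit$n_dropped, 1L)
  # all-equal signals with a matching b0: no attenuation, D ~ 0
  s_flat <- rep(100, sch$n_meas)
  fit0 <- fit_tensor(s_flat, sch)
  expect_lt(max(abs(fit0$tensor)), 1e-15)
  # too few usable measurements: flagged failure
  s_few <- s; s_few[-(1:5)] <- 0
  expect_warning(fit_fail <- fit_tensor(s_few, sch))
  expect_false(fit_fail$ok)
})

test_that("fit_volume fits voxel-wise and isolates degenerate voxels", {
  sch <- test_scheme(15)
  D <- diag(c(1.2e-3, 0.8e-3, 0.6e-3))
  s <- predict_signal(D, sch, s0 = 200)
  sig <- array(rep(s, each = 64), c(4, 4, 4, sch$n_meas))
  dwi <- dwi_volume(sig, sch)
  field <- fit_volume(dwi)
  expect_true(all(field$mask))
  for (v in list(c(1, 1, 1), c(3, 2, 4)))
    expect_rel_equal(tensor_at(field, v[1], v[2], v[3]), D, 1e-10)
  # one voxel of zeros is masked out, neighbours unaffected
  sig2 <- sig; sig2[2, 2, 2, ] <- 0
  expect_message(field2 <- fit_volume(dwi_volume(sig2, sch)), "1 voxel")
  expect_false(field2$mask[2, 2, 2])
  expect_equal(sum(field2$mask), 63L)
  expect_rel_equal(tensor_at(field2, 1, 2, 2), D, 1e-10)
  expect_error(fit_volume(dwi, mask = array(FALSE, c(4, 4, 4))), "empty mask")
})

test_that("NIfTI round trips preserve DWI volumes and tensor fields", {
  sch <- test_scheme(8)
  set.seed(5)
  sig <- array(runif(3 * 3 * 2 * sch$n_meas, 10, 100), c(3, 3, 2, sch$n_meas))
  dwi <- dwi_volume(sig, sch, voxel_size = c(2, 2, 2))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_dwi_nifti(dwi, f)
  back <- read_dwi_nifti(f, sch)
  expect_equal(back$signal, sig, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$voxel_size, c(2, 2, 2))
  ph <- generate_phantom(quick_phantom())
  tf <- withr::local_tempfile(fileext = ".nii.gz")
  write_tensor_nifti(ph$truth, tf)
  truth2 <- read_tensor_nifti(tf)
  expect_equal(truth2$D, ph$truth$D, tolerance = 1e-6, ignore_attr = TRUE)
})
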