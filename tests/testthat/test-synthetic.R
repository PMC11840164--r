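test_that("phantom generation is deterministic under a fixed seed", {
  a <- generate_phantom(quick_phantom(noise = "rician", seed = 42))
  b <- generate_phantom(quick_phantom(noise = "rician", seed = 42))
  expect_identical(a$dwi$signal, b$dwi$signal)
  expect_identical(a$truth$D, b$truth$D)
  d <- generate_phantom(quick_phantom(noise = "rician", seed = 43))
  expect_false(identical(a$dwi$signal, d$dwi$signal))
})

test_that("the phantom pipeline matches the closed-form ALPS ground truth", {
  # g = 0: no perivascular component, index 1
  ph0 <- generate_phantom(quick_phantom(g = 0))
  f0 <- fit_volume(ph0$dwi)
  expect_equal(compute_subject_alps(f0, ph0$rois)$alps_mean, 1.0,
               tolerance = 1e-8)
  # g = 0.2e-3 with radial 0.4e-3: index 1.5
  ph <- generate_phantom(quick_phantom(g = 0.2e-3))
  f <- fit_volume(ph$dwi)
  res <- compute_subject_alps(f, ph$rois)
  expect_equal(res$alps_mean, 1.5, tolerance = 1e-8)
  expect_equal(unname(alps_ground_truth(ph$spec)["mean"]), 1.5)
  # ground truth does not depend on the axial diffusivity
  ph2 <- generate_phantom(quick_phantom(g = 0.2e-3, axial = 1.8e-3))
  f2 <- fit_volume(ph2$dwi)
  expect_equal(compute_subject_alps(f2, ph2$rois)$alps_mean, 1.5,
               tolerance = 1e-8)
})

test_that("ALPS is strictly increasing in the perivascular parameter g", {
  gs <- seq(0, 0.4e-3, length.out = 5)
  alps <- vapply(gs, function(g) {
    ph <- generate_phantom(quick_phantom(g = g))
    compute_subject_alps(fit_volume(ph$dwi), ph$rois)$alps_mean
  }, 1)
  expect_true(all(diff(alps) > 0))
  expect_equal(alps, (gs + 0.4e-3) / 0.4e-3, tolerance = 1e-8)
})

test_that("noisy phantoms recover the printed group indices within 2%", {
  for (target in c(1.45, 1.64)) {
    means <- vapply(1:25, function(i) {
      sp <- quick_phantom(g = g_for_alps(target), noise = "rician",
                          seed = 1000L + i)
      ph <- generate_phantom(sp)
      field <- suppressMessages(fit_volume(ph$dwi))
      compute_subject_alps(field, ph$rois)$alps_mean
    }, 1)
    expect_lt(abs(mean(means) - target) / target, 0.02)
  }
})

test_that("cohort generation is deterministic and byte-identical on disk", {
  co1 <- generate_cohort(cohort_spec(seed = 7))
  co2 <- generate_cohort(cohort_spec(seed = 7))
  expect_identical(co1, co2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co1, f1)
  write_cohort(co2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  t1 <- sub("\\.csv$", "_truth.json", f1)
  expect_true(file.exists(t1))
  truth <- jsonlite::read_json(t1)
  expect_named(truth, c("a", "b", "c_prime", "c_total", "indirect",
                        "prop_mediated", "seed"), ignore.order = TRUE)
})

test_that("generated ALPS margins converge to the spec at large n", {
  spec <- cohort_spec(n_pd = 10000, n_nc = 10000, seed = 21)
  co <- generate_cohort(spec)
  pd <- co[co$group == "PD", ]; nc <- co[co$group == "NC", ]
  expect_lt(abs(mean(pd$alps_l) - 1.46) / 1.46, 0.01)
  expect_lt(abs(mean(pd$alps_r) - 1.44) / 1.44, 0.01)
  expect_lt(abs(mean(nc$alps_m) - 1.64) / 1.64, 0.01)
  expect_lt(abs(sd(pd$alps_l) - 0.19) / 0.19, 0.05)
  # the left/right correlation is tuned so the hemispheric mean has SD 0.17
  expect_lt(abs(sd(pd$alps_m) - 0.17) / 0.17, 0.05)
  expect_lt(abs(sd(nc$alps_m) - 0.17) / 0.17, 0.05)
  # MMSE margin of the patient group
  expect_lt(abs(mean(pd$mmse) - 23.9), 0.5)
  expect_lt(abs(sd(pd$mmse) - 4.38), 0.4)
})

test_that("ground-truth mediation metadata tracks the generating paths", {
  regions <- default_region_table()
  # no indirect path: proportion mediated 0 everywhere
  r0 <- regions; r0$a <- 0
  t0 <- attr(generate_cohort(cohort_spec(regions = r0, c_prime = 5, seed = 1)),
             "ground_truth")
  expect_true(all(t0$prop_mediated == 0))
  expect_equal(t0$c_total, 5)
  # full mediation through a single region
  r1 <- regions; r1$a <- 0; r1$b <- 0
  r1$a[r1$region == "anterior_cingulate"] <- 2
  r1$b[r1$region == "anterior_cingulate"] <- 3
  t1 <- attr(generate_cohort(cohort_spec(regions = r1, c_prime = 0,
                                         mmse_pd = c(23.9, 7), seed = 1)),
             "ground_truth")
  expect_equal(unname(t1$prop_mediated["anterior_cingulate"]), 100)
  expect_equal(t1$c_total, 6)
  # defaults encode the two published mediated percentages as ground truth
  td <- attr(generate_cohort(cohort_spec(seed = 1)), "ground_truth")
  expect_equal(unname(td$prop_mediated["anterior_cingulate"]), 17.49,
               tolerance = 1e-10)
  expect_equal(unname(td$prop_mediated["orbital_inf_frontal"]), 32.24,
               tolerance = 1e-10)
})

test_that("infeasible variance splits and heavy clamping are reported", {
  bad <- default_region_table()
  bad$a[1] <- 50  # a^2 Var(x) > sd^2
  expect_error(generate_cohort(cohort_spec(regions = bad, seed = 1)),
               "volume variance")
  expect_warning(
    generate_cohort(cohort_spec(mmse_pd = c(29.5, 4.38), seed = 1)),
    "clamped")
})
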