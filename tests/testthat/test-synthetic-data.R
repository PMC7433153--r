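# Phantom and cohort generators: forward model, geometry validation,
# truncated-normal cohort draws.

test_that("forward model: no iodine means identical channels, iodine separates them linearly", {
  spec0 <- phantom_spec(iodine_mgml = list(liver = 0, tumor = 0, aorta = 0,
                                           rim_increment = 0))
  ph0 <- generate_phantom(spec0)
  expect_identical(ph0$study$low_kv, ph0$study$high_kv)

  fx <- noiseless_phantom()
  # aorta carries 10 mg/mL; (s_low - s_high) * 10 = (48 - 15) * 10 = 330
  diff <- fx$ph$study$low_kv - fx$ph$study$high_kv
  expect_equal(unique(round(diff[fx$ph$masks$aorta], 9)), 330)
})

test_that("masks are exact rasterizations and geometry is validated", {
  fx <- noiseless_phantom()
  expect_true(all(fx$ph$masks$tumor <= fx$ph$masks$liver))
  expect_false(any(fx$ph$masks$aorta & fx$ph$masks$liver))
  # tumor poking out of the liver is a geometry error
  bad <- phantom_spec(tumor_center = c(50, 32, 32))
  expect_error(generate_phantom(bad), class = "dectpeel_geometry_error")
  expect_error(phantom_spec(spacing = c(1, 0, 1)),
               class = "dectpeel_validation_error")
  expect_error(phantom_spec(iodine_mgml = list(liver = -1, tumor = 2.5,
                                               aorta = 10,
                                               rim_increment = 0.5)),
               class = "dectpeel_validation_error")
  expect_error(phantom_spec(rim_present = TRUE, rim_thickness_mm = 0),
               class = "dectpeel_validation_error")
})

test_that("peritumoral rim raises ground-truth iodine in the 0-2 mm band only", {
  ph <- generate_phantom(phantom_spec(rim_present = TRUE,
                                      rim_thickness_mm = 2))
  # probe with the independent center-to-center EDT, staying a safe margin
  # inside the nominal 2-mm band so the sub-voxel boundary convention does
  # not matter at the band edge
  d <- distance_transform(ph$masks$tumor, c(1, 1, 1))
  band <- !ph$masks$tumor & ph$masks$liver & d <= 1.5
  distant <- ph$masks$liver & d > 6
  expect_true(min(ph$iodine_truth[band]) > max(ph$iodine_truth[distant]))
  expect_equal(min(ph$iodine_truth[band]), 0.7 + 0.5)  # liver + increment
})

test_that("phantom with noise is reproducible under its seed", {
  spec <- phantom_spec(noise_sd = 8, seed = 42)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$study$low_kv, b$study$low_kv)
  c_ <- generate_phantom(phantom_spec(noise_sd = 8, seed = 43))
  expect_false(identical(a$study$low_kv, c_$study$low_kv))
})

test_that("cohort draws match group means, respect seeds, and degenerate correctly", {
  # large-replicate group means approach the specified means
  feats <- default_nic_features <- data.frame(
    feature = "nic_outer1_2mm", mean_neg = 0.07, sd_neg = 0.03,
    mean_pos = 0.10, sd_pos = 0.03)
  big <- cohort_spec(n_neg = 20000L, n_pos = 20000L, features = feats,
                     seed = 5L)
  co <- generate_cohort(big)
  expect_within(mean(co$nic_outer1_2mm[co$mvi == 0]), 0.07, 0.005)
  expect_within(mean(co$nic_outer1_2mm[co$mvi == 1]), 0.10, 0.005)
  expect_true(all(co$nic_outer1_2mm >= 0))

  # same seed, same table; different seed differs
  s <- cohort_spec(seed = 9L)
  expect_identical(generate_cohort(s), generate_cohort(s))
  expect_false(identical(generate_cohort(s),
                         generate_cohort(cohort_spec(seed = 10L))))

  # SD -> 0 limit: every draw equals the mean
  tiny <- cohort_spec(features = data.frame(
    feature = "f", mean_neg = 0.07, sd_neg = 1e-12,
    mean_pos = 0.10, sd_pos = 1e-12), seed = 1L)
  co2 <- generate_cohort(tiny)
  expect_equal(co2$f, ifelse(co2$mvi == 1, 0.10, 0.07), tolerance = 1e-6)

  expect_error(cohort_spec(features = data.frame(
    feature = "f", mean_neg = 0.07, sd_neg = 0,
    mean_pos = 0.10, sd_pos = 0.03)), class = "dectpeel_validation_error")
  expect_error(cohort_spec(n_neg = 1L), class = "dectpeel_validation_error")
})

test_that("shared patient effect induces within-patient feature correlation", {
  s <- cohort_spec(n_neg = 400L, n_pos = 400L, patient_effect = 0.8,
                   seed = 2L)
  co <- generate_cohort(s)
  r <- cor(co$nic_outer1_2mm[co$mvi == 0], co$nic_outer2_2mm[co$mvi == 0])
  expect_gt(r, 0.5)
  s0 <- cohort_spec(n_neg = 400L, n_pos = 400L, seed = 2L)
  co0 <- generate_cohort(s0)
  r0 <- cor(co0$nic_outer1_2mm[co0$mvi == 0],
            co0$nic_outer2_2mm[co0$mvi == 0])
  expect_lt(abs(r0), 0.15)
})

test_that("qualitative reader scores are generated at the requested rates", {
  qual <- data.frame(feature = "peritumoral_enhancement",
                     p_neg = 8 / 22, p_pos = 9 / 14)
  s <- cohort_spec(n_neg = 5000L, n_pos = 5000L, qualitative = qual,
                   seed = 4L)
  co <- generate_cohort(s)
  expect_within(mean(co$peritumoral_enhancement[co$mvi == 0]), 8 / 22, 0.02)
  expect_within(mean(co$peritumoral_enhancement[co$mvi == 1]), 9 / 14, 0.02)
})
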