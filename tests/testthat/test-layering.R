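# Distance-banded layer peeling: analytic shells, set-algebra invariants,
# exclusions, thickness scaling, isotropy.

shell_vol <- function(r1, r2) 4 / 3 * pi * (r2^3 - r1^3)

test_that("sphere bands reproduce analytic shell volumes within voxelization tolerance", {
  sp <- sphere_mask(10, spacing = c(0.5, 0.5, 0.5))
  liver <- array(TRUE, dim(sp$mask))
  rs <- peel_layers(sp$mask, liver, NULL, sp$spacing, layer_config(2))
  vox <- prod(sp$spacing)
  v_out1 <- sum(rs$outer$outer1) * vox
  v_in1 <- sum(rs$inner$inner1) * vox
  expect_within(v_out1, shell_vol(10, 12), 0.03 * shell_vol(10, 12))
  expect_within(v_in1, shell_vol(8, 10), 0.03 * shell_vol(8, 10))
})

test_that("regions obey nesting, disjointness and exact partition algebra", {
  sp <- sphere_mask(8, spacing = c(1, 1, 1))
  liver <- array(TRUE, dim(sp$mask))
  rs <- peel_layers(sp$mask, liver, NULL, sp$spacing, layer_config(2))

  # nesting: voi_o2 >= voi_o1 >= tumor >= voi_i1 >= voi_i2
  expect_true(all(rs$voi_o1 <= rs$voi_o2))
  expect_true(all(rs$tumor <= rs$voi_o1))
  expect_true(all(rs$voi_i1 <= rs$tumor))
  expect_true(all(rs$voi_i2 <= rs$voi_i1))
  # outer layers pairwise disjoint and disjoint from tumor
  expect_false(any(rs$outer$outer1 & rs$outer$outer2))
  expect_false(any((rs$outer$outer1 | rs$outer$outer2) & rs$tumor))
  # inner layers disjoint subsets of tumor
  expect_false(any(rs$inner$inner1 & rs$inner$inner2))
  expect_true(all((rs$inner$inner1 | rs$inner$inner2) <= rs$tumor))
  # exact reconstructions
  expect_identical(rs$tumor, rs$voi_i1 | rs$inner$inner1)
  expect_identical(rs$tumor, rs$voi_i2 | rs$inner$inner1 | rs$inner$inner2)
  expect_identical(rs$voi_o2, rs$tumor | rs$outer$outer1 | rs$outer$outer2)
})

test_that("small tumor exhausts its interior: voi_i2 empty and recorded", {
  sp <- sphere_mask(3, spacing = c(0.5, 0.5, 0.5))
  liver <- array(TRUE, dim(sp$mask))
  rs <- peel_layers(sp$mask, liver, NULL, sp$spacing, layer_config(2))
  expect_true("voi_i2" %in% rs$empty_regions)
  expect_false(any(rs$voi_i2))
  # ... and empty regions surface as missing statistics, never zeros
  io <- array(1, dim(sp$mask))
  s <- region_stats(rs$voi_i2, io, io, 10, region_name = "voi_i2")
  expect_true(s$missing)
  expect_true(is.na(s$nic))
})

test_that("exclusion masks and the liver boundary clip outer layers only", {
  sp <- sphere_mask(6, spacing = c(1, 1, 1))
  liver <- array(TRUE, dim(sp$mask))
  excl <- array(TRUE, dim(sp$mask))  # exclude everything outside the tumor
  rs <- peel_layers(sp$mask, liver, excl, sp$spacing, layer_config(2))
  expect_true(all(c("outer1", "outer2") %in% rs$empty_regions))
  expect_false(any(rs$outer$outer1))
  # inner layers are untouched by exclusions
  expect_gt(sum(rs$inner$inner1), 0)
  expect_error(peel_layers(array(FALSE, dim(sp$mask)), liver, NULL,
                           sp$spacing),
               class = "dectpeel_empty_region")
})

test_that("doubling the thickness merges consecutive bands", {
  sp <- sphere_mask(8, spacing = c(0.5, 0.5, 0.5))
  liver <- array(TRUE, dim(sp$mask))
  rs2 <- peel_layers(sp$mask, liver, NULL, sp$spacing, layer_config(2))
  rs4 <- peel_layers(sp$mask, liver, NULL, sp$spacing, layer_config(4))
  expect_identical(rs4$outer$outer1, rs2$outer$outer1 | rs2$outer$outer2)
  expect_identical(rs4$inner$inner1, rs2$inner$inner1 | rs2$inner$inner2)
})

test_that("band volumes are isotropic under axis permutation and anisotropic spacing", {
  sp <- sphere_mask(8, spacing = c(1, 1, 1))
  liver <- array(TRUE, dim(sp$mask))
  v1 <- sum(peel_layers(sp$mask, liver, NULL, sp$spacing,
                        layer_config(2))$outer$outer1)
  perm <- aperm(sp$mask, c(3, 1, 2))
  v2 <- sum(peel_layers(perm, aperm(liver, c(3, 1, 2)), NULL, sp$spacing,
                        layer_config(2))$outer$outer1)
  expect_within(v2, v1, 0.03 * v1)

  # anisotropic grid, same physical sphere, spacings resolvable against the
  # band width (<= t/2): regression bound on the discretization error,
  # dominated by the smoothing scale of the coarsest axis
  spa <- sphere_mask(8, spacing = c(0.5, 0.75, 1))
  va <- sum(peel_layers(spa$mask, array(TRUE, dim(spa$mask)), NULL,
                        spa$spacing, layer_config(2))$outer$outer1) *
    prod(spa$spacing)
  expect_within(va, shell_vol(8, 10), 0.06 * shell_vol(8, 10))
})
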