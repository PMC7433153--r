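# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# default noiseless phantom + decomposition, cached
noiseless_phantom <- function() {
  if (is.null(.fixtures$noiseless)) {
    ph <- generate_phantom(phantom_spec())
    maps <- decompose_iodine(ph$study)
    .fixtures$noiseless <- list(ph = ph, maps = maps)
  }
  .fixtures$noiseless
}

# rasterized sphere mask of given radius (mm) centered in a cube
sphere_mask <- function(radius_mm, spacing = c(0.5, 0.5, 0.5),
                        margin_mm = 5) {
  half <- radius_mm + margin_mm
  n <- as.integer(round(2 * half / spacing)) + 1L
  g <- dectpeel:::voxel_grid_mm(n, spacing)
  ctr <- (n - 1) * spacing / 2
  r2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
  list(mask = r2 <= radius_mm^2, spacing = spacing, center = ctr, n = n)
}

expect_within <- function(value, target, tol) {
  expect_true(abs(value - target) <= tol,
              label = sprintf("%.6g within %.3g of %.6g", value, tol,
                              target))
}

# hand-computed tie-half-credit U statistic (independent of roc_auc)
u_statistic <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  sum(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}
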