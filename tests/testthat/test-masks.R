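# Coded-mask generation and the snapshot forward model.

test_that("generated masks are binary, seeded, and match the requested density", {
  ms <- generate_masks(3, 256, 256, seed = 7, density = 0.5)
  expect_true(all(ms$masks %in% c(0, 1)))
  # binomial 4-sigma band: 0.5 +/- 4 * sqrt(0.25 / 65536)
  fracs <- apply(ms$masks, 3, mean)
  expect_true(all(fracs >= 0.494 & fracs <= 0.506))
  # bit-identical regeneration under the same seed
  expect_identical(ms$masks, generate_masks(3, 256, 256, seed = 7)$masks)
  # different seed, different masks
  expect_false(identical(ms$masks, generate_masks(3, 256, 256, seed = 8)$masks))
  # plane-level counter seeding: plane b does not depend on how many planes
  # were drawn before it
  ms2 <- generate_masks(2, 256, 256, seed = 7)
  expect_identical(ms$masks[, , 1:2], ms2$masks)
})

test_that("degenerate and invalid mask parameters behave as declared", {
  expect_true(all(all_ones_masks(1, 2, 2)$masks == 1))
  expect_error(generate_masks(0, 4, 4), class = "tcs_dimension_error")
  expect_error(generate_masks(2, -1, 4), class = "tcs_dimension_error")
  expect_error(generate_masks(2, 4, 4, density = 0), class = "tcs_parameter_error")
  expect_error(generate_masks(2, 4, 4, density = 1.2), class = "tcs_parameter_error")
})

test_that("guarantee_coverage removes zero-coverage pixels deterministically", {
  # B = 2 at density 0.5 leaves ~25% of pixels uncovered
  ms <- generate_masks(2, 32, 32, seed = 5)
  expect_gt(sum(mask_coverage(ms) == 0), 0)
  msg <- generate_masks(2, 32, 32, seed = 5, guarantee_coverage = TRUE)
  expect_true(all(mask_coverage(msg) >= 1))
  expect_identical(msg$masks,
                   generate_masks(2, 32, 32, seed = 5,
                                  guarantee_coverage = TRUE)$masks)
})

test_that("encode reproduces the hand-worked example and the identity code", {
  ex <- worked_example()
  m <- encode(ex$video, ex$masks)
  expect_equal(m$y, ex$Y)
  expect_equal(m$b_used, 2L)
  expect_equal(m$mask_seed, 7L)
  # B = 1 all-ones code is the identity
  X <- matrix(runif(12, 0, 255), 3, 4)
  m1 <- encode(tcs_video(array(X, c(3, 4, 1))), all_ones_masks(1, 3, 4))
  expect_equal(m1$y, X)
  expect_error(encode(ex$video, all_ones_masks(2, 3, 3)),
               class = "tcs_dimension_error")
})

test_that("encode is linear in the video argument", {
  set.seed(11)
  masks <- generate_masks(4, 6, 6, seed = 2)
  for (rep in 1:5) {
    U <- array(runif(6 * 6 * 4, 0, 100), c(6, 6, 4))
    V <- array(runif(6 * 6 * 4, 0, 100), c(6, 6, 4))
    a <- runif(1, 0.1, 3); b <- runif(1, 0.1, 3)
    lhs <- encode(tcs_video(a * U + b * V), masks)$y
    rhs <- a * encode(tcs_video(U), masks)$y + b * encode(tcs_video(V), masks)$y
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("measurement range and payload-size contracts hold", {
  set.seed(4)
  B <- 5
  masks <- generate_masks(B, 16, 16, seed = 3)
  video <- tcs_video(array(runif(16 * 16 * B, 0, 255), c(16, 16, B)), 255)
  m <- encode(video, masks)
  expect_true(all(m$y >= 0 & m$y <= B * 255))
  expect_equal(dim(m$y), c(16L, 16L))  # one frame regardless of B
})

test_that("normalization matches the hand oracle and flags zero coverage", {
  ex <- worked_example()
  m <- encode(ex$video, ex$masks)
  nm <- normalize_measurement(m, ex$masks)
  expect_equal(nm$ybar, ex$Ybar)
  expect_false(any(nm$zero_coverage))

  # constant-scene fixed point at covered pixels
  masks <- generate_masks(4, 12, 12, seed = 9, guarantee_coverage = TRUE)
  const <- tcs_video(array(37, c(12, 12, 4)))
  nmc <- normalize_measurement(encode(const, masks), masks)
  expect_equal(nmc$ybar, matrix(37, 12, 12))

  # all-zero coverage at one pixel -> flagged and zeroed
  mk <- tcsem:::new_tcs_masks(array(1, c(2, 2, 2)), 1L, 0.5)
  mk$masks[1, 1, ] <- 0
  mz <- encode(tcs_video(array(10, c(2, 2, 2))), mk)
  expect_warning(nmz <- normalize_measurement(mz, mk), "zero mask coverage")
  expect_true(nmz$zero_coverage[1, 1])
  expect_equal(nmz$ybar[1, 1], 0)
  expect_equal(nmz$ybar[2, 2], 10)
})

test_that("ybar is bracketed by the per-pixel frame range at covered pixels", {
  set.seed(21)
  masks <- generate_masks(4, 10, 10, seed = 6, guarantee_coverage = TRUE)
  frames <- array(runif(400, 0, 255), c(10, 10, 4))
  nm <- normalize_measurement(encode(tcs_video(frames), masks), masks)
  lo <- apply(frames, c(1, 2), min)
  hi <- apply(frames, c(1, 2), max)
  expect_true(all(nm$ybar >= lo - 1e-9 & nm$ybar <= hi + 1e-9))
  expect_true(all(nm$ybar <= 255 + 1e-9))
})

test_that("normalize refuses measurements from a different mask set", {
  ex <- worked_example()
  m <- encode(ex$video, ex$masks)
  other <- generate_masks(2, 2, 2, seed = 99)
  expect_error(normalize_measurement(m, other), class = "tcs_provenance_error")
  m$b_used <- 3L
  expect_error(normalize_measurement(m, ex$masks), class = "tcs_provenance_error")
})

test_that("approximate coded frames match the hand oracle and edge cases", {
  ex <- worked_example()
  m <- encode(ex$video, ex$masks)
  nm <- normalize_measurement(m, ex$masks)
  cf <- approx_coded_frames(nm, ex$masks)
  expect_equal(cf[, , 1], matrix(c(1, 5, 0, 4), 2, 2))
  expect_equal(cf[, , 2], matrix(c(0, 5, 6, 0), 2, 2))

  # constant scene with full coverage: equals the true coded frames
  masks <- generate_masks(3, 8, 8, seed = 2, guarantee_coverage = TRUE)
  const <- tcs_video(array(12, c(8, 8, 3)))
  nmc <- normalize_measurement(encode(const, masks), masks)
  cfc <- approx_coded_frames(nmc, masks)
  for (b in 1:3) expect_equal(cfc[, , b], 12 * masks$masks[, , b])

  # all-zero ybar -> all outputs zero
  nmz <- nmc; nmz$ybar[] <- 0
  expect_true(all(approx_coded_frames(nmz, masks) == 0))
})

test_that("video blocks validate their invariants", {
  expect_error(tcs_video(array(-1, c(2, 2, 1))), class = "tcs_parameter_error")
  expect_error(tcs_video(array(NaN, c(2, 2, 1))), class = "tcs_parameter_error")
  expect_error(tcs_video(array(1, c(2, 2, 0))), class = "tcs_dimension_error")
  v <- tcs_video(matrix(1, 3, 3))
  expect_equal(v$B, 1L)
})
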