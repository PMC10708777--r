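test_that("TAR-TES reproduces the hand-worked recursions", {
  S <- column_volume(c(1, 1, 2), kind = "structural")
  A <- column_volume(c(4, 3, 5))
  got <- tartes_correct(A, S, w1 = 0.5)
  # layer1: 3 - 0.5*1*sqrt(16) = 1; layer2: 5 - 0.5*2*sqrt(16 + 1) = 5 - sqrt(17)
  expect_equal(as.vector(got), c(4, 1, 5 - sqrt(17)), tolerance = 1e-12)
  expect_equal(attr(got, "correction")$clipped_voxels, 0L)

  # clipping: 1 - 1*5*sqrt(4) = -9 -> 0, and the zero feeds the accumulator
  S2 <- column_volume(c(1, 5), kind = "structural")
  A2 <- column_volume(c(2, 1))
  got2 <- tartes_correct(A2, S2, w1 = 1)
  expect_equal(as.vector(got2), c(2, 0), tolerance = 1e-12)
  expect_equal(attr(got2, "correction")$clipped_voxels, 1L)

  clip3 <- tartes_correct(column_volume(c(2, 1, 3)),
                          column_volume(c(1, 5, 0.1), kind = "structural"), w1 = 1)
  # layer2 accumulator must hold (2, 0), not (2, -9): 3 - 0.1*sqrt(4) = 2.8
  expect_equal(as.vector(clip3), c(2, 0, 2.8), tolerance = 1e-12)
})

test_that("TAR-TES validates inputs", {
  A <- column_volume(c(1, 2))
  S <- column_volume(c(1, 2), kind = "structural")
  expect_error(tartes_correct(A, S, -0.1), "non-negative")
  S_bad <- oct_volume(array(1, c(2, 1, 1)), c(9, 2.3, 2.2))
  expect_error(tartes_correct(A, S_bad, 0.1), "grid")
  expect_error(tartes_correct(A, column_volume(1, kind = "structural"), 0.1), "grid")
})

test_that("full transmittance form reduces to the simplified form at T = 1", {
  A <- random_volume(21, d = c(16L, 6L, 6L))
  S <- random_volume(22, d = c(16L, 6L, 6L), kind = "structural", scale = 0.3)
  simple <- tartes_correct(A, S, 0.3)
  full <- tartes_correct_full(A, S, 0.3, rep(1, 16))
  expect_identical(vals(simple), vals(full))  # bit-for-bit

  # hand recursion with T = (1, 0.5): 3 - 0.5*(1/0.5)*sqrt(16/1) = -1 -> 0
  Sf <- column_volume(c(1, 1), kind = "structural")
  Af <- column_volume(c(4, 3))
  expect_equal(as.vector(tartes_correct_full(Af, Sf, 0.5, c(1, 0.5))), c(4, 0))
  expect_error(tartes_correct_full(Af, Sf, 0.5, c(1, 0)), "\\(0, 1\\]")
  expect_error(tartes_correct_full(Af, Sf, 0.5, c(1, 1, 1)), "per-layer")
})

test_that("lower transmittance strictly increases the subtracted term", {
  A <- random_volume(31, d = c(12L, 4L, 4L), scale = 1)
  S <- random_volume(32, d = c(12L, 4L, 4L), kind = "structural", scale = 0.2)
  base <- tartes_correct_full(A, S, 0.2, rep(1, 12))
  halved <- tartes_correct_full(A, S, 0.2, c(1, rep(0.5, 11)))
  expect_true(all(vals(halved) <= vals(base) + 1e-12))
  # strict wherever the accumulator was positive and no clipping floor is hit
  deeper <- vals(base)[-1, , ] > 0
  expect_true(all(vals(halved)[-1, , ][deeper] < vals(base)[-1, , ][deeper]))
})

test_that("transmittance estimation follows the layer recursion and clamps", {
  S0 <- oct_volume(array(0, c(5, 2, 2)), PITCH, kind = "structural")
  expect_true(all(estimate_transmittance(S0, 0.1) == 1))

  S <- column_volume(c(2, 3, 1), kind = "structural")
  T <- estimate_transmittance(S, 0.1)
  t1 <- 1 - 0.1 * 2 / 1
  t2 <- t1 - 0.1 * 3 / t1
  expect_equal(as.vector(T), c(1, t1, t2), tolerance = 1e-12)
  expect_true(all(diff(as.vector(T)) <= 0))  # non-increasing for S >= 0

  expect_warning(Tc <- estimate_transmittance(column_volume(c(20, 1), kind = "structural"), 0.1),
                 "clamped")
  expect_equal(as.vector(Tc)[2], 1e-3)
  expect_error(estimate_transmittance(S, 0), "positive")
})

test_that("mean subtraction uses the uncorrected column mean with clipping", {
  expect_equal(as.vector(mean_subtract_correct(column_volume(c(4, 0, 2)), 3)),
               c(0, 0, 0))
  # constant column, w2 = 1: a - a = 0
  expect_equal(as.vector(mean_subtract_correct(column_volume(c(7, 7, 7)), 1)),
               c(0, 0, 0))
  # w2 < 1 keeps shape: baseline is the same for every layer of the column
  got <- mean_subtract_correct(column_volume(c(4, 0, 2)), 0.5)
  expect_equal(as.vector(got), c(3, 0, 1))
  expect_equal(attr(got, "correction")$clipped_voxels, 1L)
})

test_that("SDEF attenuates by the exponential of corrected shallower signal", {
  expect_equal(as.vector(sdef_correct(column_volume(c(2, 3)), 0.5)),
               c(2, 3 * exp(-1)), tolerance = 1e-12)
  expect_equal(as.vector(sdef_correct(column_volume(c(0, 0, 0)), 2)), c(0, 0, 0))
  # three layers: the accumulator uses corrected, not raw, values
  got <- as.vector(sdef_correct(column_volume(c(2, 3, 1)), 0.5))
  a2 <- 3 * exp(-0.5 * 2)
  expect_equal(got, c(2, a2, 1 * exp(-0.5 * (2 + a2))), tolerance = 1e-12)
  # strictly positive wherever input is positive
  v <- random_volume(41, d = c(20L, 4L, 4L))
  out <- sdef_correct(v, 5)
  expect_true(all(vals(out)[vals(v) > 0] > 0))
})

test_that("linearized SDEF matches its hand recursion and clips", {
  expect_equal(as.vector(sdef_linearized(column_volume(c(2, 3)), 0.5)), c(2, 0))
  expect_equal(as.vector(sdef_linearized(column_volume(c(2, 3)), 0.1)),
               c(2, 3 * 0.8), tolerance = 1e-12)
})

test_that("linearized SDEF converges quadratically to the exact form", {
  v <- random_volume(51, d = c(16L, 6L, 6L))
  gap <- vapply(c(1e-2, 1e-3, 1e-4), function(w3) {
    exact <- vals(sdef_correct(v, w3))
    lin <- vals(sdef_linearized(v, w3))
    max(abs(exact - lin) / pmax(exact, 1e-300))
  }, numeric(1L))
  # each 10x drop in w3 shrinks the max relative gap ~100x
  expect_gt(gap[1] / gap[2], 50)
  expect_lt(gap[1] / gap[2], 200)
  expect_gt(gap[2] / gap[3], 50)
  expect_lt(gap[2] / gap[3], 200)
})

test_that("streaming correctors agree with naive prefix re-summation", {
  for (seed in 1:10) {
    A <- random_volume(seed, d = c(16L, 8L, 8L))
    S <- random_volume(seed + 1000, d = c(16L, 8L, 8L), kind = "structural",
                       scale = 0.5)
    expect_lt(max_rel_err(vals(tartes_correct(A, S, 0.3)), naive_tartes(A, S, 0.3)),
              1e-10)
    expect_lt(max_rel_err(vals(mean_subtract_correct(A, 1.5)), naive_msa(A, 1.5)),
              1e-10)
    expect_lt(max_rel_err(vals(sdef_correct(A, 0.4)), naive_sdef(A, 0.4)),
              1e-10)
  }
})

test_that("identity at zero weight, dominance, non-negativity, layer-0 invariance", {
  for (seed in c(3, 17, 99)) {
    A <- random_volume(seed, d = c(12L, 6L, 5L))
    S <- random_volume(seed + 7, d = c(12L, 6L, 5L), kind = "structural")
    correctors <- list(
      tartes = function(w) tartes_correct(A, S, w),
      msa = function(w) mean_subtract_correct(A, w),
      sdef = function(w) sdef_correct(A, w))
    for (nm in names(correctors)) {
      # zero weight is the identity
      expect_identical(vals(correctors[[nm]](0)), vals(A))
      out <- correctors[[nm]](0.7)
      # same grid, non-negative, dominated by the input
      expect_identical(dim(out), dim(A))
      expect_identical(attr(out, "pitch_um"), attr(A, "pitch_um"))
      expect_true(all(vals(out) >= 0))
      expect_true(all(vals(out) <= vals(A) + 1e-15))
    }
    # layer 0 bit-identical for TAR-TES and SDEF; MSA documented exception
    expect_identical(vals(tartes_correct(A, S, 0.9))[1, , ], vals(A)[1, , ])
    expect_identical(vals(sdef_correct(A, 0.9))[1, , ], vals(A)[1, , ])
    expect_false(all(vals(mean_subtract_correct(A, 2))[1, , ] == vals(A)[1, , ]))
  }
})
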