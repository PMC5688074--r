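test_that("temporal weights are exposure-normalized", {
  w <- compute_weights(ct_protocol())
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w[1], 200 / 1875)
  expect_equal(w[2], 100 / 1875)
  expect_equal(w[19], 75 / 1875)
  expect_equal(compute_weights(rep(7, 4)), rep(0.25, 4))
  expect_equal(compute_weights(50), 1.0)
  expect_error(compute_weights(c(100, -1)), "positive")
  expect_error(compute_weights(numeric(0)), "empty")
})

test_that("WTA and WTV match brute-force evaluation on random volumes", {
  set.seed(11)
  for (rep in 1:100) {
    a <- array(rnorm(3 * 3 * 3 * 5, 50, 30), c(3, 3, 3, 5))
    w <- compute_weights(runif(5, 10, 300))
    vol <- volume4d(a, c(1, 1, 1))
    wta <- weighted_temporal_average(vol, w)
    wtv <- weighted_temporal_variance(vol, w)
    expect_lt(max(abs(wta$data - bf_wta(a, w))), 1e-10)
    expect_lt(max(abs(wtv$data - bf_wtv(a, w))), 1e-10)
    expect_true(all(wtv$data >= 0))
  }
})

test_that("WTA/WTV respond correctly to constant and offset volumes", {
  vol <- volume4d(array(42, c(3, 3, 3, 4)), c(1, 1, 1))
  w <- compute_weights(c(200, 100, 100, 75))
  expect_equal(weighted_temporal_average(vol, w)$data, array(42, c(3, 3, 3)))
  expect_equal(weighted_temporal_variance(vol, w)$data, array(0, c(3, 3, 3)))

  # T = 2, equal weights, values (0, 100): WTA 50, WTV 50
  a <- array(0, c(2, 2, 2, 2)); a[, , , 2] <- 100
  v2 <- volume4d(a, c(1, 1, 1))
  expect_equal(weighted_temporal_average(v2, c(0.5, 0.5))$data[1, 1, 1], 50)
  expect_equal(weighted_temporal_variance(v2, c(0.5, 0.5))$data[1, 1, 1], 50)

  # adding a per-voxel time-constant offset shifts WTA, leaves WTV invariant
  set.seed(2)
  base <- array(rnorm(4^3 * 3), c(4, 4, 4, 3))
  offset <- array(rnorm(4^3, 0, 10), c(4, 4, 4))
  shifted <- base + array(offset, c(4, 4, 4, 3))
  w3 <- compute_weights(c(3, 2, 1))
  v_a <- volume4d(base, c(1, 1, 1)); v_b <- volume4d(shifted, c(1, 1, 1))
  expect_equal(weighted_temporal_average(v_b, w3)$data,
               weighted_temporal_average(v_a, w3)$data + offset)
  expect_equal(weighted_temporal_variance(v_b, w3)$data,
               weighted_temporal_variance(v_a, w3)$data, tolerance = 1e-12)

  expect_error(weighted_temporal_average(v_a, c(0.5, 0.5)), "weights")
})

test_that("local histogram parameters match a direct patch computation", {
  set.seed(21)
  arr <- array(runif(11^3, 0, 100), c(11, 11, 11))
  wtv <- volume3d(arr, c(1, 1, 1))
  for (edge in c(5L, 9L)) {
    maps <- local_histogram_params(wtv, edge, n_bins = 32)
    r <- edge %/% 2
    # interior voxels: neighborhood fully inside, no padding involved
    for (ctr in list(c(6, 6, 6), c(1 + r, 1 + r, 1 + r))) {
      patch <- arr[(ctr[1] - r):(ctr[1] + r), (ctr[2] - r):(ctr[2] + r),
                   (ctr[3] - r):(ctr[3] + r)]
      ref <- bf_hist_params(as.vector(patch))
      for (p in names(ref))
        expect_equal(maps[[p]]$data[ctr[1], ctr[2], ctr[3]], ref[[p]],
                     tolerance = 1e-12, label = sprintf("%s edge %d", p, edge))
      # mode lies within the neighborhood's range, std nonnegative
      expect_gte(maps$mode$data[ctr[1], ctr[2], ctr[3]], min(patch))
      expect_lte(maps$mode$data[ctr[1], ctr[2], ctr[3]], max(patch))
    }
  }
  expect_error(local_histogram_params(wtv, 4L), "odd")
  expect_error(local_histogram_params(wtv, 13L), "larger than grid")
})

test_that("entropy attains its single-bin floor and uniform-occupancy maximum", {
  # flat neighborhood: one occupied bin, E = -log2(1 + eps)
  flat <- volume3d(array(7, c(5, 5, 5)), c(1, 1, 1))
  maps <- local_histogram_params(flat, 5L)
  expect_equal(maps$entropy$data[3, 3, 3], -log2(1 + 1e-4), tolerance = 1e-15)
  expect_equal(maps$mode$data[3, 3, 3], 7)
  expect_equal(maps$sd$data[3, 3, 3], 0)

  # values uniformly occupying 5 bins: E within 1e-3 of log2(5)
  vals <- rep(1:5, each = 25)
  arr <- array(vals[order(rep(1:125 %% 7, length.out = 125))], c(5, 5, 5))
  u <- local_histogram_params(volume3d(arr, c(1, 1, 1)), 5L, n_bins = 5)
  expect_equal(u$entropy$data[3, 3, 3], log2(5), tolerance = 1e-3)

  # entropy decreases as a two-bin histogram concentrates
  ent2 <- sapply(c(60, 80, 100, 120), function(k) {
    v <- c(rep(0, k), rep(1, 125 - k))
    a <- array(v, c(5, 5, 5))
    local_histogram_params(volume3d(a, c(1, 1, 1)), 5L,
                           n_bins = 2)$entropy$data[3, 3, 3]
  })
  expect_true(all(diff(ent2) < 0))
})

test_that("signed cavity distance is border-zero, signed, and exact", {
  # single-voxel mask, isotropic 1 mm: a voxel 3 steps along x is +3 mm
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  d <- signed_cavity_distance(binary_mask(m, c(1, 1, 1)))
  expect_equal(d$data[5, 5, 5], 0)
  expect_equal(d$data[8, 5, 5], 3)

  # ball mask: border voxels 0, inside negative, outside positive,
  # |d| equals the unsigned distance to the border everywhere
  set.seed(31)
  ball <- rand_mask(c(16L, 16L, 16L), n_balls = 1, salt = 0)
  sp <- c(0.7, 1.1, 0.9)
  sd3 <- signed_cavity_distance(binary_mask(ball, sp))
  bvox <- bf_boundary(ball)
  expect_true(all(sd3$data[bvox] == 0))
  inside <- ball; inside[bvox] <- FALSE
  expect_true(all(sd3$data[inside] < 0))
  expect_true(all(sd3$data[!ball] > 0))
  # brute force against exhaustive nearest-border search
  bp <- sweep(bvox, 2, sp, `*`)
  coords <- as.matrix(expand.grid(x = 1:16, y = 1:16, z = 1:16))
  pts <- sweep(coords, 2, sp, `*`)
  bf <- apply(pts, 1, function(v) sqrt(min(colSums((t(bp) - v)^2))))
  expect_lt(max(abs(abs(as.vector(sd3$data[coords])) - bf)), 1e-6)

  expect_error(signed_cavity_distance(binary_mask(array(FALSE, c(4, 4, 4)),
                                                  c(1, 1, 1))), "empty")
  expect_error(signed_cavity_distance(binary_mask(array(TRUE, c(4, 4, 4)),
                                                  c(1, 1, 1))), "full")
})

test_that("Hessian eigenvalues show the expected geometric signatures", {
  sp <- c(1, 1, 1)
  # constant image: all zero
  ev <- hessian_eigenvalues(volume3d(array(5, c(12, 12, 12)), sp), 1.0)
  expect_lt(max(abs(ev$s1$l3$data)), 1e-10)

  # bright straight tube along z: at the center, |l1| near zero and
  # l2, l3 negative with similar magnitude
  arr <- array(0, c(21, 21, 21))
  xs <- (1:21 - 11)
  prof <- exp(-outer(xs^2, xs^2, "+") / (2 * 1.5^2))
  for (z in 1:21) arr[, , z] <- 100 * prof
  ev <- hessian_eigenvalues(volume3d(arr, sp), 1.5)$s1.5
  c0 <- c(11, 11, 11)
  l1 <- ev$l1$data[c0[1], c0[2], c0[3]]
  l2 <- ev$l2$data[c0[1], c0[2], c0[3]]
  l3 <- ev$l3$data[c0[1], c0[2], c0[3]]
  expect_lt(abs(l1), 0.05 * abs(l3))
  expect_lt(l2, 0); expect_lt(l3, 0)
  expect_lt(abs(l2 - l3) / abs(l3), 0.05)

  # isotropic Gaussian blob: all three equal and negative at the center
  blob <- 100 * exp(-outer(outer(xs^2, xs^2, "+"), xs^2, "+") / (2 * 2^2))
  evb <- hessian_eigenvalues(volume3d(array(blob, c(21, 21, 21)), sp), 2)$s2
  lb <- c(evb$l1$data[11, 11, 11], evb$l2$data[11, 11, 11],
          evb$l3$data[11, 11, 11])
  expect_true(all(lb < 0))
  expect_lt(diff(range(lb)) / abs(mean(lb)), 0.05)

  # ordering invariant: ascending absolute value
  set.seed(5)
  rnd <- volume3d(array(rnorm(10^3), c(10, 10, 10)), sp)
  evr <- hessian_eigenvalues(rnd, 1.0)$s1
  expect_true(all(abs(evr$l1$data) <= abs(evr$l2$data) + 1e-12))
  expect_true(all(abs(evr$l2$data) <= abs(evr$l3$data) + 1e-12))

  expect_warning(hessian_eigenvalues(rnd, 0.3), "below half")
  expect_error(hessian_eigenvalues(rnd, -1), "positive")
})

test_that("T0 extraction returns the first time point untouched", {
  set.seed(4)
  a <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  vol <- volume4d(a, c(1, 1, 1))
  expect_identical(extract_t0(vol)$data, a[, , , 1])
  a2 <- a; a2[, , , 2:4] <- 0; a2[1, 1, 1, 1] <- 99
  expect_equal(extract_t0(volume4d(a2, c(1, 1, 1)))$data[1, 1, 1], 99)
})

test_that("feature assembly yields a fixed 24-column deterministic matrix", {
  spec <- tiny_spec()
  case <- generate_phantom(spec, seed = 9)
  cand <- array(FALSE, dim(case$truth$data))
  cand[which(case$truth$data)[1:2]] <- TRUE
  cand <- binary_mask(cand, case$truth$spacing)
  fm <- assemble_features(case$volume, case$cavity, cand)
  expect_identical(dim(fm$x), c(2L, 24L))
  expect_false(anyNA(fm$x))
  expect_identical(fm$names[1:4], c("wta", "wtv", "t0", "cavity_dist"))

  fm2 <- assemble_features(case$volume, case$cavity, cand)
  expect_identical(fm$x, fm2$x)
  expect_identical(fm$index, fm2$index)

  empty <- binary_mask(array(FALSE, dim(case$truth$data)), case$truth$spacing)
  expect_error(assemble_features(case$volume, case$cavity, empty),
               "empty candidate set")
  wrong <- binary_mask(array(TRUE, c(8, 8, 8)), case$truth$spacing)
  expect_error(assemble_features(case$volume, case$cavity, wrong), "grid")
})
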