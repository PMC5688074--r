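test_that("candidate selection is an exact mean + k*sd threshold scan", {
  set.seed(41)
  arr <- array(abs(rnorm(12^3, 20, 10)), c(12, 12, 12))
  wtv <- volume3d(arr, c(1, 1, 1))
  for (k in c(1.0, 1.5, 2.0)) {
    got <- select_candidates(wtv, k)$data
    want <- arr > mean(arr) + k * sd(as.vector(arr))
    expect_identical(got, want)
  }
  # single bright outlier is always retained
  arr2 <- array(1, c(6, 6, 6)); arr2[2, 3, 4] <- 1000
  sel <- select_candidates(volume3d(arr2, c(1, 1, 1)))
  expect_true(sel$data[2, 3, 4])
  expect_identical(sum(sel$data), 1L)
  # constant map degenerates to an empty mask with a warning
  expect_warning(
    empty <- select_candidates(volume3d(array(3, c(6, 6, 6)), c(1, 1, 1))),
    "constant")
  expect_identical(sum(empty$data), 0L)
  expect_error(select_candidates(wtv, k = -1), "positive")
})

make_fake_features <- function(dims, sp = c(1, 1, 1)) {
  # feature matrix covering the whole grid with reproducible pseudo-features
  idx <- seq_len(prod(dims))
  x <- cbind(f1 = sin(idx), f2 = cos(idx), f3 = idx %% 7)
  structure(list(index = idx, x = x, names = colnames(x),
                 dims = dims, spacing = sp),
            class = "feature_matrix")
}

test_that("training sampling is balanced, seeded and contract-checked", {
  dims <- c(20L, 20L, 20L)
  sp <- c(1, 1, 1)
  box <- subvolume_box(c(1, 1, 1), c(20, 20, 13))
  ann <- array(FALSE, dims)
  ann[which(box_ind <- vessel4d:::box_to_mask(box, dims))[1:1000]] <- TRUE
  annotations <- binary_mask(ann, sp)
  fm <- make_fake_features(dims, sp)

  ts <- sample_training_set(fm, annotations, list(box), fraction = 0.10,
                            seed = 7)
  expect_identical(ts$meta$n_pos, 100L)
  expect_identical(sum(ts$y == 1L), 100L)
  expect_identical(sum(ts$y == 0L), 100L)
  expect_true(all(annotations$data[ts$index[ts$y == 1L]]))
  expect_true(all(!annotations$data[ts$index[ts$y == 0L]]))
  expect_true(all(box_ind[ts$index]))

  ts2 <- sample_training_set(fm, annotations, list(box), fraction = 0.10,
                             seed = 7)
  expect_identical(ts$index, ts2$index)
  ts3 <- sample_training_set(fm, annotations, list(box), fraction = 0.10,
                             seed = 8)
  expect_false(identical(ts$index, ts3$index))

  # fraction 1.0 takes every annotated voxel
  small <- array(FALSE, dims)
  small[which(box_ind)[seq(1, 5000, by = 100)]] <- TRUE
  ts4 <- sample_training_set(fm, binary_mask(small, sp), list(box),
                             fraction = 1.0, seed = 1)
  expect_identical(ts4$meta$n_pos, 50L)
  expect_identical(length(ts4$y), 100L)

  # annotations outside the subvolumes violate the contract
  out <- ann; out[1, 1, 20] <- TRUE
  expect_error(sample_training_set(fm, binary_mask(out, sp), list(box)),
               "confined")
  # too few negatives available
  tiny_box <- subvolume_box(c(1, 1, 1), c(10, 10, 10))
  full_ann <- array(FALSE, dims)
  full_ann[1:10, 1:10, 1:10] <- TRUE
  full_ann[1, 1, 1] <- FALSE
  expect_error(sample_training_set(fm, binary_mask(full_ann, sp),
                                   list(tiny_box), fraction = 1.0),
               "fewer non-annotated")
})

test_that("forest training separates separable data and is seed-stable", {
  set.seed(13)
  n <- 200
  x <- rbind(matrix(rnorm(3 * n, 0), ncol = 3),
             matrix(rnorm(3 * n, 6), ncol = 3))
  colnames(x) <- c("a", "b", "c")
  ts <- structure(list(x = x, y = rep(c(0L, 1L), each = n),
                       index = seq_len(2 * n), names = colnames(x),
                       meta = list()), class = "training_set")
  m <- train_classifier(ts, n_trees = 50, seed = 3)
  df <- data.frame(x, check.names = FALSE)
  p <- predict(m$forest, data = df, num.threads = 1)$predictions[, "1"]
  expect_identical(as.integer(p > 0.5), ts$y)

  m2 <- train_classifier(ts, n_trees = 50, seed = 3)
  p2 <- predict(m2$forest, data = df, num.threads = 1)$predictions[, "1"]
  expect_identical(p, p2)

  # labels independent of the features carry no signal: OOB near chance
  set.seed(99)
  xr <- matrix(rnorm(3 * 2 * n), ncol = 3,
               dimnames = list(NULL, c("a", "b", "c")))
  ts_perm <- ts; ts_perm$x <- xr; ts_perm$y <- sample(ts$y)
  mp <- train_classifier(ts_perm, n_trees = 100, seed = 5)
  oob <- mp$forest$predictions[, "1"]
  acc <- mean((oob > 0.5) == (ts_perm$y == 1L), na.rm = TRUE)
  expect_lt(abs(acc - 0.5), 0.1)

  ts_one <- ts; ts_one$y <- rep(1L, length(ts$y))
  expect_error(train_classifier(ts_one), "both classes")
})

test_that("classification is gated by the candidate mask", {
  spec <- tiny_spec()
  case <- generate_phantom(spec, seed = 3)
  w <- compute_weights(case$volume$exposures)
  wtv <- weighted_temporal_variance(case$volume, w)
  cand <- select_candidates(wtv)
  fm <- assemble_features(case$volume, case$cavity, cand)
  dims <- dim(case$truth$data)
  sv <- array(FALSE, dims)
  for (b in case$subvolumes) sv <- sv | vessel4d:::box_to_mask(b, dims)
  fmsv <- assemble_features(case$volume, case$cavity,
                            binary_mask(sv, case$truth$spacing))
  ann <- binary_mask(case$truth$data & sv, case$truth$spacing)
  ts <- sample_training_set(fmsv, ann, case$subvolumes, 0.2, seed = 2)
  model <- train_classifier(ts, seed = 2)

  res <- classify(model, fm, cand, prob_threshold = 0.5)
  expect_true(all(res$prob$data[!cand$data] == 0))
  expect_true(all(!res$mask$data[!cand$data]))
  # degenerate thresholds
  expect_identical(classify(model, fm, cand, 0)$mask$data, cand$data)
  expect_identical(sum(classify(model, fm, cand, 1 + 1e-9)$mask$data), 0L)
  # manifest mismatch is refused
  bad <- fm; bad$names <- rev(bad$names)
  expect_error(classify(model, bad, cand), "manifest")
})

test_that("small-component removal uses strict 26-connected size < threshold", {
  dims <- c(24L, 24L, 24L)
  m <- array(FALSE, dims)
  m[2:6, 2:6, 2] <- TRUE            # 25-voxel plate: survives
  m[10:13, 10:12, 10:11] <- TRUE    # 24-voxel block: removed
  mask <- binary_mask(m, c(1, 1, 1))
  out <- remove_small_components(mask, 25)
  expect_identical(sum(out$data), 25L)
  expect_true(all(out$data[2:6, 2:6, 2]))
  # surviving components are untouched, foreground never increases
  expect_true(all(out$data[m] | !out$data[m]))
  expect_lte(sum(out$data), sum(m))

  # diagonal-touching voxels form one 26-connected pair (and get removed)
  d <- array(FALSE, dims)
  d[1, 1, 1] <- TRUE; d[2, 2, 2] <- TRUE
  lab <- vessel4d:::label_components_cpp(d, dims, 26L)
  expect_identical(max(lab), 1L)
  expect_identical(sum(remove_small_components(binary_mask(d, c(1, 1, 1)))$data),
                   0L)
  # under 6-connectivity they are two components
  lab6 <- vessel4d:::label_components_cpp(d, dims, 6L)
  expect_identical(max(lab6), 2L)
})

test_that("the 25-voxel minimum corresponds to 2.3 uL at protocol voxel size", {
  expect_equal(signif(component_volume_ul(25, c(0.43, 0.43, 0.5)), 2), 2.3)
})

test_that("hole filling fills a hollow cube and fixes solid/empty masks", {
  dims <- c(11L, 11L, 11L)
  shell <- array(FALSE, dims)
  shell[4:8, 4:8, 4:8] <- TRUE
  shell[5:7, 5:7, 5:7] <- FALSE     # hollow 5^3 cube, 3^3 interior empty
  filled <- fill_holes(binary_mask(shell, c(1, 1, 1)))
  expect_true(all(filled$data[4:8, 4:8, 4:8]))
  # monotone growth: original foreground untouched
  expect_true(all(filled$data[shell]))
  # idempotent once converged
  again <- fill_holes(filled)
  expect_identical(again$data, filled$data)

  solid <- binary_mask(array(TRUE, c(5, 5, 5)), c(1, 1, 1))
  expect_identical(fill_holes(solid)$data, solid$data)
  empty <- binary_mask(array(FALSE, c(5, 5, 5)), c(1, 1, 1))
  expect_identical(sum(fill_holes(empty)$data), 0L)
})

test_that("Youden-J operating point maximizes sensitivity + specificity - 1", {
  prob <- c(0.1, 0.2, 0.4, 0.45, 0.6, 0.8, 0.9)
  truth <- c(0, 0, 0, 1, 1, 1, 1)
  th <- optimal_threshold(prob, truth)
  expect_equal(th, 0.45)
  expect_error(optimal_threshold(prob, rep(1, 7)), "both classes")
})

test_that("an all-static acquisition segments to an empty mask", {
  spec <- tiny_spec(noise_sd = 0)
  case <- generate_phantom(spec, seed = 1)
  zero <- volume4d(array(0, dim(case$volume$data)), case$volume$spacing,
                   case$volume$exposures)
  fake_model <- structure(list(forest = NULL, feature_names = "x"),
                          class = "forest_model")
  expect_warning(res <- run_pipeline(zero, case$cavity, fake_model),
                 "constant")
  expect_identical(sum(res$mask$data), 0L)
})
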