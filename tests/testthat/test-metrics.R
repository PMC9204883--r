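test_that("residual ratios and mIoU match their closed-form examples", {
  truth <- matrix(FALSE, 8, 8); truth[2, 1:8] <- TRUE; truth[3, 1:2] <- TRUE
  pred7 <- matrix(FALSE, 8, 8); pred7[2, 1:7] <- TRUE
  expect_equal(residual_fn(pred7, truth), 30)  # 3 of 10 remain

  pred20 <- matrix(FALSE, 10, 10); pred20[1:2, 1:10] <- TRUE
  truth15 <- matrix(FALSE, 10, 10); truth15[1:2, 1:10] <- TRUE
  truth15[2, 6:10] <- FALSE  # 5 predicted pixels fall outside truth
  expect_equal(residual_fp(pred20, truth15), 25)

  p <- matrix(FALSE, 6, 6); p[1:3, 1:4] <- TRUE           # 12 px
  t <- matrix(FALSE, 6, 6); t[2:3, 1:4] <- TRUE; t[1, 1:2] <- TRUE  # 10 px
  expect_equal(miou(p, t), 100 * 10 / 12)
  o <- matrix(FALSE, 6, 6); o[2:3, 1:4] <- TRUE           # overlap 8
  expect_equal(miou(p, o), 100 * 8 / 12)
  t2 <- o; t2[6, 5:6] <- TRUE                              # truth 10, ov 8
  expect_equal(miou(p, t2), 100 * 8 / 14, tolerance = 1e-12)
  expect_equal(100 * 8 / 14, 57.142857, tolerance = 1e-6)
})

test_that("identical, empty and disjoint masks hit the boundary values", {
  m <- random_mask(8, p = 0.4)
  m[1, 1] <- TRUE
  expect_equal(residual_fn(m, m), 0)
  expect_equal(residual_fp(m, m), 0)
  expect_equal(miou(m, m), 100)
  none <- matrix(FALSE, 8, 8)
  expect_equal(residual_fn(none, m), 100)
  a <- rect_mask(8, 8, 1, 2, 1, 8)
  b <- rect_mask(8, 8, 5, 6, 1, 8)
  expect_equal(residual_fp(a, b), 100)
  expect_equal(miou(a, b), 0)
  expect_warning(v <- residual_fn(m, none), "empty truth")
  expect_true(is.na(v))
  expect_warning(v <- residual_fp(none, m), "empty prediction")
  expect_true(is.na(v))
  expect_warning(v <- miou(none, none), "both masks empty")
  expect_true(is.na(v))
  expect_error(residual_fn(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               "identical dimensions")
})

test_that("metrics reduce to confusion-count formulas and their dualities", {
  set.seed(51)
  for (i in 1:25) {
    pred <- random_mask(16, p = runif(1, 0.1, 0.6))
    truth <- random_mask(16, p = runif(1, 0.1, 0.6))
    pred[1, 1] <- TRUE; truth[2, 2] <- TRUE  # keep metrics defined
    pc <- pixel_counts(pred, truth)
    expect_equal(sum(pc), 256)
    expect_equal(residual_fn(pred, truth),
                 100 * pc["fn"] / (pc["tp"] + pc["fn"]), ignore_attr = TRUE)
    expect_equal(residual_fp(pred, truth),
                 100 * pc["fp"] / (pc["tp"] + pc["fp"]), ignore_attr = TRUE)
    expect_equal(miou(pred, truth),
                 100 * pc["tp"] / (pc["tp"] + pc["fp"] + pc["fn"]),
                 ignore_attr = TRUE)
    # symmetry and FN/FP duality
    expect_equal(miou(pred, truth), miou(truth, pred))
    expect_equal(residual_fn(pred, truth), residual_fp(truth, pred))
  }
})
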