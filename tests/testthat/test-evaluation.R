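test_that("binarize thresholds with the >= convention", {
  m <- matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2)
  expect_equal(binarize(m, 0.5), matrix(c(0, 0, 1, 1), 2, 2))
  expect_true(all(binarize(matrix(0.5, 3, 3), 0.5) == 1))
  expect_true(all(binarize(matrix(0, 3, 3)) == 0))
  expect_error(binarize(matrix(1.5, 2, 2)), "\\[0, 1\\]")
})

test_that("the shifted-block worked example scores exactly as enumerated", {
  truth <- matrix(0, 4, 4); truth[1:2, 1:2] <- 1
  pred <- matrix(0, 4, 4); pred[2:3, 2:3] <- 1
  r <- score(pred, truth)
  expect_equal(r$tp, 1)
  expect_equal(r$fn, 3)
  expect_equal(r$fp, 3)
  expect_equal(r$tn, 9)
  expect_equal(r$dsc, 0.25)
  expect_equal(r$recall, 25)
  expect_equal(r$specificity, 75)
  expect_equal(r$fpr, 25)
})

test_that("score matches the nested-loop oracle exactly on random masks", {
  set.seed(99)
  for (rep in 1:100) {
    pred <- matrix(rbinom(256, 1, runif(1)), 16, 16)
    truth <- matrix(rbinom(256, 1, runif(1)), 16, 16)
    r <- score(pred, truth)
    o <- oracle_score(pred, truth)
    expect_identical(c(r$tp, r$fp, r$tn, r$fn), c(o$tp, o$fp, o$tn, o$fn))
    expect_equal(r$dsc, o$dsc)
    expect_equal(r$recall, o$recall)
    expect_equal(r$specificity, o$specificity)
  }
})

test_that("degenerate masks follow the declared conventions", {
  z <- matrix(0, 5, 5)
  o <- matrix(1, 5, 5)
  both_empty <- score(z, z)
  expect_equal(both_empty$dsc, 1)
  expect_true(is.na(both_empty$recall))
  perfect <- score(o, o)
  expect_equal(perfect$dsc, 1)
  expect_equal(perfect$recall, 100)
  expect_true(is.na(perfect$specificity))
  disjoint <- score(rbind(c(1, 0), c(0, 0)), rbind(c(0, 0), c(0, 1)))
  expect_equal(disjoint$dsc, 0)
  expect_equal(disjoint$recall, 0)
  expect_error(score(z, matrix(0, 4, 4)), "identical shapes")
  expect_error(score(matrix(2, 2, 2), matrix(0, 2, 2)), "\\{0, 1\\}")
})

test_that("dsc is symmetric and recall/specificity swap under role exchange", {
  set.seed(7)
  for (rep in 1:20) {
    a <- matrix(rbinom(64, 1, 0.4), 8, 8)
    b <- matrix(rbinom(64, 1, 0.4), 8, 8)
    rab <- score(a, b); rba <- score(b, a)
    expect_equal(rab$dsc, rba$dsc)
    expect_equal(rab$fp, rba$fn)
    expect_equal(rab$fn, rba$fp)
  }
})

test_that("aggregation is identity for one report and averages correctly", {
  r <- score(matrix(c(1, 0, 0, 0), 2, 2), matrix(c(1, 1, 0, 0), 2, 2))
  for (mode in c("macro", "micro")) {
    a <- aggregate_scores(list(r), mode)
    expect_equal(a$dsc, r$dsc)
    expect_equal(a$recall, r$recall)
  }
  two <- aggregate_scores(list(r, r), "macro")
  expect_equal(two$dsc, r$dsc)
  # macro mean of dsc {0.2, 0.4} is 0.3
  r1 <- r; r1$dsc <- 0.2
  r2 <- r; r2$dsc <- 0.4
  expect_equal(aggregate_scores(list(r1, r2), "macro")$dsc, 0.3)
  expect_error(aggregate_scores(list()), "non-empty")
})

test_that("micro aggregation over a partition equals scoring the whole image", {
  set.seed(11)
  pred <- matrix(rbinom(400, 1, 0.3), 20, 20)
  truth <- matrix(rbinom(400, 1, 0.3), 20, 20)
  parts <- list(list(1:10, 1:20), list(11:20, 1:20))
  reports <- lapply(parts, function(p) score(pred[p[[1]], p[[2]]],
                                             truth[p[[1]], p[[2]]]))
  whole <- score(pred, truth)
  micro <- aggregate_scores(reports, "micro")
  expect_equal(micro$dsc, whole$dsc)
  expect_equal(micro$recall, whole$recall)
  expect_equal(micro$tp, whole$tp)
})

test_that("overlay tints TP green, FN blue, FP red and counts agree with score", {
  set.seed(3)
  img <- array(runif(16 * 16 * 3, 0.2, 0.8), dim = c(16, 16, 3))
  pred <- matrix(rbinom(256, 1, 0.4), 16, 16)
  truth <- matrix(rbinom(256, 1, 0.4), 16, 16)
  ov <- overlay(pred, truth, img, alpha = 0.5)
  r <- score(pred, truth)
  green <- sum(pred == 1 & truth == 1)
  expect_equal(green, r$tp)
  # green-tinted pixels have boosted G and damped R/B relative to the source
  sel <- pred == 1 & truth == 1
  if (any(sel)) {
    expect_true(all(ov[, , 2][sel] > img[, , 2][sel]))
    expect_true(all(ov[, , 1][sel] < img[, , 1][sel]))
  }
  # perfect prediction: no red, no blue tint anywhere
  ov2 <- overlay(truth, truth, img)
  expect_true(all(ov2[, , 1] <= img[, , 1]))
  expect_true(all(ov2[, , 3] <= img[, , 3]))
  # empty prediction over non-empty truth: only blue tints
  ov3 <- overlay(matrix(0, 16, 16), truth, img)
  expect_true(all(ov3[, , 3] >= img[, , 3]))
  expect_true(all(ov3[, , 1] <= img[, , 1]))
})
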