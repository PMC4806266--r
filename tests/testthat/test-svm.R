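test_that("confusion-matrix metrics match direct evaluation", {
  m <- compute_metrics(5, 5, 0, 0)
  expect_equal(unlist(m), c(sn = 1, sp = 1, acc = 1, mcc = 1))

  m2 <- compute_metrics(50, 40, 10, 0)
  expect_equal(m2$sn, 1)
  expect_equal(m2$sp, 0.8)
  expect_equal(m2$acc, 0.9)
  expect_equal(m2$mcc, 2000 / sqrt(50 * 60 * 50 * 40))

  m3 <- compute_metrics(0, 0, 5, 5)
  expect_equal(m3$mcc, -1)

  expect_error(compute_metrics(0, 0, 0, 0), "zero")
  expect_error(compute_metrics(-1, 0, 1, 1), "non-negative")

  set.seed(14)
  for (rep in 1:200) {
    cnt <- sample(0:200, 4, replace = TRUE)
    if (sum(cnt) == 0) cnt[1] <- 1
    got <- compute_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    want <- direct_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("rank-based AUC behaves at the extremes and matches pROC", {
  y <- rep(c(0L, 1L), each = 10)
  expect_equal(roc_auc(seq_len(20), y), 1)
  expect_equal(roc_auc(rep(1, 20), y), 0.5)
  expect_equal(roc_auc(-seq_len(20), y), 0)
  expect_error(roc_auc(1:5, rep(1L, 5)), "both classes")

  set.seed(15)
  for (rep in 1:10) {
    s <- rnorm(60)
    yy <- rbinom(60, 1, 0.4)
    if (length(unique(yy)) < 2) next
    ref <- suppressMessages(as.numeric(pROC::auc(yy, s, direction = "<")))
    expect_equal(roc_auc(s, yy), ref, tolerance = 1e-12)
  }
})

test_that("the SVM separates linearly separable toy data", {
  toy <- toy_separable()
  model <- svm_train(toy$x, toy$y, svm_params(C = 10, gamma = 0.5))
  classes <- predict(model, toy$x, type = "class")
  expect_equal(classes, toy$y)
  scores <- predict(model, toy$x, type = "score")
  expect_length(scores, nrow(toy$x))
  expect_equal(roc_auc(scores, toy$y), 1)
  expect_error(predict(model, toy$x[, 1:2]), "features")
  expect_error(svm_train(toy$x, rep(1L, nrow(toy$x))), "single class")
})

test_that("min-max scaling is fitted on training rows only", {
  xtr <- matrix(c(0, 10, 5, 5), 2, 2)
  fit <- sulfire:::minmax_fit(xtr)
  scaled_tr <- sulfire:::minmax_apply(fit, xtr)
  expect_equal(range(scaled_tr[, 1]), c(-1, 1))
  expect_equal(scaled_tr[, 2], c(0, 0))  # constant column maps to 0
  # a test row outside the training range maps outside [-1, 1], proving the
  # statistics exclude it
  scaled_te <- sulfire:::minmax_apply(fit, matrix(c(20, 5), 1, 2))
  expect_gt(scaled_te[1, 1], 1)
})

test_that("cross-validation is stratified, seeded and averaged", {
  toy <- toy_separable(n = 80)
  rep1 <- cross_validate(toy$x, toy$y, svm_params(C = 10, gamma = 0.5),
                         folds = 5, seed = 3)
  rep2 <- cross_validate(toy$x, toy$y, svm_params(C = 10, gamma = 0.5),
                         folds = 5, seed = 3)
  expect_identical(rep1[c("sn", "sp", "acc", "mcc", "auc")],
                   rep2[c("sn", "sp", "acc", "mcc", "auc")])
  expect_equal(rep1$mcc, 1)
  expect_equal(rep1$auc, 1)
  expect_equal(nrow(rep1$per_fold), 5)
  expect_equal(rep1$acc, mean(rep1$per_fold$acc))

  expect_error(cross_validate(toy$x[1:12, ], toy$y[1:12], folds = 10),
               "folds")
})

test_that("pure-noise features score near-zero MCC", {
  mccs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    x <- matrix(rnorm(200 * 5), 200, 5)
    y <- rep(c(0L, 1L), each = 100)
    cross_validate(x, y, svm_params(C = 1, gamma = 0.2), folds = 5,
                   seed = s)$mcc
  }, numeric(1))
  expect_true(all(abs(mccs) <= 0.25))
})

test_that("models persist with scaler and survive an integrity check", {
  toy <- toy_separable()
  model <- svm_train(toy$x, toy$y, svm_params(C = 10, gamma = 0.5))
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(model, f)
  back <- load_model(f)
  expect_equal(predict(back, toy$x, type = "score"),
               predict(model, toy$x, type = "score"))

  trunc <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", trunc)
  expect_error(load_model(trunc), "unreadable|integrity")
  wrong <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), wrong)
  expect_error(load_model(wrong), "integrity")
})
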