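# Small synthetic feature tables for classifier tests, built in code.
toy_feature_table <- function(n_per_class = 20L, classes = c("a", "b"),
                              sep = 5, thickness = 30, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_along(classes), function(i) {
    f <- matrix(rnorm(n_per_class * 12, mean = (i - 1) * sep), ncol = 12,
                dimnames = list(NULL, paste0("f", 1:12)))
    data.frame(voc = classes[i], thickness_um = thickness,
               replicate_id = rep(1:2, length.out = n_per_class),
               cycle_index = seq_len(n_per_class), f,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("assemble_dataset filters one thickness and validates classes", {
  tab <- rbind(toy_feature_table(thickness = 30),
               toy_feature_table(thickness = 60))
  ds <- assemble_dataset(tab, 30)
  expect_s3_class(ds, "voc_dataset")
  expect_equal(nrow(ds$features), 40L)
  expect_equal(ds$thickness_um, 30)
  expect_identical(levels(ds$labels), c("a", "b"))

  expect_error(assemble_dataset(tab, 45), "no rows with thickness 45")
  expect_error(assemble_dataset(tab[0, ], 30), "empty")
  expect_error(assemble_dataset(tab, 30, min_class_size = 25L),
               "fewer than 25 cycles: a, b")
})

test_that("stratified folds are balanced per class and seed-deterministic", {
  tab <- toy_feature_table(n_per_class = 30L, classes = c("a", "b", "c"))
  ds <- assemble_dataset(tab, 30)
  fold <- lcnose:::make_folds(ds$labels, 10L, seed = 4)
  expect_identical(fold, lcnose:::make_folds(ds$labels, 10L, seed = 4))
  for (lv in levels(ds$labels))
    expect_true(all(table(fold[ds$labels == lv]) == 3L))
  expect_false(identical(fold, lcnose:::make_folds(ds$labels, 10L, seed = 5)))
})

test_that("crossval_predict is leak-free, deterministic and exact on separable data", {
  tab <- toy_feature_table(n_per_class = 30L, sep = 8)
  ds <- assemble_dataset(tab, 30)
  cfg <- cv_config(n_folds = 5L, seed = 2)
  pred <- crossval_predict(ds, cfg)
  expect_equal(mean(pred$predicted == pred$labels), 1)      # point masses
  expect_true(all(table(pred$fold) > 0))
  expect_identical(pred$predicted, crossval_predict(ds, cfg)$predicted)

  # training-fold standardization statistics ignore the held-out rows:
  # shifting an entire held-out fold leaves them unchanged
  fold <- lcnose:::make_folds(ds$labels, cfg$n_folds, cfg$seed, TRUE)
  tr <- fold != 1L
  mu1 <- colMeans(ds$features[tr, ]); sd1 <- apply(ds$features[tr, ], 2, sd)
  shifted <- ds
  shifted$features[!tr, ] <- shifted$features[!tr, ] + 1e6
  mu2 <- colMeans(shifted$features[tr, ]); sd2 <- apply(shifted$features[tr, ], 2, sd)
  expect_identical(mu1, mu2)
  expect_identical(sd1, sd2)

  # degenerate single-class dataset: warning, not an error
  one <- assemble_dataset(toy_feature_table(classes = "a"), 30)
  expect_warning(p1 <- crossval_predict(one, cfg), "single-class")
  expect_true(all(p1$predicted == "a"))

  # classes smaller than the fold count are refused by name
  tiny <- assemble_dataset(toy_feature_table(n_per_class = 3L), 30)
  expect_error(crossval_predict(tiny, cv_config(n_folds = 5L)), "fewer rows")
})

test_that("confusion_matrix_normalized is row-stochastic with the stated examples", {
  perfect <- confusion_matrix_normalized(c("a", "b", "c"), c("a", "b", "c"),
                                         c("a", "b", "c"))
  expect_equal(unclass(perfect), diag(3), ignore_attr = TRUE)

  m <- confusion_matrix_normalized(c("a", "a", "b", "b"),
                                   c("a", "b", "b", "b"), c("a", "b"))
  expect_equal(unname(m["a", ]), c(0.5, 0.5))
  expect_equal(unname(m["b", ]), c(0, 1))

  set.seed(3)
  t10 <- sample(letters[1:4], 200, TRUE)
  p10 <- sample(letters[1:4], 200, TRUE)
  mm <- confusion_matrix_normalized(t10, p10, letters[1:4])
  expect_equal(unname(rowSums(mm)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(mm >= 0 & mm <= 1))

  zero <- confusion_matrix_normalized(c("a", "a"), c("a", "a"), c("a", "b"))
  expect_identical(attr(zero, "zero_support"), "b")
  expect_equal(unname(zero["b", ]), c(0, 0))

  expect_error(confusion_matrix_normalized("z", "a", c("a", "b")), "outside")
  expect_error(confusion_matrix_normalized(c("a", "a"), "a"), "equal length")
})

test_that("summarize_report computes pooled accuracy and macro precision", {
  mk_pred <- function(true, pred) list(
    predicted = factor(pred, levels = unique(true)),
    labels = factor(true, levels = unique(true)), fold = rep(1L, length(true)))

  p <- mk_pred(c("a", "b", "c"), c("a", "b", "c"))
  conf <- confusion_matrix_normalized(p$labels, p$predicted, c("a", "b", "c"))
  r <- summarize_report(conf, p, 30)
  expect_equal(r$overall_accuracy, 1)
  expect_equal(r$macro_precision, 1)
  expect_equal(unname(r$per_voc_accuracy), rep(1, 3))

  p2 <- mk_pred(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
  conf2 <- confusion_matrix_normalized(p2$labels, p2$predicted, c("a", "b"))
  r2 <- summarize_report(conf2, p2, 30)
  expect_equal(r2$overall_accuracy, 0.75)
  expect_equal(unname(diag(conf2)), unname(r2$per_voc_accuracy))

  # all predictions a single class in a balanced 11-class set
  lv <- paste0("v", 1:11)
  true <- rep(lv, each = 10)
  p3 <- mk_pred(true, rep(lv[1], 110))
  conf3 <- confusion_matrix_normalized(p3$labels, p3$predicted, lv)
  r3 <- summarize_report(conf3, p3, 15)
  expect_equal(r3$overall_accuracy, 1 / 11)
  expect_identical(setdiff(lv, r3$never_predicted), lv[1])
})
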