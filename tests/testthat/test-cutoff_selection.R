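test_that("class specifications pair the right curated lists per proteome and axis", {
  tp <- c("TOMM20", "MFN2")
  matrix_ref <- c("CS", "MDH2")
  mito <- c("TOMM20", "MFN2", "CS", "MDH2", "TIMM23")

  s <- build_class_spec("OMM", "hl", tp_set = tp, matrix_set = matrix_ref)
  expect_false(s$fp_is_complement)
  expect_identical(as.character(s$fp_set), matrix_ref)

  s <- build_class_spec("OMM", "hm", tp_set = tp, mito_annotation = mito)
  expect_true(s$fp_is_complement)
  expect_identical(as.character(s$fp_set), mito)

  s <- build_class_spec("ERM", "hl", tp_set = c("CANX"), matrix_set = matrix_ref)
  expect_false(s$fp_is_complement)

  s <- build_class_spec("ERM", "hm", tp_set = c("CANX", "SEC61B"))
  expect_true(s$fp_is_complement)
  expect_identical(s$fp_set, s$tp_set)

  expect_error(build_class_spec("OMM", "hl", tp_set = tp), "matrix")
  expect_error(build_class_spec("OMM", "hm", tp_set = tp), "annotation")
  expect_error(build_class_spec("OMM", "hl", tp_set = tp,
                                matrix_set = c("CS", "TOMM20")), "overlap")
})

test_that("ROC sweeps enumerate observed thresholds with >= semantics", {
  spec <- list(tp_set = c("t1", "t2"), fp_set = c("f1", "f2"),
               fp_is_complement = FALSE)
  # separable classes
  roc <- roc_curve(c(t1 = 3, t2 = 4, f1 = 0, f2 = 1), spec)
  at3 <- roc$sweep[roc$sweep$threshold == 3, ]
  expect_equal(at3$tpr, 1)
  expect_equal(at3$fpr, 0)
  expect_equal(roc$max_j, 1)

  # interleaved classes: full hand-enumerated sweep
  roc <- roc_curve(c(t1 = 1, t2 = 3, f1 = 2, f2 = 4), spec)
  expect_equal(roc$sweep$threshold, c(4, 3, 2, 1))
  expect_equal(roc$sweep$tpr, c(0, 0.5, 0.5, 1))
  expect_equal(roc$sweep$fpr, c(0.5, 0.5, 1, 1))

  # one TP, one FP
  roc <- roc_curve(c(t1 = 5, f1 = 1), list(tp_set = "t1", fp_set = "f1",
                                           fp_is_complement = FALSE))
  expect_equal(roc$sweep$threshold, c(5, 1))
  expect_equal(roc$sweep$tpr, c(1, 1))
  expect_equal(roc$sweep$fpr, c(0, 1))

  expect_error(roc_curve(c(f1 = 1), spec), "true positives")
  expect_error(roc_curve(c(t1 = 1), spec), "false positives")
})

test_that("complement false-positive classes score everything off the annotation union", {
  spec <- list(tp_set = c("t1", "t2"), fp_set = c("t1", "t2", "m1"),
               fp_is_complement = TRUE)
  roc <- roc_curve(c(t1 = 3, t2 = 2, m1 = 1, u1 = 0, u2 = 0.5), spec)
  expect_equal(roc$n_tp_detected, 2)
  expect_equal(roc$n_fp_detected, 2)  # u1, u2 lack annotation
})

test_that("cutoff selection maximizes TPR - FPR, breaking ties stringently, and truncates for reporting", {
  spec <- list(tp_set = c("t1", "t2"), fp_set = c("f1", "f2"),
               fp_is_complement = FALSE)
  # J = 0 at t = 1 and t = 3; tie broken toward the larger threshold
  roc <- roc_curve(c(t1 = 1, t2 = 3, f1 = 2, f2 = 4), spec)
  sel <- select_cutoff(roc)
  expect_equal(sel$cutoff, 3)
  expect_equal(sel$max_j, 0)

  # all scores equal -> that single threshold, J = 0
  roc <- roc_curve(c(t1 = 2, t2 = 2, f1 = 2, f2 = 2), spec)
  expect_equal(select_cutoff(roc)$cutoff, 2)
  expect_equal(select_cutoff(roc)$max_j, 0)

  # truncation toward zero, not rounding
  roc <- roc_curve(c(t1 = 1.0699, t2 = 1.2, f1 = 0.4, f2 = -0.317), spec)
  sel <- select_cutoff(roc)
  expect_equal(sel$cutoff, 1.0699)
  expect_equal(sel$reported, 1.06)
  roc <- roc_curve(c(t1 = -0.317, t2 = 1.2, f1 = -2, f2 = -1), spec)
  expect_equal(select_cutoff(roc)$reported, -0.31)
})

test_that("selected cutoffs agree with an exhaustive sweep oracle on random instances", {
  set.seed(2024)
  for (i in 1:200) {
    n <- sample(6:50, 1)
    ids <- sprintf("p%02d", 1:n)
    n_tp <- sample(2:max(2, n %/% 3), 1)
    n_fp <- sample(2:max(2, n %/% 3), 1)
    tp <- ids[1:n_tp]
    fp <- ids[(n_tp + 1):(n_tp + n_fp)]
    scores <- round(rnorm(n), sample(0:2, 1))  # coarse rounding forces ties
    names(scores) <- ids
    roc <- roc_curve(scores, list(tp_set = tp, fp_set = fp,
                                  fp_is_complement = FALSE))
    sel <- select_cutoff(roc)
    ora <- oracle_roc_argmax(scores, ids %in% tp, ids %in% fp)
    expect_equal(sel$cutoff, ora$threshold)
    expect_equal(sel$max_j, ora$j)
  }
})

test_that("TPR and FPR are invariant under monotone score transforms", {
  set.seed(5)
  ids <- sprintf("p%d", 1:40)
  scores <- stats::setNames(rnorm(40), ids)
  spec <- list(tp_set = ids[1:8], fp_set = ids[9:20], fp_is_complement = FALSE)
  r1 <- roc_curve(scores, spec)
  r2 <- roc_curve(exp(scores), spec)  # strictly increasing transform
  expect_equal(r1$sweep$tpr, r2$sweep$tpr)
  expect_equal(r1$sweep$fpr, r2$sweep$fpr)
  expect_equal(exp(select_cutoff(r1)$cutoff), select_cutoff(r2)$cutoff,
               tolerance = 1e-12)
})

test_that("ROC rates are monotone as the threshold decreases and adding a high TP never hurts", {
  set.seed(9)
  ids <- sprintf("p%d", 1:30)
  scores <- stats::setNames(rnorm(30), ids)
  spec <- list(tp_set = ids[1:6], fp_set = ids[7:16], fp_is_complement = FALSE)
  roc <- roc_curve(scores, spec)
  expect_true(all(diff(roc$sweep$tpr) >= 0))  # thresholds descend
  expect_true(all(diff(roc$sweep$fpr) >= 0))

  sel <- select_cutoff(roc)
  scores2 <- c(scores, newtp = sel$cutoff + 1)
  spec2 <- list(tp_set = c(spec$tp_set, "newtp"), fp_set = spec$fp_set,
                fp_is_complement = FALSE)
  expect_gte(roc_curve(scores2, spec2)$max_j, sel$max_j - 1e-12)
})
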