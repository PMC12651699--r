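box1 <- function(x_min = 0, y_min = 0, x_max = 1, y_max = 1) {
  tibble::tibble(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
}

test_that("IoU does the area arithmetic", {
  expect_equal(iou(box1(), box1()), 1)
  expect_equal(iou(box1(), box1(5, 5, 6, 6)), 0)
  expect_equal(iou(box1(), box1(0.5, 0, 1.5, 1)), 1 / 3)
  expect_error(iou(box1(), box1(0, 0, 0, 1)), class = "dentalign_degenerate_box")
})

test_that("greedy matching is one-to-one, score-ordered and class-aware on demand", {
  truth <- detections(x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                      label = 5, score = 1)
  pred1 <- detections(x_min = 1, y_min = 0, x_max = 10, y_max = 10,
                      label = 5, score = 0.8)
  m <- match_detections(pred1, truth)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(length(m$fp), 0)

  # two predictions on one truth: the higher score wins, the other is FP
  pred2 <- dplyr::bind_rows(pred1, pred1)
  pred2$score <- c(0.6, 0.9)
  m2 <- match_detections(pred2, truth)
  expect_equal(m2$pairs$pred, 2L)
  expect_equal(m2$fp, 1L)

  # wrong label at high IoU: FP + FN when class-aware, TP when class-blind
  predw <- pred1
  predw$label <- 6L
  mw <- match_detections(predw, truth, class_aware = TRUE)
  expect_equal(nrow(mw$pairs), 0)
  expect_equal(length(mw$fp), 1)
  expect_equal(length(mw$fn), 1)
  mb <- match_detections(predw, truth, class_aware = FALSE)
  expect_equal(nrow(mb$pairs), 1)

  # raising a matched prediction's score keeps it matched
  m3 <- match_detections(dplyr::mutate(pred1, score = 0.99), truth)
  expect_equal(nrow(m3$pairs), 1)
})

test_that("rate formulas are literal and flag undefined ratios", {
  expect_equal(metric_precision(3, 1), 0.75)
  expect_equal(metric_sensitivity(3, 2), 0.6)
  expect_equal(metric_specificity(98, 2), 0.98)
  expect_true(is.na(metric_precision(0, 0)))
  expect_true(is.na(metric_f1(NA_real_, 0.5)))
  # harmonic-mean identities and bounds
  for (p in c(0.2, 0.5, 0.9)) expect_equal(metric_f1(p, p), p)
  set.seed(5)
  for (i in 1:50) {
    p <- runif(1); r <- runif(1)
    f <- metric_f1(p, r)
    expect_gte(f, min(p, r) - 1e-12)
    expect_lte(f, (p + r) / 2 + 1e-12)
  }
})

test_that("average precision matches trivial cases and the brute-force oracle", {
  truth <- boxes_for(c(3, 4, 5))
  # perfect detection at any scores: AP 1 per class
  preds <- truth
  preds$score <- c(0.5, 0.9, 0.2)
  for (cl in 3:5) expect_equal(average_precision_50(preds, truth, cl), 1)
  expect_equal(mean_ap50(preds, truth), 1)

  # single truth, rank-1 FP then rank-2 TP: AP = 0.5
  t1 <- detections(x_min = 0, y_min = 0, x_max = 10, y_max = 10, label = 7, score = 1)
  p1 <- detections(x_min = c(50, 1), y_min = 0, x_max = c(60, 10), y_max = 10,
                   label = 7, score = c(0.9, 0.8))
  expect_equal(average_precision_50(p1, t1, 7), 0.5)

  # absent class: skipped, not zero
  expect_true(is.na(average_precision_50(preds, truth, 9)))
  expect_equal(mean_ap50(p1, t1), 0.5)

  set.seed(99)
  for (i in 1:40) {
    sc <- random_scene()
    for (cl in sc$classes) {
      expect_equal(average_precision_50(sc$preds, sc$truths, cl),
                   ap_oracle(sc$preds, sc$truths, cl),
                   tolerance = 1e-12)
    }
  }
})

test_that("FDI position error averages linear-index distances with a cross-arch cap", {
  pairs <- tibble::tibble(pred_label = c(8L, 9L), true_label = c(8L, 10L),
                          score = 1)
  expect_equal(fdi_error(pairs), 0.5)
  expect_equal(fdi_error(tibble::tibble(pred_label = 5L, true_label = 7L, score = 1)), 2)
  expect_equal(fdi_error(tibble::tibble(pred_label = c(3L, 3L), true_label = c(3L, 3L), score = 1)), 0)
  # cross-arch pair contributes the cap of 16
  expect_equal(fdi_error(tibble::tibble(pred_label = 1L, true_label = 17L, score = 1)), 16)
  expect_true(is.na(fdi_error(tibble::tibble(pred_label = integer(), true_label = integer(), score = numeric()))))
})

test_that("top-1 confidence is the mean score of correct predictions", {
  pairs <- tibble::tibble(pred_label = c(1L, 2L), true_label = c(1L, 2L),
                          score = c(0.9, 0.8))
  expect_equal(top1_conf(pairs), 0.85)
  expect_equal(top1_conf(pairs[1, ]), 0.9)
  expect_true(is.na(top1_conf(pairs[0, ])))
  set.seed(3)
  sc <- random_scene()
  m <- match_detections(sc$preds, sc$truths, class_aware = TRUE)
  if (nrow(m$pairs) > 0) {
    v <- top1_conf(m)
    expect_gte(v, min(m$pairs$score))
    expect_lte(v, max(m$pairs$score))
  }
})

test_that("the confusion matrix counts matched pairs by (true, predicted)", {
  pairs <- tibble::tibble(
    pred_label = c(3L, 3L, fdi_to_linear(47)),
    true_label = c(3L, 3L, fdi_to_linear(37)),
    score = 1
  )
  cm <- confusion_matrix(pairs)
  expect_equal(sum(cm), 3)
  expect_equal(cm[3, 3], 2L)
  expect_equal(cm["37", "47"], 1L)  # mandibular-molar contralateral confusion
  expect_equal(sum(diag(cm)), 2)
  # purely diagonal when all labels agree
  ok <- tibble::tibble(pred_label = 1:5, true_label = 1:5, score = 1)
  cmo <- confusion_matrix(ok)
  expect_equal(sum(cmo), 5)
  expect_equal(sum(diag(cmo)), 5)
  # row sums equal per-true-class pair counts
  expect_equal(rowSums(cm)[3], c("16" = 2))
})

test_that("macro specificity sits near one with few FPs and is undefined without negatives", {
  # perfect predictions over >= 2 classes
  truth <- boxes_for(c(3, 4, 5))
  m <- match_detections(truth, truth)
  expect_equal(specificity_detection(m), 1)

  # one FP of one class among other-class TNs: just below 1
  preds <- dplyr::bind_rows(truth, detections(
    x_min = 500, y_min = 0, x_max = 550, y_max = 80, label = 3, score = 0.7))
  m2 <- match_detections(preds, truth)
  sp <- specificity_detection(m2)
  expect_lt(sp, 1)
  expect_gt(sp, 0.8)

  # single-class scene has no negatives at all
  one <- detections(x_min = 0, y_min = 0, x_max = 10, y_max = 10, label = 4, score = 1)
  m3 <- match_detections(one, one)
  expect_true(is.na(specificity_detection(m3)))
})

test_that("the evaluation report ties all metrics together", {
  set.seed(17)
  sc <- random_scene(n_truth = 8, n_classes = 5)
  ev <- evaluate_detections(sc$preds, sc$truths)
  g <- glance(ev)
  rates <- c(g$precision, g$sensitivity, g$f1, g$map50, g$top1_conf)
  expect_true(all(is.na(rates) | (rates >= 0 & rates <= 1)))
  expect_equal(g$tp + g$fp, nrow(sc$preds))
  expect_equal(g$tp + g$fn, nrow(sc$truths))
  expect_equal(g$f1, metric_f1(g$precision, g$sensitivity))
  expect_equal(sum(ev$confusion), nrow(ev$match_blind$pairs))
  td <- tidy(ev)
  expect_equal(nrow(td), 32)
  expect_s3_class(autoplot(ev), "ggplot")
  # fdi_error is zero iff all matched labels agree
  agree <- all(ev$match_blind$pairs$pred_label == ev$match_blind$pairs$true_label)
  expect_equal(ev$fdi_error == 0, agree)
})

test_that("multi-image evaluation pools images without cross-talk", {
  t1 <- boxes_for(c(3, 4, 5)); t1$image_id <- "a"
  t2 <- boxes_for(c(20, 21)); t2$image_id <- "b"
  truths <- dplyr::bind_rows(t1, t2)
  preds <- truths
  preds$score <- 0.9
  ev <- evaluate_images(preds, truths)
  expect_equal(glance(ev)$tp, 5)
  expect_equal(glance(ev)$precision, 1)
  # a prediction for an unknown image id is a domain error
  bad <- preds
  bad$image_id[1] <- "zz"
  expect_error(evaluate_images(bad, truths), class = "dentalign_domain_error")
})
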