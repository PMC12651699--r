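#' Intersection over union of axis-aligned boxes
#'
#' Boxes use the package's internal 0-based half-open convention, so area is
#' `(x_max - x_min) * (y_max - y_min)`. Inputs are data frames with the box
#' columns (rows recycled to a common length), so the function vectorises
#' over pairs.
#'
#' @param a,b Data frames with columns `x_min`, `y_min`, `x_max`, `y_max`.
#' @return Numeric vector of IoU values in `[0, 1]`; 0 for disjoint boxes.
#' @examples
#' u <- tibble::tibble(x_min = 0, y_min = 0, x_max = 1, y_max = 1)
#' v <- tibble::tibble(x_min = 0.5, y_min = 0, x_max = 1.5, y_max = 1)
#' iou(u, v) # 1/3
#' @export
iou <- function(a, b) {
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  if (any(area_a <= 0) || any(area_b <= 0)) {
    rlang::abort("Boxes must have positive area.", class = c("dentalign_degenerate_box", "dentalign_error"))
  }
  iw <- pmax(0, pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min))
  ih <- pmax(0, pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min))
  inter <- iw * ih
  inter / (area_a + area_b - inter)
}

iou_matrix <- function(preds, truths) {
  np <- nrow(preds)
  nt <- nrow(truths)
  m <- matrix(0, np, nt)
  if (np == 0L || nt == 0L) return(m)
  for (i in seq_len(np)) {
    m[i, ] <- iou(preds[rep.int(i, nt), , drop = FALSE], truths)
  }
  m
}

#' Match predicted detections to ground-truth boxes
#'
#' Greedy one-to-one matching in descending confidence order, the standard
#' detection-evaluation convention: each prediction, from highest score down,
#' claims the still-unmatched ground truth with which it has the highest IoU
#' at or above the threshold (and the same class, when `class_aware`).
#' Predictions left over are false positives, ground truths left over false
#' negatives.
#'
#' @param preds Detections tibble with scores.
#' @param truths Ground-truth detections tibble (scores ignored).
#' @param iou_threshold Minimum IoU for a spatial match. Default 0.5.
#' @param class_aware Require label agreement for a match. Default `TRUE`.
#' @return An object of class `tooth_matches`: list with `pairs` (tibble:
#'   `pred`, `truth` row indices, `iou`, `pred_label`, `true_label`,
#'   `score`), `fp` and `fn` (row indices), `per_class` tallies
#'   (tibble: `label`, `tp`, `fp`, `fn`, `tn`), and the settings used.
#' @export
match_detections <- function(preds, truths, iou_threshold = 0.5, class_aware = TRUE) {
  preds <- as_detections(preds)
  truths <- as_detections(truths)
  if (any(preds$label == 0L) || any(truths$label == 0L)) {
    rlang::abort("Placeholders (label 0) cannot enter detection matching.",
                 class = c("dentalign_placeholder_index", "dentalign_error"))
  }
  m <- iou_matrix(preds, truths)
  ord <- order(-preds$score)
  truth_taken <- rep(FALSE, nrow(truths))
  pair_pred <- integer()
  pair_truth <- integer()
  pair_iou <- numeric()
  for (i in ord) {
    cand <- m[i, ] >= iou_threshold & !truth_taken
    if (class_aware) cand <- cand & truths$label == preds$label[i]
    if (!any(cand)) next
    j <- which(cand)[which.max(m[i, cand])]
    truth_taken[j] <- TRUE
    pair_pred <- c(pair_pred, i)
    pair_truth <- c(pair_truth, j)
    pair_iou <- c(pair_iou, m[i, j])
  }
  pairs <- tibble::tibble(
    pred = pair_pred,
    truth = pair_truth,
    iou = pair_iou,
    pred_label = preds$label[pair_pred],
    true_label = truths$label[pair_truth],
    score = preds$score[pair_pred]
  )
  fp <- setdiff(seq_len(nrow(preds)), pair_pred)
  fn <- which(!truth_taken)
  per_class <- purrr::map_dfr(1:32, function(cl) {
    tp_c <- sum(pairs$pred_label == cl & pairs$true_label == cl)
    tibble::tibble(
      label = cl,
      tp = tp_c,
      fp = sum(preds$label == cl) - tp_c,
      fn = sum(truths$label == cl) - tp_c,
      tn = sum(pairs$pred_label != cl & pairs$true_label != cl)
    )
  })
  structure(
    list(pairs = pairs, fp = fp, fn = fn, per_class = per_class,
         n_preds = nrow(preds), n_truths = nrow(truths),
         iou_threshold = iou_threshold, class_aware = class_aware),
    class = "tooth_matches"
  )
}

#' @export
print.tooth_matches <- function(x, ...) {
  cat(sprintf("<tooth_matches> %d TP, %d FP, %d FN (IoU >= %g, %s)\n",
              nrow(x$pairs), length(x$fp), length(x$fn), x$iou_threshold,
              if (x$class_aware) "class-aware" else "class-blind"))
  invisible(x)
}

#' Elementary detection rates
#'
#' Literal count ratios: precision `TP/(TP+FP)`, sensitivity (recall)
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, and F1 as the harmonic mean of
#' precision and sensitivity. A zero denominator yields `NA` (an explicit
#' undefined flag, never silently 0) so aggregation can skip undefined
#' values.
#'
#' @param tp,fp,fn,tn Non-negative counts (vectorised).
#' @param precision,sensitivity Rates in `[0, 1]` (vectorised).
#' @return Numeric rates in `[0, 1]`, or `NA` where undefined.
#' @name detection_rates
#' @examples
#' metric_precision(3, 1)       # 0.75
#' metric_f1(0.5, 0.5)          # 0.5
#' metric_precision(0, 0)       # NA: undefined, not 0
NULL

#' @rdname detection_rates
#' @export
metric_precision <- function(tp, fp) {
  ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
}

#' @rdname detection_rates
#' @export
metric_sensitivity <- function(tp, fn) {
  ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
}

#' @rdname detection_rates
#' @export
metric_specificity <- function(tn, fp) {
  ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
}

#' @rdname detection_rates
#' @export
metric_f1 <- function(precision, sensitivity) {
  ifelse(!is.na(precision) & !is.na(sensitivity) & precision + sensitivity > 0,
         2 * precision * sensitivity / (precision + sensitivity),
         NA_real_)
}

#' Precision-recall curve for one tooth class
#'
#' Ranks the class's predictions by descending confidence, greedily matches
#' each to the unmatched ground truth of that class with the highest IoU at
#' or above the threshold, and accumulates precision and recall rank by
#' rank.
#'
#' @param preds,truths Detections tibbles.
#' @param class_id Linear index (1..32) of the class.
#' @param iou_threshold Minimum IoU. Default 0.5.
#' @return A tibble with one row per prediction of the class, in rank order:
#'   `score`, `tp` (logical), `cum_tp`, `cum_fp`, `recall`, `precision`.
#' @export
pr_curve <- function(preds, truths, class_id, iou_threshold = 0.5) {
  preds <- as_detections(preds)
  truths <- as_detections(truths)
  p <- preds[preds$label == class_id, , drop = FALSE]
  t <- truths[truths$label == class_id, , drop = FALSE]
  p <- p[order(-p$score), , drop = FALSE]
  m <- iou_matrix(p, t)
  taken <- rep(FALSE, nrow(t))
  tp <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    cand <- if (nrow(t)) m[i, ] >= iou_threshold & !taken else logical(0)
    if (any(cand)) {
      j <- which(cand)[which.max(m[i, cand])]
      taken[j] <- TRUE
      tp[i] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  tibble::tibble(
    score = p$score,
    tp = tp,
    cum_tp = cum_tp,
    cum_fp = cum_fp,
    recall = if (nrow(t)) cum_tp / nrow(t) else rep(NA_real_, nrow(p)),
    precision = ifelse(cum_tp + cum_fp > 0, cum_tp / (cum_tp + cum_fp), NA_real_)
  )
}

#' Average precision at IoU 0.5 for one class, and its mean over classes
#'
#' `average_precision_50()` computes the area under the precision envelope
#' of the score-ranked precision-recall curve (all-point interpolation:
#' precision at each recall level is replaced by the maximum precision at
#' any equal-or-higher recall, and the envelope is integrated over recall).
#' `mean_ap50()` averages AP over the classes present in the ground truth;
#' classes with no ground-truth instances are excluded from the mean rather
#' than counted as 0.
#'
#' @inheritParams pr_curve
#' @return `average_precision_50()`: scalar AP in `[0, 1]`, or `NA` when the
#'   class has no ground-truth instances. `mean_ap50()`: scalar mean AP.
#' @export
average_precision_50 <- function(preds, truths, class_id, iou_threshold = 0.5) {
  truths <- as_detections(truths)
  if (sum(truths$label == class_id) == 0L) return(NA_real_)
  pc <- pr_curve(preds, truths, class_id, iou_threshold)
  if (nrow(pc) == 0L || sum(pc$tp) == 0L) return(0)
  rec <- pc$recall
  prec <- pc$precision
  env <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * env)
}

#' @rdname average_precision_50
#' @export
mean_ap50 <- function(preds, truths, iou_threshold = 0.5) {
  truths <- as_detections(truths)
  classes <- sort(unique(truths$label))
  if (length(classes) == 0L) return(NA_real_)
  aps <- vapply(classes, function(cl) {
    average_precision_50(preds, truths, cl, iou_threshold)
  }, numeric(1))
  mean(aps)
}

#' Mean absolute FDI position error over matched pairs
#'
#' For each spatially matched (class-blind, IoU >= 0.5) prediction/truth
#' pair, the absolute difference of the two linear arch indices measures how
#' far along the arch the predicted numbering landed from the true tooth; a
#' pair whose labels sit on different arches contributes the cap 16 (the
#' arch length — there is no meaningful spatial distance across arches).
#' A low mean indicates the detector has learned the spatial structure of
#' the numbering even where the exact class is wrong.
#'
#' @param pairs Pair tibble from a class-blind [match_detections()] (columns
#'   `pred_label`, `true_label`), or a `tooth_matches` object.
#' @return Non-negative scalar; `NA` when there are no matched pairs.
#' @export
fdi_error <- function(pairs) {
  if (inherits(pairs, "tooth_matches")) pairs <- pairs$pairs
  if (nrow(pairs) == 0L) return(NA_real_)
  same <- (pairs$pred_label <= 16L) == (pairs$true_label <= 16L)
  d <- ifelse(same, abs(pairs$pred_label - pairs$true_label), 16)
  mean(d)
}

#' Mean confidence of correct predictions
#'
#' The average confidence score over true positives of a class-aware match
#' (IoU >= 0.5 and a consistent category): high values mean the detector is
#' confident exactly when it is right.
#'
#' @param pairs Pair tibble from a class-aware [match_detections()] (column
#'   `score`), or a `tooth_matches` object.
#' @return Scalar in `[0, 1]`; `NA` when there are no true positives.
#' @export
top1_conf <- function(pairs) {
  if (inherits(pairs, "tooth_matches")) pairs <- pairs$pairs
  if (nrow(pairs) == 0L) return(NA_real_)
  mean(pairs$score)
}

#' 32 x 32 tooth-class confusion matrix
#'
#' Built from class-blind spatially matched pairs: cell (true, predicted) is
#' incremented once per pair, so the diagonal counts correct numberings and
#' each off-diagonal cell a specific confusion (typically between adjacent
#' or contralateral teeth). The matrix total equals the number of matched
#' pairs.
#'
#' @param pairs Pair tibble from a class-blind [match_detections()], or a
#'   `tooth_matches` object.
#' @return 32 x 32 integer matrix; rows are true classes, columns predicted,
#'   dimnames are the FDI code strings in linear order.
#' @export
confusion_matrix <- function(pairs) {
  if (inherits(pairs, "tooth_matches")) pairs <- pairs$pairs
  codes <- sprintf("%d", linear_to_fdi(1:32))
  m <- matrix(0L, 32, 32, dimnames = list(true = codes, predicted = codes))
  if (nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      m[pairs$true_label[i], pairs$pred_label[i]] <-
        m[pairs$true_label[i], pairs$pred_label[i]] + 1L
    }
  }
  m
}

#' Macro-averaged one-vs-rest specificity for detection
#'
#' A detection task has no natural "true negative" box; specificity is
#' therefore defined one-vs-rest per class over the class-aware match: for
#' class c, the true negatives are the matched pairs involving neither c as
#' truth nor as prediction, and the false positives are the predictions of
#' class c that matched no ground truth of class c. Per-class specificities
#' `TN/(TN+FP)` are macro-averaged over the classes present in the data;
#' classes with no negatives are skipped. With 32 classes this sits near 1
#' unless one class floods the scene with false positives.
#'
#' @param match A class-aware `tooth_matches` object.
#' @return Scalar in `[0, 1]`; `NA` when no class has any negatives.
#' @export
specificity_detection <- function(match) {
  stopifnot(inherits(match, "tooth_matches"))
  pc <- match$per_class
  pc <- pc[pc$tp + pc$fp + pc$fn > 0, , drop = FALSE]  # classes present in the scene
  if (nrow(pc) == 0L) return(NA_real_)
  sp <- metric_specificity(pc$tn, pc$fp)
  if (all(is.na(sp))) return(NA_real_)
  mean(sp, na.rm = TRUE)
}

#' Full detection-evaluation report
#'
#' Runs both matchings at the IoU threshold — class-aware for the
#' counting rates and confidence, class-blind for the spatial numbering
#' error and the confusion matrix — plus per-class average precision, and
#' collects every metric in one object:
#' precision, sensitivity and F1 (micro over all classes, class-aware),
#' macro specificity, mAP50, the mean FDI position error, the mean
#' confidence of correct predictions, and the 32 x 32 confusion matrix.
#'
#' @param preds Predicted detections tibble (with scores).
#' @param truths Ground-truth detections tibble.
#' @param iou_threshold Spatial match threshold. Default 0.5.
#' @return An object of class `tooth_eval`; use [glance.tooth_eval()] for
#'   the one-row metric summary and [tidy.tooth_eval()] for per-class rows.
#' @export
evaluate_detections <- function(preds, truths, iou_threshold = 0.5) {
  preds <- as_detections(preds)
  truths <- as_detections(truths)
  m_aware <- match_detections(preds, truths, iou_threshold, class_aware = TRUE)
  m_blind <- match_detections(preds, truths, iou_threshold, class_aware = FALSE)
  tp <- nrow(m_aware$pairs)
  fp <- length(m_aware$fp)
  fn <- length(m_aware$fn)
  prec <- metric_precision(tp, fp)
  sens <- metric_sensitivity(tp, fn)
  classes <- sort(unique(truths$label))
  ap <- vapply(classes, function(cl) {
    average_precision_50(preds, truths, cl, iou_threshold)
  }, numeric(1))
  per_class <- dplyr::left_join(
    m_aware$per_class,
    tibble::tibble(label = classes, ap = ap),
    by = "label"
  )
  structure(
    list(
      match_aware = m_aware,
      match_blind = m_blind,
      precision = prec,
      sensitivity = sens,
      specificity = specificity_detection(m_aware),
      f1 = metric_f1(prec, sens),
      map50 = if (length(classes)) mean(ap) else NA_real_,
      fdi_error = fdi_error(m_blind),
      top1_conf = top1_conf(m_aware),
      confusion = confusion_matrix(m_blind),
      per_class = per_class,
      iou_threshold = iou_threshold
    ),
    class = "tooth_eval"
  )
}

#' @export
print.tooth_eval <- function(x, ...) {
  cat("<tooth_eval> detection evaluation at IoU >=", x$iou_threshold, "\n")
  print(glance(x))
  invisible(x)
}

#' One-row metric summary of an evaluation
#'
#' @param x A `tooth_eval` from [evaluate_detections()].
#' @param ... Unused.
#' @return One-row tibble: `n_preds`, `n_truths`, `tp`, `fp`, `fn`,
#'   `precision`, `sensitivity`, `specificity`, `f1`, `map50`, `fdi_error`,
#'   `top1_conf`.
#' @method glance tooth_eval
#' @export
glance.tooth_eval <- function(x, ...) {
  tibble::tibble(
    n_preds = x$match_aware$n_preds,
    n_truths = x$match_aware$n_truths,
    tp = nrow(x$match_aware$pairs),
    fp = length(x$match_aware$fp),
    fn = length(x$match_aware$fn),
    precision = x$precision,
    sensitivity = x$sensitivity,
    specificity = x$specificity,
    f1 = x$f1,
    map50 = x$map50,
    fdi_error = x$fdi_error,
    top1_conf = x$top1_conf
  )
}

#' Per-class view of an evaluation
#'
#' @param x A `tooth_eval`.
#' @param ... Unused.
#' @return Tibble with one row per tooth class: `label`, `fdi`, `tp`, `fp`,
#'   `fn`, `tn`, `precision`, `sensitivity`, `ap`.
#' @method tidy tooth_eval
#' @export
tidy.tooth_eval <- function(x, ...) {
  pc <- x$per_class
  dplyr::mutate(
    pc,
    fdi = sprintf("%d", linear_to_fdi(.data$label)),
    precision = metric_precision(.data$tp, .data$fp),
    sensitivity = metric_sensitivity(.data$tp, .data$fn),
    .after = "label"
  )
}

#' Confusion-matrix heatmap of an evaluation
#'
#' @param object A `tooth_eval`.
#' @param ... Unused.
#' @return A ggplot tile map of the 32 x 32 confusion matrix (true class on
#'   the vertical axis, predicted on the horizontal, FDI codes in linear
#'   arch order).
#' @method autoplot tooth_eval
#' @export
autoplot.tooth_eval <- function(object, ...) {
  codes <- sprintf("%d", linear_to_fdi(1:32))
  df <- tidyr::expand_grid(true = codes, predicted = codes)
  df$count <- as.vector(t(object$confusion))[
    match(paste(df$true, df$predicted),
          paste(rep(codes, each = 32), rep(codes, 32)))]
  df$true <- factor(df$true, levels = rev(codes))
  df$predicted <- factor(df$predicted, levels = codes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#0072B2") +
    ggplot2::labs(x = "predicted FDI", y = "true FDI",
                  title = "Tooth numbering confusion (matched pairs)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
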