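# shared fixtures and independent oracles, built in code at test time

# evenly spaced boxes for a given label sequence (pitch 60, width 50)
boxes_for <- function(labels, pitch = 60, width = 50, height = 80, x0 = 0,
                      score = 0.9) {
  n <- length(labels)
  centers <- x0 + pitch * seq_len(n)
  detections(
    x_min = centers - width / 2,
    y_min = 0,
    x_max = centers + width / 2,
    y_max = height,
    label = labels,
    score = score
  )
}

# random probability vector over 32 classes
random_dist <- function() {
  w <- stats::rexp(32)
  w / sum(w)
}

# brute-force average precision oracle: rank-by-rank PR points, then the
# all-point interpolated area computed by explicit max-scans (independent of
# the cummax-based production code)
ap_oracle <- function(preds, truths, class_id, iou_threshold = 0.5) {
  p <- preds[preds$label == class_id, , drop = FALSE]
  t <- truths[truths$label == class_id, , drop = FALSE]
  if (nrow(t) == 0L) return(NA_real_)
  p <- p[order(-p$score), , drop = FALSE]
  taken <- rep(FALSE, nrow(t))
  tp <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    best_j <- 0L
    best_iou <- -1
    for (j in seq_len(nrow(t))) {
      if (taken[j]) next
      v <- iou(p[i, ], t[j, ])
      if (v >= iou_threshold && v > best_iou) {
        best_iou <- v
        best_j <- j
      }
    }
    if (best_j > 0L) {
      taken[best_j] <- TRUE
      tp[i] <- TRUE
    }
  }
  if (!any(tp)) return(0)
  rec <- cumsum(tp) / nrow(t)
  prec <- cumsum(tp) / seq_along(tp)
  ap <- 0
  prev_r <- 0
  for (i in seq_along(tp)) {
    p_env <- max(prec[i:length(prec)])
    ap <- ap + (rec[i] - prev_r) * p_env
    prev_r <- rec[i]
  }
  ap
}

# random single-image detection scene (boxes roughly on a grid so some
# overlap, plus label and score noise) for AP cross-checks
random_scene <- function(n_truth = 6, n_classes = 4) {
  classes <- sample.int(32L, n_classes)
  truth <- purrr::map_dfr(seq_len(n_truth), function(i) {
    cx <- stats::runif(1, 0, 400)
    cy <- stats::runif(1, 0, 200)
    w <- stats::runif(1, 30, 60)
    h <- stats::runif(1, 40, 80)
    tibble::tibble(x_min = cx, y_min = cy, x_max = cx + w, y_max = cy + h,
                   label = sample(classes, 1L), score = 1)
  })
  n_pred <- stats::rpois(1, n_truth) + 1L
  preds <- purrr::map_dfr(seq_len(n_pred), function(i) {
    if (i <= n_truth && stats::runif(1) < 0.7) {
      b <- truth[i, ]
      jit <- stats::runif(4, -8, 8)
      tibble::tibble(
        x_min = b$x_min + jit[1], y_min = b$y_min + jit[2],
        x_max = b$x_max + jit[3], y_max = b$y_max + jit[4],
        label = if (stats::runif(1) < 0.8) b$label else sample(classes, 1L),
        score = stats::runif(1, 0.3, 1)
      )
    } else {
      cx <- stats::runif(1, 0, 400)
      cy <- stats::runif(1, 0, 200)
      tibble::tibble(x_min = cx, y_min = cy,
                     x_max = cx + stats::runif(1, 30, 60),
                     y_max = cy + stats::runif(1, 40, 80),
                     label = sample(classes, 1L),
                     score = stats::runif(1, 0.05, 1))
    }
  })
  preds <- preds[preds$x_max > preds$x_min & preds$y_max > preds$y_min, ]
  list(preds = as_detections(preds), truths = as_detections(truth),
       classes = classes)
}
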