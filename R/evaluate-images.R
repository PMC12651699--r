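#' Evaluate detections pooled over several images
#'
#' Detection metrics are defined per image (a prediction can only match a
#' ground truth from the same radiograph) but reported pooled over a test
#' set, with average precision ranking all of a class's predictions across
#' images by confidence. Both requirements are met by translating every
#' image onto its own disjoint horizontal band of one virtual canvas —
#' cross-image IoU is then exactly zero — and evaluating the pooled tables
#' once with [evaluate_detections()].
#'
#' @param preds,truths Detections tibbles with an `image_id` column.
#' @param iou_threshold Spatial match threshold. Default 0.5.
#' @return A `tooth_eval` object, as [evaluate_detections()].
#' @export
evaluate_images <- function(preds, truths, iou_threshold = 0.5) {
  for (nm in c("preds", "truths")) {
    df <- get(nm)
    if (!"image_id" %in% names(df)) {
      rlang::abort(sprintf("`%s` needs an `image_id` column.", nm),
                   class = c("dentalign_schema_error", "dentalign_error"))
    }
  }
  stray <- setdiff(unique(preds$image_id), unique(truths$image_id))
  if (length(stray) > 0) {
    rlang::abort(
      paste0("Predictions reference image id(s) absent from the ground truth: ",
             paste(stray, collapse = ", ")),
      class = c("dentalign_domain_error", "dentalign_error")
    )
  }
  ids <- sort(unique(c(preds$image_id, truths$image_id)))
  span <- max(c(preds$x_max, truths$x_max, 0)) + 1000
  shift <- function(df) {
    df$x_min <- df$x_min + span * (match(df$image_id, ids) - 1L)
    df$x_max <- df$x_max + span * (match(df$image_id, ids) - 1L)
    df
  }
  evaluate_detections(shift(preds), shift(truths), iou_threshold)
}
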