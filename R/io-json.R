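#' Read and write detection records as JSON
#'
#' Detector output travels in a COCO-flavoured JSON dialect: a flat array of
#' records, each with keys
#' `image_id` (string), `bbox` (`[x, y, width, height]` in pixels),
#' `category` (two-digit FDI code string), `score` (in `[0, 1]`), and
#' optionally `probs` (length-32 class-probability vector over the linear
#' arch index, summing to 1). On read, boxes are converted to the internal
#' corner convention (`x_min = x`, `x_max = x + width`) and categories to
#' linear indices; writing applies the inverse, so round trips are lossless.
#'
#' @param path JSON file path.
#' @return `read_detections()`: a detections tibble with an `image_id`
#'   column (and a `probs` list-column when any record carries one). An
#'   empty array yields an empty tibble.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Detections file not found: ", path),
                 class = c("dentalign_io_error", "dentalign_error"))
  }
  recs <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                   error = function(e) {
                     rlang::abort(paste0("Cannot parse JSON ", path, ": ",
                                         conditionMessage(e)),
                                  class = c("dentalign_parse_error", "dentalign_error"))
                   })
  if (length(recs) == 0L) {
    return(tibble::tibble(image_id = character(), x_min = numeric(),
                          y_min = numeric(), x_max = numeric(),
                          y_max = numeric(), label = integer(),
                          score = numeric()))
  }
  need_key <- function(r, key, i) {
    if (is.null(r[[key]])) {
      rlang::abort(sprintf("Detection record %d is missing key '%s'.", i, key),
                   class = c("dentalign_schema_error", "dentalign_error"))
    }
    r[[key]]
  }
  rows <- purrr::imap(recs, function(r, i) {
    bbox <- as.numeric(need_key(r, "bbox", i))
    if (length(bbox) != 4L || any(is.na(bbox)) || bbox[3] <= 0 || bbox[4] <= 0) {
      rlang::abort(sprintf(
        "Detection record %d: 'bbox' must be [x, y, width, height] with positive size.", i),
        class = c("dentalign_schema_error", "dentalign_error"))
    }
    score <- as.numeric(need_key(r, "score", i))
    if (length(score) != 1L || is.na(score) || score < 0 || score > 1) {
      rlang::abort(sprintf("Detection record %d: 'score' must be a number in [0, 1].", i),
                   class = c("dentalign_schema_error", "dentalign_error"))
    }
    category <- as.character(need_key(r, "category", i))
    label <- tryCatch(fdi_to_linear(category), error = function(e) {
      rlang::abort(sprintf("Detection record %d: 'category' %s is not a valid FDI code.",
                           i, category),
                   class = c("dentalign_schema_error", "dentalign_error"))
    })
    probs <- NULL
    if (!is.null(r$probs)) {
      probs <- as.numeric(r$probs)
      if (length(probs) != 32L || any(is.na(probs)) || any(probs < 0) ||
          abs(sum(probs) - 1) > 1e-6) {
        rlang::abort(sprintf(
          "Detection record %d: 'probs' must be 32 non-negative numbers summing to 1.", i),
          class = c("dentalign_schema_error", "dentalign_error"))
      }
    }
    tibble::tibble(
      image_id = as.character(need_key(r, "image_id", i)),
      x_min = bbox[1], y_min = bbox[2],
      x_max = bbox[1] + bbox[3], y_max = bbox[2] + bbox[4],
      label = label, score = score,
      probs = list(probs)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (all(vapply(out$probs, is.null, logical(1)))) out$probs <- NULL
  as_detections(out)
}

#' @param dets Detections tibble; an `image_id` column tags each record
#'   (default `"image"` when absent).
#' @rdname read_detections
#' @return `write_detections()`: the path, invisibly.
#' @export
write_detections <- function(dets, path) {
  dets <- as_detections(dets)
  if (any(dets$label == 0L)) {
    rlang::abort("Placeholders (label 0) have no FDI category and cannot be serialized as detections.",
                 class = c("dentalign_placeholder_index", "dentalign_error"))
  }
  ids <- if ("image_id" %in% names(dets)) dets$image_id else rep("image", nrow(dets))
  recs <- purrr::map(seq_len(nrow(dets)), function(i) {
    r <- list(
      image_id = ids[i],
      bbox = c(dets$x_min[i], dets$y_min[i],
               dets$x_max[i] - dets$x_min[i], dets$y_max[i] - dets$y_min[i]),
      category = sprintf("%d", linear_to_fdi(dets$label[i])),
      score = dets$score[i]
    )
    if ("probs" %in% names(dets) && !is.null(dets$probs[[i]])) {
      r$probs <- dets$probs[[i]]
    }
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
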