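#' Detection record tibbles
#'
#' Throughout the package a set of detections (or ground-truth annotations)
#' is a tibble with one row per bounding box and columns:
#' \describe{
#'   \item{x_min, y_min, x_max, y_max}{box corners in pixels, 0-based
#'     half-open (`x_min < x_max`, `y_min < y_max`); placeholder rows carry a
#'     synthesized box}
#'   \item{label}{linear arch index 1..32 of the (predicted or true) tooth;
#'     0 only for missing-tooth placeholders}
#'   \item{score}{detector confidence in `[0, 1]`; 0 for placeholders}
#' }
#' An optional `probs` list-column may hold per-detection length-32 class
#' probability vectors, and an `image_id` column may tag the source image.
#'
#' `detections()` builds such a tibble from vectors; `as_detections()`
#' validates an existing data frame and returns it as a tibble.
#'
#' @param x_min,y_min,x_max,y_max Numeric box corners.
#' @param label Integer linear indices (0 allowed for placeholders), or FDI
#'   codes as character strings.
#' @param score Numeric scores in `[0, 1]`; defaults to 1.
#' @param probs Optional list of length-32 probability vectors.
#' @return A validated detections tibble.
#' @examples
#' detections(x_min = c(0, 60), y_min = 0, x_max = c(50, 110), y_max = 80,
#'            label = c("11", "21"), score = c(0.9, 0.8))
#' @export
detections <- function(x_min, y_min, x_max, y_max, label, score = 1, probs = NULL) {
  if (is.character(label)) label <- fdi_to_linear(label)
  out <- tibble::tibble(
    x_min = as.numeric(x_min),
    y_min = as.numeric(y_min),
    x_max = as.numeric(x_max),
    y_max = as.numeric(y_max),
    label = as.integer(label),
    score = as.numeric(score)
  )
  if (!is.null(probs)) out$probs <- probs
  as_detections(out)
}

#' @param x A data frame with the columns above.
#' @rdname detections
#' @export
as_detections <- function(x) {
  need <- c("x_min", "y_min", "x_max", "y_max", "label", "score")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("Detections are missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = c("dentalign_schema_error", "dentalign_error")
    )
  }
  x <- tibble::as_tibble(x)
  x$label <- as.integer(x$label)
  if (any(is.na(x$label)) || any(x$label < 0L | x$label > 32L)) {
    rlang::abort("Detection labels must be linear indices in 0..32.",
                 class = c("dentalign_schema_error", "dentalign_error"))
  }
  if (any(is.na(x$score)) || any(x$score < 0 | x$score > 1)) {
    rlang::abort("Detection scores must lie in [0, 1].",
                 class = c("dentalign_schema_error", "dentalign_error"))
  }
  real <- x$label > 0L
  if (any(real & (x$x_min >= x$x_max | x$y_min >= x$y_max))) {
    rlang::abort("Real detections must have x_min < x_max and y_min < y_max.",
                 class = c("dentalign_degenerate_box", "dentalign_error"))
  }
  x
}
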