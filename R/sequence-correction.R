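#' Sort detections left-to-right
#'
#' The first stage of the numbering-correction pipeline: detections are
#' ordered by the horizontal coordinate `x_min` ascending, so the label
#' sequence reads left to right as the teeth do on the radiograph. Ties on
#' `x_min` break by `y_min`, then by input order (stable).
#'
#' @param dets Detections tibble (see [detections()]).
#' @return The same tibble, reordered.
#' @export
sort_by_xmin <- function(dets) {
  dets <- as_detections(dets)
  dets[order(dets$x_min, dets$y_min), , drop = FALSE]
}

#' Gap rule controlling missing-tooth placeholder insertion
#'
#' Between each pair of horizontally adjacent detections the pipeline
#' measures the empty gap `x_min(next) - x_max(prev)`. A gap larger than a
#' preset threshold is read as one or more missing teeth and filled with
#' placeholder records (label 0, score 0). The threshold is by default
#' relative — a fraction of the median box width of the sequence, which makes
#' it scale-free across radiograph resolutions — or can be given in absolute
#' pixels. The number of placeholders per gap is `round(gap / pitch)`
#' (at least 1) where pitch is the median centre-to-centre spacing of the
#' sequence, capped at `max_insertions` because gaps spanning more than two
#' missing teeth are beyond what a single periapical view supports.
#'
#' @param threshold Positive gap threshold: a fraction of the median box
#'   width when `mode = "relative"` (default 0.5), or pixels when
#'   `mode = "absolute"`.
#' @param mode `"relative"` or `"absolute"`.
#' @param max_insertions Maximum placeholders inserted into one gap
#'   (default 2).
#' @return An object of class `gap_rule`.
#' @export
gap_rule <- function(threshold = 0.5, mode = c("relative", "absolute"),
                     max_insertions = 2L) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    rlang::abort("`threshold` must be a single positive number.",
                 class = c("dentalign_config_error", "dentalign_error"))
  }
  max_insertions <- as.integer(max_insertions)
  if (is.na(max_insertions) || max_insertions < 1L) {
    rlang::abort("`max_insertions` must be an integer >= 1.",
                 class = c("dentalign_config_error", "dentalign_error"))
  }
  structure(
    list(threshold = threshold, mode = mode, max_insertions = max_insertions),
    class = "gap_rule"
  )
}

#' @export
print.gap_rule <- function(x, ...) {
  cat(sprintf("<gap_rule> threshold %g (%s), max %d insertion(s) per gap\n",
              x$threshold, x$mode, x$max_insertions))
  invisible(x)
}

#' Insert missing-tooth placeholders into a sorted detection sequence
#'
#' Applies the [gap_rule()] to each adjacent pair of a sorted sequence and
#' inserts placeholder detections (label 0, score 0, a synthesized box filling
#' the gap) where the horizontal gap exceeds the threshold. The placeholders
#' keep the sequence's slot structure aligned with the physical arch so the
#' sliding-template correction can line up the surviving teeth.
#'
#' @param dets Sorted detections tibble.
#' @param rule A [gap_rule()].
#' @return Detections tibble with placeholder rows inserted, still sorted;
#'   the non-placeholder rows are unchanged.
#' @export
insert_missing_placeholders <- function(dets, rule = gap_rule()) {
  dets <- as_detections(dets)
  n <- nrow(dets)
  if (n < 2L) return(dets)
  if (is.unsorted(dets$x_min)) {
    rlang::abort("Detections must be sorted by x_min (see sort_by_xmin()).",
                 class = c("dentalign_config_error", "dentalign_error"))
  }
  widths <- dets$x_max - dets$x_min
  med_w <- stats::median(widths)
  thr <- if (rule$mode == "relative") rule$threshold * med_w else rule$threshold
  centers <- (dets$x_min + dets$x_max) / 2
  spacings <- diff(centers)
  gaps <- dets$x_min[-1L] - dets$x_max[-n]
  # pitch from the presumed-intact pairs: spacings across a missing-tooth gap
  # would inflate the estimate, especially in short sequences. With no intact
  # pair left, fall back to crown width: adjacent teeth nearly abut, so the
  # centre spacing exceeds the crown width only by the interproximal margin
  intact <- gaps <= thr
  pitch <- if (any(intact)) stats::median(spacings[intact]) else 1.2 * med_w
  med_h <- stats::median(dets$y_max - dets$y_min)
  med_y <- stats::median(dets$y_min)

  pieces <- vector("list", 2L * n - 1L)
  for (i in seq_len(n - 1L)) {
    pieces[[2L * i - 1L]] <- dets[i, , drop = FALSE]
    gap <- dets$x_min[i + 1L] - dets$x_max[i]
    if (gap > thr) {
      k <- if (is.finite(pitch) && pitch > 0) round(gap / pitch) else 1
      k <- min(max(1L, as.integer(k)), rule$max_insertions)
      w <- min(med_w, gap)
      ph_centers <- dets$x_max[i] + gap * seq_len(k) / (k + 1)
      ph <- dets[rep.int(1L, k), , drop = FALSE]
      ph$x_min <- ph_centers - w / 2
      ph$x_max <- ph_centers + w / 2
      ph$y_min <- rep(med_y, k)
      ph$y_max <- rep(med_y + med_h, k)
      ph$label <- rep(0L, k)
      ph$score <- rep(0, k)
      if ("probs" %in% names(ph)) ph$probs <- rep(list(NULL), k)
      pieces[[2L * i]] <- ph
    }
  }
  pieces[[2L * n - 1L]] <- dets[n, , drop = FALSE]
  out <- dplyr::bind_rows(pieces[!vapply(pieces, is.null, logical(1))])
  out[order(out$x_min), , drop = FALSE]
}

#' Count detected teeth per arch
#'
#' Line 1 of the correction algorithm: `U` counts labels on the upper arch
#' (linear index 1..16), `L` on the lower (17..32). Placeholders (label 0)
#' carry no arch evidence and are counted in neither.
#'
#' @param labels Integer vector of linear indices (0 allowed).
#' @return Named integer vector `c(U = ..., L = ...)`.
#' @export
count_arches <- function(labels) {
  labels <- as.integer(labels)
  c(U = sum(labels >= 1L & labels <= 16L),
    L = sum(labels >= 17L & labels <= 32L))
}

#' Select the arch template from the arch counts
#'
#' Line 2: the upper template is chosen iff `U > L`; everything else —
#' including ties — goes to the lower template.
#'
#' @param U,L Arch counts from [count_arches()].
#' @return An [arch_template()].
#' @export
select_template <- function(U, L) {
  arch_template(if (U > L) "upper" else "lower")
}

#' Best sliding alignment of a label sequence against an arch template
#'
#' Lines 3-4: the ideal 16-tooth template is slid along the detected label
#' sequence; for each offset the match count is the number of slots whose
#' label equals the template value at that slot, and the best offset is the
#' argmax (smallest offset on ties). Placeholders (0) never match.
#'
#' @param labels Integer vector of linear indices (0 allowed), length 1..16.
#' @param template An [arch_template()], or an integer template sequence.
#' @return List with `offset` (0-based, in `0..16 - n`) and `M` (the match
#'   count at that offset).
#' @examples
#' best_alignment(c(3, 4, 9, 6), arch_template("upper")) # offset 2, M 3
#' @export
best_alignment <- function(labels, template) {
  labels <- as.integer(labels)
  seq_t <- if (inherits(template, "arch_template")) template$sequence else as.integer(template)
  n <- length(labels)
  if (n < 1L) {
    rlang::abort("Label sequence must contain at least one detection.",
                 class = c("dentalign_config_error", "dentalign_error"))
  }
  if (n > length(seq_t)) {
    rlang::abort(
      sprintf(paste0(
        "Sequence of %d labels cannot fit a %d-tooth arch template; ",
        "the image likely spans both arches or contains duplicate detections."),
        n, length(seq_t)),
      class = c("dentalign_sequence_too_long", "dentalign_error")
    )
  }
  offsets <- 0:(length(seq_t) - n)
  counts <- vapply(offsets, function(o) {
    sum(labels == seq_t[o + seq_len(n)])
  }, integer(1))
  best <- which.max(counts)  # which.max returns the first maximum: smallest offset
  list(offset = offsets[best], M = counts[best])
}

#' Brute-force alignment oracle
#'
#' A deliberately naive re-statement of [best_alignment()] — an explicit
#' double loop over offsets and slots — kept separate from the production
#' path so the two can be checked against each other.
#'
#' @inheritParams best_alignment
#' @return As [best_alignment()].
#' @export
brute_force_alignment <- function(labels, template) {
  labels <- as.integer(labels)
  seq_t <- if (inherits(template, "arch_template")) template$sequence else as.integer(template)
  n <- length(labels)
  if (n < 1L) {
    rlang::abort("Label sequence must contain at least one detection.",
                 class = c("dentalign_config_error", "dentalign_error"))
  }
  if (n > length(seq_t)) {
    rlang::abort("Sequence longer than the template.",
                 class = c("dentalign_sequence_too_long", "dentalign_error"))
  }
  best_offset <- 0L
  best_m <- -1L
  for (o in 0:(length(seq_t) - n)) {
    m <- 0L
    for (j in seq_len(n)) {
      if (labels[j] == seq_t[o + j]) m <- m + 1L
    }
    if (m > best_m) {
      best_m <- m
      best_offset <- o
    }
  }
  list(offset = best_offset, M = best_m)
}

#' Apply the template correction at a chosen offset
#'
#' Lines 5-6: when the match count `M` exceeds 1 (at least two agreeing
#' anchor teeth), every slot whose label is positive and disagrees with the
#' template value at its slot is rewritten to that template value;
#' placeholder slots (label 0) keep 0 — the guard `p_i > 0` — but the
#' template value they would take is reported in `missing_slots` as the
#' inferred number of the missing tooth. When `M <= 1` the labels are
#' returned unchanged (a single agreeing tooth is no evidence of the
#' alignment), with `missing_slots` still reported against the offset for
#' display.
#'
#' @param labels Integer label sequence.
#' @param template An [arch_template()] (or integer sequence).
#' @param offset,M Result of [best_alignment()].
#' @return List with `corrected` (integer vector), `modified` (logical
#'   per-slot flags) and `missing_slots` (tibble with `slot`,
#'   `inferred_linear`, `inferred_fdi`).
#' @export
apply_correction <- function(labels, template, offset, M) {
  labels <- as.integer(labels)
  seq_t <- if (inherits(template, "arch_template")) template$sequence else as.integer(template)
  n <- length(labels)
  slot_values <- seq_t[offset + seq_len(n)]
  corrected <- labels
  modified <- rep(FALSE, n)
  if (M > 1L) {
    change <- labels > 0L & labels != slot_values
    corrected[change] <- slot_values[change]
    modified <- change
  }
  ph <- which(labels == 0L)
  missing_slots <- tibble::tibble(
    slot = ph,
    inferred_linear = slot_values[ph],
    inferred_fdi = if (length(ph)) sprintf("%d", linear_to_fdi(slot_values[ph])) else character()
  )
  list(corrected = corrected, modified = modified, missing_slots = missing_slots)
}

#' Correct a tooth-numbering detection sequence
#'
#' The full post-processing pipeline for one periapical image: sort the
#' detections left-to-right, insert missing-tooth placeholders where the
#' horizontal gaps demand them, choose the arch whose teeth dominate the
#' sequence, slide that arch's ideal numbering template to the
#' maximum-overlap offset, and — when at least two teeth anchor the
#' alignment — rewrite disagreeing labels to the template numbering.
#' Placeholder slots keep label 0 and report the tooth number the template
#' infers for the gap.
#'
#' @param dets Detections tibble for one image (one arch; at most 16 teeth).
#' @param rule A [gap_rule()] controlling placeholder insertion.
#' @param try_reversed Also score the reversed template and use it if it
#'   matches strictly better (for mirrored acquisitions). Default `FALSE`.
#' @return An object of class `tooth_correction`; see [tidy.tooth_correction()]
#'   and [glance.tooth_correction()] for tabular views. Fields include
#'   `sequence` (the sorted, placeholder-augmented detections),
#'   `original_labels`, `corrected_labels`, `arch`, `offset`, `match_count`,
#'   `modified`, `missing_slots` and `reversed`.
#' @examples
#' d <- detections(x_min = c(0, 60, 120, 180), y_min = 0,
#'                 x_max = c(50, 110, 170, 230), y_max = 80,
#'                 label = c(3, 4, 9, 6), score = 0.9)
#' correct_sequence(d)$corrected_labels # 3 4 5 6
#' @export
correct_sequence <- function(dets, rule = gap_rule(), try_reversed = FALSE) {
  dets <- as_detections(dets)
  if (nrow(dets) == 0L) {
    return(new_tooth_correction(
      sequence = dets, original = integer(), corrected = integer(),
      arch = NA_character_, offset = NA_integer_, M = 0L,
      modified = logical(), missing_slots = apply_correction(integer(0), 1:16, 0L, 0L)$missing_slots,
      rule = rule, reversed = FALSE
    ))
  }
  seqd <- insert_missing_placeholders(sort_by_xmin(dets), rule)
  labels <- seqd$label
  counts <- count_arches(labels)
  template <- select_template(counts[["U"]], counts[["L"]])
  if (length(labels) > 16L) {
    rlang::abort(
      sprintf(paste0(
        "Sequence of %d slots (after placeholder insertion) cannot fit a ",
        "16-tooth arch template."), length(labels)),
      class = c("dentalign_sequence_too_long", "dentalign_error")
    )
  }
  al <- best_alignment(labels, template)
  seq_used <- template$sequence
  reversed <- FALSE
  if (isTRUE(try_reversed)) {
    al_rev <- best_alignment(labels, rev(template$sequence))
    if (al_rev$M > al$M) {
      al <- al_rev
      seq_used <- rev(template$sequence)
      reversed <- TRUE
    }
  }
  res <- apply_correction(labels, seq_used, al$offset, al$M)
  new_tooth_correction(
    sequence = seqd, original = labels, corrected = res$corrected,
    arch = template$arch, offset = al$offset, M = al$M,
    modified = res$modified, missing_slots = res$missing_slots,
    rule = rule, reversed = reversed
  )
}

new_tooth_correction <- function(sequence, original, corrected, arch, offset,
                                 M, modified, missing_slots, rule, reversed) {
  structure(
    list(
      sequence = sequence,
      original_labels = original,
      corrected_labels = corrected,
      arch = arch,
      offset = offset,
      match_count = M,
      modified = modified,
      missing_slots = missing_slots,
      rule = rule,
      reversed = reversed
    ),
    class = "tooth_correction"
  )
}

#' @export
print.tooth_correction <- function(x, ...) {
  n <- length(x$original_labels)
  cat(sprintf("<tooth_correction> %d slot(s), arch %s, offset %s, M = %d%s\n",
              n, x$arch %||% "?",
              if (is.na(x$offset)) "-" else x$offset, x$match_count,
              if (x$reversed) " (reversed template)" else ""))
  if (n > 0) {
    fmt <- function(l) ifelse(l == 0L, "(0)", sprintf("%d", vapply(l, function(v) {
      if (v == 0L) 0L else linear_to_fdi(v)
    }, integer(1))))
    cat("  original : ", paste(fmt(x$original_labels), collapse = " "), "\n", sep = "")
    cat("  corrected: ", paste(fmt(x$corrected_labels), collapse = " "), "\n", sep = "")
  }
  if (nrow(x$missing_slots) > 0) {
    cat("  missing  : slot ",
        paste(sprintf("%d (tooth %s)", x$missing_slots$slot, x$missing_slots$inferred_fdi),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Per-slot view of a corrected sequence
#'
#' @param x A `tooth_correction` from [correct_sequence()].
#' @param ... Unused.
#' @return A tibble with one row per slot: `slot`, the box `x_min`/`x_max`,
#'   `original` and `corrected` linear labels, FDI code strings (`NA` for
#'   placeholders), `score`, and flags `placeholder` and `modified`;
#'   placeholder rows carry the template-inferred tooth in `inferred_fdi`.
#' @method tidy tooth_correction
#' @export
tidy.tooth_correction <- function(x, ...) {
  n <- length(x$original_labels)
  fdi_or_na <- function(l) {
    ifelse(l == 0L, NA_character_,
           sprintf("%d", vapply(l, function(v) if (v == 0L) NA_integer_ else linear_to_fdi(v), integer(1))))
  }
  out <- tibble::tibble(
    slot = seq_len(n),
    x_min = x$sequence$x_min,
    x_max = x$sequence$x_max,
    original = x$original_labels,
    corrected = x$corrected_labels,
    original_fdi = fdi_or_na(x$original_labels),
    corrected_fdi = fdi_or_na(x$corrected_labels),
    score = x$sequence$score,
    placeholder = x$original_labels == 0L,
    modified = x$modified,
    inferred_fdi = NA_character_
  )
  if (nrow(x$missing_slots) > 0) {
    out$inferred_fdi[x$missing_slots$slot] <- x$missing_slots$inferred_fdi
  }
  out
}

#' One-row summary of a corrected sequence
#'
#' @param x A `tooth_correction`.
#' @param ... Unused.
#' @return A one-row tibble: `n_slots`, `n_teeth` (non-placeholder),
#'   `n_placeholders`, `arch`, `offset`, `match_count`, `n_modified`,
#'   `reversed`.
#' @method glance tooth_correction
#' @export
glance.tooth_correction <- function(x, ...) {
  tibble::tibble(
    n_slots = length(x$original_labels),
    n_teeth = sum(x$original_labels > 0L),
    n_placeholders = sum(x$original_labels == 0L),
    arch = x$arch,
    offset = x$offset,
    match_count = x$match_count,
    n_modified = sum(x$modified),
    reversed = x$reversed
  )
}

#' Plot a corrected sequence along the image axis
#'
#' @param object A `tooth_correction`.
#' @param ... Unused.
#' @return A ggplot showing each slot's box span with the original and
#'   corrected FDI labels; modified slots and placeholders are highlighted.
#' @method autoplot tooth_correction
#' @export
autoplot.tooth_correction <- function(object, ...) {
  df <- tidy(object)
  df$status <- ifelse(df$placeholder, "missing (placeholder)",
                      ifelse(df$modified, "corrected", "kept"))
  df$shown <- ifelse(df$placeholder,
                     paste0("(", df$inferred_fdi, ")"), df$corrected_fdi)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = 0, ymax = 1, fill = .data$status),
      colour = "grey30", alpha = 0.6
    ) +
    ggplot2::geom_text(
      ggplot2::aes(x = (.data$x_min + .data$x_max) / 2, y = 0.5,
                   label = .data$shown)
    ) +
    ggplot2::scale_fill_manual(values = c(
      "kept" = "grey85", "corrected" = "#56B4E9",
      "missing (placeholder)" = "#F0E442"
    )) +
    ggplot2::labs(x = "image x (px)", y = NULL, fill = NULL,
                  title = "Corrected tooth-numbering sequence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
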