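#' Configuration of a synthetic detection scenario
#'
#' The generator emulates what an FDI tooth-numbering detector emits for one
#' periapical field of view: 2-8 consecutive teeth of a single arch laid out
#' left-to-right at roughly regular pitch, with the failure modes that real
#' periapical radiographs produce — adjacent-tooth label confusion (the
#' dominant error mode, since neighbouring teeth share imaging features),
#' dropped teeth that leave a horizontal gap (extractions, implants the
#' detector skips), occasional spurious boxes, and confidence scores that run
#' lower for corrupted detections (damaged or ambiguous teeth) than for
#' clean ones.
#'
#' @param arch `"upper"`, `"lower"`, or `"either"` (drawn per case).
#' @param n_teeth Number of consecutive teeth in view, 2..8. Default 5.
#' @param start_index First (viewer-left) linear index of the run, or `NULL`
#'   to draw it uniformly among the starts that keep the run inside the
#'   arch.
#' @param pitch Mean centre-to-centre tooth spacing in pixels. Default 60.
#' @param box_width,box_height Mean box dimensions in pixels. Defaults 50
#'   and 80.
#' @param jitter Fractional uniform jitter applied to pitch and box
#'   dimensions. Default 0.05.
#' @param p_neighbor_shift Probability a surviving tooth's label is replaced
#'   by a same-arch neighbour at distance 1. Default 0.2.
#' @param p_drop Probability a tooth is omitted, leaving its gap.
#'   Default 0.1.
#' @param p_spurious Probability, per interior gap, of an extra off-grid box
#'   with a random label. Default 0.05.
#' @param score_clean,score_corrupt Beta shape parameters `c(a, b)` of the
#'   confidence-score distributions for clean and corrupted detections.
#'   Defaults `c(18, 2)` (mean 0.9) and `c(6, 4)` (mean 0.6).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(arch = c("either", "upper", "lower"),
                            n_teeth = 5L,
                            start_index = NULL,
                            pitch = 60,
                            box_width = 50,
                            box_height = 80,
                            jitter = 0.05,
                            p_neighbor_shift = 0.2,
                            p_drop = 0.1,
                            p_spurious = 0.05,
                            score_clean = c(18, 2),
                            score_corrupt = c(6, 4)) {
  arch <- match.arg(arch)
  n_teeth <- as.integer(n_teeth)
  if (is.na(n_teeth) || n_teeth < 2L || n_teeth > 8L) {
    rlang::abort("`n_teeth` must be an integer in 2..8 (one periapical field of view).",
                 class = c("dentalign_config_error", "dentalign_error"))
  }
  probs <- c(p_neighbor_shift = p_neighbor_shift, p_drop = p_drop,
             p_spurious = p_spurious)
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("Corruption probabilities must lie in [0, 1].",
                 class = c("dentalign_config_error", "dentalign_error"))
  }
  if (pitch <= 0 || box_width <= 0 || box_height <= 0 || jitter < 0 || jitter >= 1) {
    rlang::abort("Geometry parameters must be positive (jitter in [0, 1)).",
                 class = c("dentalign_config_error", "dentalign_error"))
  }
  if (!is.null(start_index)) {
    start_index <- as.integer(start_index)
    check_no_placeholder(start_index)
    arch_lo <- if (start_index <= 16L) 1L else 17L
    if (start_index + n_teeth - 1L > arch_lo + 15L) {
      rlang::abort("`start_index` + `n_teeth` - 1 must stay within one arch.",
                   class = c("dentalign_config_error", "dentalign_error"))
    }
    if (arch != "either") {
      want_lo <- if (arch == "upper") 1L else 17L
      if (arch_lo != want_lo) {
        rlang::abort("`start_index` lies on a different arch than `arch`.",
                     class = c("dentalign_config_error", "dentalign_error"))
      }
    }
  }
  structure(
    list(arch = arch, n_teeth = n_teeth, start_index = start_index,
         pitch = pitch, box_width = box_width, box_height = box_height,
         jitter = jitter, p_neighbor_shift = p_neighbor_shift,
         p_drop = p_drop, p_spurious = p_spurious,
         score_clean = score_clean, score_corrupt = score_corrupt),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<scenario_config> %s arch, %d teeth, pitch %g px, box %gx%g px, jitter %g\n",
    "  p(neighbour shift) %g, p(drop) %g, p(spurious) %g\n"),
    x$arch, x$n_teeth, x$pitch, x$box_width, x$box_height, x$jitter,
    x$p_neighbor_shift, x$p_drop, x$p_spurious))
  invisible(x)
}

runif_jitter <- function(n, mean, frac) {
  mean * stats::runif(n, 1 - frac, 1 + frac)
}

#' Generate the clean ground-truth layout of one scenario
#'
#' Draws `n_teeth` boxes left-to-right at jittered pitch with labels forming
#' a consecutive run of the arch template starting at `start_index` (drawn
#' uniformly when unset). Uses the R session RNG; fix it with `set.seed()`
#' or use [generate_batch()] for seeded streams.
#'
#' @param cfg A [scenario_config()].
#' @return A detections tibble of clean ground truth (scores 1).
#' @export
generate_layout <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  arch <- cfg$arch
  if (arch == "either") arch <- sample(c("upper", "lower"), 1L)
  start <- cfg$start_index
  if (is.null(start)) {
    lo <- if (arch == "upper") 1L else 17L
    start <- lo + sample.int(16L - cfg$n_teeth + 1L, 1L) - 1L
  }
  n <- cfg$n_teeth
  steps <- runif_jitter(n - 1L, cfg$pitch, cfg$jitter)
  centers <- cumsum(c(cfg$pitch, steps))
  w <- runif_jitter(n, cfg$box_width, cfg$jitter)
  h <- runif_jitter(n, cfg$box_height, cfg$jitter)
  y0 <- runif_jitter(n, 10, cfg$jitter)
  detections(
    x_min = centers - w / 2,
    y_min = y0,
    x_max = centers + w / 2,
    y_max = y0 + h,
    label = start:(start + n - 1L),
    score = 1
  )
}

#' Corrupt a clean layout into detector-like output
#'
#' Applies, independently per tooth: omission with probability `p_drop`
#' (the box disappears, leaving its horizontal gap); label replacement by a
#' uniformly chosen same-arch neighbour at distance 1 with probability
#' `p_neighbor_shift`; and a confidence score drawn from the clean Beta
#' model for untouched teeth or the lower corrupted model for shifted ones.
#' Each interior gap then receives, with probability `p_spurious`, one extra
#' box with a uniformly random label and a corrupted-model score.
#'
#' @param truth Clean layout from [generate_layout()].
#' @param cfg The [scenario_config()].
#' @return An object of class `scenario_case`: list with `truth`,
#'   `observed` (both detections tibbles) and `provenance` (tibble with one
#'   row per observed or dropped item: `truth_slot`, `kind` in
#'   clean/shifted/dropped/spurious, `true_label`, `observed_label`).
#' @export
corrupt <- function(truth, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  truth <- as_detections(truth)
  n <- nrow(truth)
  dropped <- stats::runif(n) < cfg$p_drop
  shifted <- !dropped & stats::runif(n) < cfg$p_neighbor_shift
  obs_label <- truth$label
  for (i in which(shifted)) {
    nb <- neighbour_labels(truth$label[i])
    obs_label[i] <- if (length(nb) == 1L) nb else sample(nb, 1L)
  }
  score <- numeric(n)
  score[!shifted] <- stats::rbeta(sum(!shifted), cfg$score_clean[1], cfg$score_clean[2])
  score[shifted] <- stats::rbeta(sum(shifted), cfg$score_corrupt[1], cfg$score_corrupt[2])

  observed <- truth
  observed$label <- obs_label
  observed$score <- score
  kind <- ifelse(dropped, "dropped", ifelse(shifted, "shifted", "clean"))
  prov <- tibble::tibble(
    truth_slot = seq_len(n),
    kind = kind,
    true_label = truth$label,
    observed_label = ifelse(dropped, NA_integer_, obs_label)
  )
  observed <- observed[!dropped, , drop = FALSE]

  if (n >= 2L && cfg$p_spurious > 0) {
    for (i in seq_len(n - 1L)) {
      if (stats::runif(1) < cfg$p_spurious) {
        cx <- (truth$x_max[i] + truth$x_min[i + 1L]) / 2
        w <- cfg$box_width * 0.8
        sp <- detections(
          x_min = cx - w / 2, y_min = truth$y_min[i],
          x_max = cx + w / 2, y_max = truth$y_max[i],
          label = sample.int(32L, 1L),
          score = stats::rbeta(1, cfg$score_corrupt[1], cfg$score_corrupt[2])
        )
        observed <- dplyr::bind_rows(observed, sp)
        prov <- dplyr::bind_rows(prov, tibble::tibble(
          truth_slot = NA_integer_, kind = "spurious",
          true_label = NA_integer_, observed_label = sp$label
        ))
      }
    }
  }
  observed <- observed[order(observed$x_min, observed$y_min), , drop = FALSE]
  structure(
    list(truth = truth, observed = observed, provenance = prov, config = cfg),
    class = "scenario_case"
  )
}

# same-arch neighbours at distance 1 on the linear axis
neighbour_labels <- function(idx) {
  lo <- if (idx <= 16L) 1L else 17L
  cand <- c(idx - 1L, idx + 1L)
  cand[cand >= lo & cand <= lo + 15L]
}

#' @export
print.scenario_case <- function(x, ...) {
  cat(sprintf("<scenario_case> %d true teeth (%s..%s), %d observed; %s\n",
              nrow(x$truth),
              linear_to_fdi(x$truth$label[1]),
              linear_to_fdi(x$truth$label[nrow(x$truth)]),
              nrow(x$observed),
              paste(sprintf("%d %s", table(x$provenance$kind),
                            names(table(x$provenance$kind))), collapse = ", ")))
  invisible(x)
}

#' Generate a seeded batch of scenarios
#'
#' Draws `n_cases` independent scenario cases. The batch seed initialises a
#' stream of per-case seeds (each recorded in the case), so any case can be
#' regenerated on its own and the whole batch is reproducible byte for
#' byte.
#'
#' @param cfg A [scenario_config()].
#' @param n_cases Number of cases, >= 1.
#' @param seed Integer batch seed.
#' @return A list of `scenario_case` objects (class `scenario_batch`).
#' @export
generate_batch <- function(cfg, n_cases, seed = 1L) {
  stopifnot(inherits(cfg, "scenario_config"))
  n_cases <- as.integer(n_cases)
  if (is.na(n_cases) || n_cases < 1L) {
    rlang::abort("`n_cases` must be >= 1.", class = c("dentalign_empty_batch", "dentalign_error"))
  }
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max - 1L, n_cases)
  cases <- purrr::map(case_seeds, function(s) {
    set.seed(s)
    case <- corrupt(generate_layout(cfg), cfg)
    case$seed <- s
    case
  })
  structure(cases, class = c("scenario_batch", "list"))
}

#' @export
print.scenario_batch <- function(x, ...) {
  cat(sprintf("<scenario_batch> %d case(s)\n", length(x)))
  invisible(x)
}

#' Measure what sequence correction buys on a scenario batch
#'
#' For every case, the observed detections are scored against the ground
#' truth before and after [correct_sequence()]: label accuracy and the mean
#' FDI position error are computed over spatially matched (class-blind,
#' IoU >= 0.5) pairs. Missing-tooth detection is scored as recall over the
#' interior drops — dropped teeth whose flanking neighbours both survive, so
#' that a measurable gap exists between two boxes (an edge drop leaves no
#' gap and is invisible to any gap-based mechanism).
#' `missing_recall_eligible` restricts further to gaps that exceed the rule
#' threshold and hold at most `rule$max_insertions` dropped teeth, the
#' regime the gap mechanism is designed for.
#'
#' @param cases A `scenario_batch` (or list of `scenario_case`).
#' @param rule A [gap_rule()].
#' @return An object of class `correction_gain`: list with `per_case`
#'   (tibble, one row per case) and `summary` (one-row tibble with
#'   `accuracy_pre`, `accuracy_post`, `fdi_error_pre`, `fdi_error_post`,
#'   `missing_recall`, `missing_recall_eligible`, `n_cases`).
#' @export
evaluate_correction_gain <- function(cases, rule = gap_rule()) {
  if (length(cases) == 0L) {
    rlang::abort("Empty scenario batch.", class = c("dentalign_empty_batch", "dentalign_error"))
  }
  per_case <- purrr::map_dfr(seq_along(cases), function(ci) {
    case <- cases[[ci]]
    truth <- case$truth
    obs <- case$observed
    pre <- case_label_stats(obs, truth)
    corr <- tryCatch(correct_sequence(obs, rule),
                     dentalign_sequence_too_long = function(e) NULL)
    if (is.null(corr)) {
      post <- pre
      miss <- missing_slot_stats(case, obs, rule)
    } else {
      keep <- corr$original_labels > 0L
      obs_post <- corr$sequence[keep, , drop = FALSE]
      obs_post$label <- corr$corrected_labels[keep]
      post <- case_label_stats(obs_post, truth)
      miss <- missing_slot_stats(case, corr$sequence, rule)
    }
    tibble::tibble(
      case = ci,
      n_truth = nrow(truth),
      n_observed = nrow(obs),
      accuracy_pre = pre$accuracy,
      accuracy_post = post$accuracy,
      fdi_error_pre = pre$fdi_error,
      fdi_error_post = post$fdi_error,
      n_interior_drops = miss$n_interior,
      n_interior_flagged = miss$n_flagged,
      n_eligible_drops = miss$n_eligible,
      n_eligible_flagged = miss$n_eligible_flagged
    )
  })
  summary <- tibble::tibble(
    n_cases = nrow(per_case),
    accuracy_pre = mean(per_case$accuracy_pre, na.rm = TRUE),
    accuracy_post = mean(per_case$accuracy_post, na.rm = TRUE),
    fdi_error_pre = mean(per_case$fdi_error_pre, na.rm = TRUE),
    fdi_error_post = mean(per_case$fdi_error_post, na.rm = TRUE),
    missing_recall = rate_or_na(sum(per_case$n_interior_flagged),
                                sum(per_case$n_interior_drops)),
    missing_recall_eligible = rate_or_na(sum(per_case$n_eligible_flagged),
                                         sum(per_case$n_eligible_drops))
  )
  structure(list(per_case = per_case, summary = summary),
            class = "correction_gain")
}

rate_or_na <- function(num, den) if (den > 0) num / den else NA_real_

# label accuracy and FDI error of observed vs truth over class-blind matches
case_label_stats <- function(obs, truth) {
  if (nrow(obs) == 0L) return(list(accuracy = NA_real_, fdi_error = NA_real_))
  m <- match_detections(obs, truth, iou_threshold = 0.5, class_aware = FALSE)
  if (nrow(m$pairs) == 0L) return(list(accuracy = NA_real_, fdi_error = NA_real_))
  list(
    accuracy = mean(m$pairs$pred_label == m$pairs$true_label),
    fdi_error = fdi_error(m)
  )
}

# interior-drop bookkeeping: which dropped teeth fall in a gap between two
# surviving boxes, and did that gap receive enough placeholders. "Eligible"
# drops sit in a gap that exceeds the rule threshold and holds at most
# max_insertions drops — the regime the gap mechanism is designed for.
missing_slot_stats <- function(case, seq_after, rule) {
  dropped <- case$provenance$truth_slot[case$provenance$kind == "dropped"]
  real_after <- seq_after[seq_after$label > 0L, , drop = FALSE]
  real_after <- real_after[order(real_after$x_min), , drop = FALSE]
  out <- list(n_interior = 0L, n_flagged = 0L, n_eligible = 0L, n_eligible_flagged = 0L)
  if (length(dropped) == 0L || nrow(real_after) < 2L) return(out)
  med_w <- stats::median(real_after$x_max - real_after$x_min)
  thr <- if (rule$mode == "relative") rule$threshold * med_w else rule$threshold
  ph <- seq_after[seq_after$label == 0L, , drop = FALSE]
  drop_centers <- (case$truth$x_min[dropped] + case$truth$x_max[dropped]) / 2
  for (i in seq_len(nrow(real_after) - 1L)) {
    lo <- real_after$x_max[i]
    hi <- real_after$x_min[i + 1L]
    n_d <- sum(drop_centers > lo & drop_centers < hi)
    if (n_d == 0L) next
    ph_centers <- (ph$x_min + ph$x_max) / 2
    n_p <- sum(ph_centers > lo & ph_centers < hi)
    out$n_interior <- out$n_interior + n_d
    out$n_flagged <- out$n_flagged + min(n_d, n_p)
    if (hi - lo > thr && n_d <= rule$max_insertions) {
      out$n_eligible <- out$n_eligible + n_d
      out$n_eligible_flagged <- out$n_eligible_flagged + min(n_d, n_p)
    }
  }
  out
}

#' @export
print.correction_gain <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "<correction_gain> %d case(s)\n",
    "  label accuracy : %.4f -> %.4f\n",
    "  FDI error      : %.4f -> %.4f\n",
    "  missing recall : %s (eligible gaps: %s)\n"),
    s$n_cases, s$accuracy_pre, s$accuracy_post,
    s$fdi_error_pre, s$fdi_error_post,
    format_rate(s$missing_recall), format_rate(s$missing_recall_eligible)))
  invisible(x)
}

format_rate <- function(x) if (is.na(x)) "n/a" else sprintf("%.4f", x)

#' @method glance correction_gain
#' @export
glance.correction_gain <- function(x, ...) x$summary

#' @method tidy correction_gain
#' @export
tidy.correction_gain <- function(x, ...) x$per_case

#' Before/after comparison plot for a correction-gain run
#'
#' @param object A `correction_gain` from [evaluate_correction_gain()].
#' @param ... Unused.
#' @return A ggplot comparing the per-case label accuracy before and after
#'   correction.
#' @method autoplot correction_gain
#' @export
autoplot.correction_gain <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_case,
                            cols = c("accuracy_pre", "accuracy_post"),
                            names_to = "stage", values_to = "accuracy")
  df$stage <- factor(df$stage, levels = c("accuracy_pre", "accuracy_post"),
                     labels = c("before correction", "after correction"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$accuracy)) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.alpha = 0.3) +
    ggplot2::labs(x = NULL, y = "per-case label accuracy",
                  title = "Sequence correction gain on synthetic scenarios") +
    ggplot2::theme_minimal()
}
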