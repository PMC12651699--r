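test_that("detections sort by x_min with y_min tie-break, stably", {
  d <- detections(x_min = c(50, 10, 30), y_min = c(0, 0, 0),
                  x_max = c(60, 20, 40), y_max = 10,
                  label = c(1, 2, 3), score = 0.5)
  expect_equal(sort_by_xmin(d)$x_min, c(10, 30, 50))
  tie <- detections(x_min = c(10, 10), y_min = c(5, 1),
                    x_max = c(20, 20), y_max = 10,
                    label = c(1, 2), score = 0.5)
  expect_equal(sort_by_xmin(tie)$label, c(2L, 1L))
  empty <- detections(x_min = numeric(), y_min = numeric(),
                      x_max = numeric(), y_max = numeric(),
                      label = integer(), score = numeric())
  expect_equal(nrow(sort_by_xmin(empty)), 0)
})

test_that("placeholder insertion follows the gap-rule arithmetic", {
  # gap 2 with threshold 0.5 * 18 = 9: below threshold, nothing inserted
  near <- detections(x_min = c(1, 21), y_min = 0, x_max = c(19, 39), y_max = 10,
                     label = c(4, 5), score = 0.9)
  expect_equal(insert_missing_placeholders(near)$label, c(4L, 5L))

  # gap 22 > 9, pitch 40: exactly one placeholder
  far <- detections(x_min = c(1, 41), y_min = 0, x_max = c(19, 59), y_max = 10,
                    label = c(4, 6), score = 0.9)
  out <- insert_missing_placeholders(far)
  expect_equal(out$label, c(4L, 0L, 6L))
  expect_equal(out$score[2], 0)
  expect_true(out$x_min[2] > 19 && out$x_max[2] < 41)

  # double-width gap of about twice the pitch: two placeholders, cap respected
  trip <- boxes_for(c(4, 5, 8))
  trip$x_min[3] <- trip$x_min[3] + 120  # teeth 6 and 7 missing
  trip$x_max[3] <- trip$x_max[3] + 120
  out2 <- insert_missing_placeholders(trip)
  expect_equal(out2$label, c(4L, 5L, 0L, 0L, 8L))
  out_cap1 <- insert_missing_placeholders(trip, gap_rule(max_insertions = 1))
  expect_equal(sum(out_cap1$label == 0L), 1)
})

test_that("non-placeholder detections survive insertion unchanged and sorted", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    d <- boxes_for(sample.int(16L, n))
    drop <- sample(2:(n - 1), 1)  # knock a hole somewhere interior-ish
    d2 <- sort_by_xmin(d[-drop, , drop = FALSE])
    out <- insert_missing_placeholders(d2)
    expect_false(is.unsorted(out$x_min))
    kept <- out[out$label > 0L, , drop = FALSE]
    expect_equal(kept$label, d2$label)
    expect_equal(kept$x_min, d2$x_min)
  }
})

test_that("arch counts skip placeholders and template choice sends ties lower", {
  expect_equal(count_arches(c(3, 4, 5)), c(U = 3L, L = 0L))
  expect_equal(count_arches(c(3, 0, 20)), c(U = 1L, L = 1L))
  expect_equal(count_arches(integer()), c(U = 0L, L = 0L))
  expect_equal(select_template(3, 1)$arch, "upper")
  expect_equal(select_template(2, 2)$arch, "lower")
  expect_equal(select_template(0, 5)$arch, "lower")
})

test_that("best alignment finds the argmax offset with smallest-offset ties", {
  up <- arch_template("upper")
  expect_equal(best_alignment(c(3, 4, 9, 6), up), list(offset = 2L, M = 3L))
  expect_equal(best_alignment(5, up), list(offset = 4L, M = 1L))
  expect_equal(best_alignment(c(0, 0), up), list(offset = 0L, M = 0L))
  expect_error(best_alignment(rep(1, 17), up),
               class = "dentalign_sequence_too_long")
  expect_error(best_alignment(integer(), up), class = "dentalign_config_error")
})

test_that("production alignment agrees with the brute-force oracle", {
  up <- arch_template("upper")
  lo <- arch_template("lower")
  expect_equal(brute_force_alignment(c(3, 4, 9, 6), up), list(offset = 2L, M = 3L))
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(1:16, 1)
    labels <- sample(0:32, n, replace = TRUE)
    tpl <- if (i %% 2 == 0) up else lo
    expect_identical(best_alignment(labels, tpl), brute_force_alignment(labels, tpl))
  }
})

test_that("correction rewrites disagreeing labels only when M > 1", {
  up <- arch_template("upper")
  r <- apply_correction(c(3, 4, 9, 6), up, offset = 2L, M = 3L)
  expect_equal(r$corrected, c(3L, 4L, 5L, 6L))
  expect_equal(r$modified, c(FALSE, FALSE, TRUE, FALSE))

  # placeholders keep 0; the inferred number is reported separately
  r0 <- apply_correction(c(4, 5, 0, 7), up, offset = 3L, M = 3L)
  expect_equal(r0$corrected, c(4L, 5L, 0L, 7L))
  expect_equal(r0$missing_slots$slot, 3L)
  expect_equal(r0$missing_slots$inferred_linear, 6L)

  # M <= 1: no changes
  r1 <- apply_correction(c(1, 30), arch_template("lower"), offset = 0L, M = 1L)
  expect_equal(r1$corrected, c(1L, 30L))
  expect_false(any(r1$modified))
})

test_that("the full pipeline composes sorting, gaps, and correction", {
  # perfect consecutive run: fixed point
  d <- boxes_for(c(4, 5, 6, 7))
  cr <- correct_sequence(d)
  expect_equal(cr$corrected_labels, c(4L, 5L, 6L, 7L))
  expect_equal(cr$match_count, 4L)
  expect_equal(nrow(cr$missing_slots), 0)
  expect_false(any(cr$modified))

  # run 4,5,7 with a real gap before 7: 4,5,(6),7
  dg <- boxes_for(c(4, 5, 7))
  dg$x_min[3] <- dg$x_min[3] + 60
  dg$x_max[3] <- dg$x_max[3] + 60
  crg <- correct_sequence(dg)
  expect_equal(crg$original_labels, c(4L, 5L, 0L, 7L))
  expect_equal(crg$corrected_labels, c(4L, 5L, 0L, 7L))
  expect_equal(crg$missing_slots$inferred_linear, 6L)
  expect_equal(crg$missing_slots$inferred_fdi, "13")

  # single detection: M = 1, untouched
  single <- boxes_for(9)
  expect_equal(correct_sequence(single)$corrected_labels, 9L)

  # [1, 30]: tie U = L = 1 goes to the lower template, best M = 1, unchanged
  two <- boxes_for(c(1, 30))
  cr2 <- correct_sequence(two)
  expect_equal(cr2$arch, "lower")
  expect_equal(cr2$match_count, 1L)
  expect_equal(cr2$corrected_labels, c(1L, 30L))

  # empty input
  empty <- detections(x_min = numeric(), y_min = numeric(), x_max = numeric(),
                      y_max = numeric(), label = integer(), score = numeric())
  expect_equal(length(correct_sequence(empty)$corrected_labels), 0)
})

test_that("correction is idempotent and conserves teeth and order", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    start <- sample.int(16L - n + 1L, 1)
    labels <- start:(start + n - 1L)
    labels[sample.int(n, 1)] <- sample.int(32L, 1)  # corrupt one slot
    d <- boxes_for(labels)
    cr <- correct_sequence(d)
    expect_equal(sum(cr$original_labels > 0), n)
    expect_false(is.unsorted(cr$sequence$x_min))
    # run again on the corrected output
    d2 <- cr$sequence[cr$original_labels > 0, , drop = FALSE]
    d2$label <- cr$corrected_labels[cr$original_labels > 0]
    cr2 <- correct_sequence(d2)
    expect_equal(cr2$corrected_labels, cr$corrected_labels)
    expect_false(any(cr2$modified))
  }
})

test_that("corrected non-zero labels form a consecutive template run when M > 1", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    labels <- sample(1:16, n)
    cr <- correct_sequence(boxes_for(labels))
    if (cr$match_count > 1) {
      nz_slots <- which(cr$corrected_labels > 0)
      nz <- cr$corrected_labels[nz_slots]
      # every non-zero slot equals the template at its position, so the run
      # is strictly increasing with steps matching the slot spacing
      expect_equal(nz, arch_template(cr$arch)$sequence[cr$offset + nz_slots])
      expect_equal(diff(nz), diff(nz_slots))
    }
  }
})

test_that("one wrong label in a run of three or more is always repaired", {
  # subset here; the exhaustive sweep lives in the acceptance suite
  for (n in c(3, 5, 8)) {
    start <- 2L
    truth <- start:(start + n - 1L)
    for (slot in c(1L, n)) {
      for (wrong in c(truth[slot] + 16L, 32L)) {
        labels <- truth
        labels[slot] <- wrong
        cr <- correct_sequence(boxes_for(labels))
        expect_equal(cr$corrected_labels, truth)
      }
    }
  }
})

test_that("reversed-template scoring recovers mirrored sequences when asked", {
  mirrored <- boxes_for(c(7, 6, 5, 4))
  plain <- correct_sequence(mirrored)
  rev_cr <- correct_sequence(mirrored, try_reversed = TRUE)
  expect_lte(plain$match_count, rev_cr$match_count)
  expect_true(rev_cr$reversed)
  expect_equal(rev_cr$corrected_labels, c(7L, 6L, 5L, 4L))
})

test_that("tidy and glance views expose the per-slot story", {
  dg <- boxes_for(c(4, 5, 7))
  dg$x_min[3] <- dg$x_min[3] + 60
  dg$x_max[3] <- dg$x_max[3] + 60
  cr <- correct_sequence(dg)
  td <- tidy(cr)
  expect_equal(nrow(td), 4)
  expect_equal(td$placeholder, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(td$inferred_fdi[3], "13")
  g <- glance(cr)
  expect_equal(g$n_teeth, 3L)
  expect_equal(g$n_placeholders, 1L)
  expect_s3_class(autoplot(cr), "ggplot")
})
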