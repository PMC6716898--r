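test_that("the staining decision table is total on the 4x3 grid", {
  grid <- expand.grid(intensity = c("negative", "weak", "moderate", "strong"),
                      fraction = c("lt25", "between25and75", "gt75"),
                      stringsAsFactors = FALSE)
  levels <- level_from_staining(grid$intensity, grid$fraction)
  expect_equal(length(levels), 12L)
  expect_true(all(levels %in% c("not_detected", "low", "medium", "high")))
  # round trip: every cell maps on to a valid score
  expect_true(all(score_from_level(levels) %in% c(0, 3, 6, 12)))
  # spot checks from the decision table
  expect_equal(level_from_staining("strong", "gt75"), "high")
  expect_equal(level_from_staining("negative", "lt25"), "not_detected")
  expect_equal(level_from_staining("moderate", "between25and75"), "medium")
  expect_equal(level_from_staining("weak", "lt25"), "not_detected")
  expect_equal(level_from_staining("strong", "lt25"), "medium")
})

test_that("staining enum synonyms and dialects are accepted", {
  expect_equal(level_from_staining("medium", "25-75%"), "medium")
  expect_equal(level_from_staining("Strong", ">75%"), "high")
  expect_equal(level_from_staining("weak", "<25%"), "not_detected")
  expect_error(level_from_staining("faint", "gt75"), "faint")
  expect_error(level_from_staining("weak", "half"), "half")
})

test_that("levels convert to the 0/3/6/12 score scale", {
  expect_equal(score_from_level(c("not_detected", "low", "medium", "high")),
               c(0, 3, 6, 12))
  expect_equal(score_from_level("not detected"), 0) # space accepted
  expect_error(score_from_level("very high"), "very_high")
})

test_that("adjust_zero replaces 0 by 0.1 and is idempotent", {
  expect_equal(adjust_zero(c(0, 3, 6, 12)), c(0.1, 3, 6, 12))
  expect_equal(adjust_zero(adjust_zero(c(0, 3, 6, 12))), c(0.1, 3, 6, 12))
})

test_that("score_annotations prefers a provided level and flags mismatches", {
  ann <- tibble::tibble(
    protein_id = "p1", sample_id = c("s1", "s2"), group = "glioma",
    cell_type = NA_character_,
    intensity = c("strong", "strong"), fraction = c("gt75", "gt75"),
    level = c("high", "low")
  )
  expect_warning(scored <- score_annotations(ann), "disagrees")
  expect_equal(scored$score, c(12, 3))
  expect_equal(scored$adjusted, c(12, 3))
})

test_that("score_annotations validates structure", {
  ann <- toy_annotations("p1")
  dup <- dplyr::bind_rows(ann, ann[1, ])
  expect_error(score_annotations(dup), "duplicate")
  bad <- dplyr::mutate(ann, group = "tumour")
  expect_error(score_annotations(bad), "tumour")
  expect_error(score_annotations(ann[, c("protein_id", "sample_id", "group")]),
               "level")
  scored <- score_annotations(ann)
  expect_equal(scored$adjusted, ifelse(scored$score == 0, 0.1, scored$score))
})

test_that("filter_min_samples enforces per-group coverage", {
  full <- score_annotations(toy_annotations("kept_full"))
  three_three <- dplyr::filter(
    score_annotations(toy_annotations("kept_3_3")),
    sample_id %in% c("glioma_01", "glioma_02", "glioma_03",
                     "endothelial", "glial", "neuronal")
  )
  two_four <- dplyr::filter(
    score_annotations(toy_annotations("dropped_2_4")),
    !sample_id %in% sprintf("glioma_%02d", 3:12)
  )
  scores <- dplyr::bind_rows(full, three_three, two_four)
  expect_message(out <- filter_min_samples(scores), "1 protein")
  expect_setequal(unique(out$protein_id), c("kept_full", "kept_3_3"))
  # idempotent, never adds proteins
  expect_identical(suppressMessages(filter_min_samples(out)), out)
  expect_error(suppressMessages(filter_min_samples(scores, min_glioma = 13)),
               "no protein")
})

test_that("a zero score counts as an assessed sample for the coverage filter", {
  scored <- score_annotations(
    toy_annotations("p0", glioma_levels = rep("not_detected", 12)))
  out <- filter_min_samples(scored)
  expect_equal(unique(out$protein_id), "p0")
})

test_that("score matrix TSV keeps missing distinct from zero", {
  scored <- score_annotations(
    toy_annotations(c("p1", "p2"),
                    glioma_levels = rep(c("not_detected", "high"), 6)))
  # drop p1's first annotation -> missing cell, distinct from score 0
  scored <- dplyr::filter(scored,
                          !(protein_id == "p1" & sample_id == "glioma_01"))
  scored <- dplyr::filter(scored, protein_id == "p1" |
                            sample_id != "glioma_02") # ragged second protein
  path <- tempfile(fileext = ".tsv")
  meta <- tempfile(fileext = ".tsv")
  write_score_matrix(scored, path, meta)
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  p1 <- wide[wide$protein_id == "p1", ]
  p2 <- wide[wide$protein_id == "p2", ]
  expect_true(is.na(p1$glioma_01))   # missing annotation
  expect_equal(p1$glioma_02, 12)
  expect_equal(p1$glioma_03, 0)      # assessed "not detected"
  expect_equal(p2$glioma_01, 0)
  expect_true(is.na(p2$glioma_02))
  md <- readr::read_tsv(meta, show_col_types = FALSE)
  expect_setequal(md$group, c("glioma", "normal"))
})
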