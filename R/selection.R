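#' Aggregate expression scores within one proteome
#'
#' Collapses a proteome's samples (the 12 glioma samples, or one normal cell
#' type's samples) to a single per-protein aggregate: the arithmetic mean of
#' zero-adjusted scores over the proteome's non-missing samples. Proteins
#' with no scored sample in the proteome are excluded with a message.
#'
#' @param scores A score table from [score_annotations()].
#' @param proteome `"glioma"` or one normal cell-type label (matched against
#'   `cell_type`).
#' @return A tibble with columns `protein_id`, `proteome`, `aggregate_score`.
#' @export
aggregate_proteome_scores <- function(scores, proteome) {
  stopifnot(is.data.frame(scores), length(proteome) == 1L)
  sub <- if (proteome == "glioma") {
    dplyr::filter(scores, .data$group == "glioma")
  } else {
    dplyr::filter(scores, .data$group == "normal",
                  .data$cell_type == proteome)
  }
  if (nrow(sub) == 0L) {
    stop("no samples found for proteome '", proteome, "'", call. = FALSE)
  }
  n_all <- dplyr::n_distinct(sub$protein_id)
  out <- sub |>
    dplyr::filter(!is.na(.data$adjusted)) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(aggregate_score = mean(.data$adjusted), .groups = "drop") |>
    dplyr::mutate(proteome = proteome, .after = "protein_id")
  if (nrow(out) < n_all) {
    message(n_all - nrow(out),
            " protein(s) with no scored sample in '", proteome,
            "' excluded from aggregation")
  }
  out
}

#' Select highly and lowly expressed proteins
#'
#' Selects the extreme-expression protein sets of one proteome. In percentile
#' modes (`pct1`, `pct3`, `pct5`), the top (bottom) `ceiling(fraction * N)`
#' proteins by aggregate score form the high (low) set, extended to include
#' every protein tied with the boundary value. In `threshold` mode the high
#' set is every protein at the maximum expression score (the scale maximum 12
#' by default, or the empirical maximum with `threshold_max = "empirical"`)
#' and the low set is every protein with aggregate score at or below 0.1.
#'
#' Boundary ties are always included, so percentile sets can exceed their
#' nominal size. In pathological mass-tie inputs a tied value can span both
#' the top and bottom boundary; such proteins are removed from both sets with
#' a warning to keep the sets disjoint.
#'
#' @param scores A tibble from [aggregate_proteome_scores()] (columns
#'   `protein_id`, `aggregate_score`; a `proteome` column is carried through).
#' @param mode One of `"pct1"`, `"pct3"`, `"pct5"`, `"threshold"`.
#' @param threshold_max `"scale"` (high = score 12) or `"empirical"`
#'   (high = observed maximum), used only in threshold mode.
#' @param low_threshold Upper bound of the low set in threshold mode.
#' @return A tibble with columns `protein_id`, `proteome`, `aggregate_score`,
#'   `set` (`"high"` or `"low"`).
#' @export
select_extreme <- function(scores,
                           mode = c("pct1", "pct3", "pct5", "threshold"),
                           threshold_max = c("scale", "empirical"),
                           low_threshold = 0.1) {
  mode <- match.arg(mode)
  threshold_max <- match.arg(threshold_max)
  stopifnot(is.data.frame(scores),
            all(c("protein_id", "aggregate_score") %in% names(scores)))
  x <- scores$aggregate_score
  n <- length(x)
  if (mode == "threshold") {
    hi_cut <- if (threshold_max == "scale") 12 else max(x)
    high <- scores$protein_id[x >= hi_cut]
    low <- scores$protein_id[x <= low_threshold]
    if (length(high) == 0L) {
      warning("threshold mode: empty high set", call. = FALSE)
    }
    if (length(low) == 0L) {
      warning("threshold mode: empty low set", call. = FALSE)
    }
  } else {
    frac <- c(pct1 = 0.01, pct3 = 0.03, pct5 = 0.05)[[mode]]
    if (n < 100L) {
      warning("percentile selection on fewer than 100 proteins", call. = FALSE)
    }
    k <- ceiling(frac * n)
    desc <- sort(x, decreasing = TRUE)
    asc <- sort(x)
    high <- scores$protein_id[x >= desc[k]]
    low <- scores$protein_id[x <= asc[k]]
  }
  both <- intersect(high, low)
  if (length(both) > 0L && dplyr::n_distinct(x) > 1L) {
    warning(length(both), " protein(s) tied across both selection boundaries ",
            "removed from both sets", call. = FALSE)
    high <- setdiff(high, both)
    low <- setdiff(low, both)
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(dplyr::filter(scores, .data$protein_id %in% high),
                  set = "high"),
    dplyr::mutate(dplyr::filter(scores, .data$protein_id %in% low),
                  set = "low")
  )
  if (!"proteome" %in% names(out)) out$proteome <- NA_character_
  dplyr::select(out, "protein_id", "proteome", "aggregate_score", "set")
}
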