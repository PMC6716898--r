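.INTENSITIES <- c("negative", "weak", "moderate", "strong")
.FRACTIONS <- c("lt25", "between25and75", "gt75")
.LEVELS <- c("not_detected", "low", "medium", "high")
.SCORES <- c(not_detected = 0, low = 3, medium = 6, high = 12)

# tolerant normalisation of the input enumerations ("medium" is accepted as a
# synonym of "moderate" intensity; "not detected" with space or dash, "<25%"
# style fractions, etc.)
.norm_intensity <- function(x) {
  x <- tolower(trimws(x))
  x[x == "medium"] <- "moderate"
  x
}

.norm_fraction <- function(x) {
  x <- tolower(gsub("[[:space:]%]", "", x))
  x[x %in% c("<25", "lt25")] <- "lt25"
  x[x %in% c("25-75", "25–75", "between25and75", "25to75")] <- "between25and75"
  x[x %in% c(">75", "gt75")] <- "gt75"
  x
}

.norm_level <- function(x) {
  x <- tolower(trimws(x))
  gsub("[ -]", "_", x)
}

#' Ordinal expression level from staining intensity and fraction
#'
#' Maps an immunohistochemistry staining call (intensity × stained-cell
#' fraction) to the 4-level ordinal expression scale used by the Human
#' Protein Atlas: negative staining is `not_detected` at any fraction; weak
#' staining in <25% of cells is `not_detected`, otherwise `low`; moderate
#' staining in <25% is `low`, otherwise `medium`; strong staining in <25% is
#' `medium`, otherwise `high`.
#'
#' @param intensity Character vector in `negative`, `weak`, `moderate`
#'   (synonym `medium`), `strong`.
#' @param fraction Character vector in `lt25`, `between25and75`, `gt75`
#'   (`<25%`, `25-75%`, `>75%` accepted).
#' @return Character vector of levels `not_detected`, `low`, `medium`,
#'   `high`.
#' @examples
#' level_from_staining("strong", "gt75") # "high"
#' @export
level_from_staining <- function(intensity, fraction) {
  intensity <- .norm_intensity(intensity)
  fraction <- .norm_fraction(fraction)
  bad_i <- setdiff(unique(intensity), .INTENSITIES)
  bad_f <- setdiff(unique(fraction), .FRACTIONS)
  if (length(bad_i) > 0L || length(bad_f) > 0L) {
    stop("unknown staining enumeration(s): ",
         paste(sQuote(c(bad_i, bad_f)), collapse = ", "), call. = FALSE)
  }
  high_fraction <- fraction != "lt25"
  dplyr::case_when(
    intensity == "negative" ~ "not_detected",
    intensity == "weak" & !high_fraction ~ "not_detected",
    intensity == "weak" ~ "low",
    intensity == "moderate" & !high_fraction ~ "low",
    intensity == "moderate" ~ "medium",
    intensity == "strong" & !high_fraction ~ "medium",
    intensity == "strong" ~ "high"
  )
}

#' Numeric score from ordinal expression level
#'
#' `not_detected`, `low`, `medium`, `high` map to 0, 3, 6, 12.
#'
#' @param level Character vector of levels.
#' @return Numeric vector of scores in `{0, 3, 6, 12}`.
#' @export
score_from_level <- function(level) {
  level <- .norm_level(level)
  bad <- setdiff(unique(level), .LEVELS)
  if (length(bad) > 0L) {
    stop("unknown expression level(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  unname(.SCORES[level])
}

#' Replace zero scores by 0.1
#'
#' "Not detected" scores of 0 are replaced by 0.1 so that log2 expression
#' ratios stay defined; non-zero scores pass through unchanged. Idempotent.
#'
#' @param score Numeric vector of scores.
#' @return Numeric vector with 0 replaced by 0.1.
#' @export
adjust_zero <- function(score) {
  ifelse(score == 0, 0.1, score)
}

#' Read staining annotations from TSV
#'
#' Expects a header with columns `protein_id`, `sample_id`, `group`,
#' `cell_type`, and either `intensity` + `fraction`, a pre-computed `level`,
#' or both.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble of raw annotations.
#' @export
read_staining_annotations <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Score staining annotations
#'
#' Converts raw annotations to the long score table the rest of the pipeline
#' consumes: one row per (protein, sample) with the ordinal `level`, its
#' numeric `score` and the zero-`adjusted` score. When the input carries both
#' raw staining columns and a pre-computed `level`, the `level` column wins
#' and a warning reports any disagreement with the decision table.
#'
#' @param annotations A data frame with columns `protein_id`, `sample_id`,
#'   `group` (`glioma` or `normal`), `cell_type`, and `intensity`/`fraction`
#'   and/or `level`.
#' @return A tibble with columns `protein_id`, `sample_id`, `group`,
#'   `cell_type`, `level`, `score`, `adjusted`.
#' @export
score_annotations <- function(annotations) {
  stopifnot(is.data.frame(annotations),
            all(c("protein_id", "sample_id", "group") %in% names(annotations)))
  has_raw <- all(c("intensity", "fraction") %in% names(annotations))
  has_level <- "level" %in% names(annotations)
  if (!has_raw && !has_level) {
    stop("annotations need either intensity+fraction columns or a level column",
         call. = FALSE)
  }
  dup <- duplicated(annotations[c("protein_id", "sample_id")])
  if (any(dup)) {
    stop("duplicate annotation(s) for the same (protein, sample): ",
         paste(head(unique(annotations$protein_id[dup]), 5L), collapse = ", "),
         call. = FALSE)
  }
  bad_group <- setdiff(unique(annotations$group), c("glioma", "normal"))
  if (length(bad_group) > 0L) {
    stop("unknown sample group(s): ",
         paste(sQuote(bad_group), collapse = ", "), call. = FALSE)
  }
  level <- if (has_level) .norm_level(annotations$level)
           else level_from_staining(annotations$intensity, annotations$fraction)
  if (has_level && has_raw) {
    derived <- level_from_staining(annotations$intensity, annotations$fraction)
    n_mismatch <- sum(derived != level)
    if (n_mismatch > 0L) {
      warning(n_mismatch, " annotation(s) where the provided level disagrees ",
              "with the intensity/fraction decision table; the level column ",
              "was used", call. = FALSE)
    }
  }
  score <- score_from_level(level)
  tibble::tibble(
    protein_id = annotations$protein_id,
    sample_id = annotations$sample_id,
    group = annotations$group,
    cell_type = if ("cell_type" %in% names(annotations))
      annotations$cell_type else NA_character_,
    level = level,
    score = score,
    adjusted = adjust_zero(score)
  )
}

#' Filter proteins by minimum sample coverage
#'
#' Keeps only proteins with an assessed score (including "not detected") in
#' at least `min_glioma` glioma samples and `min_normal` normal cell-type
#' samples. Missing annotations are absent rows (or `NA` scores), distinct
#' from a score of 0.
#'
#' @param scores A score table from [score_annotations()].
#' @param min_glioma,min_normal Minimum number of scored samples per group.
#' @return The filtered score table; a message reports how many proteins were
#'   removed. Errors if no protein survives.
#' @export
filter_min_samples <- function(scores, min_glioma = 3, min_normal = 3) {
  stopifnot(is.data.frame(scores),
            all(c("protein_id", "group", "score") %in% names(scores)))
  if (!all(c("glioma", "normal") %in% unique(scores$group))) {
    stop("score table must contain both glioma and normal samples",
         call. = FALSE)
  }
  coverage <- scores |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::count(.data$protein_id, .data$group) |>
    tidyr::pivot_wider(names_from = "group", values_from = "n",
                       values_fill = 0L)
  if (!"glioma" %in% names(coverage)) coverage$glioma <- 0L
  if (!"normal" %in% names(coverage)) coverage$normal <- 0L
  keep <- coverage$protein_id[coverage$glioma >= min_glioma &
                                coverage$normal >= min_normal]
  n_removed <- dplyr::n_distinct(scores$protein_id) - length(keep)
  if (length(keep) == 0L) {
    stop("no protein passes the minimum-sample filter", call. = FALSE)
  }
  if (n_removed > 0L) {
    message(n_removed, " protein(s) removed by the minimum-sample filter")
  }
  dplyr::filter(scores, .data$protein_id %in% keep)
}

#' Write the score matrix to TSV
#'
#' Pivots the long score table to a proteins-by-samples matrix (raw scores;
#' missing annotations are empty cells) and writes it alongside a sample
#' metadata table.
#'
#' @param scores A score table from [score_annotations()].
#' @param path Output path for the matrix TSV.
#' @param metadata_path Optional output path for the sample metadata TSV.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(scores, path, metadata_path = NULL) {
  wide <- scores |>
    dplyr::select("protein_id", "sample_id", "score") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "score")
  readr::write_tsv(wide, path, na = "")
  if (!is.null(metadata_path)) {
    meta <- scores |>
      dplyr::distinct(.data$sample_id, .data$group, .data$cell_type)
    readr::write_tsv(meta, metadata_path, na = "")
  }
  invisible(path)
}
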