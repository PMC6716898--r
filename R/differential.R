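#' Log2 expression ratio
#'
#' Base-2 logarithm of the ratio of mean zero-adjusted expression scores,
#' glioma over normal. Inputs must be strictly positive, which the 0 → 0.1
#' replacement guarantees.
#'
#' @param glioma_mean,normal_mean Positive numeric vectors.
#' @return `log2(glioma_mean / normal_mean)`.
#' @examples
#' log2_ratio(12, 3) # 2
#' @export
log2_ratio <- function(glioma_mean, normal_mean) {
  if (any(glioma_mean <= 0) || any(normal_mean <= 0)) {
    stop("mean scores must be positive; was the 0 -> 0.1 replacement skipped?",
         call. = FALSE)
  }
  log2(glioma_mean / normal_mean)
}

#' Exact two-sample rank-sum test
#'
#' Two-sided Wilcoxon rank-sum test on the pooled mid-ranks, appropriate for
#' heavily tied ordinal scores. When the number of group assignments
#' `choose(n, n_a)` is at most `max_enum`, the permutation null of the
#' rank-sum statistic is enumerated exhaustively and the two-sided p-value is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`; otherwise a normal approximation
#' with tie correction is used. Constant pooled data yield p = 1 (flagged via
#' the `constant` field).
#'
#' @param a,b Numeric vectors (each of length >= 1; tests in this pipeline
#'   see >= 3 per group after the minimum-sample filter).
#' @param max_enum Largest number of assignments enumerated exactly.
#' @return A list with `statistic` (rank sum of `a`), `p.value`, `exact`
#'   (logical) and `constant` (logical).
#' @export
rank_sum_test <- function(a, b, max_enum = 2e5) {
  stopifnot(length(a) >= 1L, length(b) >= 1L,
            !anyNA(a), !anyNA(b))
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  w <- sum(r[seq_len(na)])
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = w, p.value = 1, exact = TRUE, constant = TRUE))
  }
  if (choose(n, na) <= max_enum) {
    cm <- combn(n, na)
    ws <- colSums(matrix(r[cm], nrow = na))
    eps <- 1e-9 * n
    p_le <- mean(ws <= w + eps)
    p_ge <- mean(ws >= w - eps)
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    nb <- n - na
    mu <- na * (n + 1) / 2
    ties <- table(pooled)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = w, p.value = p, exact = exact, constant = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; order-preserving with the input
#' index and monotone along sorted p-values.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Classify proteins as up/down regulated
#'
#' A protein is `up` when its log2 ratio is at least `lfc`, its p-value below
#' `alpha` and its q-value below `fdr`; `down` when the log2 ratio is at most
#' `-lfc` under the same significance gates; otherwise `none`. Both
#' fold-change boundaries are inclusive.
#'
#' @param log2_ratio,p_value,q_value Numeric vectors of equal length.
#' @param lfc Absolute log2-ratio gate (default 1).
#' @param alpha P-value gate (default 0.05).
#' @param fdr Q-value gate (default 0.01).
#' @return Character vector in `up`, `down`, `none`.
#' @export
classify_deps <- function(log2_ratio, p_value, q_value,
                          lfc = 1, alpha = 0.05, fdr = 0.01) {
  significant <- p_value < alpha & q_value < fdr
  dplyr::case_when(
    log2_ratio >= lfc & significant ~ "up",
    log2_ratio <= -lfc & significant ~ "down",
    TRUE ~ "none"
  )
}

#' Differential protein expression between glioma and normal samples
#'
#' For each protein, compares the zero-adjusted scores of the glioma samples
#' (12 in the reference design) against the normal cell types (4 observations,
#' one per cell type) with an exact rank-sum test, computes the log2 ratio of
#' group mean scores, Benjamini-Hochberg q-values across all tested proteins,
#' and classifies each protein as `up`, `down` or `none`. Identical score
#' patterns share one test evaluation, which makes the exhaustive permutation
#' test cheap on ordinal data.
#'
#' @param scores A filtered score table (see [filter_min_samples()]).
#' @inheritParams classify_deps
#' @return A tibble of class `stoich_dep`, one row per protein, sorted by
#'   `protein_id`: `protein_id`, `mean_glioma`, `mean_normal`, `log2_ratio`,
#'   `p_value`, `q_value`, `class`.
#' @export
dep_analysis <- function(scores, lfc = 1, alpha = 0.05, fdr = 0.01) {
  stopifnot(is.data.frame(scores),
            all(c("protein_id", "group", "adjusted") %in% names(scores)))
  split_scores <- scores |>
    dplyr::filter(!is.na(.data$adjusted)) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      glioma = list(.data$adjusted[.data$group == "glioma"]),
      normal = list(.data$adjusted[.data$group == "normal"]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$protein_id)
  cache <- new.env(parent = emptyenv())
  p_one <- function(g, n) {
    key <- paste(c(g, "|", n), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    p <- rank_sum_test(g, n)$p.value
    cache[[key]] <- p
    p
  }
  mean_g <- vapply(split_scores$glioma, mean, numeric(1))
  mean_n <- vapply(split_scores$normal, mean, numeric(1))
  p <- purrr::map2_dbl(split_scores$glioma, split_scores$normal, p_one)
  q <- fdr_adjust(p)
  lr <- log2_ratio(mean_g, mean_n)
  out <- tibble::tibble(
    protein_id = split_scores$protein_id,
    mean_glioma = mean_g,
    mean_normal = mean_n,
    log2_ratio = lr,
    p_value = p,
    q_value = q,
    class = classify_deps(lr, p, q, lfc = lfc, alpha = alpha, fdr = fdr)
  )
  class(out) <- c("stoich_dep", class(out))
  attr(out, "gates") <- c(lfc = lfc, alpha = alpha, fdr = fdr)
  out
}

#' Write a differential expression table to TSV
#'
#' @param dep A `stoich_dep` tibble from [dep_analysis()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dep_table <- function(dep, path) {
  readr::write_tsv(dplyr::arrange(tibble::as_tibble(dep), .data$protein_id),
                   path)
  invisible(path)
}

#' @exportS3Method generics::tidy
tidy.stoich_dep <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "stoich_dep")
  attr(out, "gates") <- NULL
  out
}

#' @exportS3Method generics::glance
glance.stoich_dep <- function(x, ...) {
  gates <- attr(x, "gates")
  tibble::tibble(
    n_proteins = nrow(x),
    n_up = sum(x$class == "up"),
    n_down = sum(x$class == "down"),
    lfc = gates[["lfc"]],
    alpha = gates[["alpha"]],
    fdr = gates[["fdr"]]
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.stoich_dep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_ratio,
                                   y = -log10(.data$p_value),
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(up = "#d73027", down = "#4575b4", none = "grey60")) +
    ggplot2::labs(x = "log2 ratio (glioma / normal)",
                  y = "-log10 p", colour = "class") +
    ggplot2::theme_minimal()
}
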