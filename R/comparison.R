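#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over the pooled support of the absolute difference
#' between the two empirical CDFs; the p-value comes from the asymptotic
#' two-sample Kolmogorov distribution with effective sample size
#' `n_a * n_b / (n_a + n_b)`, the conventional choice at the sample sizes of
#' proteome-scale comparisons (hundreds to thousands).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A list with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 values for a KS comparison",
         call. = FALSE)
  }
  res <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Directed percent difference
#'
#' `100 * (value - reference) / reference`: how much `value` sits above (+)
#' or below (-) the declared reference. The direction matters; percent
#' differences are never symmetric in their arguments.
#'
#' @param value Numeric vector.
#' @param reference Numeric vector (non-zero), the declared baseline.
#' @return Percent difference(s).
#' @examples
#' percent_difference(0.481, 0.469) # 2.56% higher
#' @export
percent_difference <- function(value, reference) {
  if (any(reference == 0)) {
    stop("percent difference is undefined against a zero reference",
         call. = FALSE)
  }
  100 * (value - reference) / reference
}

#' Mean percent difference across pairs
#'
#' Arithmetic mean of per-pair percent-difference magnitudes, e.g. "on
#' average X% lower" summaries over several proteome pairs.
#'
#' @param value Numeric vector of values.
#' @param reference Numeric vector of references (recycled if length 1).
#' @return Mean of `abs(percent_difference(value, reference))`.
#' @export
mean_percent_across_pairs <- function(value, reference) {
  if (length(value) == 0L) {
    stop("at least one pair is required", call. = FALSE)
  }
  mean(abs(percent_difference(value, reference)))
}

#' Compare an element-content variable between two protein sets
#'
#' Computes group means, the directed percent difference of group A against
#' the reference group B, and the two-sample KS statistic and p-value.
#' `NA` values (e.g. undefined C:O ratios) are dropped per group.
#'
#' @param a,b Numeric vectors of element frequencies or C:O ratios.
#' @param labels Length-2 character vector naming the groups; the second is
#'   the reference of the percent difference.
#' @return An object of class `group_comparison`; see [tidy()] and
#'   [glance()] methods, and [autoplot()] for a density plot.
#' @export
compare_groups <- function(a, b, labels = c("A", "B")) {
  stopifnot(length(labels) == 2L)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  ks <- ks_two_sample(a, b)
  structure(
    list(
      labels = labels,
      values_a = a,
      values_b = b,
      mean_a = mean(a),
      mean_b = mean(b),
      percent_diff = percent_difference(mean(a), mean(b)),
      reference = labels[2L],
      ks_D = ks$D,
      ks_p = ks$p
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison:", x$labels[1], "vs", x$labels[2],
      "(reference:", paste0(x$reference, ")"), "\n")
  cat(sprintf("  n = %d vs %d; means %.4f vs %.4f (%+.2f%% vs reference)\n",
              length(x$values_a), length(x$values_b),
              x$mean_a, x$mean_b, x$percent_diff))
  cat(sprintf("  KS D = %.4f, p = %.3g\n", x$ks_D, x$ks_p))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(
    group = x$labels,
    n = c(length(x$values_a), length(x$values_b)),
    mean = c(x$mean_a, x$mean_b)
  )
}

#' @exportS3Method generics::glance
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    group_a = x$labels[1],
    group_b = x$labels[2],
    n_a = length(x$values_a),
    n_b = length(x$values_b),
    mean_a = x$mean_a,
    mean_b = x$mean_b,
    percent_diff = x$percent_diff,
    reference = x$reference,
    ks_D = x$ks_D,
    ks_p = x$ks_p
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.group_comparison <- function(object, ...) {
  df <- tibble::tibble(
    value = c(object$values_a, object$values_b),
    group = rep(object$labels, c(length(object$values_a),
                                 length(object$values_b)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "value", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Tukey HSD multiple comparisons across proteomes
#'
#' One-way ANOVA with Tukey honest-significant-difference adjusted pairwise
#' p-values (studentized range on the pooled residual variance), e.g. for
#' oxygen contents across the glioma and four normal proteomes. Degenerate
#' input with zero residual variance and equal group means returns all
#' adjusted p-values of 1.
#'
#' @param data A data frame.
#' @param value Name of the numeric column (string).
#' @param group Name of the grouping column (string); >= 2 groups with >= 2
#'   values each.
#' @return An object of class `multi_group_comparison` with `tidy()` and
#'   `glance()` methods; `tidy()` gives one row per pair with the adjusted p.
#' @export
tukey_multi <- function(data, value = "value", group = "group") {
  stopifnot(is.data.frame(data), value %in% names(data),
            group %in% names(data))
  df <- tibble::tibble(value = data[[value]],
                       group = factor(data[[group]]))
  df <- df[!is.na(df$value), ]
  counts <- table(df$group)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop("Tukey comparison needs >= 2 groups with >= 2 values each",
         call. = FALSE)
  }
  group_means <- tapply(df$value, df$group, mean)
  resid_var <- sum(tapply(df$value, df$group,
                          function(v) sum((v - mean(v))^2))) /
    (nrow(df) - length(counts))
  if (resid_var <= .Machine$double.eps * max(abs(df$value), 1)) {
    # zero residual variance: pairs with equal means are indistinguishable
    # (p = 1); pairs with different means are separated with certainty
    pairs <- combn(names(counts), 2)
    d <- group_means[pairs[1, ]] - group_means[pairs[2, ]]
    pairwise <- tibble::tibble(
      group_1 = pairs[1, ], group_2 = pairs[2, ],
      diff = unname(d), lwr = unname(d), upr = unname(d),
      p_adj = ifelse(abs(d) <= .Machine$double.eps, 1, 0)
    )
    fit <- NULL
  } else {
    fit <- aov(value ~ group, data = df)
    tk <- TukeyHSD(fit)$group
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- tibble::tibble(
      group_1 = vapply(nm, `[[`, character(1), 1L),
      group_2 = vapply(nm, `[[`, character(1), 2L),
      diff = tk[, "diff"],
      lwr = tk[, "lwr"],
      upr = tk[, "upr"],
      p_adj = tk[, "p adj"]
    )
  }
  structure(list(fit = fit, pairwise = pairwise,
                 n_groups = length(counts), n = nrow(df)),
            class = "multi_group_comparison")
}

#' @exportS3Method generics::tidy
tidy.multi_group_comparison <- function(x, ...) {
  x$pairwise
}

#' @exportS3Method generics::glance
glance.multi_group_comparison <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(n_groups = x$n_groups, n = x$n,
                          statistic = NA_real_, p_value = 1))
  }
  s <- summary(x$fit)[[1]]
  tibble::tibble(
    n_groups = x$n_groups,
    n = x$n,
    statistic = s[["F value"]][1],
    p_value = s[["Pr(>F)"]][1]
  )
}

#' @export
print.multi_group_comparison <- function(x, ...) {
  cat("Tukey multiple comparisons over", x$n_groups, "groups (n =", x$n, ")\n")
  print(x$pairwise)
  invisible(x)
}

#' Filter proteins by high oxygen content
#'
#' Retains proteins whose side-chain oxygen frequency is at or above the
#' threshold (inclusive). The default 0.482 is the whole-proteome average
#' oxygen content of the reference glioma analysis and should be replaced by
#' the dataset's own mean when applied to other data.
#'
#' @param profiles A tibble from [element_profile()].
#' @param threshold Inclusive lower bound on `o_freq`.
#' @return The filtered profile tibble.
#' @export
filter_high_oxygen <- function(profiles, threshold = 0.482) {
  stopifnot(is.data.frame(profiles), "o_freq" %in% names(profiles))
  dplyr::filter(profiles, .data$o_freq >= threshold)
}
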