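#' Baseline amino-acid composition
#'
#' A typical vertebrate proteome-wide residue composition used as the default
#' by the synthetic proteome generator. It is a round-number stand-in for an
#' average vertebrate composition, not a measurement of the human proteome;
#' override it via `synthetic_config(aa_frequencies = ...)` when a specific
#' composition is needed.
#'
#' @return Named numeric vector over the 20 canonical residues, summing to 1.
#' @export
baseline_aa_frequencies <- function() {
  c(A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.037,
    G = 0.066, H = 0.026, I = 0.043, K = 0.057, L = 0.100,
    M = 0.021, N = 0.036, P = 0.063, Q = 0.048, R = 0.056,
    S = 0.083, T = 0.054, V = 0.060, W = 0.012, Y = 0.027)
}

# residues carrying side-chain oxygen
.O_RESIDUES <- c("D", "E", "N", "Q", "S", "T", "Y")

# Scale the probability mass of oxygen-bearing residues by (1 + delta/100)
# and renormalise the rest. Because only these residues contribute side-chain
# oxygen, the expected per-residue oxygen frequency scales by exactly the
# same factor.
.shift_o_frequencies <- function(freqs, delta) {
  f <- 1 + delta / 100
  m_o <- sum(freqs[.O_RESIDUES])
  max_delta <- 100 * (1 / m_o - 1)
  if (f <= 0 || f * m_o > 1) {
    stop("infeasible oxygen shift delta = ", delta,
         "%; feasible range is (-100, ", round(max_delta, 2), "] for this ",
         "baseline composition", call. = FALSE)
  }
  out <- freqs
  out[.O_RESIDUES] <- freqs[.O_RESIDUES] * f
  rest <- setdiff(names(freqs), .O_RESIDUES)
  out[rest] <- freqs[rest] * (1 - f * m_o) / (1 - m_o)
  out
}

#' Configuration of the synthetic glioma study
#'
#' Defines the conditions the generator emulates: a proteome of `n_proteins`
#' log-normal-length sequences; a planted differential-expression structure
#' (`dep_fraction` of proteins split `up_share` up vs the rest down,
#' mirroring the roughly 1:5 up:down ratio of the reference glioma analysis);
#' a planted oxygen shift of `delta` percent between the up and down sets'
#' compositions; an association of slope `beta` between a protein's oxygen
#' frequency z-score and its latent expression level; and an
#' immunohistochemistry-like design of `n_glioma` glioma samples and
#' `n_normal` normal cell types scored on the 4-level ordinal scale with
#' per-sample level jitter and a small missing-annotation rate.
#'
#' @param n_proteins Number of proteins.
#' @param median_length Median sequence length (log-normal).
#' @param length_sdlog Log-scale SD of the length distribution.
#' @param aa_frequencies Baseline residue composition (sums to 1).
#' @param beta Logit slope of latent expression per unit o_freq z-score.
#' @param dep_fraction Fraction of proteins with a planted expression shift.
#' @param up_share Share of planted proteins that are up-regulated.
#' @param delta Planted percent oxygen shift of up vs down compositions.
#' @param dep_shift Latent-scale expression shift of planted proteins
#'   (applied with opposite signs to glioma and normal samples).
#' @param n_glioma,n_normal Sample counts per group.
#' @param ordinal_noise Per-sample probability of a one-level jitter.
#' @param missing_rate Per-annotation probability of a missing score
#'   (default 0: complete matrices; raise it to exercise the
#'   minimum-sample filter).
#' @param cutpoints Latent cutpoints between the four ordinal levels.
#' @param seed Integer random seed; every emitted artifact is a pure function
#'   of the configuration including the seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 5000,
                             median_length = 375,
                             length_sdlog = 0.4,
                             aa_frequencies = baseline_aa_frequencies(),
                             beta = 2,
                             dep_fraction = 0.12,
                             up_share = 0.15,
                             delta = 5,
                             dep_shift = 12,
                             n_glioma = 12,
                             n_normal = 4,
                             ordinal_noise = 0.05,
                             missing_rate = 0,
                             cutpoints = c(-2, 0, 2),
                             seed = 1) {
  stopifnot(n_proteins >= 1, median_length >= 30, length_sdlog >= 0,
            n_glioma >= 1, n_normal >= 1, length(cutpoints) == 3,
            !is.unsorted(cutpoints))
  probs <- c(dep_fraction = dep_fraction, up_share = up_share,
             ordinal_noise = ordinal_noise, missing_rate = missing_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("dep_fraction, up_share, ordinal_noise and missing_rate must lie ",
         "in [0, 1]", call. = FALSE)
  }
  if (!setequal(names(aa_frequencies), .AA)) {
    stop("aa_frequencies must be named by the 20 canonical residues",
         call. = FALSE)
  }
  aa_frequencies <- aa_frequencies[.AA]
  if (abs(sum(aa_frequencies) - 1) > 1e-9 || any(aa_frequencies < 0)) {
    stop("aa_frequencies must be non-negative and sum to 1 (within 1e-9)",
         call. = FALSE)
  }
  .shift_o_frequencies(aa_frequencies, delta) # validates feasibility
  structure(
    list(n_proteins = as.integer(n_proteins),
         median_length = median_length,
         length_sdlog = length_sdlog,
         aa_frequencies = aa_frequencies,
         beta = beta,
         dep_fraction = dep_fraction,
         up_share = up_share,
         delta = delta,
         dep_shift = dep_shift,
         n_glioma = as.integer(n_glioma),
         n_normal = as.integer(n_normal),
         ordinal_noise = ordinal_noise,
         missing_rate = missing_rate,
         cutpoints = cutpoints,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic proteome
#'
#' Draws sequences i.i.d. from the baseline residue composition; proteins
#' planted as up-regulated use a composition whose oxygen-bearing residues
#' are scaled so that their expected side-chain oxygen frequency is `delta`
#' percent above the baseline (the planted down set keeps the baseline).
#' Deterministic for a fixed configuration.
#'
#' @param config A [synthetic_config()].
#' @return A list with `proteins` (tibble: `protein_id`, `sequence`) and
#'   `truth` (tibble: `protein_id`, `planted_class`, `oxygen_shifted`,
#'   `length`).
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  lens <- pmax(30L, as.integer(round(
    rlnorm(n, meanlog = log(config$median_length),
           sdlog = config$length_sdlog))))
  n_up <- round(n * config$dep_fraction * config$up_share)
  n_down <- round(n * config$dep_fraction * (1 - config$up_share))
  planted <- rep("none", n)
  idx <- sample.int(n)
  planted[idx[seq_len(n_up)]] <- "up"
  if (n_down > 0) planted[idx[n_up + seq_len(n_down)]] <- "down"
  shifted <- planted == "up"
  freq_base <- config$aa_frequencies
  freq_shift <- .shift_o_frequencies(freq_base, config$delta)
  draw <- function(which, freqs) {
    total <- sum(lens[which])
    res <- sample(.AA, total, replace = TRUE, prob = freqs)
    vapply(split(res, rep(seq_along(which), lens[which])),
           paste, character(1), collapse = "")
  }
  seqs <- character(n)
  if (any(!shifted)) seqs[!shifted] <- draw(which(!shifted), freq_base)
  if (any(shifted)) seqs[shifted] <- draw(which(shifted), freq_shift)
  ids <- sprintf("P%05d", seq_len(n))
  list(
    proteins = tibble::tibble(protein_id = ids, sequence = seqs),
    truth = tibble::tibble(protein_id = ids, planted_class = planted,
                           oxygen_shifted = shifted, length = lens)
  )
}

#' Generate a synthetic expression matrix
#'
#' Ordinal scores come from a proportional-odds latent model: a protein's
#' latent expression is `beta` times the z-score of its realized side-chain
#' oxygen frequency plus standard logistic noise, cut at the configured
#' cutpoints into the four ordinal levels. Planted up-regulated proteins get
#' a latent shift of `+dep_shift` in glioma samples and `-dep_shift` in
#' normal samples (reversed for down-regulated ones) so that expected
#' adjusted-score log2 ratios clear the ±1 classification gates. A per-sample
#' one-level jitter and missing annotations are then applied. Deterministic
#' for a fixed configuration.
#'
#' @param config A [synthetic_config()].
#' @param proteome Output of [simulate_proteome()].
#' @return A list with `scores` (a long score table as produced by
#'   [score_annotations()]) and `truth` (per-protein planted classes,
#'   realized `o_freq`; attributes `realized_delta` and `beta`).
#' @export
simulate_expression <- function(config, proteome) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  proteins <- proteome$proteins
  truth <- proteome$truth
  n <- nrow(proteins)
  o_freq <- element_frequency(proteins$sequence, "O")
  z <- if (n > 1L && stats::sd(o_freq) > 0) {
    (o_freq - mean(o_freq)) / stats::sd(o_freq)
  } else {
    rep(0, n)
  }
  normal_types <- c("endothelial", "glial", "neuronal", "neuropil")
  if (config$n_normal > 4L) {
    normal_types <- c(normal_types,
                      sprintf("normal_%02d", 5:config$n_normal))
  }
  normal_types <- normal_types[seq_len(config$n_normal)]
  samples <- tibble::tibble(
    sample_id = c(sprintf("glioma_%02d", seq_len(config$n_glioma)),
                  normal_types),
    group = rep(c("glioma", "normal"), c(config$n_glioma, config$n_normal)),
    cell_type = c(rep(NA_character_, config$n_glioma), normal_types)
  )
  ns <- nrow(samples)
  grid <- tidyr::expand_grid(protein = seq_len(n), sample = seq_len(ns))
  dir <- c(up = 1, none = 0, down = -1)[truth$planted_class[grid$protein]]
  sign_g <- ifelse(samples$group[grid$sample] == "glioma", 1, -1)
  latent <- config$beta * z[grid$protein] +
    dir * sign_g * config$dep_shift +
    rlogis(nrow(grid))
  lev <- findInterval(latent, config$cutpoints)
  jit <- runif(nrow(grid)) < config$ordinal_noise
  step <- sample(c(-1L, 1L), nrow(grid), replace = TRUE)
  lev[jit] <- pmin(3L, pmax(0L, lev[jit] + step[jit]))
  keep <- runif(nrow(grid)) >= config$missing_rate
  score <- .SCORES[lev + 1L]
  scores <- tibble::tibble(
    protein_id = proteins$protein_id[grid$protein],
    sample_id = samples$sample_id[grid$sample],
    group = samples$group[grid$sample],
    cell_type = samples$cell_type[grid$sample],
    level = .LEVELS[lev + 1L],
    score = unname(score),
    adjusted = adjust_zero(unname(score))
  )[keep, ]
  truth_out <- dplyr::mutate(truth, o_freq = o_freq, o_zscore = z)
  up_o <- o_freq[truth$planted_class == "up"]
  down_o <- o_freq[truth$planted_class == "down"]
  attr(truth_out, "realized_delta") <-
    if (length(up_o) > 0 && length(down_o) > 0) {
      percent_difference(mean(up_o), mean(down_o))
    } else {
      NA_real_
    }
  attr(truth_out, "beta") <- config$beta
  list(scores = scores, truth = truth_out)
}

#' Run the full synthetic study generator
#'
#' Convenience wrapper: generates the proteome and its expression matrix in
#' one call.
#'
#' @param config A [synthetic_config()].
#' @return A list with `proteins`, `scores`, `truth` and `config`.
#' @export
simulate_study <- function(config = synthetic_config()) {
  proteome <- simulate_proteome(config)
  expr <- simulate_expression(config, proteome)
  list(proteins = proteome$proteins, scores = expr$scores,
       truth = expr$truth, config = config)
}

#' Write a proteome to FASTA
#'
#' @param proteins A tibble with `protein_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- proteins$protein_id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
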