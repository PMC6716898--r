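#' Read protein sequences from FASTA
#'
#' Reads a (possibly line-wrapped, multi-record) amino-acid FASTA file into a
#' tibble. The record identifier is the first whitespace-delimited token of
#' the header line.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `protein_id` and `sequence`.
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    protein_id = vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L),
    sequence = unname(as.character(aa))
  )
}

# Uppercase and strip whitespace; returns cleaned sequence.
.clean_sequence <- function(sequence) {
  gsub("[[:space:]]+", "", toupper(sequence))
}

# Per-sequence element totals and scorable length. Non-canonical characters
# (X, B, Z, J, U, O, *, -, ...) contribute to neither numerator nor
# denominator.
.sequence_stats <- function(sequence, elements = c("C", "O")) {
  weights <- lapply(elements, .weight_lookup)
  names(weights) <- elements
  n <- length(sequence)
  out <- matrix(0, nrow = n, ncol = length(elements) + 2L,
                dimnames = list(NULL, c("length", "n_nonstandard", elements)))
  for (i in seq_len(n)) {
    codes <- utf8ToInt(sequence[i])
    codes <- codes[codes >= 1L & codes <= 127L]
    ok <- .canonical_lookup[codes]
    scorable <- codes[ok]
    out[i, "length"] <- length(scorable)
    out[i, "n_nonstandard"] <- length(codes) - length(scorable)
    for (el in elements) out[i, el] <- sum(weights[[el]][scorable])
  }
  out
}

#' Side-chain element frequency of protein sequences
#'
#' Computes the average number of side-chain atoms of `element` per residue:
#' the sum over residue types of (side-chain atom count × residue count),
#' divided by the scorable sequence length. Ambiguous or non-standard
#' residues are excluded from both numerator and denominator.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @param element Element symbol (`"C"`, `"H"`, `"N"`, `"O"`, `"S"`).
#' @return Numeric vector of per-protein frequencies.
#' @examples
#' element_frequency("DDDD", "O") # 2
#' element_frequency("ACDEFGHIKLMNPQRSTVWY", "O") # 0.45
#' @export
element_frequency <- function(sequence, element) {
  if (length(element) != 1L || !element %in% .ELEMENTS) {
    stop("unknown element: '", paste(element, collapse = ","), "'",
         call. = FALSE)
  }
  st <- .sequence_stats(.clean_sequence(sequence), element)
  if (any(st[, "length"] == 0)) {
    stop("unscorable protein: no canonical residues left after filtering",
         call. = FALSE)
  }
  unname(st[, element] / st[, "length"])
}

#' Side-chain carbon:oxygen ratio of protein sequences
#'
#' Total side-chain carbon atoms divided by total side-chain oxygen atoms,
#' computed from atom totals (not from independently rounded frequencies).
#' Proteins with zero side-chain oxygen have an undefined ratio, returned as
#' `NA`.
#'
#' @inheritParams element_frequency
#' @return Numeric vector; `NA` where the side-chain oxygen total is zero.
#' @examples
#' co_ratio("D") # 1
#' co_ratio("AAA") # NA: no side-chain oxygen
#' @export
co_ratio <- function(sequence) {
  st <- .sequence_stats(.clean_sequence(sequence), c("C", "O"))
  if (any(st[, "length"] == 0)) {
    stop("unscorable protein: no canonical residues left after filtering",
         call. = FALSE)
  }
  unname(ifelse(st[, "O"] > 0, st[, "C"] / st[, "O"], NA_real_))
}

#' Per-protein side-chain element profiles
#'
#' The entry point of the composition stage: takes a tibble of protein
#' sequences (as returned by [read_proteins()]) and computes, per protein,
#' the scorable length, side-chain oxygen and carbon frequencies, and the
#' C:O ratio. Sequences are uppercased and whitespace-stripped; ambiguous or
#' non-standard residues are excluded from both numerator and denominator
#' with a warning naming the affected proteins; proteins with no scorable
#' residues are dropped with a warning.
#'
#' @param proteins A data frame with columns `protein_id` and `sequence`.
#' @return A tibble with columns `protein_id`, `length`, `o_freq`, `c_freq`,
#'   `co_ratio` (`NA` when the protein has no side-chain oxygen).
#' @examples
#' element_profile(tibble::tibble(protein_id = "p1", sequence = "DDWGA"))
#' @export
element_profile <- function(proteins) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "sequence") %in% names(proteins)))
  seqs <- .clean_sequence(proteins$sequence)
  st <- .sequence_stats(seqs, c("C", "O"))
  ns <- st[, "n_nonstandard"] > 0
  if (any(ns)) {
    ids <- proteins$protein_id[ns]
    warning(sum(ns), " protein(s) contain non-standard residues, excluded ",
            "from scoring: ", paste(head(ids, 5L), collapse = ", "),
            if (length(ids) > 5L) ", ..." else "", call. = FALSE)
  }
  drop <- st[, "length"] == 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " protein(s) with no scorable residues: ",
            paste(head(proteins$protein_id[drop], 5L), collapse = ", "),
            call. = FALSE)
  }
  keep <- which(!drop)
  len <- unname(st[keep, "length"])
  o <- unname(st[keep, "O"])
  cc <- unname(st[keep, "C"])
  tibble::tibble(
    protein_id = proteins$protein_id[keep],
    length = as.integer(len),
    o_freq = o / len,
    c_freq = cc / len,
    co_ratio = ifelse(o > 0, cc / o, NA_real_)
  )
}

#' Proteome-average element frequency
#'
#' Unweighted arithmetic mean of per-protein side-chain frequencies — the
#' average element content over all sequences of a proteome, not a
#' length-weighted pool.
#'
#' @param profiles A tibble from [element_profile()].
#' @param element `"O"` or `"C"`.
#' @return A single number.
#' @export
proteome_mean_frequency <- function(profiles, element = c("O", "C")) {
  element <- match.arg(element)
  col <- if (element == "O") "o_freq" else "c_freq"
  stopifnot(is.data.frame(profiles), col %in% names(profiles))
  if (nrow(profiles) == 0L) {
    stop("cannot average an empty profile list", call. = FALSE)
  }
  mean(profiles[[col]])
}

#' Write element profiles to TSV
#'
#' Writes the per-protein profile table with frequencies rounded to six
#' decimals; undefined C:O ratios become empty cells.
#'
#' @param profiles A tibble from [element_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_element_profiles <- function(profiles, path) {
  out <- dplyr::mutate(profiles,
                       dplyr::across(c("o_freq", "c_freq", "co_ratio"),
                                     ~ round(.x, 6)))
  readr::write_tsv(out, path, na = "")
  invisible(path)
}
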