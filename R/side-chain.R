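# Side-chain atom counts for the 20 canonical residues, R-group only
# (backbone excluded). Derived once from standard free amino-acid molecular
# formulas minus the free glycine formula C2H5NO2, so glycine's side chain
# counts as zero for every element.

.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.ELEMENTS <- c("C", "H", "N", "O", "S")

.SIDE_CHAIN <- matrix(
  c(
    # C  H  N  O  S
      1, 2, 0, 0, 0,  # A
      1, 2, 0, 0, 1,  # C
      2, 2, 0, 2, 0,  # D
      3, 4, 0, 2, 0,  # E
      7, 6, 0, 0, 0,  # F
      0, 0, 0, 0, 0,  # G
      4, 4, 2, 0, 0,  # H
      4, 8, 0, 0, 0,  # I
      4, 9, 1, 0, 0,  # K
      4, 8, 0, 0, 0,  # L
      3, 6, 0, 0, 1,  # M
      2, 3, 1, 1, 0,  # N
      3, 4, 0, 0, 0,  # P
      3, 5, 1, 1, 0,  # Q
      4, 9, 3, 0, 0,  # R
      1, 2, 0, 1, 0,  # S
      2, 4, 0, 1, 0,  # T
      3, 6, 0, 0, 0,  # V
      9, 7, 1, 0, 0,  # W
      7, 6, 0, 1, 0   # Y
  ),
  nrow = 20, byrow = TRUE,
  dimnames = list(.AA, .ELEMENTS)
)

#' Side-chain atom counts per residue
#'
#' Returns the number of atoms of each element (C, H, N, O, S) in the side
#' chain (R-group) of each of the 20 canonical amino acids. Backbone atoms
#' are excluded, so glycine has zero for every element. The table is derived
#' from standard free amino-acid molecular formulas minus the free glycine
#' formula.
#'
#' @return A tibble with columns `residue` (one-letter code) and one integer
#'   column per element (`C`, `H`, `N`, `O`, `S`).
#' @examples
#' side_chain_table()
#' @export
side_chain_table <- function() {
  tibble::as_tibble(.SIDE_CHAIN, rownames = "residue")
}

#' Atom count in an amino-acid side chain
#'
#' @param residue Character vector of one-letter amino-acid codes
#'   (case-insensitive).
#' @param element Single element symbol, one of `"C"`, `"H"`, `"N"`, `"O"`,
#'   `"S"`.
#' @return Integer vector of side-chain atom counts, one per residue.
#' @examples
#' side_chain_count("D", "O") # 2
#' side_chain_count(c("G", "W"), "C")
#' @export
side_chain_count <- function(residue, element) {
  if (length(element) != 1L || !element %in% .ELEMENTS) {
    stop("unknown element: '", paste(element, collapse = ","),
         "' (expected one of ", paste(.ELEMENTS, collapse = ", "), ")",
         call. = FALSE)
  }
  res <- toupper(residue)
  bad <- setdiff(unique(res), .AA)
  if (length(bad) > 0L) {
    stop("unknown residue(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  unname(.SIDE_CHAIN[res, element])
}

# fast per-byte lookup of side-chain weights; 0 for non-canonical characters,
# NA-free. Returns numeric vector indexed by utf8 code.
.weight_lookup <- function(element) {
  w <- numeric(127L)
  w[utf8ToInt(paste(.AA, collapse = ""))] <- .SIDE_CHAIN[, element]
  w
}

# byte lookup flagging canonical residues
.canonical_lookup <- local({
  ok <- logical(127L)
  ok[utf8ToInt(paste(.AA, collapse = ""))] <- TRUE
  ok
})
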