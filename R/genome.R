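.PRIMARY_CHROMS <- c(as.character(1:22), "X", "Y", "MT", "M")

# strip a leading "chr" prefix so GFF/GTF dialects tally together
.norm_chrom <- function(x) {
  sub("^chr", "", x, ignore.case = TRUE)
}

#' Load gene loci from a GFF3/GTF annotation
#'
#' Imports gene-level features and returns one locus per gene symbol. The
#' symbol is taken from the first available of the `Name`, `gene_name`,
#' `gene_id`, `ID` attributes. When a symbol occurs more than once, the
#' record on a primary-assembly chromosome (1-22, X, Y, MT) is kept and the
#' duplicates are reported via a message; among several primary records the
#' first wins.
#'
#' @param path Path to a GFF3 or GTF file.
#' @return A tibble with columns `gene`, `chromosome` (with any `chr` prefix
#'   stripped), `start`, `end`, `strand`.
#' @export
load_gene_loci <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path),
    error = function(e) {
      stop("failed to parse annotation '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (!is.null(gr$type)) {
    genes <- gr[as.character(gr$type) == "gene"]
  } else {
    genes <- gr
  }
  if (length(genes) == 0L) {
    warning("annotation contains no gene-level features", call. = FALSE)
    return(tibble::tibble(gene = character(), chromosome = character(),
                          start = integer(), end = integer(),
                          strand = character()))
  }
  mc <- as.data.frame(genes)
  symbol_cols <- intersect(c("Name", "gene_name", "gene_id", "ID"), names(mc))
  symbol <- rep(NA_character_, nrow(mc))
  for (col in symbol_cols) {
    symbol <- dplyr::coalesce(symbol, as.character(mc[[col]]))
  }
  loci <- tibble::tibble(
    gene = trimws(symbol),
    chromosome = .norm_chrom(as.character(mc$seqnames)),
    start = mc$start,
    end = mc$end,
    strand = as.character(mc$strand)
  ) |>
    dplyr::filter(!is.na(.data$gene), .data$gene != "")
  loci <- loci |>
    dplyr::mutate(.primary = .data$chromosome %in% .PRIMARY_CHROMS) |>
    dplyr::arrange(.data$gene, dplyr::desc(.data$.primary))
  dup <- duplicated(loci$gene)
  if (any(dup)) {
    message(sum(dup), " duplicate gene record(s) dropped (non-primary or ",
            "repeated): ", paste(head(unique(loci$gene[dup]), 5L),
                                 collapse = ", "))
  }
  loci |>
    dplyr::filter(!dup) |>
    dplyr::select(-".primary")
}

#' Count up/down regulated genes per chromosome
#'
#' Tallies how many up- and down-regulated genes fall on each chromosome of
#' the annotation. Gene sets are deduplicated first (with a message); genes
#' without a locus are collected into the `unmapped` attribute so that mapped
#' counts plus unmapped genes always equal the input set size per direction.
#'
#' @param up,down Character vectors of gene symbols.
#' @param loci A tibble from [load_gene_loci()].
#' @return A tibble of class `chrom_counts` with columns `chromosome`,
#'   `n_up`, `n_down` (all chromosomes present in `loci`, zero-filled), and
#'   attribute `unmapped` (a list with `up` and `down`).
#' @export
chromosome_counts <- function(up, down, loci) {
  stopifnot(is.data.frame(loci),
            all(c("gene", "chromosome") %in% names(loci)))
  dedupe <- function(x, label) {
    x <- trimws(x)
    n_dup <- sum(duplicated(x))
    if (n_dup > 0L) {
      message(n_dup, " duplicate id(s) removed from the ", label, " set")
    }
    unique(x)
  }
  up <- dedupe(up, "up")
  down <- dedupe(down, "down")
  chrom_of <- stats::setNames(loci$chromosome, loci$gene)
  tally <- function(genes) {
    chroms <- chrom_of[genes]
    list(mapped = table(chroms[!is.na(chroms)]),
         unmapped = genes[is.na(chroms)])
  }
  t_up <- tally(up)
  t_down <- tally(down)
  all_chroms <- unique(loci$chromosome)
  ord <- order(match(all_chroms, .PRIMARY_CHROMS, nomatch = 999L), all_chroms)
  all_chroms <- all_chroms[ord]
  out <- tibble::tibble(
    chromosome = all_chroms,
    n_up = as.integer(t_up$mapped[all_chroms]),
    n_down = as.integer(t_down$mapped[all_chroms])
  ) |>
    dplyr::mutate(n_up = dplyr::coalesce(.data$n_up, 0L),
                  n_down = dplyr::coalesce(.data$n_down, 0L))
  class(out) <- c("chrom_counts", class(out))
  attr(out, "unmapped") <- list(up = t_up$unmapped, down = t_down$unmapped)
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.chrom_counts <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("n_up", "n_down"), names_to = "direction",
                        values_to = "n") |>
    dplyr::mutate(
      direction = ifelse(.data$direction == "n_up", "up", "down"),
      chromosome = factor(.data$chromosome, levels = object$chromosome)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chromosome, y = .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(up = "#d73027", down = "#4575b4")) +
    ggplot2::labs(x = "chromosome", y = "differentially expressed genes",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Write chromosome counts to TSV
#'
#' @param counts A `chrom_counts` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chromosome_counts <- function(counts, path) {
  readr::write_tsv(tibble::as_tibble(counts), path)
  invisible(path)
}
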