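# Independent oracles used only by tests. Each re-derives the quantity it
# checks from first principles, on a code path separate from the package.

# Molecular formulas of the free amino acids (C, H, N, O, S). The side-chain
# composition oracle is (free amino acid) - (free glycine), an independent
# second derivation of the package's hard-coded table.
free_aa_formulas <- function() {
  m <- rbind(
    A = c(3, 7, 1, 2, 0),
    R = c(6, 14, 4, 2, 0),
    N = c(4, 8, 2, 3, 0),
    D = c(4, 7, 1, 4, 0),
    C = c(3, 7, 1, 2, 1),
    E = c(5, 9, 1, 4, 0),
    Q = c(5, 10, 2, 3, 0),
    G = c(2, 5, 1, 2, 0),
    H = c(6, 9, 3, 2, 0),
    I = c(6, 13, 1, 2, 0),
    L = c(6, 13, 1, 2, 0),
    K = c(6, 14, 2, 2, 0),
    M = c(5, 11, 1, 2, 1),
    F = c(9, 11, 1, 2, 0),
    P = c(5, 9, 1, 2, 0),
    S = c(3, 7, 1, 3, 0),
    T = c(4, 9, 1, 3, 0),
    W = c(11, 12, 2, 2, 0),
    Y = c(9, 11, 1, 3, 0),
    V = c(5, 11, 1, 2, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S")
  m
}

oracle_side_chain <- function(residue, element) {
  m <- free_aa_formulas()
  m[residue, element] - m["G", element]
}

oracle_element_freq <- function(sequence, element) {
  res <- strsplit(sequence, "")[[1]]
  res <- res[res %in% rownames(free_aa_formulas())]
  sum(vapply(res, oracle_side_chain, numeric(1), element = element)) /
    length(res)
}

random_protein <- function(len) {
  paste(sample(rownames(free_aa_formulas()), len, replace = TRUE),
        collapse = "")
}

# mid-ranks computed from sorted positions rather than rank()
oracle_midranks <- function(x) {
  s <- sort(x)
  vapply(x, function(v) mean(which(abs(s - v) < 1e-12)), numeric(1))
}

# exhaustive permutation two-sided rank-sum p-value (doubling convention)
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- oracle_midranks(pooled)
  n <- length(pooled)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)])
  sets <- utils::combn(n, na)
  ws <- apply(sets, 2, function(ix) sum(r[ix]))
  eps <- 1e-9 * n
  min(1, 2 * min(mean(ws <= w_obs + eps), mean(ws >= w_obs - eps)))
}

# brute-force ECDF scan for the two-sample KS statistic
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}

# Benjamini-Hochberg step-up by hand: q_(i) = min_{j >= i} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(ps[i:m] * m / (i:m), 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# small staining-annotation table covering the 12 glioma + 4 normal design
toy_annotations <- function(proteins = c("p1", "p2"),
                            glioma_levels = rep("high", 12),
                            normal_levels = rep("not_detected", 4)) {
  normals <- c("endothelial", "glial", "neuronal", "neuropil")
  per_protein <- tibble::tibble(
    sample_id = c(sprintf("glioma_%02d", 1:12), normals),
    group = rep(c("glioma", "normal"), c(12, 4)),
    cell_type = c(rep(NA_character_, 12), normals),
    level = c(glioma_levels, normal_levels)
  )
  dplyr::bind_rows(lapply(proteins, function(p) {
    dplyr::mutate(per_protein, protein_id = p, .before = 1)
  }))
}

# three-chromosome GFF3 fixture with a duplicate gene on an alt scaffold
write_toy_gff <- function(path = tempfile(fileext = ".gff3")) {
  lines <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t100\t500\t.\t+\t.\tID=g1;Name=GENE1",
    "chr1\ttest\tgene\t900\t1500\t.\t-\t.\tID=g2;Name=GENE2",
    "chr2\ttest\tgene\t200\t700\t.\t+\t.\tID=g3;Name=GENE3",
    "chrX\ttest\tgene\t300\t800\t.\t+\t.\tID=g4;Name=GENE4",
    "KI270713.1\ttest\tgene\t10\t90\t.\t+\t.\tID=g5;Name=GENE1"
  )
  writeLines(lines, path)
  path
}
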