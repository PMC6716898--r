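test_that("side-chain table matches the free-amino-acid formula derivation", {
  tab <- side_chain_table()
  expect_setequal(tab$residue, rownames(free_aa_formulas()))
  for (el in c("C", "H", "N", "O", "S")) {
    expect_equal(
      tab[[el]],
      unname(oracle_side_chain(tab$residue, el)),
      info = paste("element", el)
    )
  }
  gly <- tab[tab$residue == "G", c("C", "H", "N", "O", "S")]
  expect_true(all(gly == 0))
  expect_true(all(tab[c("C", "H", "N", "O", "S")] <= 11))
  # side-chain oxygen counts are exactly D/E = 2, N/Q/S/T/Y = 1, others 0
  o <- setNames(tab$O, tab$residue)
  expect_equal(o[c("D", "E")], c(D = 2, E = 2))
  expect_equal(o[c("N", "Q", "S", "T", "Y")],
               c(N = 1, Q = 1, S = 1, T = 1, Y = 1))
  expect_true(all(o[setdiff(names(o), c("D", "E", "N", "Q", "S", "T", "Y"))] == 0))
})

test_that("side_chain_count returns stored counts and rejects unknown symbols", {
  expect_identical(side_chain_count("G", "O"), 0)
  expect_identical(side_chain_count("D", "O"), 2)
  expect_identical(side_chain_count("W", "C"), 9)
  expect_identical(side_chain_count(c("d", "w"), "C"), c(2, 9)) # case-insensitive
  expect_error(side_chain_count("X", "O"), "X")
  expect_error(side_chain_count("A", "P"), "element")
})

test_that("element_frequency computes sum(wi * pi) / L", {
  expect_equal(element_frequency("GG", "O"), 0)
  expect_equal(element_frequency("DDDD", "O"), 2)
  expect_equal(element_frequency("ACDEFGHIKLMNPQRSTVWY", "O"), 9 / 20)
  expect_equal(element_frequency("ACDEFGHIKLMNPQRSTVWY", "C"), 67 / 20)
})

test_that("element_frequency matches the formula oracle on random sequences", {
  set.seed(42)
  for (i in 1:200) {
    s <- random_protein(sample(10:200, 1))
    expect_equal(element_frequency(s, "O"), oracle_element_freq(s, "O"),
                 tolerance = 1e-12)
    expect_equal(element_frequency(s, "C"), oracle_element_freq(s, "C"),
                 tolerance = 1e-12)
  }
})

test_that("element_frequency is permutation-invariant and concatenation-consistent", {
  set.seed(7)
  for (i in 1:20) {
    s1 <- random_protein(sample(5:80, 1))
    s2 <- random_protein(sample(5:80, 1))
    shuffled <- paste(sample(strsplit(s1, "")[[1]]), collapse = "")
    expect_identical(element_frequency(shuffled, "O"),
                     element_frequency(s1, "O"))
    l1 <- nchar(s1); l2 <- nchar(s2)
    expect_equal(
      element_frequency(paste0(s1, s2), "O"),
      (l1 * element_frequency(s1, "O") + l2 * element_frequency(s2, "O")) /
        (l1 + l2),
      tolerance = 1e-14
    )
  }
})

test_that("replacing a residue with a more oxygen-rich one increases o_freq", {
  base <- "ALKGWFAVM"             # zero side-chain oxygen
  one_o <- sub("A", "S", base)    # S carries one side-chain oxygen
  two_o <- sub("A", "D", base)    # D carries two
  expect_lt(element_frequency(base, "O"), element_frequency(one_o, "O"))
  expect_lt(element_frequency(one_o, "O"), element_frequency(two_o, "O"))
})

test_that("frequencies stay within the attainable bounds", {
  set.seed(11)
  seqs <- vapply(1:100, function(i) random_protein(sample(5:100, 1)),
                 character(1))
  o <- element_frequency(seqs, "O")
  cc <- element_frequency(seqs, "C")
  expect_true(all(o >= 0 & o <= 2))
  expect_true(all(cc >= 0 & cc <= 9))
  expect_equal(element_frequency("DEDE", "O"), 2) # attained by poly-D/E
  expect_equal(element_frequency("WWW", "C"), 9)  # attained by poly-W
})

test_that("co_ratio uses atom totals and flags zero-oxygen proteins", {
  expect_equal(co_ratio("D"), 1)
  expect_equal(co_ratio("ACDEFGHIKLMNPQRSTVWY"), 67 / 9)
  expect_true(is.na(co_ratio("AAA")))
  set.seed(3)
  s <- random_protein(60)
  prof <- element_profile(tibble::tibble(protein_id = "x", sequence = s))
  if (!is.na(prof$co_ratio)) {
    expect_equal(prof$co_ratio, prof$c_freq / prof$o_freq, tolerance = 1e-12)
  }
})

test_that("element_profile handles case, whitespace and non-standard residues", {
  prof <- element_profile(tibble::tibble(protein_id = "p", sequence = "d w\nw"))
  expect_equal(prof$length, 3L)
  expect_equal(prof$o_freq, 2 / 3)
  expect_warning(
    prof2 <- element_profile(
      tibble::tibble(protein_id = "p", sequence = "DXXD")),
    "non-standard"
  )
  expect_equal(prof2$length, 2L)  # X excluded from numerator and denominator
  expect_equal(prof2$o_freq, 2)
  expect_warning(
    expect_warning(
      prof3 <- element_profile(
        tibble::tibble(protein_id = c("ok", "gone"),
                       sequence = c("DD", "XXX"))),
      "non-standard"),
    "dropping"
  )
  expect_equal(prof3$protein_id, "ok")
  expect_error(element_frequency("XXX", "O"), "unscorable")
})

test_that("proteome_mean_frequency is the unweighted mean of per-protein values", {
  prof <- tibble::tibble(o_freq = c(0.4, 0.6), c_freq = c(3, 4))
  expect_equal(proteome_mean_frequency(prof, "O"), 0.5)
  expect_equal(proteome_mean_frequency(prof[1, ], "O"), 0.4)
  expect_error(proteome_mean_frequency(prof[0, ], "O"), "empty")
  set.seed(5)
  seqs <- vapply(1:100, function(i) random_protein(50), character(1))
  profs <- element_profile(tibble::tibble(protein_id = as.character(1:100),
                                          sequence = seqs))
  expect_equal(proteome_mean_frequency(profs, "O"),
               sum(vapply(seqs, oracle_element_freq, numeric(1), "O")) / 100,
               tolerance = 1e-12)
})

test_that("FASTA and profile TSV round-trip", {
  proteins <- tibble::tibble(protein_id = c("a", "b"),
                             sequence = c("DDWG", "ACDEFGHIKLMNPQRSTVWY"))
  fa <- tempfile(fileext = ".fasta")
  write_proteome_fasta(proteins, fa)
  back <- read_proteins(fa)
  expect_equal(back, proteins)
  prof <- element_profile(proteins)
  tsv <- tempfile(fileext = ".tsv")
  write_element_profiles(prof, tsv)
  re <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(re$o_freq, round(prof$o_freq, 6))
  # undefined C:O is written as an empty cell
  prof_na <- element_profile(tibble::tibble(protein_id = "z", sequence = "AAA"))
  write_element_profiles(prof_na, tsv)
  expect_true(is.na(readr::read_tsv(tsv, show_col_types = FALSE)$co_ratio))
})
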