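test_that("collapse_to_nt_alleles collapses exact duplicates and orders deterministically", {
  s <- random_codon_nt(28 * 3, seed = 3)
  tab <- collapse_to_nt_alleles(seq_table(rep(s, 5), rep("g1", 5)))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$count, 5L)
  expect_identical(tab$nt_allele_id, "p1")

  # counts sum to input size; permuting input changes nothing
  seqs <- vapply(c(1, 1, 2, 3, 3, 3), function(i)
    random_codon_nt(28, seed = i), character(1))
  groups <- c("a", "a", "b", "b", "a", "b")
  tab1 <- collapse_to_nt_alleles(seq_table(seqs, groups))
  expect_equal(sum(tab1$count), 6L)
  perm <- c(4, 2, 6, 1, 3, 5)
  tab2 <- collapse_to_nt_alleles(seq_table(seqs[perm], groups[perm],
                                           samples = paste0("s", perm)))
  expect_identical(tab1, tab2)
  # descending count, then lexicographic
  expect_true(all(diff(tab1$count) <= 0))

  expect_equal(nrow(collapse_to_nt_alleles(seq_table(character(), character()))),
               0L)
  expect_error(collapse_to_nt_alleles(seq_table("ACGR", "g")),
               class = "ambiguous_sequence")
})

test_that("collapse_to_aa_alleles merges synonymous-only nucleotide alleles", {
  nt1 <- paste(rep(base_nt(), 2), collapse = "")
  nt2 <- nt1
  substr(nt2, 3, 3) <- "C"   # TAT -> TAC, still Tyr
  substr(nt2, 87, 87) <- "C"
  expect_identical(translate_nt(nt1), translate_nt(nt2))
  nt_tab <- collapse_to_nt_alleles(seq_table(c(nt1, nt2, nt2),
                                             c("g1", "g2", "g2")))
  expect_equal(nrow(nt_tab), 2L)
  aa_tab <- collapse_to_aa_alleles(nt_tab)
  expect_equal(nrow(aa_tab), 1L)
  expect_equal(aa_tab$count, 3L)
  expect_identical(aa_tab$groups, "g1,g2")

  # no synonymous pairs -> aa count equals nt count
  distinct <- vapply(1:4, function(i) random_codon_nt(28, seed = 40 + i),
                     character(1))
  nt_tab2 <- collapse_to_nt_alleles(seq_table(distinct, rep("g", 4)))
  expect_equal(nrow(collapse_to_aa_alleles(nt_tab2)), 4L)
})

test_that("aa allele count equals a brute-force distinct-translation oracle", {
  set.seed(77)
  base <- vapply(1:5, function(i) random_codon_nt(10, seed = 60 + i),
                 character(1))
  pool <- unlist(lapply(base, function(s) {
    v <- s
    # synonymous toggle of a random codon, when one exists
    for (k in 1:2) {
      col <- sample(0:9, 1)
      alt <- prdm9znf:::synonymous_variant(v, col)
      if (!is.null(alt)) v <- alt
    }
    c(s, v)
  }))
  seqs <- sample(pool, 30, replace = TRUE)
  nt_tab <- collapse_to_nt_alleles(seq_table(seqs, rep("g", 30)))
  aa_tab <- collapse_to_aa_alleles(nt_tab)
  oracle <- length(unique(vapply(seqs, translate_nt, character(1))))
  expect_equal(nrow(aa_tab), oracle)
  expect_equal(sum(aa_tab$count), 30L)
})

test_that("assign_repeat_letters encodes aa identity and synonymous variants", {
  al1 <- allele_from_repeats(rep(base_nt(), 7))
  enc1 <- assign_repeat_letters(list(al1))
  expect_identical(unname(enc1$encodings[[1]]), rep("A", 7))

  # one synonymous nt difference in one repeat -> same letters, one '*'
  syn <- prdm9znf:::synonymous_variant(base_nt(), 0)
  al2 <- allele_from_repeats(c(rep(base_nt(), 3), syn, rep(base_nt(), 3)),
                             id = "a2")
  enc2 <- assign_repeat_letters(list(al1, al2))
  e1 <- enc2$encodings[["a1"]]; e2 <- enc2$encodings[["a2"]]
  expect_identical(unname(e1), rep("A", 7))
  expect_identical(unname(e2), c("A", "A", "A", "A*", "A", "A", "A"))
  expect_identical(substr(e2, 1, 1), rep("A", 7))

  # three distinct aa repeats in known orders match the construction
  r1 <- base_nt()
  r2 <- mutate_repeat(base_nt(), 11, "K")
  r3 <- mutate_repeat(base_nt(), 17, "D")
  alx <- allele_from_repeats(c(r1, r2, r3, r2), id = "x")
  aly <- allele_from_repeats(c(r3, r1), id = "y")
  encx <- assign_repeat_letters(list(alx, aly))
  expect_identical(unname(encx$encodings[["x"]]), c("A", "B", "C", "B"))
  expect_identical(unname(encx$encodings[["y"]]), c("C", "A"))
  # injective on distinct aa repeats
  expect_equal(anyDuplicated(encx$legend$aa_seq), 0L)
})

test_that("find_polymorphic_sites counts planted columns and contact fraction", {
  expect_equal(find_polymorphic_sites(rep(base_aa(), 4))$n_polymorphic, 0L)

  two <- c(base_aa(), translate_nt(mutate_repeat(base_nt(), 7, "T")))
  rep2 <- find_polymorphic_sites(two)
  expect_equal(rep2$columns, 7L)

  # generator closure: k planted columns, half at contact offsets
  lib <- simulate_repeat_library(sim_config(seed = 31))
  repx <- find_polymorphic_sites(lib$aa)
  expect_setequal(repx$columns, lib$ground_truth$variable_columns)
  expect_equal(repx$fraction_at_contact, 0.5)

  expect_error(find_polymorphic_sites(c("AAA", "AAAA")),
               class = "ragged_alignment")
})

test_that("cross_group_sharing lists multi-group alleles at both levels", {
  s_shared <- paste(rep(base_nt(), 2), collapse = "")
  s_a <- paste(c(base_nt(), mutate_repeat(base_nt(), 11, "K")), collapse = "")
  s_b <- paste(c(base_nt(), mutate_repeat(base_nt(), 17, "D")), collapse = "")
  tab <- collapse_to_nt_alleles(seq_table(c(s_shared, s_shared, s_a, s_b),
                                          c("g1", "g2", "g1", "g2")))
  sh <- cross_group_sharing(tab, collapse_to_aa_alleles(tab))
  expect_equal(sum(sh$level == "nt"), 1L)
  expect_identical(sh$groups[sh$level == "nt"], "g1,g2")

  # disjoint groups -> empty report
  tab2 <- collapse_to_nt_alleles(seq_table(c(s_a, s_b), c("g1", "g2")))
  sh2 <- cross_group_sharing(tab2, collapse_to_aa_alleles(tab2))
  expect_equal(nrow(sh2), 0L)
})

test_that("the published spectrum encodes the printed sharing structure", {
  spec_nt <- pan_prdm9_spectrum("nt")
  shared_nt <- Reduce(intersect, spec_nt$groups[c("central", "eastern")])
  expect_identical(shared_nt, "p6")
  expect_length(Reduce(intersect, spec_nt$groups[c("eastern", "bonobo")]), 0L)

  spec_aa <- pan_prdm9_spectrum("aa")
  expect_identical(Reduce(intersect, spec_aa$groups[c("eastern", "bonobo")]),
                   "P1")
  # group totals unchanged by the aa collapse
  expect_identical(lengths(spec_aa$groups), lengths(spec_nt$groups))
})
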