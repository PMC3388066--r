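test_that("split_into_repeats cuts arrays and round-trips", {
  units <- vapply(1:7, function(i) random_codon_nt(28, seed = i), character(1))
  arr <- paste(units, collapse = "")
  reps <- split_into_repeats(arr)
  expect_length(reps, 7L)
  expect_identical(vapply(reps, `[[`, character(1), "nt_seq"), units)
  expect_identical(paste(vapply(reps, `[[`, character(1), "nt_seq"),
                         collapse = ""), arr)

  one <- split_into_repeats(units[1])
  expect_length(one, 1L)
  expect_identical(one[[1]]$nt_seq, units[1])

  # 5 distinct units in a known order come back in that order
  ord <- c(3, 1, 5, 2, 4)
  reps5 <- split_into_repeats(paste(units[ord], collapse = ""))
  expect_identical(vapply(reps5, `[[`, character(1), "nt_seq"), units[ord])
})

test_that("split_into_repeats handles the truncated leading repeat", {
  arr <- paste0(trunc_nt(), base_nt(), base_nt())
  reps <- split_into_repeats(arr, leading_truncated = TRUE)
  expect_length(reps, 3L)
  expect_true(reps[[1]]$is_truncated)
  expect_identical(reps[[1]]$nt_seq, trunc_nt())
  expect_false(any(vapply(reps[-1], `[[`, logical(1), "is_truncated")))
  al <- znf_allele("x", repeats = reps)
  expect_equal(n_full_repeats(al), 2L)
  expect_true(al$leading_truncated_present)

  # exact multiple + truncated flag needs an explicit length
  expect_error(split_into_repeats(strrep("A", 84), leading_truncated = TRUE),
               class = "malformed_array")
})

test_that("malformed array lengths raise classed errors with remainder", {
  err <- tryCatch(split_into_repeats(strrep("ACGT", 22)),  # 88 nt
                  malformed_array = identity)
  expect_s3_class(err, "malformed_array")
  expect_equal(err$remainder, 4L)
  expect_error(split_into_repeats(""), class = "malformed_array")
})

test_that("round trip holds on generated arrays (property)", {
  for (seed in 1:10) {
    k <- 1 + (seed %% 9)
    arr <- random_codon_nt(28 * k, seed = seed)
    reps <- split_into_repeats(arr)
    expect_identical(paste(vapply(reps, `[[`, character(1), "nt_seq"),
                           collapse = ""), arr)
    expect_length(reps, k)
  }
})

test_that("translate_repeats fills 28-aa translations and flags stops", {
  poly_a <- strrep("GCT", 28)
  reps <- translate_repeats(split_into_repeats(poly_a))
  expect_identical(reps[[1]]$aa_seq, strrep("A", 28))

  with_stop <- paste0(substr(poly_a, 1, 30), "TAA", substr(poly_a, 34, 84))
  err <- tryCatch(translate_repeats(split_into_repeats(with_stop)),
                  invalid_repeat = identity)
  expect_s3_class(err, "invalid_repeat")

  # full repeats always translate to 28 residues (property)
  for (seed in 21:26) {
    nt <- random_codon_nt(28, seed = seed)
    expect_equal(nchar(translate_repeats(split_into_repeats(nt))[[1]]$aa_seq),
                 28L)
  }
})

test_that("translation agrees with the Biostrings oracle", {
  for (seed in 1:8) {
    nt <- random_codon_nt(40, seed = 100 + seed)
    expect_identical(
      translate_nt(nt),
      as.character(Biostrings::translate(Biostrings::DNAString(nt))))
  }
})

test_that("locate_scaffold finds planted C2H2 offsets", {
  aa <- make_scaffold_aa(c1 = 4, c2 = 7, h1 = 20, h2 = 24)
  sc <- locate_scaffold(aa)
  expect_equal(sc$cys1, 4L)
  expect_equal(sc$cys2, 7L)
  expect_equal(sc$his1, 20L)
  expect_equal(sc$his2, 24L)

  # truncated leading repeat: first cysteine absent
  tr_aa <- translate_repeats(split_into_repeats(
    paste0(trunc_nt(), base_nt()), leading_truncated = TRUE))[[1]]$aa_seq
  sc_tr <- locate_scaffold(tr_aa, truncated = TRUE)
  expect_true(is.na(sc_tr$cys1))
  expect_false(is.na(sc_tr$his1))

  expect_error(locate_scaffold(strrep("CGA", 9)),  # no histidine
               class = "scaffold_not_found")
})

test_that("extract_contact_residues pulls helix -1/2/3/6 residues", {
  # plant known residues at the contact offsets of the base repeat
  nt <- base_nt()
  nt <- mutate_repeat(nt, 11, "Q")  # -1
  nt <- mutate_repeat(nt, 14, "N")  # 3
  nt <- mutate_repeat(nt, 17, "E")  # 6
  aa <- translate_nt(nt)
  cr <- extract_contact_residues(aa, locate_scaffold(aa))
  expect_identical(cr$pos_minus1, "Q")
  expect_identical(cr$pos2, "S")
  expect_identical(cr$pos3, "N")
  expect_identical(cr$pos6, "E")
  expect_identical(cr$triplet, "QNE")

  # invariant to changes outside contact offsets
  nt2 <- mutate_repeat(nt, 8, "W")
  aa2 <- translate_nt(nt2)
  cr2 <- extract_contact_residues(aa2, locate_scaffold(aa2))
  expect_identical(unclass(cr)[c("pos_minus1", "pos2", "pos3", "pos6")],
                   unclass(cr2)[c("pos_minus1", "pos2", "pos3", "pos6")])

  # out-of-range offsets error
  expect_error(
    extract_contact_residues("CAACHAH", list(his1 = 4L)),
    class = "out_of_range")
})

test_that("the synthetic default library keeps serine at position 2", {
  lib <- simulate_repeat_library(sim_config(seed = 9))
  for (aa in lib$aa) {
    cr <- extract_contact_residues(aa, locate_scaffold(aa))
    expect_identical(cr$pos2, "S")
  }
})

test_that("validate_array reports issues without dropping repeats", {
  clean <- allele_from_repeats(rep(base_nt(), 3))
  rep_clean <- validate_array(clean)
  expect_equal(nrow(rep_clean), 0L)
  expect_true(attr(rep_clean, "ok"))

  # ambiguity base flagged
  amb_nt <- paste0("R", substr(base_nt(), 2, 84))
  amb <- znf_allele("amb", repeats = split_into_repeats(
    paste0(base_nt(), amb_nt)))
  rep_amb <- validate_array(amb)
  expect_equal(rep_amb$type, "ambiguity")
  expect_equal(rep_amb$repeat_index, 1L)

  # exactly one scaffold-broken repeat out of 7
  broken <- mutate_repeat(base_nt(), 18, "G")  # destroy his1
  nts <- rep(base_nt(), 7)
  nts[4] <- broken
  al <- allele_from_repeats(nts)
  rep7 <- validate_array(al)
  expect_equal(nrow(rep7), 1L)
  expect_equal(rep7$type, "scaffold")
  expect_equal(rep7$repeat_index, 3L)  # 0-based
})

test_that("parse_znf_allele auto-detects the truncated lead and repeat_table is complete", {
  arr <- paste0(trunc_nt(), base_nt(), base_nt(), base_nt())
  al <- parse_znf_allele(arr, "al1", "s1", "g1")
  expect_true(al$leading_truncated_present)
  expect_equal(n_full_repeats(al), 3L)
  expect_identical(allele_nt(al), arr)
  tab <- repeat_table(list(al))
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$pos2[!tab$is_truncated] == "S"))
})
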