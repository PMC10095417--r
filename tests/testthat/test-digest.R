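test_that("tryptic digest of the nisin S core yields the three expected spans", {
  d <- tryptic_digest(NISIN_S, 0)
  expect_equal(d$start, c(1L, 13L, 23L))
  expect_equal(d$end, c(12L, 22L, 34L))
  expect_equal(d$sequence, c("ITSYSLCTPGCK", "TGALMGCTMK", "TASCGCHVHISK"))
  expect_equal(d$missed_cleavages, c(0L, 0L, 0L))
})

test_that("digest edge cases: terminal K, proline rule, empty input", {
  d <- tryptic_digest("KAK", 0)
  expect_equal(d$sequence, c("K", "AK"))
  expect_equal(d$start, c(1L, 2L))
  expect_equal(d$end, c(1L, 3L))

  d <- tryptic_digest("AKPR", 0)
  expect_equal(d$sequence, "AKPR")

  expect_error(tryptic_digest("", 0), class = "lanthi_domain_error")
})

test_that("digest equals brute-force enumeration on random sequences", {
  withr::local_seed(13)
  for (i in 1:20) {
    s <- random_protein(60)
    for (mm in 0:2) {
      got <- as.data.frame(tryptic_digest(s, mm))
      ref <- oracle_digest(s, mm)
      rownames(got) <- rownames(ref) <- NULL
      expect_equal(got[c("sequence", "start", "end", "missed_cleavages")],
                   ref[c("sequence", "start", "end", "missed_cleavages")])
    }
  }
})

test_that("zero-missed fragments tile the parent", {
  withr::local_seed(17)
  for (i in 1:20) {
    s <- random_protein(sample(10:80, 1))
    d <- tryptic_digest(s, 0)
    expect_equal(paste(d$sequence, collapse = ""), s)
    expect_equal(d$start[1], 1L)
    expect_equal(d$end[nrow(d)], nchar(s))
  }
})

test_that("modform enumeration counts and collapses forms as expected", {
  # CAM fixed on both C of the mid fragment, up to two oxidations on two M:
  # 4 positional forms, 3 distinct masses
  f <- enumerate_modforms("TGALMGCTMK")
  expect_equal(nrow(f), 4L)
  expect_equal(length(unique(round(f$neutral_mono, 6))), 3L)
  expect_equal(f$n_variable, c(0L, 1L, 1L, 2L))

  # no eligible residues: a single unmodified-beyond-fixed form
  f0 <- enumerate_modforms("GAGAK")
  expect_equal(nrow(f0), 1L)
  expect_equal(f0$mod_label, "unmodified")

  # k eligible sites with max_variable >= k: 2^k positional forms
  withr::local_seed(19)
  for (i in 1:10) {
    s <- random_protein(sample(6:14, 1))
    k <- stringr::str_count(s, "M")
    f <- enumerate_modforms(s, max_variable = 14)
    expect_equal(nrow(f), 2^k)
  }
})

test_that("m/z follows the proton convention and inverts exactly", {
  cam <- 57.02146
  m1 <- peptide_mass(modified_peptide("ITSYSLCTPGCK", c(7, 11), rep(cam, 2),
                                      rep("cam", 2)))
  expect_equal(round(mz(m1, 2), 2), 693.82)
  ox <- 15.994915
  m2 <- peptide_mass(modified_peptide("TGALMGCTMK", c(5, 7), c(ox, cam),
                                      c("ox", "cam")))
  expect_equal(round(mz(m2, 2), 2), 543.24)
  expect_equal(mz(1000, 1), 1000 + 1.007276)
  expect_error(mz(1000, 0), class = "lanthi_domain_error")

  withr::local_seed(23)
  for (i in 1:50) {
    m <- runif(1, 500, 5000); z <- sample(1:6, 1)
    expect_equal(neutral_from_mz(mz(m, z), z), m, tolerance = 1e-9)
  }
})

test_that("inclusion list covers expected targets deterministically", {
  il <- build_inclusion_list(NISIN_S)
  # 5 mass-distinct forms (1 + 3 + 1) at three charges
  expect_equal(nrow(il), 15L)
  expect_true(any(il$charge == 2 & abs(il$mz - 693.82) < 0.005))
  expect_false(is.unsorted(il$mz))

  # no K/R core: one fragment, one form, one target per charge
  il0 <- build_inclusion_list("GGG", fixed = NULL, variable = NULL)
  expect_equal(nrow(il0), 3L)

  # byte-identical TSV on repeated runs
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_inclusion_list(build_inclusion_list(NISIN_S), f1)
  write_inclusion_list(build_inclusion_list(NISIN_S), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(build_inclusion_list(NISIN_S, charges = 7),
               class = "lanthi_domain_error")
})

test_that("inclusion-list size equals forms x charges before deduplication", {
  withr::local_seed(29)
  for (i in 1:10) {
    s <- random_protein(sample(20:50, 1))
    frags <- tryptic_digest(s, 0)
    n_forms <- sum(vapply(frags$sequence, function(fr) {
      f <- enumerate_modforms(fr)
      length(unique(f$multiset_label))
    }, numeric(1)))
    il <- build_inclusion_list(s)
    expect_lte(nrow(il), n_forms * 3)
    # with distinct fragment sequences the dedup keeps every (form, charge)
    if (!anyDuplicated(frags$sequence)) {
      expect_equal(nrow(il), n_forms * 3)
    }
  }
})
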