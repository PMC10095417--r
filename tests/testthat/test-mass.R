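test_that("mass constants are complete and mono < avg throughout", {
  k <- mass_constants()
  expect_setequal(k$residues$residue, AA20)
  expect_true(all(k$residues$mono < k$residues$avg))
  expect_equal(unname(k$water["mono"]), 18.010565)
  expect_equal(unname(k$water["avg"]), 18.0153)
  expect_equal(k$proton, 1.007276)
  # the shipped text resource mirrors the in-memory table
  tsv <- read.delim(system.file("extdata", "residue_masses.tsv",
                                package = "lanthominer"),
                    comment.char = "#", header = FALSE,
                    col.names = c("residue", "mono", "avg"))
  expect_equal(tsv$mono, k$residues$mono, tolerance = 1e-6)
  expect_equal(tsv$avg, k$residues$avg, tolerance = 1e-6)
})

test_that("peptide_mass reproduces hand-checked and published values", {
  expect_equal(peptide_mass("G"), 75.0321, tolerance = 1e-4)
  # carbamidomethylated N-terminal tryptic fragment of the nisin S core
  cam <- mass_constants()$mods[["carbamidomethyl"]]
  p <- modified_peptide("ITSYSLCTPGCK", c(7, 11), rep(cam, 2),
                        rep("carbamidomethyl", 2))
  expect_equal(round(peptide_mass(p, "mono"), 2), 1385.63)
  # average mass of the full core rounds to the deduced intact mass
  expect_equal(round(peptide_mass(NISIN_S, "avg")), 3491)
  expect_error(peptide_mass("MKB"), class = "lanthi_alphabet_error")
})

test_that("mass is additive over concatenation and modification order", {
  withr::local_seed(7)
  for (i in 1:100) {
    a <- random_protein(sample(3:25, 1))
    b <- random_protein(sample(3:25, 1))
    for (mt in c("mono", "avg")) {
      expect_equal(peptide_mass(paste0(a, b), mt),
                   peptide_mass(a, mt) + peptide_mass(b, mt) - .subset2(
                     list(mono = 18.010565, avg = 18.0153), mt),
                   tolerance = 1e-6)
    }
  }
  # applying the same mods in any order gives the same mass
  s <- "MCMCM"
  m1 <- modified_peptide(s, c(1, 3, 5), c(15.994915, 15.994915, 15.994915),
                        rep("ox", 3))
  m2 <- modified_peptide(s, c(5, 1, 3), rep(15.994915, 3), rep("ox", 3))
  expect_equal(peptide_mass(m1), peptide_mass(m2))
})

test_that("mono mass is below average mass for any peptide", {
  withr::local_seed(11)
  for (i in 1:50) {
    s <- random_protein(sample(1:40, 1))
    expect_lt(peptide_mass(s, "mono"), peptide_mass(s, "avg"))
  }
})

test_that("dehydration inference recovers planted counts exactly", {
  inf <- infer_dehydrations(peptide_mass(NISIN_S, "avg"), 3347.15, "avg")
  expect_equal(inf$n_dehydrations, 8L)
  expect_lt(abs(inf$residual), 18.0153 / 2)

  same <- infer_dehydrations(1000, 1000, "mono")
  expect_equal(same$n_dehydrations, 0L)
  expect_equal(same$residual, 0)

  withr::local_seed(3)
  for (i in 1:200) {
    core <- random_protein(sample(15:40, 1))
    cap <- dehydration_capacity(core)$capacity
    k <- sample(0:cap, 1)
    for (mt in c("mono", "avg")) {
      ded <- peptide_mass(core, mt)
      obs <- modified_core_mass(core, k, mt)
      inf <- infer_dehydrations(ded, obs, mt)
      expect_identical(inf$n_dehydrations, as.integer(k))
      expect_equal(inf$residual, 0, tolerance = 1e-9)
    }
  }
})

test_that("inference invariant deduced - n*water - residual = observed holds", {
  withr::local_seed(5)
  w <- c(mono = 18.010565, avg = 18.0153)
  for (i in 1:50) {
    ded <- runif(1, 1000, 5000)
    obs <- ded - runif(1, -5, 200)
    mt <- sample(c("mono", "avg"), 1)
    inf <- infer_dehydrations(ded, obs, mt)
    expect_gte(inf$n_dehydrations, 0)
    expect_equal(ded - inf$n_dehydrations * w[[mt]] - inf$residual, obs,
                 tolerance = 1e-9)
  }
})

test_that("modified core mass respects the Ser+Thr capacity", {
  expect_equal(modified_core_mass(NISIN_S, 0, "avg"),
               peptide_mass(NISIN_S, "avg"))
  m8 <- modified_core_mass(NISIN_S, 8, "avg")
  expect_lt(abs(m8 - 3347.15), 0.5)
  expect_error(modified_core_mass(NISIN_S, 10, "avg"),
               class = "lanthi_capacity_error")
})

test_that("dehydration capacity counts S, T, C correctly", {
  cap <- dehydration_capacity(NISIN_S)
  expect_equal(cap$n_ser, 4L)
  expect_equal(cap$n_thr, 5L)
  expect_equal(cap$n_cys, 5L)
  expect_equal(cap$capacity, 9L)
  # the 8 inferred dehydrations fit within the 9 dehydratable residues
  expect_gte(cap$capacity, 8L)
  expect_equal(unlist(dehydration_capacity("GGG")[, 1:3], use.names = FALSE),
               c(0L, 0L, 0L))
})

test_that("tidy and glance expose the inference fields", {
  inf <- infer_dehydrations(3491.17, 3347.15, "avg")
  td <- tidy(inf)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$n_dehydrations, 8L)
  expect_equal(glance(inf), td)
})
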