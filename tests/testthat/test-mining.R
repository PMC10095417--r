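test_that("simple hand-checkable ORF calls", {
  # no start codon anywhere
  orfs <- six_frame_orfs("CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC",
                         min_protein_len = 10)
  expect_equal(nrow(orfs), 0L)

  # one forward ORF: M A A stop
  seq <- paste0("ATGGCTGCT", paste(rep("GCT", 8), collapse = ""), "TAA")
  orfs <- six_frame_orfs(seq, min_protein_len = 10)
  fwd <- dplyr::filter(orfs, strand == "+")
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$start, 0L)
  expect_equal(fwd$end, nchar(seq))
  expect_equal(fwd$protein, paste0("MAA", paste(rep("A", 8), collapse = "")))
})

test_that("ORF extraction agrees with a brute-force scan of all frames", {
  withr::local_seed(61)
  for (i in 1:12) {
    g <- random_dna(1500)
    got <- six_frame_orfs(g, min_protein_len = 10)
    ref <- oracle_orfs(g, 10)
    got_keys <- sort(paste(got$start, got$end, got$strand))
    ref_keys <- sort(paste(ref$start, ref$end, ref$strand))
    expect_equal(got_keys, ref_keys)
  }
})

test_that("ORF calls are strand-symmetric under reverse complement", {
  withr::local_seed(67)
  for (i in 1:5) {
    g <- random_dna(1200)
    rc <- oracle_revcomp(g)
    a <- six_frame_orfs(g, 10)
    b <- six_frame_orfs(rc, 10)
    L <- nchar(g)
    mirrored <- sort(paste(L - b$end, L - b$start,
                           ifelse(b$strand == "+", "-", "+")))
    expect_equal(sort(paste(a$start, a$end, a$strand)), mirrored)
  }
})

test_that("precursor scoring reproduces the published identity and split", {
  prec <- make_precursor(NISIN_S, leader_len = 25, minus1 = "K", seed = 71)
  orfs <- tibble::tibble(contig = "c", start = 0L,
                         end = 3L * (nchar(prec) + 1L), strand = "+",
                         frame = 0L, protein = prec)
  cand <- score_precursors(orfs, tibble::tibble(
    name = c("nisin A", "nisin F"), core = c(NISIN_A, NISIN_F)), 40)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$best_reference, "nisin F")
  expect_equal(cand$core_identity_pct, 82.35)
  expect_equal(nchar(cand$leader), 25L)
  expect_equal(nchar(cand$core), 34L)
  expect_equal(cand$core, NISIN_S)
  expect_equal(cand$minus1_residue, "K")
  # the split is lossless
  expect_equal(paste0(cand$leader, cand$core), prec)
})

test_that("random ORFs stay below a 40% identity threshold almost surely", {
  withr::local_seed(73)
  n_hits <- 0L
  for (i in 1:200) {
    orfs <- tibble::tibble(contig = "c", start = 0L, end = 183L,
                           strand = "+", frame = 0L,
                           protein = random_protein(60))
    cand <- score_precursors(orfs, nisin_panel(), 40)
    n_hits <- n_hits + nrow(cand)
  }
  expect_lte(n_hits, 4L) # expected false-positive rate ~0 at this threshold
})

test_that("leader/core split classifies the cleavage-site residue", {
  prec_k <- make_precursor(NISIN_S, 25, "K", seed = 79)
  prec_r <- make_precursor(NISIN_A, 25, "R", seed = 79)
  orf <- function(p) tibble::tibble(contig = "c", start = 0L,
                                    end = 3L * (nchar(p) + 1L), strand = "+",
                                    frame = 0L, protein = p)
  ck <- score_precursors(orf(prec_k), nisin_panel(), 40)
  sk <- split_leader_core(ck[1, ])
  expect_equal(sk$minus1_residue, "K")
  expect_equal(sk$minus1_class, "lysine")

  cr <- score_precursors(orf(prec_r), nisin_panel(), 40)
  sr <- split_leader_core(cr[1, ])
  expect_equal(sr$minus1_residue, "R")
  expect_equal(sr$minus1_class, "arginine")

  # single-residue leader: boundary case, class "other"
  cm <- tibble::tibble(leader = "M", core = NISIN_S)
  sm <- split_leader_core(cm)
  expect_equal(sm$minus1_residue, "M")
  expect_equal(sm$minus1_class, "other")

  expect_error(split_leader_core(tibble::tibble(leader = "", core = NISIN_S)),
               class = "lanthi_domain_error")
})

test_that("cluster annotation assigns families and flags truncations", {
  withr::local_seed(83)
  refs <- tibble::tibble(
    identifier = c("transporter", "dehydratase"),
    residues = c(random_protein(120), random_protein(200))
  )
  orf <- function(p) tibble::tibble(contig = "c", start = 0L,
                                    end = 3L * (nchar(p) + 1L), strand = "+",
                                    frame = 0L, protein = p)
  # exact copy: assigned, full length, not truncated
  ann <- annotate_cluster(orf(refs$residues[1]), refs)
  expect_equal(ann$assigned_family, "transporter")
  expect_equal(ann$identity_pct, 100)
  expect_equal(ann$length_ratio, 1)
  expect_false(ann$truncated)

  # first 40% of a reference, no substitutions: assigned and truncated
  stub <- substr(refs$residues[2], 1, 80)
  ann <- annotate_cluster(orf(stub), refs)
  expect_equal(ann$assigned_family, "dehydratase")
  expect_true(ann$truncated)
  expect_equal(ann$length_ratio, 0.4)

  # random proteins stay unassigned
  unass <- 0L
  for (i in 1:20) {
    ann <- annotate_cluster(orf(random_protein(150)), refs)
    unass <- unass + (ann$assigned_family == "unassigned")
  }
  expect_equal(unass, 20L)
})
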