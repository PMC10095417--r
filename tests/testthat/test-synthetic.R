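test_that("synthetic precursors have the requested shape and are deterministic", {
  p <- make_precursor(NISIN_S, leader_len = 25, minus1 = "K", seed = 1)
  expect_equal(nchar(p), 25 + 34)
  expect_equal(substr(p, 1, 1), "M")
  expect_equal(substr(p, 25, 25), "K")
  expect_equal(substr(p, 26, 59), NISIN_S)

  p5 <- make_precursor(NISIN_S, leader_len = 5, minus1 = "R", seed = 2)
  expect_equal(nchar(p5), 5 + 34)

  expect_identical(make_precursor(NISIN_S, 25, "K", seed = 9),
                   make_precursor(NISIN_S, 25, "K", seed = 9))
  expect_false(make_precursor(NISIN_S, 25, "K", seed = 9) ==
                 make_precursor(NISIN_S, 25, "K", seed = 10))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(make_precursor(NISIN_S, 25, "K", seed = 5))
  invisible(mutate_panel(NISIN_S, 2, 3, seed = 5))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("mining recovers a planted cluster at exact coordinates on both strands", {
  prec <- make_precursor(NISIN_S, 25, "K", seed = 11)
  for (strand in c("+", "-")) {
    emb <- embed_cluster(6000, prec, strand, seed = 13)
    cand <- score_precursors(six_frame_orfs(emb$genome, 30), nisin_panel(), 40)
    expect_gte(nrow(cand), 1L)
    top <- cand[1, ]
    expect_equal(top$core_identity_pct, 100)
    expect_equal(top$start, emb$truth$start)
    expect_equal(top$end, emb$truth$end)
    expect_equal(top$strand, strand)
    expect_equal(top$core, NISIN_S)
    expect_equal(top$protein, prec)
  }
  expect_error(embed_cluster(100, prec, "+", seed = 1),
               class = "lanthi_size_error")
})

test_that("flanking genes are planted at recorded coordinates", {
  withr::local_seed(17)
  prec <- make_precursor(NISIN_S, 25, "K", seed = 19)
  flank <- paste0("M", random_protein(80))
  emb <- embed_cluster(8000, prec, "+", seed = 23, flank_proteins = flank)
  orfs <- six_frame_orfs(emb$genome, 30)
  fl <- emb$truth$flanks
  hit <- dplyr::filter(orfs, start == fl$start[1], end == fl$end[1])
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$protein, flank)
  ann <- annotate_cluster(hit, tibble::tibble(identifier = "modB",
                                              residues = flank))
  expect_equal(ann$assigned_family, "modB")
  expect_false(ann$truncated)
})

test_that("genomes without a planted precursor rarely yield candidates", {
  withr::local_seed(29)
  hits <- 0L
  for (i in 1:60) {
    g <- random_dna(10000)
    cand <- score_precursors(six_frame_orfs(g, 30), nisin_panel(), 40)
    hits <- hits + (nrow(cand) > 0)
  }
  expect_lte(hits / 60, 0.05)
})

test_that("noiseless simulated peaks reproduce the planted truth exactly", {
  sim <- simulate_peaks(NISIN_S, n_dehydrations = 8, jitter_sd = 0,
                        n_decoys = 0, dropout_p = 0, seed = 1)
  v <- verify_core(NISIN_S, sim$peaks)
  expect_equal(v$reconciliation$n_dehydrations, 8L)
  expect_equal(v$reconciliation$residual, 0, tolerance = 1e-9)
  expect_equal(v$coverage$coverage_pct, 100)
  expect_true(all(v$matches$matched))
})

test_that("full dropout leaves nothing to verify", {
  sim <- simulate_peaks(NISIN_S, 8, 0, 0, dropout_p = 1, seed = 3)
  v <- verify_core(NISIN_S, sim$peaks)
  expect_null(v$reconciliation)
  expect_equal(v$coverage$coverage_pct, 0)
  expect_false(any(v$matches$matched))
})

test_that("match precision stays high under jitter and decoys", {
  tol <- 0.02
  targets <- build_inclusion_list(NISIN_S)
  correct <- 0L
  matched_total <- 0L
  for (seed in 1:200) {
    sim <- simulate_peaks(NISIN_S, 8, jitter_sd = tol / 3, n_decoys = 20,
                          dropout_p = 0, seed = seed)
    mz_peaks <- dplyr::filter(sim$peaks, value_kind == "mz")
    m <- match_targets(targets, mz_peaks, tol)
    truth <- dplyr::filter(sim$truth, kind == "fragment")
    joined <- dplyr::left_join(
      dplyr::filter(m, matched),
      truth[, c("sequence", "mod_label", "charge", "observed")],
      by = c("sequence", "mod_label", "charge"),
      suffix = c("_assigned", "_true")
    )
    # a matched target is correct when its assigned peak is its own
    # (jittered) true peak, not a decoy or another fragment's peak
    correct <- correct +
      sum(abs(joined$observed_assigned - joined$observed_true) < 1e-9)
    matched_total <- matched_total + nrow(joined)
  }
  expect_gt(matched_total, 0)
  expect_gte(correct / matched_total, 0.95)
})

test_that("mutated panels carry exactly the requested substitution load", {
  panel <- mutate_panel(NISIN_S, n_variants = 5, subs_per_variant = 7, seed = 7)
  expect_equal(nrow(panel), 5L)
  for (v in panel$core) {
    expect_equal(hamming(NISIN_S, v), 7L)
    expect_equal(percent_identity(NISIN_S, v), 79.41)
    expect_equal(length(substitution_list(NISIN_S, v)), 7L)
  }
  same <- mutate_panel(NISIN_S, 3, 0, seed = 9)
  expect_true(all(same$core == NISIN_S))
  expect_true(all(vapply(same$core, function(v)
    percent_identity(NISIN_S, v), 0) == 100))
})
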