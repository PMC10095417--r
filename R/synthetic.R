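# Seeded generators for every input the pipeline consumes, with planted
# ground truth: precursor proteins, genomes with an embedded nisin-like
# cluster, noisy peak lists consistent with the dehydration/digestion model,
# and mutated variant panels. Every generator is a pure function of
# (parameters, seed); the caller's RNG state is left untouched.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.AA20 <- c("G","A","S","P","V","T","C","L","I","N",
           "D","Q","K","E","M","H","F","R","Y","W")

# codons per amino acid, standard code
.codons_for <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  names(gc[gc == aa])
}

#' Generate a synthetic precursor protein
#'
#' Builds a precursor shaped like a nisin gene product: an N-terminal Met, a
#' random leader of the requested length ending in the requested cleavage-site
#' residue, then the core.
#'
#' @param core Mature core sequence.
#' @param leader_len Leader length including the initiator Met (>= 5).
#' @param minus1 Residue at the cleavage site's -1 position (leader's last
#'   residue).
#' @param seed Integer seed.
#' @return The precursor sequence (leader + core).
#' @examples
#' make_precursor(nisin_panel()$core[3], leader_len = 25, minus1 = "K", seed = 1)
#' @export
make_precursor <- function(core, leader_len = 25L, minus1 = "K", seed = 1L) {
  stopifnot(leader_len >= 5, nchar(minus1) == 1L)
  core <- str_to_upper(core)
  .with_seed(seed, {
    mid <- paste(sample(.AA20, leader_len - 2L, replace = TRUE), collapse = "")
    paste0("M", mid, str_to_upper(minus1), core)
  })
}

#' Embed a precursor gene in a random genome
#'
#' Reverse-translates the precursor (uniform choice among synonymous codons,
#' ATG for the initiator Met, a random stop appended and an in-frame stop
#' planted immediately upstream so the ORF boundary is exact), inserts it at
#' a seeded position on the requested strand inside a uniform-ACGT background,
#' and optionally embeds flanking protein-coding genes downstream (emulating
#' the biosynthesis genes that surround a lanthipeptide structural gene).
#'
#' @param genome_len Total genome length (>= 3 * precursor length + 200).
#' @param precursor Precursor protein, starting with Met (see
#'   [make_precursor()]).
#' @param strand `"+"` or `"-"`.
#' @param seed Integer seed.
#' @param flank_proteins Optional character vector of extra proteins to embed
#'   (each starting with Met), placed after the precursor gene with short
#'   spacers, on the same strand orientation as given.
#' @return A list with `genome` (single-row tibble as from [read_fasta()])
#'   and `truth` (list: `start`, `end` 0-based half-open forward-strand ORF
#'   coordinates, `strand`, `precursor`, `flanks` tibble, `seed`).
#' @export
embed_cluster <- function(genome_len, precursor, strand = c("+", "-"),
                          seed = 1L, flank_proteins = NULL) {
  strand <- match.arg(strand)
  precursor <- str_to_upper(precursor)
  if (str_sub(precursor, 1, 1) != "M") {
    abort("precursor must start with Met", class = "lanthi_domain_error")
  }
  if (genome_len < 3 * nchar(precursor) + 200) {
    abort("genome_len too short for the precursor",
          class = "lanthi_size_error")
  }
  .with_seed(seed, {
    encode <- function(protein) {
      aa <- str_split_1(protein, "")
      codons <- map_chr(seq_along(aa), function(i) {
        if (i == 1L) "ATG" else sample(.codons_for(aa[i]), 1L)
      })
      paste0(paste(codons, collapse = ""), sample(.STOP_CODONS, 1L))
    }
    guard <- sample(.STOP_CODONS, 1L)
    main_cds <- encode(precursor)          # ATG ... stop
    pieces <- list(paste0(guard, main_cds))
    flank_info <- list()
    offset <- nchar(pieces[[1]])
    for (fp in flank_proteins %||% character(0)) {
      spacer <- paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
                      collapse = "")
      g2 <- sample(.STOP_CODONS, 1L)
      cds <- encode(str_to_upper(fp))
      flank_info[[length(flank_info) + 1L]] <- tibble(
        protein = str_to_upper(fp),
        rel_start = offset + nchar(spacer) + 3L,
        rel_end = offset + nchar(spacer) + 3L + nchar(cds)
      )
      pieces[[length(pieces) + 1L]] <- paste0(spacer, g2, cds)
      offset <- offset + nchar(spacer) + 3L + nchar(cds)
    }
    insert <- paste(unlist(pieces), collapse = "")
    l_ins <- nchar(insert)
    if (genome_len < l_ins + 20L) {
      abort("genome_len too short for precursor plus flanking genes",
            class = "lanthi_size_error")
    }
    if (strand == "-") insert <- .revcomp(insert)
    pos <- sample.int(genome_len - l_ins + 1L, 1L) - 1L  # 0-based insert pos
    n_bg <- genome_len - l_ins
    bg <- sample(c("A", "C", "G", "T"), n_bg, replace = TRUE)
    genome_seq <- paste0(
      paste(bg[seq_len(pos)], collapse = ""),
      insert,
      paste(bg[seq_len(n_bg - pos) + pos], collapse = "")
    )
    # ORF span within the forward insert: [3, l_main) where l_main is
    # guard + cds length of the precursor gene
    l_main_orf <- 3L * nchar(precursor) + 3L
    rel <- c(3L, 3L + l_main_orf)
    flanks <- if (length(flank_info) > 0) list_rbind(flank_info) else
      tibble(protein = character(0), rel_start = integer(0),
             rel_end = integer(0))
    to_forward <- function(a, b) {
      if (strand == "+") c(pos + a, pos + b) else
        c(pos + l_ins - b, pos + l_ins - a)
    }
    main_fwd <- to_forward(rel[1], rel[2])
    flank_fwd <- map2(flanks$rel_start, flanks$rel_end, to_forward)
    truth <- list(
      start = main_fwd[1], end = main_fwd[2], strand = strand,
      precursor = precursor,
      flanks = mutate(flanks,
                      start = map_int(flank_fwd, ~ as.integer(.x[1])),
                      end = map_int(flank_fwd, ~ as.integer(.x[2]))),
      seed = seed
    )
    list(
      genome = tibble(identifier = "synthetic_contig",
                      description = "synthetic_contig planted nisin-like cluster",
                      residues = genome_seq, alphabet = "nucleotide"),
      truth = truth
    )
  })
}

#' Simulate observed peaks for a dehydrated core
#'
#' Produces the observables the verification stage consumes: one intact
#' average-mass peak at `peptide_mass(core, "avg") - n * water`, plus the
#' monoisotopic m/z of every default inclusion-list target (tryptic digest,
#' carbamidomethyl fixed, up to two oxidations, charges 2--4). Each value is
#' jittered with Gaussian noise, dropped with probability `dropout_p`, and
#' uniform decoy m/z peaks are added over the fragment range widened by
#' 50 Th.
#'
#' @param core Core sequence.
#' @param n_dehydrations Planted dehydration count (<= Ser+Thr capacity).
#' @param jitter_sd Gaussian noise SD (Da / Th).
#' @param n_decoys Number of decoy m/z peaks.
#' @param dropout_p Per-peak dropout probability.
#' @param seed Integer seed.
#' @return A list with `peaks` (tibble with columns `value`, `intensity`,
#'   `value_kind`; intact rows are `neutral_mass`, fragment and decoy rows
#'   `mz`; filter on `value_kind` before matching) and `truth` (tibble with
#'   columns `kind`, `sequence`, `mod_label`, `charge`, `true_value`,
#'   `observed`, `dropped`).
#' @export
simulate_peaks <- function(core, n_dehydrations = 8L, jitter_sd = 0,
                           n_decoys = 0L, dropout_p = 0, seed = 1L) {
  core <- str_to_upper(core)
  intact <- modified_core_mass(core, n_dehydrations, "avg")
  targets <- build_inclusion_list(core)
  .with_seed(seed, {
    truth <- bind_rows(
      tibble(kind = "intact", sequence = core, mod_label = sprintf(
        "%d dehydrations", n_dehydrations),
        charge = NA_integer_, true_value = intact),
      tibble(kind = "fragment", sequence = targets$sequence,
             mod_label = targets$mod_label, charge = targets$charge,
             true_value = targets$mz)
    )
    truth$observed <- truth$true_value +
      if (jitter_sd > 0) stats::rnorm(nrow(truth), 0, jitter_sd) else 0
    truth$dropped <- runif(nrow(truth)) < dropout_p
    frag_rng <- range(targets$mz)
    decoys <- if (n_decoys > 0) {
      runif(n_decoys, frag_rng[1] - 50, frag_rng[2] + 50)
    } else {
      numeric(0)
    }
    kept <- filter(truth, !.data$dropped)
    peaks <- bind_rows(
      tibble(value = kept$observed,
             intensity = rep(1, nrow(kept)),
             value_kind = as.character(ifelse(kept$kind == "intact",
                                              "neutral_mass", "mz"))),
      tibble(value = decoys, intensity = 1, value_kind = "mz")
    )
    peaks <- filter(peaks, .data$value > 0)
    peaks <- arrange(peaks, .data$value)
    if (length(decoys) > 0) {
      truth <- bind_rows(truth, tibble(
        kind = "decoy", sequence = NA_character_, mod_label = NA_character_,
        charge = NA_integer_, true_value = decoys, observed = decoys,
        dropped = FALSE
      ))
    }
    list(peaks = peaks, truth = truth)
  })
}

#' Generate a panel of mutated variants of a core
#'
#' Each variant differs from the ancestor at exactly `subs_per_variant`
#' seeded positions (substituted to a different residue), giving test panels
#' with known pairwise identities.
#'
#' @param core Ancestral core sequence.
#' @param n_variants Number of variants.
#' @param subs_per_variant Substitutions per variant (<= core length).
#' @param seed Integer seed.
#' @return A tibble with columns `name` (`variant_01`, ...), `core`.
#' @export
mutate_panel <- function(core, n_variants = 5L, subs_per_variant = 7L,
                         seed = 1L) {
  core <- str_to_upper(core)
  stopifnot(subs_per_variant <= nchar(core), n_variants >= 1)
  .with_seed(seed, {
    chars <- str_split_1(core, "")
    variants <- map_chr(seq_len(n_variants), function(i) {
      v <- chars
      pos <- sample.int(length(v), subs_per_variant)
      for (p in pos) v[p] <- sample(setdiff(.AA20, v[p]), 1L)
      paste(v, collapse = "")
    })
    tibble(name = sprintf("variant_%02d", seq_len(n_variants)),
           core = variants)
  })
}
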