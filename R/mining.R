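# Genome mining for nisin-family precursors. The precursor gene is found by
# brute force: extract every open reading frame from all six frames, then
# slide each known mature core along each ORF protein and keep ORFs whose
# best ungapped window identity clears a threshold. The matched window marks
# the leader/core boundary; flanking ORFs are assigned to biosynthesis
# protein families by global identity, with truncations flagged.

.START_CODONS <- c("ATG", "GTG", "TTG")
.STOP_CODONS <- c("TAA", "TAG", "TGA")

.translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract open reading frames from all six frames
#'
#' Scans both strands in all three frames for ORFs: every start codon
#' (ATG/GTG/TTG, translated as Met) paired with its nearest in-frame
#' downstream stop (TAA/TAG/TGA, standard code). Nested ORFs that share a
#' stop are all reported; ORFs without an in-frame stop inside the contig are
#' not. Reverse-strand ORFs are reported in forward-strand coordinates
#' (0-based, half-open, stop codon included in the span).
#'
#' @param genome A single-row tibble from [read_fasta()] (nucleotide), or a
#'   bare nucleotide string.
#' @param min_protein_len Minimum protein length (start codon included,
#'   terminal stop excluded); must be >= 10.
#' @return A tibble with columns `contig`, `start`, `end`, `strand`, `frame`
#'   (0--2 on its own strand), `protein`.
#' @examples
#' six_frame_orfs("ATGGCTGCTTAAATGTTTTGTTCTTCTTCTTCTTCTTCTTGA", min_protein_len = 10)
#' @export
six_frame_orfs <- function(genome, min_protein_len = 30L) {
  stopifnot(min_protein_len >= 10)
  if (is.data.frame(genome)) {
    stopifnot(nrow(genome) == 1L)
    contig <- genome$identifier[1]
    seq <- genome$residues[1]
    if (!is.null(genome$alphabet) && genome$alphabet[1] != "nucleotide") {
      abort("six_frame_orfs needs a nucleotide record",
            class = "lanthi_alphabet_error")
    }
  } else {
    contig <- "contig"
    seq <- genome
  }
  seq <- str_to_upper(seq)
  .check_alphabet(seq, .NUC_CHARS, contig)
  L <- nchar(seq)
  scan_strand <- function(s, strand) {
    rows <- list()
    for (frame in 0:2) {
      n_codons <- (nchar(s) - frame) %/% 3
      if (n_codons < 2) next
      starts_nt <- frame + 1 + 3 * (seq_len(n_codons) - 1)
      codons <- substring(s, starts_nt, starts_nt + 2)
      stop_ix <- which(codons %in% .STOP_CODONS)
      start_ix <- which(codons %in% .START_CODONS)
      if (length(stop_ix) == 0 || length(start_ix) == 0) next
      # nearest stop strictly after each start
      nxt <- stop_ix[findInterval(start_ix, stop_ix) + 1L]
      ok <- !is.na(nxt) & (nxt - start_ix) >= min_protein_len
      for (k in which(ok)) {
        si <- start_ix[k]; ti <- nxt[k]
        aa <- .translate_codons(codons[si:(ti - 1L)])
        aa[1] <- "M"
        nt0 <- frame + 3 * (si - 1L)       # 0-based start on this strand
        nt1 <- frame + 3 * ti              # 0-based end (after stop codon)
        if (strand == "+") {
          fs <- nt0; fe <- nt1
        } else {
          fs <- L - nt1; fe <- L - nt0
        }
        rows[[length(rows) + 1L]] <- tibble(
          contig = contig, start = fs, end = fe, strand = strand,
          frame = frame, protein = paste(aa, collapse = "")
        )
      }
    }
    rows
  }
  rows <- c(scan_strand(seq, "+"), scan_strand(.revcomp(seq), "-"))
  if (length(rows) == 0L) {
    return(tibble(contig = character(0), start = integer(0), end = integer(0),
                  strand = character(0), frame = integer(0),
                  protein = character(0)))
  }
  arrange(list_rbind(rows), .data$start, .data$end, .data$strand)
}

#' Score ORFs as nisin-family precursor candidates
#'
#' For each ORF protein, slides every panel core along the protein (equal
#' length, ungapped) and records the best window identity over all panel
#' entries. ORFs at or above the identity threshold become candidates: the
#' prefix before the best window is the leader, the window through the
#' protein's C-terminus is the core (nisin precursors carry no follower
#' peptide), and the last leader residue is the cleavage-site -1 position.
#'
#' @param orfs Tibble from [six_frame_orfs()].
#' @param panel Tibble with columns `name`, `core` (e.g. [nisin_panel()]).
#' @param min_identity_pct Identity threshold, percent.
#' @return A tibble of candidates sorted by identity (desc), contig, start:
#'   ORF columns plus `best_reference`, `core_identity_pct`, `leader`,
#'   `core`, `minus1_residue`.
#' @export
score_precursors <- function(orfs, panel = nisin_panel(),
                             min_identity_pct = 40) {
  stopifnot(nrow(panel) > 0, all(c("name", "core") %in% names(panel)))
  if (nrow(orfs) == 0L) {
    return(mutate(orfs, best_reference = character(0),
                  core_identity_pct = numeric(0), leader = character(0),
                  core = character(0), minus1_residue = character(0)))
  }
  panel_chars <- map(panel$core, ~ str_split_1(str_to_upper(.x), ""))
  score_one <- function(protein) {
    pc <- str_split_1(protein, "")
    n <- length(pc)
    best <- list(identity = -1, ref = NA_character_, win = NA_integer_)
    for (p in seq_len(nrow(panel))) {
      cc <- panel_chars[[p]]
      m <- length(cc)
      if (m > n) next
      for (i in seq_len(n - m + 1L)) {
        id <- 100 * sum(pc[i:(i + m - 1L)] == cc) / m
        if (id > best$identity) {
          best <- list(identity = id, ref = panel$name[p], win = i)
        }
      }
    }
    best
  }
  scored <- map(orfs$protein, score_one)
  out <- mutate(orfs,
    best_reference = map_chr(scored, "ref"),
    core_identity_pct = round(map_dbl(scored, "identity"), 2),
    .win = map_int(scored, function(s) as.integer(s$win %||% NA))
  )
  out <- filter(out, !is.na(.data$.win),
                .data$core_identity_pct >= min_identity_pct)
  out <- mutate(out,
    leader = str_sub(.data$protein, 1L, .data$.win - 1L),
    core = str_sub(.data$protein, .data$.win, -1L),
    minus1_residue = ifelse(nchar(.data$leader) > 0,
                            str_sub(.data$leader, -1L, -1L), NA_character_)
  )
  out <- select(out, -".win")
  # identity desc, then position; among nested ORFs sharing a stop the
  # longest (earliest start / latest end) ranks first
  arrange(out, desc(.data$core_identity_pct), .data$contig, .data$start,
          desc(.data$end))
}

#' Split a precursor candidate into leader, core and cleavage-site class
#'
#' Returns the stored leader/core split together with the classification of
#' the -1 residue (last leader residue before the cleavage site): most nisins
#' carry Arg there; a Lys marks the rarer cleavage-site class.
#'
#' @param candidate One row of [score_precursors()] output.
#' @return A one-row tibble with columns `leader`, `core`, `minus1_residue`,
#'   `minus1_class` (`"arginine"`, `"lysine"` or `"other"`).
#' @export
split_leader_core <- function(candidate) {
  stopifnot(is.data.frame(candidate), nrow(candidate) == 1L)
  leader <- candidate$leader[1]
  if (is.na(leader) || nchar(leader) == 0L) {
    abort("degenerate candidate: empty leader", class = "lanthi_domain_error")
  }
  minus1 <- str_sub(leader, -1L, -1L)
  tibble(
    leader = leader,
    core = candidate$core[1],
    minus1_residue = minus1,
    minus1_class = switch(minus1, K = "lysine", R = "arginine", "other")
  )
}

#' Assign cluster ORFs to biosynthesis protein families
#'
#' Compares each ORF protein against reference biosynthesis proteins by
#' ungapped global identity from position 1, with the shorter sequence padded
#' with mismatches (denominator = longer length). ORFs reaching the family
#' threshold are assigned to their best reference; assigned ORFs whose
#' length ratio to the reference falls below `truncation_ratio` are flagged
#' truncated (e.g. frameshift remnants of a transport or modification gene).
#'
#' @param orfs Tibble from [six_frame_orfs()].
#' @param protein_refs Tibble of reference proteins: columns
#'   `identifier`/`residues` (as from [read_fasta()]) or `name`/`core`.
#' @param family_threshold_pct Minimum identity to assign a family.
#' @param truncation_ratio Length-ratio threshold below which an assigned ORF
#'   is flagged truncated.
#' @return The `orfs` tibble plus `assigned_family`, `identity_pct`,
#'   `length_ratio`, `truncated`.
#' @export
annotate_cluster <- function(orfs, protein_refs, family_threshold_pct = 35,
                             truncation_ratio = 0.8) {
  refs <- if (all(c("identifier", "residues") %in% names(protein_refs))) {
    tibble(name = protein_refs$identifier, seq = protein_refs$residues)
  } else if (all(c("name", "core") %in% names(protein_refs))) {
    tibble(name = protein_refs$name, seq = protein_refs$core)
  } else {
    abort("protein_refs needs columns identifier/residues or name/core",
          class = "lanthi_input_error")
  }
  stopifnot(nrow(refs) > 0)
  global_id <- function(a, b) {
    la <- nchar(a); lb <- nchar(b)
    k <- min(la, lb)
    matches <- sum(str_split_1(str_sub(a, 1, k), "") ==
                     str_split_1(str_sub(b, 1, k), ""))
    100 * matches / max(la, lb)
  }
  ann <- map(orfs$protein, function(p) {
    ids <- vapply(refs$seq, function(r) global_id(p, r), numeric(1),
                  USE.NAMES = FALSE)
    best <- which.max(ids)
    if (ids[best] >= family_threshold_pct) {
      ratio <- nchar(p) / nchar(refs$seq[best])
      tibble(assigned_family = refs$name[best],
             identity_pct = round(ids[best], 2),
             length_ratio = ratio,
             truncated = ratio < truncation_ratio)
    } else {
      tibble(assigned_family = "unassigned",
             identity_pct = round(ids[best], 2),
             length_ratio = NA_real_, truncated = FALSE)
    }
  })
  dplyr::bind_cols(orfs, list_rbind(ann))
}
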