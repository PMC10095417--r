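# Orchestration: the three pipeline stages as data-frame-first functions,
# plus the JSON evidence report that chains them together (candidate ->
# intact-mass reconciliation -> digest matching and coverage -> topology ->
# variant comparison).

.REPORT_SCHEMA <- "1.0"

#' Default pipeline configuration
#'
#' All tunable thresholds in one list, overridable from a YAML file via
#' [lanthi_config()]: mining identity threshold and minimum protein length,
#' m/z and intact-mass match tolerances, digest settings, charge range.
#'
#' @return A named list of defaults.
#' @export
default_config <- function() {
  list(
    mining = list(min_identity_pct = 40, min_protein_len = 30L,
                  family_threshold_pct = 35, truncation_ratio = 0.8),
    digest = list(charges = 2:4, max_variable = 2L, max_missed = 0L),
    match = list(mz_tolerance = 0.02, intact_tolerance = 0.5,
                 intact_mass_type = "avg")
  )
}

#' Load a pipeline configuration
#'
#' Reads a YAML file with any subset of the sections of [default_config()]
#' and merges it over the defaults (file values win).
#'
#' @param path Path to a YAML config, or `NULL` for pure defaults.
#' @return A config list.
#' @export
lanthi_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (section in names(user)) {
    for (key in names(user[[section]])) {
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  cfg
}

#' Mine a genome for nisin-family precursor candidates
#'
#' Runs six-frame ORF extraction and panel-based precursor scoring over every
#' contig of a genome.
#'
#' @param genome Tibble of nucleotide records from [read_fasta()], or a path
#'   to a nucleotide FASTA.
#' @param panel Variant panel tibble (`name`, `core`) or path to a protein
#'   FASTA of mature cores.
#' @param config Config list from [lanthi_config()].
#' @return Candidate tibble as from [score_precursors()] (possibly empty,
#'   with a warning).
#' @export
mine_genome <- function(genome, panel = nisin_panel(),
                        config = default_config()) {
  if (is.character(genome)) genome <- read_fasta(genome, "nucleotide")
  if (is.character(panel)) {
    p <- read_fasta(panel, "protein")
    panel <- tibble(name = p$identifier, core = p$residues)
  }
  orfs <- list_rbind(map(seq_len(nrow(genome)), function(i)
    six_frame_orfs(genome[i, ], config$mining$min_protein_len)))
  out <- score_precursors(orfs, panel, config$mining$min_identity_pct)
  if (nrow(out) == 0L) {
    warn("no precursor candidate reached the identity threshold")
  }
  out
}

#' Verify a candidate core against observed masses
#'
#' Runs the full verification chain: intact-mass reconciliation (dehydration
#' counting) against neutral-mass peaks, inclusion-list matching against m/z
#' peaks, sequence coverage, and template ring-topology threading.
#'
#' @param core Candidate core sequence.
#' @param peaks Peak-list tibble. Rows with `value_kind == "neutral_mass"`
#'   feed the intact reconciliation; rows with `value_kind == "mz"` feed
#'   fragment matching. Either subset may be empty.
#' @param config Config list from [lanthi_config()].
#' @param template Ring-topology template ([nisin_a_template()]).
#' @return A `lanthi_verification` list: `core`, `reconciliation`
#'   (`dehydration_inference` or `NULL`), `matches`, `coverage`, `topology`
#'   (or `NULL` if threading fails), `capacity`.
#' @export
verify_core <- function(core, peaks, config = default_config(),
                        template = nisin_a_template()) {
  core <- str_to_upper(core)
  intact_peaks <- filter(peaks, .data$value_kind == "neutral_mass")
  mz_peaks <- filter(peaks, .data$value_kind == "mz")
  recon <- reconcile_intact(intact_peaks, core,
                            config$match$intact_mass_type,
                            config$match$intact_tolerance)
  targets <- build_inclusion_list(
    core, charges = config$digest$charges,
    max_variable = config$digest$max_variable,
    max_missed = config$digest$max_missed
  )
  matches <- match_targets(targets, mz_peaks, config$match$mz_tolerance)
  coverage <- sequence_coverage(matches, nchar(core))
  topology <- tryCatch(thread_template(core, template),
                       error = function(e) NULL)
  structure(
    list(core = core, reconciliation = recon, matches = matches,
         coverage = coverage, topology = topology,
         capacity = dehydration_capacity(core)),
    class = "lanthi_verification"
  )
}

#' @export
print.lanthi_verification <- function(x, ...) {
  cat("<lanthi_verification> core ", x$core, "\n", sep = "")
  if (!is.null(x$reconciliation)) {
    cat(sprintf("  intact: %d dehydrations (residual %+.3f Da)\n",
                x$reconciliation$n_dehydrations, x$reconciliation$residual))
  } else {
    cat("  intact: no reconciling peak\n")
  }
  cat(sprintf("  fragments: %d/%d targets matched, coverage %.2f%%\n",
              sum(x$matches$matched), nrow(x$matches),
              x$coverage$coverage_pct))
  if (!is.null(x$topology)) {
    cat("  topology:", format_topology(x$topology), "\n")
  }
  invisible(x)
}

#' Summarise a verification result
#'
#' @param x A `lanthi_verification`.
#' @param ... Unused.
#' @return One-row tibble: `core_length`, `n_dehydrations`, `residual`,
#'   `n_targets`, `n_matched`, `coverage_pct`, `n_bridges`.
#' @method glance lanthi_verification
#' @export
glance.lanthi_verification <- function(x, ...) {
  tibble(
    core_length = nchar(x$core),
    n_dehydrations = if (is.null(x$reconciliation)) NA_integer_ else
      x$reconciliation$n_dehydrations,
    residual = if (is.null(x$reconciliation)) NA_real_ else
      x$reconciliation$residual,
    n_targets = nrow(x$matches),
    n_matched = sum(x$matches$matched),
    coverage_pct = x$coverage$coverage_pct,
    n_bridges = if (is.null(x$topology)) 0L else nrow(x$topology)
  )
}

#' Compare a candidate core against a variant panel
#'
#' Percent identities, substitution lists, unique residues, p-distance
#' matrix and (for panels of three or more) a neighbor-joining tree.
#'
#' @param core Candidate core sequence.
#' @param panel Panel tibble (`name`, `core`) or protein FASTA path; the
#'   candidate is added under `query_name` if absent.
#' @param query_name Name for the candidate in the panel.
#' @return A `lanthi_comparison` list: `identities` (tibble `name`,
#'   `identity_pct`, `n_substitutions`, `substitutions` list-column),
#'   `unique_residues`, `distances`, `tree` (`phylo` or `NULL` with a
#'   warning for panels of < 3).
#' @export
compare_variants <- function(core, panel = nisin_panel(),
                             query_name = "query") {
  if (is.character(panel) && length(panel) == 1L && file.exists(panel)) {
    p <- read_fasta(panel, "protein")
    panel <- tibble(name = p$identifier, core = p$residues)
  }
  core <- str_to_upper(core)
  if (!any(panel$core == core)) {
    panel <- bind_rows(panel, tibble(name = query_name, core = core))
  } else {
    query_name <- panel$name[match(core, panel$core)]
  }
  qcore <- core
  others <- filter(panel, .data$name != query_name)
  identities <- mutate(others,
    identity_pct = map_dbl(.data$core, ~ percent_identity(.x, qcore)),
    substitutions = map(.data$core, ~ substitution_list(.x, qcore)),
    n_substitutions = map_int(.data$substitutions, length)
  )
  identities <- select(identities, "name", "identity_pct",
                       "n_substitutions", "substitutions")
  d <- p_distance_matrix(panel)
  tree <- if (nrow(panel) >= 3L) {
    nj_tree(d)
  } else {
    warn("panel has fewer than 3 entries; skipping the tree")
    NULL
  }
  structure(
    list(query_name = query_name, core = core, identities = identities,
         unique_residues = unique_residues(query_name, panel),
         distances = d, tree = tree),
    class = "lanthi_comparison"
  )
}

#' @export
print.lanthi_comparison <- function(x, ...) {
  cat("<lanthi_comparison> query: ", x$query_name, "\n", sep = "")
  for (i in seq_len(nrow(x$identities))) {
    cat(sprintf("  vs %-12s %6.2f%% (%d substitutions)\n",
                x$identities$name[i], x$identities$identity_pct[i],
                x$identities$n_substitutions[i]))
  }
  cat("  unique residues:",
      if (length(x$unique_residues)) paste(x$unique_residues, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Tidy a variant comparison
#'
#' @param x A `lanthi_comparison`.
#' @param ... Unused.
#' @return The identity tibble with list-column `substitutions`.
#' @method tidy lanthi_comparison
#' @export
tidy.lanthi_comparison <- function(x, ...) x$identities

#' Assemble the full evidence report
#'
#' Collects the mining, verification and comparison stages into one
#' versioned, JSON-serialisable report mirroring the evidence chain that
#' identifies a novel variant: candidate gene -> intact mass -> fragment
#' coverage -> predicted topology -> relation to known variants.
#'
#' @param candidate One-row candidate tibble from [mine_genome()] (optional).
#' @param verification A `lanthi_verification` (optional).
#' @param comparison A `lanthi_comparison` (optional).
#' @return A `lanthi_report` list.
#' @export
nisin_report <- function(candidate = NULL, verification = NULL,
                         comparison = NULL) {
  rep <- list(schema_version = .REPORT_SCHEMA)
  if (!is.null(candidate)) {
    stopifnot(nrow(candidate) == 1L)
    split <- split_leader_core(candidate)
    rep$candidate <- list(
      contig = candidate$contig[1],
      start_1based = candidate$start[1] + 1L,   # reports are 1-based inclusive
      end_1based = candidate$end[1],
      strand = candidate$strand[1],
      best_reference = candidate$best_reference[1],
      core_identity_pct = candidate$core_identity_pct[1],
      leader = split$leader, core = split$core,
      minus1_residue = split$minus1_residue,
      minus1_class = split$minus1_class
    )
  }
  if (!is.null(verification)) {
    v <- verification
    rep$intact <- if (is.null(v$reconciliation)) NULL else
      as.list(tidy(v$reconciliation))
    rep$digest <- map(seq_len(nrow(v$matches)), function(i) {
      m <- v$matches[i, ]
      list(sequence = m$sequence, mods = m$mod_label, z = m$charge,
           theoretical_mz = round(m$mz, 4),
           observed = if (is.na(m$observed)) NULL else round(m$observed, 4),
           delta = if (is.na(m$delta)) NULL else round(m$delta, 4),
           matched = m$matched)
    })
    rep$coverage_pct <- v$coverage$coverage_pct
    if (!is.null(v$topology)) {
      rep$topology <- list(
        template = attr(v$topology, "template_name"),
        bridges = map(seq_len(nrow(v$topology)), function(i) {
          b <- v$topology[i, ]
          list(ring = b$ring, type = b$type,
               donor = sprintf("%s%d", b$donor_res, b$donor_pos),
               acceptor = sprintf("%s%d", b$acceptor_res, b$acceptor_pos))
        }),
        hinge = hinge_residues(v$core)
      )
    }
  }
  if (!is.null(comparison)) {
    rep$comparison <- list(
      identities = map(seq_len(nrow(comparison$identities)), function(i) {
        r <- comparison$identities[i, ]
        list(name = r$name, identity_pct = r$identity_pct,
             substitutions = as.list(r$substitutions[[1]]))
      }),
      unique_residues = as.list(comparison$unique_residues),
      newick = if (is.null(comparison$tree)) NULL else
        ape::write.tree(comparison$tree)
    )
  }
  structure(rep, class = c("lanthi_report", "list"))
}

#' Write an evidence report as JSON
#'
#' @param report A `lanthi_report` from [nisin_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write precursor candidates as TSV (1-based coordinates)
#'
#' @param candidates Tibble from [mine_genome()] / [score_precursors()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  header <- paste("contig", "start", "end", "strand", "best_reference",
                  "identity_pct", "leader", "core", "minus1", sep = "\t")
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%.2f\t%s\t%s\t%s",
                   candidates$contig, candidates$start + 1L, candidates$end,
                   candidates$strand, candidates$best_reference,
                   candidates$core_identity_pct, candidates$leader,
                   candidates$core, candidates$minus1_residue)
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

#' Write cluster annotations as GFF3
#'
#' Emits one CDS feature per ORF with `family`, `identity` and `truncated`
#' attributes, 1-based inclusive coordinates per the GFF3 convention.
#'
#' @param annotations Tibble from [annotate_cluster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_gff3 <- function(annotations, path) {
  lines <- sprintf(
    "%s\tlanthominer\tCDS\t%d\t%d\t%.2f\t%s\t0\tfamily=%s;identity=%.2f;truncated=%s",
    annotations$contig, annotations$start + 1L, annotations$end,
    annotations$identity_pct, annotations$strand,
    annotations$assigned_family, annotations$identity_pct,
    tolower(as.character(annotations$truncated))
  )
  writeLines(c("##gff-version 3", lines), path, useBytes = TRUE)
  invisible(path)
}
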