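# File formats the pipeline touches: FASTA (sequences in and out), peak-list
# TSV (observed masses / m/z), Newick (trees). All text I/O is UTF-8 and
# locale-independent; sequences are upper-cased on input.

.NUC_CHARS <- "ACGTUNRYSWKMBDHV"
.PROT_CHARS <- "ACDEFGHIKLMNPQRSTVWYX"

#' Read a FASTA file into a tibble of sequence records
#'
#' Parses a (possibly multi-line) FASTA file via [Biostrings::readBStringSet()]
#' and returns one row per record. The record identifier is the first
#' whitespace-delimited token of the header; the full header is retained as
#' the description. Sequences are upper-cased and validated against the
#' requested alphabet (IUPAC ambiguity codes allowed for nucleotides, `X`
#' allowed for protein).
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return A tibble with columns `identifier`, `description`, `residues`,
#'   `alphabet`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">nisS example", "ITSYSLCT", "PGCK"), fa)
#' read_fasta(fa, "protein")
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "lanthi_input_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("malformed FASTA '", path, "': ", conditionMessage(e)),
            class = "lanthi_format_error")
    }
  )
  if (length(set) == 0L) {
    abort(paste0("FASTA file '", path, "' contains no records"),
          class = "lanthi_format_error")
  }
  headers <- names(set)
  residues <- str_to_upper(as.character(set))
  ids <- map_chr(headers, function(h) str_split_1(str_trim(h), "\\s+")[1])
  allowed <- if (alphabet == "nucleotide") .NUC_CHARS else .PROT_CHARS
  for (i in seq_along(residues)) {
    .check_alphabet(residues[i], allowed, ids[i])
    if (nchar(residues[i]) == 0L) {
      abort(paste0("record '", ids[i], "' has an empty sequence"),
            class = "lanthi_format_error")
    }
  }
  tibble(
    identifier = ids,
    description = headers,
    residues = residues,
    alphabet = alphabet
  )
}

.check_alphabet <- function(seq, allowed, id) {
  bad <- setdiff(str_split_1(seq, ""), str_split_1(allowed, ""))
  if (length(bad) > 0L) {
    abort(
      paste0("record '", id, "' contains characters outside the alphabet: ",
             paste(unique(bad), collapse = ", ")),
      class = "lanthi_alphabet_error"
    )
  }
  invisible(TRUE)
}

#' Write sequence records to FASTA
#'
#' @param records A tibble as returned by [read_fasta()] (columns
#'   `identifier`, `residues`, optionally `description`).
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("identifier", "residues") %in% names(records)))
  headers <- if ("description" %in% names(records) &&
                 !all(is.na(records$description))) {
    records$description
  } else {
    records$identifier
  }
  set <- Biostrings::BStringSet(setNames(records$residues, headers))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a peak list from a two-column TSV
#'
#' Loads observed masses or m/z values (one per line, optional second column
#' with intensities; `#` comment lines skipped) and returns them sorted
#' ascending by value. Missing intensities default to 1.
#'
#' @param path Path to the TSV.
#' @param value_kind What the first column holds: `"neutral_mass"` (Da) or
#'   `"mz"` (Th).
#' @return A tibble with columns `value`, `intensity`, `value_kind`, sorted
#'   ascending by `value`.
#' @examples
#' pk <- tempfile(fileext = ".tsv")
#' writeLines(c("# MALDI peak", "3347.15\t100"), pk)
#' read_peaklist(pk, "neutral_mass")
#' @export
read_peaklist <- function(path, value_kind = c("neutral_mass", "mz")) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) {
    abort(paste0("peak list not found: ", path), class = "lanthi_input_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  keep <- which(!str_detect(lines, "^\\s*#") & str_trim(lines) != "")
  if (length(keep) == 0L) {
    warn(paste0("peak list '", path, "' is empty after removing comments"))
    return(peaklist(numeric(0), numeric(0), value_kind))
  }
  parse_row <- function(i) {
    fields <- str_split_1(str_trim(lines[i]), "\t")
    value <- suppressWarnings(as.numeric(fields[1]))
    if (is.na(value)) {
      abort(paste0("non-numeric peak value at line ", i, " of '", path, "'"),
            class = "lanthi_parse_error")
    }
    intensity <- if (length(fields) >= 2L) {
      v <- suppressWarnings(as.numeric(fields[2]))
      if (is.na(v)) {
        abort(paste0("non-numeric intensity at line ", i, " of '", path, "'"),
              class = "lanthi_parse_error")
      }
      v
    } else {
      1.0
    }
    c(value = value, intensity = intensity)
  }
  rows <- t(vapply(keep, parse_row, c(value = 0, intensity = 0)))
  if (any(rows[, "value"] <= 0)) {
    abort("peak values must be strictly positive", class = "lanthi_domain_error")
  }
  if (any(rows[, "intensity"] < 0)) {
    abort("peak intensities must be non-negative", class = "lanthi_domain_error")
  }
  peaklist(rows[, "value"], rows[, "intensity"], value_kind)
}

#' Construct a peak list in memory
#'
#' @param value Numeric vector of neutral masses (Da) or m/z (Th), all > 0.
#' @param intensity Intensities (recycled; default 1).
#' @param value_kind `"neutral_mass"` or `"mz"`.
#' @return A sorted peak-list tibble, as from [read_peaklist()].
#' @export
peaklist <- function(value, intensity = 1,
                     value_kind = c("neutral_mass", "mz")) {
  value_kind <- match.arg(value_kind)
  stopifnot(all(value > 0))
  out <- tibble(
    value = as.numeric(value),
    intensity = as.numeric(rep_len(intensity, length(value))),
    value_kind = rep_len(value_kind, length(value))
  )
  arrange(out, .data$value)
}

#' Write a peak list as TSV
#'
#' @param peaks A peak-list tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path) {
  lines <- sprintf("%.6g\t%.6g", peaks$value, peaks$intensity)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a phylogenetic tree in Newick format
#'
#' Serializes an [ape::phylo] tree with branch lengths, terminated by `;`.
#'
#' @param tree A `phylo` object with at least two uniquely labelled leaves.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) {
    abort("tree must have at least two leaves", class = "lanthi_domain_error")
  }
  if (anyDuplicated(tree$tip.label)) {
    abort("duplicate leaf labels in tree", class = "lanthi_label_error")
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
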