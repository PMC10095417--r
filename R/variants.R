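# Comparing a candidate core against the known nisin variants: percent
# identity, substitution lists, residues unique to the query, p-distance
# matrices and neighbor-joining dendrograms. Mature nisin cores are short
# (31-35 aa) and near-identical, so the raw proportion of mismatching
# positions (p-distance) is the distance of choice; no model correction.

.NISIN_S_CORE <- "ITSYSLCTPGCKTGALMGCTMKTASCGCHVHISK"
.NISIN_F_CORE <- "ITSISLCTPGCKTGALMGCNMKTATCHCSVHVSK"

#' Built-in panel of mature nisin cores
#'
#' The three cores the package's worked analyses use: nisin A and nisin F
#' (known lactococcal variants) and nisin S (the *Ligilactobacillus
#' salivarius* variant the verification workflow targets). Extend or replace
#' the panel with user-supplied FASTA via [read_fasta()].
#'
#' @return A tibble with columns `name`, `core`.
#' @examples
#' nisin_panel()
#' @export
nisin_panel <- function() {
  tibble(
    name = c("nisin A", "nisin F", "nisin S"),
    core = c(.NISIN_A_CORE, .NISIN_F_CORE, .NISIN_S_CORE)
  )
}

.check_equal_length <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort(
      paste0("sequences have different lengths (", nchar(a), " vs ", nchar(b),
             "); align or anchor them first (see thread_template(align = \"offset\"))"),
      class = "lanthi_domain_error"
    )
  }
}

#' Percent identity between two aligned sequences
#'
#' `100 * matches / length`, reported to two decimals. Sequences must have
#' equal length (the package's gapless-offset anchoring handles the 31--35
#' residue spread of natural variants upstream).
#'
#' @param a,b Sequences of equal length.
#' @return Percent identity (2 dp).
#' @examples
#' p <- nisin_panel()
#' percent_identity(p$core[p$name == "nisin S"], p$core[p$name == "nisin A"])
#' @export
percent_identity <- function(a, b) {
  a <- str_to_upper(a); b <- str_to_upper(b)
  .check_equal_length(a, b)
  round(100 * sum(str_split_1(a, "") == str_split_1(b, "")) / nchar(a), 2)
}

#' Substitutions between a reference and a query sequence
#'
#' One token per mismatching position, reference residue first:
#' `"N20T"` means the reference has N and the query T at position 20.
#'
#' @param reference,query Aligned sequences of equal length.
#' @return Character vector of substitution tokens (empty if identical).
#' @examples
#' p <- nisin_panel()
#' substitution_list(p$core[1], p$core[3])
#' @export
substitution_list <- function(reference, query) {
  reference <- str_to_upper(reference); query <- str_to_upper(query)
  .check_equal_length(reference, query)
  r <- str_split_1(reference, ""); q <- str_split_1(query, "")
  pos <- which(r != q)
  sprintf("%s%d%s", r[pos], pos, q[pos])
}

#' Residues unique to one panel member
#'
#' Positions where the query's residue occurs in no other panel entry —
#' candidate determinants of variant-specific behaviour.
#'
#' @param query_name Name of the query entry in the panel.
#' @param panel Tibble with columns `name`, `core`, all cores aligned
#'   (equal length).
#' @return Character vector of `"X<pos>"` tokens (query residue + position).
#' @examples
#' unique_residues("nisin S", nisin_panel())
#' @export
unique_residues <- function(query_name, panel) {
  stopifnot(all(c("name", "core") %in% names(panel)))
  if (!query_name %in% panel$name) {
    abort(paste0("'", query_name, "' is not in the panel"),
          class = "lanthi_domain_error")
  }
  q <- panel$core[panel$name == query_name][1]
  others <- panel$core[panel$name != query_name]
  if (length(others) == 0L) return(character(0))
  for (o in others) .check_equal_length(q, o)
  qc <- str_split_1(q, "")
  om <- do.call(rbind, map(others, ~ str_split_1(.x, "")))
  pos <- which(vapply(seq_along(qc),
                      function(i) !qc[i] %in% om[, i], logical(1)))
  sprintf("%s%d", qc[pos], pos)
}

#' p-distance matrix for a variant panel
#'
#' `d(a, b)` is the fraction of mismatching positions between the aligned
#' cores — zero diagonal, symmetric, values in `[0, 1]`.
#'
#' @param panel Tibble with columns `name`, `core`.
#' @return A symmetric numeric matrix with the panel names as dimnames.
#' @export
p_distance_matrix <- function(panel) {
  stopifnot(all(c("name", "core") %in% names(panel)))
  if (anyDuplicated(panel$name)) {
    abort("panel names must be unique", class = "lanthi_label_error")
  }
  n <- nrow(panel)
  d <- matrix(0, n, n, dimnames = list(panel$name, panel$name))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        .check_equal_length(panel$core[i], panel$core[j])
        mism <- sum(str_split_1(panel$core[i], "") !=
                      str_split_1(panel$core[j], ""))
        d[i, j] <- d[j, i] <- mism / nchar(panel$core[i])
      }
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou--Nei neighbor joining (via [ape::nj()]) on a p-distance
#' matrix; negative branch lengths arising from noise are clamped to zero.
#' The result is unrooted.
#'
#' @param d Symmetric distance matrix with >= 3 labelled taxa.
#' @return An [ape::phylo] tree.
#' @examples
#' nj_tree(p_distance_matrix(nisin_panel()))
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) < 3L) {
    abort("neighbor joining needs at least 3 taxa",
          class = "lanthi_size_error")
  }
  tree <- ape::nj(as.dist(d))
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' @importFrom stats as.dist
NULL
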