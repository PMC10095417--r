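# Peptide mass arithmetic: neutral monoisotopic / average masses of
# (optionally modified) peptides, and the dehydration accounting that
# reconciles a deduced unmodified core mass with an observed intact mass.
# Lanthipeptide maturation dehydrates Ser (-> dehydroalanine) and Thr
# (-> dehydrobutyrine), each event removing one water; the count of waters
# lost is what links the gene-deduced mass to the mass the spectrometer sees.

#' Attach modifications to a peptide sequence
#'
#' A modified peptide is the unit of all mass computation: a sequence plus a
#' set of per-position mass deltas. At most one modification per position.
#'
#' @param sequence Amino-acid sequence (upper case).
#' @param positions 1-based positions carrying a modification (may be empty).
#' @param deltas Mass deltas in Da, one per position.
#' @param labels Modification labels, one per position (e.g.
#'   `"carbamidomethyl"`).
#' @return An object of class `modified_peptide`.
#' @examples
#' modified_peptide("ITSYSLCTPGCK", c(7, 11),
#'                  rep(mass_constants()$mods[["carbamidomethyl"]], 2),
#'                  rep("carbamidomethyl", 2))
#' @export
modified_peptide <- function(sequence, positions = integer(0),
                             deltas = numeric(0), labels = character(0)) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0)
  sequence <- str_to_upper(sequence)
  positions <- as.integer(positions)
  stopifnot(length(positions) == length(deltas),
            length(positions) == length(labels))
  if (length(positions) > 0) {
    if (any(positions < 1L | positions > nchar(sequence))) {
      abort("modification positions outside the sequence",
            class = "lanthi_domain_error")
    }
    if (anyDuplicated(positions)) {
      abort("at most one modification per position",
            class = "lanthi_domain_error")
    }
    ord <- order(positions)
    positions <- positions[ord]; deltas <- deltas[ord]; labels <- labels[ord]
  }
  structure(
    list(sequence = sequence,
         mods = tibble(position = positions, delta = as.numeric(deltas),
                       label = as.character(labels))),
    class = "modified_peptide"
  )
}

#' @export
print.modified_peptide <- function(x, ...) {
  lab <- if (nrow(x$mods) == 0) "unmodified" else
    paste(sprintf("%s@%d", x$mods$label, x$mods$position), collapse = ", ")
  cat("<modified_peptide> ", x$sequence, " [", lab, "]\n", sep = "")
  invisible(x)
}

.as_modified_peptide <- function(p) {
  if (inherits(p, "modified_peptide")) p else modified_peptide(p)
}

#' Neutral mass of a (modified) peptide
#'
#' Sums residue masses, adds one water for the free peptide termini, and adds
#' all modification deltas. The result is the neutral, uncharged mass;
#' protonated species are formed downstream with [mz()].
#'
#' @param p A `modified_peptide` or a bare sequence string (treated as
#'   unmodified).
#' @param mass_type `"mono"` (monoisotopic) or `"avg"` (isotope-averaged).
#' @return Neutral mass in Da.
#' @examples
#' peptide_mass("G") # 75.0321
#' peptide_mass("ITSYSLCTPGCKTGALMGCTMKTASCGCHVHISK", "avg")
#' @export
peptide_mass <- function(p, mass_type = c("mono", "avg")) {
  mass_type <- match.arg(mass_type)
  p <- .as_modified_peptide(p)
  table <- .residue_table(mass_type)
  chars <- str_split_1(p$sequence, "")
  unknown <- which(!chars %in% names(table))
  if (length(unknown) > 0L) {
    abort(
      paste0("unknown residue '", chars[unknown[1]], "' at position ",
             unknown[1], " of '", p$sequence, "'"),
      class = "lanthi_alphabet_error"
    )
  }
  sum(table[chars]) + .water(mass_type) + sum(p$mods$delta)
}

#' Infer the dehydration count from deduced and observed masses
#'
#' Explains the gap between the mass deduced from an unmodified sequence and
#' the observed intact mass as an integer number of water losses plus a
#' residual: `n = round((deduced - observed) / water)`, clipped at zero, with
#' `residual = (deduced - observed) - n * water`.
#'
#' @param deduced Deduced (unmodified) neutral mass, Da.
#' @param observed Observed intact neutral mass, Da.
#' @param mass_type `"mono"` or `"avg"` — selects the water mass used.
#' @return A `dehydration_inference` object; see [tidy.dehydration_inference()].
#' @examples
#' infer_dehydrations(3491.17, 3347.15, "avg")
#' @export
infer_dehydrations <- function(deduced, observed, mass_type = c("mono", "avg")) {
  mass_type <- match.arg(mass_type)
  w <- .water(mass_type)
  diff <- deduced - observed
  n <- max(0L, as.integer(round(diff / w)))
  structure(
    list(deduced_mass = deduced, observed_mass = observed,
         n_dehydrations = n, residual = diff - n * w, mass_type = mass_type),
    class = "dehydration_inference"
  )
}

#' @export
print.dehydration_inference <- function(x, ...) {
  cat(sprintf(
    "<dehydration_inference> deduced %.2f Da, observed %.2f Da (%s)\n  n = %d waters lost, residual %+.4f Da\n",
    x$deduced_mass, x$observed_mass, x$mass_type, x$n_dehydrations, x$residual
  ))
  invisible(x)
}

#' Tidy a dehydration inference
#'
#' @param x A `dehydration_inference`.
#' @param ... Unused.
#' @return A one-row tibble with columns `deduced_mass`, `observed_mass`,
#'   `n_dehydrations`, `residual`, `mass_type`.
#' @method tidy dehydration_inference
#' @export
tidy.dehydration_inference <- function(x, ...) {
  tibble(
    deduced_mass = x$deduced_mass, observed_mass = x$observed_mass,
    n_dehydrations = x$n_dehydrations, residual = x$residual,
    mass_type = x$mass_type
  )
}

#' @rdname tidy.dehydration_inference
#' @method glance dehydration_inference
#' @export
glance.dehydration_inference <- function(x, ...) tidy(x)

#' Predicted mass of a dehydrated core peptide
#'
#' The mature-core mass implied by `n` dehydration events:
#' `peptide_mass(core) - n * water`. Errors if `n` exceeds the number of
#' dehydratable residues (Ser + Thr).
#'
#' @param core Core peptide sequence.
#' @param n_dehydrations Number of water losses.
#' @param mass_type `"mono"` or `"avg"`.
#' @return Neutral mass in Da.
#' @export
modified_core_mass <- function(core, n_dehydrations,
                               mass_type = c("mono", "avg")) {
  mass_type <- match.arg(mass_type)
  stopifnot(n_dehydrations >= 0)
  cap <- dehydration_capacity(core)
  if (n_dehydrations > cap$capacity) {
    abort(
      paste0("n_dehydrations (", n_dehydrations, ") exceeds the Ser+Thr ",
             "capacity (", cap$capacity, ") of the core"),
      class = "lanthi_capacity_error"
    )
  }
  peptide_mass(core, mass_type) - n_dehydrations * .water(mass_type)
}

#' Dehydratable-residue accounting for a core peptide
#'
#' Counts serines and threonines (dehydration substrates) and cysteines
#' (thioether-bridge acceptors). The dehydration capacity is `n_ser + n_thr`.
#'
#' @param core Core peptide sequence.
#' @return A one-row tibble with columns `n_ser`, `n_thr`, `n_cys`,
#'   `capacity`.
#' @examples
#' dehydration_capacity("ITSYSLCTPGCKTGALMGCTMKTASCGCHVHISK")
#' @export
dehydration_capacity <- function(core) {
  core <- str_to_upper(core)
  tibble(
    n_ser = str_count(core, "S"),
    n_thr = str_count(core, "T"),
    n_cys = str_count(core, "C"),
    capacity = str_count(core, "[ST]")
  )
}
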