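# In-silico tryptic digestion and targeted-MS inclusion lists. Trypsin
# cleaves C-terminal of Lys/Arg except when the next residue is Pro; the
# digest of a candidate core, expanded over fixed/variable modifications and
# charge states 2-4, is the inclusion list a targeted proteomics run uses to
# look for the peptide in a sample.

#' Describe a modification rule
#'
#' @param residue Single residue the modification applies to.
#' @param delta Mass delta in Da.
#' @param label Modification name.
#' @return A one-row tibble with columns `residue`, `delta`, `label`.
#' @export
mod_spec <- function(residue, delta, label) {
  stopifnot(nchar(residue) == 1L)
  tibble(residue = str_to_upper(residue), delta = as.numeric(delta),
         label = label)
}

#' Default fixed modification: cysteine carbamidomethylation
#' @return A `mod_spec()` tibble.
#' @export
fixed_cam <- function() {
  mod_spec("C", mass_constants()$mods[["carbamidomethyl"]], "carbamidomethyl")
}

#' Default variable modification: methionine oxidation
#' @return A `mod_spec()` tibble.
#' @export
variable_ox <- function() {
  mod_spec("M", mass_constants()$mods[["oxidation"]], "oxidation")
}

#' In-silico tryptic digest
#'
#' Cleaves after every Lys or Arg not followed by Pro and returns all
#' fragments with at most `max_missed` internal (missed) cleavage sites.
#' Spans are 1-based inclusive on the parent; fragments with zero missed
#' cleavages tile the parent exactly.
#'
#' @param sequence Parent amino-acid sequence.
#' @param max_missed Maximum missed cleavages per fragment (>= 0).
#' @return A tibble with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`, ordered by start then length.
#' @examples
#' tryptic_digest("ITSYSLCTPGCKTGALMGCTMKTASCGCHVHISK")
#' @export
tryptic_digest <- function(sequence, max_missed = 0L) {
  sequence <- str_to_upper(sequence)
  n <- nchar(sequence)
  if (n == 0L) {
    abort("cannot digest an empty sequence", class = "lanthi_domain_error")
  }
  stopifnot(max_missed >= 0)
  chars <- str_split_1(sequence, "")
  # cleavage after position i: K/R at i, next residue not P
  sites <- which(chars[-n] %in% c("K", "R") & chars[-1] != "P")
  bounds <- c(0L, sites, n)
  k <- length(bounds)
  frags <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):min(k, i + 1L + max_missed)) {
      frags[[length(frags) + 1L]] <- tibble(
        start = bounds[i] + 1L,
        end = bounds[j],
        missed_cleavages = j - i - 1L
      )
    }
  }
  out <- list_rbind(frags)
  out$sequence <- str_sub(sequence, out$start, out$end)
  out <- select(out, "sequence", "start", "end", "missed_cleavages")
  arrange(out, .data$start, .data$end - .data$start)
}

#' Enumerate modification forms of a digest fragment
#'
#' Applies every fixed modification to each eligible residue and enumerates
#' all position-wise combinations of at most `max_variable` variable
#' modifications. Forms are ordered by ascending variable-mod count, then by
#' modified positions lexicographically.
#'
#' @param fragment Fragment sequence (string) or a one-row tibble from
#'   [tryptic_digest()].
#' @param fixed,variable Modification rules (tibbles from [mod_spec()];
#'   several rules may be row-bound). Defaults: carbamidomethyl on C fixed,
#'   oxidation on M variable.
#' @param max_variable Maximum number of variable modifications per form.
#' @return A tibble with one row per positional form: columns `sequence`,
#'   `n_variable`, `mod_label` (position-annotated), `multiset_label`
#'   (positions dropped; equal-mass forms share it), `neutral_mono`,
#'   and a list-column `peptide` of [modified_peptide()] objects.
#' @export
enumerate_modforms <- function(fragment, fixed = fixed_cam(),
                               variable = variable_ox(), max_variable = 2L) {
  seq <- if (is.data.frame(fragment)) fragment$sequence[1] else fragment
  seq <- str_to_upper(seq)
  stopifnot(max_variable >= 0)
  chars <- str_split_1(seq, "")

  fixed_tbl <- if (is.null(fixed) || nrow(fixed) == 0) {
    tibble(position = integer(0), delta = numeric(0), label = character(0))
  } else {
    list_rbind(map(seq_len(nrow(fixed)), function(i) {
      pos <- which(chars == fixed$residue[i])
      tibble(position = pos, delta = fixed$delta[i], label = fixed$label[i])
    }))
  }

  var_sites <- if (is.null(variable) || nrow(variable) == 0) {
    tibble(position = integer(0), delta = numeric(0), label = character(0))
  } else {
    list_rbind(map(seq_len(nrow(variable)), function(i) {
      pos <- which(chars == variable$residue[i])
      tibble(position = pos, delta = variable$delta[i], label = variable$label[i])
    }))
  }
  var_sites <- arrange(var_sites, .data$position)

  combos <- list(integer(0))
  if (nrow(var_sites) > 0 && max_variable > 0) {
    for (m in seq_len(min(max_variable, nrow(var_sites)))) {
      cmb <- utils::combn(seq_len(nrow(var_sites)), m, simplify = FALSE)
      # lexicographic by position vectors within each count
      cmb <- cmb[order(map_chr(cmb, function(ix)
        paste(sprintf("%06d", var_sites$position[ix]), collapse = ",")))]
      combos <- c(combos, cmb)
    }
  }

  rows <- map(combos, function(ix) {
    vm <- var_sites[ix, , drop = FALSE]
    all_pos <- c(fixed_tbl$position, vm$position)
    all_delta <- c(fixed_tbl$delta, vm$delta)
    all_label <- c(fixed_tbl$label, vm$label)
    pep <- modified_peptide(seq, all_pos, all_delta, all_label)
    lab_pos <- if (length(all_pos) == 0) "unmodified" else
      paste(sprintf("%s@%d", pep$mods$label, pep$mods$position), collapse = ";")
    counts <- sort(table(all_label))
    lab_set <- if (length(counts) == 0) "unmodified" else
      paste(sprintf("%s x%d", names(counts), as.integer(counts)),
            collapse = " + ")
    tibble(
      sequence = seq,
      n_variable = length(ix),
      mod_label = lab_pos,
      multiset_label = lab_set,
      neutral_mono = peptide_mass(pep, "mono"),
      peptide = list(pep)
    )
  })
  list_rbind(rows)
}

#' m/z of a charged peptide ion
#'
#' `(neutral_mass + charge * 1.007276) / charge` — the proton convention used
#' for positive-mode electrospray species.
#'
#' @param neutral_mass Neutral mass in Da.
#' @param charge Positive integer charge.
#' @return m/z in Th.
#' @examples
#' mz(1385.632, 2) # 693.82
#' @export
mz <- function(neutral_mass, charge) {
  if (any(charge < 1)) {
    abort("charge must be >= 1", class = "lanthi_domain_error")
  }
  (neutral_mass + charge * .PROTON) / charge
}

#' Recover a neutral mass from an observed m/z
#'
#' @param mz_value Observed m/z (Th).
#' @param charge Charge state.
#' @return Neutral mass in Da.
#' @export
neutral_from_mz <- function(mz_value, charge) {
  if (any(charge < 1)) {
    abort("charge must be >= 1", class = "lanthi_domain_error")
  }
  mz_value * charge - charge * .PROTON
}

#' Build a targeted-MS inclusion list for a core peptide
#'
#' Digests the core, enumerates modification forms of each fragment, computes
#' m/z at every requested charge, collapses positional isomers with identical
#' modification multisets (they are isobaric and indistinguishable at MS1),
#' and returns the targets sorted by m/z.
#'
#' @param core Core peptide sequence.
#' @param charges Integer charge states (within 1--6; default 2:4).
#' @param fixed,variable Modification rules, as in [enumerate_modforms()].
#' @param max_variable Maximum variable modifications per fragment.
#' @param max_missed Maximum missed cleavages.
#' @return A tibble with columns `sequence`, `start`, `end`, `mod_label`
#'   (multiset form), `n_variable`, `charge`, `neutral_mass`, `mz`, sorted by
#'   `mz`.
#' @examples
#' build_inclusion_list("ITSYSLCTPGCKTGALMGCTMKTASCGCHVHISK")
#' @export
build_inclusion_list <- function(core, charges = 2:4, fixed = fixed_cam(),
                                 variable = variable_ox(), max_variable = 2L,
                                 max_missed = 0L) {
  charges <- as.integer(charges)
  if (any(charges < 1L) || any(charges > 6L)) {
    abort("charges must lie within 1..6", class = "lanthi_domain_error")
  }
  frags <- tryptic_digest(core, max_missed)
  forms <- list_rbind(map(seq_len(nrow(frags)), function(i) {
    f <- enumerate_modforms(frags$sequence[i], fixed, variable, max_variable)
    mutate(f, start = frags$start[i], end = frags$end[i])
  }))
  # collapse positional isomers: one representative per modification multiset
  forms <- distinct(forms, .data$sequence, .data$start, .data$end,
                    .data$multiset_label, .keep_all = TRUE)
  out <- list_rbind(map(charges, function(z) {
    mutate(forms, charge = z, mz = mz(.data$neutral_mono, z))
  }))
  out <- distinct(out, .data$sequence, .data$multiset_label, .data$charge,
                  .keep_all = TRUE)
  out <- tibble(
    sequence = out$sequence, start = out$start, end = out$end,
    mod_label = out$multiset_label, n_variable = out$n_variable,
    charge = out$charge, neutral_mass = out$neutral_mono, mz = out$mz
  )
  arrange(out, .data$mz, .data$sequence, .data$charge)
}

#' Write an inclusion list as TSV
#'
#' Columns `sequence`, `mod_labels`, `z`, `mz` (4 dp), `neutral_mass`
#' (4 dp); row order is the stable m/z order of [build_inclusion_list()], so
#' repeated runs are byte-identical.
#'
#' @param targets Tibble from [build_inclusion_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inclusion_list <- function(targets, path) {
  header <- "sequence\tmod_labels\tz\tmz\tneutral_mass"
  lines <- sprintf("%s\t%s\t%d\t%.4f\t%.4f",
                   targets$sequence, targets$mod_label, targets$charge,
                   targets$mz, targets$neutral_mass)
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}
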