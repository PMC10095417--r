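# Matching theory against observation: inclusion-list targets vs observed
# peak lists, sequence coverage from matched fragments, and the intact-mass
# reconciliation that ties a candidate core to the secreted peptide.

#' Match inclusion-list targets against an observed peak list
#'
#' Each target is assigned its nearest observed peak; the match flag is set
#' when the absolute difference is within the tolerance. One peak may satisfy
#' several targets; ties between equidistant peaks break toward the lower
#' value, so the assignment is deterministic.
#'
#' @param targets Tibble from [build_inclusion_list()] (needs columns `mz` or
#'   `neutral_mass`, matched against the peak list's `value_kind`).
#' @param peaks Peak-list tibble from [read_peaklist()] / [peaklist()].
#' @param tolerance Match tolerance, in the units of the peak values
#'   (Th for m/z lists, Da for neutral-mass lists). Must be > 0.
#' @return The `targets` tibble with added columns `observed`, `delta`
#'   (observed - theoretical) and `matched`, classed `lanthi_matches`.
#' @export
match_targets <- function(targets, peaks, tolerance = 0.02) {
  if (tolerance <= 0) {
    abort("tolerance must be positive", class = "lanthi_domain_error")
  }
  kind <- if (nrow(peaks) > 0) peaks$value_kind[1] else "mz"
  theo <- if (kind == "mz") {
    if (!"mz" %in% names(targets)) {
      abort("peak list holds m/z but targets have no 'mz' column",
            class = "lanthi_domain_error")
    }
    targets$mz
  } else {
    if (!"neutral_mass" %in% names(targets)) {
      abort("peak list holds neutral masses but targets have no 'neutral_mass' column",
            class = "lanthi_domain_error")
    }
    targets$neutral_mass
  }
  if (nrow(peaks) == 0L) {
    out <- mutate(targets, observed = NA_real_, delta = NA_real_,
                  matched = FALSE)
    return(structure(out, class = c("lanthi_matches", class(out))))
  }
  vals <- peaks$value # sorted ascending
  nearest <- vapply(theo, function(t) {
    d <- abs(vals - t)
    # ties toward the lower value: which.min returns the first minimum and
    # vals is sorted ascending
    vals[which.min(d)]
  }, numeric(1))
  out <- mutate(targets,
    observed = nearest,
    delta = .data$observed - theo,
    matched = abs(.data$delta) <= tolerance
  )
  structure(out, class = c("lanthi_matches", class(out)))
}

#' Sequence coverage from matched fragments
#'
#' Takes the union of the parent spans of all matched targets and reports the
#' fraction of core positions covered by at least one identified fragment.
#'
#' @param matches Tibble from [match_targets()] (needs columns `start`, `end`,
#'   `matched`).
#' @param core_length Length of the core peptide.
#' @return A `coverage_report` object (see [tidy.coverage_report()]), with
#'   fields `core_length`, `covered_positions`, `coverage_pct`.
#' @export
sequence_coverage <- function(matches, core_length) {
  stopifnot(core_length >= 1)
  hit <- filter(matches, .data$matched)
  if (nrow(hit) > 0 &&
      (any(hit$start < 1) || any(hit$end > core_length))) {
    abort("matched spans fall outside [1, core_length]",
          class = "lanthi_domain_error")
  }
  covered <- sort(unique(unlist(
    map2(hit$start, hit$end, seq.int),
    use.names = FALSE
  )))
  structure(
    list(core_length = as.integer(core_length),
         covered_positions = as.integer(covered),
         coverage_pct = 100 * length(covered) / core_length),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %d/%d positions covered (%.2f%%)\n",
              length(x$covered_positions), x$core_length, x$coverage_pct))
  invisible(x)
}

#' Tidy / summarise a coverage report
#'
#' `tidy()` returns one row per core position with its covered flag;
#' `glance()` returns the one-row summary.
#'
#' @param x A `coverage_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy coverage_report
#' @export
tidy.coverage_report <- function(x, ...) {
  tibble(position = seq_len(x$core_length),
         covered = seq_len(x$core_length) %in% x$covered_positions)
}

#' @rdname tidy.coverage_report
#' @method glance coverage_report
#' @export
glance.coverage_report <- function(x, ...) {
  tibble(core_length = x$core_length,
         n_covered = length(x$covered_positions),
         coverage_pct = x$coverage_pct)
}

#' Reconcile an observed intact mass with a candidate core
#'
#' For every peak in a neutral-mass peak list, infers a dehydration count
#' against the unmodified core mass and keeps the inference with the smallest
#' absolute residual, provided the residual is within `max_residual` and the
#' count does not exceed the core's Ser+Thr capacity. This is the step that
#' identifies a genome-mined candidate as the peptide actually secreted.
#'
#' @param peaks Neutral-mass peak list (MALDI-style; convert protonated lists
#'   with [neutral_from_mz()] first).
#' @param core Candidate core sequence.
#' @param mass_type `"avg"` (default, linear-mode MALDI convention for intact
#'   masses) or `"mono"`.
#' @param max_residual Largest acceptable residual, Da.
#' @return The best `dehydration_inference`, or `NULL` if no peak reconciles.
#' @examples
#' pk <- peaklist(3347.15, value_kind = "neutral_mass")
#' reconcile_intact(pk, "ITSYSLCTPGCKTGALMGCTMKTASCGCHVHISK")
#' @export
reconcile_intact <- function(peaks, core, mass_type = c("avg", "mono"),
                             max_residual = 0.5) {
  mass_type <- match.arg(mass_type)
  if (nrow(peaks) == 0L) return(NULL)
  deduced <- peptide_mass(core, mass_type)
  cap <- dehydration_capacity(core)$capacity
  inferences <- map(peaks$value, function(obs)
    infer_dehydrations(deduced, obs, mass_type))
  ok <- map_dbl(inferences, function(inf) {
    if (inf$n_dehydrations <= cap) abs(inf$residual) else Inf
  })
  best <- which.min(ok)
  if (!is.finite(ok[best]) || ok[best] > max_residual) return(NULL)
  inferences[[best]]
}
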