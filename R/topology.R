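# Template-based ring-topology threading. Nisin-family lanthipeptides carry
# five thioether rings (A-E): a dehydrated Ser/Thr (donor) condensed onto a
# downstream Cys (acceptor). Ring positions are strongly conserved across
# natural variants, so a candidate core can be threaded onto the nisin A
# topology position-by-position; each bridge is then classified by its donor
# residue (Ser -> lanthionine, Thr -> 3-methyllanthionine).

.NISIN_A_CORE <- "ITSISLCTPGCKTGALMGCNMKTATCHCSIHVSK"

#' The nisin A ring-topology template
#'
#' Five bridges on the 34-residue nisin A core — A: 3--7, B: 8--11,
#' C: 13--19, D: 23--26, E: 25--28 — plus the flexible hinge at positions
#' 20--22 that links the lipid-II-binding N-terminal domain to the
#' pore-forming C-terminal domain.
#'
#' @return A list with elements `name`, `core`, `bridges` (tibble with
#'   columns `ring`, `donor_pos`, `acceptor_pos`) and `hinge` (integer
#'   positions).
#' @export
nisin_a_template <- function() {
  list(
    name = "nisin A",
    core = .NISIN_A_CORE,
    bridges = tibble(
      ring = c("A", "B", "C", "D", "E"),
      donor_pos = c(3L, 8L, 13L, 23L, 25L),
      acceptor_pos = c(7L, 11L, 19L, 26L, 28L)
    ),
    hinge = 20:22
  )
}

#' Thread a candidate core onto a template ring topology
#'
#' Maps each template bridge to the same positions in the candidate core
#' (after an optional gapless offset for cores of different length),
#' validates that every mapped donor is Ser or Thr and every acceptor is Cys,
#' and classifies each bridge as lanthionine (`Lan`, Ser donor) or
#' 3-methyllanthionine (`MeLan`, Thr donor).
#'
#' @param core Candidate core sequence. Must match the template core length
#'   unless `align = "offset"`.
#' @param template Template from [nisin_a_template()].
#' @param align `"none"` (equal-length positional threading, the default) or
#'   `"offset"` (search gapless offsets within ±3, anchored by maximum
#'   identity over the overlap, for 31--35-residue variants).
#' @return A `ring_topology` tibble with columns `ring`, `donor_pos`,
#'   `donor_res`, `acceptor_pos`, `acceptor_res`, `type`; the template name
#'   and core are attached as attributes.
#' @examples
#' thread_template("ITSYSLCTPGCKTGALMGCTMKTASCGCHVHISK")
#' @export
thread_template <- function(core, template = nisin_a_template(),
                            align = c("none", "offset")) {
  align <- match.arg(align)
  core <- str_to_upper(core)
  offset <- 0L
  if (nchar(core) != nchar(template$core)) {
    if (align == "none") {
      abort(
        paste0("core length (", nchar(core), ") differs from template length (",
               nchar(template$core),
               "); use align = \"offset\" for unequal-length variants"),
        class = "lanthi_threading_error"
      )
    }
    offset <- .best_offset(core, template$core)
  }
  chars <- str_split_1(core, "")
  b <- mutate(template$bridges,
              donor_pos = .data$donor_pos + offset,
              acceptor_pos = .data$acceptor_pos + offset)
  in_range <- b$donor_pos >= 1 & b$acceptor_pos <= nchar(core)
  donor_res <- ifelse(in_range, chars[pmax(b$donor_pos, 1L)], NA_character_)
  acceptor_res <- ifelse(in_range, chars[pmin(b$acceptor_pos, nchar(core))],
                         NA_character_)
  bad <- !in_range | !(donor_res %in% c("S", "T")) | acceptor_res != "C"
  if (any(bad)) {
    abort(
      paste0("cannot thread template '", template$name, "': ring(s) ",
             paste(b$ring[bad], collapse = ", "),
             " map to residues that are not Ser/Thr donor + Cys acceptor"),
      class = "lanthi_threading_error"
    )
  }
  out <- tibble(
    ring = b$ring,
    donor_pos = b$donor_pos,
    donor_res = donor_res,
    acceptor_pos = b$acceptor_pos,
    acceptor_res = acceptor_res,
    type = ifelse(donor_res == "S", "Lan", "MeLan")
  )
  structure(out, class = c("ring_topology", class(out)),
            template_name = template$name, core = core, offset = offset)
}

# best gapless offset of core against template (max identity over overlap)
.best_offset <- function(core, template_core) {
  offsets <- -3:3
  score <- vapply(offsets, function(o) {
    # template position p maps to core position p + o
    p <- seq_len(nchar(template_core))
    q <- p + o
    keep <- q >= 1 & q <= nchar(core)
    sum(str_split_1(template_core, "")[p[keep]] ==
          str_split_1(core, "")[q[keep]])
  }, numeric(1))
  offsets[which.max(score)]
}

#' Hinge-region residues of a candidate core
#'
#' Returns the residues at the template's hinge positions (20--22 for the
#' nisin A template).
#'
#' @param core Candidate core sequence (length >= last hinge position).
#' @param template Template from [nisin_a_template()].
#' @return A three-character string, e.g. `"TMK"`.
#' @examples
#' hinge_residues("ITSYSLCTPGCKTGALMGCTMKTASCGCHVHISK") # "TMK"
#' @export
hinge_residues <- function(core, template = nisin_a_template()) {
  core <- str_to_upper(core)
  if (nchar(core) < max(template$hinge)) {
    abort("core shorter than the template hinge region",
          class = "lanthi_domain_error")
  }
  paste(str_split_1(core, "")[template$hinge], collapse = "")
}

#' Dehydratable residues not consumed by ring formation
#'
#' Ser/Thr positions outside the threaded bridges can still be dehydrated to
#' dehydroalanine/dehydrobutyrine, but which ones actually are is not decided
#' by threading; they are reported as dehydratable, unassigned.
#'
#' @param topology A `ring_topology` from [thread_template()].
#' @return A tibble with columns `position`, `residue` for each non-ring
#'   Ser/Thr.
#' @export
unassigned_dehydratables <- function(topology) {
  core <- attr(topology, "core")
  chars <- str_split_1(core, "")
  st <- which(chars %in% c("S", "T"))
  free <- setdiff(st, topology$donor_pos)
  tibble(position = free, residue = chars[free])
}

#' @export
print.ring_topology <- function(x, ...) {
  cat("<ring_topology> template: ", attr(x, "template_name"), "\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  ring %s: %-5s %s%d-%s%d\n", x$ring[i], x$type[i],
                x$donor_res[i], x$donor_pos[i],
                x$acceptor_res[i], x$acceptor_pos[i]))
  }
  invisible(x)
}

#' Tidy a threaded ring topology
#'
#' @param x A `ring_topology`.
#' @param ... Unused.
#' @return The underlying bridge tibble with the template name added.
#' @method tidy ring_topology
#' @export
tidy.ring_topology <- function(x, ...) {
  mutate(as_tibble(x), template = attr(x, "template_name"))
}

#' One-line schematic of a ring topology
#'
#' @param topology A `ring_topology`.
#' @return A string such as `"A:Lan(S3-C7) B:MeLan(T8-C11) ..."`.
#' @export
format_topology <- function(topology) {
  paste(sprintf("%s:%s(%s%d-%s%d)", topology$ring, topology$type,
                topology$donor_res, topology$donor_pos,
                topology$acceptor_res, topology$acceptor_pos),
        collapse = " ")
}
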