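# Local in-silico PCR: predict amplicons for a primer pair against one
# or more templates.  Amplicons can be fed back as new design templates
# (iterative redesign).

#' Simulate PCR amplification of a primer pair
#'
#' Scans each template for binding sites of both primers on both
#' strands and reports every product a polymerase could make: a
#' plus-strand site of the forward-acting primer paired with a
#' downstream minus-strand site of the reverse-acting primer, with
#' product length at most `max_product`.  Both orientations are tried
#' (either primer may act as forward) unless `strict_orientation`.
#' When `max_mismatch > 0`, a primer's 3'-terminal base must still
#' match the template exactly (a terminal mismatch blocks extension).
#'
#' Product coordinates: `start` is the forward-acting primer's 5'
#' plus-strand position, `end` the plus-strand position the
#' reverse-acting primer's 5' base anneals to; `length = end - start
#' + 1`.
#'
#' @param fwd,rev primer sequences, both written 5'->3'.
#' @param templates a [dna_seq], plain string, list of either, or a
#'   FASTA path.
#' @param max_mismatch mismatches tolerated per binding site
#'   (default 0).
#' @param max_product maximum product length reported (default 4000).
#' @param strict_orientation only pair `fwd` on the plus strand with
#'   `rev` on the minus strand.
#' @return A data frame of amplicons (`template_id`, `start`, `end`,
#'   `length`, `orientation`, `sequence`), sorted by (template_id,
#'   start, length); zero rows when nothing amplifies.
#' @examples
#' t <- dna_seq(strrep("A", 30))
#' simulate_pcr("AAAAA", "TTTTT", t)[, 1:5]
#' @export
simulate_pcr <- function(fwd, rev, templates, max_mismatch = 0L,
                         max_product = 4000L,
                         strict_orientation = FALSE) {
  stopifnot(max_product > 0)
  templates <- resolve_templates(templates)
  fwd <- seq_string(fwd); rev <- seq_string(rev)
  rows <- list()
  for (t in templates) {
    rows[[length(rows) + 1L]] <-
      pair_sites(fwd, rev, t, max_mismatch, max_product, "forward")
    if (!strict_orientation && !identical(fwd, rev))
      rows[[length(rows) + 1L]] <-
        pair_sites(rev, fwd, t, max_mismatch, max_product, "swapped")
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) return(empty_amplicons())
  out <- out[order(out$template_id, out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

resolve_templates <- function(templates) {
  if (inherits(templates, "dna_seq")) return(list(templates))
  if (is.character(templates) && length(templates) == 1L &&
      file.exists(templates)) return(read_fasta(templates))
  if (is.list(templates)) return(lapply(templates, as_dna_seq))
  list(as_dna_seq(templates))
}

empty_amplicons <- function() {
  data.frame(template_id = character(), start = integer(),
             end = integer(), length = integer(),
             orientation = character(), sequence = character(),
             stringsAsFactors = FALSE)
}

pair_sites <- function(f, r, t, max_mismatch, max_product, orientation) {
  anchor <- max_mismatch > 0L
  fs <- binding_sites(f, t, max_mismatch, anchor_3prime = anchor)
  rs <- binding_sites(r, t, max_mismatch, anchor_3prime = anchor)
  fplus <- fs$start[fs$strand == "+"]
  rminus <- rs$start[rs$strand == "-"]
  if (!length(fplus) || !length(rminus)) return(empty_amplicons())
  rows <- list()
  for (a in fplus) {
    # reverse primer 5' base sits at the right edge of its minus site
    for (b in rminus + nchar(r) - 1L) {
      if (b < a) next
      len <- b - a + 1L
      if (len > max_product) next
      rows[[length(rows) + 1L]] <-
        data.frame(template_id = t$id, start = a, end = b, length = len,
                   orientation = orientation,
                   sequence = substr(t$bases, a, b),
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_amplicons())
  do.call(rbind, rows)
}

#' Turn a predicted amplicon into a new design template
#'
#' The record id encodes the origin template and coordinates
#' (`<template_id>:<start>-<end>`), so iterative redesign on the
#' product keeps track of where it came from.
#'
#' @param a one amplicon: a single row of the [simulate_pcr()] result
#'   (or an equivalent list with `template_id`, `start`, `end`,
#'   `sequence`).
#' @return A [dna_seq] usable as a design template.
#' @export
amplicon_as_template <- function(a) {
  if (is.data.frame(a)) {
    stopifnot(nrow(a) == 1L)
    a <- as.list(a)
  }
  dna_seq(a$sequence,
          id = sprintf("%s:%d-%d", a$template_id, a$start, a$end))
}

#' Parse the coordinates encoded in an amplicon-template id
#'
#' Inverse of the id convention of [amplicon_as_template()].
#'
#' @param id an id of the form `<template_id>:<start>-<end>`.
#' @return A list with `template_id`, `start`, `end`.
#' @export
parse_amplicon_id <- function(id) {
  m <- regmatches(id, regexec("^(.*):([0-9]+)-([0-9]+)$", id))[[1]]
  if (length(m) != 4L)
    stop("not an amplicon-template id: ", id, call. = FALSE)
  list(template_id = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}
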