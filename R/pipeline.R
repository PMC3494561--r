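# Pipeline: single-template design, primer-pair checking, and
# high-throughput batch mode over multi-FASTA input.

#' Structure-marker check of a given primer pair
#'
#' Runs all five secondary-structure markers (cross-dimer, self-dimers,
#' hairpins, GC clamps) and the internal template specificity for a
#' user-supplied pair, without any design step.
#'
#' @param fwd,rev primer sequences, 5'->3'.
#' @param t template (optional; specificity is skipped when absent).
#' @param max_mismatch mismatches allowed in the specificity scan.
#' @return A data frame with one row per marker: `marker`, `value`,
#'   `detail`.
#' @export
check_primers <- function(fwd, rev, t = NULL, max_mismatch = 0L) {
  fwd <- seq_string(fwd); rev <- seq_string(rev)
  cd <- cross_dimer(fwd, rev)
  sf <- self_dimer(fwd); sr <- self_dimer(rev)
  hf <- hairpin(fwd); hr <- hairpin(rev)
  rows <- data.frame(
    marker = c("cross_dimer", "self_dimer_f", "self_dimer_r",
               "hairpin_f", "hairpin_r", "gc_clamp_f", "gc_clamp_r"),
    value = c(cd$best_contiguous_run, sf$best_contiguous_run,
              sr$best_contiguous_run, hf$best_contiguous_run,
              hr$best_contiguous_run, gc_clamp(fwd), gc_clamp(rev)),
    detail = c(sprintf("total %d at offset %d", cd$best_total_matches,
                       cd$offset),
               sprintf("total %d", sf$best_total_matches),
               sprintf("total %d", sr$best_total_matches),
               sprintf("stem1 %d", hf$offset),
               sprintf("stem1 %d", hr$offset),
               "3' terminal G/C", "3' terminal G/C"),
    stringsAsFactors = FALSE)
  if (!is.null(t)) {
    t <- as_dna_seq(t)
    rows <- rbind(rows, data.frame(
      marker = "specific",
      value = as.numeric(is_specific(fwd, rev, t, max_mismatch)),
      detail = sprintf("%d fwd / %d rev site(s) on '%s'",
                       nrow(binding_sites(fwd, t, max_mismatch)),
                       nrow(binding_sites(rev, t, max_mismatch)), t$id),
      stringsAsFactors = FALSE))
  }
  rows
}

#' High-throughput design over many templates
#'
#' Applies [design_primers()] to every record of a multi-FASTA file
#' (or list of templates).  A failure on one template is logged and
#' does not stop the others.
#'
#' @param templates FASTA path, list of [dna_seq], or character vector.
#' @inheritParams design_primers
#' @param out_dir if given, one report file per template plus a
#'   `summary.tsv` are written there.
#' @return A list: `designs` (named list of `primer_design` /
#'   `NULL` on failure) and `summary` (one row per input record:
#'   `template_id`, `status`, `n_pairs`, `best_penalty`).
#' @export
design_batch <- function(templates, constraints = design_constraints(),
                         params = evolution_params(),
                         cond = thermo_conditions(),
                         weights = default_weights(), out_dir = NULL) {
  templates <- resolve_templates(templates)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  designs <- list(); rows <- list()
  for (t in templates) {
    res <- tryCatch(
      design_primers(t, constraints, params, cond, weights),
      error = function(e) e)
    if (inherits(res, "error")) {
      message("design failed for '", t$id, "': ", conditionMessage(res))
      designs[[t$id]] <- NULL
      rows[[t$id]] <- data.frame(template_id = t$id,
                                 status = conditionMessage(res),
                                 n_pairs = 0L, best_penalty = NA_real_,
                                 stringsAsFactors = FALSE)
      next
    }
    designs[[t$id]] <- res
    tab <- res$ranking$table
    rows[[t$id]] <- data.frame(
      template_id = t$id, status = "ok", n_pairs = nrow(tab),
      best_penalty = if (nrow(tab)) tab$penalty[1] else NA_real_,
      stringsAsFactors = FALSE)
    if (!is.null(out_dir))
      report(res, file.path(out_dir, paste0(t$id, "_report.txt")))
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(out_dir))
    write.table(summary, file.path(out_dir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  list(designs = designs, summary = summary)
}

#' Run the full design pipeline
#'
#' The three-step pipeline over one of three input modes:
#' \itemize{
#'   \item single template: design, rank, report, then (optionally)
#'     in-silico PCR of the rank-1 pair and a virtual gel;
#'   \item multi-template (high throughput): [design_batch()] with one
#'     report per record and a summary table;
#'   \item primer-pair mode (`fwd`/`rev` given): skips design and runs
#'     the structure check, in-silico PCR and gel only.
#' }
#'
#' @param templates FASTA path, [dna_seq], or list of them.
#' @param fwd,rev optional primer pair activating check mode.
#' @inheritParams design_primers
#' @param out_dir directory for the report/TSV/gel artifacts.
#' @param do_pcr,do_gel run the in-silico PCR / virtual gel stages.
#' @param gel a [gel_model] for the gel stage.
#' @return A list describing the artifacts written, with a `mode`
#'   field (`"design"`, `"batch"`, or `"check"`).
#' @export
run_pipeline <- function(templates, fwd = NULL, rev = NULL,
                         constraints = design_constraints(),
                         params = evolution_params(),
                         cond = thermo_conditions(),
                         out_dir = tempdir(), do_pcr = TRUE,
                         do_gel = TRUE, gel = gel_model()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tpls <- resolve_templates(templates)
  if (!is.null(fwd) && !is.null(rev)) {
    markers <- check_primers(fwd, rev, tpls[[1]],
                             constraints$specificity_mismatch)
    amp <- if (do_pcr) simulate_pcr(fwd, rev, tpls) else empty_amplicons()
    paths <- list(markers = file.path(out_dir, "markers.tsv"),
                  amplicons = file.path(out_dir, "amplicons.tsv"))
    write.table(markers, paths$markers, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(amp, paths$amplicons, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (do_gel && nrow(amp)) {
      paths$gel <- file.path(out_dir, "gel.txt")
      render_gel(split(amp$length, amp$template_id), gel, paths$gel)
    }
    return(list(mode = "check", markers = markers, amplicons = amp,
                paths = paths))
  }
  if (length(tpls) > 1L) {
    batch <- design_batch(tpls, constraints, params, cond,
                          out_dir = out_dir)
    return(list(mode = "batch", summary = batch$summary,
                designs = batch$designs, paths = list(out_dir = out_dir)))
  }
  t <- tpls[[1]]
  des <- design_primers(t, constraints, params, cond)
  paths <- list(report = file.path(out_dir, paste0(t$id, "_report.txt")))
  report(des, paths$report)
  tab <- des$ranking$table
  amp <- empty_amplicons()
  if (do_pcr && nrow(tab)) {
    amp <- simulate_pcr(tab$f_seq[1], tab$r_seq[1], t)
    paths$amplicons <- file.path(out_dir, "amplicons.tsv")
    write.table(amp, paths$amplicons, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (do_gel && nrow(amp)) {
      paths$gel <- file.path(out_dir, "gel.txt")
      render_gel(list(product = amp$length), gel, paths$gel)
    }
  }
  list(mode = "design", design = des, amplicons = amp, paths = paths)
}
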