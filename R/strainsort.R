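#' Abundance-aware re-assignment of aligned metagenomic reads
#'
#' The main entry point. Takes a SAM/BAM alignment, estimates reference
#' abundances by EM over the score-normalized mapping probabilities, then
#' re-assigns every mapped read to exactly one reference under
#' abundance-derived capacities, using the priority-tiered greedy
#' assignment and the open-up-space swap move. Reads the aligner could
#' not map are reported as `"NO ALIGNMENT"`; reads no reference could
#' accept as `"UNASSIGNED"`.
#'
#' @param input Path to a SAM or BAM file, or a pre-collapsed data.frame
#'   of (`read_id`, `reference_id`, `score`).
#' @param score_tag Integer tag holding the per-alignment score
#'   (default `"AS"`).
#' @param threshold Priority 2/3 second-best/best score-ratio threshold
#'   (default 0.5).
#' @param em [em_settings()] controlling the abundance EM.
#' @param open_space_passes Sweeps of the swap phase (default 1).
#' @param taxonomy Optional taxonomy table ([read_taxonomy()] result or
#'   path) used only to decorate outputs.
#' @param require_score See [read_alignments()].
#' @return An object of class `strainsort` with components `assignment`
#'   (data.frame `read_id`, `reference` over all input reads including
#'   sentinels), `theta` (EM abundances), `active`, `counts`,
#'   `fractions` (assigned-read fractions over mapped reads),
#'   `priorities`, `objective`, `em` (the full [run_em()] fit), `matrix`,
#'   `n_unaligned`, `n_unassigned`, `call`. Methods: `print`, `summary`,
#'   `coef` (abundances), `fitted` (per-read assignment), `logLik`,
#'   `plot`.
#' @export
#' @examples
#' spec <- community_spec(c("strainA", "strainB"), c(0.7, 0.3), 200,
#'                        ambiguity = 0.2, seed = 42)
#' sam <- tempfile(fileext = ".sam")
#' sim <- simulate_alignment(spec, sam)
#' fit <- strainsort(sam)
#' coef(fit)
#' head(fitted(fit))
strainsort <- function(input, score_tag = "AS", threshold = 0.5,
                       em = em_settings(), open_space_passes = 1L,
                       taxonomy = NULL, require_score = TRUE) {
  cl <- match.call()
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  if (is.data.frame(input)) {
    collapsed <- collapse_multimappings(input)
    catalog <- NULL
    unaligned <- character(0)
  } else {
    aln <- read_alignments(input, score_tag = score_tag,
                           require_score = require_score)
    collapsed <- collapse_multimappings(aln$records)
    catalog <- aln$catalog
    unaligned <- aln$unaligned
  }
  mat <- build_mapping_matrix(collapsed)
  classes <- build_equivalence_classes(mat)
  em_fit <- run_em(mat, classes, em)
  re <- reassign_reads(mat, em_fit$theta, threshold = threshold,
                       open_space_passes = open_space_passes)

  all_refs <- if (is.null(catalog)) mat$refs else names(catalog)
  theta <- stats::setNames(rep(0, length(all_refs)), all_refs)
  theta[names(em_fit$theta)] <- em_fit$theta
  counts <- stats::setNames(rep(0L, length(all_refs)), all_refs)
  counts[names(re$counts)] <- re$counts

  assignment <- data.frame(
    read_id = c(mat$reads, unaligned),
    reference = c(unname(re$assignment),
                  rep("NO ALIGNMENT", length(unaligned))),
    stringsAsFactors = FALSE
  )
  assignment <- assignment[order(assignment$read_id), ]
  rownames(assignment) <- NULL

  structure(
    list(assignment = assignment, theta = theta,
         active = theta > 0, counts = counts,
         fractions = counts / length(mat$reads),
         priorities = re$priorities, objective = re$objective,
         em = em_fit, reassignment = re, matrix = mat,
         taxonomy = taxonomy, catalog = catalog,
         n_unaligned = length(unaligned),
         n_unassigned = sum(re$assignment == "UNASSIGNED"),
         settings = list(threshold = threshold, em = em,
                         open_space_passes = open_space_passes,
                         score_tag = score_tag),
         call = cl),
    class = "strainsort"
  )
}

#' @export
print.strainsort <- function(x, ...) {
  cat("Abundance-aware read re-assignment\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  M <- length(x$matrix$reads)
  cat("  reads: ", M, " mapped, ", x$n_unaligned, " unaligned, ",
      x$n_unassigned, " left unassigned\n", sep = "")
  cat("  references: ", sum(x$active), " active of ", length(x$theta),
      "; EM ", x$em$iterations, " iterations",
      if (x$em$converged) " (converged)" else "", "\n", sep = "")
  cat("  objective F = ", format(x$objective, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
coef.strainsort <- function(object, ...) object$theta

#' @export
fitted.strainsort <- function(object, ...) {
  stats::setNames(object$assignment$reference, object$assignment$read_id)
}

#' @export
logLik.strainsort <- function(object, ...) {
  ll <- mapping_loglik(object$em$theta, object$matrix)
  structure(ll, df = sum(object$active) - 1L,
            nobs = length(object$matrix$reads), class = "logLik")
}

#' @export
summary.strainsort <- function(object, ...) {
  tab <- data.frame(
    reference_id = names(object$theta),
    abundance = unname(object$theta),
    assigned_reads = unname(object$counts),
    assigned_fraction = unname(object$fractions),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$abundance, tab$reference_id), ]
  rownames(tab) <- NULL
  structure(list(call = object$call, table = tab,
                 n_mapped = length(object$matrix$reads),
                 n_unaligned = object$n_unaligned,
                 n_unassigned = object$n_unassigned,
                 priorities = table(object$priorities),
                 objective = object$objective,
                 em_iterations = object$em$iterations,
                 converged = object$em$converged),
            class = "summary.strainsort")
}

#' @export
print.summary.strainsort <- function(x, ...) {
  cat("Abundance-aware read re-assignment\n\n")
  cat("Reads: ", x$n_mapped, " mapped (priorities ",
      paste(sprintf("%s: %d", names(x$priorities), x$priorities),
            collapse = ", "),
      "), ", x$n_unaligned, " unaligned, ", x$n_unassigned,
      " unassigned\n", sep = "")
  cat("EM: ", x$em_iterations, " iterations",
      if (x$converged) " (converged)" else "",
      "; objective F = ", format(x$objective, digits = 6), "\n\n",
      sep = "")
  tab <- x$table
  tab$abundance <- round(tab$abundance, 4)
  tab$assigned_fraction <- round(tab$assigned_fraction, 4)
  print(utils::head(tab, 20), row.names = FALSE)
  if (nrow(tab) > 20) cat("... (", nrow(tab) - 20, " more)\n", sep = "")
  invisible(x)
}

#' @export
plot.strainsort <- function(x, ...) {
  act <- x$active | x$counts > 0
  m <- rbind(EM = x$theta[act], assigned = x$fractions[act])
  graphics::barplot(m, beside = TRUE, las = 2,
                    legend.text = c("EM abundance", "assigned fraction"),
                    ylab = "fraction of reads", ...)
  invisible(x)
}

#' Run the full pipeline and write its outputs
#'
#' Command-style wrapper over [strainsort()]: reads the alignment, runs
#' EM and re-assignment, and writes `<prefix>_assignments.tsv`,
#' `<prefix>_abundance.tsv`, a JSON manifest of the configuration, and —
#' when ground truth is supplied — `<prefix>_metrics.tsv`.
#'
#' @param input SAM/BAM path.
#' @param out_prefix Output path prefix.
#' @param truth Optional named vector (or 2-column TSV path) of true
#'   source accessions per read, enabling evaluation.
#' @param taxonomy Optional taxonomy table or TSV path.
#' @inheritParams strainsort
#' @param verbose Log record counts per stage.
#' @return Invisibly, the [strainsort()] fit (with `metrics` attached
#'   when truth was given).
#' @export
run_pipeline <- function(input, out_prefix, threshold = 0.5,
                         em = em_settings(), open_space_passes = 1L,
                         taxonomy = NULL, truth = NULL,
                         score_tag = "AS", verbose = TRUE) {
  say <- function(...) if (verbose) message("[strainsort] ", ...)
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  say("reading ", input)
  fit <- strainsort(input, score_tag = score_tag, threshold = threshold,
                    em = em, open_space_passes = open_space_passes,
                    taxonomy = taxonomy)
  say(length(fit$matrix$reads), " mapped reads, ", fit$n_unaligned,
      " unaligned; ", sum(fit$active), " active references after EM (",
      fit$em$iterations, " iterations)")
  write_assignments(paste0(out_prefix, "_assignments.tsv"),
                    fit$assignment, taxonomy)
  write_abundance_table(paste0(out_prefix, "_abundance.tsv"),
                        fit$theta, fit$counts)
  manifest <- list(
    package = "strainsort",
    version = as.character(utils::packageVersion("strainsort")),
    input = input,
    settings = list(threshold = threshold,
                    em = unclass(em),
                    open_space_passes = open_space_passes,
                    score_tag = score_tag),
    n_mapped = length(fit$matrix$reads),
    n_unaligned = fit$n_unaligned,
    n_unassigned = fit$n_unassigned,
    objective = fit$objective
  )
  jsonlite::write_json(manifest, paste0(out_prefix, "_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(truth)) {
    if (is.character(truth) && length(truth) == 1 && file.exists(truth)) {
      tt <- utils::read.table(truth, sep = "\t", header = TRUE,
                              quote = "", stringsAsFactors = FALSE)
      truth <- stats::setNames(tt[[2]], tt[[1]])
    }
    metrics <- evaluate_assignment(fitted(fit), truth, taxonomy)
    write_metrics(paste0(out_prefix, "_metrics.tsv"), metrics)
    fit$metrics <- metrics
    say("strain-rank F1 = ",
        round(metrics$table$f1[metrics$table$rank == "strain"], 2))
  }
  say("wrote ", out_prefix, "_{assignments,abundance}.tsv")
  invisible(fit)
}
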