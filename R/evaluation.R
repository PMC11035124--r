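#' Read an accession-to-taxonomy table
#'
#' Tab-separated with columns `accession`, `taxid`, `species`, `genus`
#' (header optional when columns are in that order). Two references are
#' the same strain when their accessions are equal, the same species or
#' genus when the respective name fields are equal.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `accession`, `taxid`, `species`,
#'   `genus`.
#' @export
read_taxonomy <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^accession\t", first)
  tx <- utils::read.table(path, sep = "\t", header = has_header,
                          quote = "", stringsAsFactors = FALSE,
                          comment.char = "")
  if (!has_header) {
    names(tx)[1:4] <- c("accession", "taxid", "species", "genus")
  }
  missing <- setdiff(c("accession", "taxid", "species", "genus"), names(tx))
  if (length(missing) > 0) {
    stop("taxonomy table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tx$accession)) {
    stop("duplicate accessions in taxonomy table")
  }
  tx
}

#' Label reads as true/false positives at a taxonomic rank
#'
#' A read is a true positive when the reference it was assigned to agrees
#' with its true source at the requested rank (strain: same accession;
#' species or genus: same name in the taxonomy table), a false positive
#' when they disagree, and unlabeled when the read was left unassigned.
#' Only reads the initial aligner mapped are evaluated, so the metric
#' reflects the re-assignment alone.
#'
#' @param assignment Named character vector read -> assigned accession
#'   (may contain `"UNASSIGNED"`; `"NO ALIGNMENT"` reads are excluded
#'   from evaluation).
#' @param truth Named character vector read -> true source accession.
#' @param taxonomy Taxonomy table from [read_taxonomy()]; only needed for
#'   ranks above strain.
#' @param rank One of `"strain"`, `"species"`, `"genus"`.
#' @return List with `TP`, `FP`, `n_unassigned`, `n_na` (reads whose
#'   accession could not be resolved at the rank) and `M_eval`.
#' @export
label_reads <- function(assignment, truth, taxonomy = NULL,
                        rank = c("strain", "species", "genus")) {
  rank <- match.arg(rank)
  keep <- assignment != "NO ALIGNMENT"
  assignment <- assignment[keep]
  reads <- names(assignment)
  stopifnot(all(reads %in% names(truth)))
  tr <- truth[reads]
  M_eval <- length(reads)
  un <- assignment == "UNASSIGNED"

  resolve <- function(acc) {
    if (rank == "strain") return(acc)
    stopifnot(!is.null(taxonomy))
    taxonomy[[rank]][match(acc, taxonomy$accession)]
  }
  got <- resolve(assignment)
  want <- resolve(tr)
  na <- !un & (is.na(got) | is.na(want))
  tp <- sum(!un & !na & got == want, na.rm = TRUE)
  fp <- sum(!un & !na & got != want, na.rm = TRUE)
  list(TP = tp, FP = fp, n_unassigned = sum(un), n_na = sum(na),
       M_eval = M_eval)
}

#' Sensitivity, precision and F1 from TP/FP counts
#'
#' Sensitivity = TP / M, precision = TP / (TP + FP), F1 their harmonic
#' mean, all on the 0-100 scale. When no read is labeled (TP + FP = 0),
#' precision is reported as 0 with a warning.
#'
#' @param TP,FP True/false positive counts.
#' @param M_eval Number of evaluated reads (aligned reads, including any
#'   left unassigned).
#' @return One-row data.frame: `TP`, `FP`, `sensitivity`, `precision`,
#'   `f1`.
#' @export
compute_metrics <- function(TP, FP, M_eval) {
  stopifnot(M_eval >= 1)
  sens <- 100 * TP / M_eval
  if (TP + FP == 0) {
    warning("no labeled reads; precision reported as 0")
    prec <- 0
  } else {
    prec <- 100 * TP / (TP + FP)
  }
  f1 <- if (sens + prec == 0) 0 else 2 * sens * prec / (sens + prec)
  data.frame(TP = TP, FP = FP, sensitivity = sens, precision = prec,
             f1 = f1)
}

#' L1 error between abundance vectors
#'
#' Sum of absolute differences between an estimated and a true abundance
#' vector; labels present in only one vector count with the full mass
#' they carry.
#'
#' @param estimated,truth Named numeric vectors.
#' @return Non-negative real.
#' @export
l1_error <- function(estimated, truth) {
  labs <- union(names(estimated), names(truth))
  e <- stats::setNames(rep(0, length(labs)), labs)
  t <- e
  e[names(estimated)] <- estimated
  t[names(truth)] <- truth
  sum(abs(e - t))
}

#' Rank-aware evaluation of a read assignment
#'
#' Computes TP/FP, sensitivity, precision and F1 at the strain, species
#' and genus ranks, plus the L1 abundance error between the assigned-read
#' fractions (over all evaluated reads, so unassigned reads dilute every
#' fraction) and the true fractions.
#'
#' @inheritParams label_reads
#' @param taxonomy Taxonomy table (required for species/genus rows).
#' @return A list of class `metrics_report`: `table` (one row per rank)
#'   and `l1`.
#' @export
evaluate_assignment <- function(assignment, truth, taxonomy = NULL) {
  ranks <- if (is.null(taxonomy)) "strain" else
    c("strain", "species", "genus")
  rows <- lapply(ranks, function(rk) {
    lab <- label_reads(assignment, truth, taxonomy, rk)
    cbind(rank = rk, compute_metrics(lab$TP, lab$FP, lab$M_eval),
          unassigned = lab$n_unassigned, na = lab$n_na)
  })
  tab <- do.call(rbind, rows)

  keep <- assignment != "NO ALIGNMENT"
  asg <- assignment[keep]
  tr <- truth[names(asg)]
  M_eval <- length(asg)
  est <- table(asg[asg != "UNASSIGNED"]) / M_eval
  tru <- table(tr) / M_eval
  l1 <- l1_error(
    stats::setNames(as.numeric(est), names(est)),
    stats::setNames(as.numeric(tru), names(tru))
  )
  structure(list(table = tab, l1 = l1), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, 2)
  print(tab, row.names = FALSE)
  cat("l1 abundance error:", format(x$l1, digits = 4), "\n")
  invisible(x)
}

#' Write a metrics report as TSV
#' @param path Output path.
#' @param report A [evaluate_assignment()] result.
#' @return Invisibly, the written data.frame.
#' @export
write_metrics <- function(path, report) {
  tab <- report$table
  tab$l1 <- report$l1
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}
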