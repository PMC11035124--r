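#' Read a SAM/BAM alignment into mapping records
#'
#' Parses a SAM or BAM file into one record per alignment line, keeping the
#' per-alignment score carried in an integer tag (by default `AS`, the
#' aligner's alignment score). Unmapped reads are diverted into a separate
#' set so they can be reported as `"NO ALIGNMENT"` in the final output.
#' Only the (read, reference, score) triple is used downstream; positions,
#' CIGAR strings and sequences are ignored.
#'
#' For paired-end data each mate is treated as an independent read unit:
#' read identifiers of paired records are suffixed `/1` or `/2` according
#' to the first/last-segment FLAG bits.
#'
#' @param path Path to a SAM (text) or BAM (binary) file. A header with
#'   `@SQ` lines is required.
#' @param score_tag Two-letter integer tag holding the mapping score
#'   (default `"AS"`). MAPQ is never used.
#' @param require_score If `TRUE` (default) a mapped record without the
#'   score tag is an error; if `FALSE` such records are skipped and
#'   counted.
#' @return A list with components:
#' \describe{
#'   \item{records}{data.frame with columns `read_id`, `reference_id`,
#'     `score` (integer) and `secondary` (logical), one row per mapped
#'     alignment record carrying a score.}
#'   \item{catalog}{named integer vector of reference lengths from the
#'     `@SQ` header lines (stored for bookkeeping; never used in scoring).}
#'   \item{unaligned}{character vector of read ids with no mapped record.}
#'   \item{n_skipped}{number of mapped records dropped for a missing score
#'     tag (always 0 when `require_score = TRUE`).}
#' }
#' @export
#' @examples
#' sam <- tempfile(fileext = ".sam")
#' writeLines(c(
#'   "@HD\tVN:1.6",
#'   "@SQ\tSN:refA\tLN:1000",
#'   "r1\t0\trefA\t1\t60\t100M\t*\t0\t0\t*\t*\tAS:i:100",
#'   "r2\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), sam)
#' aln <- read_alignments(sam)
#' aln$records
#' aln$unaligned
read_alignments <- function(path, score_tag = "AS", require_score = TRUE) {
  if (!file.exists(path)) {
    stop("alignment file not found: ", path)
  }
  bam <- .as_bam(path)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  catalog <- hdr$targets
  if (is.null(catalog) || length(catalog) == 0L) {
    stop("alignment header has no @SQ reference lines: ", path)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname"),
    tag = score_tag
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- x$flag
  qname <- x$qname
  # mate suffix for paired records (FLAG 0x1 set, 0x40/0x80 = first/last)
  paired <- bitwAnd(flag, 0x1L) != 0L
  if (any(paired)) {
    mate <- ifelse(bitwAnd(flag, 0x80L) != 0L, "/2", "/1")
    qname[paired] <- paste0(qname[paired], mate[paired])
  }
  unmapped <- bitwAnd(flag, 0x4L) != 0L
  score <- x$tag[[score_tag]]
  if (is.null(score)) score <- rep(NA_integer_, length(flag))

  mapped_idx <- which(!unmapped)
  no_score <- mapped_idx[is.na(score[mapped_idx])]
  n_skipped <- 0L
  if (length(no_score) > 0L) {
    if (require_score) {
      stop(length(no_score), " mapped record(s) lack the ", score_tag,
           ":i score tag (first read: ", qname[no_score[1]], ")")
    }
    warning(length(no_score), " mapped record(s) without ", score_tag,
            ":i tag were skipped")
    n_skipped <- length(no_score)
    mapped_idx <- setdiff(mapped_idx, no_score)
  }

  records <- data.frame(
    read_id = qname[mapped_idx],
    reference_id = as.character(x$rname[mapped_idx]),
    score = as.integer(score[mapped_idx]),
    secondary = bitwAnd(flag[mapped_idx], 0x100L) != 0L,
    stringsAsFactors = FALSE
  )
  bad_ref <- !(records$reference_id %in% names(catalog))
  if (any(bad_ref)) {
    stop("mapped record references a sequence absent from the header: ",
         records$reference_id[which(bad_ref)[1]])
  }
  unaligned <- setdiff(unique(qname[unmapped]), unique(records$read_id))
  list(records = records, catalog = catalog,
       unaligned = unaligned, n_skipped = n_skipped)
}

# Convert SAM text to a temporary BAM so a single scanBam path serves both
# formats; BAM input is used as-is.
.as_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    return(path)
  }
  dest <- tempfile(fileext = "")
  tryCatch(
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE),
    error = function(e) {
      stop("failed to parse SAM (is the @SQ header present?): ",
           conditionMessage(e))
    }
  )
}

#' Collapse multi-mappings to one score per (read, reference) pair
#'
#' A read may align to the same reference several times (secondary or
#' supplementary alignments); only the best score per (read, reference)
#' pair is kept, with secondary alignments on equal footing with primaries.
#' If any retained score is non-positive, a global affine shift
#' `s' = s - min(s) + 1` is applied so every score is at least 1 while the
#' ordering is preserved; the shift is reported via a message and stored
#' in the `"score_shift"` attribute.
#'
#' @param records data.frame of mapped records as produced by
#'   [read_alignments()] (`read_id`, `reference_id`, `score`).
#' @return A data.frame with columns `read_id`, `reference_id`, `score`
#'   (one row per pair, the maximum observed score), carrying attribute
#'   `score_shift` (0 when no shift was needed).
#' @export
collapse_multimappings <- function(records) {
  stopifnot(all(c("read_id", "reference_id", "score") %in% names(records)))
  if (nrow(records) == 0L) {
    out <- records[, c("read_id", "reference_id", "score")]
    attr(out, "score_shift") <- 0
    return(out)
  }
  key <- paste(records$read_id, records$reference_id, sep = "\r")
  mx <- tapply(records$score, key, max)
  parts <- strsplit(names(mx), "\r", fixed = TRUE)
  out <- data.frame(
    read_id = vapply(parts, `[[`, "", 1L),
    reference_id = vapply(parts, `[[`, "", 2L),
    score = as.numeric(mx),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$read_id, -out$score, out$reference_id), ]
  rownames(out) <- NULL
  shift <- 0
  if (min(out$score) <= 0) {
    shift <- 1 - min(out$score)
    out$score <- out$score + shift
    message("non-positive mapping scores: applied affine shift of +", shift)
  }
  attr(out, "score_shift") <- shift
  out
}

#' Write the per-read assignment table
#'
#' One tab-separated row per read template: the read id and the reference
#' it was assigned to, or the sentinel `"NO ALIGNMENT"` (read had no mapped
#' record) or `"UNASSIGNED"` (no reference could accept it). When a
#' taxonomy table is supplied, `taxid`, `species` and `genus` columns are
#' appended; accessions missing from the table are rendered `NA`.
#'
#' @param path Output file path.
#' @param assignments data.frame with columns `read_id` and `reference`
#'   (sentinels included), or a named character vector.
#' @param taxonomy Optional taxonomy table from [read_taxonomy()].
#' @return Invisibly, the written data.frame.
#' @export
write_assignments <- function(path, assignments, taxonomy = NULL) {
  if (!is.data.frame(assignments)) {
    assignments <- data.frame(
      read_id = names(assignments),
      reference = unname(assignments),
      stringsAsFactors = FALSE
    )
  }
  out <- assignments[, c("read_id", "reference")]
  if (!is.null(taxonomy)) {
    i <- match(out$reference, taxonomy$accession)
    out$taxid <- taxonomy$taxid[i]
    out$species <- taxonomy$species[i]
    out$genus <- taxonomy$genus[i]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(out)
}

#' Read back an assignment table written by [write_assignments()]
#' @param path Path to the TSV file.
#' @return data.frame with at least `read_id` and `reference` columns.
#' @export
read_assignments <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, colClasses = NA,
                    comment.char = "")
}

#' Write the reference abundance table
#'
#' One row per reference: the EM abundance estimate, the number of reads
#' finally assigned to it, and the assigned-read fraction. References that
#' were deactivated by the set-cover filter (or received no reads) appear
#' with abundance and count 0.
#'
#' @param path Output file path.
#' @param theta Named abundance vector (must sum to 1 over its non-zero
#'   entries within 1e-9).
#' @param counts Named integer vector of final assigned-read counts; names
#'   not in `theta` are allowed and vice versa (missing entries are 0).
#' @return Invisibly, the written data.frame.
#' @export
write_abundance_table <- function(path, theta, counts) {
  stopifnot(abs(sum(theta) - 1) < 1e-9 || sum(theta) == 0)
  refs <- union(names(theta), names(counts))
  refs <- sort(refs)
  ab <- ifelse(refs %in% names(theta), theta[refs], 0)
  ct <- ifelse(refs %in% names(counts), counts[refs], 0)
  ct[is.na(ct)] <- 0
  total <- sum(ct)
  out <- data.frame(
    reference_id = refs,
    abundance = unname(ab),
    assigned_reads = as.integer(unname(ct)),
    assigned_fraction = if (total > 0) unname(ct) / total else 0,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(out)
}
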