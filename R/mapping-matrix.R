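#' Build the sparse read-by-reference mapping matrix
#'
#' Central data structure of the method: for read \eqn{r_i} with mapping
#' score \eqn{s_{ij}} against reference \eqn{R_j}, the total score is
#' \eqn{T(r_i) = \sum_j s_{ij}} and the origin probability is the
#' score-normalized \eqn{p_{ij} = s_{ij} / T(r_i)}, so each read's
#' probabilities sum to exactly 1. No reference-length or positional term
#' enters the model.
#'
#' @param collapsed data.frame with columns `read_id`, `reference_id`,
#'   `score` holding one positive score per (read, reference) pair, as
#'   produced by [collapse_multimappings()].
#' @return An object of class `mapping_matrix`: a list with
#' \describe{
#'   \item{reads}{character vector of read ids (row identities).}
#'   \item{refs}{character vector of reference ids, lexicographically
#'     sorted (column identities).}
#'   \item{scores, probs}{sparse `dgCMatrix` of \eqn{s_{ij}} and
#'     \eqn{p_{ij}}.}
#'   \item{totals}{numeric vector \eqn{T(r_i)}.}
#'   \item{edges}{data.frame (`read`, `ref`, `score`, `p` with integer
#'     read/ref indices) sorted by read, then score descending, then
#'     reference id ascending — the per-read mapping lists in flat form.}
#' }
#' @export
build_mapping_matrix <- function(collapsed) {
  stopifnot(nrow(collapsed) > 0L)
  if (any(collapsed$score <= 0)) {
    stop("mapping scores must be positive; apply collapse_multimappings() first")
  }
  key <- paste(collapsed$read_id, collapsed$reference_id)
  if (anyDuplicated(key)) {
    stop("duplicate (read, reference) pairs; collapse multi-mappings first")
  }
  reads <- sort(unique(collapsed$read_id))
  refs <- sort(unique(collapsed$reference_id))
  i <- match(collapsed$read_id, reads)
  j <- match(collapsed$reference_id, refs)
  scores <- Matrix::sparseMatrix(
    i = i, j = j, x = as.numeric(collapsed$score),
    dims = c(length(reads), length(refs)),
    dimnames = list(reads, refs)
  )
  totals <- Matrix::rowSums(scores)
  if (any(totals <= 0)) {
    stop("read with empty mapping set: ", reads[which(totals <= 0)[1]])
  }
  probs <- Matrix::Diagonal(x = 1 / totals) %*% scores
  probs <- methods::as(probs, "CsparseMatrix")
  dimnames(probs) <- dimnames(scores)

  edges <- data.frame(read = i, ref = j,
                      score = as.numeric(collapsed$score))
  edges$p <- edges$score / totals[edges$read]
  ord <- order(edges$read, -edges$score, refs[edges$ref])
  edges <- edges[ord, ]
  rownames(edges) <- NULL

  structure(
    list(reads = reads, refs = refs, scores = scores, probs = probs,
         totals = totals, edges = edges,
         score_shift = attr(collapsed, "score_shift") %||% 0),
    class = "mapping_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mapping_matrix <- function(x, ...) {
  cat("mapping_matrix:", length(x$reads), "reads x", length(x$refs),
      "references,", nrow(x$edges), "mappings\n")
  invisible(x)
}

#' Per-read mapping lists, sorted by score
#'
#' Returns, for every read, its candidate references ordered by mapping
#' score (non-increasing), ties broken by reference id ascending — the
#' list \eqn{M(r)} the re-assignment algorithm walks.
#'
#' @param matrix A [build_mapping_matrix()] object.
#' @return Named list (by read id); each element a data.frame with columns
#'   `ref` (reference id), `score`, `p`.
#' @export
sorted_mapping_lists <- function(matrix) {
  e <- matrix$edges
  out <- split(
    data.frame(ref = matrix$refs[e$ref], score = e$score, p = e$p,
               stringsAsFactors = FALSE),
    factor(e$read, levels = seq_along(matrix$reads))
  )
  names(out) <- matrix$reads
  out
}

#' Reduce reads to equivalence classes for EM
#'
#' Reads are grouped into classes of interchangeable reads: two reads fall
#' in the same class when they map to the same set of references with the
#' same score profile. Classes are the sufficient statistic of the EM —
#' running EM on class weight sums reproduces the read-level update
#' exactly — and shrink the per-iteration work from the number of reads to
#' the number of distinct mapping profiles. (Grouping on the reference set
#' alone, ignoring scores, would only approximate the read-level EM; see
#' the package vignette.)
#'
#' @param matrix A [build_mapping_matrix()] object.
#' @return An object of class `equivalence_classes`: list with
#' \describe{
#'   \item{W}{sparse class-by-reference matrix of weight sums
#'     \eqn{w_{cj} = \sum_{i \in c} p_{ij}}.}
#'   \item{sizes}{integer member counts per class.}
#'   \item{members}{list of member read indices per class.}
#'   \item{ref_sets}{list of reference index vectors per class.}
#' }
#' @export
build_equivalence_classes <- function(matrix) {
  e <- matrix$edges
  # edges are sorted by read then (score desc, ref asc), so the profile
  # string is canonical per read
  prof <- vapply(
    split(paste(e$ref, e$score, sep = ":"),
          factor(e$read, levels = seq_along(matrix$reads))),
    paste, "", collapse = ";"
  )
  cls <- match(prof, unique(prof))
  n_class <- max(cls)
  members <- split(seq_along(matrix$reads), cls)
  rep_read <- vapply(members, `[[`, 0L, 1L)

  first_edges <- e[e$read %in% rep_read, ]
  ci <- cls[first_edges$read]
  sizes <- vapply(members, length, 0L)
  W <- Matrix::sparseMatrix(
    i = ci, j = first_edges$ref,
    x = first_edges$p * sizes[ci],
    dims = c(n_class, length(matrix$refs)),
    dimnames = list(NULL, matrix$refs)
  )
  structure(
    list(W = W, sizes = sizes, members = members,
         ref_sets = lapply(split(first_edges$ref, ci), sort)),
    class = "equivalence_classes"
  )
}

#' @export
print.equivalence_classes <- function(x, ...) {
  cat("equivalence_classes:", length(x$sizes), "classes over",
      sum(x$sizes), "reads\n")
  invisible(x)
}
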