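#' Tiny assignment instance
#'
#' A dense read-by-reference instance small enough for exhaustive
#' minimization of the assignment objective; used as the correctness
#' oracle for the greedy solver. Bounds: at most 8 reads, 4 references.
#'
#' @param p Dense numeric matrix of origin probabilities (0 where the read
#'   does not map); each row must sum to 1 over its mapped references.
#' @param copies Integer vector of per-reference copy counts \eqn{c_j}.
#' @param scores Optional dense score matrix consistent with `p` (needed
#'   to run the production greedy on the instance); when omitted, `p`
#'   itself is used as the score.
#' @param a Optional abundance vector the copies derive from.
#' @return A list of class `tiny_instance`.
#' @export
tiny_instance <- function(p, copies, scores = NULL, a = NULL) {
  p <- as.matrix(p)
  if (nrow(p) > 8L || ncol(p) > 4L) {
    stop("tiny_instance bounds exceeded (max 8 reads, 4 references)")
  }
  rs <- rowSums(p)
  stopifnot(all(abs(rs - 1) < 1e-9), length(copies) == ncol(p))
  if (is.null(scores)) scores <- p
  if (is.null(rownames(p))) rownames(p) <- sprintf("r%02d", seq_len(nrow(p)))
  if (is.null(colnames(p))) colnames(p) <- sprintf("R%d", seq_len(ncol(p)))
  dimnames(scores) <- dimnames(p)
  structure(list(p = p, copies = as.integer(copies), scores = scores,
                 a = a), class = "tiny_instance")
}

# Optimal value of distributing reads with survival factors q = 1 - p
# across `copies` identical copies of one reference (empty copy = 1).
# Exhaustive search over set partitions into at most `copies` groups with
# symmetry breaking (an item may only start group max_used + 1).
.opt_ref_value <- function(q, copies) {
  if (copies == 0L) return(0)
  m <- length(q)
  if (m == 0L) return(copies)
  best <- Inf
  grp <- integer(m)
  recurse <- function(idx, max_used) {
    if (idx > m) {
      prods <- vapply(seq_len(max_used), function(g) prod(q[grp == g]), 0)
      val <- sum(prods) + (copies - max_used)
      if (val < best) best <<- val
      return(invisible(NULL))
    }
    for (g in seq_len(min(max_used + 1L, copies))) {
      grp[idx] <<- g
      recurse(idx + 1L, max(max_used, g))
    }
  }
  recurse(1L, 0L)
  best
}

#' Exact minimum of the assignment objective on a tiny instance
#'
#' Exhaustively minimizes
#' \eqn{F = \sum_j \sum_{k=1}^{c_j} \prod_i (1-p_{ij})^{x_{i,(j,k)}}}
#' subject to each read being assigned to at most one reference copy
#' (leaving a read unassigned is always allowed; several reads may share
#' a copy, which the optimal within-reference split decides). Every
#' read-to-(reference or unassigned) map is enumerated; for each
#' reference the assigned set is split optimally across its copies.
#'
#' @param instance A [tiny_instance()].
#' @return A list with `min_F` (the minimum objective) and `placement`
#'   (integer vector per read: a reference index or 0 for unassigned; the
#'   lexicographically first argmin).
#' @export
brute_force_min <- function(instance) {
  p <- instance$p
  copies <- instance$copies
  m <- nrow(p)
  n <- ncol(p)
  # choices per read: 0 (unassigned) or a mapped reference
  choice_list <- lapply(seq_len(m), function(i) c(0L, which(p[i, ] > 0)))
  grid <- as.matrix(expand.grid(rev(choice_list), KEEP.OUT.ATTRS = FALSE))
  grid <- grid[, rev(seq_len(m)), drop = FALSE]  # lexicographic in read order
  # order rows lexicographically (read 1 varies slowest)
  ordargs <- lapply(seq_len(m), function(i) grid[, i])
  grid <- grid[do.call(order, ordargs), , drop = FALSE]

  pow2 <- bitwShiftL(1L, seq_len(m) - 1L)
  total <- numeric(nrow(grid))
  for (j in seq_len(n)) {
    sid <- as.integer((grid == j) %*% pow2)
    # optimal within-reference split, memoized over occurring subsets
    vals <- numeric(2^m)
    for (s in unique(sid)) {
      idx <- which(bitwAnd(s, pow2) != 0L)
      vals[s + 1] <- .opt_ref_value(1 - p[idx, j], copies[j])
    }
    total <- total + vals[sid + 1]
  }
  r <- which.min(total)   # grid is in lexicographic order: first argmin
  list(min_F = total[r], placement = unname(grid[r, ]))
}

#' Literal per-copy evaluation of the assignment objective
#'
#' Evaluates \eqn{F} exactly as written — a sum over references, copies
#' and reads of \eqn{(1-p_{ij})^{x_{i,(j,k)}}} — given an explicit
#' per-copy assignment. This is the independent evaluator the faster
#' [objective_value()] is checked against.
#'
#' @param x_copy Integer matrix, reads by 2: columns `ref` and `copy`
#'   (0 = unassigned).
#' @param p Dense probability matrix.
#' @param copies Per-reference copy counts.
#' @return The objective value.
#' @export
eval_objective_percopy <- function(x_copy, p, copies) {
  total <- 0
  for (j in seq_len(ncol(p))) {
    for (k in seq_len(copies[j])) {
      term <- 1
      for (i in seq_len(nrow(p))) {
        xijk <- as.integer(x_copy[i, 1] == j && x_copy[i, 2] == k)
        term <- term * (1 - p[i, j])^xijk
      }
      total <- total + term
    }
  }
  total
}

#' Per-copy layout of an assignment state
#'
#' Expands a read-to-reference placement into the per-copy layout the
#' production objective uses: within each reference, reads occupy copies
#' one per copy in score order (ties by read id), any over-assigned reads
#' sharing the last copy. Reads placed in a reference with zero copies
#' get copy 0 (they contribute nothing).
#'
#' @param state An assignment state (see [reassign_reads()]).
#' @param matrix The mapping matrix.
#' @return Integer matrix, reads by 2 (`ref`, `copy`).
#' @export
state_copy_layout <- function(state, matrix) {
  out <- matrix(0L, nrow = length(matrix$reads), ncol = 2,
                dimnames = list(matrix$reads, c("ref", "copy")))
  for (j in seq_along(state$refs)) {
    ms <- state$members[[j]]
    if (length(ms) == 0L) next
    s <- matrix$scores[ms, j]
    ms <- ms[order(-s, matrix$reads[ms])]
    cj <- state$copies[j]
    for (k in seq_along(ms)) {
      out[ms[k], 1] <- j
      out[ms[k], 2] <- if (cj == 0L) 0L else min(k, cj)
    }
  }
  out
}

#' Run the production greedy solver on a tiny instance
#'
#' Convenience bridge: builds a [build_mapping_matrix()] from the
#' instance scores and runs [reassign_reads()] with abundances matching
#' the instance's copy counts, so greedy and oracle answers are directly
#' comparable.
#'
#' @param instance A [tiny_instance()]; its `a` slot (abundances) must be
#'   set (copy counts alone do not determine capacities).
#' @param ... Passed to [reassign_reads()].
#' @return The [reassign_reads()] result.
#' @export
greedy_on_instance <- function(instance, ...) {
  stopifnot(!is.null(instance$a))
  sc <- instance$scores
  idx <- which(sc > 0, arr.ind = TRUE)
  collapsed <- data.frame(
    read_id = rownames(sc)[idx[, 1]],
    reference_id = colnames(sc)[idx[, 2]],
    score = sc[idx],
    stringsAsFactors = FALSE
  )
  attr(collapsed, "score_shift") <- 0
  mat <- build_mapping_matrix(collapsed)
  theta <- instance$a
  names(theta) <- colnames(sc)
  out <- reassign_reads(mat, theta[mat$refs], ...)
  out$matrix <- mat
  out
}
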