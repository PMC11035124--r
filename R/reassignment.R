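#' Abundance-derived reference capacities
#'
#' Each reference is treated as a bin: with estimated abundance
#' \eqn{a_j} and \eqn{M} mapped reads, its capacity is
#' \eqn{C_j = a_j + 1/M} (as each read occupies \eqn{1/M} of a bin, the
#' algorithm over-assigns at most one read per reference), and it
#' contributes \eqn{c_j = \mathrm{round}(a_j M)} integer copies to the
#' assignment objective. A bin is full when \eqn{(n+1)/M \ge C_j}, i.e.
#' when \eqn{n \ge a_j M}; a reference with \eqn{a_j = 0} accepts no reads.
#'
#' @param theta Named abundance vector \eqn{a_j}.
#' @param M Total number of mapped reads.
#' @return A list of class `reference_bins` with `refs`, `a`, `capacity`
#'   (\eqn{C_j}), and `copies` (\eqn{c_j}, rounded half away from zero).
#' @export
compute_capacities <- function(theta, M) {
  stopifnot(M >= 1)
  a <- as.numeric(theta)
  refs <- names(theta)
  cj <- sign(a * M) * floor(abs(a * M) + 0.5)  # round half away from zero
  structure(
    list(refs = refs, a = a, capacity = a + 1 / M,
         copies = as.integer(cj), M = as.integer(M)),
    class = "reference_bins"
  )
}

# Initial (empty) assignment state over the bins of a mapping matrix.
new_assignment_state <- function(matrix, theta) {
  theta <- .align_theta(theta, matrix$refs)
  names(theta) <- matrix$refs
  bins <- compute_capacities(theta, length(matrix$reads))
  list(
    M = length(matrix$reads),
    refs = matrix$refs,
    a = bins$a,
    capacity = bins$capacity,
    copies = bins$copies,
    n = integer(length(matrix$refs)),
    members = rep(list(integer(0)), length(matrix$refs)),
    placed = rep(NA_integer_, length(matrix$reads)),
    unassigned = integer(0)
  )
}

.bin_full <- function(state, j) {
  state$n[j] >= state$a[j] * state$M - 1e-9
}

#' Assignment objective F(x)
#'
#' The quantity the greedy re-assignment minimizes: each reference
#' \eqn{R_j} contributes \eqn{c_j} single-read copies, and
#' \eqn{F = \sum_j \sum_{k=1}^{c_j} \prod_i (1 - p_{ij})^{x_{i,(j,k)}}}.
#' An empty copy contributes 1, so leaving a read unassigned and assigning
#' it to a hopeless reference cost the same; over-assigning never lowers
#' F. Reads in a bin fill copies one per copy in score order, any
#' over-assigned reads sharing the last copy.
#'
#' @param state An assignment state as produced by the greedy stages of
#'   [reassign_reads()].
#' @param matrix The [build_mapping_matrix()] object.
#' @return The objective value (a non-negative real).
#' @export
objective_value <- function(state, matrix) {
  total <- 0
  for (j in seq_along(state$refs)) {
    cj <- state$copies[j]
    if (cj == 0L) next
    ms <- state$members[[j]]
    if (length(ms) == 0L) {
      total <- total + cj
      next
    }
    s <- matrix$scores[ms, j]
    ord <- order(-s, matrix$reads[ms])
    q <- 1 - matrix$probs[ms, j][ord]
    n <- length(q)
    if (n <= cj) {
      total <- total + (cj - n) + sum(q)
    } else {
      total <- total + sum(q[seq_len(cj - 1L)]) + prod(q[cj:n])
    }
  }
  total
}

#' Read priority tiers
#'
#' Reads are assigned in three tiers: priority 1 reads map to a single
#' reference; priority 2 reads have a second-best/best score ratio below
#' `threshold` (default 0.5), i.e. a clearly best reference; all remaining
#' reads are priority 3. Ratios use the raw (post-shift) scores.
#'
#' @param matrix A [build_mapping_matrix()] object.
#' @param threshold Ratio threshold separating priority 2 from 3.
#' @return Named integer vector (1, 2 or 3) over reads.
#' @export
assign_priorities <- function(matrix, threshold = 0.5) {
  e <- matrix$edges
  first <- !duplicated(e$read)            # edges sorted: best score first
  best <- e$score[first][order(e$read[first])]
  n_map <- tabulate(e$read, nbins = length(matrix$reads))
  second <- rep(NA_real_, length(matrix$reads))
  e2 <- e[!first, ]
  f2 <- !duplicated(e2$read)
  second[e2$read[f2]] <- e2$score[f2]
  pri <- ifelse(n_map == 1L, 1L,
                ifelse(second / best < threshold, 2L, 3L))
  names(pri) <- matrix$reads
  pri
}

#' Greedy capacity-constrained assignment
#'
#' First pass of the re-assignment: priority 1 reads go to their unique
#' reference unconditionally; priority 2 reads, in order of best score,
#' go to their best reference if it has space (else they are relabeled
#' priority 3); then all (priority 3 read, reference-with-space) mappings
#' are pooled, sorted by score, and walked in order, placing each
#' still-unplaced read into the mapping's reference if space remains.
#' Reads left over become the input of [open_space_phase()].
#'
#' @param state State from `new_assignment_state` (internal) or as
#'   returned by a previous stage.
#' @param priorities Vector from [assign_priorities()].
#' @param matrix The mapping matrix.
#' @return Updated state; `state$unassigned` holds the leftover reads.
#' @export
greedy_assign <- function(state, priorities, matrix) {
  e <- matrix$edges
  reads <- matrix$reads
  first_edge <- which(!duplicated(e$read))
  best_ref <- integer(length(reads))
  best_score <- numeric(length(reads))
  best_ref[e$read[first_edge]] <- e$ref[first_edge]
  best_score[e$read[first_edge]] <- e$score[first_edge]

  place <- function(state, i, j) {
    state$placed[i] <- j
    state$n[j] <- state$n[j] + 1L
    state$members[[j]] <- c(state$members[[j]], i)
    state
  }

  pri <- as.integer(priorities)

  # priority 1: unconditional (their unique reference is the only option)
  for (i in which(pri == 1L)) {
    state <- place(state, i, best_ref[i])
  }

  # priority 2: best score descending, read id ascending
  p2 <- which(pri == 2L)
  p2 <- p2[order(-best_score[p2], reads[p2])]
  for (i in p2) {
    j <- best_ref[i]
    if (!.bin_full(state, j)) {
      state <- place(state, i, j)
    } else {
      pri[i] <- 3L
    }
  }

  # priority 3: pool mappings to references that still have space,
  # sorted by score descending (ties: read id, then reference id)
  p3 <- which(pri == 3L)
  if (length(p3) > 0L) {
    has_space <- !vapply(seq_along(state$refs), function(j)
      .bin_full(state, j), logical(1))
    pool <- e[e$read %in% p3 & has_space[e$ref], ]
    pool <- pool[order(-pool$score, reads[pool$read],
                       state$refs[pool$ref]), ]
    for (r in seq_len(nrow(pool))) {
      i <- pool$read[r]
      if (!is.na(state$placed[i])) next
      j <- pool$ref[r]
      if (!.bin_full(state, j)) {
        state <- place(state, i, j)
      }
    }
    state$unassigned <- p3[is.na(state$placed[p3])]
  }
  state
}

#' Can a full reference open up space for a read?
#'
#' A full reference \eqn{R_j} can open up space for read \eqn{r_i} when
#' some occupant \eqn{r_k} can be moved to another, non-full reference
#' \eqn{R_l} in its mapping list such that
#' \eqn{p_{ij} - p_{kj} \ge p_{kj} - p_{kl}}: the incoming read gains at
#' least as much probability as the evicted read loses, which guarantees
#' the objective does not increase. Occupants are scanned from the most
#' ambiguously assigned (lowest score) upward; the destination maximizing
#' \eqn{p_{kl}} over non-full references is tried for each.
#'
#' @param state Current assignment state.
#' @param i Read index (must map to `j`).
#' @param j Reference index (must be full).
#' @param matrix The mapping matrix.
#' @return `NULL`, or a list `(victim, dest)` of indices for the first
#'   occupant/destination pair satisfying the condition.
#' @export
can_open_space <- function(state, i, j, matrix) {
  ms <- state$members[[j]]
  if (length(ms) == 0L) return(NULL)
  p_ij <- matrix$probs[i, j]
  s <- matrix$scores[ms, j]
  ord <- order(s, matrix$reads[ms])     # lowest score first
  e <- matrix$edges
  for (k in ms[ord]) {
    p_kj <- matrix$probs[k, j]
    cand <- e[e$read == k & e$ref != j, ]
    if (nrow(cand) == 0L) next
    open <- !vapply(cand$ref, function(l) .bin_full(state, l), logical(1))
    cand <- cand[open, ]
    if (nrow(cand) == 0L) next
    cand <- cand[order(-cand$p, state$refs[cand$ref]), ]
    l <- cand$ref[1]
    p_kl <- cand$p[1]
    if (p_ij - p_kj >= p_kj - p_kl) {
      return(list(victim = k, dest = l))
    }
  }
  NULL
}

#' Open-up-space phase for leftover reads
#'
#' For each read left unassigned by [greedy_assign()] (processed best
#' score descending, then read id), its candidate references are tried in
#' mapping-list order; the first that [can_open_space()] for it has the
#' victim moved to its destination and the read placed. Reads for which
#' no reference can open space remain unassigned and are reported as
#' `"UNASSIGNED"`. Each executed swap strictly never increases the
#' objective.
#'
#' @param state State after [greedy_assign()].
#' @param matrix The mapping matrix.
#' @param passes Number of sweeps over the unassigned set (default 1).
#' @param trace_objective If `TRUE`, record the objective before and after
#'   every executed swap in the returned `swaps` attribute (costly on
#'   large inputs; meant for verification).
#' @return Updated state, with attribute `"swaps"`: a data.frame of
#'   executed swaps (read, ref, victim, dest and, when traced, F_before /
#'   F_after).
#' @export
open_space_phase <- function(state, matrix, passes = 1L,
                             trace_objective = FALSE) {
  e <- matrix$edges
  reads <- matrix$reads
  swaps <- list()
  for (pass in seq_len(passes)) {
    un <- state$unassigned
    if (length(un) == 0L) break
    first_edge <- which(!duplicated(e$read))
    bs <- numeric(length(reads))
    bs[e$read[first_edge]] <- e$score[first_edge]
    un <- un[order(-bs[un], reads[un])]
    for (i in un) {
      my <- e[e$read == i, ]            # already in mapping-list order
      for (r in seq_len(nrow(my))) {
        j <- my$ref[r]
        if (!.bin_full(state, j)) {
          # defensive: space appeared without a swap
          state$placed[i] <- j
          state$n[j] <- state$n[j] + 1L
          state$members[[j]] <- c(state$members[[j]], i)
          state$unassigned <- setdiff(state$unassigned, i)
          break
        }
        sw <- can_open_space(state, i, j, matrix)
        if (!is.null(sw)) {
          f_before <- if (trace_objective)
            objective_value(state, matrix) else NA_real_
          k <- sw$victim; l <- sw$dest
          state$members[[j]] <- setdiff(state$members[[j]], k)
          state$members[[l]] <- c(state$members[[l]], k)
          state$n[l] <- state$n[l] + 1L
          state$placed[k] <- l
          state$members[[j]] <- c(state$members[[j]], i)
          state$placed[i] <- j
          state$unassigned <- setdiff(state$unassigned, i)
          f_after <- if (trace_objective)
            objective_value(state, matrix) else NA_real_
          swaps[[length(swaps) + 1L]] <- data.frame(
            read = i, ref = j, victim = k, dest = l,
            F_before = f_before, F_after = f_after
          )
          break
        }
      }
    }
  }
  attr(state, "swaps") <- if (length(swaps) > 0)
    do.call(rbind, swaps)
  else
    data.frame(read = integer(0), ref = integer(0), victim = integer(0),
               dest = integer(0), F_before = numeric(0),
               F_after = numeric(0))
  state
}

#' Re-assign reads under abundance-derived capacities
#'
#' The full re-assignment: capacities from the abundance estimate,
#' priority labelling, greedy assignment, then the open-up-space swap
#' phase. Deterministic for identical inputs.
#'
#' @param matrix A [build_mapping_matrix()] object.
#' @param theta Abundance vector (typically `run_em(...)$theta`).
#' @param threshold Priority 2/3 score-ratio threshold (default 0.5).
#' @param open_space_passes Sweeps of the swap phase (default 1).
#' @param trace_objective Record the objective around each swap (see
#'   [open_space_phase()]).
#' @return A list of class `reassignment`:
#' \describe{
#'   \item{assignment}{named character vector read -> reference id, with
#'     `"UNASSIGNED"` for reads no reference could take.}
#'   \item{counts}{named integer vector of assigned reads per reference.}
#'   \item{priorities}{the priority labels used.}
#'   \item{objective}{final objective value F.}
#'   \item{state}{the final assignment state.}
#'   \item{swaps}{data.frame of executed open-space swaps.}
#' }
#' @export
reassign_reads <- function(matrix, theta, threshold = 0.5,
                           open_space_passes = 1L,
                           trace_objective = FALSE) {
  state <- new_assignment_state(matrix, theta)
  pri <- assign_priorities(matrix, threshold)
  state <- greedy_assign(state, pri, matrix)
  state <- open_space_phase(state, matrix, passes = open_space_passes,
                            trace_objective = trace_objective)
  assignment <- ifelse(is.na(state$placed), "UNASSIGNED",
                       matrix$refs[state$placed])
  names(assignment) <- matrix$reads
  counts <- vapply(state$members, length, 0L)
  names(counts) <- matrix$refs
  structure(
    list(assignment = assignment, counts = counts, priorities = pri,
         objective = objective_value(state, matrix), state = state,
         swaps = attr(state, "swaps")),
    class = "reassignment"
  )
}

#' @export
print.reassignment <- function(x, ...) {
  cat("reassignment:", sum(x$assignment != "UNASSIGNED"), "of",
      length(x$assignment), "reads assigned; objective F =",
      format(x$objective, digits = 6), "\n")
  invisible(x)
}

#' Naive best-score assignment (baseline)
#'
#' Assigns every read to its highest-scoring reference (ties broken by
#' reference id), ignoring abundances entirely. Used as the comparison
#' baseline for the abundance-aware re-assignment.
#'
#' @param matrix A [build_mapping_matrix()] object.
#' @return Named character vector read -> reference id.
#' @export
assign_best_score <- function(matrix) {
  e <- matrix$edges
  first <- e[!duplicated(e$read), ]
  out <- character(length(matrix$reads))
  out[first$read] <- matrix$refs[first$ref]
  names(out) <- matrix$reads
  out
}
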