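# Run code with a private RNG stream seeded from `seed`, restoring the
# caller's RNG state afterwards.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic strain community
#'
#' Defines the score-level alignment simulator: a set of reference strains
#' with a true abundance vector, and a controllable fraction of reads that
#' multi-map across the similar strains of their source's similarity group
#' with near-equal scores — the situation that makes strain-level read
#' assignment hard. Only (read, reference, score) triples are simulated;
#' no sequences or positions (POS is fixed at 1 with a full-length match
#' CIGAR), since the method consumes nothing else.
#'
#' Score model: the true source always scores `score_high`; each other
#' reference in the source's similarity group independently scores either
#' `score_high` (probability `p_high`, a near-identical region) or
#' `score_low`, plus an integer jitter uniform on `[-score_jitter,
#' score_jitter]`. Defaults mimic a 150 bp short-read alignment: perfect
#' match 150, half-length match 75, jitter 5.
#'
#' @param ref_ids Character vector of reference (strain) names.
#' @param abundance True abundance vector (sums to 1).
#' @param n_reads Number of reads.
#' @param ambiguity Fraction of reads that multi-map within their
#'   similarity group (default 0.3).
#' @param groups List of integer/character vectors partitioning the
#'   references into similarity groups (default: all in one group).
#' @param score_high,score_low,score_jitter Integer score parameters.
#' @param p_high Probability a non-source group member scores high.
#' @param lengths Reference lengths for the `@SQ` header lines.
#' @param read_length Read length used in the CIGAR string.
#' @param seed RNG seed; the same spec yields byte-identical SAM text.
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(ref_ids, abundance, n_reads,
                           ambiguity = 0.3, groups = NULL,
                           score_high = 150L, score_low = 75L,
                           score_jitter = 5L, p_high = 0.5,
                           lengths = NULL, read_length = 150L,
                           seed = 1L) {
  stopifnot(length(ref_ids) == length(abundance),
            abs(sum(abundance) - 1) < 1e-9,
            n_reads >= 1, ambiguity >= 0, ambiguity <= 1,
            score_high >= score_low, score_low >= 1, score_jitter >= 0)
  if (is.null(groups)) groups <- list(seq_along(ref_ids))
  groups <- lapply(groups, function(g) {
    if (is.character(g)) g <- match(g, ref_ids)
    stopifnot(!anyNA(g), length(g) >= 1)
    g
  })
  stopifnot(setequal(unlist(groups), seq_along(ref_ids)))
  if (is.null(lengths)) lengths <- rep(1000000L, length(ref_ids))
  structure(
    list(ref_ids = ref_ids, abundance = abundance,
         n_reads = as.integer(n_reads), ambiguity = ambiguity,
         groups = groups, score_high = as.integer(score_high),
         score_low = as.integer(score_low),
         score_jitter = as.integer(score_jitter), p_high = p_high,
         lengths = as.integer(lengths),
         read_length = as.integer(read_length), seed = as.integer(seed)),
    class = "community_spec"
  )
}

#' Simulate a ground-truthed community alignment
#'
#' Draws read sources from the community's abundance vector and emits a
#' valid SAM text (with `@SQ` header lines and `AS:i` score tags) plus
#' the true source of every read. A `1 - ambiguity` fraction of reads is
#' single-mapped to its source; the rest receive one record per reference
#' in the source's similarity group, scored per the [community_spec()]
#' score model, yielding the near-equal-score multi-mappings
#' characteristic of similar strains.
#'
#' @param spec A [community_spec()].
#' @param path Optional file path; when given, the SAM text is written
#'   there.
#' @return A list with `sam` (character vector of SAM lines), `truth`
#'   (named character vector read -> source reference) and `path` (or
#'   `NULL`).
#' @export
simulate_alignment <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_reads
    k <- length(spec$ref_ids)
    src <- sample.int(k, n, replace = TRUE, prob = spec$abundance)
    ambig <- stats::runif(n) < spec$ambiguity
    group_of <- integer(k)
    for (gi in seq_along(spec$groups)) group_of[spec$groups[[gi]]] <- gi
    read_ids <- sprintf("read_%06d", seq_len(n))

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      s <- src[i]
      grp <- spec$groups[[group_of[s]]]
      if (!ambig[i] || length(grp) == 1L) {
        rows[[i]] <- c(i, s, spec$score_high)
      } else {
        others <- setdiff(grp, s)
        base <- ifelse(stats::runif(length(others)) < spec$p_high,
                       spec$score_high, spec$score_low)
        jit <- if (spec$score_jitter > 0)
          sample.int(2L * spec$score_jitter + 1L, length(others),
                     replace = TRUE) - spec$score_jitter - 1L
        else rep(0L, length(others))
        sc <- pmax(1L, as.integer(base + jit))
        rows[[i]] <- rbind(c(i, s, spec$score_high),
                           cbind(i, others, sc))
      }
    }
    rec <- do.call(rbind, lapply(rows, rbind))
    rec <- data.frame(read = rec[, 1], ref = rec[, 2], score = rec[, 3])
    # primary = best-scoring record per read (ties: listed order)
    ord <- order(rec$read, -rec$score)
    firsts <- ord[!duplicated(rec$read[ord])]
    is_primary <- rep(FALSE, nrow(rec))
    is_primary[firsts] <- TRUE
    flag <- ifelse(is_primary, 0L, 256L)
    cigar <- paste0(spec$read_length, "M")
    body <- sprintf("%s\t%d\t%s\t1\t%d\t%s\t*\t0\t0\t*\t*\tAS:i:%d",
                    read_ids[rec$read], flag, spec$ref_ids[rec$ref],
                    ifelse(is_primary, 60L, 0L), cigar, rec$score)
    header <- c(
      "@HD\tVN:1.6\tSO:unknown",
      sprintf("@SQ\tSN:%s\tLN:%d", spec$ref_ids, spec$lengths),
      "@PG\tID:strainsort-sim\tPN:strainsort-sim"
    )
    sam <- c(header, body)
    if (!is.null(path)) writeLines(sam, path)
    truth <- stats::setNames(spec$ref_ids[src], read_ids)
    list(sam = sam, truth = truth, path = path)
  })
}

#' Randomized suite of tiny oracle instances
#'
#' Deterministic (given `seed`) random [tiny_instance()]s for the
#' greedy-versus-exact-oracle property suites: 2-6 reads, 2-4 references,
#' random integer scores, abundances drawn from a flat Dirichlet and copy
#' counts rounded from them.
#'
#' @param n Number of instances.
#' @param seed RNG seed.
#' @param unique_mapping If `TRUE`, every read maps to exactly one
#'   reference (the regime where the greedy provably attains the exact
#'   minimum).
#' @return List of [tiny_instance()] objects.
#' @export
tiny_instance_suite <- function(n = 200L, seed = 1L,
                                unique_mapping = FALSE) {
  .with_seed(seed, {
    lapply(seq_len(n), function(t) {
      m <- sample(2:6, 1)
      k <- sample(2:4, 1)
      sc <- matrix(0, m, k)
      for (i in seq_len(m)) {
        n_map <- if (unique_mapping) 1L else sample.int(k, 1)
        cols <- sample.int(k, n_map)
        sc[i, cols] <- sample(1:100, n_map, replace = TRUE)
      }
      # drop references no read maps to (a real mapping matrix only
      # carries observed references)
      keep <- colSums(sc) > 0
      sc <- sc[, keep, drop = FALSE]
      k <- ncol(sc)
      a <- stats::rgamma(k, shape = 1)
      a <- a / sum(a)
      p <- sc / rowSums(sc)
      copies <- as.integer(sign(a * m) * floor(abs(a * m) + 0.5))
      tiny_instance(p, copies, scores = sc, a = a)
    })
  })
}
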