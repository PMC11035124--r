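# Shared fixtures and independent oracles, built in code.

toy_sam_lines <- function() {
  c("@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:refA\tLN:5000",
    "@SQ\tSN:refB\tLN:4000",
    "r1\t0\trefA\t1\t60\t100M\t*\t0\t0\t*\t*\tAS:i:50",
    "r1\t256\trefB\t1\t0\t100M\t*\t0\t0\t*\t*\tAS:i:40",
    "r2\t0\trefB\t1\t60\t100M\t*\t0\t0\t*\t*\tAS:i:50",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*")
}

write_sam <- function(lines) {
  path <- tempfile(fileext = ".sam")
  writeLines(lines, path)
  path
}

toy_taxonomy <- function() {
  data.frame(
    accession = c("CP0001", "CP0005", "CP1001"),
    taxid = c(101L, 105L, 201L),
    species = c("Escherichia coli", "Escherichia coli",
                "Escherichia fergusonii"),
    genus = c("Escherichia", "Escherichia", "Escherichia"),
    stringsAsFactors = FALSE
  )
}

# random collapsed (read, ref, score) table with every reference mapped
rand_collapsed <- function(n_reads, n_refs, seed, max_maps = n_refs) {
  set.seed(seed)
  repeat {
    rows <- do.call(rbind, lapply(seq_len(n_reads), function(i) {
      k <- sample.int(max_maps, 1)
      data.frame(read_id = sprintf("r%03d", i),
                 reference_id = sprintf("R%d", sample.int(n_refs, k)),
                 score = sample(1:100, k, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    if (length(unique(rows$reference_id)) == n_refs) return(rows)
  }
}

# independent read-level EM oracle on a dense probability matrix
naive_em_trajectory <- function(P, iters) {
  n <- ncol(P)
  theta <- rep(1 / n, n)
  out <- matrix(NA_real_, iters, n, dimnames = list(NULL, colnames(P)))
  for (t in seq_len(iters)) {
    g <- sweep(P, 2, theta, `*`)
    g <- g / rowSums(g)
    theta <- colSums(g) / nrow(P)
    out[t, ] <- theta
  }
  out
}

# independent naive double-loop log-likelihood
naive_loglik <- function(theta, P) {
  total <- 0
  for (i in seq_len(nrow(P))) {
    s <- 0
    for (j in seq_len(ncol(P))) s <- s + theta[j] * P[i, j]
    total <- total + log(s)
  }
  total
}

# dense probability matrix from a mapping_matrix
dense_probs <- function(mat) as.matrix(mat$probs)

# fixture in which the open-up-space swap must fire:
# r1 unique to R1 (fills it); r2 takes R2 then is evicted to R3 so the
# higher-probability r3 can enter R2.
openspace_fixture <- function() {
  collapsed <- data.frame(
    read_id = c("r1", "r2", "r2", "r3", "r3"),
    reference_id = c("R1", "R2", "R3", "R2", "R1"),
    score = c(100, 95, 90, 90, 50),
    stringsAsFactors = FALSE
  )
  mat <- build_mapping_matrix(collapse_multimappings(collapsed))
  theta <- c(R1 = 1 / 3, R2 = 1 / 3, R3 = 1 / 3)
  list(matrix = mat, theta = theta)
}

# all-equal-probability fixture where the swap condition can never hold
adversarial_fixture <- function() {
  collapsed <- data.frame(
    read_id = c(rep(c("r1", "r2", "r3", "r4"), each = 2), "r5"),
    reference_id = c(rep(c("R1", "R2"), 4), "R3"),
    score = c(rep(10, 8), 10),
    stringsAsFactors = FALSE
  )
  mat <- build_mapping_matrix(collapse_multimappings(collapsed))
  theta <- c(R1 = 0.2, R2 = 0.2, R3 = 0.6)
  list(matrix = mat, theta = theta)
}

# the 6/2/2 instance whose EM fixed point is theta = (0.75, 0.25)
closed_form_622 <- function() {
  data.frame(
    read_id = c(sprintf("u%d", 1:6), sprintf("v%d", 1:2),
                "a1", "a1", "a2", "a2"),
    reference_id = c(rep("R1", 6), rep("R2", 2), rep(c("R1", "R2"), 2)),
    score = 10,
    stringsAsFactors = FALSE
  )
}

community_3strain <- function(seed = 7, n_reads = 10000) {
  community_spec(c("strainA", "strainB", "strainC"), c(0.6, 0.3, 0.1),
                 n_reads = n_reads, ambiguity = 0.3, seed = seed)
}
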