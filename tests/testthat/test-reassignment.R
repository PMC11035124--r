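test_that("capacities follow C_j = a_j + 1/M and rounded copies", {
  bins <- compute_capacities(c(R1 = 0.5, R2 = 0.5), 10)
  expect_equal(bins$capacity, c(0.6, 0.6))
  expect_equal(bins$copies, c(5L, 5L))
  # a bin is full exactly when n >= a_j * M (here 5)
  st <- list(n = c(4L, 5L), a = bins$a, M = 10)
  expect_false(strainsort:::.bin_full(st, 1))
  expect_true(strainsort:::.bin_full(st, 2))

  # a_j = 0 accepts zero reads
  bins <- compute_capacities(c(R1 = 1, R2 = 0), 10)
  st <- list(n = c(0L, 0L), a = bins$a, M = 10)
  expect_true(strainsort:::.bin_full(st, 2))

  # rounding: sum of copies equals M here
  bins <- compute_capacities(c(0.34, 0.33, 0.33), 3)
  expect_equal(bins$copies, c(1L, 1L, 1L))
})

test_that("priority labels follow the mapping count and score ratio", {
  collapsed <- data.frame(
    read_id = c("u", "c", "c", "a", "a"),
    reference_id = c("R1", "R1", "R2", "R1", "R2"),
    score = c(7, 10, 4, 10, 8)
  )
  pri <- assign_priorities(build_mapping_matrix(collapsed))
  expect_equal(unname(pri[c("u", "c", "a")]), c(1L, 2L, 3L))
  # threshold is configurable
  pri <- assign_priorities(build_mapping_matrix(collapsed),
                           threshold = 0.9)
  expect_equal(unname(pri[c("c", "a")]), c(2L, 2L))
})

test_that("objective value matches the literal per-copy evaluation", {
  # nothing assigned: F equals the total number of copies
  fx <- adversarial_fixture()
  st <- strainsort:::new_assignment_state(fx$matrix, fx$theta)
  expect_equal(objective_value(st, fx$matrix), sum(st$copies))

  # two perfect reads on a two-copy reference: F = 0
  mat <- build_mapping_matrix(data.frame(
    read_id = c("r1", "r2"), reference_id = "R1", score = 5))
  st <- strainsort:::new_assignment_state(mat, c(R1 = 1))
  st$members[[1]] <- c(1L, 2L); st$n[1] <- 2L; st$placed <- c(1L, 1L)
  expect_equal(objective_value(st, mat), 0)

  # random tiny placements against the naive triple-sum evaluator
  suite <- tiny_instance_suite(25, seed = 31)
  for (ins in suite) {
    gr <- greedy_on_instance(ins)
    xc <- state_copy_layout(gr$state, gr$matrix)
    p <- ins$p[gr$matrix$reads, gr$matrix$refs, drop = FALSE]
    expect_equal(gr$objective,
                 eval_objective_percopy(xc, p, gr$state$copies),
                 tolerance = 1e-12)
  }
})

test_that("greedy assignment follows the hand-traced priority order", {
  # r1, r2 unique; r3 confidently best (priority 2) takes R1; r4 is then
  # relabeled priority 3 and lands in R2
  collapsed <- data.frame(
    read_id = c("r1", "r2", "r3", "r3", "r4", "r4"),
    reference_id = c("R1", "R2", "R1", "R2", "R1", "R2"),
    score = c(10, 10, 10, 4, 10, 4)
  )
  mat <- build_mapping_matrix(collapsed)
  re <- reassign_reads(mat, c(R1 = 0.5, R2 = 0.5))
  expect_equal(unname(re$assignment[c("r1", "r2", "r3", "r4")]),
               c("R1", "R2", "R1", "R2"))
  expect_equal(unname(re$counts), c(2L, 2L))
})

test_that("unique-mapping instances reproduce the input mapping", {
  collapsed <- data.frame(
    read_id = sprintf("r%d", 1:6),
    reference_id = c("R1", "R1", "R1", "R2", "R2", "R3"),
    score = 50
  )
  mat <- build_mapping_matrix(collapsed)
  re <- reassign_reads(mat, c(R1 = 0.5, R2 = 1 / 3, R3 = 1 / 6))
  expect_equal(unname(re$assignment),
               c("R1", "R1", "R1", "R2", "R2", "R3"))
})

test_that("the open-up-space condition follows the probability inequality", {
  # p_ij=.8, p_kj=.5, p_kl=.3: condition holds (0.3 >= 0.2)
  collapsed <- data.frame(
    read_id = c("ri", "ri", "rk", "rk", "rk"),
    reference_id = c("R1", "R3", "R1", "R2", "R3"),
    score = c(8, 2, 5, 3, 2)
  )
  mat <- build_mapping_matrix(collapsed)
  st <- strainsort:::new_assignment_state(mat, c(R1 = 0.2, R2 = 0.4,
                                                 R3 = 0.4))
  k <- match("rk", mat$reads); j <- match("R1", mat$refs)
  st$members[[j]] <- k; st$n[j] <- 1L; st$placed[k] <- j
  res <- can_open_space(st, match("ri", mat$reads), j, mat)
  expect_equal(mat$reads[res$victim], "rk")
  expect_equal(mat$refs[res$dest], "R2")   # highest-p non-full destination

  # p_ij=.5, p_kj=.5, p_kl=.4: condition fails (0 < 0.1)
  collapsed <- data.frame(
    read_id = c("ri", "ri", "rk", "rk", "rk"),
    reference_id = c("R1", "R3", "R1", "R2", "R3"),
    score = c(5, 5, 5, 4, 1)
  )
  mat <- build_mapping_matrix(collapsed)
  st <- strainsort:::new_assignment_state(mat, c(R1 = 0.2, R2 = 0.4,
                                                 R3 = 0.4))
  k <- match("rk", mat$reads); j <- match("R1", mat$refs)
  st$members[[j]] <- k; st$n[j] <- 1L; st$placed[k] <- j
  expect_null(can_open_space(st, match("ri", mat$reads), j, mat))
})

test_that("the swap phase places a blocked read and lowers the objective", {
  fx <- openspace_fixture()
  pri <- assign_priorities(fx$matrix)
  st <- strainsort:::new_assignment_state(fx$matrix, fx$theta)
  st <- greedy_assign(st, pri, fx$matrix)
  expect_equal(fx$matrix$reads[st$unassigned], "r3")
  f_before <- objective_value(st, fx$matrix)
  st2 <- open_space_phase(st, fx$matrix, trace_objective = TRUE)
  expect_length(st2$unassigned, 0)
  f_after <- objective_value(st2, fx$matrix)
  expect_lt(f_after, f_before)
  # r2 was evicted to R3 so r3 could enter R2
  expect_equal(fx$matrix$refs[st2$placed[match("r2", fx$matrix$reads)]],
               "R3")
  expect_equal(fx$matrix$refs[st2$placed[match("r3", fx$matrix$reads)]],
               "R2")
})

test_that("when the swap condition never holds, reads stay unassigned", {
  fx <- adversarial_fixture()
  re <- reassign_reads(fx$matrix, fx$theta)
  expect_equal(sum(re$assignment == "UNASSIGNED"), 2L)
  st_counts <- re$counts
  expect_equal(unname(st_counts[c("R1", "R2")]), c(1L, 1L))
  expect_equal(nrow(re$swaps), 0L)
})

test_that("no swap ever increases the objective across random runs", {
  suite <- tiny_instance_suite(60, seed = 33)
  for (ins in suite) {
    gr <- greedy_on_instance(ins, trace_objective = TRUE)
    if (nrow(gr$swaps) > 0) {
      expect_true(all(gr$swaps$F_after <= gr$swaps$F_before + 1e-12))
    }
  }
})

test_that("capacity and priority-1 invariants hold on random instances", {
  suite <- tiny_instance_suite(60, seed = 34)
  for (ins in suite) {
    gr <- greedy_on_instance(ins)
    st <- gr$state
    pri <- gr$priorities
    n1 <- vapply(seq_along(st$refs), function(j)
      sum(pri[st$members[[j]]] == 1L), 0L)
    # bins exceed a_j*M + 1 only through priority-1 reads
    over <- st$n - (st$a * st$M + 1)
    expect_true(all(over <= pmax(0, n1 - 1) + 1e-9))
    # every single-mapping read sits in its unique reference
    e <- gr$matrix$edges
    singles <- which(tabulate(e$read, length(gr$matrix$reads)) == 1L)
    for (i in singles) {
      expect_equal(st$placed[i], e$ref[e$read == i])
    }
  }
})

test_that("re-assignment beats naive best-score on the strain community", {
  sim <- simulate_alignment(community_3strain(seed = 19, n_reads = 4000))
  sam <- write_sam(sim$sam)
  fit <- strainsort(sam)
  truth <- c(strainA = 0.6, strainB = 0.3, strainC = 0.1)
  expect_lt(max(abs(fit$fractions[names(truth)] - truth)), 0.05)
  m_re <- evaluate_assignment(fitted(fit), sim$truth)
  m_naive <- evaluate_assignment(assign_best_score(fit$matrix), sim$truth)
  expect_lt(m_re$l1, m_naive$l1)
})

test_that("identical inputs give byte-identical outputs", {
  sim <- simulate_alignment(community_3strain(seed = 23, n_reads = 500))
  sam <- write_sam(sim$sam)
  out1 <- tempfile(); out2 <- tempfile()
  run_pipeline(sam, out1, verbose = FALSE)
  run_pipeline(sam, out2, verbose = FALSE)
  for (suffix in c("_assignments.tsv", "_abundance.tsv")) {
    expect_identical(readLines(paste0(out1, suffix)),
                     readLines(paste0(out2, suffix)))
  }
})
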