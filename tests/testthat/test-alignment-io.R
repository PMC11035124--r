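test_that("SAM parsing separates mapped records, catalog and unaligned reads", {
  sam <- write_sam(toy_sam_lines())
  aln <- read_alignments(sam)
  expect_equal(nrow(aln$records), 3L)
  expect_equal(aln$catalog, c(refA = 5000L, refB = 4000L))
  expect_equal(aln$unaligned, "r3")
  expect_equal(aln$n_skipped, 0L)
  expect_true(aln$records$secondary[aln$records$reference_id == "refB" &
                                      aln$records$read_id == "r1"])
  # mapped stream and unaligned set partition the input reads
  expect_length(intersect(aln$records$read_id, aln$unaligned), 0)
  expect_setequal(c(unique(aln$records$read_id), aln$unaligned),
                  c("r1", "r2", "r3"))
})

test_that("BAM input yields the identical record stream as SAM", {
  sam <- write_sam(toy_sam_lines())
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  a <- read_alignments(sam)
  b <- read_alignments(bam)
  key <- function(r) r[order(r$read_id, r$reference_id), ]
  expect_equal(key(a$records), key(b$records), ignore_attr = TRUE)
  expect_equal(a$catalog, b$catalog)
  expect_equal(a$unaligned, b$unaligned)
})

test_that("mapped records without the score tag error or are skipped", {
  lines <- c("@HD\tVN:1.6",
             "@SQ\tSN:refA\tLN:1000",
             "r1\t0\trefA\t1\t60\t100M\t*\t0\t0\t*\t*")
  sam <- write_sam(lines)
  expect_error(read_alignments(sam, require_score = TRUE), "AS")
  expect_warning(aln <- read_alignments(sam, require_score = FALSE),
                 "skipped")
  expect_equal(nrow(aln$records), 0L)
  expect_equal(aln$n_skipped, 1L)
})

test_that("a SAM without @SQ header lines is rejected", {
  sam <- write_sam(c("@HD\tVN:1.6",
                     "r1\t0\trefA\t1\t60\t100M\t*\t0\t0\t*\t*\tAS:i:10"))
  expect_error(read_alignments(sam))
})

test_that("paired-end mates become independent read units", {
  lines <- c("@HD\tVN:1.6",
             "@SQ\tSN:refA\tLN:1000",
             "p1\t67\trefA\t1\t60\t100M\t*\t0\t0\t*\t*\tAS:i:90",
             "p1\t131\trefA\t1\t60\t100M\t*\t0\t0\t*\t*\tAS:i:80")
  aln <- read_alignments(write_sam(lines))
  expect_setequal(aln$records$read_id, c("p1/1", "p1/2"))
})

test_that("collapse keeps the maximum score per (read, reference) pair", {
  recs <- data.frame(
    read_id = c("r1", "r1", "r1"),
    reference_id = c("R1", "R1", "R2"),
    score = c(50L, 44L, 40L)
  )
  out <- collapse_multimappings(recs)
  expect_equal(out$score[out$reference_id == "R1"], 50)
  expect_equal(out$score[out$reference_id == "R2"], 40)
  expect_equal(nrow(out), 2L)

  single <- collapse_multimappings(
    data.frame(read_id = "r1", reference_id = "R1", score = 30L))
  expect_equal(single$score, 30)

  # brute-force scan oracle on random records
  set.seed(41)
  recs <- data.frame(
    read_id = sprintf("r%d", sample(1:5, 100, TRUE)),
    reference_id = sprintf("R%d", sample(1:3, 100, TRUE)),
    score = sample(-10:100, 100, TRUE)
  )
  out <- collapse_multimappings(recs)
  shift <- attr(out, "score_shift")
  for (r in seq_len(nrow(out))) {
    sub <- recs$score[recs$read_id == out$read_id[r] &
                        recs$reference_id == out$reference_id[r]]
    expect_equal(out$score[r], max(sub) + shift)
  }
})

test_that("non-positive scores get an order-preserving affine shift", {
  recs <- data.frame(read_id = c("r1", "r1", "r2"),
                     reference_id = c("R1", "R2", "R1"),
                     score = c(-5L, 0L, 3L))
  expect_message(out <- collapse_multimappings(recs), "shift")
  expect_equal(attr(out, "score_shift"), 6)
  expect_true(all(out$score >= 1))
  got <- setNames(out$score, paste(out$read_id, out$reference_id))
  expect_equal(got[["r1 R1"]], 1)   # -5 + 6
  expect_equal(got[["r1 R2"]], 6)   #  0 + 6
  expect_equal(got[["r2 R1"]], 9)   #  3 + 6
})

test_that("assignment tables round-trip losslessly and cover every read", {
  asg <- data.frame(
    read_id = c("r1", "r2", "r3"),
    reference = c("refA", "refB", "NO ALIGNMENT"),
    stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".tsv")
  write_assignments(path, asg)
  back <- read_assignments(path)
  expect_equal(back, asg)

  # with taxonomy, and a deliberate accession gap rendered NA
  tax <- toy_taxonomy()
  asg2 <- data.frame(read_id = c("r1", "r2"),
                     reference = c("CP0001", "UNKNOWN999"))
  write_assignments(path, asg2, tax)
  back <- read_assignments(path)
  expect_equal(back$species[1], "Escherichia coli")
  expect_true(is.na(back$species[2]))

  # degenerate: empty assignment set -> header-only file
  write_assignments(path, asg[0, ])
  expect_equal(length(readLines(path)), 1L)
})

test_that("abundance table reports fractions and zero rows", {
  path <- tempfile(fileext = ".tsv")
  out <- write_abundance_table(path, c(R1 = 1), c(R1 = 10L))
  expect_equal(out$assigned_fraction, 1)

  out <- write_abundance_table(path, c(R1 = 0.75, R2 = 0.25),
                               c(R1 = 3L, R2 = 1L))
  expect_equal(out$assigned_fraction, c(0.75, 0.25))

  # reference deactivated by the set-cover filter still gets a row
  out <- write_abundance_table(path, c(R1 = 1, R2 = 0),
                               c(R1 = 4L, R2 = 0L))
  expect_equal(out$abundance[out$reference_id == "R2"], 0)
  expect_equal(out$assigned_reads[out$reference_id == "R2"], 0L)
})
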