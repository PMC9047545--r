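test_that("unmapped-read extraction follows samtools flag semantics", {
  sam <- make_sam_fixture(withr::local_tempfile(fileext = ".sam"))
  reads <- read_alignments(sam)
  expect_equal(nrow(reads), 12L)

  singles <- extract_unmapped_single(reads)
  expect_setequal(singles$read_id, c("r01", "r02", "r05"))

  expect_warning(pp <- extract_unmapped_pairs(reads), "orphan")
  expect_equal(pp$pairs$read_id, c("r03", "r03"))
  expect_equal(pp$pairs$mate_role, c("first", "second"))
  expect_equal(pp$orphans$read_id, "r04")

  # single and pair predicates are mutually exclusive on any flag set
  expect_length(intersect(singles$read_id, pp$pairs$read_id), 0L)

  # bit-arithmetic oracle over the same records
  want_single <- bitwAnd(reads$flag, 4L) == 4L &
    bitwAnd(reads$flag, 264L) == 0L
  expect_setequal(singles$read_id, reads$read_id[want_single])
  want_pairish <- bitwAnd(reads$flag, 12L) == 12L &
    bitwAnd(reads$flag, 256L) == 0L
  expect_setequal(c(pp$pairs$read_id, pp$orphans$read_id),
                  reads$read_id[want_pairish])
})

test_that("flag predicates match samtools itself on the fixture", {
  skip_if(Sys.which("samtools") == "")
  sam <- make_sam_fixture(withr::local_tempfile(fileext = ".sam"))
  reads <- read_alignments(sam)
  for (spec in list(c("-f", "4", "-F", "264"), c("-f", "12", "-F", "256"))) {
    out <- system2("samtools", c("view", spec, sam), stdout = TRUE)
    ids <- vapply(strsplit(out, "\t"), `[[`, "", 1L)
    mine <- if (spec[[2]] == "4") {
      extract_unmapped_single(reads)$read_id
    } else {
      reads$read_id[bitwAnd(reads$flag, 12L) == 12L &
                      bitwAnd(reads$flag, 256L) == 0L]
    }
    expect_setequal(mine, ids)
  }
})

test_that("malformed SAM flags are rejected", {
  expect_error(read_records("r1", "ACGT", flag = -1L), "malformed")
  bad <- withr::local_tempfile(fileext = ".sam")
  writeLines("r1\tXX\tchr1\t1\t0\t*\t*\t0\t0\tACGT\tIIII", bad)
  expect_error(read_alignments(bad), "malformed")
})

test_that("qc_filter applies length, N and quality thresholds", {
  q <- function(scores) intToUtf8(scores + 33L)
  reads <- read_records(
    c("len30", "n6", "lowq", "edge_n5", "edge_len36", "edge_q40"),
    c(strrep("A", 30),                      # 30 bp, dropped: length
      paste0(strrep("N", 6), strrep("A", 44)),  # 6 N, dropped
      strrep("A", 50),                      # 50% bases < Q15, dropped
      paste0(strrep("N", 5), strrep("A", 45)),  # exactly 5 N, kept
      strrep("A", 36),                      # exactly 36 bp, kept
      strrep("A", 50)),                     # exactly 40% < Q15, kept
    c(q(rep(30, 30)),
      q(rep(30, 50)),
      q(c(rep(10, 25), rep(30, 25))),
      q(rep(30, 50)),
      q(rep(30, 36)),
      q(c(rep(10, 20), rep(30, 30)))))
  res <- qc_filter(reads, qc_policy())
  expect_setequal(res$reads$read_id, c("edge_n5", "edge_len36", "edge_q40"))
  expect_equal(unname(res$report[c("input", "kept", "drop_length",
                                   "drop_n", "drop_quality")]),
               c(6L, 3L, 1L, 1L, 1L))

  # subset + idempotence
  again <- qc_filter(res$reads, qc_policy())
  expect_equal(again$reads, res$reads)
  expect_true(all(res$reads$read_id %in% reads$read_id))

  # empty input is a zero-count report, not an error
  res0 <- qc_filter(reads[0, ], qc_policy())
  expect_equal(nrow(res0$reads), 0L)
  expect_equal(sum(res0$report), 0L)
})

test_that("reverse complement is correct and involutive", {
  expect_equal(reverse_complement("AACC"), "GGTT")
  expect_equal(reverse_complement("N"), "N")
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_error(reverse_complement("ACGX"), "invalid sequence")
  set.seed(42)
  for (i in 1:1000) {
    s <- random_seq(sample(1:60, 1))
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("singleton reads acquire reverse-complement mates", {
  reads <- read_records(c("s1", "s2"), c("AACC", "ACGTN"),
                        c("IIII", "IIIII"))
  paired <- pair_singleton_with_revcomp(reads)
  expect_equal(nrow(paired), 4L)
  expect_equal(paired$mate_role, rep(c("first", "second"), 2))
  expect_equal(paired$sequence[paired$read_id == "s1" &
                                 paired$mate_role == "second"], "GGTT")
  expect_equal(paired$sequence[paired$read_id == "s2" &
                                 paired$mate_role == "second"], "NACGT")
  expect_error(pair_singleton_with_revcomp(
    read_records("x", "ACGT", flag = 69L)), "unpaired")
})

test_that("FASTQ and FASTA round-trips preserve records", {
  set.seed(7)
  n <- 20L
  seqs <- vapply(rep(50L, n), random_seq, "")
  quals <- vapply(seq_len(n), function(i) {
    intToUtf8(sample(0:40, 50L, replace = TRUE) + 33L)
  }, "")
  reads <- read_records(sprintf("read%02d", seq_len(n)), seqs, quals)

  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_equal(back$read_id, reads$read_id)
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$quality, reads$quality)

  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(reads, fa)
  back_fa <- read_fasta(fa)
  expect_equal(back_fa$sequence, reads$sequence)
  expect_true(all(is.na(back_fa$quality)))

  # empty stream -> empty valid file
  fq0 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads[0, ], fq0)
  expect_equal(nrow(read_fastq(fq0)), 0L)

  # id collision -> suffix disambiguation with warning
  dup <- read_records(c("a", "a"), c("ACGT", "TTTT"), c("IIII", "IIII"))
  expect_warning(write_fastq(dup, fq), "duplicate")
  expect_equal(anyDuplicated(read_fastq(fq)$read_id), 0L)
})

test_that("BAM adapter agrees with SAM text parsing", {
  skip_if_not_installed("Rsamtools")
  sam <- make_sam_fixture(withr::local_tempfile(fileext = ".sam"))
  bam <- Rsamtools::asBam(sam, withr::local_tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  a <- read_alignments(sam)
  b <- read_alignments(bam)
  o <- order(b$read_id, b$flag)
  expect_equal(b[o, c("read_id", "flag", "sequence")],
               a[order(a$read_id, a$flag), c("read_id", "flag", "sequence")],
               ignore_attr = TRUE)
})
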