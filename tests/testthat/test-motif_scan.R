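grh <- pwm_from_consensus("ACYGGTTT")

test_that("pwm_from_consensus encodes IUPAC codes as 0/1 columns", {
  expect_equal(ncol(grh$matrix), 8)
  expect_equal(unname(grh$matrix[, 3]), c(0, 1, 0, 1))  # Y = C or T
  expect_equal(unname(grh$matrix[, 1]), c(1, 0, 0, 0))
  one <- pwm_from_consensus("A")
  expect_equal(unname(one$matrix[, 1]), c(1, 0, 0, 0))
  expect_error(pwm_from_consensus("ACXG"), "invalid IUPAC")
})

test_that("reverse complement algebra", {
  expect_equal(pwm_reverse_complement(grh)$consensus, "AAACCRGT")
  # involution
  back <- pwm_reverse_complement(pwm_reverse_complement(grh))
  expect_equal(back$matrix, grh$matrix)
  expect_equal(back$consensus, grh$consensus)
})

test_that("scan finds self-matches and respects strand/threshold semantics", {
  # exact consensus (Y -> C): one forward full-score hit at 0
  hits <- scan_pwm("ACCGGTTT", grh, threshold_frac = 0.85,
                   both_strands = FALSE)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 0L)
  expect_equal(hits$end, 8L)
  expect_equal(hits$frac_of_max, 1.0)
  # the reverse-complement sequence matches on the minus strand only
  rc_hits <- scan_pwm("AAACCGGT", grh, threshold_frac = 0.85,
                      both_strands = TRUE)
  expect_equal(nrow(rc_hits), 1)
  expect_equal(rc_hits$strand, "-")
  expect_equal(rc_hits$start, 0L)
  # unreachable threshold: zero hits
  set.seed(2)
  long <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  expect_equal(nrow(scan_pwm(long, grh, threshold_frac = 1.01)), 0)
  # sequence shorter than the motif: empty result
  expect_equal(nrow(scan_pwm("ACG", grh)), 0)
  # N positions score zero, so an N window cannot reach a full-score threshold
  expect_equal(nrow(scan_pwm("ACNGGTTT", grh, threshold_frac = 1)), 0)
  expect_equal(nrow(scan_pwm("ACNGGTTT", grh, threshold_frac = 7 / 8)), 1)
})

test_that("threshold 1.0 recovers exactly the planted consensus positions", {
  set.seed(10)
  bg <- sample(c("A", "C", "G", "T"), 400, TRUE)
  plant_at <- c(50, 200, 377)  # 1-based starts
  for (p in plant_at) bg[p:(p + 7)] <- strsplit("ACTGGTTT", "")[[1]]
  seq <- paste(bg, collapse = "")
  hits <- scan_pwm(seq, grh, threshold_frac = 1, both_strands = FALSE)
  expect_true(all((plant_at - 1) %in% hits$start))
  expect_true(all(hits$frac_of_max[hits$start %in% (plant_at - 1)] == 1))
})

test_that("forward scan equals reverse-strand scan of the reverse complement", {
  set.seed(20)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  fwd <- scan_pwm(s, grh, threshold_frac = 0.8, both_strands = FALSE)
  rev_of_rc <- scan_pwm(rc, grh, threshold_frac = 0.8, both_strands = TRUE)
  rev_of_rc <- rev_of_rc[rev_of_rc$strand == "-", ]
  # map minus-strand coordinates on the reverse complement back
  expect_setequal(fwd$start, 300 - rev_of_rc$end)
  expect_equal(sort(fwd$score), sort(rev_of_rc$score))
})

test_that("hit counts are non-increasing in the threshold", {
  set.seed(30)
  s <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
  counts <- vapply(c(0.5, 0.7, 0.85, 1), function(th)
    nrow(scan_pwm(s, grh, threshold_frac = th)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("scanner agrees with Biostrings::matchPWM on a numeric matrix", {
  set.seed(40)
  mat <- matrix(runif(32), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- rxagsp:::new_pwm(mat, id = "rand")
  s <- paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = "")
  mine <- scan_pwm(s, pwm, threshold_frac = 0.85, both_strands = FALSE)
  ref <- Biostrings::matchPWM(mat, Biostrings::DNAString(s),
                              min.score = "85%")
  expect_equal(mine$start + 1L, Biostrings::start(ref))
})

test_that("FASTA scanning, dedup, and BED export", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">prom1 geneA upstream", "TTTACCGGTTTAAA",
               ">prom2", "GGGAAACCAGTGGG"), fa)
  hits <- scan_promoters(fa, grh, threshold_frac = 0.85)
  expect_setequal(unique(hits$sequence_id), c("prom1", "prom2"))
  expect_true(any(hits$strand == "-" & hits$sequence_id == "prom2"))
  # duplicated rows (same id/start/strand) collapse; opposite strands stay
  dup <- rbind(hits, hits[1, ])
  expect_equal(nrow(dedup_hits(dup)), nrow(hits))
  two_strand <- hits[1, ]
  two_strand$strand <- setdiff(c("+", "-"), hits$strand[1])
  expect_equal(nrow(dedup_hits(rbind(hits[1, ], two_strand))), 2)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(hits, bed)
  back <- read.delim(bed, header = FALSE)
  expect_equal(nrow(back), nrow(hits))
  expect_equal(back$V2, hits$start)
  expect_true(all(back$V5 >= 0 & back$V5 <= 1000))
})

test_that("PWM text formats parse", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A C G T", "1 0 0 0", "0 1 0 0", "0 0.5 0 0.5"), f)
  p <- read_pwm(f, id = "plain")
  expect_equal(ncol(p$matrix), 3)
  expect_equal(unname(p$matrix[, 3]), c(0, 0.5, 0, 0.5))
  writeLines(c("ID grh_like", "P0 A C G T",
               "01 4 0 0 0", "02 0 4 0 0", "03 0 2 0 2"), f)
  tf <- read_pwm(f)
  expect_equal(tf$id, "grh_like")
  expect_equal(unname(tf$matrix[, 1]), c(4, 0, 0, 0))
  expect_equal(unname(tf$matrix[, 3]), c(0, 2, 0, 2))
})
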