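# brute-force oracle: expand a degenerate pattern's full matching behavior
# by checking every window against every IUPAC-compatible base set
iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"), I = c("A", "C", "G", "T"))

match_primer_oracle <- function(read, pattern, error_rate) {
  pch <- strsplit(pattern, "")[[1]]
  rch <- strsplit(read, "")[[1]]
  k <- length(pch)
  max_mm <- floor(error_rate * k)
  if (k > length(rch)) return(NULL)
  for (start in seq_len(length(rch) - k + 1)) {
    mm <- 0
    for (p in seq_len(k)) {
      base <- rch[start + p - 1]
      ok <- if (base == "N") pch[p] %in% c("N", "I")
            else any(iupac_sets[[base]] %in% iupac_sets[[pch[p]]])
      if (!ok) mm <- mm + 1
    }
    if (mm <= max_mm) return(c(start, start + k - 1))
  }
  NULL
}

test_that("primer matching agrees with the set-expansion oracle", {
  pp <- primer_pair()
  set.seed(21)
  for (rep in 1:60) {
    read <- random_seq(sample(30:80, 1), c("A", "C", "G", "T", "N"))
    for (pat in c(pp$fwd, pp$rev, "ACGTRY", "NNSWKM")) {
      got <- match_primer(read, pat, 0.10)
      want <- match_primer_oracle(read, pat, 0.10)
      if (is.null(want)) expect_null(got, info = paste(read, pat))
      else expect_equal(got, want, ignore_attr = TRUE,
                        info = paste(read, pat))
    }
  }
})

test_that("primer detection at 5' end with mismatch budget floor(rate * len)", {
  pp <- primer_pair()
  expect_equal(nchar(pp$fwd), 23)
  # concrete instantiation of the forward pattern plus trailing payload
  read <- paste0("CCTACACCACCTGGTGAAGGTAA", "GGGTTT")
  expect_equal(match_primer(read, pp$fwd, 0.10), c(1, 23))
  # two mismatches allowed (floor(0.10 * 23) = 2), three not
  read2 <- mutate_seq(read, 0, positions = NULL)
  v <- strsplit(read, "")[[1]]
  v[c(1, 5)] <- c("G", "T")   # positions with concrete primer symbols C, C
  expect_equal(match_primer(paste(v, collapse = ""), pp$fwd, 0.10), c(1, 23))
  v[14] <- "C"                # G-column of GGN
  expect_null(match_primer(paste(v, collapse = ""), pp$fwd, 0.10))
  # too-short read
  expect_null(match_primer("ACGT", pp$fwd, 0.10))
  # leftmost qualifying window wins
  shifted <- paste0("TTTTT", read)
  expect_equal(match_primer(shifted, pp$fwd, 0.10)[1], 6)
})

test_that("3' quality trimming equals the all-cut-points oracle and is idempotent", {
  expect_equal(quality_trim_3prime("ACGT", c(40, 40, 40, 40), 20)$seq, "ACGT")
  expect_equal(nchar(quality_trim_3prime("ACGT", c(40, 40, 2, 2), 20)$seq), 2)
  expect_equal(quality_trim_3prime("ACG", c(2, 2, 2), 20)$seq, "")
  set.seed(31)
  for (rep in 1:300) {
    L <- sample(1:60, 1)
    qual <- sample(0:41, L, replace = TRUE)
    seq <- random_seq(L)
    tr <- quality_trim_3prime(seq, qual, 20)
    expect_equal(nchar(tr$seq), trim_oracle(qual, 20))
    # idempotence
    if (nchar(tr$seq) > 0) {
      tr2 <- quality_trim_3prime(tr$seq, tr$qual, 20)
      expect_identical(tr2, tr)
    }
  }
  expect_error(quality_trim_3prime("ACGT", NULL, 20), "quality")
})

test_that("read filtering applies primer, trim, truncate, length checks in order", {
  pp <- primer_pair()
  params <- qc_params()
  primer_inst <- "CCTACACCACCTGGTGAAGGTAA"
  payload <- random_seq(277)
  read <- paste0(primer_inst, payload)
  res <- qc_filter_read(read, rep(40L, 300), pp, "R1", params)
  expect_null(res$reason)
  expect_equal(nchar(res$seq), 277)
  expect_equal(res$seq, payload)

  # no primer
  res2 <- qc_filter_read(random_seq(200), rep(40L, 200), pp, "R1", params)
  expect_equal(res2$reason, "no_primer")
  # keep primerless reads when not required
  res2b <- qc_filter_read(random_seq(200), rep(40L, 200), pp, "R1",
                          qc_params(require_primer = FALSE))
  expect_null(res2b$reason)

  # surviving read of 119 nt is too short at min_length 120
  short <- paste0(primer_inst, random_seq(119))
  res3 <- qc_filter_read(short, rep(40L, nchar(short)), pp, "R1", params)
  expect_equal(res3$reason, "too_short")

  # truncation to max_length
  long <- paste0(primer_inst, random_seq(400))
  res4 <- qc_filter_read(long, rep(40L, nchar(long)), pp, "R1", params)
  expect_equal(nchar(res4$seq), 300)

  # R2 reads are screened with the reverse pattern
  r2 <- paste0("ATCTTAGCAAATGGTCCTGCTTG", random_seq(150))
  expect_null(qc_filter_read(r2, rep(40L, nchar(r2)), pp, "R2", qc_params())$reason)
  expect_equal(qc_filter_read(r2, rep(40L, nchar(r2)), pp, "R1",
                              qc_params())$reason, "no_primer")
})

test_that("batch QC conserves read counts across reasons", {
  pp <- primer_pair()
  set.seed(41)
  primer_inst <- "CCAACACCATCAGGAGAAGGAAA"
  good <- vapply(1:20, function(i) paste0(primer_inst, random_seq(200)),
                 character(1))
  bad <- vapply(1:10, function(i) random_seq(220), character(1))
  seqs <- c(good, bad)
  recs <- seq_records(sprintf("r%02d", seq_along(seqs)), seqs,
                      lapply(nchar(seqs), function(L) rep(40L, L)))
  res <- qc_filter_reads(recs, pp, "R1", qc_params())
  expect_equal(unname(res$tally["input"]),
               unname(res$tally["kept"] + res$tally["no_primer"] +
                      res$tally["too_short"] + res$tally["empty_after_trim"]))
  expect_equal(unname(res$tally["kept"]), 20)
  expect_true(all(nchar(res$kept$seq) >= 120 & nchar(res$kept$seq) <= 300))
})
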