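test_that("mock reference is deterministic and structurally sound", {
  mr <- tiny_mock()
  mr2 <- build_mock_reference(n_genera = 5, variants_per_genus = 2,
                              divergence = 0.05, seed = 101)
  expect_identical(mr$taxa, mr2$taxa)
  expect_identical(mr$db$proteins, mr2$db$proteins)

  pp <- primer_pair()
  for (t in mr$taxa) {
    L <- nchar(t$nuc_trimmed)
    expect_true(L >= 629 && L <= 641)          # 635 +/- 6
    # begins with a forward-primer instantiation, 0 mismatches
    expect_equal(match_primer(t$nuc_trimmed, pp$fwd, 0)[1], 1)
    # ends with the reverse-complemented reverse primer
    tail23 <- substr(t$nuc_trimmed, L - 22, L)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tail23)))
    expect_equal(match_primer(rc, pp$rev, 0)[1], 1)
    # frame +1 stop-free; best frame recovers the reference protein
    expect_false(grepl("[*]", t$protein))
    bf <- best_frame(t$nuc_trimmed)
    expect_equal(bf$frame, "+1")
    expect_equal(bf$protein, substr(t$protein, 1, nchar(bf$protein)))
    # error-free amplicon passes QC
    res <- qc_filter_read(t$nuc_trimmed, rep(40L, L), pp, "R1", qc_params())
    expect_null(res$reason)
  }
})

test_that("length datasets have the exact stated geometry", {
  mr <- tiny_mock()
  ds <- derive_length_datasets(mr$taxa)
  expect_true(all(nchar(ds$d300$seq) == 300))
  expect_true(all(nchar(ds$d150$seq) == 150))
  expect_true(all(nchar(ds$trimmed$seq) >= 629 & nchar(ds$trimmed$seq) <= 641))
  expect_true(all(nchar(ds$full$seq) > nchar(ds$trimmed$seq)))
  # prefix chain: 150 < 300 < trimmed, and full contains trimmed
  for (i in seq_len(nrow(ds$trimmed))) {
    expect_equal(ds$d150$seq[i], substr(ds$d300$seq[i], 1, 150))
    expect_equal(ds$d300$seq[i], substr(ds$trimmed$seq[i], 1, 300))
    expect_true(grepl(ds$trimmed$seq[i], ds$full$seq[i], fixed = TRUE))
  }
})

test_that("FASTA-to-FASTQ conversion is constant-quality and lossless", {
  recs <- seq_records(c("a", "b"), c(strrep("ACGT", 5), strrep("GT", 10)))
  fq <- fasta_to_fastq(recs)
  expect_equal(fq$qual[[1]], rep(40L, 20))
  f <- withr::local_tempfile(fileext = ".fastq.gz")
  write_sequences(fq, f, "fastq", gzipped = TRUE)
  back <- read_sequences(f, "fastq")
  expect_equal(back$seq, recs$seq)
  # Q40 survives Phred-20 trimming untouched
  tr <- quality_trim_3prime(fq$seq[1], fq$qual[[1]], 20)
  expect_equal(tr$seq, fq$seq[1])
})

test_that("read simulation is deterministic with exact chimera counts and truth", {
  mr <- tiny_mock()
  accs <- names(mr$taxa)[1:4]
  spec <- community_spec(
    samples = list(S1 = setNames(c(200L, 100L, 50L, 50L), accs),
                   S2 = setNames(c(100L, 100L, 100L, 100L), accs)),
    error_rate = 0, chimera_rate = 0.05, seed = 77)
  sim <- simulate_community_reads(spec, mr$taxa, "R1")
  expect_equal(nrow(sim$truth), 800)
  chim <- grepl("@", sim$truth$source, fixed = TRUE)
  # exact count per sample: round(0.05 * 400) = 20
  expect_equal(sum(chim & sim$truth$sample == "S1"), 20)
  expect_equal(sum(chim & sim$truth$sample == "S2"), 20)
  sim2 <- simulate_community_reads(spec, mr$taxa, "R1")
  expect_identical(sim$reads, sim2$reads)
  expect_identical(sim$truth, sim2$truth)

  # R2 reads start with a reverse-primer instantiation
  spec0 <- community_spec(samples = list(S = setNames(100L, accs[1])),
                          error_rate = 0, chimera_rate = 0, seed = 3)
  r2 <- simulate_community_reads(spec0, mr$taxa, "R2")$reads$S
  pp <- primer_pair()
  expect_false(is.null(match_primer(r2$seq[1], pp$rev, 0.10)))

  # error injection is recorded in the ground truth
  spec_err <- community_spec(samples = list(S = setNames(50L, accs[1])),
                             error_rate = 0.01, chimera_rate = 0, seed = 5)
  sim_err <- simulate_community_reads(spec_err, mr$taxa, "R1")
  expect_true(sum(sim_err$truth$errors_introduced) > 0)
  expect_error(simulate_community_reads(
    community_spec(samples = list(S = c(NOPE = 5L)), seed = 1), mr$taxa),
    "unknown accession")
})

test_that("file output follows the naming convention and re-parses", {
  mr <- tiny_mock()
  d <- withr::local_tempdir()
  spec <- community_spec(samples = list(SampA = setNames(30L, names(mr$taxa)[1])),
                         error_rate = 0, chimera_rate = 0, seed = 9)
  sim <- simulate_community_reads(spec, mr$taxa, "R1", out_dir = d)
  f <- file.path(d, "SampA_L001_R1_001.fastq.gz")
  expect_true(file.exists(f))
  p <- parse_sample_filename(f)
  expect_equal(p$sample_id, "SampA")
  back <- read_sequences(f, "fastq")
  expect_equal(nrow(back), 30)
  expect_identical(back$seq, sim$reads$SampA$seq)
})

test_that("error-free community recovers ground truth end to end at threshold 1.0", {
  mr <- tiny_mock()
  accs <- names(mr$taxa)
  spec <- community_spec(
    samples = list(A = setNames(rep(20L, length(accs)), accs),
                   B = setNames(rep(10L, length(accs)), accs)),
    error_rate = 0, chimera_rate = 0, seed = 13)
  sim <- simulate_community_reads(spec, mr$taxa, "R1")
  pp <- primer_pair()
  seqs <- character(0); samples <- character(0)
  for (s in names(sim$reads)) {
    res <- qc_filter_reads(sim$reads[[s]], pp, "R1", qc_params())
    expect_equal(unname(res$tally["kept"]), unname(res$tally["input"]))
    seqs <- c(seqs, res$kept$seq)
    samples <- c(samples, rep(s, nrow(res$kept)))
  }
  d <- dereplicate(seqs, samples)
  otus <- greedy_cluster(d, cluster_params(identity_threshold = 1.0,
                                           min_cluster_size = 1))
  n_distinct <- length(unique(vapply(mr$taxa, function(t)
    qc_filter_read(substr(t$nuc_full, 1, 300), rep(40L, 300), pp, "R1",
                   qc_params())$seq, character(1))))
  expect_equal(length(otus), n_distinct)
  bt <- build_otu_table(otus, cluster_params(min_cluster_size = 1))
  expect_equal(unname(colSums(bt$table)), c(20L * length(accs),
                                            10L * length(accs)))
  # every OTU classifies back to a source accession with perfect identity
  for (o in bt$otus) {
    cl <- classify_otu(o$centroid, mr$db, otu_id = "x")
    expect_true(cl$target)
    expect_equal(cl$best_hit$pct_identity, 100)
  }
})
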