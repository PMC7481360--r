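test_that("dereplication pools samples, keeps per-sample counts, sorts deterministically", {
  d <- dereplicate(c("ACGT", "ACGT", "ACGT", "ACGT", "TTTT"),
                   c("A", "A", "A", "B", "A"))
  expect_equal(d$seq, c("ACGT", "TTTT"))
  expect_equal(d$size, c(4L, 1L))
  expect_equal(d$counts["ACGT", ], c(A = 3L, B = 1L))
  expect_equal(sum(d$size), 5)

  expect_equal(length(dereplicate(character(0), character(0))$seq), 0)

  # equal sizes tie-break lexicographically
  d2 <- dereplicate(c("TT", "AA"), c("A", "A"))
  expect_equal(d2$seq, c("AA", "TT"))
})

test_that("global identity excludes terminal gaps and matches direct construction", {
  expect_equal(global_identity(strrep("ACGT", 25), strrep("ACGT", 25)), 1.0)
  expect_equal(global_identity("AAAA", "TTTT"), 0.0)
  set.seed(51)
  s <- random_seq(100)
  expect_equal(global_identity(s, mutate_seq(s, 10)), 0.90)
  # a read and its own prefix score 1.0 (terminal gaps excluded)
  expect_equal(global_identity(s, substr(s, 1, 40)), 1.0)
  expect_error(global_identity("", "ACGT"), "empty")
})

test_that("greedy clustering joins first qualifying centroid; 1.0 means exact groups", {
  set.seed(61)
  a <- random_seq(100)
  near <- mutate_seq(a, 10)    # 0.90 identity
  far <- mutate_seq(a, 30)     # 0.70 identity
  d <- dereplicate(c(a, a, near, far), rep("S", 4))
  otus80 <- greedy_cluster(d, cluster_params(identity_threshold = 0.80))
  expect_equal(length(otus80), 2)
  expect_equal(otus80[[1]]$centroid, a)

  # one-mismatch pair at threshold 1.0 stays separate
  d2 <- dereplicate(c(a, mutate_seq(a, 1)), rep("S", 2))
  expect_equal(length(greedy_cluster(d2, cluster_params(identity_threshold = 1.0))), 2)
  expect_equal(length(greedy_cluster(d2, cluster_params(identity_threshold = 0.80))), 1)

  # identical sequences collapse at any threshold
  d3 <- dereplicate(c(a, a), rep("S", 2))
  expect_equal(length(greedy_cluster(d3, cluster_params(identity_threshold = 1.0))), 1)
})

test_that("OTU count is monotone in the identity threshold and stable to read order", {
  set.seed(71)
  base <- replicate(6, random_seq(120))
  reads <- c(base, vapply(base, function(s) mutate_seq(s, 12), character(1)))
  reads <- rep(reads, times = sample(1:4, length(reads), replace = TRUE))
  samples <- sample(c("A", "B"), length(reads), replace = TRUE)
  counts <- vapply(c(0.8, 0.9, 1.0), function(thr) {
    length(greedy_cluster(dereplicate(reads, samples),
                          cluster_params(identity_threshold = thr)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))

  # permutation stability
  perm <- sample(length(reads))
  d1 <- dereplicate(reads, samples)
  d2 <- dereplicate(reads[perm], samples[perm])
  expect_identical(d1$seq, d2$seq)
  expect_identical(d1$counts[, c("A", "B")], d2$counts[, c("A", "B")])
  o1 <- greedy_cluster(d1, cluster_params())
  o2 <- greedy_cluster(d2, cluster_params())
  expect_identical(vapply(o1, `[[`, character(1), "centroid"),
                   vapply(o2, `[[`, character(1), "centroid"))

  # threshold 1.0 clustering is equivalent to dereplication
  o100 <- greedy_cluster(d1, cluster_params(identity_threshold = 1.0))
  expect_equal(length(o100), length(d1$seq))
})

test_that("two-parent chimeras are flagged; parents and copies are not", {
  set.seed(81)
  A <- random_seq(300)
  B <- mutate_seq(A, 30)                     # parents at 0.90 identity
  chim <- paste0(substr(A, 1, 150), substr(B, 151, 300))
  reads <- c(rep(A, 10), rep(B, 10), chim)
  d <- dereplicate(reads, rep("S", length(reads)))
  flagged <- flag_chimeras(d, cluster_params())
  expect_true(chim %in% flagged)
  expect_false(A %in% flagged)
  expect_false(B %in% flagged)

  # single sequence: nothing to flag
  expect_equal(length(flag_chimeras(dereplicate("ACGT", "S"),
                                    cluster_params())), 0)

  # an exact low-abundance copy of a parent cannot beat the single parent
  d2 <- dereplicate(c(rep(A, 10), rep(B, 10), A), rep("S", 21))
  expect_equal(length(flag_chimeras(d2, cluster_params())), 0)
})

test_that("OTU table drops small and chimeric OTUs and conserves reads", {
  set.seed(91)
  a <- random_seq(150); b <- mutate_seq(a, 60); c2 <- mutate_seq(b, 60)
  reads <- c(rep(a, 5), rep(b, 3), c2)
  samples <- c(rep("S1", 5), rep("S2", 3), "S1")
  d <- dereplicate(reads, samples)
  otus <- greedy_cluster(d, cluster_params(identity_threshold = 0.95))
  bt <- build_otu_table(otus, cluster_params(min_cluster_size = 2))
  expect_equal(nrow(bt$table), 2)             # singleton dropped
  expect_equal(unname(bt$discarded["small_otus"]), 1)
  expect_equal(rownames(bt$table), c("OTU_1", "OTU_2"))
  # conservation: table + discards == input reads
  expect_equal(sum(bt$table) + sum(bt$discarded[c("chimera_reads", "small_reads")]),
               length(reads))
  # column sums equal per-sample surviving read counts
  expect_equal(unname(colSums(bt$table)), c(5, 3))

  # min_cluster_size 1 keeps everything
  bt1 <- build_otu_table(otus, cluster_params(min_cluster_size = 1))
  expect_equal(sum(bt1$table), length(reads))

  # chimera-flagged OTU is dropped and counted
  otus_fl <- mark_chimeric_otus(otus, c2)
  bt2 <- build_otu_table(otus_fl, cluster_params(min_cluster_size = 1))
  expect_equal(unname(bt2$discarded["chimera_otus"]), 1)
  expect_equal(sum(bt2$table) + sum(bt2$discarded[c("chimera_reads", "small_reads")]),
               length(reads))
})
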