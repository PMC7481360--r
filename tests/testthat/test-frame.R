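test_that("six-frame translation follows the standard code and strand symmetry", {
  tr <- six_frame_translate("ATGGCC")
  expect_equal(unname(tr["+1"]), "MA")
  expect_equal(unname(six_frame_translate("ATGTAA")["+1"]), "M*")
  expect_error(six_frame_translate("AT"), "3 nt")
  # ambiguous codon resolves when redundancy allows, else X
  expect_equal(unname(six_frame_translate("GGNATN")["+1"]), "GX")
  # frame -1 of the reverse complement equals frame +1
  set.seed(101)
  for (i in 1:20) {
    s <- random_seq(sample(30:90, 1))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(six_frame_translate(rc)[["-1"]],
                 six_frame_translate(s)[["+1"]])
  }
})

test_that("best frame matches the exhaustive all-runs oracle", {
  # clean CDS in frame +1; TTA codons reverse-complement to TAA stops, so
  # the reading frame is unambiguous on both strands
  cds <- paste0("ATG", strrep("TTA", 30), "AAA")
  bf <- best_frame(cds)
  expect_equal(bf$frame, "+1")
  expect_equal(nchar(bf$protein) * 3, bf$nt_span[2] - bf$nt_span[1])
  expect_false(grepl("[*]", bf$protein))
  # reverse complement picks a negative frame with the same protein
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  expect_equal(best_frame(rc)$protein, bf$protein)
  expect_equal(best_frame(rc)$frame, "-1")

  for (i in 1:150) {
    s <- random_seq(sample(60:300, 1))
    got <- best_frame(s)
    want <- best_frame_oracle(s)
    expect_equal(nchar(got$protein), want$len, info = s)
    # same length guaranteed; on frame-order tie the earliest frame wins
  }
  # short runs everywhere flag the sequence as degenerate
  expect_true(best_frame("TAATAGTGATAATAG")$degenerate)
})

test_that("local alignment agrees with an independent DP oracle", {
  B <- blosum62_matrix()
  p <- "MKVLAWFQ"
  al <- sw_align(p, p)
  expect_equal(al$raw_score, sum(diag(B[strsplit(p, "")[[1]],
                                        strsplit(p, "")[[1]]])))
  expect_equal(al$pct_identity, 100)
  expect_equal(sw_align("AAAA", "WWWW")$raw_score, 0)
  expect_error(sw_align("MK1", "MK"), "alphabet")
  set.seed(121)
  aas <- rownames(B)[1:20]
  for (i in 1:60) {
    q <- paste(sample(aas, sample(5:60, 1), TRUE), collapse = "")
    s <- paste(sample(aas, sample(5:60, 1), TRUE), collapse = "")
    expect_equal(sw_align(q, s)$raw_score, sw_oracle(q, s, B), info = paste(q, s))
    # symmetry of the optimal score
    expect_equal(sw_align(q, s)$raw_score, sw_align(s, q)$raw_score)
  }
})

test_that("E-value follows the Karlin-Altschul form", {
  ev0 <- estimate_evalue(0, 200, 10000)
  expect_equal(ev0$evalue, 0.041 * 200 * 10000)
  # linear in database size
  expect_equal(estimate_evalue(50, 200, 20000)$evalue,
               2 * estimate_evalue(50, 200, 10000)$evalue)
  # independent re-evaluation at S = 100
  bit <- (0.267 * 100 - log(0.041)) / log(2)
  ev <- estimate_evalue(100, 200, 10000)
  expect_equal(ev$bit_score, bit)
  expect_equal(ev$evalue, 200 * 10000 * 2^(-bit))
  # strictly decreasing in S
  es <- vapply(seq(0, 200, 20), function(s)
    estimate_evalue(s, 100, 1e4)$evalue, numeric(1))
  expect_true(all(diff(es) < 0))
  expect_error(estimate_evalue(10, 0, 100), "positive")
})

test_that("classification recovers mock taxa and respects tie-breaks", {
  mr <- tiny_mock()
  for (acc in names(mr$taxa)[c(1, 4, 7)]) {
    for (len in c(NA, 300, 150)) {
      s <- mr$taxa[[acc]]$nuc_trimmed
      if (!is.na(len)) s <- substr(s, 1, len)
      cl <- classify_otu(s, mr$db, otu_id = acc)
      expect_true(cl$target)
      expect_equal(cl$best_hit$subject_accession, acc)
      expect_equal(cl$best_hit$pct_identity, 100)
      expect_equal(cl$lineage, mr$taxa[[acc]]$lineage)
    }
  }
  # random non-coding sequence is non-target against the mock database
  set.seed(131)
  nt_hits <- vapply(1:10, function(i) {
    classify_otu(random_seq(200), mr$db)$target
  }, logical(1))
  expect_false(any(nt_hits))

  # identical proteins, distinct accessions: lexicographically smaller wins
  prot <- frame1 <- substr(mr$db$proteins[[1]], 1, 60)
  db2 <- acetoscan:::build_reference_db(
    setNames(rep(prot, 2), c("ZZ2", "AA1")),
    data.frame(accession = c("ZZ2", "AA1"), domain = "B", phylum = "P",
               class = "C", order = "O", family = "F", genus = c("G1", "G2"),
               species = c("s1", "s2")))
  cl <- classify_otu(mr$taxa[[1]]$nuc_trimmed, db2)
  expect_equal(cl$best_hit$subject_accession, "AA1")

  # classification is invariant to database entry order (canonical load order)
  expect_equal(classify_otu(mr$taxa[[2]]$nuc_trimmed, mr$db)$best_hit$subject_accession,
               names(mr$taxa)[2])
})

test_that("rank labels render annotated, nearest-ancestor .NA, and Unclassified", {
  lin <- setNames(c("Bacteria", "Firmicutes", "Clostridia", "Clostridiales",
                    "Tepidimicrobiaceae", "Tepidimicrobium", NA),
                  c("domain", "phylum", "class", "order", "family", "genus",
                    "species"))
  expect_equal(render_rank_label(lin, "species"), "Tepidimicrobium.NA")
  expect_equal(render_rank_label(lin, "genus"), "Tepidimicrobium")
  lin2 <- lin; lin2[5:7] <- NA
  expect_equal(render_rank_label(lin2, "genus"), "Clostridiales.NA")
  expect_equal(render_rank_label(setNames(rep(NA_character_, 7),
                                          names(lin)), "genus"),
               "Unclassified")
  expect_equal(render_rank_label(NULL, "genus"), "Unclassified")
})
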