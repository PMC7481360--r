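# aa -> synonymous codon table from the standard genetic code
codon_table <- function() {
  if (is.null(.pkg_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_cache$codons <- split(names(gc), unname(gc))
  }
  .pkg_cache$codons
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

revcomp <- function(x) {
  vapply(x, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1), USE.NAMES = FALSE)
}

# concrete instantiation of a degenerate pattern (one base per symbol)
instantiate_pattern <- function(pattern) {
  choices <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"), I = c("A", "C", "G", "T"))
  ch <- strsplit(pattern, "")[[1]]
  paste(vapply(ch, function(s) sample(choices[[s]], 1), character(1)),
        collapse = "")
}

mutate_protein <- function(p, rate) {
  aa <- strsplit(p, "")[[1]]
  k <- round(rate * length(aa))
  if (k > 0) {
    pos <- sample(length(aa), k)
    aa[pos] <- vapply(aa[pos], function(a) sample(setdiff(AA20, a), 1),
                      character(1))
  }
  paste(aa, collapse = "")
}

random_codon_for <- function(aa) {
  vapply(aa, function(a) sample(codon_table()[[a]], 1), character(1),
         USE.NAMES = FALSE)
}

#' Build a synthetic reference database of primer-flanked amplicons
#'
#' Generates a hierarchical synthetic taxonomy (genera grouped two per
#' family, families three per phylum), one ancestral protein per genus, and
#' per-genus sequence variants. Each amplicon (`nuc_trimmed`) is laid out as
#' a concrete instantiation of the forward primer (23 nt), one pad base,
#' `196 +/- 2` internal codons and the reverse-complemented instantiation of
#' the reverse primer (23 nt), for a total of 635 +/- 6 nt, and translates
#' stop-free in reading frame +1; both primer regions are stop-free in that
#' frame for every degenerate instantiation, and the pad base keeps the
#' internal codons frame-aligned. The reference protein of each entry is
#' that frame +1 translation (~211 residues). Amino-acid divergence along
#' the hierarchy is 0.40 (root to phylum), 0.25 (phylum to family) and 0.18
#' (family to genus); within a genus, variants diverge by `divergence` with
#' a synonymous codon redraw rate of 0.15, placing within-genus nucleotide
#' identity near 0.90 and between-genus identity near 0.72 - either side of
#' the 0.80 clustering default. Full-length records add random 30-60 nt
#' flanks on both sides. Deterministic under `seed`.
#'
#' @param n_genera number of genera (>= 2).
#' @param variants_per_genus sequence variants per genus (default 1).
#' @param divergence within-genus amino-acid divergence, in (0, 0.5).
#' @param seed integer seed (mandatory).
#' @param conserved_prefix_aa if > 0, the first `3 * conserved_prefix_aa`
#'   nucleotides (primer included) are identical across all taxa - used to
#'   emulate a marker whose 5' region is uninformative.
#' @return list with `db` (a `reference_db`, including nucleotides) and
#'   `taxa` (per-entry records with `accession`, `lineage`, `protein`,
#'   `nuc_trimmed`, `nuc_full`).
#' @export
build_mock_reference <- function(n_genera = 20, variants_per_genus = 1,
                                 divergence = 0.05, seed,
                                 conserved_prefix_aa = 0) {
  stopifnot(n_genera >= 2, divergence > 0, divergence < 0.5,
            variants_per_genus >= 1)
  if (missing(seed)) stop("seed is mandatory")
  primers <- primer_pair()
  withr::with_seed(seed, {
    root_len <- 198L
    root_prot <- paste(sample(AA20, root_len, replace = TRUE), collapse = "")
    n_fam <- ceiling(n_genera / 2)
    n_phy <- ceiling(n_fam / 3)
    phy_prot <- vapply(seq_len(n_phy), function(p)
      mutate_protein(root_prot, 0.40), character(1))
    fam_prot <- vapply(seq_len(n_fam), function(f)
      mutate_protein(phy_prot[(f - 1) %/% 3 + 1], 0.25), character(1))
    gen_len <- 196L + sample(-2:2, n_genera, replace = TRUE)
    gen_prot <- vapply(seq_len(n_genera), function(g)
      substr(mutate_protein(fam_prot[(g - 1) %/% 2 + 1], 0.18), 1, gen_len[g]),
      character(1))
    # distinguishability guard on genus ancestors
    for (i in seq_len(n_genera - 1)) for (j in (i + 1):n_genera) {
      a <- strsplit(gen_prot[i], "")[[1]]; b <- strsplit(gen_prot[j], "")[[1]]
      L <- min(length(a), length(b))
      if (mean(a[seq_len(L)] == b[seq_len(L)]) > 0.97)
        stop("inter-genus protein identity > 0.97; taxa not distinguishable")
    }
    gen_codons <- lapply(gen_prot, function(p)
      random_codon_for(strsplit(p, "")[[1]]))
    root_head <- paste0(instantiate_pattern(primers$fwd), sample(c("A","C","G","T"), 1))
    root_internal <- paste(random_codon_for(strsplit(root_prot, "")[[1]]),
                           collapse = "")
    taxa <- list()
    idx <- 0L
    for (g in seq_len(n_genera)) {
      fam <- (g - 1) %/% 2 + 1
      phy <- (fam - 1) %/% 3 + 1
      for (v in seq_len(variants_per_genus)) {
        idx <- idx + 1L
        aa <- strsplit(gen_prot[g], "")[[1]]
        codons <- gen_codons[[g]]
        k <- round(divergence * length(aa))
        if (variants_per_genus > 1 && k > 0) {
          # variants must stay distinguishable at every analyzed read length,
          # so at least two substitutions land within the first 40 internal
          # codons (covered even by 150 nt reads)
          front <- sample(5:40, min(2L, k))
          pos <- c(front, sample(setdiff(seq_along(aa), front),
                                 k - length(front)))
          aa[pos] <- vapply(aa[pos], function(a) sample(setdiff(AA20, a), 1),
                            character(1))
          codons[pos] <- random_codon_for(aa[pos])
        }
        syn <- runif(length(aa)) < 0.15
        if (any(syn)) codons[syn] <- random_codon_for(aa[syn])
        head <- paste0(instantiate_pattern(primers$fwd),
                       sample(c("A", "C", "G", "T"), 1))
        tail <- revcomp(instantiate_pattern(primers$rev))
        nuc <- paste0(head, paste(codons, collapse = ""), tail)
        if (conserved_prefix_aa > 0) {
          pre <- substr(paste0(root_head, root_internal), 1,
                        3L * conserved_prefix_aa)
          nuc <- paste0(pre, substr(nuc, nchar(pre) + 1L, nchar(nuc)))
        }
        flank5 <- paste(sample(c("A", "C", "G", "T"), sample(30:60, 1),
                               replace = TRUE), collapse = "")
        flank3 <- paste(sample(c("A", "C", "G", "T"), sample(30:60, 1),
                               replace = TRUE), collapse = "")
        acc <- sprintf("MOCK%04d", idx)
        taxa[[acc]] <- list(
          accession = acc,
          lineage = stats::setNames(
            c("Bacteria", sprintf("Phylum_%d", phy), sprintf("Class_%d", phy),
              sprintf("Order_%d", phy), sprintf("Family_%d", fam),
              sprintf("Genus_%d", g), sprintf("Genus_%d_sp%d", g, v)), RANKS),
          protein = frame1_protein(nuc),
          nuc_trimmed = nuc,
          nuc_full = paste0(flank5, nuc, flank3))
      }
    }
    tax_df <- do.call(rbind, lapply(taxa, function(t)
      data.frame(accession = t$accession, as.list(t$lineage),
                 stringsAsFactors = FALSE)))
    rownames(tax_df) <- NULL
    db <- build_reference_db(
      stats::setNames(vapply(taxa, `[[`, character(1), "protein"),
                      names(taxa)),
      tax_df,
      nuc = stats::setNames(vapply(taxa, `[[`, character(1), "nuc_trimmed"),
                            names(taxa)))
    list(db = db, taxa = taxa)
  })
}

frame1_protein <- function(nuc) {
  L <- nchar(nuc)
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nuc, 1, 3L * (L %/% 3L)))))
}

#' Derive the four read-length datasets from mock taxa
#'
#' `full` is the flanked molecule, `trimmed` the primer-to-primer amplicon,
#' and `d300` / `d150` are 5' prefixes of `trimmed` of exactly 300 and
#' 150 nt (the read lengths of short-read chemistries).
#'
#' @param taxa the `taxa` element of [build_mock_reference()].
#' @return named list of four `seq_records` (`full`, `trimmed`, `d300`,
#'   `d150`).
#' @export
derive_length_datasets <- function(taxa) {
  ids <- names(taxa)
  trimmed <- vapply(taxa, `[[`, character(1), "nuc_trimmed")
  full <- vapply(taxa, `[[`, character(1), "nuc_full")
  if (any(nchar(trimmed) < 300))
    stop("trimmed amplicon shorter than requested 300 nt prefix")
  list(full = seq_records(ids, unname(full)),
       trimmed = seq_records(ids, unname(trimmed)),
       d300 = seq_records(ids, substr(unname(trimmed), 1, 300)),
       d150 = seq_records(ids, substr(unname(trimmed), 1, 150)))
}

#' Convert FASTA records to constant-quality FASTQ
#'
#' Assigns every base the same quality character (default `I`, Phred 40,
#' which survives Phred-20 trimming untouched).
#'
#' @param records `seq_records` without qualities.
#' @param quality_char single quality character (Phred+33).
#' @return `seq_records` with qualities.
#' @export
fasta_to_fastq <- function(records, quality_char = "I") {
  q <- utf8ToInt(quality_char) - 33L
  seq_records(records$id, records$seq,
              lapply(nchar(records$seq), function(L) rep(q, L)))
}

#' Community specification for read simulation
#'
#' @param samples named list: sample id -> named integer vector of intended
#'   read counts per accession.
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param chimera_rate fraction of reads replaced by two-parent chimeras;
#'   the count is exact (`round(rate * n)` per sample), not binomial.
#' @param seed integer seed (mandatory).
#' @return list of class `community_spec`.
#' @export
community_spec <- function(samples, error_rate = 0, chimera_rate = 0, seed) {
  stopifnot(error_rate >= 0, error_rate < 1, chimera_rate >= 0, chimera_rate < 1)
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(unlist(samples) >= 0))
  structure(list(samples = samples, error_rate = error_rate,
                 chimera_rate = chimera_rate, seed = seed),
            class = "community_spec")
}

#' Simulate per-sample amplicon reads with ground truth
#'
#' R1 reads are the 5' 300 nt of the flanked molecule (forward primer
#' included); R2 reads the 5' 300 nt of its reverse complement (reverse
#' primer included). Substitution errors are injected per base at
#' `error_rate` with the quality dropped to Phred 14 at error positions
#' (Phred 40 elsewhere). An exact `round(chimera_rate * n)` of each sample's
#' reads are replaced by single-crossover joins of two distinct taxa's
#' amplicons. Output files follow the `<sample>_L001_R<1|2>_001.fastq.gz`
#' naming convention. Deterministic under the spec's seed.
#'
#' @param spec a [community_spec()].
#' @param taxa the `taxa` element of [build_mock_reference()].
#' @param read_type `"R1"` or `"R2"`.
#' @param out_dir if non-NULL, gzipped FASTQ files and a `ground_truth.tsv`
#'   are written there.
#' @return list with `reads` (named list of `seq_records` per sample),
#'   `truth` (data frame: read_id, sample, source, errors_introduced) and
#'   `files`.
#' @export
simulate_community_reads <- function(spec, taxa, read_type = c("R1", "R2"),
                                     out_dir = NULL) {
  read_type <- match.arg(read_type)
  accs_all <- names(taxa)
  bad <- setdiff(unique(unlist(lapply(spec$samples, names))), accs_all)
  if (length(bad)) stop("unknown accession in community spec: ", bad[1])
  base_read <- function(nuc) substr(nuc, 1, 300)
  withr::with_seed(spec$seed, {
    out_reads <- list(); truth <- list(); files <- character(0)
    for (s in names(spec$samples)) {
      counts <- spec$samples[[s]]
      counts <- counts[counts > 0]
      src <- rep(names(counts), counts)
      n <- length(src)
      n_chi <- round(spec$chimera_rate * n)
      if (n_chi > 0) {
        if (length(accs_all) < 2)
          stop("chimera simulation needs at least 2 taxa")
        # replace reads of the most abundant taxa, round-robin
        drop_from <- rep(names(sort(counts, decreasing = TRUE)),
                         length.out = n_chi)
        for (a in drop_from) src[match(a, src)] <- NA
        src <- src[!is.na(src)]
      }
      seqs <- character(n); sources <- character(n); nerr <- integer(n)
      quals <- vector("list", n)
      for (i in seq_along(src)) {
        mol <- if (read_type == "R1") taxa[[src[i]]]$nuc_full
               else revcomp(taxa[[src[i]]]$nuc_full)
        seqs[i] <- base_read(mol)
        sources[i] <- src[i]
      }
      if (n_chi > 0) {
        pairs_a <- sample(accs_all, n_chi, replace = TRUE)
        pairs_b <- vapply(pairs_a, function(a)
          sample(setdiff(accs_all, a), 1), character(1))
        for (k in seq_len(n_chi)) {
          ta <- taxa[[pairs_a[k]]]$nuc_trimmed
          tb <- taxa[[pairs_b[k]]]$nuc_trimmed
          L <- min(nchar(ta), nchar(tb))
          x <- sample(seq(floor(0.3 * L), ceiling(0.7 * L)), 1)
          chim <- paste0(substr(ta, 1, x), substr(tb, x + 1, nchar(tb)))
          i <- length(src) + k
          mol <- if (read_type == "R1") chim else revcomp(chim)
          seqs[i] <- base_read(mol)
          sources[i] <- sprintf("%s+%s@%d", pairs_a[k], pairs_b[k], x)
        }
      }
      for (i in seq_len(n)) {
        L <- nchar(seqs[i])
        q <- rep(40L, L)
        if (spec$error_rate > 0) {
          err <- which(runif(L) < spec$error_rate)
          if (length(err)) {
            ch <- strsplit(seqs[i], "")[[1]]
            ch[err] <- vapply(ch[err], function(b)
              sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
            seqs[i] <- paste(ch, collapse = "")
            q[err] <- 14L
          }
          nerr[i] <- length(err)
        }
        quals[[i]] <- q
      }
      ids <- sprintf("%s_read%05d", s, seq_len(n))
      out_reads[[s]] <- seq_records(ids, seqs, quals)
      truth[[s]] <- data.frame(read_id = ids, sample = s, source = sources,
                               errors_introduced = nerr,
                               stringsAsFactors = FALSE)
      if (!is.null(out_dir)) {
        f <- file.path(out_dir, sprintf("%s_L001_%s_001.fastq.gz", s, read_type))
        write_sequences(out_reads[[s]], f, "fastq", gzipped = TRUE)
        files <- c(files, f)
      }
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    if (!is.null(out_dir)) {
      utils::write.table(truth, file.path(out_dir, "ground_truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, file.path(out_dir, "ground_truth.tsv"))
    }
    list(reads = out_reads, truth = truth, files = files)
  })
}
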