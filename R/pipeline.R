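#' Pipeline run configuration
#'
#' Defaults are the pipeline's published parameter set: quality cutoff 20,
#' length bounds 120-300 nt, clustering threshold 0.80, minimum cluster
#' size 2, E-value cutoff 1e-3.
#'
#' @param input_dir directory of `<sample>_L001_R<1|2>_001.fastq[.gz]` files.
#' @param output_dir results directory (created if needed).
#' @param read_type `"R1"` or `"R2"`; only files of this read type are used.
#' @param db_fasta,db_tax reference protein FASTA and taxonomy TSV paths
#'   (alternatively pass a prebuilt `reference_db` to [run_acetoscan()]).
#' @param qc a [qc_params()].
#' @param cluster a [cluster_params()].
#' @param evalue_cutoff E-value cutoff for target filtering (default 1e-3).
#' @param bootstraps bootstrap replicates for the tree (default 100).
#' @param primers a [primer_pair()].
#' @param seed integer seed (bootstrap reproducibility).
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir, read_type = "R1",
                       db_fasta = NULL, db_tax = NULL,
                       qc = qc_params(), cluster = cluster_params(),
                       evalue_cutoff = 1e-3, bootstraps = 100,
                       primers = primer_pair(), seed = 1) {
  stopifnot(read_type %in% c("R1", "R2"))
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 read_type = read_type, db_fasta = db_fasta, db_tax = db_tax,
                 qc = qc, cluster = cluster, evalue_cutoff = evalue_cutoff,
                 bootstraps = bootstraps, primers = primers, seed = seed),
            class = "run_config")
}

list_input_files <- function(input_dir, read_type) {
  all <- list.files(input_dir, pattern = "_001\\.fastq(\\.gz)?$",
                    full.names = TRUE)
  parsed <- lapply(all, function(f)
    tryCatch(parse_sample_filename(f), error = function(e) NULL))
  parsed <- parsed[!vapply(parsed, is.null, logical(1))]
  sel <- Filter(function(p) p$read_type == read_type, parsed)
  if (length(sel) == 0) {
    cand <- vapply(parsed, function(p)
      sprintf("%s (%s)", basename(p$path), p$read_type), character(1))
    stop("no ", read_type, " input files in ", input_dir,
         if (length(cand)) paste0("; candidates found: ",
                                  paste(cand, collapse = ", ")) else "")
  }
  sel[order(vapply(sel, `[[`, character(1), "sample_id"))]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full amplicon analysis pipeline
#'
#' Executes the four stages in order: (1) primer/quality filtering of every
#' input file of the selected read type; (2) joint dereplication, de novo
#' chimera flagging, greedy centroid clustering, OTU table construction and
#' translated-search taxonomic classification; (3) multiple sequence
#' alignment of target OTU centroids and a neighbor-joining tree with
#' bootstrap supports; (4) rank-collapsed abundance tables, minor-taxon
#' merging, diversity summaries and stacked-bar plots. A machine-readable
#' manifest (parameters, per-stage read counts, content hashes of every
#' output) is written alongside the results. With a fixed seed the run is
#' fully deterministic. A run that ends with zero surviving OTUs completes
#' with empty tables and a warning rather than an error.
#'
#' @param config a [run_config()].
#' @param db optional prebuilt `reference_db` (otherwise loaded from the
#'   config's `db_fasta`/`db_tax`).
#' @return list with `otu_table`, `otus`, `classifications`, `rank_tables`,
#'   `tree`, `manifest` and `output_dir`, invisibly classed
#'   `acetoscan_result`.
#' @export
run_acetoscan <- function(config, db = NULL) {
  if (is.null(db)) db <- load_reference_db(config$db_fasta, config$db_tax)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  log_lines <- character(0)
  logi <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  # stage 1: QC
  files <- list_input_files(config$input_dir, config$read_type)
  qc_rows <- list(); seqs <- character(0); samples <- character(0)
  for (f in files) {
    recs <- read_sequences(f$path, "fastq")
    res <- qc_filter_reads(recs, config$primers, config$read_type, config$qc)
    qc_rows[[f$sample_id]] <- data.frame(sample = f$sample_id,
                                         t(res$tally))
    seqs <- c(seqs, res$kept$seq)
    samples <- c(samples, rep(f$sample_id, nrow(res$kept)))
    logi("qc: %s %d reads in, %d kept", f$sample_id, res$tally["input"],
         res$tally["kept"])
  }
  qc_report <- do.call(rbind, qc_rows)
  write_tsv(qc_report, out("qc_report.tsv"))

  # stage 2: dereplication, chimeras, clustering, classification
  derep <- dereplicate(seqs, samples)
  logi("derep: %d reads -> %d unique", length(seqs), length(derep$seq))
  flagged <- if (config$cluster$chimera_check)
    flag_chimeras(derep, config$cluster) else character(0)
  logi("chimera: %d unique sequences flagged", length(flagged))
  otus_raw <- greedy_cluster(derep, config$cluster)
  otus_raw <- mark_chimeric_otus(otus_raw, flagged)
  bt <- build_otu_table(otus_raw, config$cluster)
  logi("cluster: %d clusters, %d kept (%d chimeric, %d below min size)",
       length(otus_raw), nrow(bt$table), bt$discarded["chimera_otus"],
       bt$discarded["small_otus"])
  if (nrow(bt$table) == 0)
    warning("zero surviving OTUs; writing empty outputs")
  centroids <- stats::setNames(
    vapply(bt$otus, `[[`, character(1), "centroid"),
    rownames(bt$table))
  write_sequences(seq_records(names(centroids), unname(centroids)),
                  out("otus.fasta"), "fasta")
  write_tsv(data.frame(otu_id = rownames(bt$table), bt$table,
                       check.names = FALSE),
            out("otu_table.tsv"))
  cls <- lapply(names(centroids), function(oid)
    classify_otu(centroids[[oid]], db, config$evalue_cutoff, otu_id = oid))
  names(cls) <- names(centroids)
  target <- vapply(cls, `[[`, logical(1), "target")
  logi("classify: %d/%d OTUs are targets", sum(target), length(cls))
  cls_df <- do.call(rbind, lapply(cls[target], function(x)
    data.frame(otu_id = x$otu_id, accession = x$best_hit$subject_accession,
               pct_identity = x$best_hit$pct_identity,
               evalue = x$best_hit$evalue, bit_score = x$best_hit$bit_score,
               as.list(x$lineage), stringsAsFactors = FALSE)))
  if (is.null(cls_df))
    cls_df <- data.frame(otu_id = character(0), accession = character(0),
                         pct_identity = numeric(0), evalue = numeric(0),
                         bit_score = numeric(0))
  write_tsv(cls_df, out("classification.tsv"))
  nt_df <- data.frame(otu_id = names(cls)[!target],
                      reason = vapply(cls[!target], function(x)
                        as.character(x$reason), character(1)))
  write_tsv(nt_df, out("non_target.tsv"))

  # stage 3: alignment + tree over target OTUs
  tree <- NULL
  target_ids <- names(centroids)[target]
  if (length(target_ids) >= 2) {
    msa <- progressive_msa(centroids[target_ids])
    write_sequences(seq_records(names(msa), unname(msa)),
                    out("otus.aln.fasta"), "fasta")
    if (length(target_ids) >= 3) {
      tree <- bootstrap_supports(msa, B = config$bootstraps,
                                 seed = config$seed)
      write_newick(tree, out("otus.nwk"))
      logi("tree: %d leaves, %d bootstrap replicates", length(target_ids),
           config$bootstraps)
    } else logi("tree: skipped (<3 target OTUs)")
  } else logi("alignment/tree: skipped (<2 target OTUs)")

  # stage 4: community summaries
  rank_tables <- list()
  if (sum(target) > 0) {
    tab_target <- bt$table[target_ids, , drop = FALSE]
    for (rank in RANKS[-1]) {
      rt <- collapse_rank(tab_target, cls[target_ids], rank)
      rank_tables[[rank]] <- rt
      merged <- merge_minor(rt)
      ra <- sweep(merged$counts, 2, pmax(colSums(merged$counts), 1), "/")
      utils::write.csv(data.frame(label = rownames(ra), ra,
                                  check.names = FALSE),
                       out(sprintf("abundance_%s.csv", rank)),
                       row.names = FALSE)
      plot_rank_barplot(merged, out(sprintf("abundance_%s.svg", rank)))
    }
    utils::write.csv(alpha_diversity(bt$table), out("alpha_diversity.csv"),
                     row.names = FALSE)
    if (ncol(bt$table) >= 2) {
      bc <- bray_curtis(bt$table)
      write_tsv(data.frame(sample = rownames(bc), bc, check.names = FALSE),
                out("bray_curtis.tsv"))
    }
  }

  writeLines(log_lines, out("run.log"))
  outputs <- sort(list.files(config$output_dir, full.names = TRUE))
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    parameters = list(read_type = config$read_type,
                      quality_cutoff = config$qc$quality_cutoff,
                      min_length = config$qc$min_length,
                      max_length = config$qc$max_length,
                      primer_error_rate = config$qc$primer_error_rate,
                      identity_threshold = config$cluster$identity_threshold,
                      min_cluster_size = config$cluster$min_cluster_size,
                      chimera_check = config$cluster$chimera_check,
                      evalue_cutoff = config$evalue_cutoff,
                      bootstraps = config$bootstraps, seed = config$seed),
    stage_counts = list(
      input_reads = sum(qc_report$input),
      qc_kept = sum(qc_report$kept),
      unique_sequences = length(derep$seq),
      clusters = length(otus_raw),
      otus = nrow(bt$table),
      chimera_discarded_reads = unname(bt$discarded["chimera_reads"]),
      size_discarded_reads = unname(bt$discarded["small_reads"]),
      target_otus = sum(target)),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(structure(list(otu_table = bt$table, otus = bt$otus,
                           classifications = cls, rank_tables = rank_tables,
                           tree = tree, manifest = manifest,
                           output_dir = config$output_dir),
                      class = "acetoscan_result"))
}

#' Filter a FASTA to sequences matching the reference
#'
#' Keeps sequences whose best-reading-frame protein hits the reference
#' database at or below the E-value cutoff; emits both the retained
#' nucleotide records and their best-frame proteins.
#'
#' @param fasta_in input FASTA path, or a `seq_records`.
#' @param db a `reference_db`.
#' @param evalue_cutoff E-value cutoff (default 1e-3).
#' @param out_prefix if non-NULL, writes `<prefix>.filtered.fasta` and
#'   `<prefix>.proteins.fasta`.
#' @return list with `kept` (`seq_records`), `proteins` (`seq_records`),
#'   `classifications` and `rejected` ids.
#' @export
acetocheck <- function(fasta_in, db, evalue_cutoff = 1e-3, out_prefix = NULL) {
  recs <- if (is.data.frame(fasta_in)) fasta_in
          else read_sequences(fasta_in, "fasta")
  if (nrow(recs) == 0) warning("empty input FASTA")
  cls <- lapply(seq_len(nrow(recs)), function(i)
    classify_otu(recs$seq[i], db, evalue_cutoff, otu_id = recs$id[i]))
  keep <- vapply(cls, `[[`, logical(1), "target")
  kept <- recs[keep, , drop = FALSE]
  prots <- vapply(which(keep), function(i)
    best_frame(recs$seq[i])$protein, character(1))
  proteins <- seq_records(recs$id[keep], if (length(prots)) prots else character(0))
  if (!is.null(out_prefix)) {
    write_sequences(kept, paste0(out_prefix, ".filtered.fasta"), "fasta")
    write_sequences(proteins, paste0(out_prefix, ".proteins.fasta"), "fasta")
  }
  list(kept = kept, proteins = proteins, classifications = cls[keep],
       rejected = recs$id[!keep])
}

#' Filter plus taxonomic annotation
#'
#' [acetocheck()] followed by per-sequence taxonomy from the best hit.
#'
#' @inheritParams acetocheck
#' @return the [acetocheck()] result plus `taxonomy`, a data frame with one
#'   row per retained sequence.
#' @export
acetotax <- function(fasta_in, db, evalue_cutoff = 1e-3, out_prefix = NULL) {
  chk <- acetocheck(fasta_in, db, evalue_cutoff, out_prefix)
  tax <- do.call(rbind, lapply(chk$classifications, function(x)
    data.frame(id = x$otu_id, accession = x$best_hit$subject_accession,
               pct_identity = x$best_hit$pct_identity,
               evalue = x$best_hit$evalue, as.list(x$lineage),
               stringsAsFactors = FALSE)))
  if (is.null(tax)) tax <- data.frame(id = character(0))
  rownames(tax) <- NULL
  if (!is.null(out_prefix)) write_tsv(tax, paste0(out_prefix, ".taxonomy.tsv"))
  c(chk, list(taxonomy = tax))
}

#' Filter, annotate and build a phylogeny
#'
#' [acetotax()] followed by multiple sequence alignment and an NJ tree with
#' bootstrap supports over the retained sequences. With fewer than three
#' retained sequences the tree is skipped with a warning.
#'
#' @inheritParams acetocheck
#' @param bootstraps bootstrap replicates (default 100).
#' @param seed integer seed.
#' @return the [acetotax()] result plus `msa` and `tree` (or NULL).
#' @export
acetotree <- function(fasta_in, db, evalue_cutoff = 1e-3, out_prefix = NULL,
                      bootstraps = 100, seed = 1) {
  tx <- acetotax(fasta_in, db, evalue_cutoff, out_prefix)
  msa <- NULL; tree <- NULL
  if (nrow(tx$kept) >= 2) {
    msa <- progressive_msa(stats::setNames(tx$kept$seq, tx$kept$id))
    if (nrow(tx$kept) >= 3) {
      tree <- bootstrap_supports(msa, B = bootstraps, seed = seed)
      if (!is.null(out_prefix)) {
        write_sequences(seq_records(names(msa), unname(msa)),
                        paste0(out_prefix, ".aln.fasta"), "fasta")
        write_newick(tree, paste0(out_prefix, ".nwk"))
      }
    } else warning("fewer than 3 retained sequences; tree skipped")
  } else warning("fewer than 2 retained sequences; alignment and tree skipped")
  c(tx, list(msa = msa, tree = tree))
}
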