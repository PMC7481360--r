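#' @useDynLib acetoscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# seven-rank lineage order used throughout
RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

NUC_ALPHABET <- c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "I")
PROT_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                   "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

#' Construct a set of sequence records
#'
#' Records are stored as a data frame with columns `id` (character), `seq`
#' (character) and `qual` (a list column of integer Phred scores, or `NULL`
#' entries for records without qualities).
#'
#' @param id character vector of identifiers.
#' @param seq character vector of sequences.
#' @param qual optional list of integer Phred score vectors (one per record),
#'   each the same length as its sequence.
#' @return a `data.frame` with class `seq_records`.
#' @export
seq_records <- function(id, seq, qual = NULL) {
  stopifnot(length(id) == length(seq))
  if (any(!nzchar(seq))) stop("sequences must be non-empty")
  if (is.null(qual)) qual <- vector("list", length(seq))
  stopifnot(length(qual) == length(seq))
  for (i in seq_along(qual)) {
    if (!is.null(qual[[i]]) && length(qual[[i]]) != nchar(seq[[i]]))
      stop(sprintf("record %d: quality length %d != sequence length %d",
                   i, length(qual[[i]]), nchar(seq[[i]])))
  }
  out <- data.frame(id = as.character(id), seq = toupper(as.character(seq)),
                    stringsAsFactors = FALSE)
  out$qual <- qual
  class(out) <- c("seq_records", "data.frame")
  out
}

is_gzipped_path <- function(path) grepl("\\.gz$", path)

open_text <- function(path, mode, gzipped) {
  if (gzipped) gzfile(path, mode) else file(path, mode)
}

#' Read sequences from a FASTA or FASTQ file
#'
#' FASTQ qualities are decoded from the Phred+33 encoding (the only supported
#' encoding; `encoding = "phred64"` is rejected). Gzip compression is handled
#' transparently. Identifiers are taken up to the first whitespace.
#'
#' @param path input file.
#' @param format `"fasta"` or `"fastq"`.
#' @param gzipped logical; `NA` (default) auto-detects from a `.gz` suffix.
#' @param encoding FASTQ quality encoding; only `"phred33"` is supported.
#' @return a `seq_records` data frame (empty for an empty file).
#' @export
read_sequences <- function(path, format = c("fasta", "fastq"), gzipped = NA,
                           encoding = "phred33") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (!identical(encoding, "phred33"))
    stop("unsupported FASTQ quality encoding '", encoding,
         "'; only phred33 is supported")
  if (is.na(gzipped)) gzipped <- is_gzipped_path(path)
  con <- open_text(path, "rt", gzipped)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0) return(seq_records(character(), character()))
  if (format == "fasta") parse_fasta_lines(lines) else parse_fastq_lines(lines)
}

parse_fasta_lines <- function(lines, alphabet = NULL) {
  starts <- grep("^>", lines)
  if (length(starts) == 0 || starts[1] != 1)
    stop("malformed FASTA: first line does not start with '>'")
  ends <- c(starts[-1] - 1, length(lines))
  ids <- character(length(starts))
  seqs <- character(length(starts))
  for (k in seq_along(starts)) {
    header <- sub("^>", "", lines[starts[k]])
    ids[k] <- strsplit(header, "[ \t]")[[1]][1]
    if (ends[k] < starts[k] + 1)
      stop(sprintf("malformed FASTA record %d ('%s'): no sequence lines",
                   k, ids[k]))
    seqs[k] <- paste(lines[(starts[k] + 1):ends[k]], collapse = "")
    if (!nzchar(seqs[k]))
      stop(sprintf("malformed FASTA record %d ('%s'): empty sequence", k, ids[k]))
  }
  seq_records(ids, seqs)
}

parse_fastq_lines <- function(lines) {
  if (length(lines) %% 4 != 0)
    stop(sprintf("truncated FASTQ: %d lines is not a multiple of 4 (record %d)",
                 length(lines), length(lines) %/% 4 + 1))
  n <- length(lines) %/% 4
  ids <- character(n); seqs <- character(n); quals <- vector("list", n)
  for (k in seq_len(n)) {
    i <- 4 * (k - 1) + 1
    if (!startsWith(lines[i], "@"))
      stop(sprintf("malformed FASTQ record %d: header does not start with '@'", k))
    if (!startsWith(lines[i + 2], "+"))
      stop(sprintf("malformed FASTQ record %d: separator line missing", k))
    ids[k] <- strsplit(sub("^@", "", lines[i]), "[ \t]")[[1]][1]
    seqs[k] <- lines[i + 1]
    q <- utf8ToInt(lines[i + 3]) - 33L
    if (length(q) != nchar(seqs[k]))
      stop(sprintf(
        "malformed FASTQ record %d ('%s'): %d quality characters for %d bases",
        k, ids[k], length(q), nchar(seqs[k])))
    if (any(q < 0))
      stop(sprintf("malformed FASTQ record %d: quality character below '!'", k))
    quals[[k]] <- q
  }
  seq_records(ids, seqs, quals)
}

#' Write sequences to a FASTA or FASTQ file
#'
#' The writer is intentionally verbatim: duplicate identifiers are written
#' as-is with a warning. FASTQ output requires qualities on every record.
#' Round-trips through [read_sequences()] are bit-exact on id, sequence and
#' qualities.
#'
#' @param records a `seq_records` data frame.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @param gzipped logical; `NA` auto-detects from the path suffix.
#' @return the path, invisibly.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq"),
                            gzipped = NA) {
  format <- match.arg(format)
  if (is.na(gzipped)) gzipped <- is_gzipped_path(path)
  if (anyDuplicated(records$id))
    warning("duplicate record ids written verbatim")
  lines <- character(0)
  if (nrow(records) > 0) {
    if (format == "fasta") {
      lines <- as.vector(rbind(paste0(">", records$id), records$seq))
    } else {
      if (any(vapply(records$qual, is.null, logical(1))))
        stop("FASTQ output requires qualities on every record")
      qstr <- vapply(records$qual,
                     function(q) intToUtf8(q + 33L), character(1))
      lines <- as.vector(rbind(paste0("@", records$id), records$seq,
                               "+", qstr))
    }
  }
  con <- open_text(path, "wt", gzipped)
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Parse an Illumina-style sample filename
#'
#' Accepts basenames of the form `<sample>_L<lane>_R<1|2>_001.fastq[.gz]`;
#' the sample id is everything before the `_L<lane>` token and the read type
#' comes from the `_R1_` / `_R2_` token, never from file content.
#'
#' @param filename a path or basename.
#' @return a list with `path`, `sample_id`, `read_type` and `lane`.
#' @export
parse_sample_filename <- function(filename) {
  base <- basename(filename)
  m <- regmatches(base,
                  regexec("^(.+)_L(\\d+)_R([12])_001\\.fastq(\\.gz)?$", base))[[1]]
  if (length(m) == 0)
    stop("filename '", base, "' does not match the expected pattern ",
         "'<sample>_L<lane>_R<1|2>_001.fastq[.gz]'")
  list(path = filename, sample_id = m[2], read_type = paste0("R", m[4]),
       lane = m[3])
}

#' Load a protein reference database with seven-rank taxonomy
#'
#' The database is a protein FASTA plus a tab-separated taxonomy table with a
#' header row of `accession, domain, phylum, class, order, family, genus,
#' species`. Empty cells denote missing ranks. Lineages are normalized to
#' prefix-annotated form: once a rank is missing, all lower ranks are blanked
#' (with a warning when labels are dropped).
#'
#' @param protein_fasta_path FASTA of reference proteins (>= 50 residues each).
#' @param taxonomy_tsv_path taxonomy TSV; accessions must match the FASTA
#'   exactly (both directions).
#' @param nuc optional named character vector of nucleotide sequences
#'   (used by the mock-community generator).
#' @return an object of class `reference_db` with elements `proteins` (named
#'   character), `taxonomy` (data frame with rank columns) and `nuc`.
#' @export
load_reference_db <- function(protein_fasta_path, taxonomy_tsv_path, nuc = NULL) {
  prot <- read_sequences(protein_fasta_path, "fasta")
  tax <- utils::read.delim(taxonomy_tsv_path, header = TRUE,
                           colClasses = "character", na.strings = c("", "NA"))
  names(tax) <- tolower(names(tax))
  need <- c("accession", RANKS)
  if (!identical(names(tax)[seq_along(need)], need))
    stop("taxonomy TSV must have header columns: ", paste(need, collapse = ", "))
  build_reference_db(stats::setNames(prot$seq, prot$id), tax, nuc = nuc)
}

build_reference_db <- function(proteins, taxonomy, nuc = NULL) {
  if (anyDuplicated(names(proteins)))
    stop("duplicate accession in protein FASTA: ",
         names(proteins)[duplicated(names(proteins))][1])
  if (anyDuplicated(taxonomy$accession))
    stop("duplicate accession in taxonomy: ",
         taxonomy$accession[duplicated(taxonomy$accession)][1])
  only_fa <- setdiff(names(proteins), taxonomy$accession)
  only_tx <- setdiff(taxonomy$accession, names(proteins))
  if (length(only_fa))
    stop("accession present only in protein FASTA: ", only_fa[1])
  if (length(only_tx))
    stop("accession present only in taxonomy: ", only_tx[1])
  bad <- names(proteins)[nchar(proteins) < 50]
  if (length(bad))
    stop("reference protein shorter than 50 residues: ", bad[1])
  chars <- unique(unlist(strsplit(proteins, "")))
  if (length(setdiff(chars, PROT_ALPHABET)))
    stop("invalid protein residue(s): ",
         paste(setdiff(chars, PROT_ALPHABET), collapse = ","))
  # canonical accession order makes the load order-independent
  ord <- order(taxonomy$accession)
  taxonomy <- taxonomy[ord, , drop = FALSE]
  rownames(taxonomy) <- NULL
  proteins <- proteins[taxonomy$accession]
  # prefix normalization of lineages
  dropped <- FALSE
  for (r in seq_along(RANKS)) {
    miss <- is.na(taxonomy[[RANKS[r]]])
    if (any(miss) && r < length(RANKS)) {
      lower <- RANKS[(r + 1):length(RANKS)]
      had <- miss & Reduce(`|`, lapply(taxonomy[lower], function(x) !is.na(x)))
      if (any(had)) dropped <- TRUE
      for (l in lower) taxonomy[[l]][miss] <- NA_character_
    }
  }
  if (dropped)
    warning("lineage gap(s) truncated: labels below a missing rank were blanked")
  if (!is.null(nuc)) nuc <- nuc[taxonomy$accession]
  structure(list(proteins = proteins, taxonomy = taxonomy, nuc = nuc),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db: %d entries, %d genera, %d phyla\n",
              length(x$proteins),
              length(unique(stats::na.omit(x$taxonomy$genus))),
              length(unique(stats::na.omit(x$taxonomy$phylum)))))
  invisible(x)
}

#' Lineage of a reference entry
#'
#' @param db a `reference_db`.
#' @param accession entry accession.
#' @return named character vector over the seven ranks (NA = missing).
#' @export
db_lineage <- function(db, accession) {
  i <- match(accession, db$taxonomy$accession)
  if (is.na(i)) stop("unknown accession: ", accession)
  stats::setNames(unlist(db$taxonomy[i, RANKS], use.names = FALSE), RANKS)
}
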