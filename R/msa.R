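kmer_set <- function(seq, k = 6) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  unique(substring(seq, 1:(L - k + 1), k:L))
}

# fractional common-kmer distance: 1 - |shared| / min(|A|, |B|)
kmer_distance_matrix <- function(seqs, k = 6) {
  sets <- lapply(seqs, kmer_set, k = k)
  n <- length(seqs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    denom <- min(length(sets[[i]]), length(sets[[j]]))
    d <- if (denom == 0) 1 else 1 - length(intersect(sets[[i]], sets[[j]])) / denom
    D[i, j] <- D[j, i] <- d
  }
  D
}

msa_to_matrix <- function(msa) {
  do.call(rbind, strsplit(unname(msa), ""))
}

profile_counts <- function(aln_mat) {
  L <- ncol(aln_mat)
  prof <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (r in c("A", "C", "G", "T"))
    prof[r, ] <- colSums(aln_mat == r)
  prof
}

apply_ops <- function(aln_mat, ops, own_op) {
  # ops: 0 = column from both, own_op = column from this profile, other = gap
  out <- matrix("-", nrow(aln_mat), length(ops))
  take <- ops == 0L | ops == own_op
  out[, take] <- aln_mat
  out
}

#' Progressive multiple sequence alignment
#'
#' Guide tree from fractional common 6-mer distances via UPGMA (average
#' linkage), then profile-profile global alignment with affine gaps
#' (match +5, mismatch -4, gap open -10, gap extend -0.5, sum-of-pairs
#' column scores). Sequences are processed in lexicographic id order, which
#' makes the result independent of input order. Ungapping any row recovers
#' its input sequence exactly.
#'
#' @param seqs named character vector of >= 2 nucleotide sequences with
#'   unique ids.
#' @param match,mismatch,gap_open,gap_ext alignment scoring constants.
#' @return named character vector of gapped rows (class `msa`), all the same
#'   width.
#' @export
progressive_msa <- function(seqs, match = 5, mismatch = -4,
                            gap_open = -10, gap_ext = -0.5) {
  if (length(seqs) < 2) stop("progressive_msa needs at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  seqs <- seqs[order(names(seqs))]
  n <- length(seqs)
  if (n == 2) {
    merged <- align_pair_profiles(
      matrix(strsplit(seqs[[1]], "")[[1]], 1),
      matrix(strsplit(seqs[[2]], "")[[1]], 1),
      match, mismatch, gap_open, gap_ext)
    rows <- apply(merged, 1, paste, collapse = "")
    return(structure(stats::setNames(rows, names(seqs)), class = "msa"))
  }
  D <- kmer_distance_matrix(unname(seqs))
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  # alignments per cluster: rows follow the order of `ids`
  alns <- lapply(seqs, function(s) matrix(strsplit(s, "")[[1]], nrow = 1))
  ids <- lapply(seq_len(n), function(i) names(seqs)[i])
  node_aln <- vector("list", n - 1)
  node_ids <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    get <- function(x) {
      if (x < 0) list(aln = alns[[-x]], ids = ids[[-x]])
      else list(aln = node_aln[[x]], ids = node_ids[[x]])
    }
    a <- get(hc$merge[step, 1]); b <- get(hc$merge[step, 2])
    merged <- align_pair_profiles(a$aln, b$aln, match, mismatch,
                                  gap_open, gap_ext)
    node_aln[[step]] <- merged
    node_ids[[step]] <- c(a$ids, b$ids)
  }
  final <- node_aln[[n - 1]]
  rows <- apply(final, 1, paste, collapse = "")
  names(rows) <- node_ids[[n - 1]]
  structure(rows[order(names(rows))], class = "msa")
}

align_pair_profiles <- function(alnA, alnB, match, mismatch, gap_open, gap_ext) {
  ops <- cpp_align_profiles(profile_counts(alnA), profile_counts(alnB),
                            nrow(alnA), nrow(alnB),
                            match, mismatch, gap_open, gap_ext)
  rbind(apply_ops(alnA, ops, 1L), apply_ops(alnB, ops, 2L))
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences, %d columns\n", length(x), nchar(x[[1]])))
  invisible(x)
}

#' Remove gaps from an alignment row
#' @param x gapped sequence string(s).
#' @return ungapped string(s).
#' @export
ungap <- function(x) gsub("-", "", x)
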