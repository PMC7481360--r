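#' Clustering parameters
#'
#' @param identity_threshold greedy clustering identity threshold in
#'   `[0.5, 1]` (default 0.80). At 1.0, clusters are exact-duplicate groups.
#' @param min_cluster_size OTUs with fewer total reads are discarded
#'   (default 2).
#' @param chimera_check run de novo chimera flagging (default TRUE).
#' @param abundance_skew a chimera's candidate parents must be at least this
#'   many times more abundant (default 2).
#' @return a list of class `cluster_params`.
#' @export
cluster_params <- function(identity_threshold = 0.80, min_cluster_size = 2,
                           chimera_check = TRUE, abundance_skew = 2.0) {
  stopifnot(identity_threshold >= 0.5, identity_threshold <= 1.0,
            min_cluster_size >= 1, abundance_skew > 1)
  structure(list(identity_threshold = identity_threshold,
                 min_cluster_size = min_cluster_size,
                 chimera_check = chimera_check,
                 abundance_skew = abundance_skew), class = "cluster_params")
}

#' Exact-string dereplication across samples
#'
#' Collapses identical sequences over all samples jointly, keeping per-sample
#' counts. Output is sorted by total abundance (decreasing), ties broken
#' lexicographically by sequence, which makes every downstream step
#' independent of read order.
#'
#' @param seqs character vector of (post-QC) read sequences.
#' @param samples character vector of sample ids, parallel to `seqs`.
#' @return an object of class `derep`: list with `seq`, `size` and `counts`
#'   (unique sequence x sample integer matrix).
#' @export
dereplicate <- function(seqs, samples) {
  stopifnot(length(seqs) == length(samples))
  sample_levels <- unique(samples)
  if (length(seqs) == 0) {
    return(structure(list(seq = character(), size = integer(),
                          counts = matrix(0L, 0, length(sample_levels),
                                          dimnames = list(NULL, sample_levels))),
                     class = "derep"))
  }
  tab <- table(factor(seqs, levels = unique(seqs)),
               factor(samples, levels = sample_levels))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  size <- rowSums(counts)
  ord <- order(-size, rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  structure(list(seq = rownames(counts), size = as.integer(size[ord]),
                 counts = counts), class = "derep")
}

#' @export
print.derep <- function(x, ...) {
  cat(sprintf("derep: %d unique sequences, %d reads, %d samples\n",
              length(x$seq), sum(x$size), ncol(x$counts)))
  invisible(x)
}

#' Pairwise global identity between two nucleotide sequences
#'
#' Needleman-Wunsch global alignment with terminal gaps free on the longer
#' sequence's side, so the shorter sequence is always aligned end to end
#' (match +2, mismatch -4, gap open -10, gap extend -1 by default).
#' Identity is the fraction of matching columns over alignment columns
#' excluding terminal-gap columns, so a read and its own prefix score 1.0
#' while equal-length divergent sequences are compared over their full span.
#'
#' @param a,b non-empty nucleotide strings.
#' @param match,mismatch,gap_open,gap_ext alignment scoring constants.
#' @return identity in `[0, 1]`.
#' @export
global_identity <- function(a, b, match = 2, mismatch = -4,
                            gap_open = -10, gap_ext = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("global_identity: empty sequence")
  cpp_align_overlap(a, b, match, mismatch, gap_open, gap_ext)$identity
}

#' Greedy centroid clustering
#'
#' Scans dereplicated sequences in abundance order; each sequence joins the
#' first existing centroid (in creation order) with identity at least the
#' threshold, else founds a new cluster. At a threshold of 1.0, membership
#' requires exact string equality, so clusters are exact-duplicate groups.
#'
#' @param derep a [dereplicate()] result.
#' @param params a [cluster_params()].
#' @return list of OTUs; each is a list with `centroid`, `members` (indices
#'   into `derep`), `size`, `per_sample` and `flags`.
#' @export
greedy_cluster <- function(derep, params = cluster_params()) {
  thr <- params$identity_threshold
  centroids <- character(0)
  members <- list()
  for (i in seq_along(derep$seq)) {
    q <- derep$seq[i]
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      ok <- if (thr >= 1.0) identical(q, centroids[ci])
            else global_identity(q, centroids[ci]) >= thr
      if (ok) {
        members[[ci]] <- c(members[[ci]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, q)
      members[[length(centroids)]] <- i
    }
  }
  lapply(seq_along(centroids), function(ci) {
    idx <- members[[ci]]
    ps <- if (length(idx) == 1) derep$counts[idx, ]
          else colSums(derep$counts[idx, , drop = FALSE])
    list(centroid = centroids[ci], members = idx,
         size = sum(derep$size[idx]), per_sample = ps, flags = character(0))
  })
}

#' De novo two-parent chimera flagging
#'
#' For each query, candidate parents are sequences at least `abundance_skew`
#' times more abundant. The query is aligned to its top candidates by
#' identity; for every ordered parent pair and crossover position the
#' two-parent model identity (query positions matching parent A left of the
#' crossover and parent B right of it) is computed from per-position match
#' vectors. A query is flagged when the best model identity is >= 0.99 and
#' beats the best single-parent identity by >= 0.04.
#'
#' @param derep a [dereplicate()] result (abundance-sorted).
#' @param params a [cluster_params()].
#' @param max_parents number of top candidates examined (default 8).
#' @return character vector of flagged sequences.
#' @export
flag_chimeras <- function(derep, params = cluster_params(), max_parents = 8) {
  flagged <- character(0)
  n <- length(derep$seq)
  if (n < 3) return(flagged)
  for (i in seq_len(n)) {
    q <- derep$seq[i]
    cand <- which(derep$size >= params$abundance_skew * derep$size[i])
    cand <- setdiff(cand, i)
    if (length(cand) < 2) next
    alns <- lapply(cand, function(j)
      cpp_align_overlap(q, derep$seq[j], 2, -4, -10, -1))
    ident <- vapply(alns, `[[`, numeric(1), "identity")
    keep <- order(-ident)[seq_len(min(max_parents, length(cand)))]
    alns <- alns[keep]; ident <- ident[keep]
    if (length(alns) < 2) next
    nq <- nchar(q)
    # prefix sums of per-query-position matches against each candidate
    pref <- lapply(alns, function(al) cumsum(as.integer(al$match_a)))
    single_best <- max(vapply(pref, function(p) p[nq], numeric(1))) / nq
    model_best <- 0
    for (ai in seq_along(pref)) for (bi in seq_along(pref)) {
      if (ai == bi) next
      pa <- pref[[ai]]; pb <- pref[[bi]]
      # crossover after position x, x in 0..nq
      tot <- c(pb[nq], pa + (pb[nq] - pb))
      model_best <- max(model_best, max(tot) / nq)
    }
    if (model_best >= 0.99 && model_best - single_best >= 0.04)
      flagged <- c(flagged, q)
  }
  flagged
}

#' Apply chimera flags to clustered OTUs
#'
#' An OTU carries the chimera flag when its centroid sequence was flagged.
#'
#' @param otus output of [greedy_cluster()].
#' @param flagged_seqs output of [flag_chimeras()].
#' @return `otus` with updated `flags`.
#' @export
mark_chimeric_otus <- function(otus, flagged_seqs) {
  lapply(otus, function(o) {
    if (o$centroid %in% flagged_seqs) o$flags <- union(o$flags, "chimera")
    o
  })
}

#' Build the OTU table
#'
#' Drops chimera-flagged OTUs and OTUs below the minimum cluster size, then
#' renumbers the survivors `OTU_1, OTU_2, ...` in decreasing total abundance.
#'
#' @param otus output of [greedy_cluster()] (after [mark_chimeric_otus()]).
#' @param params a [cluster_params()].
#' @return list with `table` (OTU x sample integer matrix), `otus` (the kept
#'   OTU records, with `otu_id` set) and `discarded`
#'   (`c(chimera_reads, small_reads, chimera_otus, small_otus)`).
#' @export
build_otu_table <- function(otus, params = cluster_params()) {
  is_chim <- vapply(otus, function(o) "chimera" %in% o$flags, logical(1))
  sizes <- vapply(otus, `[[`, numeric(1), "size")
  small <- !is_chim & sizes < params$min_cluster_size
  keep <- !is_chim & !small
  kept <- otus[keep]
  ord <- order(-vapply(kept, `[[`, numeric(1), "size"),
               vapply(kept, `[[`, character(1), "centroid"))
  kept <- kept[ord]
  samples <- if (length(otus)) names(otus[[1]]$per_sample) else character(0)
  tab <- matrix(0L, nrow = length(kept), ncol = length(samples),
                dimnames = list(character(length(kept)), samples))
  for (k in seq_along(kept)) {
    kept[[k]]$otu_id <- sprintf("OTU_%d", k)
    tab[k, ] <- as.integer(kept[[k]]$per_sample)
    rownames(tab)[k] <- kept[[k]]$otu_id
  }
  list(table = tab, otus = kept,
       discarded = c(chimera_reads = sum(sizes[is_chim]),
                     small_reads = sum(sizes[small]),
                     chimera_otus = sum(is_chim), small_otus = sum(small)))
}
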