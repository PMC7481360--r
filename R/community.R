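RANK_PLURALS <- c(domain = "domains", phylum = "phyla", class = "classes",
                  order = "orders", family = "families", genus = "genera",
                  species = "species")

#' Collapse an OTU table to a taxonomic rank
#'
#' Sums OTU counts by the rendered rank label (see [render_rank_label()]);
#' OTUs with a missing rank contribute to their nearest annotated ancestor's
#' `.NA` label. Labels are ordered by total abundance (decreasing), then
#' lexicographically. Every OTU in the table must have a classification.
#'
#' @param otu_table OTU x sample count matrix (rownames = OTU ids).
#' @param classifications list of `classification` objects, named by or
#'   carrying the matching `otu_id`s.
#' @param rank one of the seven rank names.
#' @return list of class `rank_table` with `rank` and `counts`
#'   (label x sample matrix).
#' @export
collapse_rank <- function(otu_table, classifications, rank) {
  rank <- match.arg(rank, RANKS)
  ids <- vapply(classifications, function(x) as.character(x$otu_id), character(1))
  miss <- setdiff(rownames(otu_table), ids)
  if (length(miss))
    stop("OTU without classification: ", miss[1])
  labels <- vapply(rownames(otu_table), function(oid) {
    cl <- classifications[[match(oid, ids)]]
    render_rank_label(cl$lineage, rank)
  }, character(1))
  counts <- rowsum(otu_table, group = labels)
  counts <- counts[order(-rowSums(counts), rownames(counts)), , drop = FALSE]
  storage.mode(counts) <- "integer"
  structure(list(rank = rank, counts = counts), class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf("rank_table (%s): %d labels x %d samples\n",
              x$rank, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Merge minor taxa
#'
#' A label is minor when its relative abundance is strictly below the
#' threshold in every sample (a taxon at exactly the threshold anywhere
#' survives). Minor labels are summed into a single `Minor <rank>` row,
#' placed last. Idempotent.
#'
#' @param rank_table a [collapse_rank()] result.
#' @param threshold relative-abundance threshold in (0, 1); default 0.01.
#' @return a `rank_table` with minor labels merged.
#' @export
merge_minor <- function(rank_table, threshold = 0.01) {
  stopifnot(threshold > 0, threshold < 1)
  counts <- rank_table$counts
  totals <- colSums(counts)
  ra <- sweep(counts, 2, pmax(totals, 1), "/")
  minor_label <- paste("Minor", RANK_PLURALS[[rank_table$rank]])
  minor <- apply(ra, 1, function(r) all(r < threshold))
  if (!any(minor)) return(rank_table)
  kept <- counts[!minor, , drop = FALSE]
  minor_row <- matrix(colSums(counts[minor, , drop = FALSE]), nrow = 1,
                      dimnames = list(minor_label, colnames(counts)))
  out <- rbind(kept, minor_row)
  storage.mode(out) <- "integer"
  structure(list(rank = rank_table$rank, counts = out), class = "rank_table")
}

#' Per-sample alpha diversity
#'
#' Observed richness, Shannon `H = -sum p ln p`, Simpson `D = 1 - sum p^2`
#' and Pielou evenness `J = H / ln(observed)`, all with natural logarithms.
#' Empty samples report NA.
#'
#' @param x a `rank_table` or a count matrix (rows = taxa).
#' @return data frame with one row per sample.
#' @export
alpha_diversity <- function(x) {
  counts <- if (inherits(x, "rank_table")) x$counts else x
  res <- lapply(colnames(counts), function(s) {
    v <- counts[, s]
    tot <- sum(v)
    if (tot == 0)
      return(data.frame(sample = s, observed = NA_integer_, shannon = NA_real_,
                        simpson = NA_real_, pielou = NA_real_))
    obs <- sum(v > 0)
    H <- unname(vegan::diversity(v, index = "shannon"))
    D <- unname(vegan::diversity(v, index = "simpson"))
    J <- if (obs > 1) H / log(obs) else NA_real_
    data.frame(sample = s, observed = obs, shannon = H, simpson = D, pielou = J)
  })
  do.call(rbind, res)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`; symmetric, zero diagonal,
#' in `[0, 1]`. A pair of all-zero samples is reported as NA.
#'
#' @param x a `rank_table` or count matrix (rows = taxa, >= 2 samples).
#' @return sample x sample dissimilarity matrix.
#' @export
bray_curtis <- function(x) {
  counts <- if (inherits(x, "rank_table")) x$counts else x
  if (ncol(counts) < 2) stop("bray_curtis needs at least 2 samples")
  d <- suppressWarnings(vegan::vegdist(t(counts), method = "bray"))
  m <- as.matrix(d)
  m[is.nan(m)] <- NA_real_
  diag(m) <- 0
  m
}

#' Compare two analysis runs at a rank
#'
#' Compares the per-label total abundances of two runs collapsed at the same
#' rank (e.g. forward-read vs reverse-read analyses), after a
#' `log10(x + 1)` transform: two-sample t test, Mann-Whitney U and
#' Kruskal-Wallis, plus the unique/shared label breakdown. Degenerate group
#' sizes (< 2) are reported as underpowered with NA p-values.
#'
#' @param rank_table_a,rank_table_b `rank_table`s at the same rank.
#' @return list with `rank`, `p_t`, `p_mannwhitney`, `p_kruskal`,
#'   `underpowered`, `shared_labels`, `unique_a`, `unique_b` (named totals).
#' @export
compare_runs <- function(rank_table_a, rank_table_b) {
  if (!identical(rank_table_a$rank, rank_table_b$rank))
    stop("rank mismatch: ", rank_table_a$rank, " vs ", rank_table_b$rank)
  ta <- rowSums(rank_table_a$counts)
  tb <- rowSums(rank_table_b$counts)
  x <- log10(ta + 1); y <- log10(tb + 1)
  underpowered <- length(x) < 2 || length(y) < 2
  safe_p <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  res <- list(
    rank = rank_table_a$rank,
    n_a = length(x), n_b = length(y),
    underpowered = underpowered,
    p_t = if (underpowered) NA_real_ else safe_p(stats::t.test(x, y)$p.value),
    p_mannwhitney = if (underpowered) NA_real_ else
      safe_p(stats::wilcox.test(x, y, exact = FALSE)$p.value),
    p_kruskal = if (underpowered) NA_real_ else
      safe_p(stats::kruskal.test(list(x, y))$p.value),
    shared_labels = intersect(names(ta), names(tb)),
    unique_a = ta[setdiff(names(ta), names(tb))],
    unique_b = tb[setdiff(names(tb), names(ta))]
  )
  res
}
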