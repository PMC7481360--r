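#' Jukes-Cantor distance matrix from an alignment
#'
#' Pairwise proportions of differing sites are computed over columns where
#' neither row has a gap (pairwise deletion) and transformed as
#' `d = -(3/4) ln(1 - (4/3) p)`, with p capped at 0.749 to keep the
#' logarithm finite.
#'
#' @param msa an [progressive_msa()] result (named gapped rows).
#' @return symmetric numeric distance matrix.
#' @export
jc_distance <- function(msa) {
  m <- msa_to_matrix(msa)
  n <- nrow(m)
  ids <- names(msa)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  gap <- m == "-"
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok))
      stop(sprintf("no comparable columns between '%s' and '%s'",
                   ids[i], ids[j]))
    p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    p <- min(p, 0.749)
    D[i, j] <- D[j, i] <- -0.75 * log(1 - 4 * p / 3)
  }
  D
}

#' Neighbor-joining tree from an alignment
#'
#' Jukes-Cantor distances with pairwise gap deletion, then Saitou-Nei
#' neighbor joining with Studier-Keppler branch lengths (via [ape::nj()]).
#' Negative branch lengths are clamped to zero.
#'
#' @param msa an alignment, or a precomputed distance matrix.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(msa) {
  D <- if (is.matrix(msa) && is.numeric(msa)) msa else jc_distance(msa)
  if (nrow(D) < 3) stop("neighbor joining needs at least 3 sequences")
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap supports for the NJ tree
#'
#' Resamples alignment columns with replacement B times, rebuilds the NJ
#' tree for each replicate, and scores every internal bipartition of the
#' point-estimate tree by the fraction of replicates containing it.
#' Reproducible under a fixed seed. A replicate pair left with no comparable
#' columns is assigned the maximum (capped) distance.
#'
#' @param msa an alignment.
#' @param B number of replicates (>= 1, default 100).
#' @param seed integer seed.
#' @return the point-estimate `phylo` with `node.label` set to supports in
#'   `[0, 1]` (root label empty).
#' @export
bootstrap_supports <- function(msa, B = 100, seed = 1) {
  stopifnot(B >= 1)
  main <- nj_tree(msa)
  m <- msa_to_matrix(msa)
  ids <- names(msa)
  boot_dist <- function(cols) {
    sub <- m[, cols, drop = FALSE]
    gap <- sub == "-"
    n <- nrow(sub)
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      p <- if (!any(ok)) 0.749 else min(sum(sub[i, ok] != sub[j, ok]) / sum(ok), 0.749)
      D[i, j] <- D[j, i] <- -0.75 * log(1 - 4 * p / 3)
    }
    D
  }
  trees <- withr::with_seed(seed, {
    lapply(seq_len(B), function(b) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      nj_tree(boot_dist(cols))
    })
  })
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(main, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  sup <- counts / B
  main$node.label <- c("", format(sup[-1], trim = TRUE))
  attr(main, "supports") <- sup
  main
}

needs_quoting <- function(label) {
  grepl("[] \t(){}:;,'[]", label)
}

quote_label <- function(label) {
  if (needs_quoting(label))
    paste0("'", gsub("'", "''", label), "'") else label
}

#' Write a tree in Newick format
#'
#' Branch lengths are written with six decimal places; internal node labels
#' (bootstrap supports) are kept; labels containing Newick metacharacters
#' are single-quoted with internal quotes doubled. The output parses back
#' (e.g. with [ape::read.tree()]) to an isomorphic tree.
#'
#' @param tree a `phylo` object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_len <- function(e) {
    if (is.null(tree$edge.length) || is.na(e)) ""
    else sprintf(":%.6f", tree$edge.length[e])
  }
  rec <- function(node, edge_in) {
    if (node <= ntip)
      return(paste0(quote_label(tree$tip.label[node]), fmt_len(edge_in)))
    kids <- children[[as.character(node)]]
    inner <- paste(vapply(kids, function(e) rec(tree$edge[e, 2], e),
                          character(1)), collapse = ",")
    lab <- if (!is.null(tree$node.label)) {
      l <- tree$node.label[node - ntip]
      if (is.na(l) || !nzchar(l)) "" else quote_label(l)
    } else ""
    paste0("(", inner, ")", lab, fmt_len(edge_in))
  }
  writeLines(paste0(rec(root, NA), ";"), path)
  invisible(path)
}
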