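FRAME_NAMES <- c("+1", "+2", "+3", "-1", "-2", "-3")

# cached BLOSUM62 from Biostrings
.pkg_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames under the
#' standard genetic code. Frames -1..-3 translate the reverse complement.
#' Trailing 1-2 nt are dropped; internal stops appear as `*`; codons with
#' ambiguity codes translate to `X` unless the redundancy still determines a
#' unique residue.
#'
#' @param seq nucleotide string, length >= 3.
#' @return named character vector of the six frame translations.
#' @export
six_frame_translate <- function(seq) {
  if (nchar(seq) < 3) stop("sequence shorter than 3 nt cannot be translated")
  fwd <- toupper(seq)
  if (!grepl("^[ACGTUNRYSWKMBDHVI]+$", fwd))
    stop("invalid nucleotide character in sequence")
  fwd <- chartr("UI", "TN", fwd)
  rev <- chartr("ACGTNRYSWKMBDHV",
                "TGCANYRSWMKVHDB",
                paste(rev(strsplit(fwd, "")[[1]]), collapse = ""))
  stats::setNames(c(translate_frame(fwd, 0L), translate_frame(fwd, 1L),
                    translate_frame(fwd, 2L), translate_frame(rev, 0L),
                    translate_frame(rev, 1L), translate_frame(rev, 2L)),
                  FRAME_NAMES)
}

# vectorized standard-code translation; ambiguity codes translate to X
# unless every expansion encodes the same residue
translate_frame <- function(seq, off) {
  L <- nchar(seq) - off
  if (L < 3) return("")
  n_codon <- L %/% 3L
  starts <- off + 3L * (seq_len(n_codon) - 1L) + 1L
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  fuzzy <- which(is.na(aa))
  if (length(fuzzy)) {
    aa[fuzzy] <- vapply(codons[fuzzy], solve_fuzzy_codon, character(1))
  }
  paste(aa, collapse = "")
}

IUPAC_EXPAND <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))

solve_fuzzy_codon <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  combos <- expand.grid(IUPAC_EXPAND[[ch[1]]], IUPAC_EXPAND[[ch[2]]],
                        IUPAC_EXPAND[[ch[3]]], stringsAsFactors = FALSE)
  aa <- unique(unname(Biostrings::GENETIC_CODE[
    paste0(combos[[1]], combos[[2]], combos[[3]])]))
  if (length(aa) == 1) aa else "X"
}

#' Best reading frame: longest stop-free segment
#'
#' Over all six frame translations, finds the longest contiguous run of
#' residues without a stop codon. Ties are broken by frame order
#' (+1, +2, +3, -1, -2, -3), then by leftmost run. Runs shorter than
#' `min_run` residues in every frame mark the sequence as degenerate.
#'
#' @param seq nucleotide string.
#' @param min_run minimum acceptable stop-free run, in residues (default 10).
#' @return list with `frame`, `protein` (the stop-free segment), `nt_span`
#'   (0-based half-open interval on the translated strand) and `degenerate`.
#' @export
best_frame <- function(seq, min_run = 10) {
  prots <- six_frame_translate(seq)
  best <- NULL
  for (f in seq_along(prots)) {
    p <- prots[[f]]
    if (!nzchar(p)) next
    runs <- gregexpr("[^*]+", p)[[1]]
    if (runs[1] == -1) next
    lens <- attr(runs, "match.length")
    r <- which.max(lens)  # leftmost maximal run within the frame
    if (is.null(best) || lens[r] > best$len) {
      off <- (f - 1L) %% 3L  # frame offset on its strand
      p1 <- runs[r]          # 1-based residue start
      best <- list(len = lens[r], frame = FRAME_NAMES[f],
                   protein = substr(p, p1, p1 + lens[r] - 1L),
                   nt_span = c(off + 3L * (p1 - 1L), off + 3L * (p1 - 1L + lens[r])))
    }
  }
  if (is.null(best)) stop("no translatable frame")
  list(frame = best$frame, protein = best$protein, nt_span = best$nt_span,
       degenerate = best$len < min_run)
}

#' Local protein alignment (Smith-Waterman, BLOSUM62)
#'
#' Affine-gap local alignment; a gap of length L costs
#' `gap_open + L * gap_ext` (defaults 11 and 1, the usual BLOSUM62 pairing).
#' Traceback is deterministic: highest-scoring cell, ties resolved to the
#' smallest row then column.
#'
#' @param q,s protein strings over the BLOSUM62 alphabet.
#' @param gap_open,gap_ext positive gap penalties.
#' @return list with `raw_score`, `q_span`, `s_span` (1-based inclusive),
#'   `pct_identity`, `n_id`, `n_aln`.
#' @export
sw_align <- function(q, s, gap_open = 11, gap_ext = 1) {
  if (!nzchar(q) || !nzchar(s)) stop("sw_align: empty sequence")
  B <- blosum62()
  r <- cpp_align_local(q, s, B, paste(rownames(B), collapse = ""),
                       gap_open, gap_ext)
  list(raw_score = r$score, q_span = c(r$q_start, r$q_end),
       s_span = c(r$s_start, r$s_end), pct_identity = r$pct_identity,
       n_id = r$n_id, n_aln = r$n_aln)
}

#' Karlin-Altschul bit score and E-value
#'
#' `bit = (lambda * S - ln K) / ln 2`; `E = m * n * 2^-bit`, with the
#' published gapped BLOSUM62-11-1 constants `lambda = 0.267`, `K = 0.041`.
#' At S = 0 the E-value reduces to `K * m * n`, the maximum for the search
#' space; E is strictly decreasing in S and linear in the database size.
#'
#' @param raw_score alignment raw score (>= 0).
#' @param q_len query length in residues.
#' @param db_residues total residues in the database.
#' @param lambda,K Karlin-Altschul constants.
#' @return list with `bit_score` and `evalue`.
#' @export
estimate_evalue <- function(raw_score, q_len, db_residues,
                            lambda = 0.267, K = 0.041) {
  if (q_len <= 0 || db_residues <= 0)
    stop("query and database lengths must be positive")
  if (raw_score < 0) stop("raw score must be >= 0")
  bit <- (lambda * raw_score - log(K)) / log(2)
  list(bit_score = bit, evalue = q_len * db_residues * 2^(-bit))
}

#' Classify one OTU centroid against the reference database
#'
#' Selects the centroid's best reading frame, aligns the resulting protein
#' to every reference entry, and keeps the best hit by bit score (ties:
#' lower E-value, then lexicographically smaller accession). The OTU is a
#' target when the best E-value is at or below the cutoff; its lineage is
#' the best hit's lineage verbatim, including missing ranks.
#'
#' @param centroid nucleotide centroid sequence.
#' @param db a `reference_db`.
#' @param evalue_cutoff E-value cutoff (default 1e-3).
#' @param otu_id identifier carried through to the result.
#' @return list of class `classification`: `otu_id`, `target`, `best_hit`
#'   (or NULL), `lineage` (or NULL), `reason` for non-targets.
#' @export
classify_otu <- function(centroid, db, evalue_cutoff = 1e-3, otu_id = NA) {
  if (length(db$proteins) == 0) stop("empty reference database")
  bf <- best_frame(centroid)
  if (bf$degenerate) {
    return(structure(list(otu_id = otu_id, target = FALSE, best_hit = NULL,
                          lineage = NULL, reason = "degenerate_frame"),
                     class = "classification"))
  }
  db_res <- sum(nchar(db$proteins))
  accs <- names(db$proteins)
  hits <- lapply(accs, function(acc) {
    al <- sw_align(bf$protein, db$proteins[[acc]])
    ev <- estimate_evalue(al$raw_score, nchar(bf$protein), db_res)
    c(al, ev, list(subject = acc))
  })
  bits <- vapply(hits, `[[`, numeric(1), "bit_score")
  best <- hits[[order(-bits, accs)[1]]]
  hit <- list(query_id = otu_id, subject_accession = best$subject,
              raw_score = best$raw_score, bit_score = best$bit_score,
              evalue = best$evalue, pct_identity = best$pct_identity,
              q_span = best$q_span, s_span = best$s_span,
              frame = bf$frame)
  target <- best$evalue <= evalue_cutoff
  structure(list(otu_id = otu_id, target = target, best_hit = hit,
                 lineage = if (target) db_lineage(db, best$subject) else NULL,
                 reason = if (target) NULL else "evalue_above_cutoff"),
            class = "classification")
}

#' Display label of a lineage at a rank
#'
#' Annotated ranks show their own label. A missing rank shows the deepest
#' annotated ancestor suffixed with `.NA` (e.g. a genus-less entry in family
#' Foo renders `Foo.NA` at genus level); a fully unannotated lineage renders
#' `Unclassified`.
#'
#' @param lineage named character over the seven ranks (NA = missing), or
#'   NULL.
#' @param rank one of the seven rank names.
#' @return display label.
#' @export
render_rank_label <- function(lineage, rank) {
  rank <- match.arg(rank, RANKS)
  if (is.null(lineage) || all(is.na(lineage))) return("Unclassified")
  r <- match(rank, RANKS)
  if (!is.na(lineage[[r]])) return(lineage[[r]])
  upper <- lineage[seq_len(r - 1)]
  ann <- which(!is.na(upper))
  if (length(ann) == 0) return("Unclassified")
  paste0(upper[[max(ann)]], ".NA")
}
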