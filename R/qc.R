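# IUPAC bitmasks. Read side: concrete/degenerate bases are unions of the four
# base bits; 'N' in a read gets a private bit so that it matches only a
# primer 'N' or 'I' (which carry all bits), never an informative primer code.
IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L)
READ_N_BIT <- 16L

encode_read <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- unname(IUPAC_BITS[ch])
  out[ch == "N"] <- READ_N_BIT
  out[ch == "I"] <- 15L
  if (anyNA(out)) stop("invalid nucleotide character in read: ",
                       ch[is.na(out)][1])
  as.integer(out)
}

encode_primer <- function(pattern) {
  ch <- strsplit(pattern, "")[[1]]
  out <- unname(IUPAC_BITS[ch])
  # inosine pairs with all four bases; N is a full wildcard too
  out[ch %in% c("N", "I")] <- 15L + READ_N_BIT
  if (anyNA(out)) stop("invalid primer character: ", ch[is.na(out)][1])
  as.integer(out)
}

#' Degenerate primer pair
#'
#' Defaults are the forward/reverse degenerate primers targeting the FTHFS
#' marker gene, written 5' to 3'. Symbols are IUPAC codes plus `I` (inosine),
#' which is treated as matching any base.
#'
#' @param fwd forward primer pattern (matched at the 5' end of R1 reads).
#' @param rev reverse primer pattern (matched at the 5' end of R2 reads).
#' @return an object of class `primer_pair`.
#' @export
primer_pair <- function(fwd = "CCIACICCISYIGGNGARGGNAA",
                        rev = "ATITTIGCIAAIGGNCCNSCNTG") {
  if (!nzchar(fwd) || !nzchar(rev)) stop("primer patterns must be non-empty")
  structure(list(fwd = toupper(fwd), rev = toupper(rev),
                 fwd_mask = encode_primer(toupper(fwd)),
                 rev_mask = encode_primer(toupper(rev))),
            class = "primer_pair")
}

#' Quality-control parameters
#'
#' @param quality_cutoff Phred cutoff for 3' quality trimming (default 20).
#' @param min_length minimum surviving read length in nt (default 120).
#' @param max_length reads are truncated to this length (default 300).
#' @param primer_error_rate allowed primer mismatch fraction (default 0.10);
#'   a pattern of length L tolerates `floor(rate * L)` mismatches.
#' @param require_primer discard reads without a primer match (default TRUE).
#' @return a list of class `qc_params`.
#' @export
qc_params <- function(quality_cutoff = 20, min_length = 120, max_length = 300,
                      primer_error_rate = 0.10, require_primer = TRUE) {
  stopifnot(min_length > 0, min_length <= max_length,
            primer_error_rate >= 0, primer_error_rate < 0.5)
  structure(list(quality_cutoff = quality_cutoff, min_length = min_length,
                 max_length = max_length, primer_error_rate = primer_error_rate,
                 require_primer = require_primer), class = "qc_params")
}

#' Locate a degenerate primer in a read
#'
#' Substitution-only scan: the leftmost window of pattern length whose
#' mismatch count under IUPAC set-intersection matching is at most
#' `floor(error_rate * pattern length)` wins. A read `N` matches only a
#' primer `N`/`I`.
#'
#' @param seq read sequence (character scalar) or a single-row `seq_records`.
#' @param pattern degenerate primer pattern, or a pre-encoded integer mask.
#' @param error_rate allowed mismatch fraction.
#' @return `NULL` when no window qualifies, else `c(start, end)`, 1-based
#'   inclusive.
#' @export
match_primer <- function(seq, pattern, error_rate = 0.10) {
  if (is.data.frame(seq)) seq <- seq$seq[1]
  pat_mask <- if (is.integer(pattern)) pattern else encode_primer(toupper(pattern))
  max_mm <- floor(error_rate * length(pat_mask))
  start <- cpp_primer_scan(encode_read(seq), pat_mask, as.integer(max_mm))
  if (start == 0) NULL else c(start, start + length(pat_mask) - 1L)
}

#' 3' quality trimming (running-sum rule)
#'
#' Scanning from the 3' end, the suffix penalty at cut point k is
#' `sum(cutoff - q[j])` over trimmed positions j > k; the read is cut at the
#' k maximizing that penalty, keeping as much sequence as possible on ties.
#' An all-good read is returned unchanged; a uniformly bad read becomes empty.
#' The operation is idempotent.
#'
#' @param seq sequence string.
#' @param qual integer Phred scores, same length as `seq`.
#' @param cutoff Phred cutoff.
#' @return list with trimmed `seq` and `qual` (possibly zero-length).
#' @export
quality_trim_3prime <- function(seq, qual, cutoff = 20) {
  if (is.null(qual)) stop("quality scores required for 3' trimming")
  L <- nchar(seq)
  stopifnot(length(qual) == L)
  pen <- cutoff - qual
  s <- c(rev(cumsum(rev(pen))), 0)   # s[k+1] = suffix penalty of cut at k
  keep <- max(which(s == max(s))) - 1L  # largest k among ties: trim least
  list(seq = substr(seq, 1L, keep), qual = qual[seq_len(keep)])
}

#' QC-filter a single read
#'
#' Order of operations: (1) primer match (forward pattern for R1 reads,
#' reverse pattern for R2) and removal of everything up to and including the
#' primer's 3' end; (2) 3' quality trimming; (3) truncation to `max_length`;
#' (4) length check against `min_length`.
#'
#' @param seq read sequence.
#' @param qual integer Phred vector.
#' @param primers a [primer_pair()].
#' @param read_type `"R1"` or `"R2"`.
#' @param params a [qc_params()].
#' @return list with `seq`/`qual` (the surviving read) and `reason = NULL`,
#'   or `seq = NULL` and a rejection `reason` in
#'   `c("no_primer", "empty_after_trim", "too_short")`.
#' @export
qc_filter_read <- function(seq, qual, primers, read_type = c("R1", "R2"),
                           params = qc_params()) {
  read_type <- match.arg(read_type)
  pat <- if (read_type == "R1") primers$fwd_mask else primers$rev_mask
  span <- match_primer(seq, pat, params$primer_error_rate)
  if (is.null(span)) {
    if (params$require_primer)
      return(list(seq = NULL, qual = NULL, reason = "no_primer"))
  } else {
    seq <- substr(seq, span[2] + 1L, nchar(seq))
    qual <- qual[-seq_len(span[2])]
  }
  if (!nzchar(seq))
    return(list(seq = NULL, qual = NULL, reason = "empty_after_trim"))
  tr <- quality_trim_3prime(seq, qual, params$quality_cutoff)
  if (!nzchar(tr$seq))
    return(list(seq = NULL, qual = NULL, reason = "empty_after_trim"))
  if (nchar(tr$seq) > params$max_length) {
    tr$seq <- substr(tr$seq, 1L, params$max_length)
    tr$qual <- tr$qual[seq_len(params$max_length)]
  }
  if (nchar(tr$seq) < params$min_length)
    return(list(seq = NULL, qual = NULL, reason = "too_short"))
  list(seq = tr$seq, qual = tr$qual, reason = NULL)
}

#' QC-filter a set of reads
#'
#' Applies [qc_filter_read()] to every record, memoizing identical
#' (sequence, quality) pairs, and tallies rejections by reason.
#'
#' @param records a `seq_records` data frame with qualities.
#' @param primers a [primer_pair()].
#' @param read_type `"R1"` or `"R2"`.
#' @param params a [qc_params()].
#' @return list with `kept` (a `seq_records`), and `tally`, a named integer
#'   vector over `input`, `kept`, `no_primer`, `too_short`,
#'   `empty_after_trim`.
#' @export
qc_filter_reads <- function(records, primers, read_type = c("R1", "R2"),
                            params = qc_params()) {
  read_type <- match.arg(read_type)
  n <- nrow(records)
  keys <- paste0(records$seq, "#",
                 vapply(records$qual,
                        function(q) if (is.null(q)) "" else intToUtf8(q + 33L),
                        character(1)))
  uk <- !duplicated(keys)
  cache <- vector("list", sum(uk))
  names(cache) <- keys[uk]
  for (key in names(cache)) {
    i <- match(key, keys)
    cache[[key]] <- qc_filter_read(records$seq[i], records$qual[[i]],
                                   primers, read_type, params)
  }
  res <- cache[keys]
  reasons <- vapply(res, function(r) if (is.null(r$reason)) "kept" else r$reason,
                    character(1))
  kept_i <- which(reasons == "kept")
  kept <- seq_records(records$id[kept_i],
                      vapply(res[kept_i], `[[`, character(1), "seq"),
                      lapply(res[kept_i], `[[`, "qual"))
  tally <- c(input = n, kept = length(kept_i),
             no_primer = sum(reasons == "no_primer"),
             too_short = sum(reasons == "too_short"),
             empty_after_trim = sum(reasons == "empty_after_trim"))
  list(kept = kept, tally = tally, reasons = unname(reasons))
}
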