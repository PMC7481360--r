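random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_records <- function(n, len_range = c(50, 120), with_qual = FALSE) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  seqs <- vapply(lens, random_seq, character(1))
  qual <- if (with_qual) lapply(lens, function(L) sample(2:40, L, replace = TRUE))
          else NULL
  seq_records(sprintf("read_%03d", seq_len(n)), seqs, qual)
}

mutate_seq <- function(seq, n_sub, positions = NULL) {
  v <- strsplit(seq, "")[[1]]
  if (is.null(positions)) positions <- sample(length(v), n_sub)
  for (p in positions)
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# independent quadratic-DP Smith-Waterman oracle (linear approximation of the
# affine gap as open + L * ext via explicit state DP)
sw_oracle <- function(q, s, submat, gap_open = 11, gap_ext = 1) {
  qi <- match(strsplit(q, "")[[1]], rownames(submat))
  si <- match(strsplit(s, "")[[1]], rownames(submat))
  m <- length(qi); n <- length(si)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    E[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, E[i, j - 1] - gap_ext)
    F[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, F[i - 1, j] - gap_ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + submat[qi[i - 1], si[j - 1]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# all-cut-points oracle for 3' quality trimming
trim_oracle <- function(qual, cutoff) {
  L <- length(qual)
  pens <- vapply(0:L, function(k)
    if (k == L) 0 else sum(cutoff - qual[(k + 1):L]), numeric(1))
  max(which(pens == max(pens))) - 1L
}

# exhaustive best-frame oracle: enumerate all stop-free runs in all frames
best_frame_oracle <- function(seq) {
  prots <- six_frame_translate(seq)
  best <- NULL
  for (f in seq_along(prots)) {
    p <- strsplit(prots[[f]], "")[[1]]
    if (!length(p)) next
    run_start <- NULL
    for (i in seq_len(length(p) + 1)) {
      if (i <= length(p) && p[i] != "*") {
        if (is.null(run_start)) run_start <- i
      } else if (!is.null(run_start)) {
        len <- i - run_start
        if (is.null(best) || len > best$len)
          best <- list(len = len, frame = names(prots)[f],
                       protein = paste(p[run_start:(i - 1)], collapse = ""))
        run_start <- NULL
      }
    }
  }
  best
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# small shared mock reference (built once per test run)
tiny_mock <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_mock_reference(n_genera = 5, variants_per_genus = 2,
                                     divergence = 0.05, seed = 101)
    cache
  }
})
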