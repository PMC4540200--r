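# Independent brute-force oracles used to validate the production code.
# These are deliberately naive re-derivations from first principles and share
# no code with the implementations they check.

# adapter trimming: enumerate every offset, count mismatches directly
trim_oracle <- function(sequence, adapter, min_overlap = 7) {
  rc <- strsplit(sequence, "")[[1]]
  ac <- strsplit(adapter, "")[[1]]
  for (s in 0:(length(rc) - 1)) {
    L <- min(length(ac), length(rc) - s)
    if (L < min_overlap) next
    mm <- sum(rc[(s + 1):(s + L)] != ac[seq_len(L)])
    allow <- if (L >= 10) 2 else if (L >= 7) 1 else -1
    if (mm <= allow) {
      return(list(trimmed = TRUE, match_start = s, matched_length = L,
                  mismatches = mm))
    }
  }
  list(trimmed = FALSE, match_start = NA_integer_, matched_length = 0L,
       mismatches = NA_integer_)
}

# two-sided exact Mann-Whitney p by full enumeration of label assignments
mw_oracle_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  assignments <- utils::combn(length(r), n1)
  us <- apply(assignments, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# gapless containment mapping by direct all-positions string comparison
map_oracle <- function(insert, reference, max_mismatches = 0) {
  q <- strsplit(insert, "")[[1]]
  hits <- character(0)
  for (i in seq_len(nrow(reference))) {
    r <- strsplit(reference$sequence[i], "")[[1]]
    if (length(r) < length(q)) next
    best <- Inf
    for (s in 0:(length(r) - length(q))) {
      best <- min(best, sum(q != r[s + seq_along(q)]))
    }
    if (best <= max_mismatches) hits <- c(hits, reference$name[i])
  }
  hits
}

# dinucleotide entropy by direct tabulation
entropy_oracle <- function(sequence) {
  n <- nchar(sequence)
  if (n < 2) return(0)
  d <- substring(sequence, 1:(n - 1), 2:n)
  f <- table(d) / (n - 1)
  -sum(f * log2(f))
}

# linearized de Bruijn sequence over ACGT covering all 16 dinucleotides once
DEBRUIJN_42 <- "AACAGATCCGCTGGTTA"

random_reads_tbl <- function(n, lengths = 20:40) {
  lens <- sample(lengths, n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  tibble::tibble(id = sprintf("r%04d", seq_len(n)), sequence = seqs,
                 qualities = strrep("I", lens))
}

tiny_reference <- function() {
  tibble::tibble(
    name = c("mirA", "mirB", "mirC"),
    sequence = c("ACGTGCATGCTAGCTAGCAT",
                 "TTGACCGGTTACGATCCGTA",
                 "GCATCGATTTACGGCATCAGG"),
    cluster = c("C19MC", "C19MC", ""),
    arm = c("", "", "")
  )
}
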