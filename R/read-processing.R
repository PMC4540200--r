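#' The 16-barcode demultiplexing code
#'
#' The multiplexing scheme places a 4-nt barcode at the start of every read.
#' The code used here is a Hamming-distance-two code whose 16 words all end in
#' a cytosine: any two barcodes differ in at least two positions, so a single
#' sequencing error in the barcode can be detected (the read becomes
#' unassignable) but never silently mis-assigns a read to another sample.
#'
#' @return A tibble with columns `sample` (S01..S16) and `barcode`.
#' @export
#' @examples
#' default_barcode_set()
default_barcode_set <- function() {
  codes <- c("AAAC", "ACCC", "AGGC", "ATTC", "CACC", "CCGC", "CGTC", "CTAC",
             "GAGC", "GCTC", "GGAC", "GTCC", "TATC", "TCAC", "TGCC", "TTGC")
  tibble(sample = sprintf("S%02d", seq_along(codes)), barcode = codes)
}

#' Validate a barcode set
#'
#' Computes the minimum pairwise Hamming distance of a set of barcodes by
#' position-wise comparison over all pairs, and reports the structural flags a
#' demultiplexing code should satisfy (uniform length 4, all words ending in C).
#'
#' @param codes Character vector of at least two barcodes, or a data frame with
#'   a `barcode` column.
#' @return A tibble with one row: `min_hamming_distance`, `all_length_4`,
#'   `all_end_C`, `n_codes`.
#' @export
#' @examples
#' validate_barcode_set(default_barcode_set())
validate_barcode_set <- function(codes) {
  if (is.data.frame(codes)) codes <- codes$barcode
  codes <- as.character(codes)
  if (length(codes) < 2) {
    abort("need at least two barcodes", class = "placentamir_parameter_error")
  }
  if (anyDuplicated(codes)) {
    abort("duplicate barcodes in the set", class = "placentamir_validation_error")
  }
  pairs <- utils::combn(length(codes), 2)
  dists <- apply(pairs, 2, function(ij) {
    a <- strsplit(codes[ij[1]], "")[[1]]
    b <- strsplit(codes[ij[2]], "")[[1]]
    if (length(a) != length(b)) return(NA_integer_)
    sum(a != b)
  })
  tibble(
    min_hamming_distance = as.integer(min(dists)),
    all_length_4 = all(nchar(codes) == 4L),
    all_end_C = all(substr(codes, nchar(codes), nchar(codes)) == "C"),
    n_codes = length(codes)
  )
}

#' Assign reads to samples by their barcode prefix
#'
#' A read is assigned to a sample if and only if its first four bases exactly
#' equal one of the barcodes; the barcode bases (and qualities) are then
#' stripped. Matching is exact by design: with a distance-two code a single
#' barcode error is detectable but not correctable, so error correction would
#' risk mis-assignment. Reads shorter than 5 nt cannot carry both a barcode
#' and an insert; if their first four bases still match a barcode they are
#' assigned with an empty insert (and will be removed by the length filter
#' downstream), otherwise they are unassigned.
#'
#' @param reads A tibble of reads with columns `id`, `sequence`, `qualities`
#'   (as returned by [read_fastq()] or [simulate_library()]).
#' @param barcodes A barcode tibble (`sample`, `barcode`) such as
#'   [default_barcode_set()], or a named character vector.
#' @return The input tibble with a `sample` column (`"UNASSIGNED"` for reads
#'   whose prefix matches no barcode) and `sequence`/`qualities` stripped of
#'   the barcode for assigned reads.
#' @export
demultiplex <- function(reads, barcodes = default_barcode_set()) {
  barcodes <- as_barcode_tbl(barcodes)
  stopifnot(is.data.frame(reads), all(c("sequence", "qualities") %in% names(reads)))
  prefix <- substr(reads$sequence, 1L, 4L)
  idx <- match(prefix, barcodes$barcode)
  assigned <- !is.na(idx) & nchar(reads$sequence) >= 4L
  out <- as_tibble(reads)
  out$sample <- ifelse(assigned, barcodes$sample[idx], "UNASSIGNED")
  out$sequence <- ifelse(assigned, substr(out$sequence, 5L, nchar(out$sequence)), out$sequence)
  out$qualities <- ifelse(assigned, substr(out$qualities, 5L, nchar(out$qualities)), out$qualities)
  out
}

as_barcode_tbl <- function(barcodes) {
  if (is.data.frame(barcodes)) {
    stopifnot(all(c("sample", "barcode") %in% names(barcodes)))
    return(as_tibble(barcodes[c("sample", "barcode")]))
  }
  codes <- as.character(barcodes)
  nm <- names(barcodes) %||% codes
  tibble(sample = nm, barcode = codes)
}

#' Describe a 3' adapter and its trimming rule
#'
#' The trimming rule is a mismatch-tiered prefix alignment: an alignment of the
#' adapter prefix at some read offset is accepted when its aligned length is at
#' least `min_overlap` and its mismatch count does not exceed the allowance of
#' the longest satisfied tier. The default tiers allow one mismatch for
#' alignments of at least seven bases and two mismatches for alignments of at
#' least ten bases.
#'
#' @param sequence Adapter sequence (default: classic Illumina small RNA
#'   3' adapter).
#' @param min_overlap Minimum aligned length for any trim (default 7).
#' @param tiers Two-column matrix-like of `(min aligned length, max
#'   mismatches)`, ascending in length.
#' @return An object of class `adapter_spec`.
#' @export
adapter_spec <- function(sequence = "TCGTATGCCGTCTTCTGCTTG",
                         min_overlap = 7L,
                         tiers = cbind(min_len = c(7L, 10L), max_mm = c(1L, 2L))) {
  sequence <- toupper(as.character(sequence))
  assert_scalar_number(min_overlap, "min_overlap", min = 1)
  tiers <- as.matrix(tiers)
  stopifnot(ncol(tiers) == 2, nrow(tiers) >= 1, !is.unsorted(tiers[, 1]))
  if (nchar(sequence) < min_overlap) {
    abort("adapter shorter than min_overlap", class = "placentamir_parameter_error")
  }
  structure(list(sequence = sequence, min_overlap = as.integer(min_overlap),
                 tiers = tiers),
            class = "adapter_spec")
}

as_adapter_spec <- function(x) {
  if (inherits(x, "adapter_spec")) return(x)
  adapter_spec(sequence = x)
}

# mismatch allowance for aligned length L under the tier table; -1 = reject
tier_allowance <- function(L, tiers) {
  allow <- rep(-1L, length(L))
  for (k in seq_len(nrow(tiers))) {
    allow[L >= tiers[k, 1]] <- tiers[k, 2]
  }
  allow
}

#' Trim the 3' adapter from read sequences
#'
#' Scans candidate start offsets left to right. At offset `s` (0-based) the
#' aligned length is `min(adapter length, read length - s)`; the alignment is
#' accepted when the aligned length reaches the minimum overlap and its
#' mismatch count is within the tier allowance (by default one mismatch for
#' 7-9 aligned bases, two for 10 or more). The first (leftmost) accepted offset
#' wins and everything from it onward is removed; with no accepted offset the
#' read is returned untrimmed. `N` bases always count as mismatches.
#'
#' @param sequences Character vector of read sequences (post-demultiplexing).
#' @param adapter An [adapter_spec()] or a plain adapter string.
#' @return A tibble with one row per read: `insert`, `trimmed`, `match_start`
#'   (0-based offset, `NA` if untrimmed), `matched_length`, `mismatches`.
#' @export
#' @examples
#' trim_adapter(c("ACGTACGTACGTACGTCGTATGC"), adapter_spec())
trim_adapter <- function(sequences, adapter = adapter_spec()) {
  spec <- as_adapter_spec(adapter)
  sequences <- as.character(sequences)
  n <- length(sequences)
  if (n == 0) {
    return(tibble(insert = character(), trimmed = logical(),
                  match_start = integer(), matched_length = integer(),
                  mismatches = integer()))
  }
  if (any(!nzchar(sequences))) {
    abort("empty sequence passed to trim_adapter", class = "placentamir_input_error")
  }
  lens <- nchar(sequences)
  maxlen <- max(lens)
  ad <- utf8ToInt(spec$sequence)
  nad <- length(ad)

  # integer base matrix, NA beyond each read's end
  M <- matrix(NA_integer_, n, maxlen + nad)
  idx <- cbind(rep.int(seq_len(n), lens), sequence(lens))
  M[idx] <- unlist(lapply(sequences, utf8ToInt), use.names = FALSE)
  adM <- matrix(ad, n, nad, byrow = TRUE)

  match_start <- rep(NA_integer_, n)
  matched_length <- integer(n)
  mismatches <- rep(NA_integer_, n)
  done <- logical(n)

  for (s in 0:(maxlen - 1L)) {
    if (all(done)) break
    L <- pmin.int(nad, lens - s)
    cand <- !done & L >= spec$min_overlap
    if (!any(cand)) next
    cmp <- M[, s + seq_len(nad), drop = FALSE] != adM
    mm <- rowSums(cmp, na.rm = TRUE)
    ok <- cand & mm <= tier_allowance(L, spec$tiers)
    if (any(ok)) {
      match_start[ok] <- s
      matched_length[ok] <- L[ok]
      mismatches[ok] <- as.integer(mm[ok])
      done[ok] <- TRUE
    }
  }

  trimmed <- !is.na(match_start)
  insert <- ifelse(trimmed, substr(sequences, 1L, ifelse(is.na(match_start), 0L, match_start)),
                   sequences)
  tibble(insert = insert, trimmed = trimmed, match_start = match_start,
         matched_length = matched_length, mismatches = mismatches)
}

#' Dinucleotide Shannon entropy of read sequences
#'
#' The complexity score used to flag junk reads: the Shannon entropy (bits) of
#' the frequencies of the `length - 1` overlapping dinucleotides of a
#' sequence. A homopolymer scores 0; a pure two-letter repeat such as
#' `ACACAC...` (even dinucleotide counts) scores 1; a sequence covering all 16
#' dinucleotides equally scores 4. Sequences shorter than 2 nt score 0 by
#' definition. The entropy is bounded by `log2(min(16, length - 1))`.
#'
#' @param sequences Character vector of sequences.
#' @return Numeric vector of entropies in bits.
#' @export
#' @examples
#' dinucleotide_entropy(c("AAAAAAAA", "ACACACACA"))
dinucleotide_entropy <- function(sequences) {
  sequences <- as.character(sequences)
  n <- length(sequences)
  if (n == 0) return(numeric(0))
  lens <- nchar(sequences)
  H <- numeric(n)
  use <- lens >= 2L
  if (!any(use)) return(H)
  seqs <- sequences[use]
  ulens <- lens[use]
  maxd <- max(ulens) - 1L
  dinucs <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))  # 16 words
  # codes[i, p] = dinucleotide id at position p of read i (NA beyond end / non-ACGT)
  codes <- matrix(NA_integer_, length(seqs), maxd)
  for (p in seq_len(maxd)) {
    has <- ulens >= p + 1L
    codes[has, p] <- match(substr(seqs[has], p, p + 1L), dinucs)
  }
  counts <- matrix(0L, length(seqs), 16L)
  for (k in 1:16) counts[, k] <- rowSums(codes == k, na.rm = TRUE)
  tot <- rowSums(counts)
  plogp <- counts * log2(pmax(counts, 1L))
  Hu <- ifelse(tot > 0, log2(tot) - rowSums(plogp) / tot, 0)
  H[use] <- pmax(Hu, 0)
  H
}

#' Filter inserts by complexity and length
#'
#' Applies the two junk filters in order: first the dinucleotide-entropy
#' complexity filter (removed when entropy is strictly below the threshold),
#' then the minimum-length filter (removed when strictly shorter than
#' `min_length`). Each removed read is counted in exactly one category; a read
#' failing both is counted as low-complexity.
#'
#' @param inserts Character vector of insert sequences, or a tibble with an
#'   `insert` column.
#' @param entropy_threshold Bits; inserts with entropy `<` this are removed
#'   (default 1.5: removes homopolymers and pure dinucleotide repeats, keeps
#'   typical miRNA inserts whose entropy is around 3.5-4).
#' @param min_length Inserts shorter than this are removed (default 14).
#' @return A list with `passed` (same shape as the input, filtered) and
#'   `stats`, a one-row tibble of `low_complexity_removed`, `short_removed`,
#'   `passed`.
#' @export
filter_reads <- function(inserts, entropy_threshold = 1.5, min_length = 14L) {
  assert_scalar_number(entropy_threshold, "entropy_threshold", min = 0)
  assert_scalar_number(min_length, "min_length", min = 0)
  tbl <- NULL
  if (is.data.frame(inserts)) {
    tbl <- as_tibble(inserts)
    seqs <- tbl$insert
  } else {
    seqs <- as.character(inserts)
  }
  if (length(seqs) == 0) {
    return(list(passed = inserts,
                stats = tibble(low_complexity_removed = 0L, short_removed = 0L,
                               passed = 0L)))
  }
  low <- dinucleotide_entropy(seqs) < entropy_threshold
  short <- !low & nchar(seqs) < min_length
  keep <- !low & !short
  passed <- if (is.null(tbl)) seqs[keep] else tbl[keep, , drop = FALSE]
  list(passed = passed,
       stats = tibble(low_complexity_removed = sum(low),
                      short_removed = sum(short),
                      passed = sum(keep)))
}

#' Process a multiplexed small RNA library end to end
#'
#' Runs the read-level pipeline: barcode demultiplexing, 3' adapter trimming,
#' complexity filtering and length filtering, with full read-disposition
#' accounting. Every input read lands in exactly one terminal disposition:
#' `unassigned`, or per sample one of `low_complexity_removed`,
#' `short_removed`, `passed`. Untrimmed reads (no accepted adapter alignment)
#' continue into the filters with the full read as their insert.
#'
#' @param reads Read tibble (`id`, `sequence`, `qualities`).
#' @param barcodes Barcode set, see [demultiplex()].
#' @param adapter [adapter_spec()] or adapter string.
#' @param entropy_threshold,min_length Filter settings, see [filter_reads()].
#' @return A list with `inserts` (tibble `sample`, `insert`) and `stats`, a
#'   list with `total`, `unassigned`, and `per_sample` (tibble with columns
#'   `sample`, `assigned`, `trimmed`, `untrimmed`, `low_complexity_removed`,
#'   `short_removed`, `passed`).
#' @export
process_library <- function(reads, barcodes = default_barcode_set(),
                            adapter = adapter_spec(),
                            entropy_threshold = 1.5, min_length = 14L) {
  barcodes <- as_barcode_tbl(barcodes)
  dm <- demultiplex(reads, barcodes)
  assigned <- dm[dm$sample != "UNASSIGNED", , drop = FALSE]
  n_unassigned <- sum(dm$sample == "UNASSIGNED")

  if (nrow(assigned) > 0) {
    tr <- trim_adapter_allow_empty(assigned$sequence, adapter)
    assigned$insert <- tr$insert
    assigned$trimmed <- tr$trimmed
    ent <- dinucleotide_entropy(assigned$insert)
    low <- ent < entropy_threshold
    short <- !low & nchar(assigned$insert) < min_length
    keep <- !low & !short
  } else {
    assigned$insert <- character(0)
    assigned$trimmed <- logical(0)
    low <- short <- keep <- logical(0)
  }

  per_sample <- tibble(sample = assigned$sample, was_trimmed = assigned$trimmed,
                       low = low, short = short, keep = keep) |>
    group_by(.data$sample) |>
    summarise(assigned = n(),
              trimmed = sum(.data$was_trimmed),
              untrimmed = sum(!.data$was_trimmed),
              low_complexity_removed = sum(.data$low),
              short_removed = sum(.data$short),
              passed = sum(.data$keep),
              .groups = "drop")
  # keep samples with zero assigned reads out: callers can join on barcodes
  inserts <- tibble(sample = assigned$sample[keep], insert = assigned$insert[keep])
  list(inserts = inserts,
       stats = list(total = nrow(dm), unassigned = n_unassigned,
                    per_sample = per_sample))
}

# trim_adapter but tolerating empty sequences (barcode-only reads): these pass
# through untrimmed with an empty insert and fall to the length filter
trim_adapter_allow_empty <- function(sequences, adapter) {
  empty <- !nzchar(sequences)
  out <- tibble(insert = sequences, trimmed = FALSE,
                match_start = NA_integer_, matched_length = 0L,
                mismatches = NA_integer_)
  if (any(!empty)) out[!empty, ] <- trim_adapter(sequences[!empty], adapter)
  out
}
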