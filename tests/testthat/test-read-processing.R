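test_that("the demultiplexing code is a Hamming-distance-2 code ending in C", {
  v <- validate_barcode_set(default_barcode_set())
  expect_equal(v$min_hamming_distance, 2L)
  expect_true(v$all_length_4)
  expect_true(v$all_end_C)

  expect_equal(validate_barcode_set(c("AAAA", "AAAT"))$min_hamming_distance, 1L)
  expect_error(validate_barcode_set(c("AAAC", "AAAC")),
               class = "placentamir_validation_error")
  expect_error(validate_barcode_set("AAAC"), class = "placentamir_parameter_error")
})

test_that("demultiplexing assigns on exact prefix only and strips the barcode", {
  reads <- tibble::tibble(
    id = c("a", "b", "c"),
    sequence = c("AAACTGAGGTTTACG", "AAAGTGAGGTTTACG", "AAATTGAGGTTTACG"),
    qualities = strrep("I", 15))
  dm <- demultiplex(reads, default_barcode_set())
  expect_equal(dm$sample, c("S01", "UNASSIGNED", "UNASSIGNED"))
  expect_equal(dm$sequence[1], "TGAGGTTTACG")
  expect_equal(nchar(dm$qualities[1]), 11)
  # unassigned reads keep their full sequence
  expect_equal(dm$sequence[2], "AAAGTGAGGTTTACG")
})

test_that("demultiplexing partitions reads over samples", {
  withr::with_seed(7, {
    reads <- random_reads_tbl(300, lengths = 10:36)
    dm <- demultiplex(reads, default_barcode_set())
    expect_equal(nrow(dm), 300)
    expect_true(all(table(dm$id) == 1))
    expect_equal(sum(dm$sample == "UNASSIGNED") +
                   sum(dm$sample != "UNASSIGNED"), 300)
  })
})

test_that("adapter trimming follows the 7/10-base mismatch tiers", {
  ad <- adapter_spec("TCGTATGCCGTCTTCTGCTTG")
  insert <- "ACGTGCATGCTAGCT"

  # exact 7-base adapter prefix after a 15-nt insert
  r <- trim_adapter(paste0(insert, substr(ad$sequence, 1, 7)), ad)
  expect_true(r$trimmed)
  expect_equal(r$match_start, 15L)
  expect_equal(r$matched_length, 7L)
  expect_equal(r$mismatches, 0L)
  expect_equal(r$insert, insert)

  mk <- function(frag) paste0(insert, frag)
  mut <- function(s, at) {
    substr(s, at, at) <- ifelse(substr(s, at, at) == "A", "C", "A")
    s
  }
  # 7-base alignment: 1 mismatch trims, 2 mismatches does not
  f7 <- substr(ad$sequence, 1, 7)
  expect_true(trim_adapter(mk(mut(f7, 3)), ad)$trimmed)
  expect_false(trim_adapter(mk(mut(mut(f7, 3), 5)), ad)$trimmed)
  # 9-base alignment with 2 mismatches: untrimmed; 10-base with 2: trimmed
  f9 <- substr(ad$sequence, 1, 9)
  f10 <- substr(ad$sequence, 1, 10)
  expect_false(trim_adapter(mk(mut(mut(f9, 2), 6)), ad)$trimmed)
  r10 <- trim_adapter(mk(mut(mut(f10, 2), 6)), ad)
  expect_true(r10$trimmed)
  expect_equal(r10$mismatches, 2L)
  # alignments shorter than 7 bases never trim
  expect_false(trim_adapter(mk(substr(ad$sequence, 1, 6)), ad)$trimmed)
})

test_that("trimming agrees with the brute-force all-offsets oracle", {
  withr::with_seed(11, {
    n <- 2000
    adapter <- "TCGTATGCCGTCTTCTGCTTG"
    lens <- sample(8:40, n, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i) {
      # half the reads embed a (mutated) adapter fragment to hit the tiers
      L <- lens[i]
      s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      if (i %% 2 == 0) {
        k <- sample(5:12, 1)
        frag <- substr(adapter, 1, k)
        nmut <- sample(0:3, 1)
        for (p in sample(seq_len(k), min(nmut, k))) {
          substr(frag, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                               substr(frag, p, p)), 1)
        }
        s <- paste0(substr(s, 1, max(L - k, 1)), frag)
      }
      s
    }, character(1))
    got <- trim_adapter(seqs, adapter_spec(adapter))
    for (i in seq_len(n)) {
      want <- trim_oracle(seqs[i], adapter)
      expect_equal(got$trimmed[i], want$trimmed)
      if (want$trimmed) {
        expect_equal(got$match_start[i], want$match_start)
        expect_equal(got$matched_length[i], want$matched_length)
        expect_equal(got$mismatches[i], want$mismatches)
      }
    }
  })
})

test_that("dinucleotide entropy matches closed forms and direct tabulation", {
  expect_equal(dinucleotide_entropy("AAAAAAAA"), 0)
  expect_equal(dinucleotide_entropy("ACACACACA"), 1)
  expect_equal(dinucleotide_entropy(DEBRUIJN_42), 4)
  expect_equal(dinucleotide_entropy("A"), 0)
  expect_equal(dinucleotide_entropy(character(0)), numeric(0))

  withr::with_seed(3, {
    seqs <- random_reads_tbl(200, lengths = 2:40)$sequence
    H <- dinucleotide_entropy(seqs)
    expect_equal(H, vapply(seqs, entropy_oracle, numeric(1), USE.NAMES = FALSE))
    expect_true(all(H >= 0))
    expect_true(all(H <= log2(pmin(16, nchar(seqs) - 1)) + 1e-12))
  })
})

test_that("entropy depends only on the dinucleotide multiset", {
  # pairs sharing a dinucleotide multiset
  expect_equal(dinucleotide_entropy("ACACA"), dinucleotide_entropy("CACAC"))
  expect_equal(dinucleotide_entropy("AACAA"), dinucleotide_entropy("AAACA"))
  expect_equal(dinucleotide_entropy("GATTACA"), dinucleotide_entropy("TTACAGA"))
})

test_that("filtering applies complexity then length, each counted once", {
  inserts <- c("ACGTGCATGCTAGC",      # 14 nt, complex -> kept
               "ACGTGCATGCTAG",       # 13 nt, complex -> short
               "AAAAAAAAAAAAAAAA",    # homopolymer -> low complexity
               "ACACACACACAC",        # repeat, also short -> low complexity
               "GCATCGATTTACGGCATCAGG")
  fr <- filter_reads(inserts, entropy_threshold = 1.5, min_length = 14)
  expect_equal(fr$stats$low_complexity_removed, 2L)
  expect_equal(fr$stats$short_removed, 1L)
  expect_equal(fr$stats$passed, 2L)
  expect_equal(fr$passed, inserts[c(1, 5)])

  empty <- filter_reads(character(0))
  expect_equal(empty$stats$passed, 0L)
  expect_length(empty$passed, 0)
})

test_that("processing conserves every read into exactly one disposition", {
  ref <- make_mirna_reference(12, 5, seed = 6)
  withr::with_seed(19, {
    for (k in 1:25) {
      n_reads <- sample(50:400, 1)
      junk <- runif(2, 0, 0.2)
      bc <- default_barcode_set()[sample(1:16, 1), ]
      lib <- simulate_library(ref, barcode = bc$barcode, n_reads = n_reads,
                              error_rate = runif(1, 0, 0.05), junk_fracs = junk,
                              seed = sample.int(1e6, 1))
      p <- process_library(lib$reads, barcodes = default_barcode_set())
      s <- p$stats
      expect_equal(s$unassigned + sum(s$per_sample$assigned), n_reads)
      expect_equal(s$per_sample$low_complexity_removed +
                     s$per_sample$short_removed + s$per_sample$passed,
                   s$per_sample$assigned)
      expect_equal(s$per_sample$trimmed + s$per_sample$untrimmed,
                   s$per_sample$assigned)
      expect_equal(nrow(p$inserts), sum(s$per_sample$passed))
    }
  })
})

test_that("a clean simulated library passes exactly its miRNA reads", {
  ref <- make_mirna_reference(20, 8, seed = 3)
  lib <- simulate_library(ref, barcode = "AAAC", n_reads = 800, error_rate = 0,
                          junk_fracs = c(0, 0), seed = 5)
  p <- process_library(lib$reads)
  expect_equal(sum(p$stats$per_sample$passed),
               sum(lib$truth$mirna_counts$true_count))
})

test_that("a library of unknown barcodes is fully unassigned", {
  reads <- tibble::tibble(id = c("x", "y"),
                          sequence = c("GGGGACGTACGTACGT", "CCCTACGTACGTACGT"),
                          qualities = strrep("I", 16))
  p <- process_library(reads)
  expect_equal(p$stats$unassigned, 2L)
  expect_equal(nrow(p$inserts), 0L)
})
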