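# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

# run `code` with the RNG seeded, without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# deterministic child seed; kept below 2^31 - 1
child_seed <- function(seed, k) {
  (as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483629
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, min, max),
          class = "placentamir_parameter_error")
  }
  invisible(x)
}

random_dna <- function(n, lengths) {
  lengths <- rep_len(lengths, n)
  vapply(lengths, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
}

# apply independent substitution errors at `rate` per base across a character
# vector of sequences; substitution is always to a different base
mutate_sequences <- function(sequences, rate) {
  if (rate <= 0) return(sequences)
  lens <- nchar(sequences)
  total <- sum(lens)
  hit <- runif(total) < rate
  if (!any(hit)) return(sequences)
  chars <- strsplit(sequences, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  # substitute with one of the three other bases, uniformly
  shift <- sample.int(3, sum(hit), replace = TRUE)
  old_idx <- match(flat[hit], DNA_BASES)
  old_idx[is.na(old_idx)] <- 1L  # N or other: replace as if A
  flat[hit] <- DNA_BASES[((old_idx - 1L + shift) %% 4L) + 1L]
  starts <- cumsum(c(1L, lens[-length(lens)]))
  vapply(seq_along(sequences), function(i) {
    paste(flat[starts[i]:(starts[i] + lens[i] - 1L)], collapse = "")
  }, character(1))
}
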