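#' Map an insert to a mature-miRNA reference
#'
#' Gapless containment alignment: a hit is an end-to-end placement of the
#' insert inside a mature sequence with at most `max_mismatches`
#' substitutions. Mature miRNA references make gapped alignment unnecessary,
#' so only substitutions are considered. All hits are returned, ordered by
#' (mismatch count, reference order).
#'
#' @param insert Insert sequence (>= 14 nt, alphabet ACGTN).
#' @param reference Reference tibble (`name`, `sequence`).
#' @param max_mismatches Maximum substitutions allowed (default 0).
#' @return Character vector of matching miRNA names (possibly empty).
#' @export
map_insert <- function(insert, reference, max_mismatches = 0L) {
  stopifnot(is.character(insert), length(insert) == 1)
  if (grepl("[^ACGTN]", insert)) {
    abort("insert contains characters outside ACGTN",
          class = "placentamir_input_error")
  }
  if (nchar(insert) < 14) {
    abort("insert shorter than 14 nt", class = "placentamir_input_error")
  }
  q <- utf8ToInt(insert)
  nq <- length(q)
  hits <- purrr::map(seq_len(nrow(reference)), function(i) {
    r <- utf8ToInt(reference$sequence[i])
    if (length(r) < nq) return(NULL)
    best <- NA_integer_
    for (s in 0:(length(r) - nq)) {
      mm <- sum(q != r[s + seq_len(nq)])
      if (mm <= max_mismatches && (is.na(best) || mm < best)) best <- mm
    }
    if (is.na(best)) NULL else c(i = i, mm = best)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) return(character(0))
  reference$name[hits[order(hits[, "mm"], hits[, "i"]), "i"]]
}

# fast exact-containment multi-mapper: returns, per insert, the number of
# reference entries containing it and (for single hits) which one.
# built once per reference via a substring dictionary.
build_substring_index <- function(reference, min_len = 14L) {
  keys <- character(0); owner <- integer(0)
  for (i in seq_len(nrow(reference))) {
    s <- reference$sequence[i]
    L <- nchar(s)
    if (L < min_len) next
    for (len in min_len:L) {
      st <- seq_len(L - len + 1L)
      keys <- c(keys, substring(s, st, st + len - 1L))
      owner <- c(owner, rep.int(i, length(st)))
    }
  }
  # an insert hits entry i if it equals any substring of i; dedupe (key, owner)
  kd <- !duplicated(paste0(keys, "#", owner))
  keys <- keys[kd]; owner <- owner[kd]
  n_owners <- table(keys)
  uk <- names(n_owners)
  first_owner <- owner[match(uk, keys)]
  list(keys = uk, n_owners = as.integer(n_owners), first_owner = first_owner,
       reference = reference)
}

#' Count a library's inserts against a reference
#'
#' Maps each post-filter insert by exact gapless containment (the default
#' `max_mismatches = 0`) and accumulates counts under a multi-mapper policy:
#' `unique` counts only reads with a single hit (conservative default), `all`
#' adds 1 for every hit, `fractional` adds `1/n_hits` per hit. The library
#' total is recorded as the number of processed inserts given, so
#' normalization is to total processed reads, not miRNA-assigned reads.
#'
#' @param inserts Character vector of insert sequences.
#' @param reference Reference tibble.
#' @param policy `"unique"`, `"all"` or `"fractional"`.
#' @param max_mismatches Substitutions allowed when mapping (default 0).
#' @return Tibble `name`, `count` over all reference entries, with attribute
#'   `library_total`.
#' @export
count_library <- function(inserts, reference,
                          policy = c("unique", "all", "fractional"),
                          max_mismatches = 0L) {
  policy <- match.arg(policy)
  counts <- numeric(nrow(reference))
  if (length(inserts) > 0 && max_mismatches == 0) {
    idx <- build_substring_index(reference)
    m <- match(inserts, idx$keys)
    hit <- !is.na(m)
    nh <- idx$n_owners[m[hit]]
    if (policy == "unique") {
      single <- nh == 1L
      tab <- table(idx$first_owner[m[hit]][single])
      counts[as.integer(names(tab))] <- as.numeric(tab)
    } else {
      # enumerate owners per multi-hit insert via map_insert (rare path)
      for (k in which(hit)) {
        names_k <- map_insert(inserts[k], reference, 0L)
        add <- if (policy == "all") 1 else 1 / length(names_k)
        counts[match(names_k, reference$name)] <-
          counts[match(names_k, reference$name)] + add
      }
    }
  } else if (length(inserts) > 0) {
    for (k in seq_along(inserts)) {
      names_k <- map_insert(inserts[k], reference, max_mismatches)
      if (length(names_k) == 0) next
      if (policy == "unique") {
        if (length(names_k) == 1) {
          i <- match(names_k, reference$name)
          counts[i] <- counts[i] + 1
        }
      } else {
        add <- if (policy == "all") 1 else 1 / length(names_k)
        i <- match(names_k, reference$name)
        counts[i] <- counts[i] + add
      }
    }
  }
  out <- tibble(name = reference$name, count = counts)
  attr(out, "library_total") <- length(inserts)
  out
}

#' Quantify all samples of a processed library
#'
#' Runs [count_library()] on each sample's inserts and assembles a long count
#' table with per-library totals and cluster tags.
#'
#' @param inserts Tibble with columns `sample` and `insert` (e.g. the
#'   `inserts` element of [process_library()]), or a named list of insert
#'   vectors.
#' @param reference Reference tibble.
#' @param policy,max_mismatches Passed to [count_library()].
#' @return A `count_table`: list with `counts` (tibble `name`, `library`,
#'   `count`), `totals` (tibble `library`, `total`), `cluster` (tibble `name`,
#'   `cluster`).
#' @export
quantify_samples <- function(inserts, reference,
                             policy = c("unique", "all", "fractional"),
                             max_mismatches = 0L) {
  policy <- match.arg(policy)
  if (is.data.frame(inserts)) {
    inserts <- split(inserts$insert, inserts$sample)
  }
  cols <- purrr::imap(inserts, function(v, lib) {
    cl <- count_library(v, reference, policy, max_mismatches)
    tibble(name = cl$name, library = lib, count = cl$count)
  })
  totals <- tibble(library = names(inserts),
                   total = vapply(inserts, length, integer(1)))
  structure(list(counts = bind_rows(cols), totals = totals,
                 cluster = select(as_tibble(reference), "name", "cluster")),
            class = "count_table")
}

#' Normalize a count table to reads per million with a pseudocount log2 scale
#'
#' Normalizes each miRNA count to the total number of processed reads of its
#' library, scaled to reads per `scale` (default per million), then computes
#' `log2(value + pseudocount)` with the default pseudocount of 2 so that zero
#' counts remain finite (`log2(2) = 1`). The pseudocount is added to the
#' normalized value, not the raw count.
#'
#' @param table A `count_table` from [quantify_samples()].
#' @param scale Normalization scale (default 1e6).
#' @param pseudocount Added to normalized values before log2 (default 2).
#' @return Tibble `name`, `library`, `count`, `value`, `log2_value` with
#'   attributes `scale` and `pseudocount`.
#' @export
normalize_counts <- function(table, scale = 1e6, pseudocount = 2) {
  stopifnot(inherits(table, "count_table"))
  zero <- table$totals$library[table$totals$total <= 0]
  if (length(zero) > 0) {
    abort(paste0("library with zero total reads: ", paste(zero, collapse = ", ")),
          class = "placentamir_data_error")
  }
  out <- left_join(table$counts, table$totals, by = "library") |>
    mutate(value = .data$count / .data$total * scale,
           log2_value = log2(.data$value + pseudocount)) |>
    select(-"total")
  attr(out, "scale") <- scale
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Pearson correlation of two libraries' log2 expression
#'
#' @param normalized Normalized tibble from [normalize_counts()].
#' @param library_a,library_b Library names to compare.
#' @return Pearson correlation of paired `log2_value`s (symmetric in its
#'   arguments). Errors if fewer than 3 miRNAs are shared.
#' @export
replicate_correlation <- function(normalized, library_a, library_b) {
  a <- normalized[normalized$library == library_a, c("name", "log2_value")]
  b <- normalized[normalized$library == library_b, c("name", "log2_value")]
  m <- dplyr::inner_join(a, b, by = "name", suffix = c("_a", "_b"))
  if (nrow(m) < 3) {
    abort("fewer than 3 shared miRNAs between libraries",
          class = "placentamir_data_error")
  }
  cor(m$log2_value_a, m$log2_value_b)
}

#' Fraction of miRNA reads derived from a cluster
#'
#' Per library, the summed counts of cluster-tagged miRNAs divided by the
#' summed counts of all miRNAs. Used to verify the placental signature that
#' about half of all miRNA reads derive from the chromosome-19 miRNA cluster.
#'
#' @param table A `count_table`.
#' @param tag Cluster tag (default `"C19MC"`).
#' @return Tibble `library`, `fraction` (`NA` with a warning for libraries
#'   with zero miRNA counts).
#' @export
cluster_fraction <- function(table, tag = "C19MC") {
  stopifnot(inherits(table, "count_table"))
  joined <- left_join(table$counts, table$cluster, by = "name")
  out <- joined |>
    group_by(.data$library) |>
    summarise(fraction = {
      tot <- sum(.data$count)
      if (tot == 0) NA_real_ else sum(.data$count[.data$cluster == tag]) / tot
    }, .groups = "drop")
  if (any(is.na(out$fraction))) {
    warn("cluster_fraction undefined for libraries with zero miRNA counts")
  }
  out
}

#' Compare paired control and treated libraries
#'
#' Computes per-replicate log2 fold changes on the pseudocounted normalized
#' values (`log2_value` treated minus control for each replicate pair), their
#' mean, and a consistency call: a miRNA is flagged as consistently
#' deregulated when `|log2FC|` reaches the threshold with the same sign in
#' every replicate pair.
#'
#' @param normalized Normalized tibble from [normalize_counts()].
#' @param control,treated Character vectors of library names, paired in order
#'   (equal lengths).
#' @param fc_threshold_log2 Per-replicate |log2FC| threshold (default 1, i.e.
#'   twofold in every replicate).
#' @return A `mirna_comparison`: tibble `name`, `mean_log2fc`,
#'   `consistently_deregulated`, `direction`, plus a `log2fc` matrix attribute
#'   (miRNA x replicate) and the threshold.
#' @export
compare_conditions <- function(normalized, control, treated,
                               fc_threshold_log2 = 1) {
  if (length(control) != length(treated)) {
    abort("control and treated must pair equal replicate counts",
          class = "placentamir_parameter_error")
  }
  wide <- tidyr::pivot_wider(normalized[c("name", "library", "log2_value")],
                             names_from = "library", values_from = "log2_value")
  missing <- setdiff(c(control, treated), names(wide))
  if (length(missing) > 0) {
    abort(paste0("libraries not in table: ", paste(missing, collapse = ", ")),
          class = "placentamir_data_error")
  }
  fc <- as.matrix(wide[treated]) - as.matrix(wide[control])
  rownames(fc) <- wide$name
  colnames(fc) <- paste0("pair_", seq_along(control))
  mean_fc <- unname(rowMeans(fc))
  consistent <- unname(apply(fc, 1, function(v) {
    all(abs(v) >= fc_threshold_log2) && (all(v > 0) || all(v < 0))
  }))
  out <- tibble(name = wide$name, mean_log2fc = mean_fc,
                consistently_deregulated = consistent,
                direction = ifelse(mean_fc > 0, "up",
                                   ifelse(mean_fc < 0, "down", "none")))
  class(out) <- c("mirna_comparison", class(out))
  attr(out, "log2fc") <- fc
  attr(out, "fc_threshold_log2") <- fc_threshold_log2
  attr(out, "n_pairs") <- length(control)
  out
}
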