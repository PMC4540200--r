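#' Read a FASTQ file into a read tibble
#'
#' Parses 4-line FASTQ records (Phred+33) with structural validation: every
#' record must have an `@` header, a `+` separator, and sequence/quality
#' strings of equal length. Errors name the offending line.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return Tibble with columns `id`, `sequence`, `qualities`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "placentamir_io_error")
  }
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(tibble(id = character(), sequence = character(),
                  qualities = character()))
  }
  if (length(lines) %% 4 != 0) {
    abort(sprintf("truncated FASTQ record starting at line %d",
                  4 * (length(lines) %/% 4) + 1),
          class = "placentamir_io_error")
  }
  idx <- seq(1, length(lines), by = 4)
  bad_at <- idx[!startsWith(lines[idx], "@")]
  if (length(bad_at) > 0) {
    abort(sprintf("malformed header at line %d (expected '@')", bad_at[1]),
          class = "placentamir_io_error")
  }
  bad_plus <- idx[!startsWith(lines[idx + 2], "+")]
  if (length(bad_plus) > 0) {
    abort(sprintf("malformed separator at line %d (expected '+')", bad_plus[1] + 2),
          class = "placentamir_io_error")
  }
  seqs <- lines[idx + 1]
  quals <- lines[idx + 3]
  bad_len <- idx[nchar(seqs) != nchar(quals)]
  if (length(bad_len) > 0) {
    abort(sprintf("sequence/quality length mismatch at line %d", bad_len[1] + 1),
          class = "placentamir_io_error")
  }
  tibble(id = sub("^@", "", lines[idx]), sequence = seqs, qualities = quals)
}

#' Write a read tibble as FASTQ
#'
#' @param reads Tibble with `id`, `sequence`, `qualities`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "qualities") %in% names(reads)))
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$sequence,
                             "+", reads$qualities)), path)
  invisible(path)
}

#' Read a mature-miRNA reference from FASTA plus a cluster annotation table
#'
#' Sequences are upper-cased and U is converted to T so RNA-alphabet FASTA
#' files work directly. Cluster tags (and optional arm labels) are joined by
#' name from a TSV with columns `name`, `cluster` (and optionally `arm`);
#' annotation rows naming an absent miRNA produce a warning.
#'
#' @param fasta_path FASTA of mature sequences (read via Biostrings when
#'   available, otherwise a built-in parser).
#' @param cluster_path Optional TSV path with cluster membership.
#' @return Reference tibble (`name`, `sequence`, `cluster`, `arm`).
#' @export
read_fasta_reference <- function(fasta_path, cluster_path = NULL) {
  if (!file.exists(fasta_path)) {
    abort(paste0("no such file: ", fasta_path), class = "placentamir_io_error")
  }
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(fasta_path)
    nm <- sub("\\s.*$", "", names(ss))
    seqs <- as.character(ss)
  } else {
    lines <- readLines(fasta_path)
    hdr <- grepl("^>", lines)
    nm <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    grp <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = "")
  }
  if (anyDuplicated(nm)) {
    abort("duplicate FASTA names in reference", class = "placentamir_io_error")
  }
  seqs <- chartr("Uu", "Tt", seqs)
  ref <- tibble(name = nm, sequence = toupper(unname(seqs)),
                cluster = "", arm = "")
  if (!is.null(cluster_path)) {
    ann <- readr::read_tsv(cluster_path, show_col_types = FALSE)
    stopifnot(all(c("name", "cluster") %in% names(ann)))
    unmatched <- setdiff(ann$name, ref$name)
    if (length(unmatched) > 0) {
      warn(paste0("cluster annotation for absent miRNA(s): ",
                  paste(unmatched, collapse = ", ")))
    }
    m <- match(ref$name, ann$name)
    tag <- as.character(ann$cluster[m])
    ref$cluster <- ifelse(is.na(m) | is.na(tag), "", tag)
    if ("arm" %in% names(ann)) {
      arm <- as.character(ann$arm[m])
      ref$arm <- ifelse(is.na(m) | is.na(arm), "", arm)
    }
  }
  ref
}

#' Write a reference as FASTA plus a cluster annotation TSV
#'
#' @param reference Reference tibble.
#' @param fasta_path,cluster_path Output paths (`cluster_path` optional).
#' @return `fasta_path`, invisibly.
#' @export
write_fasta_reference <- function(reference, fasta_path, cluster_path = NULL) {
  writeLines(as.vector(rbind(paste0(">", reference$name), reference$sequence)),
             fasta_path)
  if (!is.null(cluster_path)) {
    readr::write_tsv(reference[c("name", "cluster", "arm")], cluster_path)
  }
  invisible(fasta_path)
}

#' Read or write a cohort sample sheet
#'
#' The universal table dialect is TSV with a header row; one row per placenta
#' piece x target x technical replicate.
#'
#' @param path TSV path.
#' @return Sample tibble.
#' @export
read_sample_sheet <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    placenta_id = readr::col_character(),
                    group = readr::col_character(),
                    piece_id = readr::col_character(),
                    .default = readr::col_guess()
                  ))
}

#' @rdname read_sample_sheet
#' @param samples Sample tibble to write.
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_tsv(samples, path)
  invisible(path)
}
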