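#' Generate a synthetic mature-miRNA reference
#'
#' Builds a reference of unique mature miRNA sequences (19-24 nt, ACGT
#' alphabet) with a declared number of entries carrying a cluster tag, mirroring
#' the placenta-specific chromosome-19 miRNA cluster (C19MC). By default the
#' reference also contains the linked pair `miR455-3P`/`miR455-5P`, the two
#' mature products of one pre-miRNA hairpin, which are left untagged.
#'
#' @param n_total Total number of reference entries.
#' @param n_cluster Number of entries carrying `cluster_tag` (0..n_total).
#' @param cluster_tag Tag string, e.g. `"C19MC"`; empty string disables tagging.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param include_mir455 Include the miR455-3P/-5P pair (default TRUE). The
#'   pair counts toward `n_total` and is never cluster-tagged.
#' @return A tibble with columns `name`, `sequence`, `cluster`, `arm`, and a
#'   `version_label` attribute.
#' @export
#' @examples
#' make_mirna_reference(n_total = 10, n_cluster = 4, seed = 1)
make_mirna_reference <- function(n_total = 60L, n_cluster = 30L,
                                 cluster_tag = "C19MC", seed = 1L,
                                 include_mir455 = TRUE) {
  assert_scalar_number(n_total, "n_total", min = 1)
  assert_scalar_number(n_cluster, "n_cluster", min = 0)
  if (n_cluster > n_total) {
    abort("n_cluster may not exceed n_total", class = "placentamir_parameter_error")
  }
  n_455 <- if (include_mir455) 2L else 0L
  if (n_total < n_455 + n_cluster) {
    abort("n_total too small for the miR455 pair plus n_cluster tagged entries",
          class = "placentamir_parameter_error")
  }
  with_seed(seed, {
    seqs <- character(0)
    while (length(seqs) < n_total) {
      need <- n_total - length(seqs)
      seqs <- unique(c(seqs, random_dna(need, sample(19:24, need, replace = TRUE))))
    }
    n_other <- n_total - n_455 - n_cluster
    name <- c(if (include_mir455) c("miR455-3P", "miR455-5P"),
              if (n_cluster > 0) sprintf("miR-cl-%03d", seq_len(n_cluster)),
              if (n_other > 0) sprintf("miR-sim-%03d", seq_len(n_other)))
    cluster <- c(rep("", n_455), rep(cluster_tag, n_cluster), rep("", n_other))
    arm <- c(if (include_mir455) c("3P", "5P"), rep("", n_cluster + n_other))
    ref <- tibble(name = name, sequence = seqs, cluster = cluster, arm = arm)
    attr(ref, "version_label") <- sprintf("synthetic-ref-seed%d", as.integer(seed))
    ref
  })
}

#' Default abundance weights for a synthetic reference
#'
#' Draws per-miRNA log-normal abundance weights and rescales them so that the
#' cluster-tagged entries carry `cluster_mass` of the total miRNA read mass
#' (emulating the observation that about half of all placental miRNA reads
#' derive from C19MC) and each miR455 arm carries `mir455_mass`.
#'
#' @param reference Reference tibble from [make_mirna_reference()].
#' @param cluster_mass Fraction of read mass on cluster-tagged miRNAs
#'   (default 0.5).
#' @param mir455_mass Fraction of read mass on each miR455 arm (default 0.004).
#' @param sdlog Log-normal spread of individual weights (default 1).
#' @param seed Integer seed.
#' @return Named numeric vector of weights summing to 1, in reference order.
#' @export
default_abundances <- function(reference, cluster_mass = 0.5,
                               mir455_mass = 0.004, sdlog = 1, seed = 1L) {
  stopifnot(is.data.frame(reference))
  with_seed(seed, {
    w <- stats::rlnorm(nrow(reference), meanlog = 0, sdlog = sdlog)
    names(w) <- reference$name
    is455 <- reference$arm %in% c("3P", "5P") & grepl("^miR455", reference$name)
    tagged <- nzchar(reference$cluster) & !is455
    other <- !tagged & !is455
    mass_455 <- mir455_mass * sum(is455)
    other_mass <- max(1 - cluster_mass - mass_455, 0)
    if (any(tagged)) w[tagged] <- w[tagged] / sum(w[tagged]) * cluster_mass
    if (any(other)) w[other] <- w[other] / sum(w[other]) * other_mass
    if (any(is455)) w[is455] <- mir455_mass
    w / sum(w)
  })
}

#' Simulate one multiplexed small RNA library
#'
#' Emulates the read structure of a barcoded small RNA library: every read is
#' `barcode (4 nt) + insert + 3' adapter fill`, truncated to the read length.
#' miRNA inserts are drawn from the reference proportionally to the abundance
#' weights; declared fractions of low-complexity junk (homopolymer or
#' dinucleotide-repeat inserts) and too-short inserts (< 14 nt) are injected;
#' independent substitution errors are applied across the whole read at
#' `error_rate` per base. The returned ground truth records, per category, the
#' exact number of reads written, so downstream accounting can be checked
#' against it.
#'
#' @param reference Reference tibble from [make_mirna_reference()].
#' @param abundances Named non-negative weights over reference names (not all
#'   zero); defaults to [default_abundances()].
#' @param barcode 4-nt barcode string.
#' @param adapter Adapter sequence appended after the insert.
#' @param n_reads Number of reads to write.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param junk_fracs Length-2 numeric `(low_complexity, too_short)`, summing
#'   to less than 1.
#' @param read_length Machine read length (default 36 cycles).
#' @param seed Integer seed.
#' @return A list with `reads` (tibble `id`, `sequence`, `qualities`) and
#'   `truth` (list with `mirna_counts` tibble, `low_complexity`, `too_short`,
#'   `unassigned_barcode`, `n_reads`).
#' @export
simulate_library <- function(reference, abundances = NULL,
                             barcode = "AAAC",
                             adapter = "TCGTATGCCGTCTTCTGCTTG",
                             n_reads = 1000L, error_rate = 0,
                             junk_fracs = c(low_complexity = 0, too_short = 0),
                             read_length = 36L, seed = 1L) {
  stopifnot(is.data.frame(reference))
  if (nchar(barcode) != 4L) {
    abort("barcode must be exactly 4 nt", class = "placentamir_parameter_error")
  }
  assert_scalar_number(n_reads, "n_reads", min = 1)
  assert_scalar_number(error_rate, "error_rate", min = 0, max = 1 - 1e-12)
  junk_fracs <- rep_len(as.numeric(junk_fracs), 2L)
  if (any(junk_fracs < 0) || sum(junk_fracs) >= 1) {
    abort("junk fractions must be >= 0 and sum to < 1",
          class = "placentamir_parameter_error")
  }
  if (is.null(abundances)) abundances <- default_abundances(reference, seed = seed)
  w <- abundances[reference$name]
  w[is.na(w)] <- 0
  if (any(w < 0) || sum(w) <= 0) {
    abort("abundance weights must be >= 0 and not all zero",
          class = "placentamir_parameter_error")
  }

  with_seed(seed, {
    n_cat <- as.vector(rmultinom(1, n_reads,
                                 c(junk_fracs[1], junk_fracs[2],
                                   1 - sum(junk_fracs))))
    n_low <- n_cat[1]; n_short <- n_cat[2]; n_mirna <- n_cat[3]

    src <- sample.int(nrow(reference), n_mirna, replace = TRUE, prob = w)
    mirna_inserts <- reference$sequence[src]

    low_inserts <- if (n_low > 0) {
      vapply(seq_len(n_low), function(i) {
        L <- sample(17:30, 1)
        if (runif(1) < 0.5) {
          strrep(sample(DNA_BASES, 1), L)
        } else {
          d <- sample(DNA_BASES, 2)
          substr(strrep(paste0(d, collapse = ""), ceiling(L / 2) + 1), 1, L)
        }
      }, character(1))
    } else character(0)
    short_inserts <- if (n_short > 0) {
      random_dna(n_short, sample(5:13, n_short, replace = TRUE))
    } else character(0)

    inserts <- c(mirna_inserts, low_inserts, short_inserts)
    perm <- sample.int(length(inserts))
    inserts <- inserts[perm]
    reads <- paste0(barcode, inserts, adapter, strrep("A", read_length))
    reads <- substr(reads, 1L, read_length)
    reads <- mutate_sequences(reads, error_rate)

    truth_counts <- tibble(name = reference$name) |>
      left_join(count(tibble(name = reference$name[src]), .data$name,
                      name = "true_count"),
                by = "name") |>
      mutate(true_count = dplyr::coalesce(.data$true_count, 0L))

    list(
      reads = tibble(
        id = sprintf("read_%06d", seq_along(reads)),
        sequence = reads,
        qualities = strrep("I", nchar(reads))
      ),
      truth = list(mirna_counts = truth_counts,
                   low_complexity = n_low, too_short = n_short,
                   unassigned_barcode = 0L, n_reads = as.integer(n_reads))
    )
  })
}

#' Simulate a paired control/treated differentiation experiment
#'
#' Emulates replicated small RNA libraries from an in vitro trophoblast
#' differentiation experiment: control libraries are drawn from a base
#' abundance profile, treated libraries from the same profile multiplied by
#' per-miRNA linear fold changes and renormalized. By default the miR455 arms
#' are induced fivefold (the magnitude observed during forskolin-driven
#' syncytialization) and everything else is unchanged. Each replicate pair is
#' sampled independently.
#'
#' @param reference Reference tibble.
#' @param fold_changes Named linear fold changes (> 0) applied in the treated
#'   condition; names missing from the reference are ignored.
#' @param n_replicates Number of control/treated pairs (default 4).
#' @param n_reads Reads per library (default 50,000).
#' @param error_rate,junk_fracs,read_length Passed to [simulate_library()].
#' @param cluster_mass,mir455_mass Passed to [default_abundances()].
#' @param barcodes Barcode tibble; the first `2 * n_replicates` codes are used.
#' @param seed Integer seed.
#' @return A list with `libraries` (tibble `library_id`, `condition`,
#'   `replicate`, `sample`, `barcode`, and a `reads` list-column), `truth`
#'   (tibble `library_id`, `name`, `true_count`), and `abundances` (list with
#'   `control` and `treated` weight vectors).
#' @export
simulate_differentiation <- function(reference,
                                     fold_changes = c("miR455-3P" = 5, "miR455-5P" = 5),
                                     n_replicates = 4L, n_reads = 50000L,
                                     error_rate = 0.005,
                                     junk_fracs = c(0.008, 0.02),
                                     read_length = 36L,
                                     cluster_mass = 0.5, mir455_mass = 0.004,
                                     barcodes = default_barcode_set(),
                                     seed = 1L) {
  if (n_replicates < 1) {
    abort("n_replicates must be >= 1", class = "placentamir_parameter_error")
  }
  if (any(fold_changes <= 0)) {
    abort("fold changes must be > 0", class = "placentamir_parameter_error")
  }
  barcodes <- as_barcode_tbl(barcodes)
  if (nrow(barcodes) < 2 * n_replicates) {
    abort("not enough barcodes for the requested replicates",
          class = "placentamir_parameter_error")
  }
  control_w <- default_abundances(reference, cluster_mass = cluster_mass,
                                  mir455_mass = mir455_mass,
                                  seed = child_seed(seed, 1))
  fc <- setNames(rep(1, nrow(reference)), reference$name)
  known <- intersect(names(fold_changes), names(fc))
  fc[known] <- fold_changes[known]
  treated_w <- control_w * fc
  treated_w <- treated_w / sum(treated_w)

  design <- tibble(
    condition = rep(c("control", "treated"), each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2L)
  ) |>
    mutate(library_id = paste0(.data$condition, "_", .data$replicate),
           sample = barcodes$sample[seq_len(2 * n_replicates)],
           barcode = barcodes$barcode[seq_len(2 * n_replicates)])

  sims <- purrr::pmap(design, function(condition, replicate, library_id, sample, barcode) {
    w <- if (condition == "control") control_w else treated_w
    simulate_library(reference, abundances = w, barcode = barcode,
                     n_reads = n_reads, error_rate = error_rate,
                     junk_fracs = junk_fracs, read_length = read_length,
                     seed = child_seed(seed, 100 + match(library_id, design$library_id)))
  })
  design$reads <- purrr::map(sims, ~ .x$reads)
  truth <- purrr::map2(sims, design$library_id, function(s, id) {
    mutate(s$truth$mirna_counts, library_id = id, .before = 1)
  }) |> bind_rows()
  list(libraries = design, truth = truth,
       abundances = list(control = control_w, treated = treated_w))
}

#' Describe a placenta cohort design
#'
#' Captures the study conditions of a two-group placenta qPCR cohort: group
#' sizes, pieces dissected per placenta, technical replicates, per-target
#' baseline abundances and preeclampsia effect sizes (log2 fold changes), and
#' the Ct noise decomposition. The defaults emulate a cohort of 15
#' preeclampsia and 14 control placentas with 3-4 pieces each, three
#' technical qPCR replicates, miR455-3P/-5P reduced, miR210 elevated, and the
#' C19MC representatives (miR517A, miR518B, miR526B) and U6 unchanged.
#'
#' @param n_pe,n_control Number of placentas per group.
#' @param pieces_per_placenta Integer vector of allowed piece counts (a single
#'   number fixes the count; a range samples uniformly).
#' @param n_technical Technical qPCR replicates per piece and target.
#' @param baseline_log2 Named baseline log2 relative abundances per target
#'   (arbitrary units; U6 = 0).
#' @param effects Named log2 fold changes applied in the PE group.
#' @param ct_reference_mean Ct of a target with baseline 0 (cycles).
#' @param placenta_sd,piece_sd,tech_sd Gaussian noise SDs (cycles) at the
#'   placenta, piece and technical-replicate level.
#' @param rin_mean,rin_sd RNA integrity number distribution (truncated to
#'   `[1, 10]`).
#' @param seed Integer seed.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_pe = 15L, n_control = 14L,
                          pieces_per_placenta = 3:4, n_technical = 3L,
                          baseline_log2 = c("miR455-3P" = 2, "miR455-5P" = 1.5,
                                            "miR210" = -1, "miR517A" = 1,
                                            "miR518B" = 0.5, "miR526B" = 0.8,
                                            "U6" = 0, "RPLP0" = 2),
                          effects = c("miR455-3P" = -2, "miR455-5P" = -2,
                                      "miR210" = 2),
                          ct_reference_mean = 22,
                          placenta_sd = 0.8, piece_sd = 0.4, tech_sd = 0.15,
                          rin_mean = 9, rin_sd = 0.5, seed = 1L) {
  assert_scalar_number(n_pe, "n_pe", min = 1)
  assert_scalar_number(n_control, "n_control", min = 1)
  for (s in c(placenta_sd, piece_sd, tech_sd)) {
    assert_scalar_number(s, "noise sd", min = 0)
  }
  structure(list(n_pe = as.integer(n_pe), n_control = as.integer(n_control),
                 pieces_per_placenta = as.integer(pieces_per_placenta),
                 n_technical = as.integer(n_technical),
                 baseline_log2 = baseline_log2, effects = effects,
                 ct_reference_mean = ct_reference_mean,
                 placenta_sd = placenta_sd, piece_sd = piece_sd,
                 tech_sd = tech_sd, rin_mean = rin_mean, rin_sd = rin_sd,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Simulate a placenta qPCR cohort
#'
#' Generates a long-format qPCR sample sheet (one row per placenta piece x
#' target x technical replicate) and per-patient clinical records. Ct values
#' follow the idealized amplification-efficiency-1 model
#' `Ct = reference_mean - log2(relative abundance) + noise`, with abundance
#' shifted by the design's log2 effects in the PE group and Gaussian noise at
#' the placenta, piece and technical level. Clinical blood-pressure and
#' proteinuria series are constructed so that PE patients satisfy, and
#' controls fail, the severe-preeclampsia eligibility rule (see
#' [classify_severe_pe()]).
#'
#' @param design A [cohort_design()].
#' @return A list with `samples` (tibble `placenta_id`, `group`, `piece_id`,
#'   `rin`, `target`, `tech_rep`, `ct`) and `patients` (tibble `placenta_id`,
#'   `group`, `gestational_age_weeks`, `parity`, and list-columns
#'   `bp_readings`, `proteinuria_readings`).
#' @export
simulate_cohort <- function(design = cohort_design()) {
  stopifnot(inherits(design, "cohort_design"))
  d <- design
  targets <- names(d$baseline_log2)
  eff <- setNames(rep(0, length(targets)), targets)
  eff[intersect(names(d$effects), targets)] <-
    d$effects[intersect(names(d$effects), targets)]

  with_seed(d$seed, {
    groups <- c(rep("PE", d$n_pe), rep("CONTROL", d$n_control))
    ids <- c(sprintf("PE%02d", seq_len(d$n_pe)),
             sprintf("C%02d", seq_len(d$n_control)))
    n_pieces <- if (length(d$pieces_per_placenta) == 1) {
      rep(d$pieces_per_placenta, length(ids))
    } else {
      sample(d$pieces_per_placenta, length(ids), replace = TRUE)
    }
    rin <- pmin(pmax(rnorm(length(ids), d$rin_mean, d$rin_sd), 1), 10)

    rows <- purrr::map(seq_along(ids), function(i) {
      pl_eff <- rnorm(length(targets), 0, d$placenta_sd)
      base <- d$ct_reference_mean -
        (d$baseline_log2 + if (groups[i] == "PE") eff else 0) - pl_eff
      purrr::map(seq_len(n_pieces[i]), function(p) {
        piece_eff <- rnorm(length(targets), 0, d$piece_sd)
        ct <- rep(base + piece_eff, each = d$n_technical) +
          rnorm(length(targets) * d$n_technical, 0, d$tech_sd)
        tibble(placenta_id = ids[i], group = groups[i],
               piece_id = paste0(ids[i], ".", p), rin = rin[i],
               target = rep(targets, each = d$n_technical),
               tech_rep = rep(seq_len(d$n_technical), length(targets)),
               ct = ct)
      }) |> bind_rows()
    }) |> bind_rows()

    patients <- purrr::map(seq_along(ids), function(i) {
      pe <- groups[i] == "PE"
      bp <- if (pe) {
        tibble(time = c(0, 8, 16),
               systolic = round(rnorm(3, 172, 6)),
               diastolic = round(rnorm(3, 106, 4)))
      } else {
        tibble(time = c(0, 8, 16),
               systolic = round(rnorm(3, 122, 6)),
               diastolic = round(rnorm(3, 76, 4)))
      }
      prot <- if (pe) {
        tibble(time = c(0, 12), dipstick_grade = sample(2:3, 2, replace = TRUE))
      } else {
        tibble(time = c(0, 12), dipstick_grade = sample(0:1, 2, replace = TRUE))
      }
      # keep the groups on the intended side of the severe-PE thresholds
      if (pe) {
        bp$systolic <- pmax(bp$systolic, 161)
        bp$diastolic <- pmax(bp$diastolic, 101)
      } else {
        bp$systolic <- pmin(bp$systolic, 155)
        bp$diastolic <- pmin(bp$diastolic, 95)
      }
      tibble(placenta_id = ids[i], group = groups[i],
             gestational_age_weeks = round(rnorm(1, if (pe) 33.5 else 38, 1.2), 1),
             parity = sample(0:3, 1),
             bp_readings = list(bp), proteinuria_readings = list(prot))
    }) |> bind_rows()

    list(samples = rows, patients = patients)
  })
}

#' Simulate a dual-luciferase reporter plate
#'
#' Generates renilla (RL) and firefly (FL) readings for a reporter construct
#' measured under DMSO (vehicle) and FSK (forskolin) conditions, with
#' `n_bio` biological and `n_tech` technical replicates per condition. DMSO
#' wells have an RL/FL ratio around `baseline_ratio`; FSK wells around
#' `baseline_ratio * (1 - true_repression)`; multiplicative log-normal noise
#' with coefficient of variation `noise_cv` is applied per well to RL and FL
#' independently.
#'
#' @param true_repression Fraction in `[0, 1)` by which FSK represses RL.
#' @param n_bio,n_tech Biological and technical replicate counts.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param baseline_ratio DMSO RL/FL ratio (default 1).
#' @param fl_level Mean firefly luminescence (arbitrary units).
#' @param construct Construct label.
#' @param seed Integer seed.
#' @return Tibble with columns `construct`, `condition`, `bio_rep`,
#'   `tech_rep`, `rl`, `fl`.
#' @export
simulate_luciferase <- function(true_repression = 0.5, n_bio = 3L, n_tech = 3L,
                                noise_cv = 0.05, baseline_ratio = 1,
                                fl_level = 10000, construct = "UTR",
                                seed = 1L) {
  if (true_repression < 0 || true_repression >= 1) {
    abort("true_repression must be in [0, 1)", class = "placentamir_parameter_error")
  }
  assert_scalar_number(noise_cv, "noise_cv", min = 0)
  grid <- tidyr::expand_grid(condition = c("DMSO", "FSK"),
                             bio_rep = seq_len(n_bio),
                             tech_rep = seq_len(n_tech))
  with_seed(seed, {
    ratio <- ifelse(grid$condition == "FSK",
                    baseline_ratio * (1 - true_repression), baseline_ratio)
    noise <- function(n) {
      if (noise_cv == 0) return(rep(1, n))
      sdl <- sqrt(log(1 + noise_cv^2))
      stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
    }
    fl <- fl_level * noise(nrow(grid))
    rl <- fl * ratio * noise(nrow(grid))
    mutate(grid, construct = construct, .before = 1) |>
      mutate(rl = rl, fl = fl)
  })
}
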