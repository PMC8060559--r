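#' Simulation parameters for synthetic MS/MS spectra
#'
#' Controls the spectrum generator: how many uniform-random decoy
#' peaks to add, the Gaussian m/z jitter applied to surviving
#' theoretical ions, the probability that a theoretical ion is dropped,
#' a simple linearly decaying intensity model, and whether the HNCO
#' neutral-loss companion of the precursor is planted for
#' citrullinated peptides.
#'
#' @param seed Integer seed; every generator in the package is
#'   deterministic given its seed.
#' @param noise_peaks Count of decoy peaks, drawn uniformly over
#'   \[100, precursor m/z\] with exponential intensities.
#' @param mz_jitter_sd Gaussian jitter SD (Da) on surviving ion m/z.
#' @param dropout_prob Probability a theoretical ion is omitted.
#' @param base_intensity Intensity of the first fragment of each
#'   series; later fragments decay linearly to half of it.
#' @param noise_mean Mean of the exponential decoy intensities.
#' @param loss_intensity Relative intensity (fraction of
#'   `base_intensity`) of the planted precursor-loss peak.
#' @param plant_neutral_loss Plant the precursor - 43.005814/z
#'   companion when the peptide is citrullinated?
#' @return A `sim_params` list.
#' @export
sim_params <- function(seed = 1L, noise_peaks = 0L, mz_jitter_sd = 0,
                       dropout_prob = 0, base_intensity = 100,
                       noise_mean = 10, loss_intensity = 0.3,
                       plant_neutral_loss = TRUE) {
  stopifnot(dropout_prob >= 0, dropout_prob <= 1, mz_jitter_sd >= 0,
            noise_peaks >= 0, base_intensity > 0, noise_mean > 0,
            loss_intensity > 0)
  structure(
    list(seed = as.integer(seed), noise_peaks = as.integer(noise_peaks),
         mz_jitter_sd = mz_jitter_sd, dropout_prob = dropout_prob,
         base_intensity = base_intensity, noise_mean = noise_mean,
         loss_intensity = loss_intensity,
         plant_neutral_loss = isTRUE(plant_neutral_loss)),
    class = "sim_params"
  )
}

#' Simulate a CID spectrum of a modified peptide
#'
#' Generates the 1+ b/y fragment ions of `mp`, drops each with
#' probability `dropout_prob`, jitters surviving m/z with Gaussian
#' noise, adds the precursor HNCO-loss companion for citrullinated
#' peptides (when enabled), and sprinkles uniform decoy peaks.
#' Fragment intensities decay linearly with index from
#' `base_intensity` to half of it. Deterministic given
#' (`params$seed`, peptide, charge).
#'
#' @param mp A [modified_peptide()]; ground truth is its modification
#'   placement.
#' @param charge Precursor charge (default 2).
#' @param params A [sim_params()].
#' @return A list with `spectrum` (a [spectrum()]) and `truth` (a list
#'   with the true `sequence`, `positions`, `residues`, `mod_names`).
#' @export
simulate_spectrum <- function(mp, charge = 2L, params = sim_params()) {
  stopifnot(inherits(mp, "modified_peptide"), inherits(params, "sim_params"),
            charge >= 1L)
  ions <- fragment_series(mp, max_charge = 1L)
  n <- nrow(ions)
  precursor_mz <- mz(peptide_mass(mp), charge)
  residues <- strsplit(mp$sequence, "")[[1]]
  withr::with_seed(params$seed, {
    keep <- stats::runif(n) >= params$dropout_prob
    ion_mz <- ions$mz[keep] +
      stats::rnorm(sum(keep), sd = params$mz_jitter_sd)
    # per-series linear decay from base to base/2 across fragment index
    rel <- 1 - 0.5 * (ions$index[keep] - 1L) / max(1L, max(ions$index) - 1L)
    ion_int <- params$base_intensity * rel
    loss_mz <- loss_int <- numeric()
    if (params$plant_neutral_loss && length(cit_positions(mp))) {
      loss_mz <- precursor_mz - .mass$hnco_loss / charge
      loss_int <- params$loss_intensity * params$base_intensity
    }
    noise_mz <- stats::runif(params$noise_peaks, 100, precursor_mz)
    noise_int <- stats::rexp(params$noise_peaks, rate = 1 / params$noise_mean)
  })
  peaks <- tibble::tibble(
    mz = c(ion_mz, loss_mz, noise_mz),
    intensity = c(ion_int, loss_int, noise_int)
  )
  truth <- list(
    sequence = mp$sequence,
    positions = mp$positions,
    residues = residues[mp$positions],
    mod_names = vapply(mp$mods, `[[`, "", "name")
  )
  list(
    spectrum = spectrum(id = paste0("sim_", mp$sequence),
                        precursor_mz = precursor_mz,
                        precursor_charge = charge, peaks = peaks),
    truth = truth
  )
}

#' Simulate a proteome with planted motif occurrences
#'
#' Draws background sequences from stated residue frequencies and
#' inserts realizations of a motif pattern at recorded positions.
#' Useful as an exact-recovery test bed for the scanner: with a
#' background alphabet disjoint from the motif's anchor residues,
#' every reported match is a planted one.
#'
#' @param n_records Number of proteins.
#' @param length_range Integer range (min, max) of background lengths.
#' @param residue_freqs Named numeric vector of background residue
#'   frequencies (normalized internally). Default: uniform over the 20
#'   standard residues.
#' @param pattern A pattern string or [parse_pattern()] result to
#'   plant, or NULL for none.
#' @param n_planted Total number of occurrences to plant (assigned to
#'   random records, several per record allowed).
#' @param seed Integer seed.
#' @return A list with `proteome` (protein tibble as from
#'   [read_fasta()]) and `truth` (tibble `accession`, `start`, `end`).
#' @export
simulate_proteome <- function(n_records = 100L, length_range = c(120L, 400L),
                              residue_freqs = NULL, pattern = NULL,
                              n_planted = 0L, seed = 1L) {
  stopifnot(n_records >= 1L, length(length_range) == 2L,
            length_range[1] >= 10L, length_range[2] >= length_range[1])
  if (is.null(residue_freqs)) {
    residue_freqs <- stats::setNames(rep(1, 20), names(residue_formulas))
  }
  residue_freqs <- residue_freqs / sum(residue_freqs)
  alphabet <- names(residue_freqs)
  if (!is.null(pattern) && !inherits(pattern, "motif_pattern")) {
    pattern <- parse_pattern(pattern)
  }
  withr::with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n_records,
                   replace = TRUE)
    seqs <- vapply(lens, function(l) {
      paste(sample(alphabet, l, replace = TRUE, prob = residue_freqs),
            collapse = "")
    }, character(1))
    truth <- tibble::tibble(accession = character(), start = integer(),
                            end = integer())
    if (n_planted > 0L) {
      stopifnot(!is.null(pattern))
      rec <- sort(sample.int(n_records, n_planted,
                             replace = n_planted > n_records))
      for (r in rec) {
        occ <- .realize_pattern(pattern, alphabet, residue_freqs)
        s <- strsplit(seqs[r], "")[[1]]
        if (length(s) < nchar(occ)) next
        start <- sample.int(length(s) - nchar(occ) + 1L, 1L)
        s[start:(start + nchar(occ) - 1L)] <- strsplit(occ, "")[[1]]
        seqs[r] <- paste(s, collapse = "")
        truth <- dplyr::bind_rows(truth, tibble::tibble(
          accession = sprintf("SIM%05d", r), start = start,
          end = start + nchar(occ) - 1L))
      }
    }
  })
  proteome <- tibble::tibble(
    accession = sprintf("SIM%05d", seq_len(n_records)),
    isoform = NA_integer_,
    description = "simulated protein",
    sequence = seqs
  )
  # planting may overwrite an earlier planted window in the same record;
  # keep only occurrences still intact so truth is exact by construction
  if (nrow(truth)) {
    intact <- vapply(seq_len(nrow(truth)), function(i) {
      seq_i <- proteome$sequence[proteome$accession == truth$accession[i]]
      window <- substr(seq_i, truth$start[i], truth$end[i])
      length(scan_motif(pattern, window)$start) > 0 &&
        any(scan_motif(pattern, window)$start == 1L &
              scan_motif(pattern, window)$end == nchar(window))
    }, logical(1))
    truth <- truth[intact, , drop = FALSE]
  }
  list(proteome = proteome, truth = truth)
}

# draw one concrete sequence matching a motif pattern
.realize_pattern <- function(pattern, alphabet, freqs) {
  out <- character()
  for (tok in pattern$tokens) {
    if (tok$kind == "class") {
      out <- c(out, sample(tok$letters, 1L))
    } else if (tok$kind == "wildcard") {
      out <- c(out, sample(alphabet, 1L, prob = freqs))
    } else {  # gap
      len <- if (tok$min == tok$max) tok$min else
        sample(seq(tok$min, tok$max), 1L)
      if (len > 0L) {
        out <- c(out, sample(alphabet, len, replace = TRUE, prob = freqs))
      }
    }
  }
  paste(out, collapse = "")
}

#' Simulate a citrullination quantification table
#'
#' Builds per-protein intensity records across a control / 1 h / 24 h
#' time course with planted categories: baseline records with fold
#' changes near 1 at both timepoints, increased / decreased records
#' with fold changes inside the stated ranges (applied at both
#' timepoints), de-novo records absent in control, and lost records
#' absent after treatment.
#'
#' @param n_baseline,n_increased,n_decreased,n_de_novo,n_lost Record
#'   counts per planted category.
#' @param fc_increased,fc_decreased Fold-change ranges (min, max) for
#'   the differential categories.
#' @param fc_baseline_sd SD of log2 fold change around 0 for baseline
#'   records (kept well inside the thresholds).
#' @param seed Integer seed.
#' @return A list with `quant` (tibble: `accession`, `peptide`,
#'   `intensity_control`, `intensity_1h`, `intensity_24h`) and `truth`
#'   (tibble: `accession`, `category`).
#' @export
simulate_quant_table <- function(n_baseline = 10L, n_increased = 3L,
                                 n_decreased = 1L, n_de_novo = 5L,
                                 n_lost = 0L,
                                 fc_increased = c(1.6, 3),
                                 fc_decreased = c(0.3, 0.625),
                                 fc_baseline_sd = 0.1, seed = 1L) {
  categories <- c(rep("baseline", n_baseline),
                  rep("increased", n_increased),
                  rep("decreased", n_decreased),
                  rep("de_novo", n_de_novo),
                  rep("lost", n_lost))
  n <- length(categories)
  withr::with_seed(seed, {
    control <- stats::rlnorm(n, meanlog = log(1000), sdlog = 0.5)
    fc1 <- fc24 <- numeric(n)
    for (i in seq_len(n)) {
      fc1[i] <- switch(categories[i],
        baseline = 2^stats::rnorm(1, 0, fc_baseline_sd),
        increased = stats::runif(1, fc_increased[1], fc_increased[2]),
        decreased = stats::runif(1, fc_decreased[1], fc_decreased[2]),
        de_novo = NA_real_, lost = NA_real_)
      fc24[i] <- switch(categories[i],
        baseline = 2^stats::rnorm(1, 0, fc_baseline_sd),
        increased = stats::runif(1, fc_increased[1], fc_increased[2]),
        decreased = stats::runif(1, fc_decreased[1], fc_decreased[2]),
        de_novo = NA_real_, lost = NA_real_)
    }
    i1 <- control * fc1
    i24 <- control * fc24
    denovo <- categories == "de_novo"
    lost <- categories == "lost"
    i1[denovo] <- stats::rlnorm(sum(denovo), log(800), 0.5)
    i24[denovo] <- stats::rlnorm(sum(denovo), log(800), 0.5)
    control[denovo] <- 0
    i1[lost] <- 0
    i24[lost] <- 0
  })
  quant <- tibble::tibble(
    accession = sprintf("SIMQ%04d", seq_len(n)),
    peptide = NA_character_,
    intensity_control = control,
    intensity_1h = i1,
    intensity_24h = i24
  )
  list(quant = quant,
       truth = tibble::tibble(accession = quant$accession,
                              category = categories))
}
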