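#' Load the packaged citrullination events table
#'
#' The package ships a plain-text transcription of the published table
#' of citrullinated peptides across the cold time course (control
#' baseline, differentially citrullinated, and de novo sections).
#' Peptides are returned both verbatim and parsed out of their flanked
#' notation, with the positions of the table's unexplained lowercase
#' letters recorded.
#'
#' @return A tibble with columns `section`, `accession`,
#'   `description`, `mascot_score`, `mass`, `peptide` (verbatim),
#'   `pep_score`, `expect`, `fc_1h`, `fc_24h`, `sequence` (upper-cased
#'   body), `prev_residue`, `next_residue`, `lowercase_positions`
#'   (list column).
#' @examples
#' table1 <- load_table1()
#' nrow(table1)  # 19
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_fixture.tsv",
                      package = "citrullinr", mustWork = TRUE)
  raw <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  out <- tibble::as_tibble(raw)
  out$mascot_score <- as.numeric(out$mascot_score)
  out$mass <- as.numeric(out$mass)
  out$pep_score <- as.numeric(out$pep_score)
  out$expect <- as.numeric(out$expect)
  parsed <- lapply(out$peptide, parse_flanked)
  out$sequence <- vapply(parsed, `[[`, "", "sequence")
  out$prev_residue <- vapply(parsed, `[[`, "", "prev_residue")
  out$next_residue <- vapply(parsed, `[[`, "", "next_residue")
  out$lowercase_positions <- lapply(parsed, `[[`, "lowercase_positions")
  out
}

#' Pipeline configuration
#'
#' Bundles every tunable the analysis stages share: matching
#' tolerances (0.5 Da fragments, 10 ppm precursor), ion-score
#' thresholds (peptide 30, protein 32), fold-change thresholds (1.5
#' and its reciprocal), logo half-width (7), localization ambiguity
#' margin (5 score units), and the seed for the simulators. Unknown
#' keys are rejected.
#'
#' @param ... Name-value overrides of the defaults.
#' @return A `pipeline_config` list.
#' @examples
#' pipeline_config(fragment_tol = 0.4, seed = 7)
#' @export
pipeline_config <- function(...) {
  config <- list(
    fragment_tol = 0.5, precursor_ppm = 10,
    peptide_min = 30, protein_min = 32,
    fc_up = 1.5, fc_down = 1 / 1.5,
    logo_half_width = 7L, ambiguity_margin = 5,
    intensity_floor = 0.01, seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  config[names(overrides)] <- overrides
  numeric_keys <- setdiff(names(config), character())
  for (key in numeric_keys) {
    if (!is.numeric(config[[key]]) || config[[key]] <= 0) {
      stop("configuration key '", key, "' must be a positive number",
           call. = FALSE)
    }
  }
  structure(config, class = "pipeline_config")
}

#' Run the full analysis pipeline on packaged and simulated inputs
#'
#' Sequences the package's stages end to end: load the packaged
#' events table, categorize and summarize the time-course changes;
#' simulate citrullinated/deamidated spectra and re-localize their
#' sites; simulate a proteome with planted signature-motif
#' occurrences, scan it, and build the sequence-context logo from the
#' recovered sites. Deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @param n_spectra Number of simulated validation spectra.
#' @param n_proteins,n_planted Size of the simulated proteome stage.
#' @return A `pipeline_report` list: `config`, `table1_summary`,
#'   `localization` (tibble per spectrum), `site_recovery_rate`,
#'   `motif` (planted vs found counts), `logo`, `consensus`.
#' @export
run_pipeline <- function(config = pipeline_config(), n_spectra = 50L,
                         n_proteins = 100L, n_planted = 25L) {
  stopifnot(inherits(config, "pipeline_config"))
  thresholds <- score_thresholds(config$peptide_min, config$protein_min)

  # stage 1: published events table
  table1 <- load_table1()
  summary1 <- summarize_changes(
    categorize_changes(table1, up = config$fc_up, down = config$fc_down)
  )

  # stage 2: simulate spectra with known sites and re-localize
  sims <- simulate_validation_spectra(n_spectra, seed = config$seed)
  loc <- purrr::map2_dfr(sims$spectra, sims$truth, function(sp, tr) {
    assignment <- localize(sp, tr$sequence, n_deltas = length(tr$positions),
                           fragment_tol = config$fragment_tol,
                           precursor_ppm = config$precursor_ppm,
                           thresholds = thresholds,
                           margin = config$ambiguity_margin,
                           intensity_floor = config$intensity_floor)
    tibble::tibble(
      sequence = tr$sequence,
      true_positions = paste(tr$positions, collapse = ","),
      called_positions = paste(assignment$positions, collapse = ","),
      recovered = identical(assignment$positions, tr$positions),
      score = assignment$score,
      neutral_loss_found = assignment$neutral_loss_found,
      status = assignment$status
    )
  })

  # stage 3: planted-motif proteome scan and logo
  signature <- parse_pattern("[RS]xRx{4}RL")
  sim_prot <- simulate_proteome(
    n_records = n_proteins, pattern = signature, n_planted = n_planted,
    seed = config$seed + 1L
  )
  hits <- scan_motif(signature, sim_prot$proteome)
  # citrullination target = third pattern position (offset +2 from start)
  sites <- tibble::tibble(accession = sim_prot$truth$accession,
                          position = sim_prot$truth$start + 2L)
  logo <- if (nrow(sites)) {
    build_logo(sites, sim_prot$proteome,
               half_width = config$logo_half_width)
  } else NULL
  consensus <- if (!is.null(logo)) consensus_pattern(logo) else NA_character_

  structure(
    list(config = config,
         table1_summary = summary1,
         localization = loc,
         site_recovery_rate = mean(loc$recovered),
         motif = list(planted = nrow(sim_prot$truth),
                      found = nrow(hits),
                      loci_matched = count_matching_proteins(
                        signature, sim_prot$proteome)),
         logo = logo, consensus = consensus),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  events table:",
      paste(sprintf("%s=%d", names(x$table1_summary$counts),
                    x$table1_summary$counts), collapse = " "), "\n")
  cat(sprintf("  site recovery: %.1f%% over %d simulated spectra\n",
              100 * x$site_recovery_rate, nrow(x$localization)))
  cat(sprintf("  motif scan: %d planted, %d found, %d loci matched\n",
              x$motif$planted, x$motif$found, x$motif$loci_matched))
  cat("  consensus:", x$consensus, "\n")
  invisible(x)
}

#' Simulate a batch of site-validation spectra
#'
#' Draws tryptic-like peptides carrying one +0.984 Da delta on a
#' random eligible residue (R, N or Q), simulates their CID spectra
#' under a mild noise regime, and returns spectra with ground truth.
#' Used by [run_pipeline()] and the validation studies.
#'
#' @param n Number of spectra.
#' @param seed Integer seed.
#' @param params A [sim_params()] template; its seed is re-derived per
#'   spectrum from `seed`.
#' @return A list with `spectra` (list of [spectrum()]) and `truth`
#'   (list of truth records, see [simulate_spectrum()]).
#' @export
simulate_validation_spectra <- function(n, seed = 1L,
                                        params = sim_params(
                                          noise_peaks = 5L,
                                          mz_jitter_sd = 0.02,
                                          dropout_prob = 0.1)) {
  peptides <- withr::with_seed(seed, {
    replicate(n, .random_tryptic_peptide(), simplify = FALSE)
  })
  spectra <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    p <- params
    p$seed <- as.integer((seed * 1009L + i) %% .Machine$integer.max)
    sim <- simulate_spectrum(peptides[[i]], charge = 2L, params = p)
    spectra[[i]] <- sim$spectrum
    truth[[i]] <- sim$truth
  }
  list(spectra = spectra, truth = truth)
}

# a tryptic-like peptide (ends in K/R) of length 8-16 containing at
# least one R and at least one N/Q, with one delta planted on a random
# eligible residue as citrullination (R) or deamidation (N/Q)
.random_tryptic_peptide <- function() {
  letters20 <- names(residue_formulas)
  repeat {
    len <- sample(8:16, 1L)
    body <- sample(setdiff(letters20, "K"), len - 1L, replace = TRUE)
    seq <- paste(c(body, sample(c("K", "R"), 1L)), collapse = "")
    residues <- strsplit(seq, "")[[1]]
    eligible <- which(residues %in% c("R", "N", "Q"))
    # demand genuine ambiguity: both an R and an N/Q present
    if (!any(residues[eligible] == "R")) next
    if (!any(residues[eligible] %in% c("N", "Q"))) next
    pos <- sample(eligible, 1L)
    mod <- if (residues[pos] == "R") mod_citrullination() else
      mod_deamidation()
    return(modified_peptide(seq, mods = list(mod), positions = pos))
  }
}
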