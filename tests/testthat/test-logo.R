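# two-protein toy proteome with known windows around arginines
toy_proteome <- function(seqs) {
  tibble::tibble(
    accession = sprintf("AT%dG%05d", seq_along(seqs), seq_along(seqs)),
    isoform = NA_integer_, description = "", sequence = seqs
  )
}

test_that("information content reaches its limits", {
  # every window identical: the off-centre columns carry log2(20) bits
  prot <- toy_proteome(rep("GGGRGGG", 5))
  sites <- tibble::tibble(accession = prot$accession, position = 4L)
  logo <- build_logo(sites, prot, half_width = 3L)
  expect_equal(unname(logo$information["-1"]), log2(20), tolerance = 1e-12)
  expect_equal(unname(logo$information["0"]), log2(20), tolerance = 1e-12)

  # a column uniform over the 20 residues has zero bits
  letters20 <- names(citrullinr:::residue_formulas)
  seqs <- paste0(letters20, "R")
  prot <- toy_proteome(seqs)
  sites <- tibble::tibble(accession = prot$accession, position = 2L)
  logo <- build_logo(sites, prot, half_width = 1L)
  expect_equal(unname(logo$information["-1"]), 0, tolerance = 1e-12)
})

test_that("terminal truncation leaves untouched offsets unnormalized", {
  prot <- toy_proteome("RGG")  # no residues before the site
  sites <- tibble::tibble(accession = prot$accession, position = 1L)
  logo <- build_logo(sites, prot, half_width = 2L)
  expect_equal(unname(logo$n_obs[c("-2", "-1")]), c(0L, 0L))
  expect_equal(unname(logo$n_obs["1"]), 1L)
})

test_that("sites not on an arginine are refused by name", {
  prot <- toy_proteome("GGGG")
  sites <- tibble::tibble(accession = prot$accession, position = 2L)
  expect_error(build_logo(sites, prot), "not an arginine")
})

test_that("planted signature context is recovered in logo and consensus", {
  freqs <- stats::setNames(rep(1, 18),
                           setdiff(names(citrullinr:::residue_formulas),
                                   c("R", "L")))
  sim <- simulate_proteome(n_records = 120, residue_freqs = freqs,
                           pattern = "[RS]xRx{4}RL", n_planted = 60,
                           seed = 21)
  # citrullination target is the third pattern position: start + 2
  sites <- tibble::tibble(accession = sim$truth$accession,
                          position = sim$truth$start + 2L)
  logo <- build_logo(sites, sim$proteome, half_width = 7L)
  top <- apply(logo$freq, 1, function(f) names(which.max(f)))
  expect_equal(unname(top["5"]), "R")
  expect_equal(unname(top["6"]), "L")
  expect_true(top["-2"] %in% c("R", "S"))

  expect_equal(consensus_pattern(logo, threshold = 0.5), "[RS]xRx{4}RL")
})

test_that("logo frequencies are permutation-invariant in the site list", {
  sim <- simulate_proteome(n_records = 40, pattern = "GxRxG",
                           n_planted = 20, seed = 22)
  sites <- tibble::tibble(accession = sim$truth$accession,
                          position = sim$truth$start + 2L)
  l1 <- build_logo(sites, sim$proteome, half_width = 3L)
  l2 <- build_logo(sites[rev(seq_len(nrow(sites))), ], sim$proteome,
                   half_width = 3L)
  expect_equal(l1$freq, l2$freq)
})

test_that("consensus degenerates sensibly", {
  # single site: every observed offset fully specified
  prot <- toy_proteome("AGRKL")
  sites <- tibble::tibble(accession = prot$accession, position = 3L)
  logo <- build_logo(sites, prot, half_width = 2L)
  expect_equal(consensus_pattern(logo), "AGRKL")

  # near-uniform columns: everything but the centre is a wildcard
  letters20 <- names(citrullinr:::residue_formulas)
  seqs <- paste0(letters20, "R", rev(letters20))
  prot <- toy_proteome(seqs)
  sites <- tibble::tibble(accession = prot$accession, position = 2L)
  logo <- build_logo(sites, prot, half_width = 1L)
  expect_equal(consensus_pattern(logo, threshold = 0.5), "R")
})
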