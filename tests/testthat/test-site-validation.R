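test_that("candidate placements enumerate R citrullination and N/Q deamidation", {
  cands <- candidate_placements("LNGRK", 1)
  expect_length(cands, 2L)
  expect_equal(cands[[1]]$positions, 2L)
  expect_equal(cands[[1]]$mods[[1]]$name, "deamidation")
  expect_equal(cands[[2]]$positions, 4L)
  expect_equal(cands[[2]]$mods[[1]]$name, "citrullination")

  expect_length(candidate_placements("GGGG", 1), 0L)

  # two deltas on a peptide with exactly two eligible residues (both R):
  # the single all-citrulline placement at 10 and 14
  cands <- candidate_placements("ETYMLSSLARVKTR", 2)
  expect_length(cands, 1L)
  expect_equal(cands[[1]]$positions, c(10L, 14L))
  expect_equal(vapply(cands[[1]]$mods, `[[`, "", "name"),
               rep("citrullination", 2))

  expect_warning(
    truncated <- candidate_placements("RNRNRNRNRNRN", 3, max_candidates = 10),
    "truncated"
  )
  expect_length(truncated, 10L)
})

test_that("the binomial ion score has its closed-form and boundary values", {
  expect_equal(citrullinr:::.binomial_score(26L, 26L, 0.01), 520,
               tolerance = 1e-9)
  expect_equal(citrullinr:::.binomial_score(0L, 26L, 0.01), 0)
})

test_that("ion score equals the exhaustive binomial tail for small n", {
  withr::with_seed(405, {
    for (rep in 1:30) {
      n <- sample(1:8, 1)
      k <- sample(0:n, 1)
      p <- runif(1, 0.01, 0.6)
      got <- citrullinr:::.binomial_score(k, n, p)
      want <- if (k == 0) 0 else -10 * log10(oracle_binom_tail(k, n, p))
      expect_equal(got, want, tolerance = 1e-8)
    }
  })
})

test_that("ion score is monotone non-decreasing in the match count", {
  scores <- vapply(0:20, function(k) {
    citrullinr:::.binomial_score(k, 20L, 0.05)
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("noiseless spectra localize the delta to the true residue", {
  cit <- modified_peptide("LNGRK", list(mod_citrullination()), 4L)
  sim <- simulate_spectrum(cit, 2L, sim_params())
  a <- localize(sim$spectrum, "LNGRK", 1)
  expect_equal(a$positions, 4L)
  expect_equal(a$residues, "R")
  expect_equal(a$status, "accepted")
  expect_true(a$neutral_loss_found)

  deam <- modified_peptide("LNGRK", list(mod_deamidation()), 2L)
  sim <- simulate_spectrum(deam, 2L, sim_params())
  a <- localize(sim$spectrum, "LNGRK", 1)
  expect_equal(a$positions, 2L)
  expect_equal(a$residues, "N")
  # deamidation is never reported as citrullination
  expect_equal(a$status, "ambiguous")
  expect_false(a$neutral_loss_found)
})

test_that("a spectrum of only noise peaks is rejected", {
  spec <- spectrum("noise", 500, 2,
                   tibble::tibble(mz = c(150.1, 322.7),
                                  intensity = c(5, 9)))
  a <- localize(spec, "LNGRK", 1)
  expect_equal(a$status, "rejected")
})

test_that("localize errors when no residue can carry the delta", {
  spec <- spectrum("s", 500, 2, tibble::tibble(mz = 150, intensity = 1))
  expect_error(localize(spec, "GGGG", 1), "mass delta")
})

test_that("the neutral-loss diagnostic separates citrulline from deamidation", {
  cit <- modified_peptide("LNGRK", list(mod_citrullination()), 4L)
  sim <- simulate_spectrum(cit, 2L, sim_params())
  diag <- neutral_loss_diagnostic(sim$spectrum, cit)
  expect_true(diag$found)
  expect_true(diag$on_precursor)

  # companion absent: same peptide simulated without the planted loss
  sim2 <- simulate_spectrum(cit, 2L, sim_params(plant_neutral_loss = FALSE))
  expect_false(neutral_loss_diagnostic(sim2$spectrum, cit)$found)

  # deamidated placements generate no loss companions at all
  deam <- modified_peptide("LNGRK", list(mod_deamidation()), 2L)
  sim3 <- simulate_spectrum(deam, 2L, sim_params())
  expect_false(neutral_loss_diagnostic(sim3$spectrum, deam)$found)
})

test_that("counterpart verification demands identical sequence and R sites", {
  mp <- modified_peptide("ETYMLSSLARVKTR",
                         list(mod_citrullination(), mod_citrullination()),
                         c(10L, 14L))
  expect_true(verify_counterpart(mp, "ETYMLSSLARVKTR"))
  expect_false(verify_counterpart(mp, "ETYMLSSLAKVKTR"))
  deam <- modified_peptide("LNGRK", list(mod_deamidation()), 2L)
  expect_false(verify_counterpart(deam, "LNGRK"))
})

test_that("acceptance applies thresholds, residue identity and optional checks", {
  cit <- modified_peptide("LNGRK", list(mod_citrullination()), 4L)
  sim <- simulate_spectrum(cit, 2L, sim_params())
  a <- localize(sim$spectrum, "LNGRK", 1)
  expect_equal(accept(a), "accepted")
  expect_equal(accept(a, require_loss = TRUE), "accepted")
  # counterpart untested -> cannot be accepted when demanded
  expect_equal(accept(a, require_counterpart = TRUE), "ambiguous")
  a$counterpart_verified <- verify_counterpart(a$peptide, "LNGRK")
  expect_equal(accept(a, require_counterpart = TRUE), "accepted")

  # boundary: a score just below the peptide threshold is rejected
  low <- a
  low$score <- 29.9
  expect_equal(accept(low), "rejected")
  # a confident deamidation is never accepted as citrullination
  deam <- simulate_spectrum(modified_peptide("LNGRK",
                                             list(mod_deamidation()), 2L),
                            2L, sim_params())
  b <- localize(deam$spectrum, "LNGRK", 1)
  expect_gt(b$score, 35)
  expect_equal(accept(b), "ambiguous")
})
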