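test_that("MGF round-trip preserves spectra to six decimals", {
  mp <- fixture_cit_peptide()
  sims <- lapply(1:3, function(i) {
    simulate_spectrum(mp, charge = 2L,
                      params = sim_params(seed = i, noise_peaks = 5L))$spectrum
  })
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sims, path)
  back <- read_mgf(path)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$id, sims[[i]]$id)
    expect_equal(back[[i]]$precursor_charge, sims[[i]]$precursor_charge)
    expect_equal(back[[i]]$peaks$mz, sims[[i]]$peaks$mz, tolerance = 1e-6)
    expect_equal(back[[i]]$peaks$intensity, sims[[i]]$peaks$intensity,
                 tolerance = 1e-6)
  }
})

test_that("MGF corner cases: empty peak list, charge suffix, parse errors", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=empty", "PEPMASS=500.25", "CHARGE=2+",
               "END IONS"), path)
  sp <- read_mgf(path)[[1]]
  expect_equal(nrow(sp$peaks), 0L)
  expect_equal(sp$precursor_charge, 2L)
  expect_equal(sp$precursor_mz, 500.25)

  writeLines(c("BEGIN IONS", "TITLE=bad", "PEPMASS=500.25",
               "not a peak line", "END IONS"), path)
  expect_error(read_mgf(path), "line 4")

  writeLines(c("BEGIN IONS", "TITLE=unterminated", "PEPMASS=500.25"), path)
  expect_error(read_mgf(path), "unterminated")
})

test_that("an exact spectrum matches every theoretical ion with zero error", {
  mp <- fixture_cit_peptide()
  ions <- fragment_series(mp)
  spec <- spectrum("exact", mz(peptide_mass(mp), 2), 2,
                   tibble::tibble(mz = ions$mz, intensity = 100))
  res <- match_peaks(spec, ions,
                     expected_precursor_mz = mz(peptide_mass(mp), 2))
  expect_equal(res$n_matched, nrow(ions))
  expect_true(all(abs(tidy(res)$error) < 1e-12))
  expect_true(res$precursor_within_tol)
})

test_that("peaks outside the fragment tolerance stay unmatched", {
  ions <- tibble::tibble(series = "b", index = 1L, charge = 1L,
                         mz = 200, contains_cit = FALSE,
                         ion_type = "primary")
  spec <- spectrum("off", 500, 1,
                   tibble::tibble(mz = 200.6, intensity = 10))
  res <- match_peaks(spec, ions, fragment_tol = 0.5)
  expect_equal(res$n_matched, 0L)
  # exactly at tolerance counts as within
  spec2 <- spectrum("edge", 500, 1,
                    tibble::tibble(mz = 200.5, intensity = 10))
  expect_equal(match_peaks(spec2, ions, fragment_tol = 0.5)$n_matched, 1L)
})

test_that("match count equals the exhaustive-assignment oracle", {
  withr::with_seed(403, {
    for (rep in 1:20) {
      n_ion <- sample(2:8, 1)
      n_peak <- sample(2:12, 1)
      ion_mz <- sort(runif(n_ion, 100, 160))
      peak_mz <- sort(runif(n_peak, 100, 160))
      ions <- tibble::tibble(series = "b", index = seq_len(n_ion),
                             charge = 1L, mz = ion_mz,
                             contains_cit = FALSE, ion_type = "primary")
      spec <- spectrum("rand", 500, 1,
                       tibble::tibble(mz = peak_mz,
                                      intensity = runif(n_peak, 1, 100)))
      for (tol in c(0.5, 2, 5)) {
        got <- match_peaks(spec, ions, fragment_tol = tol)$n_matched
        expect_equal(got, oracle_max_matches(ion_mz, peak_mz, tol))
      }
    }
  })
})

test_that("matching is permutation-invariant and monotone in tolerance", {
  withr::with_seed(404, {
    ion_mz <- sort(runif(6, 100, 400))
    ions <- tibble::tibble(series = "b", index = 1:6, charge = 1L,
                           mz = ion_mz, contains_cit = FALSE,
                           ion_type = "primary")
    peaks <- tibble::tibble(mz = runif(15, 100, 400),
                            intensity = runif(15, 1, 100))
    shuffled <- peaks[sample.int(nrow(peaks)), ]
    s1 <- spectrum("a", 500, 1, peaks)
    s2 <- spectrum("b", 500, 1, shuffled)
    r1 <- match_peaks(s1, ions)
    r2 <- match_peaks(s2, ions)
    expect_equal(tidy(r1), tidy(r2))

    counts <- vapply(c(0.05, 0.1, 0.5, 1, 2), function(tol) {
      match_peaks(s1, ions, fragment_tol = tol)$n_matched
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  })
})
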