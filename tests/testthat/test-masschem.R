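test_that("peptide masses agree with reference values and a summation oracle", {
  expect_equal(peptide_mass(modified_peptide("G")), 75.032028,
               tolerance = 1e-6)
  expect_equal(peptide_mass(modified_peptide("ERAVEALR")),
               oracle_peptide_mass("ERAVEALR"), tolerance = 1e-4)
  # frozen value from an independent elemental-composition computation
  expect_equal(peptide_mass(modified_peptide("ERAVEALR")), 942.5246784,
               tolerance = 1e-6)
  expect_error(modified_peptide("AXC"), "unknown residue")
})

test_that("modification deltas are additive and isobaric", {
  base <- peptide_mass(modified_peptide("LNGRK"))
  cit <- peptide_mass(modified_peptide("LNGRK", list(mod_citrullination()),
                                       4L))
  deam <- peptide_mass(modified_peptide("LNGRK", list(mod_deamidation()),
                                        2L))
  expect_equal(cit - base, 0.984016, tolerance = 1e-6)
  # citrullination and deamidation are indistinguishable at precursor level
  expect_lt(abs(cit - deam), 1e-9)
})

test_that("m/z computation follows (M + z*proton)/z", {
  expect_equal(mz(75.032028, 1), 76.039304, tolerance = 1e-6)
  expect_equal(mz(75.032028, 2), 38.523290, tolerance = 1e-6)
  expect_equal(mz(500, 1) - 500, 1.007276, tolerance = 1e-6)
  expect_error(mz(100, 0), "charge")
})

test_that("fragment series have n-1 ions per series with correct termini", {
  mp <- modified_peptide("ETYMLSSLARVKTR")
  ions <- fragment_series(mp)
  expect_equal(nrow(ions), 26L)
  expect_equal(sum(ions$series == "b"), 13L)
  expect_equal(sum(ions$series == "y"), 13L)

  gg <- fragment_series(modified_peptide("GG"))
  expect_equal(gg$mz[gg$series == "b" & gg$index == 1], 58.028739,
               tolerance = 1e-5)
  expect_equal(gg$mz[gg$series == "y" & gg$index == 1], 76.039304,
               tolerance = 1e-6)
})

test_that("b/y complementarity holds on random modified peptides", {
  withr::with_seed(402, {
    letters20 <- names(citrullinr:::residue_formulas)
    for (rep in 1:20) {
      n <- sample(4:15, 1)
      seq <- paste(sample(letters20, n, replace = TRUE), collapse = "")
      residues <- strsplit(seq, "")[[1]]
      pos <- which(residues == "R")
      mp <- if (length(pos)) {
        modified_peptide(seq, list(mod_citrullination()), pos[1])
      } else {
        modified_peptide(seq)
      }
      ions <- fragment_series(mp)
      b <- ions$mz[ions$series == "b"]
      y <- ions$mz[ions$series == "y"]
      total <- peptide_mass(mp) + 2 * mass_table()$proton
      expect_true(all(abs(b + rev(y) - total) < 1e-6))
    }
  })
})

test_that("moving a citrullination between arginines preserves the precursor", {
  m1 <- modified_peptide("LARGER", list(mod_citrullination()), 3L)
  m2 <- modified_peptide("LARGER", list(mod_citrullination()), 6L)
  expect_equal(peptide_mass(m1), peptide_mass(m2), tolerance = 1e-12)
  f1 <- fragment_series(m1)
  f2 <- fragment_series(m2)
  expect_false(all(abs(f1$mz - f2$mz) < 1e-9))
})

test_that("neutral-loss companions sit 43.005814/charge below their parents", {
  mp <- fixture_cit_peptide()
  ions <- fragment_series(mp, max_charge = 2L)
  aug <- neutral_loss_ions(ions, mp, precursor_charge = 1L)
  losses <- aug[aug$ion_type == "loss", ]
  expect_gt(nrow(losses), 0L)

  prec <- losses[losses$series == "precursor", ]
  expect_equal(mz(peptide_mass(mp), 1) - prec$mz, 43.005814,
               tolerance = 1e-6)

  # a doubly charged cit fragment loses 43.005814/2
  frag2 <- ions[ions$contains_cit & ions$charge == 2L, ][1, ]
  twin <- losses[losses$series == frag2$series &
                   losses$index == frag2$index & losses$charge == 2L, ]
  expect_equal(frag2$mz - twin$mz, 21.502907, tolerance = 1e-6)

  # an unmodified peptide's ion list passes through untouched
  plain <- modified_peptide("LNGAK")
  plain_ions <- fragment_series(plain)
  expect_identical(neutral_loss_ions(plain_ions, plain), plain_ions)
})
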