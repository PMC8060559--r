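test_that("fold change returns ratios and boundary sentinels", {
  fc <- fold_change(190, 100)
  expect_equal(fc$fc, 1.90)
  expect_equal(fc$status, "ratio")
  expect_equal(fold_change(0, 100)$status, "lost")
  expect_equal(fold_change(100, 0)$status, "de_novo")
  expect_equal(fold_change(0, 0)$status, "undefined")
})

test_that("per-timepoint categories reproduce the published rows", {
  # CHR34-like: FC 1.90 then 1.84 -> increased at both
  chr34 <- tibble::tibble(accession = "AT2G21450",
                          intensity_control = 100,
                          intensity_1h = 190, intensity_24h = 184)
  cat <- categorize_changes(chr34)
  expect_equal(cat$category_1h, "increased")
  expect_equal(cat$category_24h, "increased")
  expect_equal(cat$fc_value_1h, 1.90)

  # ns at 1 h, printed FC 0.67 at 24 h -> unchanged then decreased
  exo <- tibble::tibble(accession = "AT1G29040",
                        fc_1h = "ns", fc_24h = "0.67")
  cat <- categorize_changes(exo)
  expect_equal(cat$category_1h, "unchanged")
  expect_equal(cat$category_24h, "decreased")

  # de novo at 1 h only, not detected at 24 h
  ycf4 <- tibble::tibble(accession = "ATCG00520",
                         fc_1h = "at 1 h", fc_24h = "nd")
  cat <- categorize_changes(ycf4)
  expect_equal(cat$category_1h, "de_novo")
  expect_equal(cat$category_24h, "not_detected")

  # the same from intensities
  denovo <- tibble::tibble(accession = "X",
                           intensity_control = 0,
                           intensity_1h = 50, intensity_24h = 0)
  cat <- categorize_changes(denovo)
  expect_equal(cat$category_1h, "de_novo")
  expect_equal(cat$category_24h, "not_detected")
})

test_that("categorization is scale-invariant in the intensities", {
  quant <- simulate_quant_table(n_baseline = 6, n_increased = 3,
                                n_decreased = 2, n_de_novo = 3,
                                n_lost = 2, seed = 31)$quant
  c1 <- categorize_changes(quant)
  scaled <- dplyr::mutate(quant,
                          intensity_control = intensity_control * 7.3,
                          intensity_1h = intensity_1h * 7.3,
                          intensity_24h = intensity_24h * 7.3)
  c2 <- categorize_changes(scaled)
  expect_equal(c1$category_1h, c2$category_1h)
  expect_equal(c1$category_24h, c2$category_24h)
})

test_that("summaries recover the generator's planted classes", {
  sim <- simulate_quant_table(n_baseline = 10, n_increased = 3,
                              n_decreased = 1, n_de_novo = 5, n_lost = 2,
                              seed = 33)
  s <- summarize_changes(categorize_changes(sim$quant))
  got <- merge(tidy(s), sim$truth, by = "accession")
  planted_class <- ifelse(got$category %in% c("increased", "decreased"),
                          "differential", got$category)
  expect_equal(got$class, planted_class)
  expect_equal(unname(s$counts["baseline"]), 10L)
  expect_equal(unname(s$counts["differential"]), 4L)
  expect_equal(unname(s$counts["de_novo"]), 5L)
  expect_equal(unname(s$counts["lost"]), 2L)
  # classes partition the records
  expect_equal(sum(s$counts[c("baseline", "differential", "de_novo",
                              "lost", "not_detected")]),
               nrow(sim$quant))
})

test_that("empty input summarizes to zeros", {
  empty <- tibble::tibble(accession = character(),
                          fc_1h = character(), fc_24h = character())
  s <- summarize_changes(categorize_changes(empty))
  expect_true(all(s$counts == 0))
})

test_that("a record with control signal but no follow-up is malformed", {
  bad <- tibble::tibble(accession = "X", intensity_control = 10,
                        intensity_1h = NA_real_, intensity_24h = 5)
  expect_error(categorize_changes(bad), "no 1 h")
})
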