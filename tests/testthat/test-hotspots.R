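test_that("binomial tail matches exact-arithmetic reference values", {
  # frozen values from exact rational term-by-term summation
  expect_equal(binomial_tail(3, 10, 1 / 10), 0.0701908264,
               tolerance = 1e-12)
  expect_equal(binomial_tail(10, 60, 1 / 50), 3.0958168606387626e-07,
               tolerance = 1e-12)
  expect_equal(binomial_tail(5, 200, 1 / 200), 0.0035454798045125324,
               tolerance = 1e-12)
  expect_equal(binomial_tail(8, 40, 1 / 50), 1.1112529180168366e-06,
               tolerance = 1e-12)
  # agreement with an independent term-by-term double-precision sum
  for (n in c(5, 17, 40)) {
    for (k in c(0, 1, n %/% 2, n)) {
      expect_equal(binomial_tail(k, n, 1 / 30),
                   tail_sum_oracle(k, n, 1 / 30), tolerance = 1e-11)
    }
  }
})

test_that("binomial tail boundary cases and input checks", {
  expect_equal(binomial_tail(0, 17, 0.3), 1)
  expect_equal(binomial_tail(0, 0, 0.3), 1)
  expect_equal(binomial_tail(2, 2, 0.5), 0.25)
  expect_error(binomial_tail(2, 2, 0), "strictly inside")
  expect_error(binomial_tail(2, 2, 1), "strictly inside")
  expect_error(binomial_tail(3, 2, 0.5), "0 <= k <= n")
})

test_that("tail probability strictly decreases in k at fixed n and p", {
  for (p in c(1 / 10, 1 / 200)) {
    v <- binomial_tail(0:60, 60, p)
    expect_true(all(diff(v) < 0))
  }
})

cc_row <- function(family, col, k, cls = "missense") {
  tibble::tibble(family_id = family, msa_column = as.integer(col),
                 mclass = cls, k = as.integer(k), proteins = "P1")
}

test_that("worked hotspot example: n=2, k=2, L=100 gives exactly 1e-4", {
  hs <- detect_hotspots(cc_row("F", 10, 2), c(F = 100), m_total = 1)
  expect_equal(hs$p_value, 1e-4)
  expect_equal(hs$p_corrected, 1e-4)
  expect_true(hs$significant)
  expect_equal(hs$n, 2L)
  expect_equal(hs$p, 1 / 100)
})

test_that("the minimum-count filter controls what is tested", {
  # scattered singletons: nothing to test
  scattered <- dplyr::bind_rows(lapply(1:20, function(i) {
    cc_row("F", i, 1)
  }))
  expect_equal(nrow(detect_hotspots(scattered, c(F = 100))), 0)

  # n accumulates over all columns, tested or not
  counts <- dplyr::bind_rows(cc_row("F", 5, 30), scattered)
  hs <- detect_hotspots(counts, c(F = 100))
  expect_equal(hs$n, 50L)
  expect_equal(hs$k, 30L)
  expect_true(hs$significant)  # 30 of 50 on one of 100 columns

  expect_error(detect_hotspots(cc_row("F", 200, 2), c(F = 100)),
               "exceeds MSA length")
  expect_error(detect_hotspots(cc_row("G", 5, 2), c(F = 100)),
               "no MSA length")
})

test_that("Bonferroni counts all columns of analysed families", {
  counts <- dplyr::bind_rows(cc_row("F", 5, 4), cc_row("F", 9, 3),
                             cc_row("G", 2, 4))
  lens <- c(F = 100, G = 60)
  g <- detect_hotspots(counts, lens, correction = "global")
  expect_equal(unique(g$m), 160L)  # both families pass the n filter
  f <- detect_hotspots(counts, lens, correction = "family")
  expect_equal(f$m[f$family_id == "F"], c(100L, 100L))
  expect_equal(f$m[f$family_id == "G"], 60L)
  expect_equal(g$p_value[order(g$family_id, g$msa_column)],
               f$p_value[order(f$family_id, f$msa_column)])

  # a family whose class total stays under the filter contributes
  # nothing to m
  counts2 <- dplyr::bind_rows(counts, cc_row("H", 4, 1))
  g2 <- detect_hotspots(counts2, c(lens, H = 500),
                        correction = "global")
  expect_equal(unique(g2$m), 160L)
})

test_that("dataset runs respect gene labels and class independence", {
  sim <- simulate_dataset(small_spec(seed = 8))
  cls <- suppressMessages(classify_mutations(sim$mutations))
  mapped <- map_to_msa_columns(map_to_domains(cls, sim$domains),
                               sim$msas)
  lens <- vapply(sim$msas, msa_ncol, 1L)
  scan <- run_hotspot_analysis(mapped, lens, sim$labels)

  # whole-genome results ignore the labels entirely
  perm <- sim$labels
  set.seed(1)
  perm$class <- sample(perm$class)
  scan_perm <- run_hotspot_analysis(mapped, lens, perm)
  expect_equal(
    dplyr::filter(scan_perm$results, dataset == "genome"),
    dplyr::filter(scan$results, dataset == "genome"))

  # deleting all indel records never changes missense results
  no_indel <- dplyr::filter(mapped, mclass != "indel")
  scan2 <- run_hotspot_analysis(no_indel, lens, sim$labels)
  expect_equal(
    dplyr::filter(scan2$results, mclass == "missense"),
    dplyr::filter(scan$results, mclass == "missense"))

  # empty input gives all-zero summaries
  scan0 <- run_hotspot_analysis(mapped[0, ], lens, sim$labels)
  expect_true(all(scan0$summary$recorded == 0))
  expect_true(all(scan0$summary$significant == 0))
})

test_that("hotspots planted in one gene class stay out of the other run", {
  spec <- small_spec(seed = 13)
  spec$hotspots <- tibble::tibble(
    family_id = "FAM001", mclass = "missense", gene_class = "OG",
    excess = 0.5, multiplier = 20)
  sim <- simulate_dataset(spec)
  cls <- suppressMessages(classify_mutations(sim$mutations))
  mapped <- map_to_msa_columns(map_to_domains(cls, sim$domains),
                               sim$msas)
  scan <- run_hotspot_analysis(mapped, vapply(sim$msas, msa_ncol, 1L),
                               sim$labels)
  key <- sim$truth$hotspots
  og <- significant_hotspots(scan, "OG", "missense")
  expect_true(any(og$family_id == key$family_id &
                    og$msa_column == key$msa_column))
  ts <- significant_hotspots(scan, "TS", "missense")
  expect_false(any(ts$family_id == key$family_id &
                     ts$msa_column == key$msa_column))
})
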