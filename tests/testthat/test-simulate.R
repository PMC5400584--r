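test_that("identical seeds give byte-identical simulated datasets", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(small_spec(seed = 19), dir = d1)
  simulate_dataset(small_spec(seed = 19), dir = d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the mutation catalogue
  d3 <- withr::local_tempdir()
  simulate_dataset(small_spec(seed = 20), dir = d3)
  expect_false(identical(readLines(file.path(d1, "mutations.tsv")),
                         readLines(file.path(d3, "mutations.tsv"))))
})

test_that("generator and parser agree on the change-string grammar", {
  sim <- simulate_dataset(small_spec(seed = 23))
  parsed <- parse_protein_change(sim$mutations$change)
  expect_equal(parsed$mclass, sim$truth$true_class)
  expect_false(any(parsed$mclass == "unclassified"))
})

test_that("emitted files satisfy the readers' validation rules", {
  d <- withr::local_tempdir()
  simulate_dataset(small_spec(seed = 29), dir = d)
  prot <- read_proteome(file.path(d, "proteome.fasta"))
  dom <- read_domain_table(file.path(d, "domains.tsv"), prot)
  expect_silent(mut <- read_mutations(file.path(d, "mutations.tsv"),
                                      prot))
  labels <- read_gene_labels(file.path(d, "gene_labels.tsv"))
  msas <- read_msa_collection(file.path(d, "msas.sto"))
  # every alignment row ungaps to its proteome slice
  for (fam in names(msas)) {
    expect_silent(validate_msa(msas[[fam]], prot, dom))
  }
  # all planted keys exist in the emitted files
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_true(all(truth$hotspots$family_id %in% dom$family_id))
  expect_true(all(truth$enriched$family_id %in% dom$family_id))
  lens <- vapply(msas, msa_ncol, 1L)
  expect_true(all(truth$hotspots$msa_column <=
                    lens[truth$hotspots$family_id]))
})

test_that("zero rates give an empty catalogue; zero indels a flat MSA", {
  spec <- small_spec(seed = 31)
  spec$base_rates[] <- 0
  spec$hotspots <- spec$hotspots[0, ]
  spec$enriched <- spec$enriched[0, ]
  sim <- simulate_dataset(spec)
  expect_equal(nrow(sim$mutations), 0)

  spec2 <- small_spec(seed = 31)
  spec2$del_prob <- 0
  spec2$ins_prob <- 0
  sim2 <- simulate_dataset(spec2)
  expect_false(any(grepl("-", unlist(lapply(sim2$msas, unclass)),
                         fixed = TRUE)))
})

test_that("planted hotspot counts follow the excess fraction", {
  # one family, strong signal, unrestricted: k ~ Binomial(n, ~excess)
  spec <- simulation_spec(
    n_families = 1, n_background_families = 2,
    instances_per_family = c(4, 4), domain_length = c(100, 100),
    n_ts = 5, n_og = 5, n_other = 10, n_samples = 500,
    base_rates = c(missense = 1e-3, truncation = 0, indel = 0),
    hotspots = tibble::tibble(family_id = "FAM001",
                              mclass = "missense",
                              gene_class = NA_character_,
                              excess = 0.25, multiplier = 1),
    enriched = tibble::tibble(family_id = character(),
                              mclass = character(),
                              multiplier = double()),
    seed = 37)
  sim <- simulate_dataset(spec)
  cls <- suppressMessages(classify_mutations(sim$mutations))
  mapped <- map_to_msa_columns(map_to_domains(cls, sim$domains),
                               sim$msas)
  fam <- dplyr::filter(mapped, family_id == "FAM001")
  n <- nrow(fam)
  k <- sum(fam$msa_column == sim$truth$hotspots$msa_column)
  expect_gt(n, 100)
  # binomial noise band around the planted fraction (+ uniform baseline)
  p_hit <- 0.25 + 0.75 / msa_ncol(sim$msas$FAM001)
  expect_lt(abs(k / n - p_hit), 4 * sqrt(p_hit * (1 - p_hit) / n))
})

test_that("gene-class mutation spectra follow the class weights", {
  spec <- small_spec(seed = 41)
  spec$n_samples <- 400  # more mutations for stable fractions
  sim <- simulate_dataset(spec)
  cls <- suppressMessages(classify_mutations(sim$mutations))
  by_class <- cls |>
    dplyr::left_join(sim$labels,
                     by = c(protein_accession = "gene")) |>
    dplyr::filter(class %in% c("TS", "OG")) |>
    dplyr::group_by(class) |>
    dplyr::summarise(trunc_frac = mean(mclass == "truncation"))
  ts_frac <- by_class$trunc_frac[by_class$class == "TS"]
  og_frac <- by_class$trunc_frac[by_class$class == "OG"]
  # TS truncation weight is 6, OG weight 0.5: fractions must separate
  expect_gt(ts_frac, 0.35)
  expect_lt(og_frac, 0.15)
})

test_that("stale reference injection exercises the drop-and-log path", {
  spec <- small_spec(seed = 43)
  spec$stale_ref_fraction <- 0.2
  sim <- simulate_dataset(spec)
  cls <- suppressMessages(classify_mutations(sim$mutations))
  kept <- suppressMessages(check_reference_residues(cls, sim$proteome))
  dropped <- attr(kept, "n_dropped")
  n <- nrow(sim$mutations)
  expect_gt(dropped / n, 0.1)
  expect_lt(dropped / n, 0.3)
})

test_that("planted truth names only existing families and columns", {
  spec <- small_spec(seed = 47)
  expect_error(
    simulation_spec(n_families = 2,
                    hotspots = tibble::tibble(
                      family_id = "FAM099", mclass = "missense",
                      gene_class = NA_character_, excess = 0.3,
                      multiplier = 5)),
    "unknown families")
  sim <- simulate_dataset(spec)
  expect_true(all(sim$truth$hotspots$family_id %in%
                    names(sim$msas)))
})
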