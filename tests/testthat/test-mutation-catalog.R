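test_that("protein-change strings classify into the three classes", {
  cases <- tibble::tribble(
    ~change,              ~mclass,        ~position, ~ref,  ~alt,
    "V600E",              "missense",     600L,      "V",   "E",
    "E813*",              "truncation",   813L,      "E",   "*",
    "Q1247fs*26",         "truncation",   1247L,     "Q",   "",
    "D53fs",              "truncation",   53L,       "D",   "",
    "E746_A750delELREA",  "indel",        746L,      "ELREA", "",
    "F113del",            "indel",        113L,      "F",   "",
    "M484_N486delMLN",    "indel",        484L,      "MLN", "",
    "K601insV",           "indel",        601L,      "",    "V",
    "V600delinsGG",       "indel",        600L,      "V",   "GG",
    "V600V",              "unclassified", NA,        NA,    NA,
    "c.1799T>A",          "unclassified", NA,        NA,    NA,
    "?",                  "unclassified", NA,        NA,    NA)
  parsed <- parse_protein_change(cases$change)
  expect_equal(parsed$mclass, cases$mclass)
  expect_equal(parsed$position, cases$position)
  expect_equal(parsed$ref_aa, cases$ref)
  expect_equal(parsed$alt_aa, cases$alt)
  expect_error(parse_protein_change(""), "non-empty")
})

test_that("every parsed mutation falls in exactly one class", {
  set.seed(11)
  strings <- c(
    replicate(200, paste0(sample(c("A", "G", "R", "W"), 1),
                          sample(1000, 1),
                          sample(c("E", "K", "*", "fs", "del", "insA",
                                   "delinsWW", "X!"), 1))),
    "V600E", "E813*", "")
  strings <- strings[strings != ""]
  parsed <- parse_protein_change(strings)
  expect_true(all(parsed$mclass %in%
                    c("missense", "truncation", "indel", "unclassified")))
  # classification depends on the string alone
  again <- parse_protein_change(rev(strings))
  expect_equal(again$mclass, rev(parsed$mclass))
})

test_that("reference-residue validation drops stale records", {
  prot <- tiny_proteome()  # P1 starts ACDEFGHIKL...
  mut <- tibble::tibble(
    sample_id = "S1", protein_accession = "P1",
    change = c("A1K", "C2K", "K1A", "G500R", "C2fs", "A1del"),
    cancer_type = "lung")
  cls <- classify_mutations(mut)
  expect_message(kept <- check_reference_residues(cls, prot), "dropped")
  # K1A has wrong ref (pos 1 is A); G500R is beyond the protein;
  # C2fs ref C matches position 2
  expect_equal(kept$change, c("A1K", "C2K", "C2fs", "A1del"))
  expect_equal(attr(kept, "n_dropped"), 2L)
})

test_that("mutations map to containing instances with local offsets", {
  dom <- tibble::tibble(protein_accession = "P1", family_id = "PF_K",
                        start = 457L, end = 717L,
                        instance_id = "P1/457-717")
  cls <- tibble::tibble(sample_id = "S1", protein_accession = "P1",
                        change = "V600E", cancer_type = "x",
                        mclass = "missense", position = 600L,
                        ref_aa = "V", alt_aa = "E")
  m <- map_to_domains(cls, dom)
  expect_equal(m$local_pos, 144L)  # 600 - 457 + 1

  cls$position <- 5L
  expect_equal(nrow(map_to_domains(cls, dom)), 0)
  cls$position <- 457L
  expect_equal(map_to_domains(cls, dom)$local_pos, 1L)

  # overlapping instances of different families each receive the mutation
  dom2 <- dplyr::bind_rows(dom, dplyr::mutate(
    dom, family_id = "PF_L", start = 590L, end = 650L,
    instance_id = "P1/590-650"))
  cls$position <- 600L
  m2 <- map_to_domains(cls, dom2)
  expect_equal(sort(m2$family_id), c("PF_K", "PF_L"))
})

test_that("column mapping skips gaps and flags inconsistencies", {
  msa <- domspot:::new_msa(c(`P1/10-12` = "A-CD"), "F")
  mapped <- tibble::tibble(family_id = "F", instance_id = "P1/10-12",
                           local_pos = 2L, mclass = "missense",
                           sample_id = "S1", protein_accession = "P1",
                           change = "x", position = 11L)
  out <- map_to_msa_columns(mapped, list(F = msa))
  expect_equal(out$msa_column, 3L)

  msa2 <- domspot:::new_msa(c(`P1/10-12` = "ACD-"), "F")
  mapped$local_pos <- 3L
  expect_equal(map_to_msa_columns(mapped, list(F = msa2))$msa_column, 3L)

  msa3 <- domspot:::new_msa(c(`P1/10-12` = "--A"), "F")
  mapped$local_pos <- 2L
  expect_error(map_to_msa_columns(mapped, list(F = msa3)),
               "inconsistency")
})

test_that("column aggregation conserves counts and ignores order", {
  mk <- function(col, cls, acc) {
    tibble::tibble(family_id = "F", msa_column = col, mclass = cls,
                   protein_accession = acc, sample_id = "S",
                   change = "x")
  }
  rows <- dplyr::bind_rows(
    mk(7L, "missense", "P1"), mk(7L, "missense", "P2"),
    mk(7L, "missense", "P1"), mk(9L, "missense", "P3"),
    mk(7L, "truncation", "P1"))
  agg <- aggregate_columns(rows)
  expect_equal(sum(agg$k[agg$mclass == "missense"]), 4)
  mis7 <- agg[agg$msa_column == 7 & agg$mclass == "missense", ]
  expect_equal(mis7$k, 3L)
  expect_equal(mis7$proteins, "P1,P2")
  # classes stay separate at the same column
  expect_equal(nrow(agg[agg$msa_column == 7, ]), 2)
  # permutation invariance
  expect_equal(aggregate_columns(rows[sample(nrow(rows)), ]), agg)
  expect_equal(nrow(aggregate_columns(rows[0, ])), 0)
})

test_that("mapping conserves per-class totals on simulated data", {
  sim <- simulate_dataset(small_spec(seed = 5))
  cls <- suppressMessages(classify_mutations(sim$mutations))
  cls <- suppressMessages(check_reference_residues(cls, sim$proteome))
  mapped <- map_to_domains(cls, sim$domains)
  s <- mapping_summary(cls, mapped)
  expect_true(all(s$parsed == s$mapped + s$unmapped))
  expect_equal(sum(s$parsed), nrow(cls))
  # every mapped mutation can be placed on an alignment column
  mapped2 <- map_to_msa_columns(mapped, sim$msas)
  expect_equal(nrow(mapped2), nrow(mapped))
  expect_true(all(mapped2$msa_column >= 1))
})
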