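mutrec <- function(acc, mclass, position) {
  tibble::tibble(sample_id = "S1", protein_accession = acc,
                 change = "x", cancer_type = "t", mclass = mclass,
                 position = as.integer(position), ref_aa = "A",
                 alt_aa = "K")
}

test_that("the 20:20 rule classifies mutational patterns", {
  recs <- dplyr::bind_rows(
    mutrec("G_ts", c(rep("missense", 7), rep("truncation", 3)), 1:10),
    mutrec("G_og", rep("missense", 10), rep(5, 10)),
    mutrec("G_nil", rep("missense", 10), 1:10),
    mutrec("G_both", c(rep("truncation", 3),
                       rep("missense", 7)), c(1:3, rep(9, 7))))
  prof <- gene_mutation_profiles(recs)
  rule <- twenty_twenty(prof)
  cls <- stats::setNames(rule$rule_class, rule$gene)
  expect_equal(cls[["G_ts"]], "TS")      # 30% truncations
  expect_equal(cls[["G_og"]], "OG")      # all missense at one position
  expect_equal(cls[["G_nil"]], "neither")
  expect_equal(cls[["G_both"]], "both")

  p <- prof[prof$gene == "G_og", ]
  expect_equal(p$max_missense_fraction, 1)
  expect_equal(p$truncation_fraction, 0)
})

test_that("adding truncations never demotes a TS call", {
  base <- mutrec("G", c(rep("missense", 8), rep("truncation", 2)), 1:10)
  f0 <- twenty_twenty(gene_mutation_profiles(base))$rule_class
  expect_true(f0 %in% c("TS", "both"))
  more <- dplyr::bind_rows(base, mutrec("G", "truncation", 11))
  f1 <- twenty_twenty(gene_mutation_profiles(more))$rule_class
  expect_true(f1 %in% c("TS", "both"))
})

test_that("feature matrix counts domain instances per gene", {
  dom <- tibble::tibble(
    protein_accession = c("G1", "G1", "G2", "G3"),
    family_id = c("Pkinase", "Pkinase", "SH2", "Ras"),
    start = c(1L, 101L, 1L, 1L), end = c(100L, 200L, 50L, 60L),
    instance_id = paste0(c("G1", "G1", "G2", "G3"), "/x"))
  fm <- build_feature_matrix(dom, c("G1", "G2", "G4"))
  expect_equal(fm$Pkinase, c(2L, 0L, 0L))
  expect_equal(fm$SH2, c(0L, 1L, 0L))
  expect_false("Ras" %in% names(fm))  # G3 not requested
  expect_equal(unlist(fm[fm$gene == "G4", -1]), c(Pkinase = 0L, SH2 = 0L))

  bin <- build_feature_matrix(dom, c("G1", "G2"), binary = TRUE)
  expect_equal(bin$Pkinase, c(1L, 0L))
})

test_that("rank AUC equals the trapezoidal ROC integral", {
  trapezoid_auc <- function(score, is_pos) {
    th <- sort(unique(score), decreasing = TRUE)
    tpr <- vapply(th, function(t) mean(score[is_pos] >= t), 0)
    fpr <- vapply(th, function(t) mean(score[!is_pos] >= t), 0)
    fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
  set.seed(41)
  for (i in 1:10) {
    y <- sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(.4, .6))
    s <- round(stats::rnorm(60, mean = y), 1)  # rounded: forces ties
    expect_equal(auc_rank(s, y), trapezoid_auc(s, y), tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      expect_equal(auc_rank(s, y),
                   as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
                   tolerance = 1e-12)
    }
  }
  expect_equal(auc_rank(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
})

sep_features <- function(n_per = 15) {
  tibble::tibble(
    gene = c(sprintf("T%02d", 1:n_per), sprintf("O%02d", 1:n_per)),
    famA = c(rep(3L, n_per), rep(0L, n_per)),
    famB = c(rep(0L, n_per), rep(2L, n_per)),
    famC = sample(0:2, 2 * n_per, replace = TRUE))
}

sep_labels <- function(n_per = 15) {
  tibble::tibble(gene = c(sprintf("T%02d", 1:n_per),
                          sprintf("O%02d", 1:n_per)),
                 class = rep(c("TS", "OG"), each = n_per))
}

test_that("cross-validation recovers separable structure exactly", {
  set.seed(51)
  cv <- cross_validate(sep_features(), sep_labels(), seed = 2)
  expect_equal(cv$auc, 1)
  expect_true(all(sort(unique(cv$scores$fold)) == 1:10))
  # stratification: both classes in every fold
  tab <- table(cv$scores$fold, cv$scores$label)
  expect_true(all(tab > 0))
})

test_that("cross-validation is reproducible bit-for-bit from the seed", {
  set.seed(52)
  f <- sep_features()
  l <- sep_labels()
  cv1 <- cross_validate(f, l, seed = 9)
  cv2 <- cross_validate(f, l, seed = 9)
  expect_identical(cv1$scores, cv2$scores)
  expect_identical(cv1$auc, cv2$auc)
  cv3 <- cross_validate(f, l, seed = 10)
  expect_false(identical(cv1$scores$fold, cv3$scores$fold))
})

test_that("constant features give chance-level AUC with ties halved", {
  f <- sep_features()
  f$famA <- 1L; f$famB <- 1L; f$famC <- 1L
  cv <- cross_validate(f, sep_labels(), seed = 3)
  expect_equal(cv$auc, 0.5)
})

test_that("cross-validation enforces its preconditions", {
  f <- sep_features(5)
  expect_error(cross_validate(f, sep_labels(5), k_folds = 10),
               "k_folds")
  l <- sep_labels()
  l$class[1] <- "both"
  expect_message(cross_validate(sep_features(), l, k_folds = 5,
                                seed = 1),
                 "excluded")
})

test_that("unlabelled scoring is deterministic and rank-calibrated", {
  f <- sep_features()
  l <- sep_labels()
  scorer <- train_scorer(f, l)
  # a gene identical to a training TS gene scores identically
  probe <- f[f$gene == "T01", ]
  probe$gene <- "NEW"
  s <- score_unlabelled(scorer, probe)
  t01 <- score_unlabelled(scorer, f[f$gene == "T01", ])
  expect_equal(s$score_raw, t01$score_raw)
  expect_equal(s$score, t01$score)
  expect_true(all(s$score >= 0 & s$score <= 1))
  # strongly TS-typical domain content is labelled TS at the 0.78 cut
  ts_probe <- tibble::tibble(gene = "NEWTS", famA = 10L, famB = 0L,
                             famC = 0L)
  expect_equal(score_unlabelled(scorer, ts_probe)$label, "TS")
  # strongly OG-typical content falls below 1 - 0.83
  og_probe <- tibble::tibble(gene = "NEWOG", famA = 0L, famB = 10L,
                             famC = 0L)
  expect_equal(score_unlabelled(scorer, og_probe)$label, "OG")
  # empty input gives an empty, well-formed result
  empty <- score_unlabelled(scorer, f[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty), c("gene", "score_raw", "score", "label"))
})
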