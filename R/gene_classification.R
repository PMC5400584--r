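#' Per-gene mutation profiles for the 20:20 rule
#'
#' For each protein: the total number of classified mutations, the
#' fraction that are truncations, and the largest fraction of its
#' missense mutations that recur at one protein position.
#'
#' @param classified Classified mutation tibble; unclassified records are
#'   ignored.
#' @return Tibble (`gene`, `n_mutations`, `truncation_fraction`,
#'   `max_missense_fraction`).
#' @export
gene_mutation_profiles <- function(classified) {
  x <- filter(classified, .data$mclass %in% MUTATION_CLASSES)
  peak <- x %>%
    filter(.data$mclass == "missense") %>%
    count(.data$protein_accession, .data$position) %>%
    group_by(.data$protein_accession) %>%
    summarise(peak = max(.data$n), n_missense = sum(.data$n),
              .groups = "drop")
  x %>%
    group_by(gene = .data$protein_accession) %>%
    summarise(n_mutations = dplyr::n(),
              truncation_fraction = mean(.data$mclass == "truncation"),
              .groups = "drop") %>%
    left_join(peak, by = c(gene = "protein_accession")) %>%
    mutate(max_missense_fraction = ifelse(
      is.na(.data$peak) | .data$n_missense == 0, 0,
      .data$peak / .data$n_missense)) %>%
    select("gene", "n_mutations", "truncation_fraction",
           "max_missense_fraction")
}

#' Classify genes by the 20:20 mutational-pattern rule
#'
#' A gene is called a tumour suppressor when at least `threshold` (default
#' 20%) of its mutations are truncating, and an oncogene when at least
#' `threshold` of its missense mutations recur at a single position; genes
#' meeting both tests are `"both"`, genes meeting neither `"neither"`.
#' Genes without mutations are `"neither"` (with a warning).
#'
#' @param profiles Tibble from [gene_mutation_profiles()].
#' @param threshold Fraction threshold, default `0.20`.
#' @return `profiles` with a `rule_class` column added.
#' @export
twenty_twenty <- function(profiles, threshold = 0.20) {
  stopifnot(threshold > 0, threshold <= 1)
  if (any(profiles$n_mutations == 0)) {
    warn("gene(s) without mutations classified as 'neither'")
  }
  mutate(profiles, rule_class = case_when(
    .data$n_mutations == 0 ~ "neither",
    .data$truncation_fraction >= threshold &
      .data$max_missense_fraction >= threshold ~ "both",
    .data$truncation_fraction >= threshold ~ "TS",
    .data$max_missense_fraction >= threshold ~ "OG",
    TRUE ~ "neither"))
}

#' Domain-composition feature matrix
#'
#' One row per gene, one column per domain family, cells holding the
#' number of instances of that family on the gene's protein (set
#' `binary = TRUE` for presence/absence). Genes without any domain get an
#' all-zero row and are kept.
#'
#' @param domains Domain-instance tibble.
#' @param genes Character vector of genes to build rows for; the feature
#'   columns are the union of families found on these genes.
#' @param binary Use 0/1 presence instead of counts.
#' @return Tibble with a `gene` column followed by one numeric column per
#'   family.
#' @export
build_feature_matrix <- function(domains, genes, binary = FALSE) {
  counts <- domains %>%
    filter(.data$protein_accession %in% genes) %>%
    count(gene = .data$protein_accession, .data$family_id)
  if (binary) counts$n <- as.integer(counts$n > 0)
  zero <- setdiff(genes, counts$gene)
  if (length(zero) > 0) {
    inform(paste0(length(zero), " gene(s) without domains kept as",
                  " all-zero rows"))
  }
  fams <- sort(unique(counts$family_id))
  wide <- counts %>%
    tidyr::pivot_wider(names_from = "family_id", values_from = "n",
                       values_fill = 0L)
  out <- tibble(gene = genes) %>%
    left_join(wide, by = "gene")
  out[fams] <- lapply(out[fams], function(v) {
    as.integer(dplyr::coalesce(v, 0L))
  })
  out[c("gene", fams)]
}

#' Linear support-vector-machine learner
#'
#' The default learner for [cross_validate()]: a maximum-margin linear
#' classifier. A learner is any `function(x, y)` (numeric matrix,
#' character labels `"TS"`/`"OG"`) returning a scoring
#' `function(x_new)` whose values are higher for more TS-like rows.
#'
#' @param cost Soft-margin cost parameter.
#' @return A learner function.
#' @export
learner_svm <- function(cost = 1) {
  function(x, y) {
    y <- factor(y, levels = c("OG", "TS"))
    fit <- e1071::svm(x, y, kernel = "linear", cost = cost,
                      scale = FALSE)
    train_dec <- as.numeric(attr(predict(fit, x, decision.values = TRUE),
                                 "decision.values"))
    # decision-value sign depends on which class svm saw first; orient so
    # TS scores high
    flip <- mean(train_dec[y == "TS"]) < mean(train_dec[y == "OG"])
    function(x_new) {
      d <- as.numeric(attr(predict(fit, x_new, decision.values = TRUE),
                           "decision.values"))
      if (flip) -d else d
    }
  }
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outscores a random negative, with ties counted one half (average
#' ranks). Equals the trapezoidal integral of the empirical ROC curve.
#'
#' @param score Numeric scores, higher = more positive-like.
#' @param is_pos Logical, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(score, is_pos) {
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) abort("need both classes to compute AUC")
  r <- rank(score)
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Cross-validated gene classification from domain composition
#'
#' Stratified k-fold cross-validation of a binary tumour-suppressor vs
#' oncogene scorer on the domain-composition feature matrix. Genes
#' labelled `"both"` are excluded from training and scoring (they can be
#' scored afterwards with [score_unlabelled()]). The pooled AUC uses the
#' held-out scores of all folds together.
#'
#' @param features Feature tibble from [build_feature_matrix()].
#' @param labels Tibble (`gene`, `class`) with classes `TS`/`OG` (rows
#'   labelled `both` or `other` are dropped with a message).
#' @param k_folds Number of folds (default 10).
#' @param learner A learner factory, e.g. [learner_svm()].
#' @param seed Integer seed controlling the fold assignment.
#' @return A `cv_report`: list with `scores` (gene, label, fold, score),
#'   `fold_auc`, and the pooled `auc`.
#' @export
cross_validate <- function(features, labels, k_folds = 10,
                           learner = learner_svm(), seed = 1) {
  lab <- filter(labels, .data$class %in% c("TS", "OG"))
  dropped <- nrow(labels) - nrow(lab)
  if (dropped > 0) {
    inform(paste0(dropped, " gene(s) not labelled TS/OG excluded from",
                  " cross-validation"))
  }
  lab <- semi_join(lab, features, by = "gene")
  n_per <- table(lab$class)
  if (length(n_per) < 2 || any(n_per < k_folds)) {
    abort("need at least k_folds labelled genes in each class")
  }
  x <- as.matrix(features[match(lab$gene, features$gene), -1])
  storage.mode(x) <- "double"
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  fold <- integer(nrow(lab))
  withr_seed({
    for (cl in names(n_per)) {
      idx <- sample(which(lab$class == cl))
      fold[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
  })
  score <- numeric(nrow(lab))
  for (f in seq_len(k_folds)) {
    test <- fold == f
    scorer <- learner(x[!test, , drop = FALSE], lab$class[!test])
    score[test] <- scorer(x[test, , drop = FALSE])
  }
  scores <- tibble(gene = lab$gene, label = lab$class, fold = fold,
                   score = score)
  fold_auc <- scores %>%
    group_by(.data$fold) %>%
    summarise(auc = auc_rank(.data$score, .data$label == "TS"),
              .groups = "drop")
  structure(list(scores = scores, fold_auc = fold_auc,
                 auc = auc_rank(score, lab$class == "TS"),
                 k_folds = k_folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>", x$k_folds, "folds, pooled AUC",
      sprintf("%.3f", x$auc), "\n")
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `cv_report` object.
#' @param ... Unused.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$scores

#' @rdname cross_validate
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble(auc = x$auc, k_folds = x$k_folds,
         n_ts = sum(x$scores$label == "TS"),
         n_og = sum(x$scores$label == "OG"),
         mean_fold_auc = mean(x$fold_auc$auc))
}

#' Train a scorer on all labelled genes
#'
#' @inheritParams cross_validate
#' @return A `domain_scorer`: the fitted scoring function plus the
#'   training scores used for rank calibration.
#' @export
train_scorer <- function(features, labels, learner = learner_svm()) {
  lab <- filter(labels, .data$class %in% c("TS", "OG"))
  lab <- semi_join(lab, features, by = "gene")
  x <- as.matrix(features[match(lab$gene, features$gene), -1])
  storage.mode(x) <- "double"
  scorer <- learner(x, lab$class)
  structure(list(scorer = scorer,
                 train_scores = scorer(x),
                 train_genes = lab$gene,
                 feature_names = colnames(features)[-1]),
            class = "domain_scorer")
}

#' Score genes with a trained domain-composition scorer
#'
#' Raw scores are calibrated to `[0, 1]` by their rank against the
#' training scores (the empirical CDF of the training scores, higher =
#' more TS-like). Decision labels use two probability cuts: TS when the
#' calibrated score is at least `ts_cut`, OG when it is at most
#' `1 - og_cut`, otherwise `"unresolved"`.
#'
#' @param scorer A `domain_scorer` from [train_scorer()].
#' @param features Feature tibble with rows for the genes to score (same
#'   feature columns as training).
#' @param ts_cut,og_cut Probability cuts for the TS and OG calls.
#' @return Tibble (`gene`, `score_raw`, `score`, `label`).
#' @export
score_unlabelled <- function(scorer, features, ts_cut = 0.78,
                             og_cut = 0.83) {
  if (nrow(features) == 0) {
    return(tibble(gene = character(), score_raw = double(),
                  score = double(), label = character()))
  }
  x <- as.matrix(features[, scorer$feature_names, drop = FALSE])
  storage.mode(x) <- "double"
  raw <- scorer$scorer(x)
  cal <- stats::ecdf(scorer$train_scores)(raw)
  tibble(gene = features$gene, score_raw = raw, score = cal,
         label = case_when(cal >= ts_cut ~ "TS",
                           cal <= 1 - og_cut ~ "OG",
                           TRUE ~ "unresolved"))
}
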