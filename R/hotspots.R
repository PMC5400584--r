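#' Upper tail of the binomial distribution
#'
#' Probability of observing at least `k` successes in `n` trials with
#' per-trial probability `p`, i.e. `sum_{i=k}^{n} C(n,i) p^i (1-p)^(n-i)`.
#' Under the hotspot null model every mutation lands on each alignment
#' column with equal probability `p = 1/L`, so the count at a column is
#' binomial and this tail is the hotspot p-value. Computed through the
#' survival-function form of the binomial CDF, which is numerically stable
#' far into the tail. Vectorised.
#'
#' @param k Observed count(s), `0 <= k <= n`.
#' @param n Total number of trials (mutations in the family).
#' @param p Per-column probability, strictly inside (0, 1).
#' @return Tail probability in `[0, 1]`.
#' @export
binomial_tail <- function(k, n, p) {
  if (any(p <= 0 | p >= 1)) abort("p must lie strictly inside (0, 1)")
  if (any(k < 0 | n < 0 | k > n)) abort("need 0 <= k <= n")
  pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Detect positional hotspots in family alignments
#'
#' Applies the binomial tail test to per-column mutation counts of one
#' dataset run. For each family and mutation class, `n` is the total
#' number of that class's mutations mapped anywhere in the family and the
#' null places each of them uniformly over the family's `L` alignment
#' columns (`p = 1/L`). Only columns carrying at least `min_count`
#' mutations are reported (tested), but the Bonferroni correction counts
#' every alignment column that could have produced a reportable hotspot:
#' with `correction = "global"` (default) `m` is the summed column count
#' of all families holding at least `min_count` mutations of the class in
#' the run, with `"family"` it is the family's own column count. Columns
#' screened out by the count filter are still part of the implicit test
#' family — correcting only over the columns that happened to pass the
#' filter does not control the familywise error under sparse nulls.
#'
#' @param column_counts Tibble from [aggregate_columns()].
#' @param msa_lengths Named numeric vector: alignment column count `L`
#'   per family id.
#' @param alpha Significance level on corrected p-values.
#' @param min_count Minimum per-column count for a position to be tested
#'   (a "recorded" hotspot); at least 2.
#' @param correction `"global"` or `"family"` Bonferroni scope.
#' @param m_total Optional override for the Bonferroni denominator.
#' @return A tibble with one row per tested column: `family_id`,
#'   `msa_column`, `mclass`, `n`, `k`, `p`, `p_value`, `m`,
#'   `p_corrected`, `significant`, `proteins`.
#' @export
detect_hotspots <- function(column_counts, msa_lengths, alpha = 0.05,
                            min_count = 2, correction = c("global",
                                                          "family"),
                            m_total = NULL) {
  correction <- match.arg(correction)
  stopifnot(alpha > 0, alpha < 1, min_count >= 2)
  empty <- tibble(family_id = character(), msa_column = integer(),
                  mclass = character(), n = integer(), k = integer(),
                  p = double(), p_value = double(), m = integer(),
                  p_corrected = double(), significant = logical(),
                  proteins = character())
  if (nrow(column_counts) == 0) return(empty)
  missing_l <- setdiff(unique(column_counts$family_id), names(msa_lengths))
  if (length(missing_l) > 0) {
    abort(paste0("no MSA length for family(ies): ",
                 paste(head(missing_l, 5), collapse = ", ")))
  }
  x <- column_counts %>%
    group_by(.data$family_id, .data$mclass) %>%
    mutate(n = sum(.data$k)) %>%
    ungroup() %>%
    mutate(L = unname(msa_lengths[.data$family_id]))
  if (any(x$msa_column > x$L)) {
    abort("column index exceeds MSA length")
  }
  # families whose class total reaches the filter could have shown a
  # hotspot at any of their columns: all their columns count toward m
  m_tab <- x %>%
    distinct(.data$mclass, .data$family_id, .data$n, .data$L) %>%
    filter(.data$n >= min_count) %>%
    group_by(.data$mclass) %>%
    summarise(m_global = sum(.data$L), .groups = "drop")
  x <- filter(x, .data$k >= min_count)
  if (nrow(x) == 0) return(empty)
  x <- mutate(x, p = 1 / .data$L,
              p_value = binomial_tail(.data$k, .data$n, .data$p))
  x <- if (!is.null(m_total)) {
    mutate(x, m = as.integer(m_total))
  } else if (correction == "global") {
    x %>%
      left_join(m_tab, by = "mclass") %>%
      mutate(m = as.integer(.data$m_global)) %>%
      select(-"m_global")
  } else {
    mutate(x, m = as.integer(.data$L))
  }
  x %>%
    mutate(p_corrected = pmin(1, .data$p_value * .data$m),
           significant = .data$p_corrected < alpha) %>%
    select("family_id", "msa_column", "mclass", "n", "k", "p",
           "p_value", "m", "p_corrected", "significant", "proteins") %>%
    arrange(.data$mclass, .data$p_corrected, .data$family_id,
            .data$msa_column)
}

#' Hotspot analysis over tumour suppressor, oncogene and genome datasets
#'
#' Runs the hotspot test three times — on mutations from tumour-suppressor
#' genes only, from oncogenes only, and from all genes — with mutation
#' classes tested independently inside each run, and summarises recorded
#' (count >= `min_count`) and significant hotspot counts per dataset and
#' class.
#'
#' @param mapped Column-mapped mutation tibble ([map_to_msa_columns()]).
#' @param msa_lengths Named vector of alignment lengths per family.
#' @param gene_labels Tibble (`gene`, `class`) with classes `TS`, `OG`,
#'   `both` or `other`; genes labelled `both` enter both cancer-gene
#'   datasets.
#' @inheritParams detect_hotspots
#' @return A `hotspot_scan` object: list with `results` (all tested
#'   columns, with a `dataset` column), `summary` (recorded/significant
#'   counts per dataset and class) and the run parameters.
#' @export
run_hotspot_analysis <- function(mapped, msa_lengths, gene_labels,
                                 alpha = 0.05, min_count = 2,
                                 correction = "global") {
  ts_genes <- gene_labels$gene[gene_labels$class %in% c("TS", "both")]
  og_genes <- gene_labels$gene[gene_labels$class %in% c("OG", "both")]
  datasets <- list(
    TS = filter(mapped, .data$protein_accession %in% ts_genes),
    OG = filter(mapped, .data$protein_accession %in% og_genes),
    genome = mapped
  )
  results <- purrr::imap(datasets, function(d, nm) {
    cc <- aggregate_columns(d)
    recorded <- cc %>%
      filter(.data$k >= min_count) %>%
      count(.data$mclass, name = "recorded")
    hs <- detect_hotspots(cc, msa_lengths, alpha = alpha,
                          min_count = min_count, correction = correction)
    list(results = mutate(hs, dataset = nm, .before = 1),
         summary = tibble(dataset = nm, mclass = MUTATION_CLASSES) %>%
           left_join(recorded, by = "mclass") %>%
           left_join(count(filter(hs, .data$significant), .data$mclass,
                           name = "significant"), by = "mclass") %>%
           mutate(recorded = dplyr::coalesce(.data$recorded, 0L),
                  significant = dplyr::coalesce(.data$significant, 0L)))
  })
  structure(list(results = bind_rows(purrr::map(results, "results")),
                 summary = bind_rows(purrr::map(results, "summary")),
                 alpha = alpha, min_count = min_count,
                 correction = correction),
            class = "hotspot_scan")
}

#' @export
print.hotspot_scan <- function(x, ...) {
  cat("<hotspot_scan> alpha:", x$alpha, " min count:", x$min_count,
      " correction:", x$correction, "\n")
  print(x$summary)
  invisible(x)
}

#' @rdname run_hotspot_analysis
#' @param x A `hotspot_scan` object.
#' @param ... Unused.
#' @method tidy hotspot_scan
#' @export
tidy.hotspot_scan <- function(x, ...) as_tibble(x$results)

#' @rdname run_hotspot_analysis
#' @method glance hotspot_scan
#' @export
glance.hotspot_scan <- function(x, ...) as_tibble(x$summary)

#' Significant hotspots of one dataset run and class
#'
#' Convenience accessor used by the comparative module.
#'
#' @param scan A `hotspot_scan` object.
#' @param dataset `"TS"`, `"OG"` or `"genome"`.
#' @param mclass Mutation class.
#' @return Tibble of significant hotspot rows.
#' @export
significant_hotspots <- function(scan, dataset, mclass) {
  filter(scan$results, .data$dataset == !!dataset,
         .data$mclass == !!mclass, .data$significant)
}
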