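#' Residue-opportunity exposure per domain family
#'
#' Mutational frequency is compared on the scale of mutation
#' opportunities: each family's exposure is the summed length of its
#' instances times the number of tumour samples, which jointly normalises
#' for domain frequency (instance count), domain length and cohort size.
#'
#' @param domains Domain-instance tibble.
#' @param n_samples Number of tumour samples in the cohort.
#' @return A tibble (`family_id`, `n_instances`, `total_length`,
#'   `exposure`).
#' @export
compute_exposure <- function(domains, n_samples) {
  if (n_samples < 1) abort("n_samples must be >= 1")
  if (nrow(domains) == 0) abort("no domain instances: empty family set")
  domains %>%
    mutate(len = .data$end - .data$start + 1L) %>%
    group_by(.data$family_id) %>%
    summarise(n_instances = dplyr::n(),
              total_length = sum(.data$len), .groups = "drop") %>%
    mutate(exposure = as.numeric(.data$total_length) * n_samples)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Closed-form Pearson statistic without continuity correction,
#' `N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with the p-value from the
#' chi-square distribution on 1 degree of freedom. A zero row or column
#' marginal gives statistic 0 and p-value 1 (reported via a message)
#' rather than an error, since all-zero families are legitimate inputs.
#' All arguments are vectorised.
#'
#' @param a,b,c,d Non-negative cell counts, table `[[a, b], [c, d]]`.
#' @return A tibble (`chi2_stat`, `p_value`).
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("cell counts must be non-negative")
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  degen <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  if (any(degen)) {
    inform(paste0(sum(degen), " degenerate 2x2 table(s) with a zero",
                  " marginal: statistic 0, p-value 1"))
  }
  stat <- ifelse(degen, 0, n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2))
  tibble(chi2_stat = stat,
         p_value = ifelse(degen, 1, pchisq(stat, df = 1,
                                           lower.tail = FALSE)))
}

#' Domain-family mutation enrichment
#'
#' For each tested family and mutation class, compares the family's
#' mutations-per-opportunity rate with a background rate in a 2x2
#' chi-square association test. Two background modes:
#' \describe{
#'   \item{background set}{`background_families` given: the background
#'     families are pooled into a single background row, and only families
#'     outside the background set are tested.}
#'   \item{genome-wide}{`background_families = NULL`: each family is
#'     tested against all other families pooled.}
#' }
#' P-values are Bonferroni-corrected over the number of families tested
#' for each class; a family is flagged `enriched` only when its corrected
#' p-value is below `alpha` *and* its rate exceeds the background rate, so
#' mutation-depleted families are never flagged.
#'
#' @param mapped Domain-mapped mutation tibble ([map_to_domains()]).
#' @param domains Domain-instance tibble.
#' @param n_samples Number of tumour samples.
#' @param background_families Character vector of background family ids,
#'   or `NULL` for the genome-wide mode.
#' @param alpha Significance level applied to corrected p-values.
#' @param classes Mutation classes to test (each independently).
#' @return A `domain_enrichment` object: a tibble with observed and
#'   background counts and exposures, rates, the chi-square statistic,
#'   raw and corrected p-values and the `enriched` flag.
#' @export
enrich_domains <- function(mapped, domains, n_samples,
                           background_families = NULL, alpha = 0.05,
                           classes = MUTATION_CLASSES) {
  stopifnot(alpha > 0, alpha < 1)
  expo <- compute_exposure(domains, n_samples)
  all_fams <- expo$family_id
  if (!is.null(background_families)) {
    background_families <- unique(background_families)
    unknown <- setdiff(background_families, all_fams)
    if (length(unknown) > 0) {
      abort(paste0("background families absent from the domain table: ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
    tested <- setdiff(all_fams, background_families)
    if (length(tested) == 0) abort("no families left to test")
    mode <- "background_set"
  } else {
    if (length(all_fams) < 2) {
      abort("genome-wide enrichment needs at least 2 families")
    }
    tested <- all_fams
    mode <- "genome_wide"
  }

  counts <- mapped %>%
    filter(.data$mclass %in% classes) %>%
    count(.data$family_id, .data$mclass, name = "observed")
  grid <- tidyr::expand_grid(family_id = tested, mclass = classes) %>%
    left_join(counts, by = c("family_id", "mclass")) %>%
    mutate(observed = dplyr::coalesce(.data$observed, 0L)) %>%
    left_join(select(expo, "family_id", "exposure"), by = "family_id")
  if (any(grid$observed > grid$exposure)) {
    abort("observed mutations exceed exposure: mapping is inconsistent")
  }

  if (mode == "background_set") {
    bg_counts <- counts %>%
      filter(.data$family_id %in% background_families) %>%
      group_by(.data$mclass) %>%
      summarise(bg_observed = sum(.data$observed), .groups = "drop")
    bg_exposure <- sum(expo$exposure[expo$family_id %in%
                                       background_families])
    grid <- grid %>%
      left_join(bg_counts, by = "mclass") %>%
      mutate(bg_observed = dplyr::coalesce(.data$bg_observed, 0L),
             bg_exposure = bg_exposure)
  } else {
    tot <- grid %>%
      group_by(.data$mclass) %>%
      summarise(tot_obs = sum(.data$observed), .groups = "drop")
    grid <- grid %>%
      left_join(tot, by = "mclass") %>%
      mutate(bg_observed = .data$tot_obs - .data$observed,
             bg_exposure = sum(expo$exposure) - .data$exposure) %>%
      select(-"tot_obs")
  }

  ts <- chi_square_2x2(grid$observed, grid$exposure - grid$observed,
                       grid$bg_observed,
                       grid$bg_exposure - grid$bg_observed)
  m <- length(tested)
  out <- grid %>%
    mutate(rate = .data$observed / .data$exposure,
           bg_rate = .data$bg_observed / .data$bg_exposure,
           rate_ratio = .data$rate / .data$bg_rate,
           chi2_stat = ts$chi2_stat,
           p_value = ts$p_value,
           m = m,
           p_corrected = pmin(1, .data$p_value * m),
           enriched = .data$p_corrected < alpha &
             .data$rate > .data$bg_rate) %>%
    arrange(.data$mclass, .data$p_corrected, .data$family_id)
  structure(out, class = c("domain_enrichment", class(out)),
            mode = mode, alpha = alpha, n_samples = n_samples)
}

#' @export
print.domain_enrichment <- function(x, ...) {
  cat("<domain_enrichment> mode:", attr(x, "mode"),
      " alpha:", attr(x, "alpha"),
      " families tested:", x$m[1] %||% 0,
      " enriched:", sum(x$enriched), "\n")
  NextMethod()
}

#' @rdname enrich_domains
#' @param x A `domain_enrichment` object.
#' @param ... Unused.
#' @method tidy domain_enrichment
#' @export
tidy.domain_enrichment <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @rdname enrich_domains
#' @method glance domain_enrichment
#' @export
glance.domain_enrichment <- function(x, ...) {
  x %>%
    as_tibble() %>%
    group_by(.data$mclass) %>%
    summarise(n_tested = dplyr::n(),
              n_enriched = sum(.data$enriched), .groups = "drop") %>%
    mutate(mode = attr(x, "mode"), alpha = attr(x, "alpha"))
}

unclass_result <- function(x) {
  class(x) <- setdiff(class(x), c("domain_enrichment", "hotspot_scan"))
  x
}
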