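# Shared in-code fixtures: a minimal proteome with two domain instances
# of one family and one of another, plus writers for the on-disk formats.

tiny_proteome <- function() {
  tibble::tibble(
    accession = c("P1", "P2", "P3"),
    sequence = c(
      paste(rep("ACDEFGHIKL", 10), collapse = ""),  # 100 aa
      paste(rep("MNPQRSTVWY", 8), collapse = ""),   # 80 aa
      paste(rep("ACDKLMNPQR", 6), collapse = "")),  # 60 aa
    length = c(100L, 80L, 60L))
}

tiny_domains <- function() {
  tibble::tibble(
    protein_accession = c("P1", "P2", "P3"),
    family_id = c("PF_A", "PF_A", "PF_B"),
    start = c(10L, 5L, 20L),
    end = c(29L, 24L, 39L)) |>
    dplyr::mutate(instance_id = paste0(protein_accession, "/",
                                       start, "-", end))
}

# gap-free alignment consistent with tiny_proteome()/tiny_domains()
tiny_msas <- function() {
  prot <- tiny_proteome()
  dom <- tiny_domains()
  slice_of <- function(i) {
    substr(prot$sequence[match(dom$protein_accession[i], prot$accession)],
           dom$start[i], dom$end[i])
  }
  rows_a <- stats::setNames(c(slice_of(1), slice_of(2)),
                            dom$instance_id[1:2])
  rows_b <- stats::setNames(slice_of(3), dom$instance_id[3])
  list(PF_A = domspot:::new_msa(rows_a, "PF_A"),
       PF_B = domspot:::new_msa(rows_b, "PF_B"))
}

write_fasta_tmp <- function(acc, seq) {
  f <- withr::local_tempfile(fileext = ".fa",
                             .local_envir = parent.frame())
  writeLines(paste0(">", acc, "\n", seq), f)
  f
}

write_tsv_tmp <- function(df) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  readr::write_tsv(df, f, progress = FALSE)
  f
}

# small but complete simulation spec used by the faster pipeline tests
small_spec <- function(seed = 42, ...) {
  simulation_spec(n_families = 8, n_background_families = 30,
                  instances_per_family = c(2, 4),
                  domain_length = c(40, 60),
                  n_ts = 12, n_og = 12, n_other = 20, n_samples = 100,
                  base_rates = c(missense = 2e-4, truncation = 5e-5,
                                 indel = 1e-5),
                  hotspots = tibble::tibble(
                    family_id = "FAM001", mclass = "missense",
                    gene_class = NA_character_, excess = 0.4,
                    multiplier = 10),
                  enriched = tibble::tibble(
                    family_id = "FAM002", mclass = "missense",
                    multiplier = 10),
                  seed = seed, ...)
}

# Exact binomial upper-tail by term-by-term summation over the explicit
# binomial probability mass, independent of the survival-function path.
tail_sum_oracle <- function(k, n, p) {
  if (k > n) return(0)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0))
}
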