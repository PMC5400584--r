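#' Overlap of hotspot landscapes across the three dataset runs
#'
#' Intersects the significant hotspots of the tumour-suppressor, oncogene
#' and whole-genome runs, either at the domain-family level or at the
#' (family, alignment column) position level, and reports the seven
#' exclusive intersection regions of the three sets (a three-way Venn
#' diagram in table form).
#'
#' @param ts_hotspots,og_hotspots,genome_hotspots Significant-only hotspot
#'   tibbles of one common mutation class (e.g. from
#'   [significant_hotspots()]).
#' @param level `"family"` or `"position"`.
#' @return A `hotspot_overlap` object: tibble (`region`, `count`,
#'   `items`) whose counts sum to the size of the three-set union.
#' @export
overlap_sets <- function(ts_hotspots, og_hotspots, genome_hotspots,
                         level = c("family", "position")) {
  level <- match.arg(level)
  cls <- unique(c(ts_hotspots$mclass, og_hotspots$mclass,
                  genome_hotspots$mclass))
  if (length(cls) > 1) {
    abort(paste0("mixed mutation classes in overlap inputs: ",
                 paste(cls, collapse = ", ")))
  }
  key <- function(d) {
    if (nrow(d) == 0) return(character(0))
    if (level == "family") unique(d$family_id)
    else unique(paste0(d$family_id, ":", d$msa_column))
  }
  ts <- key(ts_hotspots); og <- key(og_hotspots); g <- key(genome_hotspots)
  in_ts <- function(x) x %in% ts
  in_og <- function(x) x %in% og
  in_g <- function(x) x %in% g
  u <- unique(c(ts, og, g))
  member <- tibble(item = u, ts = in_ts(u), og = in_og(u), g = in_g(u))
  regions <- tibble(
    region = c("TS_only", "OG_only", "genome_only", "TS_OG",
               "TS_genome", "OG_genome", "TS_OG_genome"),
    ts = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
    og = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    g = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE))
  out <- regions %>%
    mutate(items = purrr::pmap(list(.data$ts, .data$og, .data$g),
                               function(a, b, c2) {
                                 sort(member$item[member$ts == a &
                                                    member$og == b &
                                                    member$g == c2])
                               }),
           count = vapply(.data$items, length, 1L)) %>%
    select("region", "count", "items")
  structure(out, class = c("hotspot_overlap", class(out)),
            level = level,
            mclass = if (length(cls) == 1) cls else NA_character_)
}

#' @export
print.hotspot_overlap <- function(x, ...) {
  cat("<hotspot_overlap> level:", attr(x, "level"),
      " class:", attr(x, "mclass"),
      " union:", sum(x$count), "\n")
  NextMethod()
}

#' Genome-wide hotspots co-located with known cancer-gene hotspots
#'
#' Finds proteins not labelled tumour suppressor or oncogene that carry a
#' significant genome-run hotspot at exactly the same (family, alignment
#' column, class) as a significant TS or OG hotspot. A match to an
#' oncogene hotspot suggests a putative gain of function, a match to a
#' tumour-suppressor hotspot a putative loss; a column matching both is
#' reported as `"ambiguous"`.
#'
#' @param genome_hotspots Significant-only genome-run hotspot tibble.
#' @param ts_hotspots,og_hotspots Significant-only hotspot tibbles of the
#'   cancer-gene runs (same class universe).
#' @param gene_labels Tibble (`gene`, `class`).
#' @return Tibble (`protein_accession`, `family_id`, `msa_column`,
#'   `mclass`, `matched`, `direction`).
#' @export
colocated_candidates <- function(genome_hotspots, ts_hotspots,
                                 og_hotspots, gene_labels) {
  labelled <- gene_labels$gene[gene_labels$class %in% c("TS", "OG", "both")]
  keyed <- function(d) {
    distinct(d, .data$family_id, .data$msa_column, .data$mclass)
  }
  empty <- tibble(protein_accession = character(), family_id = character(),
                  msa_column = integer(), mclass = character(),
                  matched = character(), direction = character())
  if (nrow(genome_hotspots) == 0) return(empty)
  hits <- genome_hotspots %>%
    mutate(in_ts = paste0(.data$family_id, ":", .data$msa_column, ":",
                          .data$mclass) %in%
             with(keyed(ts_hotspots),
                  paste0(family_id, ":", msa_column, ":", mclass)),
           in_og = paste0(.data$family_id, ":", .data$msa_column, ":",
                          .data$mclass) %in%
             with(keyed(og_hotspots),
                  paste0(family_id, ":", msa_column, ":", mclass))) %>%
    filter(.data$in_ts | .data$in_og)
  if (nrow(hits) == 0) return(empty)
  hits %>%
    mutate(protein_accession = strsplit(.data$proteins, ",", fixed = TRUE)) %>%
    tidyr::unnest("protein_accession") %>%
    filter(!.data$protein_accession %in% labelled) %>%
    mutate(matched = case_when(.data$in_ts & .data$in_og ~ "TS+OG",
                               .data$in_ts ~ "TS",
                               TRUE ~ "OG"),
           direction = case_when(
             .data$matched == "TS+OG" ~ "ambiguous",
             .data$matched == "TS" ~ "putative_loss_of_function",
             TRUE ~ "putative_gain_of_function")) %>%
    select("protein_accession", "family_id", "msa_column", "mclass",
           "matched", "direction") %>%
    arrange(.data$family_id, .data$msa_column, .data$protein_accession)
}
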