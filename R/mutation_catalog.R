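AA_RE <- "[ACDEFGHIKLMNPQRSTVWY]"

#' Parse protein-change strings
#'
#' Classifies each change string into one of three mutation classes:
#' \describe{
#'   \item{missense}{`RefPosAlt`, e.g. `"V600E"`, with two distinct
#'     standard amino acids.}
#'   \item{truncation}{stop gains (`"E813*"`) and frameshifts
#'     (`"Q1247fs*26"`, `"D53fs"`), pooled because both abolish the
#'     downstream protein.}
#'   \item{indel}{in-frame deletions (`"E746_A750delELREA"`, `"F113del"`),
#'     insertions (`"K601insV"`) and deletion-insertions
#'     (`"V600delinsGG"`).}
#' }
#' Anything else (including synonymous `"V600V"`) is returned with class
#' `"unclassified"`; such records are excluded downstream.
#'
#' @param change Character vector of protein-change strings.
#' @return A tibble with columns `change`, `mclass`, `position` (1-based
#'   index of the first affected residue), `ref_aa` and `alt_aa` (`"*"`
#'   for stop, empty for a pure insertion or deletion side).
#' @export
parse_protein_change <- function(change) {
  if (any(is.na(change) | change == "")) {
    abort("protein-change strings must be non-empty")
  }
  n <- length(change)
  mclass <- rep("unclassified", n)
  position <- rep(NA_integer_, n)
  ref_aa <- rep(NA_character_, n)
  alt_aa <- rep(NA_character_, n)

  assign_hits <- function(idx, cls, pos, ref, alt) {
    mclass[idx] <<- cls
    position[idx] <<- as.integer(pos)
    ref_aa[idx] <<- ref
    alt_aa[idx] <<- alt
  }

  todo <- rep(TRUE, n)

  # missense: RefPosAlt with distinct standard residues
  m <- stringr::str_match(change, paste0("^(", AA_RE, ")(\\d+)(", AA_RE, ")$"))
  hit <- todo & !is.na(m[, 1]) & m[, 2] != m[, 4]
  assign_hits(hit, "missense", m[hit, 3], m[hit, 2], m[hit, 4])
  todo <- todo & !hit

  # stop gain
  m <- stringr::str_match(change, paste0("^(", AA_RE, ")(\\d+)\\*$"))
  hit <- todo & !is.na(m[, 1])
  assign_hits(hit, "truncation", m[hit, 3], m[hit, 2], "*")
  todo <- todo & !hit

  # frameshift, with optional new-stop offset ("fs", "fs*26")
  m <- stringr::str_match(change,
                          paste0("^(", AA_RE, ")(\\d+)fs(\\*\\d+)?$"))
  hit <- todo & !is.na(m[, 1])
  assign_hits(hit, "truncation", m[hit, 3], m[hit, 2], "")
  todo <- todo & !hit

  # in-frame deletion-insertion
  m <- stringr::str_match(change, paste0(
    "^(", AA_RE, ")(\\d+)(?:_(", AA_RE, ")(\\d+))?delins(", AA_RE, "+)$"))
  hit <- todo & !is.na(m[, 1])
  assign_hits(hit, "indel", m[hit, 3], m[hit, 2], m[hit, 6])
  todo <- todo & !hit

  # in-frame deletion (deleted residues may be spelled out)
  m <- stringr::str_match(change, paste0(
    "^(", AA_RE, ")(\\d+)(?:_(", AA_RE, ")(\\d+))?del(", AA_RE, "*)$"))
  hit <- todo & !is.na(m[, 1])
  ref <- ifelse(m[hit, 6] != "", m[hit, 6], m[hit, 2])
  assign_hits(hit, "indel", m[hit, 3], ref, "")
  todo <- todo & !hit

  # in-frame insertion
  m <- stringr::str_match(change, paste0(
    "^(", AA_RE, ")(\\d+)(?:_(", AA_RE, ")(\\d+))?ins(", AA_RE, "+)$"))
  hit <- todo & !is.na(m[, 1])
  assign_hits(hit, "indel", m[hit, 3], "", m[hit, 6])

  tibble(change = change, mclass = mclass, position = position,
         ref_aa = ref_aa, alt_aa = alt_aa)
}

#' Classify a mutation table
#'
#' Adds `mclass`, `position`, `ref_aa`, `alt_aa` columns to a mutation
#' record table by parsing its `change` column (see
#' [parse_protein_change()]). Unparseable records are kept with class
#' `"unclassified"` and reported via a message.
#'
#' @param mutations Tibble with at least a `change` column (typically from
#'   [read_mutations()]).
#' @return The input with classification columns appended.
#' @export
classify_mutations <- function(mutations) {
  parsed <- parse_protein_change(mutations$change)
  out <- dplyr::bind_cols(mutations,
                          select(parsed, -"change"))
  n_un <- sum(out$mclass == "unclassified")
  if (n_un > 0) {
    inform(paste0(n_un, " unparseable change string(s) kept as",
                  " 'unclassified' and excluded from mapping"))
  }
  out
}

#' Drop mutations whose reference residue contradicts the proteome
#'
#' Records whose stated reference amino acid (first residue for
#' multi-residue indels) disagrees with the protein sequence at that
#' position, or whose position lies beyond the protein, are removed and
#' counted — bulk catalogues contain stale records, and a hard error would
#' make them unusable. Pure insertions carry no reference residue and are
#' kept.
#'
#' @param classified Classified mutation tibble.
#' @param proteome Proteome tibble.
#' @return The filtered tibble; attribute `n_dropped` carries the count.
#' @export
check_reference_residues <- function(classified, proteome) {
  x <- left_join(classified,
                 select(proteome, "accession", "sequence", plen = "length"),
                 by = c(protein_accession = "accession"))
  first_ref <- substr(dplyr::coalesce(x$ref_aa, ""), 1, 1)
  has_pos <- !is.na(x$position)
  in_range <- has_pos & x$position <= x$plen
  observed <- ifelse(in_range,
                     substr(x$sequence, x$position, x$position), "")
  ok <- !has_pos |
    (in_range & (first_ref == "" | first_ref == observed))
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " mutation(s) dropped: reference residue or",
                  " position inconsistent with the proteome"))
  }
  out <- select(x[ok, ], -"sequence", -"plen")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Map classified mutations onto domain instances
#'
#' A mutation maps to every domain instance whose `[start, end]` interval
#' contains its (first affected) position; mutations outside all domains
#' are unmapped. A mutation under overlapping instances of different
#' families contributes to each family independently.
#'
#' @param classified Classified mutation tibble (unclassified rows are
#'   ignored).
#' @param domains Domain-instance tibble from [read_domain_table()].
#' @return One row per (mutation, instance) pair with `local_pos`
#'   (1-based offset within the domain) and `instance_id` added.
#' @export
map_to_domains <- function(classified, domains) {
  x <- filter(classified, .data$mclass %in% MUTATION_CLASSES)
  mapped <- inner_join(
    x, select(domains, "protein_accession", "family_id", "start", "end",
              "instance_id"),
    by = join_by(protein_accession,
                 between(x$position, y$start, y$end)),
    relationship = "many-to-many")
  mutate(mapped, local_pos = .data$position - .data$start + 1L)
}

#' Summarise mapping coverage
#'
#' @param classified Classified mutation tibble.
#' @param mapped Output of [map_to_domains()].
#' @return Per-class counts of parsed, mapped (to at least one instance)
#'   and unmapped mutations; `parsed = mapped + unmapped` per class.
#' @export
mapping_summary <- function(classified, mapped) {
  classified <- mutate(classified, .mid = row_number())
  mapped_ids <- unique(mapped_row_ids(classified, mapped))
  classified %>%
    group_by(.data$mclass) %>%
    summarise(parsed = dplyr::n(),
              mapped = sum(.data$.mid %in% mapped_ids),
              .groups = "drop") %>%
    mutate(unmapped = .data$parsed - .data$mapped)
}

# Identifies which rows of `classified` appear in `mapped` by their
# defining fields (sample, protein, change).
mapped_row_ids <- function(classified, mapped) {
  key <- function(d) paste(d$sample_id, d$protein_accession, d$change)
  classified$.mid[match(key(mapped), key(classified))]
}

#' Map domain-mapped mutations to alignment columns
#'
#' The MSA column of a mutation is the column of the `local_pos`-th
#' non-gap character of its instance's alignment row.
#'
#' @param mapped Output of [map_to_domains()].
#' @param msas Named list of `domain_msa` objects keyed by family id, with
#'   row names equal to instance ids.
#' @return `mapped` with an `msa_column` column added.
#' @export
map_to_msa_columns <- function(mapped, msas) {
  pm <- msa_position_map(msas)
  out <- left_join(mapped, pm,
                   by = c("family_id", "instance_id", "local_pos"))
  bad <- is.na(out$msa_column)
  if (any(bad)) {
    eg <- out[bad, ][1, ]
    abort(paste0("alignment/domain-table inconsistency: no MSA column for ",
                 eg$instance_id, " (family ", eg$family_id,
                 ") at local position ", eg$local_pos))
  }
  out
}

#' Residue-to-column lookup for a set of family alignments
#'
#' @param msas Named list of `domain_msa` objects keyed by family id.
#' @return A tibble (`family_id`, `instance_id`, `local_pos`,
#'   `msa_column`) with one row per non-gap alignment character.
#' @export
msa_position_map <- function(msas) {
  purrr::imap(msas, function(msa, fam) {
    rows <- purrr::imap(as.list(unclass(msa)), function(s, id) {
      cols <- which(strsplit(s, "")[[1]] != "-")
      tibble(instance_id = id,
             local_pos = seq_along(cols),
             msa_column = as.integer(cols))
    })
    mutate(bind_rows(rows), family_id = fam)
  }) %>%
    bind_rows() %>%
    select("family_id", "instance_id", "local_pos", "msa_column")
}

#' Aggregate mutations per alignment column
#'
#' Counts mutations per (family, MSA column, mutation class), keeping the
#' contributing protein accessions. Classes are kept separate throughout:
#' missense, truncation and indel hotspots are tested independently.
#'
#' @param mapped Output of [map_to_msa_columns()].
#' @return A tibble (`family_id`, `msa_column`, `mclass`, `k`,
#'   `proteins`), `proteins` a comma-collapsed sorted accession list.
#' @export
aggregate_columns <- function(mapped) {
  if (nrow(mapped) == 0) {
    return(tibble(family_id = character(), msa_column = integer(),
                  mclass = character(), k = integer(),
                  proteins = character()))
  }
  mapped %>%
    group_by(.data$family_id, .data$msa_column, .data$mclass) %>%
    summarise(k = dplyr::n(),
              proteins = paste(sort(unique(.data$protein_accession)),
                               collapse = ","),
              .groups = "drop") %>%
    arrange(.data$family_id, .data$mclass, .data$msa_column)
}
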