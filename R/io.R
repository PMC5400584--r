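#' Read a proteome from a FASTA file
#'
#' Accessions are the first whitespace-delimited token of each header and
#' must be unique; sequences are upper-cased and may use the twenty
#' standard amino-acid letters plus `X`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession`, `sequence` and `length`.
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) abort(paste0("proteome file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  acc <- unname(sub("\\s.*$", "", names(set)))
  seqs <- toupper(unname(as.character(set)))
  dup <- unique(acc[duplicated(acc)])
  if (length(dup) > 0) {
    abort(paste0("duplicate accession(s) in proteome: ",
                 paste(dup, collapse = ", ")))
  }
  if (any(nchar(seqs) == 0)) {
    abort(paste0("empty sequence for accession(s): ",
                 paste(acc[nchar(seqs) == 0], collapse = ", ")))
  }
  bad <- grepl(paste0("[^", paste(AA_STANDARD, collapse = ""), "X]"), seqs)
  if (any(bad)) {
    abort(paste0("non amino-acid characters in sequence(s): ",
                 paste(acc[bad], collapse = ", ")))
  }
  tibble(accession = acc, sequence = seqs, length = nchar(seqs))
}

#' Read a domain-instance table
#'
#' A TSV with columns `protein_accession`, `family_id`, `start`, `end`
#' (1-based inclusive residue coordinates). Every instance is validated
#' against the proteome: coordinates must lie within the protein, and
#' instances of the same family on one protein may not overlap.
#'
#' @param path Path to the TSV file.
#' @param proteome Proteome tibble from [read_proteome()].
#' @return A tibble with columns `protein_accession`, `family_id`, `start`,
#'   `end` and the derived `instance_id` (`"accession/start-end"`).
#' @export
read_domain_table <- function(path, proteome) {
  if (!file.exists(path)) abort(paste0("domain table not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    protein_accession = readr::col_character(),
    family_id = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer()
  ), progress = FALSE)
  if (nrow(x) == 0) {
    warn("domain table is empty")
    return(mutate(x, instance_id = character(0)))
  }
  validate_domains(x, proteome)
}

validate_domains <- function(x, proteome) {
  x <- left_join(x, select(proteome, "accession", plen = "length"),
                 by = c(protein_accession = "accession"))
  if (anyNA(x$plen)) {
    abort(paste0("domain rows reference unknown protein(s): ",
                 paste(unique(x$protein_accession[is.na(x$plen)]),
                       collapse = ", ")))
  }
  bad <- which(x$start < 1L | x$start > x$end)
  if (length(bad) > 0) {
    abort(paste0("invalid start/end at domain row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  bad <- which(x$end > x$plen)
  if (length(bad) > 0) {
    abort(paste0("domain end exceeds protein length at row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  ov <- x %>%
    group_by(.data$protein_accession, .data$family_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    filter(dplyr::lag(.data$end, default = 0L) >= .data$start) %>%
    ungroup()
  if (nrow(ov) > 0) {
    abort(paste0("overlapping same-family instances on protein(s): ",
                 paste(unique(ov$protein_accession), collapse = ", ")))
  }
  x %>%
    select(-"plen") %>%
    mutate(instance_id = paste0(.data$protein_accession, "/",
                                .data$start, "-", .data$end))
}

#' Read a mutation table
#'
#' A TSV with columns `sample_id`, `protein_accession`, `change` (a
#' protein-change string such as `"V600E"`) and `cancer_type`.
#'
#' @param path Path to the TSV file.
#' @param proteome Optional proteome tibble; when given, rows whose
#'   accession is absent from the proteome raise an error.
#' @return A tibble of mutation records.
#' @export
read_mutations <- function(path, proteome = NULL) {
  if (!file.exists(path)) abort(paste0("mutation table not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    protein_accession = readr::col_character(),
    change = readr::col_character(),
    cancer_type = readr::col_character()
  ), progress = FALSE)
  if (any(is.na(x$change) | x$change == "")) {
    abort("empty protein-change string in mutation table")
  }
  if (!is.null(proteome)) {
    missing <- setdiff(x$protein_accession, proteome$accession)
    if (length(missing) > 0) {
      abort(paste0("mutations reference unknown protein(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    }
  }
  x
}

#' Read a gene-class label table
#'
#' A TSV with columns `gene` and `class`; classes are `TS` (tumour
#' suppressor), `OG` (oncogene), `both` or `other`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene`, `class`.
#' @export
read_gene_labels <- function(path) {
  if (!file.exists(path)) abort(paste0("label table not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    class = readr::col_character()
  ), progress = FALSE)
  bad <- setdiff(unique(x$class), c("TS", "OG", "both", "other"))
  if (length(bad) > 0) {
    abort(paste0("unknown gene class label(s): ", paste(bad, collapse = ", ")))
  }
  x
}

# ---- MSA input/output -------------------------------------------------------

new_msa <- function(rows, family_id = NA_character_) {
  if (length(rows) == 0) abort("MSA has no rows")
  if (length(unique(nchar(rows))) != 1) {
    abort("ragged MSA: rows differ in length")
  }
  structure(rows, class = "domain_msa", family_id = family_id)
}

#' @export
print.domain_msa <- function(x, ...) {
  cat("<domain_msa> family:", attr(x, "family_id") %||% "?",
      "rows:", length(x), "columns:", msa_ncol(x), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a[1])) b else a

#' Number of columns of a family alignment
#' @param msa A `domain_msa` object.
#' @return Integer column count.
#' @export
msa_ncol <- function(msa) nchar(msa[[1]])

#' Read one family multiple sequence alignment
#'
#' Supports aligned FASTA and single-alignment Stockholm. Row identifiers
#' are expected to be `"accession/start-end"` keys of domain instances.
#' Gap characters `.` are normalised to `-`.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"stockholm"`; guessed from the first line
#'   when omitted.
#' @param family_id Optional family identifier to attach.
#' @param proteome,domains Optional proteome/domain tibbles; when both are
#'   given each row is checked to ungap exactly to the corresponding domain
#'   subsequence of the proteome.
#' @return A `domain_msa`: a named character vector of equal-length gapped
#'   sequences.
#' @export
read_msa <- function(path, format = NULL, family_id = NA_character_,
                     proteome = NULL, domains = NULL) {
  if (!file.exists(path)) abort(paste0("MSA file not found: ", path))
  if (is.null(format)) {
    first <- readLines(path, n = 1)
    format <- if (startsWith(first, "# STOCKHOLM")) "stockholm" else "fasta"
  }
  rows <- switch(format,
    fasta = {
      set <- Biostrings::readBStringSet(path)
      setNames(as.character(set), sub("\\s.*$", "", names(set)))
    },
    stockholm = {
      msas <- parse_stockholm(readLines(path))
      if (length(msas) != 1) {
        abort("expected a single alignment in Stockholm file")
      }
      msas[[1]]
    },
    abort(paste0("unknown MSA format: ", format))
  )
  rows[] <- chartr(".", "-", toupper(rows))
  msa <- new_msa(rows, family_id)
  if (!is.null(proteome) && !is.null(domains)) {
    validate_msa(msa, proteome, domains)
  }
  msa
}

#' Read a collection of family alignments from one Stockholm file
#'
#' Alignments are separated by `//` records; each must carry a
#' `#=GF ID` line naming its domain family.
#'
#' @param path Path to the multi-alignment Stockholm file.
#' @return A named list of `domain_msa` objects keyed by family id.
#' @export
read_msa_collection <- function(path) {
  if (!file.exists(path)) abort(paste0("MSA file not found: ", path))
  msas <- parse_stockholm(readLines(path))
  if (any(is.na(names(msas)) | names(msas) == "")) {
    abort("every alignment needs a '#=GF ID' family identifier")
  }
  purrr::imap(msas, function(rows, fam) {
    rows[] <- chartr(".", "-", toupper(rows))
    new_msa(rows, fam)
  })
}

# Parses Stockholm text into a list of named row vectors; the list is
# named by the '#=GF ID' tag when present. Handles interleaved blocks.
parse_stockholm <- function(lines) {
  out <- list()
  rows <- character(0)
  ids <- character(0)
  fam <- NA_character_
  flush <- function() {
    if (length(rows) > 0) {
      msa <- setNames(rows, ids)
      out[[length(out) + 1]] <<- msa
      names(out)[length(out)] <<- fam %||% ""
    }
    rows <<- character(0); ids <<- character(0); fam <<- NA_character_
  }
  for (ln in lines) {
    if (grepl("^//\\s*$", ln)) { flush(); next }
    if (grepl("^#=GF\\s+ID\\s+", ln)) {
      fam <- sub("^#=GF\\s+ID\\s+", "", ln)
      next
    }
    if (startsWith(ln, "#") || grepl("^\\s*$", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) abort(paste0("malformed Stockholm line: ", ln))
    i <- match(parts[1], ids)
    if (is.na(i)) {
      ids <- c(ids, parts[1]); rows <- c(rows, parts[2])
    } else {
      rows[i] <- paste0(rows[i], parts[2])
    }
  }
  flush()
  if (length(out) == 0) abort("no alignments found in Stockholm input")
  out
}

#' Check that an alignment is consistent with the proteome
#'
#' Every row key must be an `"accession/start-end"` instance key, and
#' removing the gaps from the row must reproduce exactly that slice of the
#' protein sequence.
#'
#' @inheritParams read_msa
#' @param msa A `domain_msa`.
#' @return The `msa`, invisibly; inconsistencies raise errors.
#' @export
validate_msa <- function(msa, proteome, domains) {
  keys <- names(msa)
  m <- regmatches(keys, regexec("^(.+)/(\\d+)-(\\d+)$", keys))
  bad <- vapply(m, length, 1L) != 4
  if (any(bad)) {
    abort(paste0("MSA row id(s) not in 'accession/start-end' form: ",
                 paste(keys[bad], collapse = ", ")))
  }
  for (i in seq_along(keys)) {
    acc <- m[[i]][2]
    s <- as.integer(m[[i]][3]); e <- as.integer(m[[i]][4])
    j <- match(acc, proteome$accession)
    if (is.na(j)) abort(paste0("MSA row for unknown protein: ", keys[i]))
    ungapped <- gsub("-", "", msa[[i]], fixed = TRUE)
    slice <- substr(proteome$sequence[j], s, e)
    if (!identical(ungapped, slice)) {
      abort(paste0("MSA row ", keys[i],
                   " does not match the proteome slice"))
    }
    if (!is.null(domains) && !keys[i] %in% domains$instance_id) {
      abort(paste0("MSA row without a domain instance: ", keys[i]))
    }
  }
  invisible(msa)
}

#' Write one family alignment
#'
#' @param msa A `domain_msa`.
#' @param path Output path.
#' @param format `"fasta"` (default) or `"stockholm"`.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "fasta") {
    writeLines(paste0(">", names(msa), "\n", unname(msa)), path)
  } else {
    write_msa_collection(setNames(list(msa), attr(msa, "family_id")), path)
  }
  invisible(path)
}

#' Write a collection of family alignments as multi-alignment Stockholm
#'
#' @param msas Named list of `domain_msa` objects (names = family ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa_collection <- function(msas, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fam in names(msas)) {
    msa <- msas[[fam]]
    writeLines(c("# STOCKHOLM 1.0", paste("#=GF ID", fam),
                 sprintf("%s %s", names(msa), unname(msa)), "//"), con)
  }
  invisible(path)
}

# ---- Result tables ----------------------------------------------------------

#' Write a results table as TSV
#'
#' Column order is preserved, probability columns (`p`, `p_value`,
#' `p_corrected`) are written in scientific notation, other doubles with
#' 15 significant digits, and list columns are collapsed with commas, so
#' that writing the same table twice is byte-identical and a write/read
#' round trip reproduces values to at least 12 significant digits.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  x <- as_tibble(x)
  for (nm in names(x)) {
    col <- x[[nm]]
    if (is.list(col)) {
      x[[nm]] <- vapply(col, function(v) paste(v, collapse = ","), "")
    } else if (nm %in% c("p", "p_value", "p_corrected")) {
      x[[nm]] <- sprintf("%.12e", col)
    } else if (is.double(col)) {
      x[[nm]] <- vapply(col, function(v) format(v, digits = 15), "")
    }
  }
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to the TSV file.
#' @return A tibble with numeric columns restored.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(paste0("results file not found: ", path))
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                  guess_max = 100000)
}
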