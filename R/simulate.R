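#' Specification of a synthetic tumour cohort
#'
#' Describes the simulated study: a set of domain families under test plus
#' a large background family set, genes labelled tumour suppressor (TS),
#' oncogene (OG) or other, per-class background mutation rates, and the
#' planted signal (positional hotspots and enriched families) whose
#' recovery the downstream tests measure. Tumour suppressors receive an
#' elevated truncation weight (dispersed loss-of-function mutations) and
#' oncogenes an elevated missense weight with clustered hotspots,
#' mirroring the characteristic mutational patterns of the two gene
#' classes.
#'
#' @param n_families Number of domain families under test.
#' @param n_background_families Number of background ("random", not
#'   cancer-related) families used by the background-set enrichment mode.
#' @param instances_per_family Integer range (min, max) of instances per
#'   family.
#' @param domain_length Integer range of ancestor domain lengths
#'   (residues).
#' @param n_ts,n_og,n_other Gene counts per class.
#' @param n_samples Number of tumour samples in the cohort.
#' @param base_rates Named per-residue, per-sample background mutation
#'   rates for `missense`, `truncation`, `indel`.
#' @param class_weights Per-gene-class multipliers of the base rates,
#'   a named list of named vectors.
#' @param hotspots Planted positional hotspots: tibble with columns
#'   `family_id`, `mclass`, `gene_class` (`NA` = unrestricted), `excess`
#'   (fraction of the family's class mutations redirected to the planted
#'   column) and `multiplier` (family rate boost for that class).
#' @param enriched Planted enriched families: tibble with `family_id`,
#'   `mclass`, `multiplier`.
#' @param subst_prob Per-residue substitution probability between the
#'   family ancestor and each instance.
#' @param del_prob,ins_prob Per-instance probability of one short
#'   deletion/insertion event relative to the ancestor.
#' @param indel_max Maximum indel event length (residues).
#' @param linker_length Integer range of inter-domain linker lengths.
#' @param family_bias Host tested families preferentially on OG genes
#'   (first third), TS genes (second third) or uniformly (rest), giving
#'   the domain-composition classifier a recoverable signal.
#' @param stale_ref_fraction Fraction of emitted mutation strings given a
#'   deliberately wrong reference residue, to exercise the
#'   drop-and-log validation path.
#' @param seed Integer seed; all randomness in a simulated dataset flows
#'   from it.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_families = 24,
                            n_background_families = 450,
                            instances_per_family = c(2, 6),
                            domain_length = c(50, 120),
                            n_ts = 15, n_og = 15, n_other = 70,
                            n_samples = 200,
                            base_rates = c(missense = 5e-5,
                                           truncation = 1e-5,
                                           indel = 2e-6),
                            class_weights = list(
                              TS = c(missense = 1, truncation = 6,
                                     indel = 1),
                              OG = c(missense = 2, truncation = 0.5,
                                     indel = 1),
                              other = c(missense = 1, truncation = 1,
                                        indel = 1)),
                            hotspots = NULL,
                            enriched = NULL,
                            subst_prob = 0.15,
                            del_prob = 0.08, ins_prob = 0.05,
                            indel_max = 3,
                            linker_length = c(10, 30),
                            family_bias = TRUE,
                            stale_ref_fraction = 0,
                            seed = 1) {
  if (is.null(hotspots)) {
    # multipliers sized so each planted family accrues enough class-n
    # for near-certain recovery (the sparse truncation class needs the
    # largest boost); see the methods vignette for the power reasoning
    hotspots <- tibble(
      family_id = c("FAM001", "FAM009", "FAM017"),
      mclass = c("missense", "truncation", "missense"),
      gene_class = c("OG", "TS", NA),
      excess = c(0.30, 0.30, 0.25),
      multiplier = c(20, 25, 10))
  }
  if (is.null(enriched)) {
    enriched <- tibble(
      family_id = c("FAM018", "FAM019", "FAM020"),
      mclass = c("missense", "missense", "truncation"),
      multiplier = c(10, 10, 10))
  }
  spec <- list(n_families = n_families,
               n_background_families = n_background_families,
               instances_per_family = instances_per_family,
               domain_length = domain_length,
               n_ts = n_ts, n_og = n_og, n_other = n_other,
               n_samples = n_samples, base_rates = base_rates,
               class_weights = class_weights, hotspots = hotspots,
               enriched = enriched, subst_prob = subst_prob,
               del_prob = del_prob, ins_prob = ins_prob,
               indel_max = indel_max, linker_length = linker_length,
               family_bias = family_bias,
               stale_ref_fraction = stale_ref_fraction, seed = seed)
  validate_simulation_spec(spec)
  structure(spec, class = "simulation_spec")
}

validate_simulation_spec <- function(spec) {
  stopifnot(spec$n_families >= 1, spec$n_samples >= 1,
            all(spec$base_rates >= 0),
            all(names(spec$base_rates) == MUTATION_CLASSES),
            spec$instances_per_family[1] >= 1,
            spec$domain_length[1] >= 5,
            spec$stale_ref_fraction >= 0, spec$stale_ref_fraction < 1)
  if (nrow(spec$hotspots) > 0) {
    stopifnot(all(spec$hotspots$excess > 0),
              all(spec$hotspots$excess <= 1),
              all(spec$hotspots$mclass %in% MUTATION_CLASSES))
  }
  fam_ids <- sprintf("FAM%03d", seq_len(spec$n_families))
  bad <- setdiff(c(spec$hotspots$family_id, spec$enriched$family_id),
                 fam_ids)
  if (length(bad) > 0) {
    abort(paste0("planted signal names unknown families: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(spec)
}

# sample one integer from an inclusive range; guards against base
# sample()'s scalar expansion when the range collapses to one value
sample_range <- function(lo, hi) {
  if (lo == hi) return(as.integer(lo))
  sample(lo:hi, 1)
}

# One family: ancestor sequence mutated into n_inst instances
# (substitutions plus at most one short deletion and one insertion each),
# returned as the rows of the true alignment. Insertion blocks get their
# own columns, gapped in every other row.
simulate_family_rows <- function(spec, n_inst) {
  L0 <- sample_range(spec$domain_length[1], spec$domain_length[2])
  ancestor <- sample(AA_STANDARD, L0, replace = TRUE)
  core <- matrix("", n_inst, L0)
  inserts <- vector("list", n_inst)  # per instance: list(after, seq)
  for (i in seq_len(n_inst)) {
    s <- ancestor
    sub_at <- which(runif(L0) < spec$subst_prob)
    for (j in sub_at) s[j] <- sample(setdiff(AA_STANDARD, s[j]), 1)
    if (runif(1) < spec$del_prob) {
      dlen <- sample(seq_len(spec$indel_max), 1)
      dstart <- sample(L0 - dlen + 1, 1)
      s[dstart:(dstart + dlen - 1)] <- "-"
    }
    core[i, ] <- s
    if (runif(1) < spec$ins_prob) {
      ilen <- sample(seq_len(spec$indel_max), 1)
      inserts[[i]] <- list(after = sample(0:L0, 1),
                           seq = sample(AA_STANDARD, ilen, replace = TRUE))
    }
  }
  chunks <- list()
  for (pos in 0:L0) {
    if (pos > 0) chunks[[length(chunks) + 1]] <- core[, pos, drop = FALSE]
    for (i in seq_len(n_inst)) {
      ins <- inserts[[i]]
      if (!is.null(ins) && ins$after == pos) {
        block <- matrix("-", n_inst, length(ins$seq))
        block[i, ] <- ins$seq
        chunks[[length(chunks) + 1]] <- block
      }
    }
  }
  m <- do.call(cbind, chunks)
  apply(m, 1, paste, collapse = "")
}

#' Simulate the proteome side of a synthetic cohort
#'
#' Builds every domain family from a random ancestor (so the true
#' alignment is known), embeds the instances in host proteins joined by
#' random linkers, and assigns gene-class labels. Tested-family instances
#' live on the labelled genes; background-family instances live on
#' dedicated unlabelled proteins. Call within an RNG context —
#' [simulate_dataset()] seeds once from the spec.
#'
#' @param spec A [simulation_spec()].
#' @return List with `proteome`, `domains`, `labels` tibbles, `msas`
#'   (named list of `domain_msa`, rows keyed `"accession/start-end"`).
#' @export
simulate_proteome <- function(spec) {
  n_fam <- spec$n_families
  fam_ids <- c(sprintf("FAM%03d", seq_len(n_fam)),
               sprintf("BG%03d", seq_len(spec$n_background_families)))
  genes <- tibble(
    gene = c(sprintf("TSG%03d", seq_len(spec$n_ts)),
             sprintf("OGG%03d", seq_len(spec$n_og)),
             sprintf("GEN%03d", seq_len(spec$n_other))),
    class = rep(c("TS", "OG", "other"),
                c(spec$n_ts, spec$n_og, spec$n_other)))

  ir <- spec$instances_per_family
  assignments <- list()
  bg_counter <- 0
  third <- ceiling(n_fam / 3)
  for (fi in seq_along(fam_ids)) {
    fam <- fam_ids[fi]
    tested <- fi <= n_fam
    n_inst <- sample_range(ir[1], ir[2])
    rows <- simulate_family_rows(spec, n_inst)
    if (tested) {
      w <- rep(1, nrow(genes))
      if (spec$family_bias && fi <= third) {
        w[genes$class == "OG"] <- 4
      } else if (spec$family_bias && fi <= 2 * third) {
        w[genes$class == "TS"] <- 4
      }
      hosts <- sample(genes$gene, n_inst, prob = w)
      # a gene-class-restricted planted hotspot needs at least one
      # instance on a gene of that class
      need <- unique(spec$hotspots$gene_class[
        spec$hotspots$family_id == fam])
      need <- need[!is.na(need)]
      for (ci in seq_along(need)) {
        if (!any(genes$class[match(hosts, genes$gene)] == need[ci])) {
          hosts[ci] <- sample(genes$gene[genes$class == need[ci]], 1)
        }
      }
    } else {
      hosts <- sprintf("BGP%05d", bg_counter + seq_len(n_inst))
      bg_counter <- bg_counter + n_inst
    }
    assignments[[fi]] <- tibble(
      family_id = fam, inst = seq_len(n_inst), host = hosts,
      row = rows, seq = gsub("-", "", rows, fixed = TRUE))
  }
  asg <- bind_rows(assignments)

  bg_genes <- tibble(gene = sort(unique(asg$host[startsWith(asg$host,
                                                            "BGP")])),
                     class = "other")
  labels <- bind_rows(genes, bg_genes)

  lr <- spec$linker_length
  proteins <- vector("list", nrow(labels))
  dom_rows <- list()
  keys <- character(nrow(asg))
  ord_all <- split(seq_len(nrow(asg)), asg$host)
  for (pi in seq_len(nrow(labels))) {
    acc <- labels$gene[pi]
    idx <- ord_all[[acc]]
    if (length(idx) > 1) idx <- sample(idx)
    parts <- character(0)
    pos <- 0L
    for (j in idx) {
      linker <- paste(sample(AA_STANDARD, sample_range(lr[1], lr[2]),
                             replace = TRUE), collapse = "")
      parts <- c(parts, linker, asg$seq[j])
      start <- pos + nchar(linker) + 1L
      end <- start + nchar(asg$seq[j]) - 1L
      pos <- end
      dom_rows[[length(dom_rows) + 1]] <- tibble(
        protein_accession = acc, family_id = asg$family_id[j],
        start = start, end = end)
      keys[j] <- paste0(acc, "/", start, "-", end)
    }
    tail_linker <- paste(sample(AA_STANDARD, sample_range(lr[1], lr[2]),
                                replace = TRUE), collapse = "")
    proteins[[pi]] <- paste(c(parts, tail_linker), collapse = "")
  }
  proteome <- tibble(accession = labels$gene,
                     sequence = unlist(proteins)) %>%
    mutate(length = nchar(.data$sequence))
  domains <- bind_rows(dom_rows) %>%
    mutate(instance_id = paste0(.data$protein_accession, "/",
                                .data$start, "-", .data$end))
  asg$instance_id <- keys
  msas <- split(setNames(asg$row, asg$instance_id), asg$family_id)
  msas <- purrr::imap(msas, new_msa)
  list(proteome = proteome, domains = domains, labels = labels,
       msas = msas[c(fam_ids)], assignments = asg)
}

# Residue position lookup for a planted column: absolute protein position
# of each instance's residue aligned to `col` (NA where gapped).
column_residues <- function(msa, domains, col) {
  purrr::imap_dfr(as.list(unclass(msa)), function(row, id) {
    chars <- strsplit(row, "")[[1]]
    if (chars[col] == "-") return(tibble())
    d <- domains[domains$instance_id == id, ]
    tibble(instance_id = id, protein_accession = d$protein_accession,
           pos = d$start + sum(chars[seq_len(col)] != "-") - 1L)
  })
}

#' Simulate the mutation catalogue of a synthetic cohort
#'
#' Background mutations are scattered uniformly per residue at
#' class-specific rates modulated by gene-class weights; planted enriched
#' families get a class rate multiplier; planted hotspots redirect an
#' `excess` fraction of the family's class mutations (on eligible hosts)
#' to the residue aligned to one chosen alignment column. Change strings
#' are emitted in the catalogue grammar with reference residues taken
#' from the simulated proteome. Call after [simulate_proteome()] in the
#' same seeded RNG stream.
#'
#' @param spec A [simulation_spec()].
#' @param prot Output of [simulate_proteome()].
#' @return List with `mutations` (tibble: `sample_id`,
#'   `protein_accession`, `change`, `cancer_type`) and `truth` (planted
#'   hotspot keys with chosen columns, planted enriched families, gene
#'   classes).
#' @export
simulate_mutations <- function(spec, prot) {
  domains <- prot$domains
  labels <- prot$labels
  gene_class <- setNames(labels$class, labels$gene)

  # planted hotspot columns: honour an explicit `msa_column` when the
  # spec provides one, otherwise pick the most covered eligible column
  # in the middle half of the alignment
  hs <- spec$hotspots
  if (!"msa_column" %in% names(hs)) hs$msa_column <- NA_integer_
  hs_res <- vector("list", nrow(hs))
  eligible_cover <- function(msa, col, cls) {
    res <- column_residues(msa, domains, col)
    if (nrow(res) == 0) return(0L)
    if (!is.na(cls)) {
      sum(gene_class[res$protein_accession] == cls)
    } else nrow(res)
  }
  for (i in seq_len(nrow(hs))) {
    msa <- prot$msas[[hs$family_id[i]]]
    L <- msa_ncol(msa)
    cls <- hs$gene_class[i]
    if (!is.na(hs$msa_column[i])) {
      col <- hs$msa_column[i]
      if (col < 1 || col > L) {
        abort(paste0("planted column ", col, " outside the ",
                     hs$family_id[i], " alignment (L = ", L, ")"))
      }
      if (eligible_cover(msa, col, cls) == 0) {
        abort(paste0("planted column ", col, " in ", hs$family_id[i],
                     " is gapped in every eligible instance"))
      }
    } else {
      cand <- seq(max(1, floor(L / 4)), ceiling(3 * L / 4))
      cover <- vapply(cand, eligible_cover, 1L, msa = msa, cls = cls)
      if (all(cover == 0)) {
        abort(paste0("planted column candidates all gapped/ineligible",
                     " in ", hs$family_id[i]))
      }
      col <- cand[which.max(cover)]
      hs$msa_column[i] <- col
    }
    hs_res[[i]] <- column_residues(msa, domains, col)
  }

  # per-segment mutation rates: domain instances plus linker intervals
  segs <- domains %>%
    select("protein_accession", "family_id", "start", "end")
  linkers <- domains %>%
    group_by(.data$protein_accession) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(bounds = list(c(0L, rbind(.data$start, .data$end),
                              NA_integer_)), .groups = "drop")
  linker_rows <- purrr::map2_dfr(linkers$protein_accession,
                                 linkers$bounds, function(acc, b) {
    plen <- prot$proteome$length[prot$proteome$accession == acc]
    b[length(b)] <- plen + 1L
    # b = [0, s1, e1, s2, e2, ..., plen+1]; linkers are the gaps
    # [e_{i}+1, s_{i+1}-1] including the protein's flanks
    starts <- b[seq(1, length(b) - 1, by = 2)] + 1L  # 0+1, e1+1, e2+1, ...
    stops <- b[seq(2, length(b), by = 2)] - 1L       # s1-1, ..., plen
    keep <- starts <= stops
    tibble(protein_accession = acc, family_id = NA_character_,
           start = starts[keep], end = stops[keep])
  })
  no_dom <- setdiff(prot$proteome$accession, domains$protein_accession)
  if (length(no_dom) > 0) {
    linker_rows <- bind_rows(linker_rows, tibble(
      protein_accession = no_dom, family_id = NA_character_, start = 1L,
      end = prot$proteome$length[match(no_dom, prot$proteome$accession)]))
  }
  segs <- bind_rows(segs, linker_rows) %>%
    mutate(len = .data$end - .data$start + 1L,
           gclass = unname(gene_class[.data$protein_accession]))

  mult <- bind_rows(
    select(hs, "family_id", "mclass", "multiplier"),
    select(spec$enriched, "family_id", "mclass", "multiplier")) %>%
    group_by(.data$family_id, .data$mclass) %>%
    summarise(multiplier = prod(.data$multiplier), .groups = "drop")

  grid <- tidyr::expand_grid(seg = seq_len(nrow(segs)),
                             mclass = MUTATION_CLASSES) %>%
    mutate(family_id = segs$family_id[.data$seg],
           len = segs$len[.data$seg],
           gclass = segs$gclass[.data$seg]) %>%
    left_join(mult, by = c("family_id", "mclass")) %>%
    mutate(multiplier = dplyr::coalesce(.data$multiplier, 1),
           wclass = purrr::map2_dbl(.data$gclass, .data$mclass,
                                    function(g, m) {
                                      spec$class_weights[[g]][[m]]
                                    }),
           rate = spec$base_rates[.data$mclass] * .data$wclass *
             .data$multiplier,
           lambda = .data$len * spec$n_samples * .data$rate,
           count = rpois(dplyr::n(), .data$lambda))

  events <- grid %>%
    filter(.data$count > 0) %>%
    mutate(draw = purrr::map2(.data$seg, .data$count, function(s, k) {
      segs$start[s] - 1L + sample.int(segs$len[s], k, replace = TRUE)
    })) %>%
    select("seg", "mclass", "family_id", "draw") %>%
    tidyr::unnest("draw") %>%
    mutate(protein_accession = segs$protein_accession[.data$seg],
           position = .data$draw) %>%
    select("protein_accession", "family_id", "mclass", "position")

  # hotspot redirection
  for (i in seq_len(nrow(hs))) {
    res <- hs_res[[i]]
    cls <- hs$gene_class[i]
    if (!is.na(cls)) {
      res <- res[gene_class[res$protein_accession] == cls, ]
    }
    eligible <- !is.na(events$family_id) &
      events$family_id == hs$family_id[i] &
      events$mclass == hs$mclass[i] &
      events$protein_accession %in% res$protein_accession
    hit <- eligible & runif(nrow(events)) < hs$excess[i]
    if (any(hit)) {
      j <- sample.int(nrow(res), sum(hit), replace = TRUE)
      events$protein_accession[hit] <- res$protein_accession[j]
      events$position[hit] <- res$pos[j]
    }
  }

  n <- nrow(events)
  seqs <- setNames(prot$proteome$sequence, prot$proteome$accession)
  ref <- substr(seqs[events$protein_accession], events$position,
                events$position)
  events$change <- make_change_string(events$mclass, events$position, ref,
                                      seqs[events$protein_accession])
  if (spec$stale_ref_fraction > 0) {
    stale <- runif(n) < spec$stale_ref_fraction
    wrong <- vapply(ref[stale], function(a) {
      sample(setdiff(AA_STANDARD, a), 1)
    }, "")
    events$change[stale] <- paste0(
      wrong, substring(events$change[stale], 2))
  }
  mutations <- tibble(
    sample_id = sprintf("S%04d", sample.int(spec$n_samples, n,
                                            replace = TRUE)),
    protein_accession = events$protein_accession,
    change = events$change,
    true_class = events$mclass,
    cancer_type = sample(c("breast", "lung", "colorectal", "melanoma",
                           "ovarian"), n, replace = TRUE)) %>%
    arrange(.data$sample_id, .data$protein_accession, .data$change)
  true_class <- mutations$true_class
  mutations$true_class <- NULL

  truth <- list(
    hotspots = hs %>%
      mutate(dataset = ifelse(is.na(.data$gene_class), "genome",
                              .data$gene_class)) %>%
      select("family_id", "msa_column", "mclass", "dataset", "excess",
             "multiplier"),
    enriched = spec$enriched,
    gene_classes = labels,
    true_class = true_class)
  list(mutations = mutations, truth = truth)
}

#' Emit protein-change strings in the catalogue grammar
#'
#' Internal grammar shared with [parse_protein_change()]: missense
#' `"XnY"`, nonsense `"Xn*"`, frameshift `"Xnfs*m"`, in-frame deletions
#' `"Xn_YmdelSEQ"`/`"Xndel"`, insertions `"XninsSEQ"` and
#' `"XndelinsSEQ"`.
#'
#' @param mclass Vector of mutation classes.
#' @param position Integer positions.
#' @param ref Reference residues at `position`.
#' @param seq Full protein sequences (for multi-residue deletions);
#'   a single string is recycled across all records.
#' @return Character vector of change strings.
#' @export
make_change_string <- function(mclass, position, ref, seq) {
  n <- length(mclass)
  seq_at <- if (length(seq) == 1) function(i) seq else function(i) seq[i]
  out <- character(n)
  other_aa <- function(a) {
    vapply(a, function(x) sample(setdiff(AA_STANDARD, x), 1), "")
  }
  mis <- mclass == "missense"
  out[mis] <- paste0(ref[mis], position[mis], other_aa(ref[mis]))
  tru <- which(mclass == "truncation")
  if (length(tru) > 0) {
    nonsense <- runif(length(tru)) < 0.5
    fs_tail <- ifelse(runif(length(tru)) < 0.7,
                      paste0("*", sample(1:40, length(tru),
                                         replace = TRUE)), "")
    out[tru] <- ifelse(nonsense,
                       paste0(ref[tru], position[tru], "*"),
                       paste0(ref[tru], position[tru], "fs", fs_tail))
  }
  ind <- which(mclass == "indel")
  for (i in ind) {
    kind <- sample(c("del1", "delrange", "ins", "delins"), 1)
    p <- position[i]
    if (kind == "delrange") {
      dlen <- sample(2:3, 1)
      if (p + dlen - 1 > nchar(seq_at(i))) kind <- "del1"
    }
    out[i] <- switch(kind,
      del1 = paste0(ref[i], p, "del"),
      delrange = {
        q <- p + dlen - 1
        paste0(ref[i], p, "_", substr(seq_at(i), q, q), q, "del",
               substr(seq_at(i), p, q))
      },
      ins = paste0(ref[i], p, "ins",
                   paste(sample(AA_STANDARD, sample(1:3, 1),
                                replace = TRUE), collapse = "")),
      delins = paste0(ref[i], p, "delins",
                      paste(sample(AA_STANDARD, sample(1:3, 1),
                                   replace = TRUE), collapse = "")))
  }
  out
}

#' Simulate a complete synthetic dataset
#'
#' Seeds the RNG from the spec, generates the proteome and mutation
#' catalogue, and optionally writes the five standard input files plus
#' the machine-readable ground truth: `proteome.fasta`, `domains.tsv`,
#' `mutations.tsv`, `gene_labels.tsv`, `msas.sto` (all true family
#' alignments, multi-alignment Stockholm) and `truth.json`. Identical
#' spec (including seed) gives byte-identical outputs.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory, or `NULL` to skip writing.
#' @return List with `proteome`, `domains`, `labels`, `msas`,
#'   `mutations`, `truth` (invisibly when writing).
#' @export
simulate_dataset <- function(spec = simulation_spec(), dir = NULL) {
  set.seed(spec$seed)
  prot <- simulate_proteome(spec)
  mut <- simulate_mutations(spec, prot)
  out <- list(proteome = prot$proteome, domains = prot$domains,
              labels = prot$labels, msas = prot$msas,
              mutations = mut$mutations, truth = mut$truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(paste0(">", out$proteome$accession, "\n",
                      out$proteome$sequence),
               file.path(dir, "proteome.fasta"))
    readr::write_tsv(select(out$domains, -"instance_id"),
                     file.path(dir, "domains.tsv"), progress = FALSE)
    readr::write_tsv(out$mutations, file.path(dir, "mutations.tsv"),
                     progress = FALSE)
    readr::write_tsv(out$labels, file.path(dir, "gene_labels.tsv"),
                     progress = FALSE)
    write_msa_collection(out$msas, file.path(dir, "msas.sto"))
    jsonlite::write_json(
      list(hotspots = out$truth$hotspots,
           enriched = out$truth$enriched,
           gene_classes = out$truth$gene_classes),
      file.path(dir, "truth.json"), digits = NA)
    return(invisible(out))
  }
  out
}
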