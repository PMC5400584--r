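#' Run the complete analysis pipeline on a synthetic cohort
#'
#' Simulates a dataset from `spec`, writes the five input files, reads
#' them back through the validating readers, then runs every analysis
#' stage: mutation classification and reference validation, domain and
#' alignment-column mapping, domain enrichment (background-set and
#' genome-wide modes), hotspot detection over the tumour-suppressor,
#' oncogene and whole-genome runs, overlap and co-location comparisons,
#' and gene classification (20:20 rule plus cross-validated
#' domain-composition classifier). All result tables are written as TSV
#' under `out_dir`; outputs are byte-identical across runs with the same
#' spec and seed.
#'
#' @param spec A [simulation_spec()].
#' @param out_dir Output directory (created if needed).
#' @param alpha Significance level for both tests.
#' @param min_count Minimum per-column count for a recorded hotspot.
#' @param correction Bonferroni scope for hotspots ([detect_hotspots()]).
#' @param seed Overrides `spec$seed` when given.
#' @return Invisibly, a list with every intermediate and final object.
#' @export
run_all <- function(spec = simulation_spec(), out_dir = tempfile("run"),
                    alpha = 0.05, min_count = 2, correction = "global",
                    seed = NULL) {
  if (!is.null(seed)) spec$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  in_dir <- file.path(out_dir, "inputs")
  simulate_dataset(spec, dir = in_dir)

  proteome <- read_proteome(file.path(in_dir, "proteome.fasta"))
  domains <- read_domain_table(file.path(in_dir, "domains.tsv"), proteome)
  mutations <- read_mutations(file.path(in_dir, "mutations.tsv"), proteome)
  labels <- read_gene_labels(file.path(in_dir, "gene_labels.tsv"))
  msas <- read_msa_collection(file.path(in_dir, "msas.sto"))

  classified <- classify_mutations(mutations)
  classified <- check_reference_residues(classified, proteome)
  mapped <- map_to_domains(classified, domains)
  mapped <- map_to_msa_columns(mapped, msas)
  msum <- mapping_summary(classified, mapped)
  write_results(select(mapped, "sample_id", "protein_accession",
                       "change", "mclass", "position", "family_id",
                       "instance_id", "local_pos", "msa_column"),
                file.path(out_dir, "mapped_mutations.tsv"))
  write_results(msum, file.path(out_dir, "unmapped_counts.tsv"))

  bg_fams <- unique(domains$family_id[startsWith(domains$family_id, "BG")])
  enr_bg <- enrich_domains(mapped, domains, spec$n_samples,
                           background_families = bg_fams, alpha = alpha)
  enr_gw <- enrich_domains(mapped, domains, spec$n_samples, alpha = alpha)
  for (cls in MUTATION_CLASSES) {
    write_results(filter(tidy(enr_bg), .data$mclass == cls),
                  file.path(out_dir,
                            paste0("enrichment_background_", cls, ".tsv")))
    write_results(filter(tidy(enr_gw), .data$mclass == cls),
                  file.path(out_dir,
                            paste0("enrichment_genomewide_", cls, ".tsv")))
  }

  msa_lengths <- vapply(msas, msa_ncol, 1L)
  scan <- run_hotspot_analysis(mapped, msa_lengths, labels,
                               alpha = alpha, min_count = min_count,
                               correction = correction)
  for (ds in c("TS", "OG", "genome")) {
    for (cls in MUTATION_CLASSES) {
      write_results(
        filter(scan$results, .data$dataset == ds, .data$mclass == cls),
        file.path(out_dir, paste0("hotspots_", ds, "_", cls, ".tsv")))
    }
  }
  write_results(scan$summary, file.path(out_dir, "hotspot_summary.tsv"))

  overlaps <- list()
  for (cls in MUTATION_CLASSES) {
    for (lvl in c("family", "position")) {
      ov <- overlap_sets(significant_hotspots(scan, "TS", cls),
                         significant_hotspots(scan, "OG", cls),
                         significant_hotspots(scan, "genome", cls),
                         level = lvl)
      overlaps[[paste(cls, lvl, sep = "_")]] <- ov
      write_results(ov, file.path(out_dir,
                                  paste0("overlap_", cls, "_", lvl,
                                         ".tsv")))
    }
  }
  coloc <- bind_rows(lapply(MUTATION_CLASSES, function(cls) {
    colocated_candidates(significant_hotspots(scan, "genome", cls),
                         significant_hotspots(scan, "TS", cls),
                         significant_hotspots(scan, "OG", cls), labels)
  }))
  write_results(coloc, file.path(out_dir, "colocated_candidates.tsv"))

  profiles <- gene_mutation_profiles(classified)
  rule <- twenty_twenty(profiles)
  write_results(rule, file.path(out_dir, "twenty_twenty.tsv"))

  labelled <- labels$gene[labels$class %in% c("TS", "OG")]
  features <- build_feature_matrix(domains, labelled)
  cv <- cross_validate(features, labels, seed = spec$seed)
  write_results(glance(cv), file.path(out_dir, "classifier_report.tsv"))
  scorer <- train_scorer(features, labels)
  scores <- score_unlabelled(
    scorer, build_feature_matrix(domains, labelled) %>%
      dplyr::slice(match(labelled, .data$gene)))
  write_results(bind_rows(
    mutate(tidy(cv), type = "cv_heldout"),
    mutate(select(scores, "gene", score = "score"), type = "full_model",
           label = NA_character_, fold = NA_integer_)),
    file.path(out_dir, "gene_scores.tsv"))

  invisible(list(spec = spec, out_dir = out_dir, proteome = proteome,
                 domains = domains, mutations = mutations,
                 labels = labels, msas = msas, classified = classified,
                 mapped = mapped, mapping = msum,
                 enrichment_background = enr_bg,
                 enrichment_genomewide = enr_gw, hotspots = scan,
                 overlaps = overlaps, colocated = coloc,
                 twenty_twenty = rule, cv = cv, scores = scores,
                 truth = jsonlite::read_json(
                   file.path(in_dir, "truth.json"),
                   simplifyVector = TRUE)))
}
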