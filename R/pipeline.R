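#' Write the paper-shaped master fixture
#'
#' Generates and writes a complete, internally consistent synthetic study to
#' \code{dir}: five species (three marine, two freshwater) with 19 shared
#' toxin families out of an 80-family union, a high-content screen with 31
#' informative parameters, three venom samples in two phenotype blocks with
#' 120 co-clustering reference compounds plus 10 noise compounds, and a
#' pathway map with a 216-pathway union, 29 shared pathways over 15 target
#' systems, 70 core transcripts, 70 core compounds and a pain block of 9
#' pathways / 20 transcripts / 41 compounds (plus a smaller cardiovascular
#' block). All planted truths are recorded in \code{manifest.json}.
#'
#' Files written: \code{hits_<species>.tsv}, \code{expression_<species>.tsv},
#' \code{subject_metadata.tsv}, \code{wells.tsv}, \code{pathway_map.tsv},
#' \code{symptoms.tsv}, \code{config.yaml}, \code{manifest.json}.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving all random draws.
#' @return Invisibly, the manifest list.
#' @export
simulate_master_fixture <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  species_groups <- c(sp01 = "marine", sp02 = "marine", sp03 = "marine",
                      sp04 = "freshwater", sp05 = "freshwater")

  ann <- simulate_annotation_dataset(n_species = 5, n_shared_families = 19,
                                     n_exclusive_families = 12,
                                     hits_per_shared = 3,
                                     hits_per_exclusive = 2,
                                     n_peptide_subjects = 5,
                                     species_groups = species_groups,
                                     seed = seed)

  venom_samples <- c("venom_sp01", "venom_sp02", "venom_sp04")
  hcs <- simulate_well_data(n_compounds = 130, n_venoms = 3,
                            n_parameters = 40, seed = seed + 1L,
                            n_informative = 31,
                            compounds_per_block = c(60, 60),
                            venom_blocks = list(1:2, 3),
                            venom_ids = venom_samples)

  # core entities for the pathway map: a planted subset of the retained
  # best-hit subjects (15 shared-family + 11 exclusive per species = 70) and
  # 70 of the 120 co-clustering compounds (the pain block must fit inside)
  set.seed(seed + 2L)
  shared_subj <- metadata_subjects(ann$metadata, "^TS\\d+\\.\\d+$")
  core_shared <- sort(sample(shared_subj, 15))
  core_excl <- unlist(lapply(ann$manifest$species, function(sp)
    sort(sample(metadata_subjects(ann$metadata,
                                  sprintf("^TX_%s_", sp)), 11))),
    use.names = FALSE)
  core_transcripts <- sort(c(core_shared, core_excl))
  block_refs <- sort(hcs$manifest$expected_cocluster_union)
  core_compounds <- sort(sample(block_refs, 70))

  pmap <- simulate_pathway_map(
    transcript_ids = core_transcripts, compound_ids = core_compounds,
    n_shared = 29, n_transcript_only = 91, n_compound_only = 96,
    symptom_blocks = list(
      pain = c(pathways = 9, transcripts = 20, compounds = 41),
      cardiovascular = c(pathways = 6, transcripts = 12, compounds = 15)),
    seed = seed + 3L)

  for (sp in ann$manifest$species) {
    write_hit_table(ann$hits[[sp]],
                    file.path(dir, sprintf("hits_%s.tsv", sp)))
    write_tsv(ann$expression[[sp]],
              file.path(dir, sprintf("expression_%s.tsv", sp)))
  }
  write_tsv(ann$metadata, file.path(dir, "subject_metadata.tsv"))
  write_tsv(hcs$wells, file.path(dir, "wells.tsv"))
  write_tsv(pmap$map, file.path(dir, "pathway_map.tsv"))
  sym_df <- do.call(rbind, lapply(names(pmap$symptoms), function(s)
    data.frame(symptom = s, pathway_id = pmap$symptoms[[s]],
               stringsAsFactors = FALSE)))
  write_tsv(sym_df, file.path(dir, "symptoms.tsv"))

  cfg <- list(seed = seed,
              venom_samples = venom_samples,
              species_groups = as.list(species_groups))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))

  manifest <- list(seed = seed,
                   annotation = ann$manifest,
                   hcs = hcs$manifest,
                   pathways = pmap$manifest)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

metadata_subjects <- function(metadata, pattern) {
  sort(metadata$subject_id[grepl(pattern, metadata$subject_id)])
}

#' Write a hit table in the extended tabular dialect
#'
#' Serialises the internal hit representation back to a 13-column
#' outfmt-6-like TSV (\code{qcovs} dialect); dummy alignment coordinates are
#' filled in so the file is structurally complete.
#'
#' @param hits Hit data frame (\code{query_id}, \code{subject_id},
#'   \code{identity}, \code{coverage}, \code{bit_score}, \code{e_value}).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_hit_table <- function(hits, path) {
  n <- nrow(hits)
  df <- data.frame(qseqid = hits$query_id, sseqid = hits$subject_id,
                   pident = hits$identity, length = rep(100L, n),
                   mismatch = rep(0L, n), gapopen = rep(0L, n),
                   qstart = rep(1L, n), qend = rep(100L, n),
                   sstart = rep(1L, n), send = rep(100L, n),
                   evalue = hits$e_value, bitscore = hits$bit_score,
                   qcovs = hits$coverage, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Run the full integration pipeline on a fixture directory
#'
#' Executes every stage end to end: per-species hit filtering (identity /
#' coverage / bit score), TPM floor, best-hit resolution, family
#' relative-expression profiles, cross-species overlap and group contrast;
#' HCS profile construction, parameter reduction, complete-linkage
#' clustering under Spearman distance, threshold cut and reference
#' co-clustering; KEGG-style annotation of both entity sets, the
#' shared-pathway core, the tripartite network and symptom-cluster
#' extraction. All outputs are written to \code{out_dir}; the pipeline
#' itself draws no random numbers, so identical inputs give byte-identical
#' outputs.
#'
#' @param input_dir Directory holding the input files (the layout written by
#'   \code{\link{simulate_master_fixture}}).
#' @param out_dir Output directory (created if needed).
#' @param config Configuration list; defaults to \code{config.yaml} in
#'   \code{input_dir} if present, else \code{\link{default_config}}.
#' @return Invisibly, the summary list (also written as
#'   \code{summary.json}).
#' @export
run_pipeline <- function(input_dir, out_dir, config = NULL) {
  if (is.null(config)) {
    cfg_path <- file.path(input_dir, "config.yaml")
    config <- if (file.exists(cfg_path)) read_config(cfg_path)
              else default_config()
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- annotation stage -----------------------------------------------------
  hit_files <- sort(list.files(input_dir, "^hits_.*\\.tsv$"))
  species <- sub("^hits_(.*)\\.tsv$", "\\1", hit_files)
  meta <- read_subject_metadata(file.path(input_dir, "subject_metadata.tsv"))
  profiles_by_sp <- list()
  retained <- list()
  ann_counts <- list()
  for (sp in species) {
    hits <- read_hit_table(file.path(input_dir, sprintf("hits_%s.tsv", sp)))
    expr <- read_expression_table(file.path(input_dir,
                                            sprintf("expression_%s.tsv", sp)))
    f1 <- filter_hits(hits, config$identity, config$coverage, config$bit_score)
    f2 <- apply_tpm_floor(f1, expr, config$min_tpm)
    f3 <- select_best_hits(f2, scope = config$best_hit_scope)
    f3 <- join_subject_metadata(f3, meta)
    retained[[sp]] <- f3
    profiles_by_sp[[sp]] <- family_relative_expression(f3)
    ann_counts[[sp]] <- list(
      n_raw = nrow(hits), n_after_filter = nrow(f1),
      n_after_tpm = nrow(f2), n_survivors = nrow(f3),
      n_families = nrow(profiles_by_sp[[sp]]),
      peptide_fraction = peptide_fraction(f3))
  }
  fam_tab <- do.call(rbind, lapply(species, function(sp)
    cbind(species = sp, profiles_by_sp[[sp]], stringsAsFactors = FALSE)))
  write_tsv(fam_tab, file.path(out_dir, "family_profiles.tsv"))

  ovl <- overlap_report(profiles_by_sp)
  jsonlite::write_json(list(
    region_counts = as.list(ovl$region_counts),
    shared_families = ovl$shared_families,
    n_union = length(ovl$union_families),
    fraction_shared = ovl$fraction_shared,
    hit_share_shared = as.list(ovl$hit_share_shared)),
    file.path(out_dir, "overlap.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  contrast <- NULL
  if (!is.null(config$species_groups)) {
    groups <- unlist(config$species_groups)
    contrast <- group_contrast(profiles_by_sp, groups)
    write_tsv(contrast, file.path(out_dir, "contrast.tsv"))
  }

  # --- HCS stage ------------------------------------------------------------
  wells <- read_well_measurements(file.path(input_dir, "wells.tsv"))
  prof <- build_profiles(wells, min_objects = config$min_objects)
  red <- reduce_parameters(prof, z_min = config$z_min,
                           rho_max = config$rho_max,
                           variance_floor = config$variance_floor,
                           target_count = config$target_count)
  write_profiles_csv(red, file.path(out_dir, "profiles.csv"))
  D <- profile_distance_matrix(red, scale = config$distance_scale)
  tree <- complete_linkage(D)
  write_tsv(data.frame(step = seq_along(tree$height),
                       left = tree$merge[, 1L], right = tree$merge[, 2L],
                       height = tree$height),
            file.path(out_dir, "merges.tsv"))
  write_dendrogram_newick(tree, file.path(out_dir, "dendrogram.nwk"))

  venoms <- intersect(config$venom_samples, rownames(red))
  refs <- setdiff(rownames(red), venoms)
  co <- if (config$cocluster_mode == "pairwise")
    coclustered_references_pairwise(D, venoms, refs, cut = config$cluster_cut)
  else
    coclustered_references(cut_tree(tree, config$cluster_cut), venoms, refs)
  jsonlite::write_json(list(references = co$references,
                            by_venom = co$by_venom),
                       file.path(out_dir, "coclusters.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- integration stage ----------------------------------------------------
  pmap <- read_pathway_map(file.path(input_dir, "pathway_map.tsv"))
  t_entities <- sort(unique(unlist(lapply(retained, function(h) h$subject_id))))
  t_annot <- annotate_entities(t_entities, "transcript_hit", pmap)
  t_cov_sp <- vapply(species, function(sp)
    annotate_entities(unique(retained[[sp]]$subject_id), "transcript_hit",
                      pmap)$coverage, numeric(1))
  c_annot <- annotate_entities(co$references, "compound", pmap)
  core <- shared_core(t_annot, c_annot, pmap)
  net <- build_network(core, pmap)
  write_network_graphml(net, file.path(out_dir, "network.graphml"))

  symptoms <- read_symptom_lists(file.path(input_dir, "symptoms.tsv"))
  clusters <- list()
  for (s in sort(names(symptoms))) {
    clusters[[s]] <- extract_symptom_cluster(net, s, symptoms[[s]])
    write_network_graphml(clusters[[s]]$subnetwork,
                          file.path(out_dir, sprintf("symptom_%s.graphml", s)))
  }

  summary <- summarize_run(
    species = species, annotation = ann_counts, overlap = ovl,
    profiles = red, tree = tree, cocluster = co,
    transcript_annotation = t_annot, transcript_coverage_by_species = t_cov_sp,
    compound_annotation = c_annot, core = core, network = net,
    symptom_clusters = clusters,
    path = file.path(out_dir, "summary.json"))
  invisible(summary)
}

#' Assemble and write the per-stage run summary
#'
#' Collects the counts every stage produced into one nested list and
#' optionally writes it as JSON (keys in deterministic order).
#'
#' @param species Character vector of species ids.
#' @param annotation Per-species list of filter-cascade counts.
#' @param overlap An \code{overlap_report}.
#' @param profiles Reduced profile matrix.
#' @param tree A \code{cluster_tree}.
#' @param cocluster A \code{cocluster_result}.
#' @param transcript_annotation,compound_annotation
#'   \code{pathway_annotation} objects.
#' @param transcript_coverage_by_species Named numeric vector.
#' @param core A \code{shared_core}.
#' @param network The integrated \code{igraph} network.
#' @param symptom_clusters Named list of \code{symptom_cluster} objects.
#' @param path Optional JSON output path.
#' @return The summary list.
#' @export
summarize_run <- function(species, annotation, overlap, profiles, tree,
                          cocluster, transcript_annotation,
                          transcript_coverage_by_species,
                          compound_annotation, core, network,
                          symptom_clusters, path = NULL) {
  out <- list(
    species = species,
    annotation = annotation[species],
    overlap = list(
      n_union_families = length(overlap$union_families),
      n_shared_families = length(overlap$shared_families),
      fraction_shared = overlap$fraction_shared,
      hit_share_shared = as.list(overlap$hit_share_shared)),
    hcs = list(
      n_samples = nrow(profiles),
      n_informative_parameters = ncol(profiles),
      n_merges = length(tree$height),
      n_coclustered_references = length(cocluster$references),
      coclustered_by_venom = lapply(cocluster$by_venom, length)),
    integration = list(
      transcript_coverage = transcript_annotation$coverage,
      transcript_coverage_by_species =
        as.list(transcript_coverage_by_species),
      transcript_coverage_mean =
        mean(unlist(transcript_coverage_by_species)),
      compound_coverage = compound_annotation$coverage,
      n_union_pathways = length(core$union),
      n_shared_pathways = length(core$shared),
      n_target_systems = length(core$systems),
      n_core_transcripts = length(core$transcripts),
      n_core_compounds = length(core$compounds),
      n_network_nodes = igraph::vcount(network),
      n_network_edges = igraph::ecount(network)),
    symptoms = lapply(symptom_clusters, function(sc) as.list(sc$counts)))
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  out
}
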