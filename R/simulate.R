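#' Simulate annotation inputs with planted ground truth
#'
#' Generates, per species, a similarity-search hit table, an expression
#' table and shared subject metadata emulating the structure of a
#' multi-species venom-gland annotation study: a core of toxin families
#' present in every species, species-exclusive families, optionally a block
#' of group-restricted families (for example marine-only), fragment and
#' no-family subjects, short peptide subjects, and decoy hits straddling
#' every filter threshold (identity 39.9 / coverage 39.9 / bit score 29.9 /
#' TPM 0.49, plus an all-boundary row at exactly 40/40/30/0.5 that survives
#' filtering but loses best-hit resolution).
#'
#' The returned manifest records the expected outcome of the default filter
#' cascade (survivor counts, family means, overlap and peptide fractions) so
#' pipeline output can be checked against the construction.
#'
#' @param n_species Number of species (>= 2).
#' @param n_shared_families Families present in every species.
#' @param n_exclusive_families Families exclusive to each species.
#' @param hits_per_shared,hits_per_exclusive Retained hits (= subjects) per
#'   family of each type.
#' @param n_peptide_subjects Shared-family subjects shorter than 50 aa.
#' @param species_groups Optional named vector species -> group; when given,
#'   one extra family is planted in every species of the first group only.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return List with \code{hits} (named list of hit tables),
#'   \code{expression} (named list), \code{metadata} (one data frame) and
#'   \code{manifest}.
#' @export
simulate_annotation_dataset <- function(n_species = 5,
                                        n_shared_families = 19,
                                        n_exclusive_families = 12,
                                        hits_per_shared = 3,
                                        hits_per_exclusive = 2,
                                        n_peptide_subjects = 5,
                                        species_groups = NULL,
                                        seed = 1L) {
  stopifnot(n_species >= 2, n_shared_families >= 1, n_exclusive_families >= 0,
            hits_per_shared >= 1, hits_per_exclusive >= 1)
  set.seed(seed)
  species <- sprintf("sp%02d", seq_len(n_species))
  if (!is.null(species_groups)) {
    stopifnot(all(species %in% names(species_groups)))
    g1 <- species_groups[[species[1L]]]
    group1_species <- species[species_groups[species] == g1]
  } else {
    group1_species <- character(0)
  }

  shared_fams <- sprintf("toxfam_shared_%02d", seq_len(n_shared_families))
  group_fam <- if (length(group1_species) >= 2L) "toxfam_groupA_01" else NULL

  # --- subject metadata -----------------------------------------------------
  meta <- list()
  fam_subjects <- list()
  for (f in seq_along(shared_fams)) {
    subj <- sprintf("TS%02d.%d", f, seq_len(hits_per_shared))
    fam_subjects[[shared_fams[f]]] <- subj
  }
  excl_fams <- list()
  for (sp in species) {
    fams <- sprintf("toxfam_%s_%02d", sp, seq_len(n_exclusive_families))
    excl_fams[[sp]] <- fams
    for (f in seq_along(fams))
      fam_subjects[[fams[f]]] <- sprintf("TX_%s_%02d.%d", sp, f,
                                         seq_len(hits_per_exclusive))
  }
  if (!is.null(group_fam))
    fam_subjects[[group_fam]] <- sprintf("TG01.%d", seq_len(hits_per_exclusive))
  nofam_subjects <- stats::setNames(sprintf("TNF_%s", species), species)

  all_subjects <- c(unlist(fam_subjects, use.names = FALSE),
                    unname(nofam_subjects))
  fam_of <- stats::setNames(rep(names(fam_subjects), lengths(fam_subjects)),
                            unlist(fam_subjects, use.names = FALSE))
  fam_col <- ifelse(all_subjects %in% names(fam_of),
                    fam_of[all_subjects], "")

  # peptide subjects: first subject of the first n_peptide_subjects shared
  # families; everything else is full length
  pep_subjects <- sprintf("TS%02d.1",
                          seq_len(min(n_peptide_subjects, n_shared_families)))
  length_aa <- ifelse(all_subjects %in% pep_subjects,
                      sample(20:49, length(all_subjects), replace = TRUE),
                      sample(60:800, length(all_subjects), replace = TRUE))
  # fragments: the first subject of each species' first two exclusive families
  frag_subjects <- unlist(lapply(species, function(sp)
    sprintf("TX_%s_%02d.1", sp, seq_len(min(2L, n_exclusive_families)))),
    use.names = FALSE)
  metadata <- data.frame(subject_id = all_subjects,
                         family = unname(fam_col),
                         length_aa = as.integer(length_aa),
                         is_fragment = all_subjects %in% frag_subjects,
                         stringsAsFactors = FALSE)

  # --- per-species hit and expression tables --------------------------------
  hits <- list(); expression <- list()
  manifest_species <- list()
  for (sp in species) {
    sp_fams <- c(shared_fams, excl_fams[[sp]],
                 if (!is.null(group_fam) && sp %in% group1_species) group_fam)
    members <- unlist(fam_subjects[sp_fams], use.names = FALSE)
    members <- c(members, nofam_subjects[[sp]])
    n <- length(members)
    q <- sprintf("%s_t%05d", sp, seq_len(n))
    main <- data.frame(
      query_id = q, subject_id = members,
      identity = round(stats::runif(n, 55, 95), 1),
      coverage = round(stats::runif(n, 50, 98), 1),
      bit_score = round(stats::runif(n, 60, 400), 1),
      e_value = signif(10^stats::runif(n, -50, -10), 3),
      stringsAsFactors = FALSE)
    tpm_main <- round(0.5 + stats::rlnorm(n, meanlog = 1.5, sdlog = 0.8), 4)

    qx <- sprintf("%s_tx%02d", sp, 1:6)
    decoys <- data.frame(
      query_id = qx,
      subject_id = c(members[1:4], members[1L], members[2L]),
      identity = c(39.9, 80, 80, 70, 40, main$identity[2L]),
      coverage = c(80, 39.9, 80, 70, 40, main$coverage[2L]),
      bit_score = c(100, 100, 29.9, 100, 30, main$bit_score[2L]),
      e_value = c(1e-20, 1e-20, 1e-20, 1e-20, 1e-5,
                  signif(main$e_value[2L] * 10, 3)),
      stringsAsFactors = FALSE)
    tpm_decoy <- c(5, 5, 5, 0.49, 0.5, 2)

    hits[[sp]] <- rbind(main, decoys)
    expression[[sp]] <- data.frame(transcript_id = c(q, qx),
                                   tpm = c(tpm_main, tpm_decoy),
                                   stringsAsFactors = FALSE)

    fam_member <- fam_of[members[seq_len(n - 1L)]]
    fam_mean <- tapply(tpm_main[seq_len(n - 1L)], fam_member, mean)
    non_frag <- !(members %in% frag_subjects)
    manifest_species[[sp]] <- list(
      n_raw = nrow(hits[[sp]]),
      n_after_filter = n + 3L,      # main + low-TPM decoy + boundary + tie row
      n_after_tpm = n + 2L,         # the TPM 0.49 decoy falls to the floor
      n_survivors = n,
      families = sort(unique(unname(fam_member))),
      family_means = as.list(round(fam_mean[sort(names(fam_mean))], 4)),
      hit_share_shared = sum(fam_member %in% shared_fams) /
        length(fam_member),
      peptide_fraction = sum(members %in% pep_subjects & non_frag) /
        sum(non_frag))
  }

  union_fams <- sort(unique(c(shared_fams,
                              unlist(excl_fams, use.names = FALSE),
                              group_fam)))
  manifest <- list(
    seed = seed,
    species = species,
    shared_families = shared_fams,
    group_family = group_fam,
    group1_species = group1_species,
    union_families = union_fams,
    fraction_shared = length(shared_fams) / length(union_fams),
    peptide_subjects = pep_subjects,
    fragment_subjects = frag_subjects,
    per_species = manifest_species)

  list(hits = hits, expression = expression, metadata = metadata,
       manifest = manifest)
}

#' Simulate HCS well data with planted co-cluster blocks
#'
#' Emulates a high-content screen: control wells, replicated treatment wells
#' for venom samples and reference compounds, informative parameters
#' carrying a planted block structure, and decoy parameters (one constant,
#' one duplicated, the rest unresponsive noise) that the reduction step must
#' remove.
#'
#' Each block (one or more venom samples plus its partner compounds) shares
#' a profile template built from a permutation of a fixed value grid;
#' replicate values are symmetric around the target so replicate medians are
#' exact. Templates are drawn under rejection until (a) every informative
#' parameter receives at least one strong response, so the z-floor cannot
#' drop it, and (b) all between-template Spearman correlations satisfy
#' \code{|rho| <= 0.25}, which puts every between-block profile distance at
#' \code{1 - rho >= 0.75}, safely above the 0.7 cut, while within-block
#' distances are exactly 0. Recovery of the planted blocks at the default
#' cut is therefore guaranteed by construction, not by chance.
#'
#' @param n_compounds Total reference compounds (block partners + noise).
#' @param n_venoms Number of venom samples.
#' @param n_parameters Total parameters (must exceed \code{n_informative}).
#' @param seed Integer seed.
#' @param n_informative Planted informative parameters.
#' @param compounds_per_block Partner compounds per block (scalar or vector,
#'   one entry per block).
#' @param venom_blocks Optional list of integer vectors grouping venoms into
#'   blocks (default: one block per venom).
#' @param venom_ids,compound_ids Optional explicit sample names.
#' @param n_replicates,n_control_wells Replication of treatment and control
#'   wells.
#' @return List with \code{wells} (long-format data frame) and
#'   \code{manifest} (planted blocks, expected co-clusters, informative and
#'   decoy parameter names).
#' @export
simulate_well_data <- function(n_compounds = 12, n_venoms = 3,
                               n_parameters = 40, seed = 1L,
                               n_informative = 20,
                               compounds_per_block = 3,
                               venom_blocks = NULL,
                               venom_ids = NULL, compound_ids = NULL,
                               n_replicates = 4, n_control_wells = 4) {
  stopifnot(n_parameters > n_informative, n_informative >= 5,
            n_venoms >= 1, n_replicates >= 2, n_control_wells >= 2)
  set.seed(seed)
  if (is.null(venom_blocks))
    venom_blocks <- as.list(seq_len(n_venoms))
  n_blocks <- length(venom_blocks)
  if (length(compounds_per_block) == 1L)
    compounds_per_block <- rep(compounds_per_block, n_blocks)
  stopifnot(length(compounds_per_block) == n_blocks,
            sum(compounds_per_block) <= n_compounds)

  venoms <- if (is.null(venom_ids)) sprintf("venom_%d", seq_len(n_venoms))
            else venom_ids
  refs <- if (is.null(compound_ids)) sprintf("ref_%03d", seq_len(n_compounds))
          else compound_ids
  stopifnot(length(venoms) == n_venoms, length(refs) == n_compounds)

  inf_params <- sprintf("feat_%02d", seq_len(n_informative))
  n_extra <- n_parameters - n_informative
  extra_params <- c("const_feat", "dup_feat",
                    sprintf("noise_feat_%02d",
                            seq_len(max(n_extra - 2L, 0L))))[seq_len(n_extra)]
  g <- seq(-4, 4, length.out = n_informative)

  # block membership ---------------------------------------------------------
  block_members <- list()
  idx <- 0L
  for (b in seq_len(n_blocks)) {
    part <- refs[idx + seq_len(compounds_per_block[b])]
    idx <- idx + compounds_per_block[b]
    block_members[[b]] <- c(venoms[venom_blocks[[b]]], part)
  }
  noise_refs <- refs[setdiff(seq_len(n_compounds), seq_len(idx))]
  samples <- c(venoms, refs)

  # template permutations under rejection ------------------------------------
  max_rho <- 0.25
  ok_pair <- function(p, prev) all(vapply(prev, function(q)
    abs(stats::cor(p, q)) <= max_rho, logical(1)))
  repeat {
    block_perms <- replicate(n_blocks, sample.int(n_informative),
                             simplify = FALSE)
    strong <- vapply(seq_len(n_informative), function(j)
      max(vapply(block_perms, function(p) abs(g[p[j]]), numeric(1))) >= 1,
      logical(1))
    pairs_ok <- TRUE
    if (n_blocks > 1L)
      for (b in 2:n_blocks)
        if (!ok_pair(block_perms[[b]], block_perms[seq_len(b - 1L)]))
          pairs_ok <- FALSE
    if (all(strong) && pairs_ok) break
  }
  noise_perms <- list()
  for (i in seq_along(noise_refs)) {
    repeat {
      p <- sample.int(n_informative)
      if (ok_pair(p, c(block_perms, noise_perms))) break
    }
    noise_perms[[i]] <- p
  }

  targets <- matrix(NA_real_, length(samples), n_informative,
                    dimnames = list(samples, inf_params))
  for (b in seq_len(n_blocks))
    for (s in block_members[[b]]) targets[s, ] <- g[block_perms[[b]]]
  for (i in seq_along(noise_refs))
    targets[noise_refs[i], ] <- g[noise_perms[[i]]]

  # Per-(sample, parameter) jitter bounded below half the grid spacing: it
  # never reorders a sample's own profile (so all planted sample-sample
  # Spearman distances are untouched) but it breaks the rank ties that
  # identical block members would otherwise create across parameters, which
  # would make informative parameters look mutually redundant.
  spacing <- g[2L] - g[1L]
  eps_bound <- min(0.05, spacing / 4)
  for (attempt in seq_len(20L)) {
    eps <- matrix(stats::runif(length(targets), -eps_bound, eps_bound),
                  nrow = nrow(targets))
    cand <- targets + eps
    rho_pp <- suppressWarnings(stats::cor(cand, method = "spearman"))
    if (max(abs(rho_pp[upper.tri(rho_pp)])) <= 0.93) break
    if (attempt == 20L)
      stop("failed to decorrelate informative parameters; ",
           "increase n_informative or reduce block count")
  }
  targets <- cand

  # decoy parameter targets
  extra_targets <- matrix(NA_real_, length(samples), length(extra_params),
                          dimnames = list(samples, extra_params))
  for (p in extra_params) {
    extra_targets[, p] <-
      if (p == "const_feat") 0.02
      else if (p == "dup_feat") targets[, 1L]
      else round(stats::runif(length(samples), -0.1, 0.1), 4)
  }
  all_targets <- cbind(targets, extra_targets)
  params <- colnames(all_targets)

  # long-format wells ---------------------------------------------------------
  offs <- seq(-0.002, 0.002, length.out = n_replicates)
  offs <- offs - mean(offs)
  cw <- seq(-0.15, 0.15, length.out = n_control_wells)
  trt <- expand.grid(sample_id = samples, replicate = seq_len(n_replicates),
                     parameter = params, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  trt$value <- all_targets[cbind(trt$sample_id, trt$parameter)] +
    offs[trt$replicate]
  trt$is_control <- FALSE
  ctl <- expand.grid(sample_id = sprintf("control_%d", seq_len(n_control_wells)),
                     replicate = seq_len(n_replicates),
                     parameter = params, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  ctl$value <- cw[as.integer(sub("control_", "", ctl$sample_id))]
  ctl$is_control <- TRUE
  wells <- rbind(trt, ctl)
  wells <- wells[order(match(wells$sample_id, c(samples, unique(ctl$sample_id))),
                       wells$replicate,
                       match(wells$parameter, params)), , drop = FALSE]
  rownames(wells) <- NULL
  wells$value <- round(wells$value, 6)

  expected_by_venom <- list()
  for (b in seq_len(n_blocks)) {
    part <- setdiff(block_members[[b]], venoms)
    for (v in intersect(block_members[[b]], venoms))
      expected_by_venom[[v]] <- sort(part)
  }
  manifest <- list(
    seed = seed,
    venoms = venoms, references = refs,
    informative_parameters = inf_params,
    decoy_parameters = extra_params,
    blocks = block_members,
    noise_references = noise_refs,
    expected_coclusters = expected_by_venom[sort(names(expected_by_venom))],
    expected_cocluster_union = sort(unique(unlist(expected_by_venom))))

  list(wells = wells, manifest = manifest)
}

#' Simulate an entity-to-pathway map with planted shared core and symptom
#' blocks
#'
#' Plants three pathway strata: pathways annotated only from transcripts,
#' only from compounds, and shared (annotated from both sides -- every
#' shared pathway is wired to at least one transcript and one compound, so
#' the intersection recovered by \code{\link{shared_core}} is exactly the
#' planted one). Within the shared stratum, disjoint symptom blocks are
#' wired to exactly the requested numbers of member transcripts and
#' compounds; entities outside a block never touch its pathways, so
#' symptom-cluster extraction recovers the planted counts exactly.
#'
#' @param transcript_ids,compound_ids Core entity ids (every one is wired to
#'   at least one shared pathway).
#' @param n_shared Number of shared pathways.
#' @param n_transcript_only,n_compound_only Pathways seen from one side only
#'   (union size = \code{n_shared + n_transcript_only + n_compound_only}).
#' @param symptom_blocks Named list; each element
#'   \code{c(pathways =, transcripts =, compounds =)}.
#' @param systems Character vector of target-system names.
#' @param seed Integer seed (controls entity shuffling).
#' @return List with \code{map} (pathway-map data frame), \code{symptoms}
#'   (named list of pathway ids) and \code{manifest}.
#' @export
simulate_pathway_map <- function(transcript_ids, compound_ids,
                                 n_shared = 29,
                                 n_transcript_only = 91,
                                 n_compound_only = 96,
                                 symptom_blocks = list(
                                   pain = c(pathways = 9, transcripts = 20,
                                            compounds = 41)),
                                 systems = default_systems(),
                                 seed = 1L) {
  set.seed(seed)
  nb_pw <- vapply(symptom_blocks, function(b) b[["pathways"]], numeric(1))
  nb_t <- vapply(symptom_blocks, function(b) b[["transcripts"]], numeric(1))
  nb_c <- vapply(symptom_blocks, function(b) b[["compounds"]], numeric(1))
  stopifnot(sum(nb_pw) <= n_shared,
            sum(nb_t) <= length(transcript_ids),
            sum(nb_c) <= length(compound_ids),
            all(nb_t >= nb_pw), all(nb_c >= nb_pw))

  shared_pw <- sprintf("pw_s%03d", seq_len(n_shared))
  t_only_pw <- sprintf("pw_t%03d", seq_len(n_transcript_only))
  c_only_pw <- sprintf("pw_c%03d", seq_len(n_compound_only))

  ts <- sample(transcript_ids)
  cs <- sample(compound_ids)

  # assign disjoint entity sets and pathway sets to symptom blocks
  blocks <- list(); ti <- 0L; ci <- 0L; pi <- 0L
  symptom_systems <- c("Signal transduction", "Nervous system",
                       "Sensory system")
  symptom_systems <- intersect(symptom_systems, systems)
  if (length(symptom_systems) == 0L) symptom_systems <- systems[1L]
  for (s in names(symptom_blocks)) {
    blocks[[s]] <- list(
      pathways = shared_pw[pi + seq_len(nb_pw[[s]])],
      transcripts = sort(ts[ti + seq_len(nb_t[[s]])]),
      compounds = sort(cs[ci + seq_len(nb_c[[s]])]))
    pi <- pi + nb_pw[[s]]; ti <- ti + nb_t[[s]]; ci <- ci + nb_c[[s]]
  }
  rest_pw <- shared_pw[setdiff(seq_len(n_shared), seq_len(pi))]
  rest_t <- ts[setdiff(seq_along(ts), seq_len(ti))]
  rest_c <- cs[setdiff(seq_along(cs), seq_len(ci))]
  if (length(rest_pw) > 0L && (length(rest_t) == 0L || length(rest_c) == 0L))
    stop("not enough entities left to wire the non-symptom shared pathways")

  # system assignment: symptom pathways cycle over the symptom systems;
  # remaining pathways first cover any unused system, then cycle over all
  pw_system <- character(0)
  for (s in names(blocks))
    pw_system[blocks[[s]]$pathways] <-
      rep_len(symptom_systems, length(blocks[[s]]$pathways))
  uncovered <- setdiff(systems, unique(pw_system))
  fill_pw <- c(rest_pw, t_only_pw, c_only_pw)
  fill_sys <- c(uncovered, rep_len(systems, max(length(fill_pw) -
                                                  length(uncovered), 0L)))
  pw_system[fill_pw] <- fill_sys[seq_along(fill_pw)]
  all_pw <- c(shared_pw, t_only_pw, c_only_pw)
  pw_name <- stats::setNames(paste("Pathway", toupper(all_pw)), all_pw)

  rows <- list()
  add <- function(entities, kind, pathway)
    rows[[length(rows) + 1L]] <<- data.frame(
      entity_id = entities, entity_kind = kind, pathway_id = pathway,
      pathway_name = unname(pw_name[pathway]),
      system = unname(pw_system[pathway]), stringsAsFactors = FALSE)

  wire <- function(entities, pathways, kind) {
    # every entity gets one pathway; every pathway then gets >= 1 entity
    np <- length(pathways)
    for (i in seq_along(entities))
      add(entities[i], kind, pathways[(i - 1L) %% np + 1L])
    if (np > length(entities))
      for (j in seq(length(entities) + 1L, np))
        add(entities[(j - 1L) %% length(entities) + 1L], kind, pathways[j])
  }
  for (s in names(blocks)) {
    wire(blocks[[s]]$transcripts, blocks[[s]]$pathways, "transcript_hit")
    wire(blocks[[s]]$compounds, blocks[[s]]$pathways, "compound")
  }
  if (length(rest_pw) > 0L) {
    wire(rest_t, rest_pw, "transcript_hit")
    wire(rest_c, rest_pw, "compound")
  }
  if (n_transcript_only > 0L)
    wire(ts[rep_len(seq_along(ts), n_transcript_only)][seq_len(n_transcript_only)],
         t_only_pw, "transcript_hit")
  if (n_compound_only > 0L)
    wire(cs[rep_len(seq_along(cs), n_compound_only)][seq_len(n_compound_only)],
         c_only_pw, "compound")

  map <- do.call(rbind, rows)
  map <- map[!duplicated(map[c("entity_id", "pathway_id")]), , drop = FALSE]
  map <- map[order(map$pathway_id, map$entity_kind, map$entity_id), ,
             drop = FALSE]
  rownames(map) <- NULL
  validate_pathway_map(map, "simulated pathway map")

  symptoms <- lapply(blocks, function(b) b$pathways)
  manifest <- list(
    seed = seed,
    n_shared = n_shared,
    n_union = n_shared + n_transcript_only + n_compound_only,
    shared_pathways = shared_pw,
    systems_of_shared = sort(unique(unname(pw_system[shared_pw]))),
    core_transcripts = sort(transcript_ids),
    core_compounds = sort(compound_ids),
    blocks = blocks)
  list(map = map, symptoms = symptoms, manifest = manifest)
}

#' Default target-system catalogue
#'
#' Fifteen KEGG BRITE-style top-level functional categories used by the
#' fixture generator.
#'
#' @return Character vector of 15 system names.
#' @export
default_systems <- function() {
  c("Signal transduction", "Nervous system", "Sensory system",
    "Circulatory system", "Immune system", "Cancer", "Endocrine system",
    "Digestive system", "Excretory system", "Development and regeneration",
    "Cell growth and death", "Membrane transport",
    "Signaling molecules and interaction", "Amino acid metabolism",
    "Infectious disease")
}
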