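#' Filter similarity-search hits by identity, coverage and bit score
#'
#' Keeps exactly the rows satisfying \code{identity >= t_id},
#' \code{coverage >= t_cov} and \code{bit_score >= t_bs} (all bounds
#' inclusive, matching the published ">= 40\% / >= 40\% / >= 30" cascade).
#' Row order is preserved; an empty result is valid.
#'
#' @param hits Hit table as returned by \code{\link{read_hit_table}}.
#' @param t_id,t_cov,t_bs Finite thresholds for identity (percent),
#'   query coverage (percent) and bit score.
#' @return The surviving rows, with attribute \code{"n_removed"}.
#' @export
filter_hits <- function(hits, t_id = 40, t_cov = 40, t_bs = 30) {
  stopifnot(is.finite(t_id), is.finite(t_cov), is.finite(t_bs))
  keep <- hits$identity >= t_id & hits$coverage >= t_cov &
    hits$bit_score >= t_bs
  keep[is.na(keep)] <- FALSE
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Keep the best hit per unique reference accession
#'
#' After threshold filtering, only the highest bit-scoring hit against each
#' unique reference accession (subject) is retained. Ties on bit score are
#' broken by lower e-value, then by lexicographically smallest query id, so
#' the result is independent of input row order. With
#' \code{scope = "query"} the same rule is applied per query instead (ties
#' then fall back to the smallest subject id).
#'
#' @param hits A filtered hit table.
#' @param scope Grouping unit: \code{"subject"} (default) or \code{"query"}.
#' @return One row per group, ordered by group key.
#' @export
select_best_hits <- function(hits, scope = c("subject", "query")) {
  scope <- match.arg(scope)
  if (nrow(hits) == 0L) return(hits)
  key <- if (scope == "subject") hits$query_id else hits$subject_id
  grp <- if (scope == "subject") hits$subject_id else hits$query_id
  # order so the winner is first within each group, then keep first per group
  ord <- order(grp, -hits$bit_score, hits$e_value, key)
  out <- hits[ord, , drop = FALSE]
  out <- out[!duplicated(if (scope == "subject") out$subject_id
                         else out$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Discard hits on weakly expressed transcripts
#'
#' Joins each hit's query transcript to its TPM and removes hits whose TPM is
#' strictly below \code{min_tpm} (a transcript at exactly the floor is
#' retained: "TPM < 0.5 discarded").
#'
#' @param hits Hit table.
#' @param expr Expression table (\code{transcript_id}, \code{tpm}); every
#'   query id must be present, otherwise an error lists the missing ids.
#' @param min_tpm Expression floor, default 0.5.
#' @return The surviving hits with a \code{tpm} column appended and
#'   attribute \code{"n_removed"}.
#' @export
apply_tpm_floor <- function(hits, expr, min_tpm = 0.5) {
  stopifnot(is.finite(min_tpm))
  idx <- match(hits$query_id, expr$transcript_id)
  if (anyNA(idx)) {
    missing_ids <- sort(unique(hits$query_id[is.na(idx)]))
    stop("query id(s) absent from expression table: ",
         paste(missing_ids, collapse = ", "))
  }
  hits$tpm <- expr$tpm[idx]
  keep <- hits$tpm >= min_tpm
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Join subject metadata onto a hit set
#'
#' @param hits Hit table (any stage).
#' @param meta Subject metadata (\code{\link{read_subject_metadata}}); every
#'   subject id must be present.
#' @return \code{hits} with \code{family}, \code{length_aa},
#'   \code{is_fragment} columns appended.
#' @export
join_subject_metadata <- function(hits, meta) {
  idx <- match(hits$subject_id, meta$subject_id)
  if (anyNA(idx)) {
    missing_ids <- sort(unique(hits$subject_id[is.na(idx)]))
    stop("subject id(s) absent from metadata: ",
         paste(missing_ids, collapse = ", "))
  }
  hits$family <- meta$family[idx]
  hits$length_aa <- meta$length_aa[idx]
  hits$is_fragment <- meta$is_fragment[idx]
  hits
}

#' Toxin-family relative expression
#'
#' The family summary statistic: the sum of the TPM values of the retained
#' hits in one toxin family divided by the number of those hits, i.e. the
#' arithmetic mean TPM over family members. Hits whose subject has an empty
#' family are excluded from aggregation and returned in the
#' \code{"unassigned"} attribute.
#'
#' @param hits Hit set carrying \code{tpm} and \code{family} columns (see
#'   \code{\link{apply_tpm_floor}} and \code{\link{join_subject_metadata}}).
#' @param superfamily_map Optional data frame (\code{family},
#'   \code{superfamily}) applied before aggregation to collapse families at
#'   the superfamily level.
#' @return Data frame (\code{family}, \code{n_hits},
#'   \code{relative_expression}) sorted by family, with attribute
#'   \code{"unassigned"} holding the rows without family attribution.
#' @export
family_relative_expression <- function(hits, superfamily_map = NULL) {
  stopifnot(all(c("tpm", "family") %in% names(hits)))
  fam <- hits$family
  if (!is.null(superfamily_map)) {
    idx <- match(fam, superfamily_map$family)
    fam <- ifelse(is.na(idx), fam, superfamily_map$superfamily[idx])
  }
  no_fam <- is.na(fam) | fam == ""
  unassigned <- hits[no_fam, , drop = FALSE]
  fam <- fam[!no_fam]
  tpm <- hits$tpm[!no_fam]
  if (length(fam) == 0L) {
    out <- data.frame(family = character(0), n_hits = integer(0),
                      relative_expression = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    n_hits <- tapply(tpm, fam, length)
    rel <- tapply(tpm, fam, function(v) sum(v) / length(v))
    fams <- sort(names(n_hits))
    out <- data.frame(family = fams,
                      n_hits = as.integer(n_hits[fams]),
                      relative_expression = as.numeric(rel[fams]),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "unassigned") <- unassigned
  out
}

#' Peptide fraction of annotated hits
#'
#' Fraction of hits whose reference protein is shorter than
#' \code{length_cutoff} amino acids (venom peptides), computed after
#' excluding fragment entries when \code{ignore_fragments} is set (a fragment
#' length says nothing about the mature protein).
#'
#' @param hits Hit set carrying \code{length_aa} and \code{is_fragment}.
#' @param length_cutoff Peptide length bound (strict \code{<}), default 50.
#' @param ignore_fragments Drop \code{is_fragment} rows first (default TRUE).
#' @return Fraction in [0, 1]; \code{NA_real_} when no hits remain.
#' @export
peptide_fraction <- function(hits, length_cutoff = 50, ignore_fragments = TRUE) {
  stopifnot(all(c("length_aa", "is_fragment") %in% names(hits)))
  if (ignore_fragments) hits <- hits[!hits$is_fragment, , drop = FALSE]
  if (nrow(hits) == 0L) return(NA_real_)
  sum(hits$length_aa < length_cutoff) / nrow(hits)
}

#' Cross-species toxin-family overlap report
#'
#' Computes the full Venn partition over the family sets of two or more
#' species: for every non-empty species subset, the number of families
#' present in exactly that subset. The headline quantities are the fraction
#' of families shared by all species (|intersection| / |union|) and, per
#' species, the fraction of its hits falling in those shared families.
#'
#' @param profiles Named list (one element per species) of family-profile
#'   data frames from \code{\link{family_relative_expression}}.
#' @return An object of class \code{overlap_report}: list with
#'   \code{region_counts} (named by \code{+}-joined species subsets),
#'   \code{shared_families}, \code{union_families},
#'   \code{fraction_shared} and \code{hit_share_shared} (per species).
#' @export
overlap_report <- function(profiles) {
  if (length(profiles) < 2L) stop("overlap_report needs >= 2 species")
  if (is.null(names(profiles)) || any(names(profiles) == ""))
    stop("profiles must be a named list")
  species <- names(profiles)
  fam_sets <- lapply(profiles, function(p) unique(p$family))
  all_fams <- sort(unique(unlist(fam_sets)))
  membership <- vapply(fam_sets, function(s) all_fams %in% s,
                       logical(length(all_fams)))
  if (is.null(dim(membership)))
    membership <- matrix(membership, nrow = length(all_fams))
  region_key <- apply(membership, 1L, function(m)
    paste(species[m], collapse = "+"))
  region_counts <- table(region_key)
  shared <- all_fams[rowSums(membership) == length(species)]
  hit_share <- vapply(profiles, function(p) {
    tot <- sum(p$n_hits)
    if (tot == 0L) NA_real_ else sum(p$n_hits[p$family %in% shared]) / tot
  }, numeric(1))
  structure(list(
    species = species,
    region_counts = stats::setNames(as.integer(region_counts),
                                    names(region_counts)),
    shared_families = shared,
    union_families = all_fams,
    fraction_shared = length(shared) / max(length(all_fams), 1L),
    hit_share_shared = hit_share
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Cross-species toxin-family overlap (", length(x$species),
      " species)\n", sep = "")
  cat("  union families:  ", length(x$union_families), "\n", sep = "")
  cat("  shared families: ", length(x$shared_families),
      sprintf(" (%.1f%% of union)\n", 100 * x$fraction_shared), sep = "")
  cat("  per-species hit share in shared families:\n")
  for (sp in x$species)
    cat(sprintf("    %s: %.1f%%\n", sp, 100 * x$hit_share_shared[[sp]]))
  invisible(x)
}

#' Group contrast of family expression patterns
#'
#' Compares family presence and relative expression between two species
#' groups (for example marine vs freshwater). A family is flagged as
#' group-differential only when at least two species of one group share the
#' pattern against the other group: either presence in >= 2 group members
#' with complete absence in the other group (\code{<group>-specific}), or
#' expression in >= 2 group members strictly above the other group's maximum
#' (\code{higher-in-<group>}) / below its minimum (\code{lower-in-<group>}).
#' A group with fewer than two species cannot support a shared pattern, so
#' flagging is disabled for it with a warning.
#'
#' @param profiles Named list of per-species family profiles.
#' @param group_labels Named character vector mapping each species to one of
#'   exactly two groups.
#' @return Data frame with one row per family: presence per species, mean
#'   relative expression per group (over species where present) and the
#'   \code{flag} column (comma-separated, empty when not differential).
#' @export
group_contrast <- function(profiles, group_labels) {
  species <- names(profiles)
  if (!all(species %in% names(group_labels)))
    stop("group_labels must cover every species in profiles")
  groups <- group_labels[species]
  glev <- sort(unique(unname(groups)))
  if (length(glev) != 2L) stop("group_contrast requires exactly two groups")
  can_flag <- stats::setNames(table(factor(groups, glev)) >= 2L, glev)
  for (g in glev[!can_flag])
    warning("group '", g, "' has fewer than two species; ",
            "differential flagging disabled for it")

  all_fams <- sort(unique(unlist(lapply(profiles, function(p) p$family))))
  expr <- vapply(species, function(sp) {
    p <- profiles[[sp]]
    p$relative_expression[match(all_fams, p$family)]
  }, numeric(length(all_fams)))
  if (is.null(dim(expr))) expr <- matrix(expr, nrow = length(all_fams))

  flags <- character(length(all_fams))
  gmeans <- matrix(NA_real_, length(all_fams), 2L,
                   dimnames = list(NULL, glev))
  for (i in seq_along(all_fams)) {
    v <- expr[i, ]
    for (j in 1:2) {
      gv <- v[groups == glev[j]]
      if (any(!is.na(gv))) gmeans[i, j] <- mean(gv, na.rm = TRUE)
    }
    f <- character(0)
    for (j in 1:2) {
      g <- glev[j]; og <- glev[3L - j]
      if (!can_flag[[g]]) next
      gv <- v[groups == g]; ov <- v[groups == og]
      n_in <- sum(!is.na(gv)); n_out <- sum(!is.na(ov))
      if (n_in >= 2L && n_out == 0L) f <- c(f, paste0(g, "-specific"))
      if (n_in >= 2L && n_out >= 1L) {
        if (sum(gv > max(ov, na.rm = TRUE), na.rm = TRUE) >= 2L)
          f <- c(f, paste0("higher-in-", g))
        if (sum(gv < min(ov, na.rm = TRUE), na.rm = TRUE) >= 2L)
          f <- c(f, paste0("lower-in-", g))
      }
    }
    flags[i] <- paste(f, collapse = ",")
  }

  presence <- apply(!is.na(expr), 1L, function(m)
    paste(species[m], collapse = "+"))
  out <- data.frame(family = all_fams, present_in = presence,
                    stringsAsFactors = FALSE)
  out[[paste0("mean_", glev[1L])]] <- gmeans[, 1L]
  out[[paste0("mean_", glev[2L])]] <- gmeans[, 2L]
  out$flag <- flags
  out
}
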