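#' Read a BLAST-style tabular hit table
#'
#' Parses a tab-delimited similarity-search hit table (BLAST "outfmt 6"-like,
#' with one header line naming the columns). Standard column names are
#' recognised (\code{qseqid}, \code{sseqid}, \code{pident}, \code{length},
#' \code{evalue}, \code{bitscore}, ...). Query coverage is not part of the
#' classic 12-column format, so the reader accepts either an extended dialect
#' with a \code{qcovs} column (percent query coverage) or a \code{qlen}
#' column from which coverage is computed as
#' \code{100 * length / qlen}.
#'
#' Lines starting with \code{#} and blank lines are skipped; the number of
#' skipped lines is recorded in the \code{"n_skipped"} attribute and reported
#' via \code{message()} so no row is dropped silently.
#'
#' @param path Path to the tab-delimited hit file.
#' @param dialect One of \code{"auto"} (default: use \code{qcovs} if present,
#'   else \code{qlen}), \code{"qcovs"} or \code{"qlen"}.
#' @return A data frame with columns \code{query_id}, \code{subject_id},
#'   \code{identity}, \code{coverage}, \code{bit_score}, \code{e_value}
#'   (percentages on the 0--100 scale). Row order follows the file.
#' @export
read_hit_table <- function(path, dialect = c("auto", "qcovs", "qlen")) {
  dialect <- match.arg(dialect)
  tab <- read_tsv_lines(path)
  header <- tab$header
  need <- c("qseqid", "sseqid", "pident", "evalue", "bitscore")
  miss <- setdiff(need, header)
  if (length(miss) > 0L)
    stop("hit table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))

  has_qcovs <- "qcovs" %in% header
  has_qlen <- all(c("qlen", "length") %in% header)
  if (dialect == "qcovs" && !has_qcovs)
    stop("hit table ", path, " is missing required column(s): qcovs")
  if (dialect == "qlen" && !has_qlen)
    stop("hit table ", path, " is missing required column(s): qlen, length")
  if (dialect == "auto") {
    dialect <- if (has_qcovs) "qcovs" else if (has_qlen) "qlen" else "none"
  }

  num_cols <- intersect(c("pident", "length", "mismatch", "gapopen", "qstart",
                          "qend", "sstart", "send", "evalue", "bitscore",
                          "qcovs", "qlen"), header)
  df <- tab$df
  for (cl in num_cols) df[[cl]] <- coerce_numeric(df[[cl]], cl, tab$lines)

  coverage <- switch(dialect,
    qcovs = df$qcovs,
    qlen  = 100 * df$length / df$qlen,
    none  = {
      if (nrow(df) > 0L)
        warning("no coverage column (qcovs or qlen) in ", path,
                "; coverage set to NA")
      rep(NA_real_, nrow(df))
    })

  out <- data.frame(query_id = df$qseqid, subject_id = df$sseqid,
                    identity = df$pident, coverage = coverage,
                    bit_score = df$bitscore, e_value = df$evalue,
                    stringsAsFactors = FALSE)
  validate_hit_table(out, path)
  attr(out, "n_skipped") <- tab$n_skipped
  out
}

validate_hit_table <- function(hits, what = "hit table") {
  if (nrow(hits) == 0L) return(invisible(hits))
  ok_id <- is.na(hits$identity) | (hits$identity >= 0 & hits$identity <= 100)
  ok_cov <- is.na(hits$coverage) | (hits$coverage >= 0 & hits$coverage <= 100)
  if (!all(ok_id)) stop(what, ": identity outside [0,100]")
  if (!all(ok_cov)) stop(what, ": coverage outside [0,100]")
  if (any(hits$bit_score < 0, na.rm = TRUE)) stop(what, ": negative bit score")
  invisible(hits)
}

# Shared low-level TSV reader: one header line, '#' comments and blank lines
# skipped, original file line numbers kept for error messages.
read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- which(keep)
  body <- raw[keep]
  if (length(body) == 0L) stop("file ", path, " has no header line")
  header <- strsplit(body[[1L]], "\t", fixed = TRUE)[[1L]]
  rows <- body[-1L]
  lines <- lines[-1L]
  n_skipped <- length(raw) - length(body)
  if (n_skipped > 0L)
    message("skipped ", n_skipped, " comment/blank line(s) in ", path)
  if (length(rows) == 0L) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(header)),
                                        header),
                        stringsAsFactors = FALSE, check.names = FALSE)
    return(list(header = header, df = df, lines = integer(0),
                n_skipped = n_skipped))
  }
  parts <- strsplit(rows, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != length(header))
  if (length(bad) > 0L)
    stop("line ", lines[bad[1L]], " of ", path, " has ", nf[bad[1L]],
         " fields, expected ", length(header))
  mat <- do.call(rbind, parts)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  list(header = header, df = df, lines = lines, n_skipped = n_skipped)
}

coerce_numeric <- function(x, column, lines) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out))
  if (length(bad) > 0L)
    stop("non-numeric value '", x[bad[1L]], "' in column '", column,
         "' at line ", if (length(lines) >= bad[1L]) lines[bad[1L]] else bad[1L])
  out
}

coerce_logical <- function(x, column, lines) {
  val <- toupper(trimws(x))
  out <- ifelse(val %in% c("TRUE", "T", "1", "YES"), TRUE,
         ifelse(val %in% c("FALSE", "F", "0", "NO"), FALSE, NA))
  bad <- which(is.na(out))
  if (length(bad) > 0L)
    stop("non-logical value '", x[bad[1L]], "' in column '", column,
         "' at line ", if (length(lines) >= bad[1L]) lines[bad[1L]] else bad[1L])
  as.logical(out)
}

read_plain_table <- function(path, required, numeric_cols = character(0),
                             integer_cols = character(0),
                             logical_cols = character(0)) {
  tab <- read_tsv_lines(path)
  miss <- setdiff(required, tab$header)
  if (length(miss) > 0L)
    stop(path, " is missing required column(s): ", paste(miss, collapse = ", "))
  df <- tab$df
  for (cl in intersect(numeric_cols, tab$header))
    df[[cl]] <- coerce_numeric(df[[cl]], cl, tab$lines)
  for (cl in intersect(integer_cols, tab$header))
    df[[cl]] <- as.integer(coerce_numeric(df[[cl]], cl, tab$lines))
  for (cl in intersect(logical_cols, tab$header))
    df[[cl]] <- coerce_logical(df[[cl]], cl, tab$lines)
  attr(df, "n_skipped") <- tab$n_skipped
  df
}

#' Read a transcript expression table
#'
#' Two required columns: \code{transcript_id} and \code{tpm}
#' (transcripts per million, non-negative). Transcript ids must be unique.
#'
#' @param path Path to a tab-delimited file.
#' @return Data frame with columns \code{transcript_id}, \code{tpm}.
#' @export
read_expression_table <- function(path) {
  df <- read_plain_table(path, c("transcript_id", "tpm"),
                         numeric_cols = "tpm")
  if (anyDuplicated(df$transcript_id))
    stop("duplicated transcript_id in ", path)
  if (any(df$tpm < 0)) stop("negative TPM in ", path)
  df[c("transcript_id", "tpm")]
}

#' Read subject (reference protein) metadata
#'
#' Columns: \code{subject_id} (unique accession), \code{family} (toxin family,
#' may be empty), \code{length_aa} (protein length, >= 1) and
#' \code{is_fragment} (logical).
#'
#' @param path Path to a tab-delimited file.
#' @return Data frame of subject metadata.
#' @export
read_subject_metadata <- function(path) {
  df <- read_plain_table(path,
                         c("subject_id", "family", "length_aa", "is_fragment"),
                         integer_cols = "length_aa",
                         logical_cols = "is_fragment")
  if (anyDuplicated(df$subject_id)) stop("duplicated subject_id in ", path)
  if (any(df$length_aa < 1L)) stop("length_aa < 1 in ", path)
  df[c("subject_id", "family", "length_aa", "is_fragment")]
}

#' Read per-well HCS measurements
#'
#' Long-format well table with columns \code{sample_id}, \code{replicate},
#' \code{parameter}, \code{value}, \code{is_control} and optionally
#' \code{n_objects} (valid object count per well, used by the QC gate).
#'
#' @param path Path to a tab-delimited file.
#' @return Data frame of well measurements.
#' @export
read_well_measurements <- function(path) {
  df <- read_plain_table(path,
                         c("sample_id", "replicate", "parameter", "value",
                           "is_control"),
                         numeric_cols = c("value", "n_objects"),
                         integer_cols = "replicate",
                         logical_cols = "is_control")
  keep <- c("sample_id", "replicate", "parameter", "value", "is_control")
  if ("n_objects" %in% names(df)) keep <- c(keep, "n_objects")
  df[keep]
}

#' Read an entity-to-pathway mapping table
#'
#' Emulates KEGG-style annotation: each row links an entity (a transcript hit
#' keyed by its reference accession, or a reference compound) to a signalling
#' pathway and that pathway's target system (top-level functional category).
#' \code{(entity_id, pathway_id)} pairs must be unique and every pathway must
#' belong to exactly one system.
#'
#' @param path Path to a tab-delimited file with columns \code{entity_id},
#'   \code{entity_kind} (\code{transcript_hit} or \code{compound}),
#'   \code{pathway_id}, \code{pathway_name}, \code{system}.
#' @return Data frame of pathway-map entries.
#' @export
read_pathway_map <- function(path) {
  df <- read_plain_table(path,
                         c("entity_id", "entity_kind", "pathway_id",
                           "pathway_name", "system"))
  validate_pathway_map(df, path)
  df[c("entity_id", "entity_kind", "pathway_id", "pathway_name", "system")]
}

validate_pathway_map <- function(map, what = "pathway map") {
  bad_kind <- setdiff(unique(map$entity_kind), c("transcript_hit", "compound"))
  if (length(bad_kind) > 0L)
    stop(what, ": unknown entity_kind: ", paste(bad_kind, collapse = ", "))
  if (anyDuplicated(map[c("entity_id", "pathway_id")]))
    stop(what, ": duplicated (entity_id, pathway_id) pair")
  sys_per_pw <- tapply(map$system, map$pathway_id,
                       function(s) length(unique(s)))
  multi <- names(sys_per_pw)[sys_per_pw > 1L]
  if (length(multi) > 0L)
    stop(what, ": pathway(s) mapped to more than one system: ",
         paste(multi, collapse = ", "))
  invisible(map)
}

#' Read symptom definitions
#'
#' A symptom is a named list of pathway ids, supplied as a two-column
#' tab-delimited file (\code{symptom}, \code{pathway_id}).
#'
#' @param path Path to the definitions file.
#' @return Named list mapping each symptom to a character vector of
#'   pathway ids.
#' @export
read_symptom_lists <- function(path) {
  df <- read_plain_table(path, c("symptom", "pathway_id"))
  lapply(split(df$pathway_id, df$symptom), unique)
}

#' Write a data frame as a plain TSV
#'
#' Tab-delimited, one header line, no quoting or row names; the format the
#' package's readers consume.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Write / read a profile matrix as CSV
#'
#' Samples in rows, cytological parameters in columns; the first column holds
#' the sample id.
#'
#' @param profiles Numeric matrix with sample row names and parameter column
#'   names.
#' @param path File path.
#' @return \code{write_profiles_csv} invisibly returns \code{path};
#'   \code{read_profiles_csv} returns the matrix.
#' @export
write_profiles_csv <- function(profiles, path) {
  df <- data.frame(sample_id = rownames(profiles), profiles,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write an integrated network as GraphML
#'
#' Node attributes \code{kind} (transcript_hit / compound / pathway / system),
#' \code{label} and \code{system}; edge attribute \code{relation}. Vertices
#' are written in a canonical order (by kind, then name) so identical runs
#' produce identical files.
#'
#' @param network An \code{igraph} object as produced by
#'   \code{\link{build_network}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_network_graphml <- function(network, path) {
  if (!igraph::is_igraph(network)) stop("network must be an igraph object")
  igraph::write_graph(canonicalize_network(network), path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  igraph::read_graph(path, format = "graphml")
}

kind_levels <- c("transcript_hit", "compound", "pathway", "system")

canonicalize_network <- function(network) {
  if (igraph::vcount(network) == 0L) return(network)
  kind <- igraph::V(network)$kind
  nm <- igraph::V(network)$name
  ord <- order(match(kind, kind_levels), nm)
  igraph::permute(network, order(ord))
}

#' Default run configuration
#'
#' Thresholds default to the published filter settings: identity >= 40,
#' coverage >= 40, bit score >= 30 (all on the 0--100 / raw score scales),
#' TPM floor 0.5 (values strictly below are discarded) and a dendrogram cut
#' at distance 0.7. Reduction settings: variance floor 1e-8, z floor 2 (in
#' control standard deviations) and a redundancy ceiling of |rho| 0.95.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    identity = 40, coverage = 40, bit_score = 30, min_tpm = 0.5,
    cluster_cut = 0.7,
    z_min = 2, rho_max = 0.95, variance_floor = 1e-8,
    target_count = NULL, min_objects = NULL,
    distance_scale = "one_minus_rho",   # or "half" for (1 - rho) / 2
    cocluster_mode = "cut",             # or "pairwise"
    best_hit_scope = "subject",         # or "query"
    seed = 1L,
    venom_samples = character(0),
    species_groups = NULL,
    paths = list()
  )
}

#' Read a YAML run configuration
#'
#' Absent keys fall back to \code{\link{default_config}}; unknown keys raise
#' a warning and are carried along untouched.
#'
#' @param path Path to a YAML file (an empty file yields all defaults).
#' @return Named configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("config file ", path, " must contain a mapping")
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L)
    warning("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  num_keys <- c("identity", "coverage", "bit_score", "min_tpm", "cluster_cut",
                "z_min", "rho_max", "variance_floor")
  for (k in num_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("config value '", k, "' must be a single finite number")
  }
  if (cfg$cluster_cut <= 0) stop("config value 'cluster_cut' must be > 0")
  if (!cfg$distance_scale %in% c("one_minus_rho", "half"))
    stop("config value 'distance_scale' must be 'one_minus_rho' or 'half'")
  if (!cfg$cocluster_mode %in% c("cut", "pairwise"))
    stop("config value 'cocluster_mode' must be 'cut' or 'pairwise'")
  if (!cfg$best_hit_scope %in% c("subject", "query"))
    stop("config value 'best_hit_scope' must be 'subject' or 'query'")
  invisible(cfg)
}
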