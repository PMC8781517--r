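# Independent oracles and fixture builders shared across test files. All
# oracles are written as plain, slow re-computations that do not share code
# paths with the package implementation.

# -- random hit tables with values planted around the filter thresholds ------
random_hit_table <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("t%03d", seq_len(n))
  subj <- sprintf("S%02d", sample.int(max(2L, n %/% 4L), n, replace = TRUE))
  pick <- function(boundary, lo, hi)
    ifelse(stats::runif(n) < 0.3,
           sample(boundary, n, replace = TRUE),
           stats::runif(n, lo, hi))
  data.frame(query_id = ids, subject_id = subj,
             identity = round(pick(c(39.9, 40, 40.1), 20, 100), 1),
             coverage = round(pick(c(39.9, 40, 40.1), 20, 100), 1),
             bit_score = round(pick(c(29.9, 30, 30.1), 10, 300), 1),
             e_value = signif(10^stats::runif(n, -30, -2), 3),
             stringsAsFactors = FALSE)
}

random_expression_for <- function(hits, seed) {
  set.seed(seed)
  q <- unique(hits$query_id)
  data.frame(transcript_id = q,
             tpm = round(sample(c(0.49, 0.5, 0.51,
                                  stats::rlnorm(length(q))), length(q),
                                replace = TRUE), 4),
             stringsAsFactors = FALSE)
}

# row-by-row re-application of the filter cascade
oracle_filter_cascade <- function(hits, expr, t_id = 40, t_cov = 40,
                                  t_bs = 30, min_tpm = 0.5) {
  keep <- logical(nrow(hits))
  tpm <- numeric(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    tpm[i] <- expr$tpm[expr$transcript_id == hits$query_id[i]]
    keep[i] <- hits$identity[i] >= t_id && hits$coverage[i] >= t_cov &&
      hits$bit_score[i] >= t_bs && tpm[i] >= min_tpm
  }
  surv <- hits[keep, , drop = FALSE]
  surv$tpm <- tpm[keep]
  # best hit per subject: max bit score, then min e-value, then min query id
  out <- NULL
  for (s in sort(unique(surv$subject_id))) {
    rows <- surv[surv$subject_id == s, , drop = FALSE]
    rows <- rows[rows$bit_score == max(rows$bit_score), , drop = FALSE]
    rows <- rows[rows$e_value == min(rows$e_value), , drop = FALSE]
    rows <- rows[rows$query_id == min(rows$query_id), , drop = FALSE]
    out <- rbind(out, rows[1L, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

# -- naive complete-linkage agglomeration ------------------------------------
# Clusters are kept as explicit leaf-index sets; every inter-cluster distance
# is recomputed from the original matrix at every step (no Lance-Williams
# update), with the same lexicographic smallest-leaf tie-break.
oracle_complete_linkage <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  codes <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (k in seq_len(n - 1L)) {
    best <- NULL
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        d_ab <- max(D[clusters[[a]], clusters[[b]]])
        key <- sort(c(min(clusters[[a]]), min(clusters[[b]])))
        cand <- list(a = a, b = b, d = d_ab, key = key)
        if (is.null(best) || d_ab < best$d ||
            (d_ab == best$d && (key[1L] < best$key[1L] ||
                                (key[1L] == best$key[1L] &&
                                 key[2L] < best$key[2L]))))
          best <- cand
      }
    }
    merge[k, ] <- sort(c(codes[best$a], codes[best$b]))
    height[k] <- best$d
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    codes[best$a] <- k
    clusters[[best$b]] <- NULL
    codes <- codes[-best$b]
  }
  list(merge = merge, height = height)
}

random_distance_matrix <- function(n, seed, tie_grid = TRUE) {
  set.seed(seed)
  vals <- if (tie_grid) sample(seq(0.1, 1.2, by = 0.1), n * (n - 1) / 2,
                               replace = TRUE)
          else stats::runif(n * (n - 1) / 2, 0.05, 1.5)
  D <- matrix(0, n, n)
  D[lower.tri(D)] <- vals
  D <- D + t(D)
  rownames(D) <- colnames(D) <- sprintf("s%02d", seq_len(n))
  D
}

# -- random pathway maps ------------------------------------------------------
random_pathway_map <- function(seed, n_pathways = 8, n_entities = 12) {
  set.seed(seed)
  pws <- sprintf("pw%02d", seq_len(n_pathways))
  sys <- stats::setNames(sample(sprintf("sys%d", 1:3), n_pathways,
                                replace = TRUE), pws)
  rows <- expand.grid(entity_id = sprintf("e%02d", seq_len(n_entities)),
                      pathway_id = pws, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  rows <- rows[stats::runif(nrow(rows)) < 0.25, , drop = FALSE]
  if (nrow(rows) == 0L) rows <- data.frame(entity_id = "e01",
                                           pathway_id = pws[1L],
                                           stringsAsFactors = FALSE)
  rows$entity_kind <- sample(c("transcript_hit", "compound"), nrow(rows),
                             replace = TRUE)
  rows$pathway_name <- paste("Pathway", rows$pathway_id)
  rows$system <- unname(sys[rows$pathway_id])
  rows <- rows[!duplicated(rows[c("entity_id", "pathway_id")]), , drop = FALSE]
  rows[c("entity_id", "entity_kind", "pathway_id", "pathway_name", "system")]
}

# small complete well table built by hand
make_wells <- function(samples, params, values, controls, n_reps = 1L) {
  # values: matrix samples x params of replicate-constant values
  trt <- expand.grid(sample_id = samples, replicate = seq_len(n_reps),
                     parameter = params, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  trt$value <- values[cbind(trt$sample_id, trt$parameter)]
  trt$is_control <- FALSE
  ctl <- expand.grid(sample_id = sprintf("ctl%d", seq_along(controls)),
                     replicate = 1L, parameter = params,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ctl$value <- controls[as.integer(sub("ctl", "", ctl$sample_id))]
  ctl$is_control <- TRUE
  rbind(trt, ctl)
}
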