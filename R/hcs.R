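#' Build control-normalised cytological profiles
#'
#' Turns long-format well measurements into one fingerprint per treatment:
#' per sample and parameter, replicate values are aggregated by their median
#' (robust to a single outlying well), then expressed as a z-score against
#' the control wells of the same parameter,
#' \code{z = (median_sample - mean_control) / sd_control}
#' with the sample (n-1) standard deviation. Parameters whose control wells
#' are constant carry no scale and are excluded with a warning.
#'
#' An optional QC gate drops wells with fewer than \code{min_objects} valid
#' objects before anything else (requires an \code{n_objects} column).
#'
#' @param wells Well table from \code{\link{read_well_measurements}}.
#' @param min_controls Minimum number of control well values per parameter
#'   (default 2; fewer makes the control sd undefined and is an error).
#' @param min_objects Optional minimum valid-object count per well.
#' @return Numeric matrix, samples in rows (first-appearance order),
#'   parameters in columns; attribute \code{"excluded_parameters"} lists
#'   constant-control parameters that were dropped.
#' @export
build_profiles <- function(wells, min_controls = 2L, min_objects = NULL) {
  req <- c("sample_id", "replicate", "parameter", "value", "is_control")
  stopifnot(all(req %in% names(wells)))
  if (!is.null(min_objects)) {
    if (!"n_objects" %in% names(wells))
      stop("min_objects given but wells have no n_objects column")
    drop <- wells$n_objects < min_objects
    if (any(drop))
      message("QC gate: dropping ", sum(drop), " well row(s) with fewer than ",
              min_objects, " valid objects")
    wells <- wells[!drop, , drop = FALSE]
  }

  params <- unique(wells$parameter)
  samples <- unique(wells$sample_id[!wells$is_control])
  if (length(samples) == 0L) stop("no treatment samples in well table")

  # completeness: every parameter measured for every (sample, replicate)
  trt <- wells[!wells$is_control, , drop = FALSE]
  n_per <- table(trt$sample_id, trt$replicate)
  if (length(unique(as.vector(n_per[n_per > 0]))) > 1L ||
      any(as.vector(n_per[n_per > 0]) != length(params)))
    stop("incomplete well table: every parameter must be present for every ",
         "(sample, replicate)")

  ctl <- wells[wells$is_control, , drop = FALSE]
  excluded <- character(0)
  prof <- matrix(NA_real_, length(samples), length(params),
                 dimnames = list(samples, params))
  keep_param <- logical(length(params))
  for (j in seq_along(params)) {
    p <- params[[j]]
    cv <- ctl$value[ctl$parameter == p]
    if (length(cv) < min_controls)
      stop("parameter '", p, "' has fewer than ", min_controls,
           " control well values")
    s <- stats::sd(cv)
    if (s == 0) {
      excluded <- c(excluded, p)
      next
    }
    m <- mean(cv)
    sub <- trt[trt$parameter == p, , drop = FALSE]
    med <- tapply(sub$value, sub$sample_id, stats::median)
    prof[, j] <- (as.numeric(med[samples]) - m) / s
    keep_param[j] <- TRUE
  }
  if (length(excluded) > 0L)
    warning("excluded constant-control parameter(s): ",
            paste(excluded, collapse = ", "))
  out <- prof[, keep_param, drop = FALSE]
  if (ncol(out) == 0L) stop("no usable parameters after control normalisation")
  if (anyNA(out)) stop("missing values in profiles after construction")
  attr(out, "excluded_parameters") <- excluded
  out
}

#' Stepwise reduction to informative parameters
#'
#' Emulates the stepwise data reduction of raw HCS feature sets down to a
#' compact informative panel. Three declared steps:
#' \enumerate{
#'   \item drop parameters with (near-)zero variance across samples
#'     (\code{variance_floor});
#'   \item drop parameters that never reach \code{|z| >= z_min} in any
#'     treatment -- they do not respond to anything;
#'   \item greedily drop redundant parameters: among pairs with Spearman
#'     \code{|rho| > rho_max}, keep the higher-variance member (ties keep the
#'     earlier column).
#' }
#' The endpoint is data-dependent; \code{target_count} optionally forces a
#' fixed panel size by keeping the highest-variance survivors.
#'
#' @param profiles Profile matrix from \code{\link{build_profiles}}.
#' @param z_min Response floor in control standard deviations (default 2).
#' @param rho_max Redundancy ceiling on pairwise |Spearman rho|
#'   (default 0.95).
#' @param variance_floor Variance below which a parameter counts as constant.
#' @param target_count Optional fixed number of parameters to keep.
#' @return The profile matrix restricted to informative parameters, with a
#'   \code{"dropped"} attribute listing per-step removals.
#' @export
reduce_parameters <- function(profiles, z_min = 2, rho_max = 0.95,
                              variance_floor = 1e-8, target_count = NULL) {
  if (nrow(profiles) < 2L) stop("need >= 2 profiles to reduce parameters")
  dropped <- list()

  v <- apply(profiles, 2L, stats::var)
  step1 <- colnames(profiles)[v <= variance_floor]
  profiles <- profiles[, v > variance_floor, drop = FALSE]
  dropped$constant <- step1

  if (ncol(profiles) > 0L) {
    responds <- apply(abs(profiles), 2L, max) >= z_min
    dropped$unresponsive <- colnames(profiles)[!responds]
    profiles <- profiles[, responds, drop = FALSE]
  }

  if (ncol(profiles) > 1L) {
    rho <- suppressWarnings(stats::cor(profiles, method = "spearman"))
    v <- apply(profiles, 2L, stats::var)
    # visit columns from highest variance (ties: earlier column first); keep
    # a column only if not redundant with anything already kept
    ord <- order(-v, seq_along(v))
    kept <- integer(0)
    for (j in ord) {
      if (length(kept) == 0L || all(abs(rho[j, kept]) <= rho_max))
        kept <- c(kept, j)
    }
    kept <- sort(kept)
    dropped$redundant <- colnames(profiles)[-kept]
    profiles <- profiles[, kept, drop = FALSE]
  } else {
    dropped$redundant <- character(0)
  }

  if (ncol(profiles) == 0L) stop("all parameters dropped during reduction")

  if (!is.null(target_count)) {
    if (ncol(profiles) > target_count) {
      v <- apply(profiles, 2L, stats::var)
      keep <- sort(order(-v, seq_along(v))[seq_len(target_count)])
      dropped$over_target <- colnames(profiles)[-keep]
      profiles <- profiles[, keep, drop = FALSE]
    } else if (ncol(profiles) < target_count) {
      warning("only ", ncol(profiles), " parameters remain; target_count = ",
              target_count, " not reachable")
    }
  }

  attr(profiles, "dropped") <- dropped
  profiles
}
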