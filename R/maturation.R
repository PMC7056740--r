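# PCA-based maturation-pathway staging. The trajectory is the first
# principal component of the standardized maturation markers; events are
# ranked along it and cut into equal-count stages (20 by default), which are
# then merged into runs of identical discrete phenotype.

#' Stage events along the CD4+ T-cell maturation pathway
#'
#' Computes PC1 on the standardized maturation markers, orients the axis so
#' that the orientation marker (CD45RA by default, high on naive cells) sits
#' at the immature end, ranks events along the axis and splits them into
#' \code{n_stages} equal-count bins (remainder events go to the earliest
#' bins; ties in PC1 score are broken by event index so the assignment is
#' invariant to event order).
#'
#' @param events numeric matrix of transformed intensities restricted to (at
#'   least) the maturation markers; column names are marker names.
#' @param n_stages number of stages (default 20).
#' @param orientation_marker marker anchoring the immature end (default
#'   \code{"CD45RA"}).
#' @param markers columns to use (default \code{CD27, CD45RA, CD62L}
#'   intersected with the available columns).
#' @return An object of class \code{maturation_path}: list with
#'   \code{stage} (per-event stage index, 1 = least mature),
#'   \code{profile} (data.frame stage x marker median/SD/n),
#'   \code{loadings} (oriented PC1 loading vector), \code{n_stages}.
#' @export
stage_pathway <- function(events, n_stages = 20, orientation_marker = "CD45RA",
                          markers = NULL) {
  if (is.null(dim(events))) stop_validation("events must be a matrix")
  markers <- markers %||% intersect(MATURATION_MARKERS, colnames(events))
  if (length(markers) < 2)
    stop_validation("need >= 2 maturation markers (got %d)", length(markers))
  x <- events[, markers, drop = FALSE]
  n <- nrow(x)
  if (!is.numeric(n_stages) || n_stages < 1 || n_stages > n)
    stop_validation("n_stages must be in [1, %d]", n)
  n_stages <- as.integer(n_stages)

  sds <- apply(x, 2, stats::sd)
  keep <- sds > 1e-12
  if (!all(keep)) {
    warning(sprintf("constant marker(s) excluded from PCA: %s",
                    paste(markers[!keep], collapse = ", ")))
    markers <- markers[keep]
    if (length(markers) < 2) stop_validation("fewer than 2 non-constant markers")
    x <- x[, markers, drop = FALSE]
  }
  z <- scale(x)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  load1 <- pc$rotation[, 1]
  # orient: the orientation marker is high at the immature (first) end,
  # so its loading must be negative along the increasing-maturity axis
  if (orientation_marker %in% names(load1) && load1[orientation_marker] > 0)
    load1 <- -load1
  score <- as.vector(z %*% load1)

  ord <- order(score, seq_len(n))  # tie-break on event index
  sizes <- rep(n %/% n_stages, n_stages)
  rem <- n %% n_stages
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  stage <- integer(n)
  stage[ord] <- rep(seq_len(n_stages), times = sizes)

  profile <- do.call(rbind, lapply(seq_len(n_stages), function(s) {
    idx <- stage == s
    data.frame(stage = s, marker = markers,
               median = apply(events[idx, markers, drop = FALSE], 2, stats::median),
               sd = apply(events[idx, markers, drop = FALSE], 2, stats::sd),
               n_events = sum(idx), row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(stage = stage, profile = profile, loadings = load1,
                 n_stages = n_stages, markers = markers),
            class = "maturation_path")
}

#' @export
print.maturation_path <- function(x, ...) {
  cat(sprintf("<maturation_path> %d stages over %d events, markers: %s\n",
              x$n_stages, length(x$stage), paste(x$markers, collapse = ", ")))
  invisible(x)
}

#' Merge adjacent maturation stages with identical phenotypes
#'
#' Discretizes each stage's per-marker medians with the given thresholds and
#' merges maximal runs of adjacent stages sharing the same discrete phenotype
#' code; merged stages are relabeled 1..k in pathway order. Idempotent and
#' never increases the stage count.
#'
#' @param path a \code{\link{stage_pathway}} result.
#' @param thresholds a \code{\link{threshold_set}} covering the maturation
#'   markers.
#' @return A \code{maturation_path} with merged stages; the per-stage
#'   phenotype codes are attached as \code{$codes} (character vector, one
#'   per merged stage, e.g. \code{"CD27pos CD45RAneg CD62Lpos"}).
#' @export
merge_stages <- function(path, thresholds) {
  stopifnot(inherits(path, "maturation_path"))
  missing <- setdiff(path$markers, names(thresholds$cutpoints))
  if (length(missing))
    stop_validation("threshold set lacks maturation marker(s): %s",
                    paste(missing, collapse = ", "))
  med <- matrix(NA_real_, nrow = path$n_stages, ncol = length(path$markers),
                dimnames = list(NULL, path$markers))
  for (i in seq_len(path$n_stages)) {
    p <- path$profile[path$profile$stage == i, ]
    med[i, p$marker] <- p$median
  }
  lv <- discretize(med, thresholds, markers = path$markers)
  codes <- apply(lv, 1, function(r) paste(paste0(path$markers, r), collapse = " "))
  run <- cumsum(c(TRUE, codes[-1] != codes[-length(codes)]))
  new_stage <- run[path$stage]
  k <- max(run)
  profile <- do.call(rbind, lapply(seq_len(k), function(s) {
    old <- which(run == s)
    idx <- path$stage %in% old
    sub <- path$profile[path$profile$stage %in% old, ]
    data.frame(stage = s, marker = path$markers,
               median = vapply(path$markers, function(mk)
                 stats::median(rep(sub$median[sub$marker == mk], sub$n_events[sub$marker == mk])), 0),
               sd = vapply(path$markers, function(mk)
                 mean(sub$sd[sub$marker == mk]), 0),
               n_events = sum(idx), row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(stage = new_stage, profile = profile, loadings = path$loadings,
                 n_stages = k, markers = path$markers,
                 codes = codes[!duplicated(run)]),
            class = "maturation_path")
}

#' Per-marker percentage contributions to the principal components
#'
#' Standardizes the markers, runs PCA, and reports the contribution of each
#' marker to PC1 (and PC2) as \code{100 * loading^2 / sum(loadings^2)}.
#' Contributions are non-negative, sum to 100 per component, and are
#' invariant to the arbitrary sign of the component.
#'
#' @param events numeric matrix of transformed intensities.
#' @param markers columns to analyze (default: all).
#' @return An object of class \code{contribution_report}: data.frame sorted
#'   by decreasing PC1 contribution, with eigenvalues as an attribute.
#' @export
marker_contributions <- function(events, markers = NULL) {
  markers <- markers %||% colnames(events)
  x <- events[, markers, drop = FALSE]
  if (nrow(x) < 3) stop_validation("need >= 3 events for a contribution analysis")
  sds <- apply(x, 2, stats::sd)
  # (near-)constant markers would be blown up to unit variance by the
  # standardization; exclude anything with negligible absolute variation
  # relative to the most variable marker
  cut <- max(1e-12, 1e-3 * max(sds))
  if (any(sds < cut)) {
    warning(sprintf("constant marker(s) excluded (zero/negligible variance): %s",
                    paste(markers[sds < cut], collapse = ", ")))
    markers <- markers[sds >= cut]
    x <- x[, markers, drop = FALSE]
  }
  pc <- prcomp(scale(x), center = FALSE, scale. = FALSE)
  contrib <- function(v) 100 * v^2 / sum(v^2)
  df <- data.frame(marker = markers,
                   pc1_contribution = contrib(pc$rotation[, 1]),
                   pc2_contribution = if (ncol(pc$rotation) >= 2)
                     contrib(pc$rotation[, 2]) else NA_real_,
                   row.names = NULL, stringsAsFactors = FALSE)
  df <- df[order(-df$pc1_contribution), ]
  rownames(df) <- NULL
  attr(df, "eigenvalues") <- pc$sdev^2
  class(df) <- c("contribution_report", "data.frame")
  df
}

#' Export a maturation path profile as CSV
#'
#' @param path a \code{maturation_path}.
#' @param file output CSV path.
#' @return Invisibly, \code{file}.
#' @export
export_maturation_csv <- function(path, file) {
  utils::write.csv(path$profile, file, row.names = FALSE)
  invisible(file)
}
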