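# The 14 fluorescence markers of the immune-monitoring TCD4 tube, in
# canonical channel order, plus forward/side scatter.
TCD4_MARKERS <- c("CD27", "CD45RA", "cyCD154", "CD62L", "CD127", "CD3",
                  "CD25", "CCR10", "CD183", "CD196", "CD194", "CD185",
                  "CD45", "CD4")
SCATTER_CHANNELS <- c("FSC-A", "SSC-A")
LEVELS <- c("neg", "lo", "pos", "hi")

#' The default 14-marker TCD4 panel
#'
#' Returns the panel definition used throughout the package: the 14
#' fluorescence markers of the immune-monitoring TCD4 tube (CD27, CD45RA,
#' cyCD154, CD62L, CD127, CD3, CD25, CCR10, CD183, CD196, CD194, CD185,
#' CD45, CD4) plus FSC-A/SSC-A, with a default detector mapping.
#'
#' @return An object of class \code{tcd4_panel}: data.frame with columns
#'   \code{marker}, \code{channel}, \code{type} ("scatter" or "fluorescence").
#' @examples
#' p <- default_tcd4_panel()
#' sum(p$type == "fluorescence")  # 14
#' @export
default_tcd4_panel <- function() {
  df <- data.frame(
    marker = c(SCATTER_CHANNELS, TCD4_MARKERS),
    channel = c(SCATTER_CHANNELS, sprintf("FL%d-A", seq_along(TCD4_MARKERS))),
    type = c(rep("scatter", 2), rep("fluorescence", length(TCD4_MARKERS))),
    stringsAsFactors = FALSE)
  structure(df, class = c("tcd4_panel", "data.frame"))
}

#' Construct a threshold set
#'
#' Per-marker cutpoints, in transformed units, partitioning each axis into
#' discrete expression levels: 1 cutpoint gives neg|pos, 2 give neg|lo|pos,
#' 3 give neg|lo|pos|hi. Values exactly at a cutpoint belong to the upper
#' level.
#'
#' @param cutpoints named list, marker -> strictly increasing numeric vector
#'   of 1-3 cutpoints.
#' @param provenance one of \code{"manual"}, \code{"fitted"},
#'   \code{"generator-truth"}.
#' @return An object of class \code{threshold_set}.
#' @export
threshold_set <- function(cutpoints, provenance = c("manual", "fitted", "generator-truth")) {
  provenance <- match.arg(provenance)
  for (m in names(cutpoints)) {
    cp <- cutpoints[[m]]
    if (!is.numeric(cp) || length(cp) < 1 || length(cp) > 3 || is.unsorted(cp, strictly = TRUE))
      stop_validation("cutpoints for %s must be 1-3 strictly increasing numbers", m)
  }
  structure(list(cutpoints = cutpoints, provenance = provenance),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set>", length(x$cutpoints), "markers, provenance:", x$provenance, "\n")
  invisible(x)
}

level_names_for <- function(n_cuts) {
  switch(n_cuts, c("neg", "pos"), c("neg", "lo", "pos"), c("neg", "lo", "pos", "hi"))
}

#' Fit per-marker discretization thresholds
#'
#' @param sample a transformed \code{flow_sample} with at least 500 events.
#' @param panel a \code{\link{default_tcd4_panel}}-style panel.
#' @param strategy \describe{
#'   \item{valley}{cutpoint at the minimum of a kernel density estimate
#'     between the two largest modes; falls back to \code{quantile} with a
#'     warning for unimodal channels.}
#'   \item{quantile}{configured quantile(s) of each marker.}
#'   \item{anchored}{offset above an internal negative reference (CD3-
#'     lymphocyte events) at the given quantile of the reference.}
#' }
#' @param quantiles quantiles used by the \code{quantile} strategy (default 0.5).
#' @param anchor_q reference quantile for the \code{anchored} strategy
#'   (default 0.99).
#' @return A \code{threshold_set} with provenance \code{fitted}.
#' @export
fit_thresholds <- function(sample, panel = default_tcd4_panel(),
                           strategy = c("valley", "quantile", "anchored"),
                           quantiles = 0.5, anchor_q = 0.99) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(sample, "flow_sample"))
  if (sample$transform_state != "transformed")
    stop_validation("thresholds are fitted in transformed space; transform the sample first")
  m <- marker_matrix(sample)
  if (nrow(m) < 500)
    stop_validation("need >= 500 events to fit thresholds (got %d)", nrow(m))
  markers <- intersect(panel$marker, colnames(m))
  cuts <- list()
  ref_idx <- NULL
  if (strategy == "anchored") {
    if (!"CD3" %in% colnames(m))
      stop_validation("anchored strategy needs a CD3 channel for the negative reference")
    cd3_cut <- valley_cutpoint(m[, "CD3"])
    if (is.na(cd3_cut)) cd3_cut <- stats::median(m[, "CD3"])
    ref_idx <- which(m[, "CD3"] < cd3_cut)
    if (length(ref_idx) < 50)
      stop_validation("anchored strategy: CD3- reference has too few events (%d)", length(ref_idx))
  }
  for (mk in markers) {
    x <- m[, mk]
    if (stats::sd(x) < 1e-12) {
      warning(sprintf("marker %s is constant; using its value as the cutpoint", mk))
      cuts[[mk]] <- unique(x)[1] + 1e-9
      next
    }
    cp <- switch(strategy,
      valley = {
        v <- valley_cutpoint(x)
        if (is.na(v)) {
          warning(sprintf("marker %s looks unimodal; falling back to quantile strategy", mk))
          unname(stats::quantile(x, quantiles, type = 7))
        } else v
      },
      quantile = unname(stats::quantile(x, quantiles, type = 7)),
      anchored = unname(stats::quantile(x[ref_idx], anchor_q, type = 7)))
    cuts[[mk]] <- sort(unique(cp))
  }
  threshold_set(cuts, provenance = "fitted")
}

# Deepest valley of a kernel density estimate between the two largest modes.
# NA when the channel is effectively unimodal: a genuine second mode must
# reach at least 5% of the main mode's height and the valley between the two
# must dip below 80% of the lower mode (KDE wiggles do neither).
valley_cutpoint <- function(x) {
  d <- stats::density(x, n = 512)
  y <- d$y
  is_peak <- which(diff(sign(diff(y))) == -2) + 1
  if (length(is_peak) < 2) return(NA_real_)
  top2 <- is_peak[order(y[is_peak], decreasing = TRUE)][1:2]
  h2 <- min(y[top2])
  if (h2 < 0.05 * max(y[top2])) return(NA_real_)
  between <- seq(min(top2), max(top2))
  vmin <- min(y[between])
  if (vmin > 0.8 * h2) return(NA_real_)
  d$x[between[which.min(y[between])]]
}

#' Discretize transformed events into phenotype levels
#'
#' Maps every event and marker to one of neg/lo/pos/hi using the marker's
#' cutpoints. A value exactly equal to a cutpoint is assigned to the upper
#' level. Pure and deterministic.
#'
#' @param events numeric matrix (or vector for a single event) with marker
#'   column names in transformed units.
#' @param thresholds a \code{\link{threshold_set}} covering all requested
#'   markers.
#' @param markers markers to discretize (default: all columns present in the
#'   threshold set).
#' @return Character matrix of levels (events x markers).
#' @export
discretize <- function(events, thresholds, markers = NULL) {
  if (is.null(dim(events))) events <- matrix(events, nrow = 1,
                                             dimnames = list(NULL, names(events)))
  markers <- markers %||% intersect(colnames(events), names(thresholds$cutpoints))
  missing <- setdiff(markers, names(thresholds$cutpoints))
  if (length(missing))
    stop_validation("threshold set is missing marker(s): %s", paste(missing, collapse = ", "))
  out <- matrix("", nrow = nrow(events), ncol = length(markers),
                dimnames = list(NULL, markers))
  for (mk in markers) {
    cp <- thresholds$cutpoints[[mk]]
    lv <- level_names_for(length(cp))
    # findInterval counts cutpoints <= x, so ties go to the upper level
    out[, mk] <- lv[findInterval(events[, mk], cp) + 1L]
  }
  out
}

#' Build a phenotype code
#'
#' A phenotype code maps markers to sets of acceptable discrete levels using
#' the field's notation: \code{"+"} means pos-or-hi, \code{"-"} means not
#' positive (neg-or-lo, as "negative" is read on a cytometry axis),
#' \code{"neg"}, \code{"lo"}, \code{"hi"} and \code{"pos"} the single level,
#' \code{"-/lo"} negative-or-low, and \code{"any"} (or \code{"+-"}) matches
#' every level. Markers not mentioned are unconstrained.
#'
#' @param ... marker = symbol pairs, e.g.
#'   \code{phenotype_code(CD25 = "hi", CD127 = "-/lo")}.
#' @return Named list mapping marker to a character vector of allowed levels.
#' @examples
#' phenotype_code(CD183 = "+", CD194 = "-", CD196 = "-", CCR10 = "-")  # Th1
#' @export
phenotype_code <- function(...) {
  syms <- list(...)
  lapply(syms, function(s) {
    if (is.character(s) && all(s %in% LEVELS)) return(s)
    switch(as.character(s),
      "+" = c("pos", "hi"),
      "-" = c("neg", "lo"),
      "neg" = "neg", "lo" = "lo", "pos" = "pos", "hi" = "hi",
      "-/lo" = c("neg", "lo"),
      "any" = LEVELS, "+-" = LEVELS, "pm" = LEVELS,
      stop_validation("unknown phenotype symbol '%s'", s))
  })
}

# Vectorized: which rows of a level matrix satisfy a phenotype code.
matches_code <- function(level_matrix, code) {
  ok <- rep(TRUE, nrow(level_matrix))
  for (mk in names(code)) {
    if (!mk %in% colnames(level_matrix))
      stop_validation("level matrix lacks marker %s required by a phenotype code", mk)
    ok <- ok & level_matrix[, mk] %in% code[[mk]]
  }
  ok
}

format_code <- function(code) {
  if (!length(code)) return("(any)")
  sym <- vapply(names(code), function(mk) {
    v <- code[[mk]]
    s <- if (identical(sort(v), sort(c("pos", "hi")))) "+"
      else if (identical(sort(v), sort(c("neg", "lo")))) "-"
      else if (identical(v, "neg")) "neg"
      else if (length(v) == 4) "±"
      else paste(v, collapse = "/")
    paste0(mk, s)
  }, "")
  paste(sym, collapse = "")
}

#' Serialize / deserialize a threshold set as JSON
#'
#' @param thresholds a \code{threshold_set}.
#' @param path file path.
#' @return \code{read_thresholds_json} returns a \code{threshold_set}.
#' @export
write_thresholds_json <- function(thresholds, path) {
  jsonlite::write_json(list(cutpoints = thresholds$cutpoints,
                            provenance = thresholds$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds_json
#' @export
read_thresholds_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_set(as.list(x$cutpoints), provenance = x$provenance)
}
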