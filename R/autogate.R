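# Database-guided automated gating. Labeled reference samples are pooled
# into per-population multivariate Gaussians (mean + shrinkage-regularized
# covariance in transformed space); new samples are classified top-down
# through the taxonomy by minimum Mahalanobis distance among siblings on the
# markers that discriminate at that level, subject to a maximum radius.

# markers that discriminate among a node's children = union of the markers
# constrained by the children's rules
level_markers <- function(taxonomy, node) {
  kids <- taxonomy$children[[node]]
  mks <- unique(unlist(lapply(kids, function(k) names(taxonomy$nodes[[k]]$rule))))
  mks[!vapply(mks, is.null, TRUE)]
}

#' Build a reference database from labeled samples
#'
#' Pools all events of all labeled samples per taxonomy node (a node's
#' events are those whose leaf label falls in its subtree) and stores the
#' pooled mean vector and covariance matrix over the gating markers, the
#' pooled event count and the pooled frequency (prior). Covariances are
#' regularized by shrinkage toward their diagonal:
#' \code{(1 - lambda) * S + lambda * diag(S)}.
#'
#' @param labeled list of \code{list(sample = flow_sample, labels =
#'   character)} pairs; samples must be transformed and share the panel;
#'   labels are taxonomy leaf names (or unclassified bins, which are
#'   ignored for statistics).
#' @param taxonomy a \code{\link{build_taxonomy}} tree.
#' @param lambda shrinkage weight in [0, 1) (default 0.1).
#' @param min_events minimum pooled events for a node to get statistics
#'   (default 3; smaller populations are omitted with a warning).
#' @return An object of class \code{reference_database}.
#' @export
build_reference <- function(labeled, taxonomy = build_taxonomy(), lambda = 0.1,
                            min_events = 3) {
  if (!length(labeled)) stop_validation("need at least one labeled sample")
  if (lambda < 0 || lambda >= 1) stop_validation("lambda must be in [0, 1)")
  mats <- list(); labs <- list()
  ref_cols <- NULL
  for (i in seq_along(labeled)) {
    s <- labeled[[i]]$sample
    l <- labeled[[i]]$labels
    stopifnot(inherits(s, "flow_sample"))
    if (s$transform_state != "transformed")
      stop_validation("reference sample %d is not transformed", i)
    if (length(l) != nrow(s$events))
      stop_validation("sample %d: %d labels for %d events", i, length(l), nrow(s$events))
    m <- marker_matrix(s)
    if (is.null(ref_cols)) ref_cols <- colnames(m)
    if (!identical(colnames(m), ref_cols))
      stop_validation("sample %d has a different panel/channel layout", i)
    mats[[i]] <- m; labs[[i]] <- l
  }
  all_m <- do.call(rbind, mats)
  all_l <- unlist(labs)
  gate_markers <- unique(unlist(lapply(names(taxonomy$children),
                                       function(nd) level_markers(taxonomy, nd))))
  gate_markers <- intersect(ref_cols, gate_markers)
  n_tot <- nrow(all_m)

  stats_map <- list()
  for (nm in names(taxonomy$nodes)) {
    if (taxonomy$nodes[[nm]]$virtual) next
    members <- all_l %in% descendants(taxonomy, nm)
    k <- sum(members)
    if (k < min_events) {
      if (k > 0) warning(sprintf("population '%s' has %d pooled events (< %d); stats omitted",
                                 nm, k, min_events))
      next
    }
    sub <- all_m[members, gate_markers, drop = FALSE]
    mu <- colMeans(sub)
    S <- if (k > 1) stats::cov(sub) else diag(1e-6, length(gate_markers))
    S <- (1 - lambda) * S + lambda * diag(diag(S), nrow = nrow(S))
    dimnames(S) <- list(gate_markers, gate_markers)
    stats_map[[nm]] <- list(mean = mu, cov = S, n = k, prior = k / n_tot)
  }
  structure(list(taxonomy = taxonomy, stats = stats_map, markers = gate_markers,
                 provenance = list(n_samples = length(labeled), n_events = n_tot),
                 config = list(lambda = lambda, min_events = min_events)),
            class = "reference_database")
}

#' @export
print.reference_database <- function(x, ...) {
  cat(sprintf("<reference_database> %d populations, %d pooled events from %d sample(s)\n",
              length(x$stats), x$provenance$n_events, x$provenance$n_samples))
  invisible(x)
}

mahalanobis_sq <- function(x, mu, S) {
  d <- sweep(x, 2, mu)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    S <- S + diag(1e-8 * mean(diag(S)) + 1e-12, nrow(S))
    R <- chol(S)
  }
  w <- backsolve(R, t(d), transpose = TRUE)
  structure(colSums(w^2), logdet = 2 * sum(log(diag(R))))
}

#' Database-guided automated gating
#'
#' Classifies every event of a transformed sample top-down through the
#' taxonomy: at each level, an event joins the sibling population with the
#' smallest Mahalanobis distance on that level's discriminating markers,
#' provided it lies inside the maximum-radius gate; otherwise it falls into
#' that level's unclassified bin (novelty flag). \code{max_radius} is a
#' chi-square quantile-equivalent radius: an event is gated out when its
#' squared distance on \code{m} markers exceeds the chi-square(m) quantile
#' matching the probability content of \code{max_radius} standard deviations
#' in one dimension, so the gate's false-exclusion rate does not grow with
#' the number of markers at a level. Populations
#' that end up with fewer than \code{min_cluster} events are suppressed from
#' the report but keep their counts internally, so conservation invariants
#' hold. Fully deterministic: distance ties are broken by higher prior, then
#' lexicographic population name.
#'
#' @param sample a transformed \code{flow_sample}.
#' @param db a \code{\link{build_reference}} database.
#' @param min_cluster minimum events for a population to be reported
#'   (default 10).
#' @param max_radius maximum Mahalanobis distance (default 4).
#' @return An object of class \code{autogate_result}: a
#'   \code{gating_result} plus \code{report} (counts with suppressed
#'   populations removed), \code{suppressed} (their names) and
#'   \code{novelty} (per-event logical).
#' @export
auto_gate <- function(sample, db, min_cluster = 10, max_radius = 4) {
  stopifnot(inherits(sample, "flow_sample"), inherits(db, "reference_database"))
  if (sample$transform_state != "transformed")
    stop_validation("auto_gate expects a transformed sample")
  m <- marker_matrix(sample)
  missing <- setdiff(db$markers, colnames(m))
  if (length(missing))
    stop_validation("sample lacks gating marker(s): %s", paste(missing, collapse = ", "))
  tax <- db$taxonomy
  n <- nrow(m)
  labels <- character(n)
  novelty <- logical(n)
  counts_env <- new.env(parent = emptyenv())

  assign_node <- function(node, idx) {
    assign(node, length(idx), envir = counts_env)
    kids <- tax$children[[node]]
    if (is.null(kids)) { labels[idx] <<- node; return(invisible()) }
    kids_with_stats <- kids[vapply(kids, function(k) !is.null(db$stats[[k]]), TRUE)]
    if (!length(kids_with_stats)) {
      # a database with no statistics at the root level is unusable; deeper
      # levels without reference statistics keep their events unclassified
      # (small reference populations are omitted by build_reference)
      if (node == root)
        stop_validation("reference database is empty at level '%s'", node)
      for (k in kids) assign_node(k, integer(0))
      labels[idx] <<- unclassified_label(node)
      assign(unclassified_label(node), length(idx), envir = counts_env)
      return(invisible())
    }
    mks <- intersect(level_markers(tax, node), db$markers)
    if (!length(mks)) mks <- db$markers
    # deterministic tie-break order: higher prior first, then name
    priors <- vapply(kids_with_stats, function(k) db$stats[[k]]$prior, 0)
    kord <- kids_with_stats[order(-priors, kids_with_stats)]
    if (length(idx)) {
      # Gaussian discriminant score: squared Mahalanobis distance plus
      # log|Sigma|, which penalizes broad (e.g. stage-pooled) clusters and
      # reduces to plain Mahalanobis for equal covariances and to
      # nearest-centroid under identity covariance. The radius gate applies
      # to the distance alone.
      D <- matrix(0, nrow = length(idx), ncol = length(kord))
      SC <- matrix(0, nrow = length(idx), ncol = length(kord))
      for (j in seq_along(kord)) {
        st <- db$stats[[kord[j]]]
        dsq <- mahalanobis_sq(m[idx, mks, drop = FALSE], st$mean[mks],
                              st$cov[mks, mks, drop = FALSE])
        D[, j] <- dsq
        SC[, j] <- dsq + attr(dsq, "logdet")
      }
      best <- max.col(-SC, ties.method = "first")
      bestd <- D[cbind(seq_along(idx), best)]
      gate_sq <- if (is.finite(max_radius))
        stats::qchisq(stats::pchisq(max_radius^2, df = 1), df = length(mks))
      else Inf
      inside <- bestd <= gate_sq
      novelty[idx[!inside]] <<- TRUE
      for (j in seq_along(kord)) {
        sel <- idx[inside & best == j]
        assign_node(kord[j], sel)
      }
      for (k in setdiff(kids, kord)) assign_node(k, integer(0))
      rest <- idx[!inside]
    } else {
      for (k in kids) assign_node(k, integer(0))
      rest <- integer(0)
    }
    labels[rest] <<- unclassified_label(node)
    assign(unclassified_label(node), length(rest), envir = counts_env)
  }
  root <- taxonomy_root(tax)
  assign_node(root, seq_len(n))

  counts <- gating_counts_table(tax, counts_env)
  suppressed <- counts$population[!counts$virtual &
                                    !startsWith(counts$population, "unclassified-") &
                                    counts$events > 0 & counts$events < min_cluster]
  report <- counts[!counts$population %in% suppressed, ]
  structure(list(labels = labels, counts = counts, taxonomy = tax,
                 n_events = n, report = report, suppressed = suppressed,
                 novelty = novelty,
                 config = list(min_cluster = min_cluster, max_radius = max_radius)),
            class = c("autogate_result", "gating_result"))
}

#' @export
print.autogate_result <- function(x, ...) {
  cat(sprintf("<autogate_result> %d events, %d reported populations, %d suppressed (< %d events), %d novelty events\n",
              x$n_events, sum(x$report$events > 0), length(x$suppressed),
              x$config$min_cluster, sum(x$novelty)))
  invisible(x)
}

#' Compare two gating analyses of the same sample set
#'
#' Pairs per-population percentages (of parent) from two analyses (e.g.
#' manual vs automated, or two time points) and delegates to
#' \code{\link{agreement}}: per-population r-squared across samples and mean
#' normalized bias with the concordance band.
#'
#' @param a,b \code{gating_result}s or lists thereof (the reference analysis
#'   first). Lists must be paired sample-wise.
#' @param config an \code{\link{agreement_config}}.
#' @return An \code{\link{agreement}} report.
#' @export
compare_analyses <- function(a, b, config = agreement_config()) {
  as_list <- function(x) if (inherits(x, "gating_result")) list(x) else x
  a <- as_list(a); b <- as_list(b)
  if (length(a) != length(b))
    stop_validation("paired comparison needs equally many results (%d vs %d)",
                    length(a), length(b))
  pops <- a[[1]]$counts$population
  for (r in c(a, b)) {
    if (!identical(r$counts$population, pops))
      stop_validation("gating results use different taxonomies; cannot compare")
  }
  keep <- !startsWith(pops, "unclassified-") & !a[[1]]$counts$virtual
  extract <- function(lst) {
    sapply(lst, function(r) {
      reported <- if (!is.null(r$report)) pops %in% r$report$population else rep(TRUE, length(pops))
      v <- r$counts$pct_parent
      v[!reported] <- NA_real_
      v
    })[keep, , drop = FALSE]
  }
  A <- extract(a); B <- extract(b)
  rownames(A) <- rownames(B) <- pops[keep]
  agreement(A, B, config)
}
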