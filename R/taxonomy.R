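# Hierarchical gating taxonomy for blood CD4+ T cells.
#
# Tree structure (default configuration):
#   Leukocytes (root, all events)
#     Lymphocytes            CD45 hi, SSC low
#       T cells              CD3+
#         CD4 T cells        CD4+
#           Tregs            CD25 hi, CD127 -/lo        (gated first)
#             Treg-like TFH  CD185+                     (gated before Treg subsets)
#             Naive Treg / 8 memory subsets x 4 stages
#           TFH              CD185+ among non-Treg
#             Naive TFH / 8 memory subsets x 4 stages
#           Classical Th     CD185- among non-Treg
#             Naive Th  / 8 memory subsets x 4 stages
#
# The 8 memory subsets are receptor codes on CD183/CD194/CD196/CCR10:
# Th1, Th2, Th17, Th1/Th17, Th22, two novel codes
# (CD183+CD194+CD196-CCR10- and CD183-CD194+CD196-CCR10+), and a catch-all
# other-memory bin. Maturation stages inside every memory subset follow the
# CD27/CD45RA/CD62L codes: CM = CD27+CD45RA-CD62L+, TM = CD27+CD45RA-CD62L-,
# EM = CD27-CD45RA-CD62L±, TE = CD27-CD45RA+CD62L-.

RECEPTOR_MARKERS <- c("CD183", "CD194", "CD196", "CCR10")
MATURATION_MARKERS <- c("CD27", "CD45RA", "CD62L")

memory_subset_codes <- function() {
  list(
    "Th1"      = phenotype_code(CD183 = "+", CD194 = "-", CD196 = "-", CCR10 = "-"),
    "Th2"      = phenotype_code(CD183 = "-", CD194 = "+", CD196 = "-", CCR10 = "-"),
    "Th17"     = phenotype_code(CD183 = "-", CD194 = "+", CD196 = "+", CCR10 = "-"),
    "Th1/Th17" = phenotype_code(CD183 = "+", CD194 = "-", CD196 = "+", CCR10 = "-"),
    "Th22"     = phenotype_code(CD183 = "-", CD194 = "+", CD196 = "+", CCR10 = "+"),
    "CD183+CD194+" = phenotype_code(CD183 = "+", CD194 = "+", CD196 = "-", CCR10 = "-"),
    "CD194+CCR10+" = phenotype_code(CD183 = "-", CD194 = "+", CD196 = "-", CCR10 = "+"),
    "Other-memory" = phenotype_code())
}

stage_codes <- function() {
  list(
    "CM" = phenotype_code(CD27 = "+", CD45RA = "-", CD62L = "+"),
    "TM" = phenotype_code(CD27 = "+", CD45RA = "-", CD62L = "-"),
    "EM" = phenotype_code(CD27 = "-", CD45RA = "-", CD62L = "any"),
    "TE" = phenotype_code(CD27 = "-", CD45RA = "+", CD62L = "-"))
}

naive_code <- function() {
  c(phenotype_code(CD27 = "+", CD45RA = "+", CD62L = "+"),
    phenotype_code(CD183 = "-", CD194 = "-", CD196 = "-", CCR10 = "-"))
}

#' Build the default CD4+ T-cell gating taxonomy
#'
#' Constructs the rooted gating tree described above. With the default
#' configuration the tree enumerates well over 89 reportable CD4+ T-cell
#' populations. Children of a node are evaluated in order; the first matching
#' rule wins, which realizes the sequential Treg -> TFH -> classical-Th
#' strategy. Treg-like TFH cells (CD25 hi, CD127 -/lo, CD185+) are gated
#' inside the Treg branch and mirrored as a virtual reporting node under TFH.
#'
#' @param config list of toggles: \code{stem_cell_memory} (default
#'   \code{FALSE}) adds a CD183lo/CD194lo naive-like subset under classical
#'   Th; \code{extended} (default \code{FALSE}) additionally keeps stage
#'   splits for the two novel receptor codes of the Treg and TFH branches
#'   disabled/enabled (the default tree already stages every memory subset).
#' @return An object of class \code{tcd4_taxonomy}: list with \code{nodes}
#'   (named list of node descriptors) and \code{children} (ordered child
#'   names per node).
#' @examples
#' tax <- build_taxonomy()
#' n_reportable(tax)  # >= 89
#' @export
build_taxonomy <- function(config = list()) {
  stem_cell_memory <- isTRUE(config$stem_cell_memory)
  nodes <- list()
  children <- list()
  add <- function(name, parent, rule, lineage, stage = NA_character_,
                  reportable = TRUE, virtual = FALSE, mirror_of = NA_character_) {
    if (!is.null(nodes[[name]])) stop_validation("duplicate taxonomy node name '%s'", name)
    nodes[[name]] <<- list(name = name, parent = parent, rule = rule,
                           lineage = lineage, stage = stage,
                           reportable = reportable, virtual = virtual,
                           mirror_of = mirror_of)
    if (!is.null(parent) && !virtual)
      children[[parent]] <<- c(children[[parent]], name)
    invisible(name)
  }

  add("Leukocytes", NULL, phenotype_code(), "pre-gate")
  add("Lymphocytes", "Leukocytes",
      c(phenotype_code(CD45 = "hi"), list(`SSC-A` = c("neg", "lo"))), "pre-gate")
  add("T cells", "Lymphocytes", phenotype_code(CD3 = "+"), "pre-gate")
  add("CD4 T cells", "T cells", phenotype_code(CD4 = "+"), "pre-gate")

  branches <- list(
    Tregs = list(rule = phenotype_code(CD25 = "hi", CD127 = "-/lo"), lineage = "Treg",
                 suffix = "Treg"),
    TFH = list(rule = phenotype_code(CD185 = "+"), lineage = "TFH", suffix = "TFH"),
    `Classical Th` = list(rule = phenotype_code(CD185 = "-"), lineage = "classicalTh",
                          suffix = "Th"))

  subsets <- memory_subset_codes()
  stages <- stage_codes()

  for (bname in names(branches)) {
    b <- branches[[bname]]
    add(bname, "CD4 T cells", b$rule, b$lineage)
    if (bname == "Tregs") {
      # CD185+ Tregs gated first inside the Treg branch
      add("Treg-like TFH", bname, phenotype_code(CD185 = "+"), "Treg")
    }
    if (stem_cell_memory && bname == "Classical Th") {
      # CD183lo naive-profile cells, gated before plain naive cells
      add("SCM-like Th", bname,
          c(phenotype_code(CD27 = "+", CD45RA = "+", CD62L = "+"),
            list(CD183 = "lo"), phenotype_code(CD194 = "-", CD196 = "-", CCR10 = "-")),
          b$lineage, stage = "N")
    }
    add(paste("Naive", b$suffix), bname, naive_code(), b$lineage, stage = "N")
    for (sname in names(subsets)) {
      sub_node <- paste(sname, b$suffix)
      add(sub_node, bname, subsets[[sname]], b$lineage)
      for (st in names(stages)) {
        add(paste(sub_node, st), sub_node, stages[[st]], b$lineage, stage = st)
      }
    }
  }
  # virtual reporting mirror of CD185+ Tregs under the TFH branch
  add("Treg-like TFH (TFH view)", "TFH", phenotype_code(), "TFH",
      virtual = TRUE, mirror_of = "Treg-like TFH")

  structure(list(nodes = nodes, children = children, version = "tcd4gate-1"),
            class = "tcd4_taxonomy")
}

#' Number of reportable populations in a taxonomy
#'
#' Counts the named, non-virtual, reportable nodes (unclassified bins and
#' virtual mirrors excluded).
#'
#' @param taxonomy a \code{tcd4_taxonomy}.
#' @return Integer count.
#' @export
n_reportable <- function(taxonomy) {
  sum(vapply(taxonomy$nodes, function(n) n$reportable && !n$virtual, TRUE))
}

#' @export
print.tcd4_taxonomy <- function(x, ...) {
  cat(sprintf("<tcd4_taxonomy> %s: %d nodes, %d reportable populations\n",
              x$version, length(x$nodes), n_reportable(x)))
  invisible(x)
}

taxonomy_root <- function(taxonomy) {
  for (n in taxonomy$nodes) if (is.null(n$parent)) return(n$name)
  stop_validation("taxonomy has no root")
}

# all real (non-virtual) descendants of a node, node included
descendants <- function(taxonomy, name) {
  out <- name
  kids <- taxonomy$children[[name]]
  for (k in kids) out <- c(out, descendants(taxonomy, k))
  out
}

unclassified_label <- function(node) paste0("unclassified-", node)

#' Classify events through the gating taxonomy
#'
#' Every event is discretized with the threshold set and pushed from the root
#' towards the leaves: at each node the children's phenotype rules are tried
#' in order and the first match wins; events matching no sibling stay in that
#' level's unclassified bin (label \code{unclassified-<node>}). The result
#' partitions the events exactly at every level.
#'
#' @param sample a transformed \code{flow_sample}.
#' @param thresholds a \code{\link{threshold_set}} covering all markers used
#'   by the taxonomy rules.
#' @param taxonomy a \code{\link{build_taxonomy}} tree.
#' @return An object of class \code{gating_result}: list with
#'   \code{labels} (per-event terminal label), \code{counts} (data.frame
#'   population/parent/events/pct_parent/pct_cd4), \code{taxonomy}.
#' @export
classify_events <- function(sample, thresholds, taxonomy = build_taxonomy()) {
  stopifnot(inherits(sample, "flow_sample"), inherits(thresholds, "threshold_set"))
  if (sample$transform_state != "transformed")
    stop_validation("classify_events expects a transformed sample")
  m <- marker_matrix(sample)
  used <- unique(unlist(lapply(taxonomy$nodes, function(n) names(n$rule))))
  missing <- setdiff(used, names(thresholds$cutpoints))
  if (length(missing))
    stop_validation("threshold set lacks marker(s) used by the taxonomy: %s",
                    paste(missing, collapse = ", "))
  missing_ch <- setdiff(used, colnames(m))
  if (length(missing_ch))
    stop_validation("sample lacks channel(s) used by the taxonomy: %s",
                    paste(missing_ch, collapse = ", "))
  lv <- discretize(m, thresholds, markers = used)

  n <- nrow(m)
  labels <- character(n)
  counts_env <- new.env(parent = emptyenv())
  assign_node <- function(node, idx) {
    assign(node, length(idx), envir = counts_env)
    kids <- taxonomy$children[[node]]
    if (is.null(kids)) { labels[idx] <<- node; return(invisible()) }
    remaining <- idx
    for (k in kids) {
      if (!length(remaining)) { assign(k, 0L, envir = counts_env); next }
      hit <- matches_code(lv[remaining, , drop = FALSE], taxonomy$nodes[[k]]$rule)
      assign_node(k, remaining[hit])
      remaining <- remaining[!hit]
    }
    labels[remaining] <<- unclassified_label(node)
    assign(unclassified_label(node), length(remaining), envir = counts_env)
  }
  root <- taxonomy_root(taxonomy)
  assign_node(root, seq_len(n))

  counts <- gating_counts_table(taxonomy, counts_env)
  structure(list(labels = labels, counts = counts, taxonomy = taxonomy,
                 n_events = n),
            class = "gating_result")
}

# Assemble the tidy counts table (real nodes, unclassified bins, virtual
# mirrors) with percentages of parent and of CD4 T cells.
gating_counts_table <- function(taxonomy, counts_env) {
  get0n <- function(nm) {
    v <- get0(nm, envir = counts_env, ifnotfound = 0L)
    as.integer(v)
  }
  rows <- list()
  for (nm in names(taxonomy$nodes)) {
    node <- taxonomy$nodes[[nm]]
    ev <- if (node$virtual) get0n(node$mirror_of) else get0n(nm)
    rows[[length(rows) + 1L]] <- data.frame(
      population = nm, parent = node$parent %||% NA_character_,
      events = ev, reportable = node$reportable, virtual = node$virtual,
      stringsAsFactors = FALSE)
    if (!node$virtual && !is.null(taxonomy$children[[nm]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        population = unclassified_label(nm), parent = nm,
        events = get0n(unclassified_label(nm)), reportable = TRUE, virtual = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  ev_of <- stats::setNames(df$events, df$population)
  df$pct_parent <- ifelse(is.na(df$parent) | ev_of[df$parent] == 0, NA_real_,
                          100 * df$events / ev_of[df$parent])
  cd4_total <- unname(ev_of["CD4 T cells"])
  under_cd4 <- vapply(df$population, function(p) {
    while (!is.na(p)) {
      if (p == "CD4 T cells") return(TRUE)
      node <- taxonomy$nodes[[p]]
      p <- if (is.null(node)) {
        # unclassified bin: parent encoded in the table
        df$parent[match(p, df$population)]
      } else node$parent %||% NA_character_
    }
    FALSE
  }, TRUE)
  df$pct_cd4 <- ifelse(under_cd4 & !is.na(cd4_total) & cd4_total > 0,
                       100 * df$events / cd4_total, NA_real_)
  rownames(df) <- NULL
  df
}

#' @export
print.gating_result <- function(x, ...) {
  cat(sprintf("<gating_result> %d events, %d populations\n",
              x$n_events, nrow(x$counts)))
  top <- x$counts[!x$counts$virtual & x$counts$events > 0, ]
  top <- utils::head(top[order(-top$events), c("population", "events", "pct_parent")], 8)
  print(top, row.names = FALSE)
  invisible(x)
}

#' Verify the partition invariant of a gating result
#'
#' Checks that at every node the (non-virtual) children plus the unclassified
#' bin sum exactly to the parent count.
#'
#' @param result a \code{gating_result}.
#' @return \code{TRUE} invisibly; errors otherwise.
#' @export
check_conservation <- function(result) {
  df <- result$counts
  ev <- stats::setNames(df$events, df$population)
  tax <- result$taxonomy
  for (nm in names(tax$children)) {
    kids <- tax$children[[nm]]
    s <- sum(ev[kids]) + ev[unclassified_label(nm)]
    if (s != ev[nm])
      stop_validation("event conservation violated at '%s': children sum %d != %d", nm, s, ev[nm])
  }
  invisible(TRUE)
}

#' Summarize a gating result
#'
#' Produces the tidy report: per population events, percentage of parent,
#' percentage of CD4 T cells, and (when a leukocyte concentration is given)
#' absolute counts computed as
#' \code{events / leukocyte_events * leukocyte_conc} (dual-platform rule).
#'
#' @param result a \code{gating_result}.
#' @param leukocyte_conc optional leukocyte concentration in cells/uL
#'   (must be positive).
#' @return data.frame with columns population, parent, events, pct_parent,
#'   pct_CD4, abs_count.
#' @export
summarize_gating <- function(result, leukocyte_conc = NULL) {
  stopifnot(inherits(result, "gating_result"))
  df <- result$counts
  out <- data.frame(population = df$population, parent = df$parent,
                    events = df$events, pct_parent = df$pct_parent,
                    pct_CD4 = df$pct_cd4, stringsAsFactors = FALSE)
  if (!is.null(leukocyte_conc)) {
    if (!is.numeric(leukocyte_conc) || leukocyte_conc <= 0)
      stop_validation("leukocyte concentration must be a positive number (cells/uL)")
    root_events <- df$events[match(taxonomy_root(result$taxonomy), df$population)]
    out$abs_count <- if (root_events > 0) df$events / root_events * leukocyte_conc else NA_real_
  } else {
    out$abs_count <- NA_real_
  }
  out
}

#' Export a gating result as tidy CSV files
#'
#' @param result a \code{gating_result}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @param leukocyte_conc optional cells/uL for absolute counts.
#' @return Invisibly, the paths written.
#' @export
export_gating_csv <- function(result, dir, prefix = "sample", leukocyte_conc = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(prefix, "_populations.csv"))
  p2 <- file.path(dir, paste0(prefix, "_event_labels.csv"))
  utils::write.csv(summarize_gating(result, leukocyte_conc), p1, row.names = FALSE)
  utils::write.csv(data.frame(event = seq_along(result$labels) - 1L,
                              label = result$labels), p2, row.names = FALSE)
  invisible(c(p1, p2))
}
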