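# Synthetic whole-blood sample generator with ground-truth labels.
#
# Stated world: every taxonomy leaf gets a template assigning each marker a
# discrete level; events are drawn as independent per-marker Gaussians in
# transformed space around the level anchors (neg 0.3, lo 1.0, pos 2.2,
# hi 3.2 display decades; SD 0.25), then inverse-transformed to raw
# intensities. Scatter channels live on a linear scale (anchors x 5e4).
# Non-CD4 filler populations (monocytes, CD3- lymphocytes, CD3+CD4- T
# cells) keep the pre-gating non-trivial. All randomness is seeded.

LEVEL_ANCHORS <- c(neg = 0.3, lo = 1.0, pos = 2.2, hi = 3.2)
LEVEL_CUTPOINTS <- c(0.65, 1.6, 2.7)   # midpoints between anchors
SCATTER_SCALE <- 5e4
DEFAULT_TEMPLATE_SD <- 0.25

#' Generator-truth thresholds
#'
#' The discretization cutpoints the simulator itself uses (midpoints between
#' the level anchors; scatter channels on the linear scatter scale). With
#' these thresholds and zero noise, classification recovers the generator's
#' labels exactly.
#'
#' @param panel a \code{\link{default_tcd4_panel}}.
#' @return A \code{\link{threshold_set}} with provenance
#'   \code{"generator-truth"}.
#' @export
generator_thresholds <- function(panel = default_tcd4_panel()) {
  cuts <- list()
  for (i in seq_len(nrow(panel))) {
    cuts[[panel$marker[i]]] <- if (panel$type[i] == "scatter")
      LEVEL_CUTPOINTS * SCATTER_SCALE else LEVEL_CUTPOINTS
  }
  threshold_set(cuts, provenance = "generator-truth")
}

# representative level per marker for a taxonomy node: walk the path from
# root, pick the most specific constraint; unconstrained markers are neg.
node_template_levels <- function(taxonomy, leaf, panel = default_tcd4_panel()) {
  lv <- stats::setNames(rep("neg", nrow(panel)), panel$marker)
  lv[c("FSC-A", "SSC-A")] <- c("lo", "neg")
  path <- character(0)
  p <- leaf
  while (!is.null(p)) { path <- c(p, path); p <- taxonomy$nodes[[p]]$parent }
  pick <- function(allowed) {
    if (length(allowed) == 4) return(NA_character_)    # 'any': keep current
    if ("pos" %in% allowed) return("pos")
    if ("hi" %in% allowed) return("hi")
    if ("neg" %in% allowed) return("neg")              # '-' sits at the neg anchor
    "lo"
  }
  for (nd in path) {
    rule <- taxonomy$nodes[[nd]]$rule
    for (mk in names(rule)) {
      v <- pick(rule[[mk]])
      if (!is.na(v)) lv[mk] <- v
    }
  }
  # branch-specific overrides that a single rule cannot express
  if (lv["CD25"] == "hi") lv["CD127"] <- "lo"   # Treg: CD127 -/lo -> lo
  lv
}

filler_templates <- function() {
  base <- stats::setNames(rep("neg", length(TCD4_MARKERS) + 2),
                          c(TCD4_MARKERS, "FSC-A", "SSC-A"))
  with_levels <- function(...) {
    tmpl <- base
    over <- c(...)
    tmpl[names(over)] <- over
    tmpl
  }
  list(
    "Monocytes" = with_levels(CD45 = "pos", CD4 = "lo",
                              `FSC-A` = "pos", `SSC-A` = "pos"),
    "CD3- lymphocytes" = with_levels(CD45 = "hi", `FSC-A` = "lo"),
    "CD3+CD4- T cells" = with_levels(CD45 = "hi", CD3 = "pos", `FSC-A` = "lo"))
}

# per-band frequency plan. Columns: fraction of leukocytes for the filler
# populations and CD4 T cells; branch and stage splits within CD4.
band_frequency_plan <- function(age_band) {
  plans <- list(
    "CB" = list(cd4 = 0.35, treg = 0.07, tfh = 0.005, naive = 0.90,
                memory = c(Th1 = .04, Th2 = .42, Th17 = .06, `Th1/Th17` = 0,
                           Th22 = 0, `CD183+CD194+` = .04, `CD194+CCR10+` = .04,
                           `Other-memory` = .40),
                stage = c(CM = .55, TM = .25, EM = .15, TE = .05)),
    "2mo-2y" = list(cd4 = 0.40, treg = 0.08, tfh = 0.06, naive = 0.80,
                memory = c(Th1 = .18, Th2 = .25, Th17 = .15, `Th1/Th17` = .03,
                           Th22 = .02, `CD183+CD194+` = .07, `CD194+CCR10+` = .05,
                           `Other-memory` = .25),
                stage = c(CM = .50, TM = .25, EM = .18, TE = .07)),
    "2-5y" = list(cd4 = 0.35, treg = 0.07, tfh = 0.08, naive = 0.70,
                memory = c(Th1 = .22, Th2 = .18, Th17 = .18, `Th1/Th17` = .05,
                           Th22 = .03, `CD183+CD194+` = .08, `CD194+CCR10+` = .05,
                           `Other-memory` = .21),
                stage = c(CM = .45, TM = .27, EM = .20, TE = .08)),
    "5-10y" = list(cd4 = 0.32, treg = 0.06, tfh = 0.09, naive = 0.62,
                memory = c(Th1 = .24, Th2 = .15, Th17 = .19, `Th1/Th17` = .06,
                           Th22 = .04, `CD183+CD194+` = .08, `CD194+CCR10+` = .05,
                           `Other-memory` = .19),
                stage = c(CM = .43, TM = .27, EM = .21, TE = .09)),
    "10-18y" = list(cd4 = 0.30, treg = 0.06, tfh = 0.10, naive = 0.55,
                memory = c(Th1 = .25, Th2 = .14, Th17 = .20, `Th1/Th17` = .07,
                           Th22 = .05, `CD183+CD194+` = .08, `CD194+CCR10+` = .04,
                           `Other-memory` = .17),
                stage = c(CM = .42, TM = .27, EM = .21, TE = .10)),
    "18-40y" = list(cd4 = 0.28, treg = 0.05, tfh = 0.12, naive = 0.45,
                memory = c(Th1 = .26, Th2 = .13, Th17 = .21, `Th1/Th17` = .08,
                           Th22 = .06, `CD183+CD194+` = .08, `CD194+CCR10+` = .04,
                           `Other-memory` = .14),
                stage = c(CM = .40, TM = .28, EM = .22, TE = .10)),
    "40-60y" = list(cd4 = 0.27, treg = 0.05, tfh = 0.12, naive = 0.38,
                memory = c(Th1 = .26, Th2 = .13, Th17 = .21, `Th1/Th17` = .10,
                           Th22 = .08, `CD183+CD194+` = .08, `CD194+CCR10+` = .03,
                           `Other-memory` = .11),
                stage = c(CM = .37, TM = .28, EM = .23, TE = .12)),
    "60-80y" = list(cd4 = 0.26, treg = 0.05, tfh = 0.13, naive = 0.30,
                memory = c(Th1 = .27, Th2 = .14, Th17 = .22, `Th1/Th17` = .10,
                           Th22 = .08, `CD183+CD194+` = .07, `CD194+CCR10+` = .03,
                           `Other-memory` = .09),
                stage = c(CM = .33, TM = .28, EM = .25, TE = .14)),
    "80+y" = list(cd4 = 0.25, treg = 0.05, tfh = 0.13, naive = 0.25,
                memory = c(Th1 = .29, Th2 = .14, Th17 = .22, `Th1/Th17` = .09,
                           Th22 = .07, `CD183+CD194+` = .07, `CD194+CCR10+` = .03,
                           `Other-memory` = .09),
                stage = c(CM = .30, TM = .28, EM = .26, TE = .16)))
  if (!age_band %in% names(plans))
    stop_validation("unknown age band '%s' (known: %s)", age_band,
                    paste(names(plans), collapse = ", "))
  plans[[age_band]]
}

#' Default population templates for an age band
#'
#' Builds one template per default-taxonomy leaf plus the three filler
#' populations, with age-plausible relative frequencies: cord blood is
#' naive-dominant with Th2 present and Th1/Th17, Th22 and TFH (near) zero;
#' older bands shift progressively towards memory phenotypes. The
#' frequencies are illustrative of the qualitative kinetics, not measured
#' values.
#'
#' @param age_band band label (see \code{\link{age_band_spec}}).
#' @param taxonomy the gating taxonomy the templates must cover.
#' @return data.frame with columns \code{name}, \code{frequency} and one
#'   column per panel marker holding the discrete level.
#' @export
default_templates <- function(age_band = "18-40y", taxonomy = build_taxonomy()) {
  plan <- band_frequency_plan(age_band)
  panel <- default_tcd4_panel()
  # leaves of the taxonomy (real nodes without children)
  leaves <- names(taxonomy$nodes)[vapply(names(taxonomy$nodes), function(nm)
    is.null(taxonomy$children[[nm]]) && !taxonomy$nodes[[nm]]$virtual, TRUE)]

  leaf_freq <- function(leaf) {
    branch_frac <- function(branch) switch(branch,
      "Tregs" = plan$treg, "TFH" = plan$tfh,
      "Classical Th" = 1 - plan$treg - plan$tfh)
    path <- character(0); p <- leaf
    while (!is.null(p)) { path <- c(p, path); p <- taxonomy$nodes[[p]]$parent }
    if (!"CD4 T cells" %in% path) return(NA_real_)
    f <- plan$cd4
    branch <- intersect(path, c("Tregs", "TFH", "Classical Th"))
    f <- f * branch_frac(branch)
    if (leaf == "Treg-like TFH") return(f * 0.04)
    if (branch == "Tregs") f <- f * 0.96   # remainder after Treg-like TFH
    if (grepl("^Naive", leaf)) return(f * plan$naive)
    f <- f * (1 - plan$naive)
    subset <- sub(" (Treg|TFH|Th) (CM|TM|EM|TE)$", "", leaf)
    stage <- sub("^.* ", "", leaf)
    f * unname(plan$memory[subset]) * unname(plan$stage[stage])
  }

  rows <- list()
  add_row <- function(name, freq, levels) {
    df <- data.frame(name = name, frequency = freq, stringsAsFactors = FALSE)
    for (mk in panel$marker) df[[mk]] <- unname(levels[mk])
    rows[[length(rows) + 1L]] <<- df
  }
  fills <- filler_templates()
  cd4_total <- plan$cd4
  rest <- 1 - cd4_total
  fill_freq <- c(Monocytes = 0.45, `CD3- lymphocytes` = 0.30,
                 `CD3+CD4- T cells` = 0.25) * rest
  for (nm in names(fills)) add_row(nm, unname(fill_freq[nm]), fills[[nm]])
  for (leaf in leaves) {
    f <- leaf_freq(leaf)
    if (is.na(f)) next
    add_row(leaf, f, node_template_levels(taxonomy, leaf, panel))
  }
  out <- do.call(rbind, rows)
  out$frequency <- out$frequency / sum(out$frequency)  # exact normalization
  out
}

#' Specification of one synthetic sample
#'
#' @param n_events number of events (>= 1).
#' @param age_band band label driving the default templates.
#' @param templates template table (default
#'   \code{\link{default_templates}(age_band)}).
#' @param seed mandatory integer seed; the same spec always reproduces the
#'   sample bit-for-bit.
#' @param noise_scale multiplier on the per-marker SD (0 puts every event
#'   exactly on its template anchors).
#' @param leukocyte_conc leukocyte concentration in cells/uL carried in the
#'   sample metadata.
#' @param transform the \code{\link{transform_spec}} whose inverse maps
#'   anchor space to raw intensities.
#' @param spillover optional synthetic spillover matrix to mix into the raw
#'   fluorescence data (stored in the sample so compensation can undo it).
#' @return A \code{sample_spec} list.
#' @export
sample_spec <- function(n_events, age_band = "18-40y", templates = NULL,
                        seed, noise_scale = 1, leukocyte_conc = 6000,
                        transform = transform_spec("logicle"),
                        spillover = NULL) {
  if (missing(seed) || is.null(seed))
    stop_validation("a seed is mandatory: the simulator has no unseeded randomness")
  if (n_events < 1) stop_validation("n_events must be >= 1")
  templates <- templates %||% default_templates(age_band)
  if (sum(templates$frequency) > 1 + 1e-9)
    stop_validation("template frequencies sum to %.4f > 1", sum(templates$frequency))
  structure(list(n_events = as.integer(n_events), age_band = age_band,
                 templates = templates, seed = as.integer(seed),
                 noise_scale = noise_scale, leukocyte_conc = leukocyte_conc,
                 transform = transform, spillover = spillover),
            class = "sample_spec")
}

#' Simulate one whole-blood sample
#'
#' Draws population sizes from a multinomial over the template frequencies,
#' then per-marker independent Gaussians in transformed space (mean = level
#' anchor, SD = 0.25 x \code{noise_scale}), inverse-transforms fluorescence
#' channels to raw intensities (scatter stays linear), and optionally mixes
#' in a synthetic spillover. Ground-truth leaf labels and the generator's
#' thresholds ride along.
#'
#' @param spec a \code{\link{sample_spec}}.
#' @return A \code{synthetic_sample}: list with \code{sample} (raw-space
#'   \code{flow_sample}), \code{labels} (ground-truth per event),
#'   \code{thresholds} (generator truth), \code{spec}.
#' @export
simulate_sample <- function(spec) {
  stopifnot(inherits(spec, "sample_spec"))
  set.seed(spec$seed)
  panel <- default_tcd4_panel()
  tpl <- spec$templates
  missing_cols <- setdiff(panel$marker, colnames(tpl))
  if (length(missing_cols))
    stop_validation("template table lacks marker column(s): %s (beware name mangling by data.frame operations)",
                    paste(missing_cols, collapse = ", "))
  n <- spec$n_events
  which_tpl <- sample.int(nrow(tpl), n, replace = TRUE, prob = tpl$frequency)
  mat <- matrix(0, nrow = n, ncol = nrow(panel),
                dimnames = list(NULL, panel$marker))
  sd_base <- DEFAULT_TEMPLATE_SD * spec$noise_scale
  for (j in seq_len(nrow(panel))) {
    mk <- panel$marker[j]
    anchors <- LEVEL_ANCHORS[tpl[[mk]][which_tpl]]
    scale_f <- if (panel$type[j] == "scatter") SCATTER_SCALE else 1
    noise <- if (sd_base > 0) stats::rnorm(n, 0, sd_base) else 0
    mat[, j] <- (anchors + noise) * scale_f
  }
  # to raw space: invert the transform on fluorescence channels
  raw <- mat
  fl <- panel$type == "fluorescence"
  for (j in which(fl)) raw[, j] <- tf_inverse(spec$transform, mat[, j])
  if (!is.null(spec$spillover)) {
    sp <- as.matrix(spec$spillover)
    dets <- colnames(sp)
    raw_dets <- panel$channel[match(dets, panel$marker)]
    raw[, match(dets, panel$marker)] <-
      raw[, match(dets, panel$marker), drop = FALSE] %*% sp
  }
  channels <- data.frame(index = seq_len(nrow(panel)),
                         short_name = panel$channel,
                         marker = ifelse(panel$type == "scatter", "", panel$marker),
                         range = 262144, stringsAsFactors = FALSE)
  # scatter channels: short_name == marker name used in rules
  spill_mat <- NULL
  if (!is.null(spec$spillover)) {
    sp <- as.matrix(spec$spillover)
    dn <- panel$channel[match(colnames(sp), panel$marker)]
    dimnames(sp) <- list(dn, dn)
    spill_mat <- sp
  }
  fs <- flow_sample(raw, channels, spillover = spill_mat,
                    transform_state = "raw",
                    metadata = list(sample_id = sprintf("sim-%d", spec$seed),
                                    age_band = spec$age_band,
                                    leukocyte_conc = spec$leukocyte_conc))
  structure(list(sample = fs, labels = tpl$name[which_tpl],
                 thresholds = generator_thresholds(panel), spec = spec),
            class = "synthetic_sample")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf("<synthetic_sample> %d events, band %s, seed %d, %d template populations\n",
              x$spec$n_events, x$spec$age_band, x$spec$seed, nrow(x$spec$templates)))
  invisible(x)
}

#' Prepare a synthetic sample for gating
#'
#' Convenience: compensates (when a spillover was simulated) and transforms
#' the raw synthetic sample with the spec's own transform, returning it in
#' the same transformed space the generator used.
#'
#' @param synth a \code{\link{simulate_sample}} result.
#' @return A transformed \code{flow_sample}.
#' @export
prepare_synthetic <- function(synth) {
  s <- synth$sample
  if (!is.null(s$spillover)) s <- compensate(s)
  transform_sample(s, synth$spec$transform)
}

#' Simulate a cohort of samples across age bands
#'
#' Generates independent samples with derived seeds (\code{base_seed + i})
#' and per-sample leukocyte concentrations from a log-normal distribution.
#'
#' @param age_distribution data.frame with columns \code{band},
#'   \code{n_samples}, or a named vector band -> n.
#' @param base_seed integer seed.
#' @param n_events events per sample (default 20000).
#' @param conc_meanlog,conc_sdlog log-normal parameters of the leukocyte
#'   concentration in cells/uL (defaults log(6000), 0.25).
#' @return List of \code{synthetic_sample}s.
#' @export
simulate_cohort <- function(age_distribution, base_seed, n_events = 20000,
                            conc_meanlog = log(6000), conc_sdlog = 0.25) {
  if (missing(base_seed)) stop_validation("base_seed is mandatory")
  if (!is.data.frame(age_distribution))
    age_distribution <- data.frame(band = names(age_distribution),
                                   n_samples = as.integer(age_distribution))
  if (any(age_distribution$n_samples < 1))
    stop_validation("n_samples must be >= 1 for every band")
  out <- list()
  i <- 0
  for (r in seq_len(nrow(age_distribution))) {
    band <- age_distribution$band[r]
    band_frequency_plan(band)  # validates the label
    for (k in seq_len(age_distribution$n_samples[r])) {
      i <- i + 1
      set.seed(base_seed + i)
      conc <- stats::rlnorm(1, conc_meanlog, conc_sdlog)
      spec <- sample_spec(n_events, age_band = band, seed = base_seed + i,
                          leukocyte_conc = conc)
      out[[i]] <- simulate_sample(spec)
    }
  }
  out
}

#' Simulate events along a continuous maturation trajectory
#'
#' Draws a latent maturation coordinate u ~ Uniform(0, 1) per event and
#' maps it to smooth CD27/CD45RA/CD62L expression profiles (CD45RA high at
#' the naive end, CD27 lost late, CD62L declining), plus Gaussian channel
#' noise — the stated world for validating the PCA staging against a known
#' ordering.
#'
#' @param n_events number of events.
#' @param seed mandatory seed.
#' @param noise SD of the channel noise (default 0.25).
#' @return List with \code{events} (matrix), \code{latent} (u per event).
#' @export
simulate_maturation_trajectory <- function(n_events, seed, noise = 0.25) {
  if (missing(seed)) stop_validation("seed is mandatory")
  set.seed(seed)
  u <- stats::runif(n_events)
  hi <- LEVEL_ANCHORS["pos"]; lo <- LEVEL_ANCHORS["neg"]
  ramp <- function(x) pmin(pmax(x, 0), 1)
  cd45ra <- hi - (hi - lo) * ramp(u / 0.4)          # lost early
  cd62l  <- hi - (hi - lo) * ramp((u - 0.2) / 0.5)  # lost mid
  cd27   <- hi - (hi - lo) * ramp((u - 0.5) / 0.4)  # lost late
  ev <- cbind(CD27 = cd27, CD45RA = cd45ra, CD62L = cd62l) +
    matrix(stats::rnorm(3 * n_events, 0, noise), ncol = 3)
  list(events = ev, latent = u)
}
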