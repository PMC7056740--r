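# Agreement metrics, canonical variates, reference intervals, profile
# flagging, group comparison, and the stain-index QC utility.

#' Agreement configuration
#'
#' Thresholds of the concordance criterion: a population is concordant when
#' its squared Pearson correlation across samples is at least \code{r2_min}
#' with p-value at most \code{p_max}, and its mean normalized bias lies
#' within \code{±mnb_band} percent.
#'
#' @param r2_min minimum r-squared (default 0.9).
#' @param mnb_band MNB half-width in percent (default 15).
#' @param p_max maximum correlation p-value (default 0.05).
#' @return An \code{agreement_config} object.
#' @export
agreement_config <- function(r2_min = 0.9, mnb_band = 15, p_max = 0.05) {
  if (r2_min <= 0 || r2_min > 1) stop_validation("r2_min must be in (0, 1]")
  if (mnb_band <= 0) stop_validation("mnb_band must be positive")
  structure(list(r2_min = r2_min, mnb_band = mnb_band, p_max = p_max),
            class = "agreement_config")
}

#' Agreement between two paired analyses
#'
#' For every population, computes across paired samples the squared Pearson
#' correlation (with its p-value) between the reference analysis \code{a}
#' and the comparison analysis \code{b}, and the mean normalized bias
#' \code{MNB = mean(100 * (b - a) / a)} (pairs with \code{a == 0} are
#' excluded with a warning, as the bias is undefined there). Populations
#' missing (NA) in either analysis for some sample are reported separately
#' as "not identified" in those pairs and excluded from the metrics.
#'
#' @param a,b numeric matrices (populations x samples) of paired
#'   non-negative values, \code{a} being the reference; named vectors are
#'   accepted for single-sample comparisons (r-squared is then NA).
#' @param config an \code{\link{agreement_config}}.
#' @return An \code{agreement_report}: data.frame with per-population
#'   \code{r2}, \code{p_value}, \code{mnb}, \code{n_pairs},
#'   \code{n_not_identified}, \code{concordant}; the fraction of concordant
#'   populations is attached as attribute \code{summary}.
#' @export
agreement <- function(a, b, config = agreement_config()) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 1, dimnames = list(names(a), NULL))
  if (is.null(dim(b))) b <- matrix(b, ncol = 1, dimnames = list(names(b), NULL))
  if (!identical(dim(a), dim(b)))
    stop_validation("a and b must have identical dimensions")
  pops <- rownames(a) %||% paste0("pop", seq_len(nrow(a)))
  zero_ref <- FALSE
  rows <- lapply(seq_len(nrow(a)), function(i) {
    av <- a[i, ]; bv <- b[i, ]
    ok <- !is.na(av) & !is.na(bv)
    n_missing <- sum(!ok)
    av <- av[ok]; bv <- bv[ok]
    nz <- av != 0
    if (any(!nz)) zero_ref <<- TRUE
    mnb <- if (sum(nz) >= 1) mean(100 * (bv[nz] - av[nz]) / av[nz]) else NA_real_
    if (length(av) >= 3 && stats::sd(av) > 0 && stats::sd(bv) > 0) {
      ct <- stats::cor.test(av, bv, method = "pearson")
      r2 <- unname(ct$estimate^2); pv <- ct$p.value
    } else if (length(av) >= 2 && stats::sd(av) > 0 && stats::sd(bv) > 0) {
      r2 <- unname(stats::cor(av, bv)^2); pv <- NA_real_
    } else if (length(av) >= 2 && isTRUE(all.equal(av, bv))) {
      r2 <- 1; pv <- 0  # identical vectors agree perfectly even if constant
    } else {
      r2 <- NA_real_; pv <- NA_real_
    }
    concordant <- !is.na(mnb) && abs(mnb) <= config$mnb_band &&
      !is.na(r2) && r2 >= config$r2_min && !is.na(pv) && pv <= config$p_max
    data.frame(population = pops[i], r2 = r2, p_value = pv, mnb = mnb,
               n_pairs = length(av), n_not_identified = n_missing,
               concordant = concordant, stringsAsFactors = FALSE)
  })
  if (zero_ref)
    warning("pairs with a zero reference value were excluded from the MNB")
  df <- do.call(rbind, rows)
  evaluable <- !is.na(df$mnb)
  attr(df, "summary") <- list(
    n_populations = nrow(df),
    n_concordant = sum(df$concordant),
    fraction_concordant = if (any(evaluable)) sum(df$concordant) / sum(evaluable) else NA_real_)
  attr(df, "config") <- config
  class(df) <- c("agreement_report", "data.frame")
  df
}

#' Canonical variate (Fisher discriminant) analysis
#'
#' Computes Fisher discriminant axes from the between-group and within-group
#' scatter of standardized markers and reports each marker's percentage
#' contribution to CA1 as \code{100 * loading^2 / sum(loadings^2)}, together
#' with group projections and centroids. A singular within-group scatter is
#' regularized by shrinkage toward its diagonal with a message.
#'
#' @param values numeric matrix of observations x markers.
#' @param groups group label per observation (>= 2 groups, each >= 2
#'   observations).
#' @param markers columns to use (default all).
#' @return A \code{canonical_variate_report}: list with \code{contributions}
#'   (data.frame, sorted), \code{loadings}, \code{scores},
#'   \code{centroids}, \code{eigenvalues}.
#' @export
canonical_variates <- function(values, groups, markers = NULL) {
  markers <- markers %||% colnames(values)
  x <- as.matrix(values[, markers, drop = FALSE])
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop_validation("need >= 2 groups")
  if (any(table(groups) < 2)) stop_validation("every group needs >= 2 observations")
  z <- scale(x)
  # guard constant markers
  z[, attr(z, "scaled:scale") < 1e-12] <- 0
  p <- ncol(z)
  mu <- colMeans(z)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (g in levels(groups)) {
    zg <- z[groups == g, , drop = FALSE]
    mg <- colMeans(zg)
    W <- W + crossprod(sweep(zg, 2, mg))
    B <- B + nrow(zg) * tcrossprod(mg - mu)
  }
  if (sum(diag(B)) < 1e-10)
    warning("between-group scatter is (near) zero: groups are indistinguishable")
  lambda <- 1e-8 * mean(diag(W)) + 1e-12
  if (rcond(W) < 1e-10) {
    message("within-group scatter is ill-conditioned; applying diagonal shrinkage")
    W <- 0.9 * W + 0.1 * diag(diag(W), p)
  }
  W <- W + diag(lambda, p)
  eig <- eigen(solve(W, B))
  ord <- order(-Re(eig$values))
  vecs <- Re(eig$vectors[, ord, drop = FALSE])
  vals <- Re(eig$values[ord])
  k <- min(nlevels(groups) - 1, p)
  vecs <- vecs[, seq_len(k), drop = FALSE]
  rownames(vecs) <- markers
  contrib <- 100 * vecs[, 1]^2 / sum(vecs[, 1]^2)
  df <- data.frame(marker = markers, ca1_contribution = contrib,
                   row.names = NULL, stringsAsFactors = FALSE)
  df <- df[order(-df$ca1_contribution), ]
  rownames(df) <- NULL
  scores <- z %*% vecs
  centroids <- apply(scores, 2, function(s) tapply(s, groups, mean))
  structure(list(contributions = df, loadings = vecs, scores = scores,
                 centroids = centroids, eigenvalues = vals[seq_len(k)]),
            class = "canonical_variate_report")
}

#' Age band specification
#'
#' Ordered, non-overlapping age bands covering 0-120 years, plus a cord
#' blood (CB) band as a special pre-birth label. The default bands anchor
#' the breakpoints at 2 months, 2, 5, 10, 18, 40, 60 and 80 years.
#'
#' @param bands data.frame with columns \code{label}, \code{low},
#'   \code{high} (ages in years, intervals \code{[low, high)}); the CB band
#'   carries NA bounds.
#' @return An \code{age_band_spec}.
#' @export
age_band_spec <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- data.frame(
      label = c("CB", "2mo-2y", "2-5y", "5-10y", "10-18y",
                "18-40y", "40-60y", "60-80y", "80+y"),
      low  = c(NA, 2 / 12, 2, 5, 10, 18, 40, 60, 80),
      high = c(NA, 2, 5, 10, 18, 40, 60, 80, 120),
      stringsAsFactors = FALSE)
  }
  ab <- bands[!is.na(bands$low), ]
  if (any(diff(ab$low) <= 0) || any(ab$high <= ab$low))
    stop_validation("age bands must be ordered and non-overlapping")
  if (nrow(ab) > 1 && any(abs(ab$high[-nrow(ab)] - ab$low[-1]) > 1e-9))
    stop_validation("age bands must be contiguous")
  structure(bands, class = c("age_band_spec", "data.frame"))
}

#' Map ages to band labels
#'
#' @param ages numeric ages in years, or the string \code{"CB"} for cord
#'   blood entries (mixed character vectors are accepted).
#' @param bands an \code{\link{age_band_spec}}.
#' @return Character vector of band labels.
#' @export
age_to_band <- function(ages, bands = age_band_spec()) {
  out <- character(length(ages))
  isCB <- ages == "CB"
  out[isCB] <- "CB"
  num <- suppressWarnings(as.numeric(ages[!isCB]))
  if (anyNA(num)) stop_validation("ages must be numeric years or 'CB'")
  if (any(num < 0)) stop_validation("negative ages are invalid")
  ab <- bands[!is.na(bands$low), ]
  idx <- findInterval(num, c(ab$low, utils::tail(ab$high, 1)))
  bad <- idx < 1 | idx > nrow(ab)
  if (any(bad))
    stop_validation("age(s) outside all bands: %s (bands cover [%g, %g))",
                    paste(num[bad], collapse = ", "), min(ab$low), max(ab$high))
  out[!isCB] <- ab$label[idx]
  out
}

#' Age-banded percentile reference intervals
#'
#' Computes, per population and age band, the order statistics of absolute
#' counts: n, min, p10, p25, p50, p75, p90, max (or any percentile list),
#' using linear interpolation between order statistics (the type-7
#' convention, the R default). Bands with fewer than \code{min_n} samples
#' are flagged.
#'
#' @param cohort data.frame with columns \code{sample_id}, \code{age}
#'   (years or "CB"), \code{population}, \code{count}.
#' @param bands an \code{\link{age_band_spec}}.
#' @param percentiles percentile probabilities (default
#'   \code{c(.10, .25, .50, .75, .90)}).
#' @param min_n per-band sample count below which the cell is flagged
#'   (default 10).
#' @return A \code{reference_interval_table}: data.frame with one row per
#'   population x band.
#' @export
reference_intervals <- function(cohort, bands = age_band_spec(),
                                percentiles = c(.10, .25, .50, .75, .90),
                                min_n = 10) {
  need <- c("sample_id", "age", "population", "count")
  if (!all(need %in% names(cohort)))
    stop_validation("cohort table needs columns: %s", paste(need, collapse = ", "))
  cohort$band <- age_to_band(cohort$age, bands)
  pn <- paste0("p", formatC(100 * percentiles, format = "fg"))
  rows <- list()
  for (b in unique(bands$label)) {
    sub_b <- cohort[cohort$band == b, ]
    if (!nrow(sub_b)) next
    for (pop in unique(sub_b$population)) {
      v <- sub_b$count[sub_b$population == pop]
      q <- stats::quantile(v, percentiles, type = 7, names = FALSE)
      row <- data.frame(population = pop, band = b, n = length(v),
                        min = min(v), stringsAsFactors = FALSE)
      for (j in seq_along(pn)) row[[pn[j]]] <- q[j]
      row$max <- max(v)
      row$low_n <- length(v) < min_n
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) stop_validation("no cohort samples fell into any band")
  out <- do.call(rbind, rows)
  attr(out, "percentiles") <- percentiles
  attr(out, "bands") <- bands
  class(out) <- c("reference_interval_table", "data.frame")
  out
}

#' Flag a patient profile against reference intervals
#'
#' Each population count is flagged \code{low} when below the band's p10,
#' \code{high} when above its p90, \code{normal} otherwise; the band sample
#' size is attached for interpretability.
#'
#' @param patient data.frame with columns \code{population}, \code{count}.
#' @param age patient age in years (or "CB").
#' @param intervals a \code{\link{reference_intervals}} table.
#' @return data.frame with columns population, count, band, band_n, p10,
#'   p90, flag.
#' @export
flag_profile <- function(patient, age, intervals) {
  bands <- attr(intervals, "bands") %||% age_band_spec()
  band <- age_to_band(age, bands)
  ref <- intervals[intervals$band == band, ]
  if (!nrow(ref))
    stop_validation("no reference intervals for band '%s' (bands present: %s)",
                    band, paste(unique(intervals$band), collapse = ", "))
  i <- match(patient$population, ref$population)
  p10 <- ref$p10[i]; p90 <- ref$p90[i]
  flag <- ifelse(is.na(i), NA_character_,
                 ifelse(patient$count < p10, "low",
                        ifelse(patient$count > p90, "high", "normal")))
  data.frame(population = patient$population, count = patient$count,
             band = band, band_n = ref$n[i], p10 = p10, p90 = p90,
             flag = flag, stringsAsFactors = FALSE)
}

#' Mann-Whitney U test (exact for small samples)
#'
#' Computes the Mann-Whitney U statistic and a two-sided p-value. For small
#' groups the p-value is exact: without ties via the classical null
#' distribution of U, with ties via full enumeration of all
#' \code{choose(n1+n2, n1)} group assignments when that is feasible
#' (<= \code{2e5} arrangements). Otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param alpha significance level (default 0.05).
#' @return A list with \code{U} (for group \code{a}), \code{p_value},
#'   \code{method}, \code{significant}.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  if (!length(a) || !length(b)) stop_validation("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  method <- NULL; p <- NULL
  if (!ties && max(n1, n2) <= 20) {
    pl <- stats::pwilcox(U, n1, n2)
    pu <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(pl, pu))
    method <- "exact (no ties)"
  } else if (choose(n1 + n2, n1) <= 2e5) {
    combs <- utils::combn(n1 + n2, n1)
    u_all <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
    pl <- mean(u_all <= U); pu <- mean(u_all >= U)
    p <- min(1, 2 * min(pl, pu))
    method <- "exact (enumeration)"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / ((n1 + n2) * (n1 + n2 - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - tie_corr))
    if (sigma == 0) { p <- 1 } else {
      zval <- (U - mu - sign(U - mu) * 0.5) / sigma
      p <- 2 * stats::pnorm(-abs(zval))
    }
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U, p_value = p, method = method, significant = p < alpha)
}

#' Stain index of a reagent
#'
#' \code{SI = (median(pos) - median(neg)) / (2 * sd(neg))} on raw
#' (untransformed) intensities — the separation metric used to rank
#' candidate antibody conjugates.
#'
#' @param pos_values intensities of the positive population.
#' @param neg_values intensities of the negative population.
#' @return The stain index (scalar).
#' @examples
#' stain_index(rnorm(100, 300, 50), rnorm(100, 100, 50))
#' @export
stain_index <- function(pos_values, neg_values) {
  if (!length(pos_values) || !length(neg_values))
    stop_validation("both populations must be non-empty")
  s <- stats::sd(neg_values)
  if (!is.finite(s) || s == 0)
    stop_numerical("stain index undefined: negative population has zero SD")
  (stats::median(pos_values) - stats::median(neg_values)) / (2 * s)
}
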