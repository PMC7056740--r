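test_that("the default taxonomy enumerates at least 89 reportable populations", {
  tax <- build_taxonomy()
  expect_gte(n_reportable(tax), 89)
  nodes <- names(tax$nodes)
  # the three major branches under CD4 T cells, gated sequentially
  expect_identical(tax$children[["CD4 T cells"]], c("Tregs", "TFH", "Classical Th"))
  # novel receptor-code subsets present under classical Th
  expect_true(all(c("CD183+CD194+ Th", "CD194+CCR10+ Th") %in% nodes))
  # Treg-like TFH inside the Treg branch, mirrored virtually under TFH
  expect_identical(tax$children[["Tregs"]][1], "Treg-like TFH")
  expect_true(tax$nodes[["Treg-like TFH (TFH view)"]]$virtual)
})

test_that("maturation stage rules carry the canonical marker codes", {
  tax <- build_taxonomy()
  rule_of <- function(n) tax$nodes[[n]]$rule
  cm <- rule_of("Th1 Th CM")
  expect_setequal(cm$CD27, c("pos", "hi"))
  expect_setequal(cm$CD45RA, c("neg", "lo"))
  expect_setequal(cm$CD62L, c("pos", "hi"))
  tm <- rule_of("Th1 Th TM")
  expect_setequal(tm$CD62L, c("neg", "lo"))
  em <- rule_of("Th1 Th EM")
  expect_length(em$CD62L, 4)                     # the "±" of effector memory
  expect_setequal(em$CD27, c("neg", "lo"))
  te <- rule_of("Th1 Th TE")
  expect_setequal(te$CD45RA, c("pos", "hi"))
  # naive requires all four chemokine receptors negative
  nv <- rule_of("Naive Th")
  for (mk in c("CD183", "CD194", "CD196", "CCR10"))
    expect_setequal(nv[[mk]], c("neg", "lo"))
})

test_that("classification routes phenotypes along the sequential strategy", {
  tax <- build_taxonomy()
  thr <- generator_thresholds()
  mk <- names(thr$cutpoints)
  base <- setNames(rep(0.3, length(mk)), mk)
  base[c("FSC-A", "SSC-A")] <- c(1.0, 0.3) * 5e4
  mkev <- function(...) {
    v <- base; ov <- c(...); v[names(ov)] <- ov
    matrix(v, 1, dimnames = list(NULL, mk))
  }
  ch <- data.frame(index = seq_along(mk), short_name = mk, marker = "",
                   range = 262144)
  classify1 <- function(ev) {
    s <- flow_sample(ev, ch, transform_state = "transformed")
    classify_events(s, thr, tax)$labels
  }
  # CD45 hi, CD3+, CD4+, CD25 hi, CD127 lo -> Treg branch
  treg <- classify1(mkev(CD45 = 3.2, CD3 = 2.2, CD4 = 2.2, CD25 = 3.2, CD127 = 1.0))
  expect_match(treg, "Treg")
  # same but CD185+ -> Treg-like TFH
  tltfh <- classify1(mkev(CD45 = 3.2, CD3 = 2.2, CD4 = 2.2, CD25 = 3.2,
                          CD127 = 0.3, CD185 = 2.2))
  expect_identical(tltfh, "Treg-like TFH")
  # CD3- event stops at the T-cell gate, never reaches a CD4 subset
  nonT <- classify1(mkev(CD45 = 3.2, CD3 = 0.3, CD4 = 2.2))
  expect_identical(nonT, "unclassified-Lymphocytes")
  # classical Th1 effector memory
  th1em <- classify1(mkev(CD45 = 3.2, CD3 = 2.2, CD4 = 2.2, CD127 = 2.2,
                          CD183 = 2.2, CD27 = 0.3, CD45RA = 0.3))
  expect_identical(th1em, "Th1 Th EM")
})

test_that("noise-free synthetic events are recovered 100% with generator truth", {
  synth <- simulate_sample(sample_spec(10000, seed = 7, noise_scale = 0))
  s <- prepare_synthetic(synth)
  res <- classify_events(s, synth$thresholds)
  cd4 <- !synth$labels %in% FILLER_NAMES
  expect_identical(res$labels[cd4], synth$labels[cd4])
  # fillers never reach a CD4 subset
  expect_true(all(startsWith(res$labels[!cd4], "unclassified-")))
  # per-population counts equal the generator's planned counts exactly
  planned <- table(synth$labels[cd4])
  got <- setNames(res$counts$events, res$counts$population)[names(planned)]
  expect_equal(unname(got), unname(as.integer(planned)))
})

test_that("events partition exactly at every tree level (conservation)", {
  synth <- simulate_sample(sample_spec(15000, seed = 31))  # noisy
  res <- classify_events(prepare_synthetic(synth), synth$thresholds)
  expect_true(check_conservation(res))
  df <- res$counts
  ev <- setNames(df$events, df$population)
  tax <- res$taxonomy
  for (nm in names(tax$children)) {
    kids <- tax$children[[nm]]
    expect_identical(unname(sum(ev[kids]) + ev[[paste0("unclassified-", nm)]]),
                     ev[[nm]], info = nm)
    # children percentages sum to 100% of the parent
    if (ev[[nm]] > 0) {
      pct <- df$pct_parent[df$parent %in% nm & !df$virtual]
      expect_equal(sum(pct), 100, info = nm)
    }
  }
  expect_equal(ev[["Leukocytes"]], 15000)
})

test_that("classification is deterministic", {
  synth <- simulate_sample(sample_spec(5000, seed = 13))
  s <- prepare_synthetic(synth)
  r1 <- classify_events(s, synth$thresholds)
  r2 <- classify_events(s, synth$thresholds)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$counts, r2$counts)
})

test_that("summaries compute percentages and dual-platform absolute counts", {
  synth <- simulate_sample(sample_spec(5000, seed = 17, noise_scale = 0))
  res <- classify_events(prepare_synthetic(synth), synth$thresholds)
  sm <- summarize_gating(res, leukocyte_conc = 6000)
  # hand oracle: population events / leukocyte events * concentration
  i <- match("CD4 T cells", sm$population)
  expect_equal(sm$abs_count[i], sm$events[i] / 5000 * 6000)
  expect_error(summarize_gating(res, leukocyte_conc = -1), "positive",
               class = "tcd4_validation_error")
})

test_that("an empty sample yields zero counts and flagged percentages", {
  panel <- default_tcd4_panel()
  ch <- data.frame(index = seq_len(nrow(panel)), short_name = panel$channel,
                   marker = ifelse(panel$type == "scatter", "", panel$marker),
                   range = 262144)
  empty <- flow_sample(matrix(numeric(0), 0, nrow(panel)), ch,
                       transform_state = "transformed")
  res0 <- classify_events(empty, generator_thresholds())
  expect_true(all(res0$counts$events == 0))
  sm <- summarize_gating(res0)
  expect_true(all(is.na(sm$pct_parent)))
  expect_true(check_conservation(res0))
})

test_that("gating results export as tidy CSV", {
  synth <- simulate_sample(sample_spec(2000, seed = 19))
  res <- classify_events(prepare_synthetic(synth), synth$thresholds)
  d <- withr::local_tempdir()
  paths <- export_gating_csv(res, d, prefix = "s1", leukocyte_conc = 5500)
  pops <- read.csv(paths[1])
  expect_true(all(c("population", "parent", "events", "pct_parent",
                    "pct_CD4", "abs_count") %in% names(pops)))
  expect_gte(sum(!startsWith(pops$population, "unclassified-")), 89)
  labs <- read.csv(paths[2])
  expect_equal(nrow(labs), 2000)
  expect_equal(labs$event[1], 0)  # event indexing is 0-based in reports
})
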