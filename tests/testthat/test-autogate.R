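test_that("pooled reference statistics match the concatenate-and-average oracle", {
  tax <- build_taxonomy()
  sy1 <- simulate_sample(sample_spec(4000, seed = 61))
  sy2 <- simulate_sample(sample_spec(6000, seed = 62))
  s1 <- prepare_synthetic(sy1); s2 <- prepare_synthetic(sy2)
  # single sample: population means equal that sample's per-population means
  db1 <- suppressWarnings(build_reference(list(list(sample = s1, labels = sy1$labels)), tax))
  m1 <- marker_matrix(s1)
  members <- sy1$labels == "Naive Th"
  expect_equal(db1$stats[["Naive Th"]]$mean,
               colMeans(m1[members, db1$markers]))
  expect_equal(db1$stats[["Naive Th"]]$n, sum(members))

  # two samples: pooled mean = (n1 m1 + n2 m2) / (n1 + n2), oracle by
  # brute-force concatenation
  db2 <- suppressWarnings(build_reference(list(
    list(sample = s1, labels = sy1$labels),
    list(sample = s2, labels = sy2$labels)), tax))
  m2 <- marker_matrix(s2)
  cat_events <- rbind(m1[sy1$labels == "Naive Th", db2$markers],
                      m2[sy2$labels == "Naive Th", db2$markers])
  expect_equal(db2$stats[["Naive Th"]]$mean, colMeans(cat_events))
  # internal-node stats pool the whole subtree
  expect_gte(db2$stats[["Tregs"]]$n,
             sum(sy1$labels == "Naive Treg") + sum(sy2$labels == "Naive Treg"))
})

test_that("a multicenter database recovers template means within 3 standard errors", {
  db <- shared_db()
  tpl <- separated_templates()
  anchors <- c(neg = 0.3, lo = 1.0, pos = 2.2, hi = 3.2)
  sd1 <- 0.25 * 0.65
  for (pop in c("Naive Th", "Th1 Th CM", "Naive Treg")) {
    st <- db$stats[[pop]]
    lv <- tpl[tpl$name == pop, ]
    for (mk in c("CD27", "CD183", "CD4")) {
      planned <- anchors[[lv[[mk]]]]
      se <- sd1 / sqrt(st$n)
      expect_lt(abs(st$mean[[mk]] - planned), 3 * se + 1e-6)
    }
  }
})

test_that("reporting suppression is a step function at exactly min_cluster events", {
  db <- shared_db()
  tax <- db$taxonomy
  # craft a sample holding exactly k events of one rare population plus bulk
  make_sample <- function(k) {
    tpl <- separated_templates()
    rare_tpl <- tpl[tpl$name == "Th22 Th CM", ]
    base <- tpl[tpl$name != "Th22 Th CM", ]
    base$frequency <- base$frequency / sum(base$frequency)
    body <- simulate_sample(sample_spec(3000, seed = 63, noise_scale = 0.65,
                                        templates = base))
    rare_one <- rare_tpl; rare_one$frequency <- 1
    rare <- simulate_sample(sample_spec(max(k, 1), seed = 64, noise_scale = 0.65,
                                        templates = rare_one))
    ev <- rbind(body$sample$events, rare$sample$events[seq_len(k), , drop = FALSE])
    s <- flow_sample(ev, body$sample$channels, transform_state = "raw")
    transform_sample(s, body$spec$transform)
  }
  r9 <- auto_gate(make_sample(9), db)
  r10 <- auto_gate(make_sample(10), db)
  expect_true("Th22 Th CM" %in% r9$suppressed)
  expect_false("Th22 Th CM" %in% r9$report$population)
  expect_false("Th22 Th CM" %in% r10$suppressed)
  expect_true("Th22 Th CM" %in% r10$report$population)
  expect_equal(r10$report$events[r10$report$population == "Th22 Th CM"], 10)
  # suppressed populations keep counts internally (conservation holds)
  expect_true(check_conservation(r9))
  expect_equal(r9$counts$events[r9$counts$population == "Th22 Th CM"], 9)
})

test_that("auto-gating is deterministic: two time points agree 100%", {
  db <- shared_db()
  test <- shared_test_sample()
  st <- prepare_synthetic(test)
  r1 <- auto_gate(st, db)
  r2 <- auto_gate(st, db)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$counts, r2$counts)
  same <- r1$report$events == r2$report$events[match(r1$report$population,
                                                     r2$report$population)]
  expect_equal(mean(same), 1)  # 100% of populations identical
})

test_that("well-separated samples from the database's world are recovered >= 99.9%", {
  db <- shared_db()
  test <- shared_test_sample()
  st <- prepare_synthetic(test)
  r <- auto_gate(st, db)
  cd4 <- !test$labels %in% FILLER_NAMES
  expect_gte(mean(r$labels[cd4] == test$labels[cd4]), 0.999)
  # filler populations are novelty-flagged, never absorbed into CD4 subsets
  expect_true(all(startsWith(r$labels[!cd4], "unclassified-")))
  expect_gte(mean(r$novelty[!cd4]), 0.99)
})

test_that("auto-gated population frequencies match the plan within binomial 99% CIs", {
  db <- shared_db()
  test <- shared_test_sample()
  st <- prepare_synthetic(test)
  r <- auto_gate(st, db)
  tpl <- separated_templates()
  n <- test$spec$n_events
  ev <- setNames(r$counts$events, r$counts$population)
  planned_of <- function(pops) sum(tpl$frequency[tpl$name %in% pops])
  tax <- db$taxonomy
  for (node in c("Tregs", "TFH", "Classical Th", "CD4 T cells")) {
    leaves <- intersect(tpl$name, descendants(tax, node))
    p <- planned_of(leaves)
    ci <- 2.576 * sqrt(p * (1 - p) / n)
    # allow the small classification loss on top of sampling noise
    expect_lt(abs(ev[[node]] / n - p), ci + 0.01 * p + 5 / n, label = node)
  }
})

test_that("classification reduces to nearest-centroid under identity covariance", {
  db <- shared_db()
  # overwrite every covariance with the identity
  for (nm in names(db$stats)) {
    p <- length(db$stats[[nm]]$mean)
    db$stats[[nm]]$cov <- diag(p)
    dimnames(db$stats[[nm]]$cov) <- list(names(db$stats[[nm]]$mean),
                                         names(db$stats[[nm]]$mean))
  }
  test <- simulate_sample(sample_spec(800, seed = 65, noise_scale = 0.65,
                                      templates = separated_templates()))
  st <- prepare_synthetic(test)
  r <- auto_gate(st, db, max_radius = Inf)
  # independent oracle: walk the tree assigning by plain Euclidean distance
  m <- marker_matrix(st)
  tax <- db$taxonomy
  oracle_label <- function(x) {
    node <- "Leukocytes"
    repeat {
      kids <- tax$children[[node]]
      if (is.null(kids)) return(node)
      kids <- kids[vapply(kids, function(k) !is.null(db$stats[[k]]), TRUE)]
      if (!length(kids)) return(node)
      pr <- vapply(kids, function(k) db$stats[[k]]$prior, 0)
      kids <- kids[order(-pr, kids)]              # the tie-break order
      mks <- intersect(tcd4gate:::level_markers(tax, node), db$markers)
      d <- vapply(kids, function(k)
        sum((x[mks] - db$stats[[k]]$mean[mks])^2), 0)
      node <- kids[which.min(d)]
    }
  }
  idx <- seq_len(200)
  oracle <- vapply(idx, function(i) oracle_label(m[i, ]), "")
  got <- r$labels[idx]
  got_node <- sub("^unclassified-", "", got)
  expect_equal(mean(oracle == got | oracle == got_node), 1)
})

test_that("databases round-trip through JSON and refuse taxonomy mismatches", {
  db <- shared_db()
  f <- withr::local_tempfile(fileext = ".json")
  write_reference_json(db, f)
  back <- read_reference_json(f)
  expect_equal(back$stats[["Naive Th"]]$mean, db$stats[["Naive Th"]]$mean,
               tolerance = 1e-12)
  expect_equal(back$stats[["Tregs"]]$cov, db$stats[["Tregs"]]$cov,
               tolerance = 1e-12)
  # classification with the deserialized database is identical
  test <- shared_test_sample()
  st <- prepare_synthetic(test)
  expect_identical(auto_gate(st, back)$labels, auto_gate(st, db)$labels)
})

test_that("compare_analyses reports MNB against the reference analysis", {
  db <- shared_db()
  sams <- lapply(1:4, function(i) {
    sy <- simulate_sample(sample_spec(6000, seed = 300 + i, noise_scale = 0.65,
                                      templates = separated_templates()))
    auto_gate(prepare_synthetic(sy), db)
  })
  rep_id <- compare_analyses(sams, sams)
  evaluable <- !is.na(rep_id$mnb)
  expect_true(all(rep_id$mnb[evaluable] == 0))
  expect_true(all(rep_id$concordant[evaluable & rep_id$n_pairs >= 3 & rep_id$r2 >= 0]))

  # inflate the comparison by 20%: discordant under the ±15% band
  inflated <- lapply(sams, function(r) {
    r$counts$pct_parent <- r$counts$pct_parent * 1.2
    r
  })
  rep_bias <- compare_analyses(sams, inflated)
  big <- !is.na(rep_bias$mnb) & rep_bias$n_pairs >= 3
  expect_true(all(abs(rep_bias$mnb[big] - 20) < 1e-9))
  expect_false(any(rep_bias$concordant[big]))
})
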