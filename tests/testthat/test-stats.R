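mkmat <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("pop", seq_len(nrow(m)))
  m
}

test_that("agreement: identity is concordant, 20% bias is discordant", {
  a <- mkmat(c(10, 12, 14, 11), c(3, 4, 5, 6), c(40, 42, 44, 41))
  rep0 <- agreement(a, a)
  expect_true(all(rep0$mnb == 0))
  expect_true(all(rep0$r2 == 1))
  expect_true(all(rep0$concordant))
  expect_equal(attr(rep0, "summary")$fraction_concordant, 1)

  rep20 <- agreement(a, a * 1.2)
  expect_equal(rep20$mnb, rep(20, 3))
  expect_false(any(rep20$concordant))   # |MNB| = 20 > 15

  # b = 1.1 a stays inside the band and perfectly correlated: concordant
  rep10 <- agreement(a, a * 1.1)
  expect_true(all(rep10$concordant))
})

test_that("agreement: low correlation is discordant even with zero bias", {
  # constructed vectors with r2 ~ 0.83 and MNB ~ 0, oracle = direct Pearson
  a <- mkmat(c(10, 20, 30, 40, 50, 60))
  b <- mkmat(c(17.4, 12.9, 34.5, 26.7, 43.0, 56.7))
  r2 <- cor(a[1, ], b[1, ])^2
  expect_lt(r2, 0.9); expect_gt(r2, 0.8)
  rep <- agreement(a, b)
  expect_equal(rep$r2, r2)
  expect_lt(abs(rep$mnb), 5)
  expect_false(rep$concordant)
})

test_that("agreement handles zero references and missing populations", {
  a <- mkmat(c(0, 10, 20))
  b <- mkmat(c(5, 11, 21))
  expect_warning(rep <- agreement(a, b), "zero reference")
  expect_equal(rep$n_pairs, 3)      # pairs kept for correlation
  # MNB computed over nonzero-reference pairs only
  expect_equal(rep$mnb, mean(100 * c(1 / 10, 1 / 20)))

  a2 <- mkmat(c(10, NA, 30, 40))
  b2 <- mkmat(c(11, 12, NA, 41))
  rep2 <- agreement(a2, b2)
  expect_equal(rep2$n_not_identified, 2)
  expect_equal(rep2$n_pairs, 2)
})

test_that("the default agreement band is r2 >= 0.9, MNB ±15%, p <= 0.05", {
  cfg <- agreement_config()
  expect_equal(cfg$r2_min, 0.9)
  expect_equal(cfg$mnb_band, 15)
  expect_equal(cfg$p_max, 0.05)
  expect_error(agreement_config(r2_min = 2), class = "tcd4_validation_error")
  expect_error(agreement_config(mnb_band = -1), class = "tcd4_validation_error")
})

test_that("canonical variates find planted separations", {
  set.seed(71)
  g <- rep(c("A", "B"), each = 300)
  # two groups separated only on one marker
  v <- cbind(m1 = rnorm(600) + ifelse(g == "A", 0, 4), m2 = rnorm(600),
             m3 = rnorm(600))
  cv <- canonical_variates(v, g)
  expect_gt(cv$contributions$ca1_contribution[cv$contributions$marker == "m1"], 95)
  expect_equal(sum(cv$contributions$ca1_contribution), 100, tolerance = 1e-9)

  # three literally identical groups: between-group scatter = 0 -> warning
  block <- cbind(m1 = rnorm(30), m2 = rnorm(30))
  v0 <- rbind(block, block, block)
  expect_warning(canonical_variates(v0, rep(c("A", "B", "C"), each = 30)),
                 "indistinguishable")
})

test_that("canonical variate loadings match the analytic 2x2 generalized eigenproblem", {
  set.seed(72)
  n <- 20000
  g <- rep(c("A", "B"), each = n / 2)
  delta <- c(2, 1)        # planted mean separation on standardized scale
  x <- cbind(m1 = rnorm(n) + ifelse(g == "A", 0, delta[1]),
             m2 = rnorm(n) + ifelse(g == "A", 0, delta[2]))
  cv <- canonical_variates(x, g)
  # closed form: for two groups, the discriminant direction is W^-1 d where
  # W is the pooled within-group covariance of the standardized data and d
  # the standardized mean difference
  z <- scale(x)
  d <- colMeans(z[g == "B", ]) - colMeans(z[g == "A", ])
  W <- (cov(z[g == "A", ]) * (n / 2 - 1) + cov(z[g == "B", ]) * (n / 2 - 1))
  w <- solve(W, d)
  expected <- 100 * w^2 / sum(w^2)
  got <- cv$contributions$ca1_contribution[match(c("m1", "m2"),
                                                 cv$contributions$marker)]
  expect_equal(got, unname(expected), tolerance = 2)
})

test_that("reference intervals use type-7 percentiles with monotone columns", {
  # degenerate distribution: every percentile equals the constant
  co <- data.frame(sample_id = 1:20, age = 30, population = "X", count = 500)
  ri <- reference_intervals(co)
  expect_equal(ri$min, 500); expect_equal(ri$p50, 500); expect_equal(ri$max, 500)

  # values 1..100: p10 = 10.9 under the type-7 linear interpolation
  co2 <- data.frame(sample_id = 1:100, age = 25, population = "X", count = 1:100)
  ri2 <- reference_intervals(co2)
  expect_equal(ri2$p10, 10.9)
  expect_equal(ri2$p90, 90.1)
  expect_false(ri2$low_n)

  # monotonicity across every population x band cell
  set.seed(73)
  co3 <- data.frame(sample_id = rep(1:60, each = 2),
                    age = rep(c(1, 30, 70), 40),
                    population = rep(c("A", "B"), 60),
                    count = rlnorm(120, 6, 0.5))
  ri3 <- reference_intervals(co3)
  for (i in seq_len(nrow(ri3))) {
    v <- unlist(ri3[i, c("min", "p10", "p25", "p50", "p75", "p90", "max")])
    expect_true(all(diff(v) >= 0))
  }
  expect_error(reference_intervals(transform(co2, age = -3)),
               class = "tcd4_validation_error")
})

test_that("age bands map ages and reject uncovered values", {
  expect_identical(age_to_band(c("CB", "0.5", "25", "85")),
                   c("CB", "2mo-2y", "18-40y", "80+y"))
  expect_identical(age_to_band(18), "18-40y")  # boundary goes to upper band
  expect_error(age_to_band(0.01), "outside", class = "tcd4_validation_error")
  expect_error(age_to_band(-2), "negative", class = "tcd4_validation_error")
})

test_that("profile flagging marks low/normal/high against the band envelope", {
  set.seed(74)
  co <- data.frame(sample_id = 1:40, age = 30,
                   population = rep(c("A", "B"), each = 40),
                   count = c(rnorm(40, 1000, 100), rnorm(40, 200, 30)))
  iv <- reference_intervals(co)
  med <- iv$p50[iv$population == "A"]
  pat <- data.frame(population = c("A", "B"), count = c(med, 1))
  fl <- flag_profile(pat, 35, iv)
  expect_identical(fl$flag, c("normal", "low"))  # the band median is normal
  # below the band minimum is low
  pat2 <- data.frame(population = "A", count = min(co$count[co$population == "A"]) - 50)
  expect_identical(flag_profile(pat2, 35, iv)$flag, "low")
  expect_error(flag_profile(pat, 200, iv), class = "tcd4_validation_error")
})

test_that("a CVID-like globally reduced profile is flagged low across subsets", {
  cohort <- simulate_cohort(c("18-40y" = 12), base_seed = 500, n_events = 4000)
  rows <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    sy <- cohort[[i]]
    res <- classify_events(prepare_synthetic(sy), sy$thresholds)
    sm <- summarize_gating(res, leukocyte_conc = sy$spec$leukocyte_conc)
    keep <- sm$population %in% c("CD4 T cells", "Tregs", "TFH", "Classical Th",
                                 "Naive Th", "Th1 Th", "Th2 Th", "Th17 Th")
    data.frame(sample_id = i, age = 30, population = sm$population[keep],
               count = sm$abs_count[keep])
  }))
  iv <- reference_intervals(rows, min_n = 10)
  # patient = cohort-median profile scaled down to 30%
  med <- aggregate(count ~ population, rows, median)
  pat <- data.frame(population = med$population, count = 0.3 * med$count)
  fl <- flag_profile(pat, 30, iv)
  expect_gte(mean(fl$flag == "low"), 0.75)
})

test_that("Mann-Whitney p-values are exact for small samples", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)
  expect_false(r$significant)
  expect_match(r$method, "exact")

  # symmetric case: U for the flipped comparison is n1 n2 - U
  r2 <- compare_groups(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$U, 9)
  expect_equal(r2$p_value, 0.1)

  # identical groups: U = n^2 / 2 with ties, p ~ 1
  r3 <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r3$U, 4.5)
  expect_gt(r3$p_value, 0.9)

  expect_error(compare_groups(numeric(0), 1), class = "tcd4_validation_error")
})

test_that("exact Mann-Whitney equals brute-force enumeration for n <= 8 per group", {
  brute_force_p <- function(a, b) {
    n1 <- length(a); r <- rank(c(a, b))
    U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combs <- combn(length(r), n1)
    u_all <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
    min(1, 2 * min(mean(u_all <= U_obs), mean(u_all >= U_obs)))
  }
  set.seed(75)
  for (i in 1:6) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    a <- round(rnorm(n1, 0, 2), 1)
    b <- round(rnorm(n2, 1, 2), 1)
    r <- compare_groups(a, b)
    expect_equal(r$p_value, brute_force_p(a, b), tolerance = 1e-12,
                 label = sprintf("case %d (n1=%d n2=%d)", i, n1, n2))
  }
  # the tie-corrected normal approximation (the large-n path) agrees with
  # exact enumeration within 0.01 in p at n = 8 per group
  a <- c(1, 1, 2, 3, 3, 4, 5, 6)
  b <- c(2, 3, 4, 4, 5, 6, 7, 7)
  exact <- compare_groups(a, b)$p_value           # enumeration (ties, small n)
  n1 <- 8; n2 <- 8
  r <- rank(c(a, b)); U <- sum(r[1:8]) - n1 * (n1 + 1) / 2
  tt <- table(c(a, b))
  corr <- sum(tt^3 - tt) / ((n1 + n2) * (n1 + n2 - 1))
  sig <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - corr))
  z <- (U - n1 * n2 / 2 - sign(U - n1 * n2 / 2) * 0.5) / sig
  approx_p <- 2 * pnorm(-abs(z))
  expect_lt(abs(approx_p - exact), 0.01)
})

test_that("the stain index follows its defining formula and invariances", {
  pos <- c(250, 300, 350); neg <- c(50, 100, 150)
  expect_equal(stain_index(pos, neg), (300 - 100) / (2 * sd(neg)))
  set.seed(76)
  p2 <- rnorm(500, 300, 40); n2 <- rnorm(500, 100, 50)
  si <- stain_index(p2, n2)
  expect_equal(stain_index(10 * p2, 10 * n2), si, tolerance = 1e-12)  # scale-free
  expect_equal(stain_index(n2, n2), 0)
  expect_error(stain_index(1:3, rep(5, 4)), class = "tcd4_numerical_error")
})
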