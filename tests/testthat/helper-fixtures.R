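# Shared fixtures, all generated in code with fixed seeds.

# Canonical 5-stage blood on the three maturation markers. Proportions
# chosen so that no 20-bin boundary of the equal-count staging falls on a
# ~50/50 cluster split (see methods vignette).
canonical_maturation_events <- function(n = 20000, seed = 11, noise = 0.25) {
  set.seed(seed)
  anch <- c(neg = 0.3, pos = 2.2)
  codes <- list(N = c(1, 1, 1), CM = c(1, 0, 1), TM = c(1, 0, 0),
                EM = c(0, 0, 0), TE = c(0, 1, 0))
  prop <- c(N = .35, CM = .25, TM = .18, EM = .14, TE = .08)
  idx <- sample(names(codes), n, TRUE, prob = prop)
  ev <- t(vapply(idx, function(s)
    ifelse(codes[[s]] == 1, anch["pos"], anch["neg"]), numeric(3))) +
    matrix(stats::rnorm(3 * n, 0, noise), ncol = 3)
  colnames(ev) <- c("CD27", "CD45RA", "CD62L")
  list(events = ev, truth = idx)
}

# A well-estimated reference world: adult templates restricted to leaves
# with frequency >= 0.002 (so every population gets enough pooled reference
# events for stable covariance estimates), at 6-SD level separation
# (noise_scale 0.65 makes the smallest used anchor gap >= 6 SD).
separated_templates <- function() {
  tpl <- default_templates("18-40y")
  tpl <- tpl[tpl$frequency >= 0.002, ]
  tpl$frequency <- tpl$frequency / sum(tpl$frequency)
  tpl
}

build_center_db <- function(n_centers = 3, n_events = 12000, seed0 = 100,
                            noise_scale = 0.65, templates = separated_templates(),
                            taxonomy = build_taxonomy()) {
  centers <- lapply(seq_len(n_centers), function(i) {
    sy <- simulate_sample(sample_spec(n_events, seed = seed0 + i,
                                      noise_scale = noise_scale,
                                      templates = templates))
    list(sample = prepare_synthetic(sy), labels = sy$labels)
  })
  suppressWarnings(build_reference(centers, taxonomy))
}

FILLER_NAMES <- c("Monocytes", "CD3- lymphocytes", "CD3+CD4- T cells")

# memoized heavy fixtures (helpers are loaded once per test session)
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}
shared_db <- function() cached("db", build_center_db())
shared_test_sample <- function() cached("test_sample",
  simulate_sample(sample_spec(12000, seed = 200, noise_scale = 0.65,
                              templates = separated_templates())))

# Hand-built FCS file with $DATATYPE I written byte by byte: the oracle for
# the integer-reading path is the known values frozen here.
write_integer_fcs_fixture <- function(path) {
  vals <- c(0, 1, 512, 1023,
            100, 200, 300, 400)          # 2 events x 4 channels
  delim <- "/"
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "I", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", "4", "$TOT", "2")
  for (i in 1:4) {
    kw <- c(kw, sprintf("$P%dB", i), "16", sprintf("$P%dE", i), "0,0",
            sprintf("$P%dN", i), sprintf("CH%d", i), sprintf("$P%dR", i), "1024")
  }
  text_start <- 256
  build <- function(db, de) paste0(delim, paste(c(kw, "$BEGINDATA", db,
                                                  "$ENDDATA", de), collapse = delim), delim)
  txt <- build(0, 0)
  for (i in 1:3) {
    db <- text_start + nchar(txt); de <- db + 2L * length(vals) - 1
    t2 <- build(db, de)
    if (nchar(t2) == nchar(txt)) { txt <- t2; break }
    txt <- t2
  }
  hdr <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                 text_start, text_start + nchar(txt) - 1, db, de, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(raw(text_start - nchar(hdr)), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.integer(vals), con, size = 2, endian = "little")
  matrix(vals, nrow = 2, byrow = TRUE)
}
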