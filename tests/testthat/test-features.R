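# Learning phase: canonical keys, EPD extraction, pooling, filtering,
# sequence-distance profile and template I/O.

test_that("canonical pair keys sort codes and track the sign factor", {
  expect_identical(canonical_pair("A", "C")$key, "AC")
  expect_equal(canonical_pair("A", "C")$multfactor, 1)
  expect_identical(canonical_pair("C", "A")$key, "AC")
  expect_equal(canonical_pair("C", "A")$multfactor, -1)
  expect_equal(canonical_pair("D", "D")$multfactor, 1)
  expect_error(canonical_pair("A", "X"), class = "escapist_invalid_residue")
})

test_that("EPD extraction is canonical under order swap (involution)", {
  cfg <- feature_config(ignore_nterm = 0, ignore_cterm = 0)
  mkpots <- function(st, phis) {
    at <- st$atoms[st$atoms$atom == "CB", ]
    data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
               atom = "CB", phi = phis, stringsAsFactors = FALSE)
  }
  s_df <- generate_peptide("DF")
  s_fd <- generate_peptide("FD")
  o1 <- compute_epd(mkpots(s_df, c(10, 4)), consecutive_pairs(s_df, 0, 0), cfg)
  o2 <- compute_epd(mkpots(s_fd, c(4, 10)), consecutive_pairs(s_fd, 0, 0), cfg)
  expect_identical(o1$key, "DF")
  expect_equal(o1$value, 6)          # phi(D) - phi(F), sorted order
  expect_identical(o2[c("key", "value")], o1[c("key", "value")])
  # equal potentials give zero for any pair type
  o3 <- compute_epd(mkpots(s_df, c(7, 7)), consecutive_pairs(s_df, 0, 0), cfg)
  expect_equal(o3$value, 0)
})

test_that("pairs lacking the required atom are skipped, not errors", {
  cfg <- feature_config(ignore_nterm = 0, ignore_cterm = 0)
  s <- generate_peptide("AGA")
  pots <- type_potentials_fun(c(A = 5))(s)
  pairs <- consecutive_pairs(s, 0, 0)
  expect_equal(nrow(pairs), 2L)
  suppressMessages({
    expect_null(compute_epd(pots, pairs[1, ], cfg))   # A-G: no glycine CB
  })
})

test_that("a constant synthetic pair is learned exactly; high spread is filtered", {
  cfg <- feature_config(ignore_nterm = 0, ignore_cterm = 0,
                        min_samples = 1)
  sts <- lapply(1:5, function(i) generate_peptide("DFDFDF", id = paste0("s", i)))
  tpl <- learn_features(sts, cfg,
                        potentials_fun = type_potentials_fun(
                          c(D = -50, F = 50)))
  df <- tpl$entries[tpl$entries$pair == "DF", ]
  expect_equal(df$mean, -100)
  expect_equal(df$sd, 0)

  # same generative model with per-atom noise sd 60: pair sd > 50 -> dropped
  set.seed(4)
  tpl2 <- learn_features(
    lapply(1:40, function(i) generate_peptide("DFDFDF", id = paste0("n", i))),
    cfg, potentials_fun = type_potentials_fun(c(D = -50, F = 50),
                                              noise_sd = 60)
  )
  expect_false("DF" %in% tpl2$entries$pair)
  expect_true("DF" %in% tpl2$dropped$pair)
})

test_that("every retained entry satisfies the sd and sample filters", {
  set.seed(11)
  sts <- make_learning_set(n = 15, len = 20, seed = 11)
  base <- c(A = 0, D = -60, F = 25, K = 55, S = -10, T = 10)
  for (thresh in c(15, 30, 50)) {
    cfg <- feature_config(ignore_nterm = 1, ignore_cterm = 1,
                          sd_thresh = thresh, min_samples = 10)
    tpl <- learn_features(sts, cfg,
                          potentials_fun = type_potentials_fun(base, 12))
    expect_true(all(tpl$entries$sd <= thresh))
    expect_true(all(tpl$entries$n >= 10))
  }
  # cysteine exclusion drops every C-containing pair
  sts_c <- make_learning_set(n = 10, len = 20, seed = 3,
                             alphabet = c("A", "C", "D", "F"))
  cfgc <- feature_config(min_samples = 1, exclude_cysteine = TRUE)
  tplc <- learn_features(sts_c, cfgc,
                         potentials_fun = type_potentials_fun(
                           c(A = 0, C = 5, D = -60, F = 25), 5))
  expect_false(any(grepl("C", tplc$entries$pair, fixed = TRUE)))
})

test_that("learning recovers injected pair means within 3 sd/sqrt(n)", {
  base <- c(A = 0, D = -80, F = 30, K = 70, S = -15, T = 12)
  noise <- 10                       # per atom; pair EPD noise sd = noise*sqrt(2)
  set.seed(19)
  sts <- make_learning_set(n = 50, len = 30, seed = 19)
  cfg <- feature_config(min_samples = 20)
  tpl <- learn_features(sts, cfg,
                        potentials_fun = type_potentials_fun(base, noise))
  expect_gt(nrow(tpl$entries), 10)
  for (i in seq_len(nrow(tpl$entries))) {
    e <- tpl$entries[i, ]
    a <- substr(e$pair, 1, 1); b <- substr(e$pair, 2, 2)
    mu <- base[[a]] - base[[b]]
    expect_lt(abs(e$mean - mu), 3 * (noise * sqrt(2)) / sqrt(e$n))
  }
})

test_that("pooled and per-protein averaging differ as documented", {
  cfg <- feature_config(ignore_nterm = 0, ignore_cterm = 0, min_samples = 1)
  # every consecutive pair of DFDFDFDF is a D/F pair: 7 observations at
  # -100 from structure 1, one at -40 from structure 2
  mk <- function(seqc, id) generate_peptide(seqc, id = id)
  s1 <- mk("DFDFDFDF", "p1"); s2 <- mk("DF", "p2")
  vals <- list(p1 = -100, p2 = -40)
  pf <- function(st) {
    at <- st$atoms[st$atoms$atom == "CB", ]
    v <- vals[[st$id]]
    # phi(D) = v, phi(F) = 0 -> each DF pair observes v
    data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
               atom = "CB", phi = ifelse(at$aa == "D", v, 0))
  }
  pooled <- learn_features(list(s1, s2), cfg, potentials_fun = pf)
  perprot <- learn_features(list(s1, s2), cfg, potentials_fun = pf,
                            pooling = "per_protein")
  dfp <- pooled$entries[pooled$entries$pair == "DF", ]
  dfa <- perprot$entries[perprot$entries$pair == "DF", ]
  expect_equal(dfp$mean, (7 * -100 + 1 * -40) / 8)
  expect_equal(dfa$mean, (-100 + -40) / 2)  # unweighted per-structure means
})

test_that("an empty learning set is a classed error", {
  cfg <- feature_config()
  gly <- generate_peptide(strrep("G", 12), id = "allgly")
  expect_error(
    learn_features(list(gly), cfg,
                   potentials_fun = type_potentials_fun(c(A = 0))),
    class = "escapist_empty_template"
  )
})

test_that("backbone C-N EPDs do not separate pair types on identical backbones", {
  set.seed(31)
  sts <- make_learning_set(n = 15, len = 25, jitter = 0, seed = 31,
                           alphabet = c("A", "F", "S", "T", "L", "V"))
  cfg <- feature_config(mode = "cn", min_samples = 5)
  tpl <- learn_features(sts, cfg)
  expect_gt(nrow(tpl$entries), 5)
  spread <- diff(range(tpl$entries$mean))
  expect_lt(spread / abs(mean(tpl$entries$mean)), 0.01)
})

test_that("EPD spread is flat over sequence distance under i.i.d. potentials", {
  set.seed(13)
  sts <- make_learning_set(n = 60, len = 30, seed = 13)
  cfg <- feature_config(ignore_nterm = 1, ignore_cterm = 1, min_samples = 30)
  prof <- epd_vs_distance(sts, "AD", max_distance = 6, config = cfg,
                          potentials_fun = type_potentials_fun(
                            c(A = 0, D = -80, F = 30, K = 70, S = -15,
                              T = 12), noise_sd = 15))
  expect_gt(nrow(prof), 3)
  expect_true(all(prof$n >= 30))
  fit <- summary(stats::lm(sd ~ distance, data = prof))$coefficients
  ci <- fit["distance", 1] + c(-2, 2) * fit["distance", 2]
  expect_true(ci[1] <= 0 && ci[2] >= 0)
})

test_that("small-sample distance bins are omitted", {
  set.seed(5)
  sts <- make_learning_set(n = 2, len = 10, seed = 5,
                           alphabet = c("A", "D"))
  cfg <- feature_config(ignore_nterm = 0, ignore_cterm = 0,
                        min_samples = 30)
  prof <- epd_vs_distance(sts, "AD", max_distance = 8, config = cfg,
                          potentials_fun = type_potentials_fun(
                            c(A = 0, D = -80), 5))
  expect_true(all(prof$n >= 30))
})

test_that("template files round-trip exactly", {
  tpl <- manual_template(c(AD = -47.9, DF = 47.7, KS = -47.6))
  path <- tempfile(fileext = ".tsv")
  write_template(tpl, path)
  back <- read_template(path)
  expect_equal(back$entries, tpl$entries)
  expect_identical(back$mode, tpl$mode)
})

test_that("template parse errors name the offending line; unsorted keys normalize", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# mode: CB CB", "PAIR\tMEAN\tSD\tN",
               "AD\t-10\tabc\t50"), path)
  err <- expect_error(read_template(path), class = "escapist_parse_error")
  expect_match(conditionMessage(err), "line 3")

  writeLines(c("# mode: CB CB", "PAIR\tMEAN\tSD\tN",
               "FD\t-47.7\t18.3\t79"), path)
  expect_warning(tpl <- read_template(path), "normalized")
  expect_identical(tpl$entries$pair, "DF")
  expect_equal(tpl$entries$mean, 47.7)   # sign flips with the key swap
})

test_that("the packaged reference template matches its published sample", {
  tpl <- reference_template()
  expect_equal(nrow(tpl$entries), 16L)
  df <- tpl$entries[tpl$entries$pair == "DF", ]
  expect_equal(c(df$mean, df$sd, df$n), c(-108.9, 29.5, 481))
  hs <- tpl$entries[tpl$entries$pair == "HS", ]
  expect_equal(c(hs$mean, hs$sd, hs$n), c(93.7, 31.8, 235))
  expect_true(all(tpl$entries$sd <= 50))
  expect_identical(toupper(tpl$mode), c("CB", "CB"))
})
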