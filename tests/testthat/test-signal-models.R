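test_that("negative model recovers sample moments and rejects degenerate input", {
  fit <- fit_negative_model(c(88, 90, 92))
  expect_equal(fit$mu0, 90)
  expect_equal(fit$sigma0, 2)  # unbiased variance 4
  expect_equal(fit$n, 3L)
  expect_error(fit_negative_model(c(90, 90, 90)), "degenerate")
  expect_error(fit_negative_model(numeric(0)), "at least 2")
  expect_error(fit_negative_model(85), "at least 2")
})

test_that("EM recovers a seeded two-Gaussian mixture and ascends the likelihood", {
  set.seed(123)
  x <- c(rnorm(4000, 100, 1), rnorm(1000, 80, 1))  # 0.8 / 0.2 mixture
  fit <- fit_positive_model(x, seed = 7)
  expect_lt(abs(fit$mu1 - 100), 0.5)
  expect_lt(abs(fit$mu2 - 80), 0.5)
  expect_lt(abs(fit$rho - 0.8), 0.05)
  expect_true(fit$mu1 >= fit$mu2)
  # EM ascent: observed-data log-likelihood is monotone non-decreasing
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # independent cross-check of the fitted optimum against mclust
  suppressPackageStartupMessages(library(mclust))
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(abs(fit$loglik - mc$loglik), 1)
  expect_equal(sort(c(fit$mu1, fit$mu2)), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
  # all-identical events collapse through every restart
  expect_error(fit_positive_model(rep(95, 50), seed = 1), "collapsed")
})

test_that("discrimination matches the equal-variance closed form and is label-symmetric", {
  # f_N = N(0,1), f_P collapses to N(6,1): 1 - 2*pnorm(-3)
  m <- kmer_model("AAGCAA", mu0 = 0, sigma0 = 1, rho = 0.5,
                  mu1 = 6, sigma1 = 1, mu2 = 6, sigma2 = 1)
  expect_equal(m$discrimination, 1 - 2 * pnorm(-3), tolerance = 1e-5)
  # identical densities: overlap 1, discrimination 0
  m0 <- kmer_model("AAGCAA", mu0 = 90, sigma0 = 2, rho = 0.4,
                   mu1 = 90, sigma1 = 2, mu2 = 90, sigma2 = 2)
  expect_equal(m0$discrimination, 0, tolerance = 1e-6)
  # exchanging the mixture component labels leaves it unchanged
  set.seed(4)
  for (i in 1:10) {
    mu0 <- runif(1, 80, 120)
    p <- list(rho = runif(1, 0.1, 0.9), mu1 = mu0 + rnorm(1, 4, 2),
              sigma1 = runif(1, 0.5, 3), mu2 = mu0 + rnorm(1, 0, 2),
              sigma2 = runif(1, 0.5, 3))
    a <- kmer_model("TTGCTT", mu0, 1.5, p$rho, p$mu1, p$sigma1, p$mu2, p$sigma2)
    b <- kmer_model("TTGCTT", mu0, 1.5, 1 - p$rho, p$mu2, p$sigma2, p$mu1, p$sigma1)
    expect_equal(a$discrimination, b$discrimination, tolerance = 1e-10)
    expect_gte(a$discrimination, 0)
    expect_lte(a$discrimination, 1)
  }
  expect_error(kmer_model("AATTAA", 0, 1, 0.5, 1, 1, 1, 1), "GpC")
})

test_that("6-mer selection applies the exclusion, maximum, and tie rules", {
  #            0123456789012
  ref <- "TTTTTAGCTTTTT"  # single GpC, C at 0-based position 7
  site <- 7L
  # of the six covering 6-mers only starts 2..6 contain the full GpC and can
  # carry a trained model
  kmers <- vapply(2:6, function(st) substr(ref, st + 1, st + 6), character(1))
  no_events <- data.frame(position = integer(0), event_level = numeric(0))
  # discrimination increases with the methylated shift delta
  make <- function(km, delta) {
    kmer_model(km, mu0 = 100, sigma0 = 1.5, rho = 0.9, mu1 = 100 + delta,
               sigma1 = 1.5, mu2 = 100, sigma2 = 1.5)
  }
  models <- setNames(lapply(seq_along(kmers), function(i) make(kmers[i], i)),
                     kmers)
  # maximal discrimination wins: the start-6 candidate has the largest delta
  sel <- select_kmer(site, ref, models, no_events)
  expect_equal(sel$start, 6L)
  # a candidate with >10 aligned events on this molecule is excluded
  busy <- data.frame(position = rep(6L, 11L), event_level = rnorm(11, 100))
  sel2 <- select_kmer(site, ref, models, busy)
  expect_equal(sel2$start, 5L)
  # untrained 6-mers are excluded like any other
  sel3 <- select_kmer(site, ref, models[kmers[1:4]], no_events)
  expect_equal(sel3$start, 5L)
  # ties in discrimination resolve to the leftmost 6-mer start
  tied <- setNames(lapply(kmers, make, delta = 3), kmers)
  expect_equal(select_kmer(site, ref, tied, no_events)$start, 2L)
  # all candidates excluded -> site skipped
  expect_null(select_kmer(site, ref, list(), no_events))
  # a 6-mer containing two GpC sites is excluded even with top discrimination
  ref2 <- "TTTTAGCGCATTT"  # GpC cytosines at 6 and 8; "AGCGCA" covers both
  cands <- vapply(1:6, function(st) substr(ref2, st + 1, st + 6), character(1))
  deltas <- ifelse(cands == "AGCGCA", 10, seq_along(cands))
  models2 <- setNames(
    lapply(seq_along(cands), function(i) make(cands[i], deltas[i])), cands)
  sel4 <- select_kmer(6L, ref2, models2, no_events)
  expect_false(sel4$kmer == "AGCGCA")
  expect_equal(length(gregexpr("GC", sel4$kmer, fixed = TRUE)[[1]]), 1L)
  expect_equal(sel4$start, 6L)  # best-discriminating single-GpC survivor
})

test_that("posterior scores follow the product rule and the likelihood filter", {
  m <- kmer_model("AAGCAA", mu0 = 0, sigma0 = 1, rho = 0.5,
                  mu1 = 2, sigma1 = 1, mu2 = 2, sigma2 = 1)
  # equal class likelihoods at the midpoint -> exactly 0.5
  expect_equal(methylation_score(1, m)$score, 0.5, tolerance = 1e-12)
  # multi-event product rule, checked against direct density arithmetic
  x <- c(1.4, 0.2)
  fp <- dnorm(x, 2, 1)
  fn <- dnorm(x, 0, 1)
  expected <- prod(fp) / (prod(fp) + prod(fn))
  got <- methylation_score(x, m)
  expect_equal(got$score, expected, tolerance = 1e-12)
  expect_equal(got$n_events, 2L)
  # an event below the -10 natural-log floor is dropped before scoring
  far <- 2 + sqrt(2 * (10 - dnorm(0, log = TRUE)))  # log f_N(far) < -10
  expect_true(dnorm(far, 0, 1, log = TRUE) < -10)
  both <- methylation_score(c(1, far), m)
  expect_equal(both$n_events, 1L)
  expect_equal(both$score, 0.5, tolerance = 1e-12)
  only_far <- methylation_score(far, m)
  expect_true(only_far$filtered)
  expect_true(is.na(only_far$score))
})

test_that("scores separate events drawn from the two class models", {
  set.seed(21)
  m <- kmer_model("ATGCAT", mu0 = 100, sigma0 = 1.5, rho = 0.9,
                  mu1 = 104, sigma1 = 1.5, mu2 = 100, sigma2 = 1.5)
  expect_gte(m$discrimination, 0.5)
  pos_draws <- ifelse(runif(1000) < m$rho, rnorm(1000, m$mu1, m$sigma1),
                      rnorm(1000, m$mu2, m$sigma2))
  neg_draws <- rnorm(1000, m$mu0, m$sigma0)
  s_pos <- vapply(pos_draws, function(x) methylation_score(x, m)$score,
                  numeric(1))
  s_neg <- vapply(neg_draws, function(x) methylation_score(x, m)$score,
                  numeric(1))
  expect_gt(mean(s_pos, na.rm = TRUE), 0.5)
  expect_lt(mean(s_neg, na.rm = TRUE), 0.5)
  expect_true(all(s_pos >= 0 & s_pos <= 1, na.rm = TRUE))
  # monotone in the likelihood ratio
  grid <- seq(96, 108, by = 0.5)
  lr <- nucfoot:::f_pos(grid, m) / nucfoot:::f_neg(grid, m)
  s <- vapply(grid, function(x) methylation_score(x, m)$score, numeric(1))
  expect_equal(order(lr), order(s))
})

test_that("cross-validated AUC beats chance and the rank AUC matches pROC", {
  set.seed(31)
  models <- synthetic_kmer_models(n = 4, delta = 3)
  neg <- make_control_events(models, 40, class = "neg")
  pos <- make_control_events(models, 40, class = "pos")
  cv <- crossval_auc(neg, pos, seed = 5)
  expect_gt(cv$auc, 0.5)
  expect_gt(cv$n_test, 100)
  # rank-based AUC agrees with an independent ROC implementation
  sc <- runif(400)
  lab <- rbinom(400, 1, plogis(6 * (sc - 0.5)))
  expect_equal(roc_auc(sc, lab),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("trained model sets keep good 6-mers and record untrained ones", {
  set.seed(41)
  models <- synthetic_kmer_models(n = 3, delta = 4)
  neg <- make_control_events(models, 30, class = "neg")
  pos <- make_control_events(models, 30, class = "pos")
  # one 6-mer with too few positive events becomes untrained
  starved <- names(models)[1]
  pos_starved <- pos[pos$kmer != starved, ]
  pos_starved <- rbind(pos_starved,
                       data.frame(read_id = "rpos1", kmer = starved,
                                  event_level = rnorm(5, 100)))
  fit <- train_kmer_models(neg, pos_starved)
  expect_s3_class(fit, "kmer_model_set")
  expect_true(starved %in% fit$untrained$kmer)
  expect_true(all(setdiff(names(models), starved) %in% names(fit$models)))
  tab <- as.data.frame(fit)
  expect_true(all(c("kmer", "mu0", "rho", "discrimination") %in% names(tab)))
  # recovered negative means sit near the generating ones
  for (k in names(fit$models)) {
    expect_lt(abs(fit$models[[k]]$mu0 - models[[k]]$mu0), 1)
  }
})

test_that("methylation efficiency arithmetic matches the worked example", {
  expect_equal(round(methylation_efficiency(53, 3, 1), 2), 99.37)
  expect_equal(methylation_efficiency(10, 2, 0), 100)
  expect_error(methylation_efficiency(10, 2, 21))
})
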