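test_that("single-molecule accessible regions follow the three pairing rules", {
  # hand-walked example: (120, 400) fails the <100 bp rule, the rest chain
  mol <- make_molecule(c(10L, 50L, 120L, 400L), c(0.9, 0.8, 0.7, 0.9))
  reg <- molecule_accessible_regions(mol)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 10L)
  expect_equal(reg$end, 120L)  # length 110
  expect_equal(reg$score, 0.8)  # median of 0.9, 0.8, 0.7
  expect_equal(reg$n_sites, 3L)
  # a 70-bp candidate fails the >=100 bp length filter
  short <- make_molecule(c(10L, 80L), c(0.9, 0.9))
  expect_equal(nrow(molecule_accessible_regions(short)), 0L)
  # nothing qualifies when all scores sit at or below 0.5
  closed <- make_molecule(c(10L, 50L, 120L), c(0.5, 0.4, 0.2))
  expect_equal(nrow(molecule_accessible_regions(closed)), 0L)
  # an interior low-score site breaks adjacency
  broken <- make_molecule(c(10L, 60L, 110L, 160L), c(0.9, 0.3, 0.9, 0.9))
  expect_equal(nrow(molecule_accessible_regions(broken)), 0L)
  # a full chain merges into one long region
  chain <- make_molecule(seq(0L, 200L, by = 40L), rep(0.9, 6))
  reg2 <- molecule_accessible_regions(chain)
  expect_equal(c(reg2$start, reg2$end), c(0L, 200L))
})

test_that("bulk peaks use the 1.5x mean-ratio threshold and the length filter", {
  # homogeneous ratios can never exceed 1.5x their own mean
  flat <- data.frame(chrom = "chr", position = seq(0L, 900L, by = 30L),
                     r = 0.4, M = 10L)
  expect_equal(nrow(bulk_peaks(flat)), 0L)
  # hand-walked toy: chain [0, 90] is 90 bp (dropped), site 300 is isolated;
  # distant low-ratio sites hold the genome-wide mean at 0.2
  filler <- data.frame(chrom = "chr",
                       position = seq(1000L, 8000L, by = 1000L),
                       r = 0.03125, M = 10L)
  toy <- rbind(data.frame(chrom = "chr", position = c(0L, 50L, 90L, 300L),
                          r = c(0.4, 0.5, 0.35, 0.9), M = 10L), filler)
  expect_equal(mean(toy$r), 0.2)
  expect_equal(nrow(bulk_peaks(toy)), 0L)
  # six high sites every 40 bp chain into one [0, 200] peak
  high <- rbind(data.frame(chrom = "chr", position = seq(0L, 200L, by = 40L),
                           r = 0.9, M = 10L),
                data.frame(chrom = "chr",
                           position = seq(1000L, 4000L, by = 1000L),
                           r = 0, M = 10L))
  pk <- bulk_peaks(high)
  expect_equal(nrow(pk), 1L)
  expect_equal(c(pk$start, pk$end), c(0L, 200L))
  expect_equal(pk$n_sites, 6L)
  # low-coverage sites are excluded; none left is an error
  thin <- data.frame(chrom = "chr", position = c(0L, 50L), r = 0.9, M = 2L)
  expect_error(bulk_peaks(thin), "min_cov")
})

test_that("bulk peaks are invariant to molecule order and strands intersect", {
  set.seed(61)
  scores <- do.call(rbind, lapply(1:20, function(i) {
    data.frame(read_id = paste0("m", i), chrom = "chr",
               position = seq(0L, 950L, by = 25L),
               score = runif(39, 0, ifelse(seq(0L, 950L, by = 25L) < 300, 1, 0.6)))
  }))
  shuffled <- scores[sample(nrow(scores)), ]
  expect_equal(bulk_peaks(site_ratios(scores)),
               bulk_peaks(site_ratios(shuffled)))
  # strand-concordant peaks are the interval intersections
  fwd <- data.frame(chrom = "chr", start = c(0L, 500L), end = c(300L, 700L))
  rev <- data.frame(chrom = "chr", start = 200L, end = 600L)
  cc <- concordant_peaks(fwd, rev)
  expect_equal(cc$start, c(200L, 500L))
  expect_equal(cc$end, c(300L, 600L))
})

test_that("promoter definition applies the three rules in order", {
  gene <- list(gene_id = "g1", chrom = "chr", tss = 10000L, strand = "+")
  # rule 3: no overlapping peak, the -500/+100 window itself
  w <- define_promoter(gene, NULL)
  expect_equal(c(w$start, w$end), c(9500L, 10101L))
  expect_equal(w$source, "window")
  # rule 1: a single overlapping peak becomes the promoter
  one <- data.frame(chrom = "chr", start = 9700L, end = 9950L)
  p1 <- define_promoter(gene, one)
  expect_equal(c(p1$start, p1$end), c(9700L, 9950L))
  expect_equal(p1$source, "peak")
  # rule 2: the longest-overlap peak wins
  two <- data.frame(chrom = "chr", start = c(9700L, 10020L),
                    end = c(9820L, 10100L))  # overlaps 120 vs 80
  p2 <- define_promoter(gene, two)
  expect_equal(p2$start, 9700L)
  # a peak on another chromosome never matches
  other <- data.frame(chrom = "chr2", start = 9700L, end = 9950L)
  expect_equal(define_promoter(gene, other)$source, "window")
  # reverse-strand genes orient upstream toward higher coordinates
  neg <- list(gene_id = "g2", chrom = "chr", tss = 10000L, strand = "-")
  wn <- define_promoter(neg, NULL)
  expect_equal(c(wn$start, wn$end), c(9900L, 10501L))
  # the unstranded switch reproduces the strand-naive window
  wu <- define_promoter(neg, NULL, unstranded = TRUE)
  expect_equal(c(wu$start, wu$end), c(9500L, 10101L))
})

test_that("promoter status is the strict median rule on covering molecules", {
  prom <- data.frame(chrom = "chr", start = 100L, end = 400L)
  m <- make_molecule(c(150L, 200L, 300L), c(0.9, 0.8, 0.2), start = 0L,
                     end = 500L)
  call <- call_promoter_status(m, prom)
  expect_equal(call$score, 0.8)
  expect_equal(call$status, "open")
  # median exactly 0.5 is closed (strict inequality)
  half <- make_molecule(c(150L, 200L, 300L), c(0.7, 0.5, 0.3), start = 0L,
                        end = 500L)
  expect_equal(call_promoter_status(half, prom)$status, "closed")
  # no GpC inside the promoter: no call
  outside <- make_molecule(c(10L, 450L), c(0.9, 0.9), start = 0L, end = 500L)
  expect_equal(call_promoter_status(outside, prom)$status, "no_call")
  # partially covering molecules are not callable
  partial <- make_molecule(c(150L, 200L), c(0.9, 0.9), start = 120L,
                           end = 500L)
  expect_null(call_promoter_status(partial, prom))
  # scores outside the promoter never change the call
  decorated <- make_molecule(c(10L, 150L, 200L, 300L, 480L),
                             c(0.01, 0.9, 0.8, 0.2, 0.02), start = 0L,
                             end = 500L)
  expect_equal(call_promoter_status(decorated, prom)$score, 0.8)
})

test_that("bulk openness and differential accessibility are simple ratios", {
  statuses <- c(rep("open", 14), rep("closed", 20))
  expect_equal(bulk_openness(statuses), 14 / 34)
  expect_equal(round(bulk_openness(statuses), 4), 0.4118)
  expect_equal(bulk_openness(c("open", "open", "no_call")), 1)
  expect_true(is.na(bulk_openness(rep("no_call", 5))))
  expect_equal(differential_accessibility(0.7, 0.2), 0.5)
  expect_equal(differential_accessibility(0.33, 0.33), 0)
  expect_true(is.na(differential_accessibility(NA_real_, 0.4)))
})

test_that("a known openness shift is recovered within sampling error", {
  set.seed(71)
  prom <- data.frame(chrom = "chr", start = 0L, end = 600L)
  delta <- 0.3
  sim_condition <- function(p_open, n = 500L) {
    statuses <- vapply(seq_len(n), function(i) {
      open <- runif(1) < p_open
      sc <- if (open) rbeta(8, 6, 1) else rbeta(8, 1, 6)
      m <- make_molecule(seq(50L, 540L, by = 70L), sc, start = 0L, end = 650L)
      call_promoter_status(m, prom)$status
    }, character(1))
    bulk_openness(statuses)
  }
  d <- differential_accessibility(sim_condition(0.8), sim_condition(0.8 - delta))
  expect_lt(abs(d - delta), 0.1)  # ~4 binomial SE at n = 500
})
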