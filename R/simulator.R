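# Synthetic methylation-footprinting molecules with ground-truth occupancy:
# alternating linkers (mixture-normal lengths) and 147-bp nucleosomes along a
# molecule, GpC sites placed per-base at a given frequency, and per-site
# methylation scores drawn from class-conditional distributions. Used to
# measure decoder accuracy across nucleosome coverage and GpC frequency.

#' Simulation configuration
#'
#' Linker lengths are drawn from `N(nu1, gamma1^2)` with probability `tau`
#' (the regular-nucleosome-array component) and from `N(nu2, gamma2^2)` with
#' probability `1 - tau` (open regions); draws are rounded to integers and
#' truncated below at 0. Site scores come either from the mirrored-Beta
#' parametric model (shape calibrated so the two-class AUC is 0.86, matching
#' realistic single-site 5mC detection) or from supplied `score_density`
#' curves.
#'
#' @param length Molecule length in bp (default 3000).
#' @param gpc_freq Per-base GpC probability in (0, 0.2\] (default 0.0375).
#' @param nu1,gamma1 Mean/SD (bp) of the short-linker component (defaults
#'   15/5).
#' @param nu2,gamma2 Mean/SD (bp) of the long-linker component (defaults
#'   100/10).
#' @param tau Probability of the short-linker component (default 0.1).
#' @param score_model `"beta"` (parametric, default) or `"densities"`.
#' @param score_shape Beta shape of the calibrated score model.
#' @param densities A `score_density` used both to draw scores and to decode,
#'   when `score_model = "densities"`.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(length = 3000L, gpc_freq = 0.0375, nu1 = 15,
                       gamma1 = 5, nu2 = 100, gamma2 = 10, tau = 0.1,
                       score_model = c("beta", "densities"),
                       score_shape = 2.1486, densities = NULL) {
  score_model <- match.arg(score_model)
  stopifnot(length >= 148L, gpc_freq > 0, gpc_freq <= 0.2,
            gamma1 > 0, gamma2 > 0, tau >= 0, tau <= 1, score_shape > 0)
  if (score_model == "densities" && !inherits(densities, "score_density")) {
    stop("score_model = 'densities' requires a score_density object")
  }
  structure(list(length = as.integer(length), gpc_freq = gpc_freq,
                 nu1 = nu1, gamma1 = gamma1, nu2 = nu2, gamma2 = gamma2,
                 tau = tau, score_model = score_model,
                 score_shape = score_shape, densities = densities),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d bp, GpC freq %.4f, linker %.1f*N(%g,%g^2) + %.1f*N(%g,%g^2), scores: %s\n",
    x$length, x$gpc_freq, x$tau, x$nu1, x$gamma1, 1 - x$tau, x$nu2, x$gamma2,
    if (x$score_model == "beta") sprintf("Beta(%.4f)", x$score_shape)
    else "densities"))
  invisible(x)
}

# one batch of linker lengths from the two-component mixture
rlinker <- function(n, config) {
  short <- runif(n) < config$tau
  raw <- rnorm(n, ifelse(short, config$nu1, config$nu2),
               ifelse(short, config$gamma1, config$gamma2))
  pmax(0L, as.integer(round(raw)))
}

#' Simulate a nucleosome/linker layout
#'
#' Alternates a sampled linker and a 147-bp nucleosome starting with a linker
#' until the molecule is filled; the final nucleosome is clipped at the
#' molecule end when it overhangs.
#'
#' @param config A [sim_config()].
#' @return Data frame `start`, `end` (0-based half-open nucleosome intervals),
#'   `clipped`.
#' @export
simulate_layout <- function(config) {
  l <- config$length
  pos <- 0L
  starts <- integer(0)
  repeat {
    s <- pos + rlinker(1L, config)
    if (s >= l) break
    starts <- c(starts, s)
    pos <- s + 147L
    if (pos >= l) break
  }
  data.frame(start = starts, end = pmin(starts + 147L, l),
             clipped = starts + 147L > l)
}

#' Simulate GpC sites and methylation scores on a layout
#'
#' Places GpC sites by independent per-base Bernoulli draws and assigns each
#' site a score from the class-conditional distribution of its ground-truth
#' state (nucleosome-covered: negative class; linker: positive class).
#'
#' @param layout Output of [simulate_layout()].
#' @param config A [sim_config()].
#' @return Object of class `sim_molecule`: `length`, `layout`, `truth`
#'   (per-base in-nucleosome indicator), `positions` (0-based GpC sites),
#'   `site_class` (`"nucleosome"`/`"linker"`), `scores`.
#' @export
simulate_scores <- function(layout, config) {
  l <- config$length
  truth <- logical(l)
  for (i in seq_len(nrow(layout))) {
    truth[(layout$start[i] + 1L):layout$end[i]] <- TRUE
  }
  positions <- which(runif(l) < config$gpc_freq) - 1L
  covered <- truth[positions + 1L]
  n_nuc <- sum(covered)
  n_lnk <- sum(!covered)
  scores <- numeric(length(positions))
  if (config$score_model == "beta") {
    scores[covered] <- rbeta(n_nuc, 1, config$score_shape)
    scores[!covered] <- rbeta(n_lnk, config$score_shape, 1)
  } else {
    scores[covered] <- rdensity(n_nuc, config$densities, "N")
    scores[!covered] <- rdensity(n_lnk, config$densities, "P")
  }
  structure(list(length = l, layout = layout, truth = truth,
                 positions = positions,
                 site_class = ifelse(covered, "nucleosome", "linker"),
                 scores = scores),
            class = "sim_molecule")
}

# sample scores from a gridded density (grid draw plus sub-grid jitter)
rdensity <- function(n, densities, class = c("N", "P")) {
  class <- match.arg(class)
  q <- if (class == "N") densities$q_N else densities$q_P
  step <- diff(densities$grid[1:2])
  x <- sample(densities$grid, n, replace = TRUE, prob = q) +
    runif(n, -step / 2, step / 2)
  pmin(pmax(x, 0), 1)
}

#' Simulate one molecule (layout plus scores)
#'
#' @param config A [sim_config()].
#' @return A `sim_molecule`.
#' @export
simulate_molecule <- function(config) {
  simulate_scores(simulate_layout(config), config)
}

#' Convert a simulated molecule to decoder input
#'
#' @param sim A `sim_molecule`.
#' @param read_id,chrom,strand Identity given to the synthetic molecule.
#' @return A [molecule_scores()] spanning `[0, length)`.
#' @export
as_molecule_scores <- function(sim, read_id = "sim", chrom = "sim",
                               strand = "+") {
  molecule_scores(read_id, chrom, 0L, sim$length, sim$positions, sim$scores,
                  strand = strand)
}

#' Emission densities matching a simulation's score model
#'
#' @param config A [sim_config()].
#' @return The `score_density` the decoder should use on this simulation's
#'   molecules.
#' @export
sim_score_density <- function(config) {
  if (config$score_model == "beta") beta_score_density(config$score_shape)
  else config$densities
}

#' Synthetic per-6-mer signal models
#'
#' Generates plausible event-level models for end-to-end testing: the
#' unmethylated mean is drawn uniformly in a pA band and the dominant
#' methylated component is shifted by `delta` pA.
#'
#' @param n Number of 6-mers (ignored when `kmers` given).
#' @param kmers Optional explicit 6-mers (each with exactly one GpC).
#' @param mu_band Range of unmethylated means in pA.
#' @param delta Methylated shift in pA.
#' @param sigma Component SD in pA.
#' @param rho Weight of the shifted (converted) component.
#' @return Named list of [kmer_model].
#' @export
synthetic_kmer_models <- function(n = 6L, kmers = NULL, mu_band = c(80, 120),
                                  delta = 6, sigma = 1.5, rho = 0.95) {
  if (is.null(kmers)) {
    kmers <- character(0)
    while (length(kmers) < n) {
      km <- paste(sample(c("A", "C", "G", "T"), 6L, replace = TRUE),
                  collapse = "")
      if (count_gpc(km) == 1L && !km %in% kmers) kmers <- c(kmers, km)
    }
  }
  models <- lapply(kmers, function(km) {
    mu0 <- runif(1, mu_band[1], mu_band[2])
    kmer_model(km, mu0 = mu0, sigma0 = sigma, rho = rho,
               mu1 = mu0 + delta, sigma1 = sigma, mu2 = mu0, sigma2 = sigma)
  })
  setNames(models, kmers)
}

#' Simulate event levels for a simulated molecule
#'
#' Draws per-site event levels from the negative model at nucleosome-covered
#' sites and from the positive mixture at linker sites, each site using a
#' randomly assigned synthetic 6-mer model. Together with
#' [methylation_score()] this exercises the signal-model scoring path ahead
#' of decoding.
#'
#' @param sim A `sim_molecule`.
#' @param models Named list of [kmer_model] (see [synthetic_kmer_models()]).
#' @param events_per_site Events drawn per site (default 1).
#' @param read_id Read identifier.
#' @return Data frame `read_id`, `position`, `kmer`, `event_level`, `class`.
#' @export
simulate_event_levels <- function(sim, models, events_per_site = 1L,
                                  read_id = "sim") {
  n <- length(sim$positions)
  if (n == 0L) {
    return(data.frame(read_id = character(0), position = integer(0),
                      kmer = character(0), event_level = numeric(0),
                      class = character(0)))
  }
  km <- sample(names(models), n, replace = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    m <- models[[km[i]]]
    x <- if (sim$site_class[i] == "nucleosome") {
      rnorm(events_per_site, m$mu0, m$sigma0)
    } else {
      comp1 <- runif(events_per_site) < m$rho
      rnorm(events_per_site, ifelse(comp1, m$mu1, m$mu2),
            ifelse(comp1, m$sigma1, m$sigma2))
    }
    data.frame(read_id = read_id, position = sim$positions[i], kmer = km[i],
               event_level = x, class = sim$site_class[i])
  })
  do.call(rbind, rows)
}

#' Score simulated events with their generating models
#'
#' @param events Output of [simulate_event_levels()].
#' @param models The same named model list.
#' @param log_filter Event likelihood floor, as in [methylation_score()].
#' @return Data frame `position`, `class`, `score` (one row per site; `NA`
#'   when all of a site's events were filtered).
#' @export
score_simulated_events <- function(events, models, log_filter = -10) {
  parts <- lapply(split(events, events$position), function(df) {
    call <- methylation_score(df$event_level, models[[df$kmer[1]]],
                              log_filter = log_filter)
    data.frame(position = df$position[1], class = df$class[1],
               score = call$score)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-base decoding accuracy
#'
#' Fraction of positions whose predicted in-nucleosome indicator matches the
#' ground truth.
#'
#' @param predicted,truth Equal-length logical vectors.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("label vectors differ in length")
  mean(predicted == truth)
}

#' Expected nucleosome coverage of a simulation configuration
#'
#' `147 / (147 + E[linker])` with the mixture mean linker
#' `tau * nu1 + (1 - tau) * nu2`.
#'
#' @param config A [sim_config()].
#' @return Expected fraction of bases covered by nucleosomes.
#' @export
expected_nucleosome_coverage <- function(config) {
  147 / (147 + config$tau * config$nu1 + (1 - config$tau) * config$nu2)
}

#' Decoder accuracy over a coverage-by-frequency grid
#'
#' For every combination of GpC frequency and long-linker mean `nu2`,
#' simulates `reps` molecules, decodes each with the dynamic program using
#' the simulation's own score densities, and averages the per-base accuracy;
#' the realized nucleosome coverage is reported alongside.
#'
#' @param freqs GpC frequencies to test.
#' @param nu2_values Long-linker means (bp) controlling nucleosome coverage.
#' @param reps Replicate molecules per cell (default 200).
#' @param config Base configuration; `gpc_freq` and `nu2` are overridden per
#'   cell.
#' @param seed Optional integer seed.
#' @return Data frame `gpc_freq`, `nu2`, `expected_coverage`, `coverage`
#'   (mean realized), `mean_accuracy`, `sd_accuracy`, `reps`.
#' @export
accuracy_grid <- function(freqs = 0.0375,
                          nu2_values = c(15, 50, 100, 200, 300, 400, 500, 600),
                          reps = 200L, config = sim_config(), seed = NULL) {
  stopifnot(reps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  cells <- expand.grid(gpc_freq = freqs, nu2 = nu2_values)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- config
    cfg$gpc_freq <- cells$gpc_freq[i]
    cfg$nu2 <- cells$nu2[i]
    dens <- sim_score_density(cfg)
    acc <- numeric(reps)
    cov <- numeric(reps)
    for (r in seq_len(reps)) {
      sim <- simulate_molecule(cfg)
      path <- decode(as_molecule_scores(sim), dens)
      acc[r] <- accuracy(path_occupancy(path), sim$truth)
      cov[r] <- mean(sim$truth)
    }
    data.frame(gpc_freq = cfg$gpc_freq, nu2 = cfg$nu2,
               expected_coverage = expected_nucleosome_coverage(cfg),
               coverage = mean(cov), mean_accuracy = mean(acc),
               sd_accuracy = sd(acc), reps = reps)
  })
  do.call(rbind, rows)
}
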