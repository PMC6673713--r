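# Per-6-mer event-level signal models: a single Gaussian for the unmethylated
# (negative-control) class and a two-component Gaussian mixture for the
# methylated (positive-control) class, the mixture absorbing incompletely
# converted molecules. Models feed the posterior methylation score per GpC
# site per molecule.

#' Fit the unmethylated (negative-control) event-level model
#'
#' Estimates the Gaussian parameters of the unmethylated class for one 6-mer
#' by the sample mean and the unbiased (n-1) sample standard deviation.
#'
#' @param events Numeric vector of event levels (pA) aligned to one 6-mer.
#' @param eps Lower bound on the fitted standard deviation; a fit below it is
#'   degenerate and raises an error (the 6-mer is left untrained upstream).
#' @return List with `mu0`, `sigma0`, `n`.
#' @export
fit_negative_model <- function(events, eps = 1e-3) {
  x <- as.numeric(events)
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least 2 event levels to fit the negative model")
  sigma0 <- sd(x)
  if (!is.finite(sigma0) || sigma0 < eps) {
    stop("degenerate event-level variance; 6-mer cannot be trained")
  }
  list(mu0 = mean(x), sigma0 = sigma0, n = length(x))
}

#' Fit the methylated (positive-control) event-level mixture by EM
#'
#' Two-component Gaussian mixture fitted by expectation-maximization.
#' Initialization places the component means at the 25th/75th percentiles
#' with a shared variance; convergence is declared when the observed-data
#' log-likelihood improves by less than `tol`. On component collapse
#' (a variance below `eps`) the fit restarts with a jittered initialization
#' up to `restarts` times. Components are ordered so that `mu1 >= mu2`.
#'
#' @param events Numeric vector of event levels (pA) aligned to one 6-mer.
#' @param min_events Minimum number of events required.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter Maximum EM iterations.
#' @param eps Component standard-deviation floor; below it the fit collapses.
#' @param restarts Number of jittered restarts after a collapse.
#' @param seed Optional integer seed for the restart jitter.
#' @return List with `rho`, `mu1`, `sigma1`, `mu2`, `sigma2`, `n`, `loglik`,
#'   `loglik_trace` (per-iteration observed-data log-likelihood), `iterations`.
#' @export
fit_positive_model <- function(events, min_events = 20L, tol = 1e-6,
                               max_iter = 500L, eps = 1e-3, restarts = 3L,
                               seed = NULL) {
  x <- as.numeric(events)
  x <- x[is.finite(x)]
  if (length(x) < min_events) {
    stop("need at least ", min_events, " event levels to fit the positive model")
  }
  if (!is.null(seed)) set.seed(seed)
  q <- unname(quantile(x, c(0.25, 0.75)))
  s0 <- max(sd(x), 0)
  for (attempt in 0:restarts) {
    mu <- if (attempt == 0L) c(q[2], q[1]) else c(q[2], q[1]) + rnorm(2, sd = max(s0, eps))
    fit <- em_gmm2(x, mu = mu, sigma = c(s0, s0), rho = 0.5,
                   tol = tol, max_iter = max_iter, eps = eps)
    if (!is.null(fit)) {
      fit$n <- length(x)
      return(fit)
    }
  }
  stop("EM collapsed in all restarts; 6-mer cannot be trained")
}

# One EM run for a 2-component Gaussian mixture; returns NULL on collapse.
em_gmm2 <- function(x, mu, sigma, rho, tol, max_iter, eps) {
  if (any(sigma < eps)) return(NULL)
  n <- length(x)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    la <- log(rho) + dnorm(x, mu[1], sigma[1], log = TRUE)
    lb <- log1p(-rho) + dnorm(x, mu[2], sigma[2], log = TRUE)
    m <- pmax(la, lb)
    lse <- m + log(exp(la - m) + exp(lb - m))
    lse[!is.finite(m)] <- -Inf
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    if (it > 1L && ll - ll_old < tol) break
    ll_old <- ll
    g <- 1 / (1 + exp(lb - la))  # responsibility of component 1
    n1 <- sum(g)
    n2 <- n - n1
    if (n1 < 1e-10 || n2 < 1e-10) return(NULL)
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sigma <- sqrt(c(sum(g * (x - mu[1])^2) / n1, sum((1 - g) * (x - mu[2])^2) / n2))
    if (any(!is.finite(sigma)) || any(sigma < eps)) return(NULL)
    rho <- n1 / n
  }
  # deterministic component order: mu1 >= mu2
  if (mu[1] < mu[2]) {
    mu <- rev(mu)
    sigma <- rev(sigma)
    rho <- 1 - rho
  }
  list(rho = rho, mu1 = mu[1], sigma1 = sigma[1], mu2 = mu[2], sigma2 = sigma[2],
       loglik = ll, loglik_trace = ll_trace, iterations = it)
}

#' Construct a per-6-mer signal model
#'
#' Bundles the unmethylated Gaussian and the methylated two-component mixture
#' for one GpC-containing 6-mer; the discrimination (1 minus the overlap area
#' of the two densities) is computed at construction.
#'
#' @param kmer 6-character DNA string containing at least one GpC ("GC").
#' @param mu0,sigma0 Unmethylated Gaussian mean and sd (pA).
#' @param rho Mixture weight of the first methylated component, in (0, 1).
#' @param mu1,sigma1,mu2,sigma2 Methylated mixture component parameters.
#' @param n_neg,n_pos Training event counts (informational).
#' @return Object of class `kmer_model`.
#' @export
kmer_model <- function(kmer, mu0, sigma0, rho, mu1, sigma1, mu2, sigma2,
                       n_neg = NA_integer_, n_pos = NA_integer_) {
  stopifnot(nchar(kmer) == 6L, sigma0 > 0, sigma1 > 0, sigma2 > 0,
            rho > 0, rho < 1)
  if (count_gpc(kmer) < 1L) stop("kmer must contain a GpC dinucleotide: ", kmer)
  obj <- structure(
    list(kmer = kmer, mu0 = mu0, sigma0 = sigma0, rho = rho,
         mu1 = mu1, sigma1 = sigma1, mu2 = mu2, sigma2 = sigma2,
         n_neg = n_neg, n_pos = n_pos),
    class = "kmer_model")
  obj$discrimination <- kmer_discrimination(obj)
  obj
}

#' @export
print.kmer_model <- function(x, ...) {
  cat(sprintf(
    "<kmer_model %s>  f_N: N(%.2f, %.2f^2)  f_P: %.2f N(%.2f, %.2f^2) + %.2f N(%.2f, %.2f^2)  D = %.3f\n",
    x$kmer, x$mu0, x$sigma0, x$rho, x$mu1, x$sigma1, 1 - x$rho, x$mu2, x$sigma2,
    x$discrimination))
  invisible(x)
}

# class-conditional event-level densities
f_neg <- function(x, model, log = FALSE) {
  dnorm(x, model$mu0, model$sigma0, log = log)
}

f_pos <- function(x, model, log = FALSE) {
  la <- log(model$rho) + dnorm(x, model$mu1, model$sigma1, log = TRUE)
  lb <- log1p(-model$rho) + dnorm(x, model$mu2, model$sigma2, log = TRUE)
  m <- pmax(la, lb)
  l <- m + log(exp(la - m) + exp(lb - m))
  l[!is.finite(m)] <- -Inf
  if (log) l else exp(l)
}

#' Discrimination of a 6-mer signal model
#'
#' One minus the overlap area of the unmethylated and methylated event-level
#' densities, computed by the trapezoid rule on 4001 points spanning
#' `[min(mu) - 6 max(sigma), max(mu) + 6 max(sigma)]` over all three
#' components, clipped to \[0, 1\]. A discrimination near 1 means the 6-mer's
#' signal separates the two classes nearly perfectly.
#'
#' @param model A [kmer_model] (or any list carrying the same parameters).
#' @return Discrimination in \[0, 1\].
#' @export
kmer_discrimination <- function(model) {
  mus <- c(model$mu0, model$mu1, model$mu2)
  sds <- c(model$sigma0, model$sigma1, model$sigma2)
  if (any(!is.finite(mus)) || any(!is.finite(sds)) || any(sds <= 0)) {
    stop("untrained or invalid model")
  }
  grid <- seq(min(mus) - 6 * max(sds), max(mus) + 6 * max(sds), length.out = 4001L)
  overlap <- trapz(grid, pmin(f_neg(grid, model), f_pos(grid, model)))
  min(max(1 - overlap, 0), 1)
}

#' Train signal models for all GpC-containing 6-mers
#'
#' Groups negative- and positive-control events by reference 6-mer and fits
#' both class models per 6-mer. 6-mers without a GpC are ignored; 6-mers whose
#' fit fails (too few events, degenerate variance, EM collapse) are recorded
#' as untrained and later treated exactly like excluded 6-mers in site-level
#' 6-mer selection.
#'
#' @param neg_events,pos_events Data frames with columns `kmer` and
#'   `event_level` (negative and positive controls of one strand group).
#' @param config Configuration list, see [default_config()].
#' @return Object of class `kmer_model_set`: list with `models` (named list of
#'   [kmer_model]) and `untrained` (data frame of kmer, reason).
#' @export
train_kmer_models <- function(neg_events, pos_events, config = default_config()) {
  stopifnot(all(c("kmer", "event_level") %in% names(neg_events)),
            all(c("kmer", "event_level") %in% names(pos_events)))
  kmers <- intersect(unique(neg_events$kmer), unique(pos_events$kmer))
  kmers <- kmers[vapply(kmers, count_gpc, integer(1)) >= 1L]
  neg_split <- split(neg_events$event_level, neg_events$kmer)
  pos_split <- split(pos_events$event_level, pos_events$kmer)
  models <- list()
  untrained <- list()
  for (k in sort(kmers)) {
    fit <- tryCatch({
      neg <- fit_negative_model(neg_split[[k]], eps = config$sigma_eps)
      pos <- fit_positive_model(pos_split[[k]],
                                min_events = config$min_pos_events,
                                tol = config$em_tol,
                                max_iter = config$em_max_iter,
                                eps = config$sigma_eps,
                                restarts = config$em_restarts,
                                seed = config$seed)
      kmer_model(k, neg$mu0, neg$sigma0, pos$rho, pos$mu1, pos$sigma1,
                 pos$mu2, pos$sigma2, n_neg = neg$n, n_pos = pos$n)
    }, error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      untrained[[k]] <- fit
    } else {
      models[[k]] <- fit
    }
  }
  structure(
    list(models = models,
         untrained = data.frame(kmer = names(untrained),
                                reason = unlist(untrained, use.names = FALSE))),
    class = "kmer_model_set")
}

#' @export
print.kmer_model_set <- function(x, ...) {
  cat(sprintf("<kmer_model_set> %d trained, %d untrained 6-mers\n",
              length(x$models), nrow(x$untrained)))
  invisible(x)
}

#' @export
as.data.frame.kmer_model_set <- function(x, ...) {
  do.call(rbind, lapply(unname(x$models), function(m) {
    data.frame(kmer = m$kmer, mu0 = m$mu0, sigma0 = m$sigma0, rho = m$rho,
               mu1 = m$mu1, sigma1 = m$sigma1, mu2 = m$mu2, sigma2 = m$sigma2,
               discrimination = m$discrimination,
               n_neg = m$n_neg, n_pos = m$n_pos)
  })) %||% data.frame()
}

#' Choose the scoring 6-mer for one GpC site on one molecule
#'
#' Enumerates the six reference 6-mers covering the cytosine of the GpC site,
#' excludes any containing more than one GpC, any with more than
#' `max_events` event levels aligned from this molecule, and any untrained
#' 6-mer, and returns the survivor with maximal discrimination (ties broken
#' by leftmost 6-mer start).
#'
#' @param site 0-based reference position of the site's cytosine (for
#'   reverse-strand molecules: the forward-strand position of the G, which
#'   faces the reverse-strand C).
#' @param refseq Reference chromosome sequence (single character string).
#' @param models A `kmer_model_set` or named list of [kmer_model].
#' @param molecule_events Data frame of this molecule's events with columns
#'   `position` (0-based 6-mer start) and `event_level`.
#' @param strand `"+"` or `"-"`; reverse-strand candidates are the
#'   reverse-complement 6-mers covering the site.
#' @param max_events Exclusion threshold on aligned event levels per 6-mer.
#' @return List with `kmer`, `start`, `n_events`, `model`, or `NULL` when all
#'   six candidates are excluded (the site is skipped on this molecule).
#' @export
select_kmer <- function(site, refseq, models, molecule_events,
                        strand = "+", max_events = 10L) {
  if (inherits(models, "kmer_model_set")) models <- models$models
  starts <- (site - 5L):site
  starts <- starts[starts >= 0L & starts + 6L <= nchar(refseq)]
  best <- NULL
  for (st in starts) {
    km <- substr(refseq, st + 1L, st + 6L)
    if (strand == "-") km <- revcomp(km)
    if (count_gpc(km) != 1L) next
    n_ev <- sum(molecule_events$position == st)
    if (n_ev > max_events) next
    model <- models[[km]]
    if (is.null(model)) next
    if (is.null(best) || model$discrimination > best$model$discrimination) {
      best <- list(kmer = km, start = st, n_events = n_ev, model = model)
    }
  }
  best
}

#' Posterior methylation score from event levels
#'
#' Discards each event whose log-likelihood under either class model falls
#' below `log_filter` (natural log); if all events are discarded the call is
#' filtered (`NA` score). Otherwise the score is the posterior probability of
#' methylation under a flat prior,
#' `s = prod f_P / (prod f_P + prod f_N)` over the retained events, evaluated
#' in log space.
#'
#' @param event_levels Numeric vector of event levels aligned to the chosen
#'   6-mer on this molecule.
#' @param model The site's chosen [kmer_model].
#' @param log_filter Natural-log likelihood floor below which an event is
#'   discarded (default -10).
#' @return List with `score` (in \[0, 1\], or `NA` when filtered),
#'   `n_events` (events retained), `filtered`.
#' @export
methylation_score <- function(event_levels, model, log_filter = -10) {
  stopifnot(length(event_levels) >= 1L)
  lp <- f_pos(event_levels, model, log = TRUE)
  ln <- f_neg(event_levels, model, log = TRUE)
  keep <- lp >= log_filter & ln >= log_filter
  if (!any(keep)) {
    return(list(score = NA_real_, n_events = 0L, filtered = TRUE))
  }
  s <- 1 / (1 + exp(sum(ln[keep]) - sum(lp[keep])))
  list(score = s, n_events = sum(keep), filtered = FALSE)
}

#' Score all GpC sites of one molecule
#'
#' Enumerates GpC sites over the molecule's aligned span, picks the scoring
#' 6-mer per site with [select_kmer()], and computes the posterior methylation
#' score from the events aligned to it. Sites with no admissible 6-mer are
#' skipped; sites whose events are all likelihood-filtered are reported with
#' an `NA` score.
#'
#' @param events One molecule's events: data frame with columns `read_id`,
#'   `chrom`, `position` (0-based 6-mer start), `kmer`, `event_level`, and
#'   optionally `strand`.
#' @param refseq Reference sequence of the molecule's chromosome.
#' @param models A `kmer_model_set` for the molecule's strand group.
#' @param config Configuration list, see [default_config()].
#' @return Data frame: `read_id`, `chrom`, `position` (0-based site), `strand`,
#'   `score`, `chosen_kmer`, `n_events`.
#' @export
call_molecule_scores <- function(events, refseq, models,
                                 config = default_config()) {
  stopifnot(nrow(events) >= 1L, length(unique(events$read_id)) == 1L)
  strand <- if ("strand" %in% names(events)) events$strand[1] else "+"
  span_start <- min(events$position)
  span_end <- max(events$position) + 6L
  sites <- gpc_sites(refseq, span_start, span_end, strand)
  out <- lapply(sites, function(site) {
    sel <- select_kmer(site, refseq, models, events, strand = strand,
                       max_events = config$max_events_per_kmer)
    if (is.null(sel)) return(NULL)
    ev <- events$event_level[events$position == sel$start]
    if (length(ev) == 0L) return(NULL)
    call <- methylation_score(ev, sel$model, log_filter = config$log_filter)
    data.frame(read_id = events$read_id[1], chrom = events$chrom[1],
               position = site, strand = strand, score = call$score,
               chosen_kmer = sel$kmer, n_events = call$n_events)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(read_id = character(0), chrom = character(0),
                      position = integer(0), strand = character(0),
                      score = numeric(0), chosen_kmer = character(0),
                      n_events = integer(0))
  }
  out
}

#' Score every molecule of a sample
#'
#' @param events Event table for many reads (columns as in
#'   [call_molecule_scores()]).
#' @param reference Named character vector of chromosome sequences.
#' @param models A `kmer_model_set`.
#' @param config Configuration list.
#' @return Row-bound per-site score table across molecules.
#' @export
call_sample_scores <- function(events, reference, models,
                               config = default_config()) {
  parts <- lapply(split(events, events$read_id), function(ev) {
    call_molecule_scores(ev, reference[[ev$chrom[1]]], models, config)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Cross-validated single-event detection AUC
#'
#' Splits the control reads in half, trains per-6-mer models on one half, and
#' scores every held-out event with its 6-mer's model (single-event posterior).
#' The returned AUC measures how well the posterior separates held-out
#' positive-control from negative-control events.
#'
#' @param neg_events,pos_events Event tables with columns `read_id`, `kmer`,
#'   `event_level`.
#' @param config Configuration list.
#' @param seed Integer seed for the read split.
#' @return List with `auc`, `n_test`, `models`.
#' @export
crossval_auc <- function(neg_events, pos_events, config = default_config(),
                         seed = 1L) {
  set.seed(seed)
  split_half <- function(ev) {
    reads <- unique(ev$read_id)
    train_reads <- sample(reads, floor(length(reads) / 2))
    list(train = ev[ev$read_id %in% train_reads, , drop = FALSE],
         test = ev[!ev$read_id %in% train_reads, , drop = FALSE])
  }
  neg <- split_half(neg_events)
  pos <- split_half(pos_events)
  models <- train_kmer_models(neg$train, pos$train, config)
  score_half <- function(ev) {
    keep <- ev$kmer %in% names(models$models)
    ev <- ev[keep, , drop = FALSE]
    vapply(seq_len(nrow(ev)), function(i) {
      methylation_score(ev$event_level[i], models$models[[ev$kmer[i]]],
                        log_filter = config$log_filter)$score
    }, numeric(1))
  }
  s_neg <- score_half(neg$test)
  s_pos <- score_half(pos$test)
  keep_n <- !is.na(s_neg)
  keep_p <- !is.na(s_pos)
  scores <- c(s_neg[keep_n], s_pos[keep_p])
  labels <- c(rep(FALSE, sum(keep_n)), rep(TRUE, sum(keep_p)))
  list(auc = roc_auc(scores, labels), n_test = length(scores), models = models)
}

#' Bisulfite methylation-efficiency arithmetic
#'
#' Percentage of methylated GpC sites over all assayed sites across sequenced
#' colonies, e.g. 53 sites x 3 colonies with 1 unmethylated site gives
#' (159 - 1)/159 = 99.37%.
#'
#' @param n_sites GpC sites assayed per colony.
#' @param n_colonies Colonies sequenced.
#' @param n_unmethylated Total unmethylated sites observed.
#' @return Efficiency in percent.
#' @export
methylation_efficiency <- function(n_sites, n_colonies, n_unmethylated) {
  total <- n_sites * n_colonies
  stopifnot(total > 0, n_unmethylated >= 0, n_unmethylated <= total)
  100 * (total - n_unmethylated) / total
}
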