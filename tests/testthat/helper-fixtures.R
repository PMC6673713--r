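# fixtures built in code: toy molecules, well-separated densities, crafted
# paths, and synthetic event tables

make_molecule <- function(positions, scores, start = 0L,
                          end = max(positions) + 10L, read_id = "m1",
                          chrom = "chr", strand = "+") {
  molecule_scores(read_id, chrom, start, end, positions, scores,
                  strand = strand)
}

# sharply separated emission densities (shape >> calibrated default)
sep_density <- function(shape = 12) beta_score_density(shape)

make_path <- function(nucleosomes, start = 0L, end = 1000L, read_id = "m1",
                      chrom = "chr", strand = "+", log_likelihood = 0) {
  if (!"truncated_start" %in% names(nucleosomes)) {
    nucleosomes$truncated_start <- rep(FALSE, nrow(nucleosomes))
    nucleosomes$truncated_end <- rep(FALSE, nrow(nucleosomes))
  }
  structure(list(read_id = read_id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand,
                 nucleosomes = nucleosomes, log_likelihood = log_likelihood),
            class = "nucleosome_path")
}

# event table for n reads of one class over the given models
make_control_events <- function(models, n_reads, events_per_read = 30L,
                                class = c("neg", "pos"), prefix = "r") {
  class <- match.arg(class)
  do.call(rbind, lapply(seq_len(n_reads), function(i) {
    km <- sample(names(models), events_per_read, replace = TRUE)
    lev <- vapply(km, function(k) {
      m <- models[[k]]
      if (class == "neg") rnorm(1, m$mu0, m$sigma0)
      else if (runif(1) < m$rho) rnorm(1, m$mu1, m$sigma1)
      else rnorm(1, m$mu2, m$sigma2)
    }, numeric(1))
    data.frame(read_id = paste0(prefix, class, i), kmer = km,
               event_level = lev)
  }))
}

# draw a random molecule of the given length for oracle comparisons
random_short_molecule <- function(len, gpc_freq = 0.05) {
  pos <- which(runif(len) < gpc_freq) - 1L
  molecule_scores("m", "chr", 0L, len, pos, runif(length(pos)))
}
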