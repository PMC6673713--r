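# Rule-based chromatin-accessibility calling: accessible regions on single
# molecules, bulk peaks from per-site methylated-molecule ratios, promoter
# definition around the TSS, and open/closed promoter status per molecule.

# Chain qualifying adjacent-site pairs into regions. `ok` flags sites passing
# the level threshold; a pair of consecutive called sites qualifies when both
# are flagged and their distance is < max_gap; chains sharing a site merge.
# Regions shorter than min_length (end - start over the flanking C positions)
# are dropped. Returns indices of the flanking sites.
chain_regions <- function(positions, ok, max_gap = 100L, min_length = 100L) {
  n <- length(positions)
  empty <- data.frame(first = integer(0), last = integer(0))
  if (n < 2L) return(empty)
  pair_ok <- ok[-n] & ok[-1] & (diff(positions) < max_gap)
  if (!any(pair_ok)) return(empty)
  r <- rle(pair_ok)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  idx <- which(r$values)
  out <- data.frame(first = run_start[idx], last = run_end[idx] + 1L)
  keep <- positions[out$last] - positions[out$first] >= min_length
  out[keep, , drop = FALSE]
}

#' Accessible regions along one molecule
#'
#' An interval between two consecutive called GpC sites is accessible when
#' both scores exceed 0.5 and the sites are less than 100 bp apart;
#' overlapping/adjacent qualifying intervals are merged and merged regions
#' shorter than 100 bp are dropped. The region score is the median
#' methylation score of all GpC sites it contains (flanking sites included).
#'
#' @param molecule A [molecule_scores()].
#' @param score_cutoff Site-level score threshold (strict, default 0.5).
#' @param max_gap Maximum adjacent-site distance in bp (strict, default 100).
#' @param min_length Minimum region length in bp (inclusive, default 100).
#' @return Data frame `read_id`, `chrom`, `start`, `end`, `score`, `n_sites`,
#'   `strand`; `end - start` is the region length over the flanking C
#'   positions. May be empty.
#' @export
molecule_accessible_regions <- function(molecule, score_cutoff = 0.5,
                                        max_gap = 100L, min_length = 100L) {
  stopifnot(inherits(molecule, "molecule_scores"))
  pos <- molecule$positions
  s <- molecule$scores
  ch <- chain_regions(pos, s > score_cutoff, max_gap, min_length)
  if (nrow(ch) == 0L) {
    return(data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), score = numeric(0),
                      n_sites = integer(0), strand = character(0)))
  }
  start <- pos[ch$first]
  end <- pos[ch$last]
  stats_ <- vapply(seq_len(nrow(ch)), function(i) {
    inside <- pos >= start[i] & pos <= end[i]
    c(median(s[inside]), sum(inside))
  }, numeric(2))
  data.frame(read_id = molecule$read_id, chrom = molecule$chrom,
             start = start, end = end, score = stats_[1, ],
             n_sites = as.integer(stats_[2, ]), strand = molecule$strand)
}

#' Per-site methylated-molecule ratios
#'
#' For every called GpC site position, the fraction `r` of covering molecules
#' whose methylation score exceeds 0.5 and the molecule coverage `M`
#' (molecules with a called score at the site).
#'
#' @param scores Per-site score table (columns `chrom`, `position`, `score`;
#'   filter to one strand group first when calling strand-specific peaks).
#' @return Data frame `chrom`, `position`, `r`, `M`, sorted by position.
#' @export
site_ratios <- function(scores) {
  scores <- scores[!is.na(scores$score), , drop = FALSE]
  dt <- as.data.table(scores)
  out <- dt[, .(r = mean(score > 0.5), M = .N), by = .(chrom, position)]
  out <- out[order(chrom, position)]
  setDF(out)
  out
}

#' Bulk chromatin-accessibility peaks
#'
#' Applies the single-molecule pairing/merging/length rules to per-site
#' methylated-molecule ratios: adjacent GpC sites whose ratios both exceed
#' `peak_factor * rbar` (where `rbar` is the mean ratio over all sites
#' with coverage at least `min_cov`) and less than 100 bp apart seed a peak;
#' chains merge; peaks shorter than 100 bp are dropped.
#'
#' @param ratios Output of [site_ratios()] for one sample/strand group.
#' @param peak_factor Threshold multiplier on the genome-wide mean ratio
#'   (default 1.5).
#' @param max_gap,min_length As in [molecule_accessible_regions()].
#' @param min_cov Minimum molecule coverage for a site to participate
#'   (default 5).
#' @return Data frame `chrom`, `start`, `end`, `score` (median contained `r`),
#'   `n_sites`.
#' @export
bulk_peaks <- function(ratios, peak_factor = 1.5, max_gap = 100L,
                       min_length = 100L, min_cov = 5L) {
  ratios <- ratios[ratios$M >= min_cov, , drop = FALSE]
  if (nrow(ratios) == 0L) stop("no GpC site reaches min_cov = ", min_cov)
  rbar <- mean(ratios$r)
  thr <- peak_factor * rbar
  parts <- lapply(split(ratios, ratios$chrom), function(df) {
    df <- df[order(df$position), , drop = FALSE]
    ch <- chain_regions(df$position, df$r > thr, max_gap, min_length)
    if (nrow(ch) == 0L) return(NULL)
    start <- df$position[ch$first]
    end <- df$position[ch$last]
    st <- vapply(seq_len(nrow(ch)), function(i) {
      inside <- df$position >= start[i] & df$position <= end[i]
      c(median(df$r[inside]), sum(inside))
    }, numeric(2))
    data.frame(chrom = df$chrom[1], start = start, end = end,
               score = st[1, ], n_sites = as.integer(st[2, ]))
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      n_sites = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Strand-concordant peak intersection
#'
#' Intersects the forward- and reverse-strand peak sets; the overlap segments
#' are the strand-concordant accessible peaks.
#'
#' @param fwd_peaks,rev_peaks Peak data frames (`chrom`, `start`, `end`,
#'   half-open).
#' @return Data frame `chrom`, `start`, `end` of overlap segments.
#' @export
concordant_peaks <- function(fwd_peaks, rev_peaks) {
  chroms <- intersect(unique(fwd_peaks$chrom), unique(rev_peaks$chrom))
  parts <- lapply(chroms, function(ch) {
    f <- fwd_peaks[fwd_peaks$chrom == ch, , drop = FALSE]
    r <- rev_peaks[rev_peaks$chrom == ch, , drop = FALSE]
    ir <- IRanges::intersect(
      IRanges::reduce(IRanges::IRanges(f$start + 1L, f$end)),
      IRanges::reduce(IRanges::IRanges(r$start + 1L, r$end)))
    if (length(ir) == 0L) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir))
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  }
  rownames(out) <- NULL
  out
}

# gene-strand-oriented promoter search window around the TSS, half-open,
# including the TSS base; upstream/downstream follow the gene strand unless
# unstranded = TRUE reproduces a strand-naive reading
promoter_window <- function(tss, strand, upstream = 500L, downstream = 100L,
                            unstranded = FALSE) {
  if (unstranded || strand == "+") {
    c(start = tss - upstream, end = tss + downstream + 1L)
  } else {
    c(start = tss - downstream, end = tss + upstream + 1L)
  }
}

#' Define the promoter region of a gene
#'
#' Looks for accessibility peaks overlapping the "-500, +100" window around
#' the TSS (oriented by gene strand): with exactly one overlapping peak the
#' peak is the promoter; with several, the peak with the longest overlap wins
#' (ties broken by the peak nearer the TSS); with none, the window itself is
#' the promoter.
#'
#' @param gene List or one-row data frame with `chrom`, `tss` (0-based),
#'   `strand`.
#' @param peaks Merged peak set (`chrom`, `start`, `end`), possibly empty or
#'   `NULL`.
#' @param upstream,downstream Window extent in bp (defaults 500/100).
#' @param unstranded Ignore gene strand when orienting the window.
#' @return Data frame `chrom`, `start`, `end`, `source` (`"peak"` or
#'   `"window"`).
#' @export
define_promoter <- function(gene, peaks = NULL, upstream = 500L,
                            downstream = 100L, unstranded = FALSE) {
  w <- promoter_window(gene$tss, gene$strand, upstream, downstream, unstranded)
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    p <- peaks[peaks$chrom == gene$chrom, , drop = FALSE]
    if (nrow(p) > 0L) {
      ov <- pmin(p$end, w[["end"]]) - pmax(p$start, w[["start"]])
      p <- p[ov > 0L, , drop = FALSE]
      ov <- ov[ov > 0L]
      if (nrow(p) > 0L) {
        dist <- ifelse(p$start <= gene$tss & gene$tss < p$end, 0L,
                       pmin(abs(p$start - gene$tss), abs(p$end - 1L - gene$tss)))
        i <- order(-ov, dist, p$start)[1]
        return(data.frame(chrom = gene$chrom, start = p$start[i],
                          end = p$end[i], source = "peak"))
      }
    }
  }
  data.frame(chrom = gene$chrom, start = w[["start"]], end = w[["end"]],
             source = "window")
}

#' Open/closed promoter status of one molecule
#'
#' The accessibility score of the promoter on this molecule is the median
#' methylation score of the GpC sites inside the promoter interval; the
#' status is open when the median strictly exceeds 0.5. Only molecules fully
#' covering the promoter are callable; a covering molecule with no called
#' GpC site inside yields no call.
#'
#' @param molecule A [molecule_scores()].
#' @param promoter Promoter interval (`start`, `end`) from
#'   [define_promoter()].
#' @return List with `read_id`, `score`, `status` (`"open"`, `"closed"`, or
#'   `"no_call"`), `n_sites`; `NULL` when the molecule does not fully cover
#'   the promoter.
#' @export
call_promoter_status <- function(molecule, promoter) {
  stopifnot(inherits(molecule, "molecule_scores"))
  if (molecule$start > promoter$start || molecule$end < promoter$end) {
    return(NULL)
  }
  inside <- molecule$positions >= promoter$start &
    molecule$positions <= promoter$end
  s <- molecule$scores[inside]
  if (length(s) == 0L) {
    return(list(read_id = molecule$read_id, score = NA_real_,
                status = "no_call", n_sites = 0L))
  }
  sc <- median(s)
  list(read_id = molecule$read_id, score = sc,
       status = if (sc > 0.5) "open" else "closed", n_sites = length(s))
}

#' Promoter calls for many molecules
#'
#' @param molecules List of [molecule_scores()].
#' @param promoter Promoter interval from [define_promoter()].
#' @param gene_id Gene identifier attached to the calls.
#' @return Data frame `gene_id`, `read_id`, `score`, `status` (one row per
#'   molecule fully covering the promoter).
#' @export
promoter_calls <- function(molecules, promoter, gene_id = NA_character_) {
  rows <- lapply(molecules, function(m) {
    call <- call_promoter_status(m, promoter)
    if (is.null(call)) return(NULL)
    data.frame(gene_id = gene_id, read_id = call$read_id, score = call$score,
               status = call$status)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), read_id = character(0),
                      score = numeric(0), status = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Bulk promoter openness
#'
#' Fraction of open molecules among those with an open/closed call (no-calls
#' excluded).
#'
#' @param statuses Character vector of `"open"` / `"closed"` / `"no_call"`.
#' @return Openness in \[0, 1\], or `NA` with zero callable molecules.
#' @export
bulk_openness <- function(statuses) {
  called <- statuses %in% c("open", "closed")
  if (!any(called)) return(NA_real_)
  mean(statuses[called] == "open")
}

#' Differential accessibility between two conditions
#'
#' @param openness_a,openness_b Bulk openness of the same promoter under two
#'   conditions (condition A minus condition B).
#' @return Difference in \[-1, 1\]; `NA` when either side is missing.
#' @export
differential_accessibility <- function(openness_a, openness_b) {
  if (is.na(openness_a) || is.na(openness_b)) return(NA_real_)
  openness_a - openness_b
}
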