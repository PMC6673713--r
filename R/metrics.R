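# Downstream single-molecule chromatin statistics: +1-nucleosome positioning
# heterogeneity across cells, nucleosome spacing uniformity, combinatorial
# promoter patterns, score-distance correlograms, openness clustering, and
# per-molecule nucleosome counts.

#' Re-anchor a decoded path on a gene's TSS
#'
#' Nucleosome centers and linker intervals of a decoded molecule expressed in
#' TSS-relative, gene-strand-oriented coordinates (positive = downstream).
#' Linkers are the gaps between adjacent nucleosome calls on the molecule.
#'
#' @param path A `nucleosome_path`.
#' @param tss 0-based TSS position.
#' @param strand Gene strand (`"+"` or `"-"`).
#' @return Object of class `tss_anchored_path`: `read_id`, `centers` (sorted
#'   relative centers), `linkers` (absolute-coordinate data frame `start`,
#'   `end`), `tss`, `strand`.
#' @export
tss_anchored_path <- function(path, tss, strand = "+") {
  nuc <- path$nucleosomes[order(path$nucleosomes$start), , drop = FALSE]
  centers_abs <- (nuc$start + nuc$end) / 2
  centers <- if (strand == "+") centers_abs - tss else tss - centers_abs
  linkers <- if (nrow(nuc) >= 2L) {
    data.frame(start = nuc$end[-nrow(nuc)], end = nuc$start[-1])
  } else {
    data.frame(start = integer(0), end = integer(0))
  }
  structure(list(read_id = path$read_id, centers = sort(centers),
                 linkers = linkers, tss = tss, strand = strand),
            class = "tss_anchored_path")
}

#' Distance from the TSS to the +1 nucleosome
#'
#' The +1 nucleosome is the one whose center lies downstream of (or exactly
#' at) the TSS and closest to it on this molecule.
#'
#' @param anchored A [tss_anchored_path()].
#' @return Distance in bp, or `NA` when no nucleosome center lies downstream.
#' @export
plus_one_distance <- function(anchored) {
  down <- anchored$centers[anchored$centers >= 0]
  if (length(down) == 0L) return(NA_real_)
  min(down)
}

#' Nucleosome positioning heterogeneity across cells
#'
#' Standard deviation of per-cell +1-nucleosome distances after discarding
#' the largest `floor(trim * n)` values for robustness against molecules
#' whose first downstream nucleosome sits far from the TSS.
#'
#' @param distances Per-cell +1 distances in bp (`NA` dropped).
#' @param min_cells Minimum number of cells required (default 10).
#' @param trim Upper trim fraction (default 0.1).
#' @return Unbiased SD of the retained distances, or `NA` below `min_cells`.
#' @export
positioning_heterogeneity <- function(distances, min_cells = 10L, trim = 0.1) {
  d <- distances[!is.na(distances)]
  n <- length(d)
  if (n < min_cells) return(NA_real_)
  k <- floor(trim * n)
  keep <- sort(d)[seq_len(n - k)]
  sd(keep)
}

#' Linker lengths within the promoter-proximal window
#'
#' Lengths of the linkers of one anchored molecule that fall in the
#' "-500, +100" window around the TSS; by default partially overlapping
#' linkers are clipped to the window, alternatively whole linkers are taken
#' when they overlap it.
#'
#' @param anchored A [tss_anchored_path()].
#' @param upstream,downstream Window extent in bp (defaults 500/100).
#' @param clip Clip linkers to the window (default) instead of taking whole
#'   overlapping linkers.
#' @return Numeric vector of linker lengths in bp.
#' @export
window_linker_lengths <- function(anchored, upstream = 500L,
                                  downstream = 100L, clip = TRUE) {
  w <- promoter_window(anchored$tss, anchored$strand, upstream, downstream)
  lk <- anchored$linkers
  if (nrow(lk) == 0L) return(numeric(0))
  ov <- pmin(lk$end, w[["end"]]) - pmax(lk$start, w[["start"]])
  if (clip) ov[ov > 0] else (lk$end - lk$start)[ov > 0]
}

#' Nucleosome spacing uniformity of one molecule
#'
#' Mean absolute pairwise deviation of linker lengths: the sum of
#' `|d_i - d_j|` over all unordered linker pairs divided by the number of
#' pairs. Zero means perfectly even spacing.
#'
#' @param linker_lengths Linker lengths in bp (at least 2).
#' @return Mean pairwise absolute deviation, or `NA` with fewer than 2
#'   linkers.
#' @export
spacing_uniformity <- function(linker_lengths) {
  x <- linker_lengths[!is.na(linker_lengths)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- abs(outer(x, x, "-"))
  sum(m[upper.tri(m)]) / choose(n, 2)
}

#' Combinatorial promoter-status patterns
#'
#' Tabulates the joint open/closed pattern over a set of gene promoters across
#' molecules that carry a status for every listed gene; molecules missing any
#' status are excluded and counted.
#'
#' @param status Matrix or data frame (molecules x genes) of `"open"` /
#'   `"closed"` entries, `NA` or `"no_call"` marking a missing status.
#' @return Object of class `pattern_table`: `genes`, `possible`
#'   (`2^n_genes`), `counts` (named integer vector, patterns as
#'   comma-separated status strings, decreasing), `n_molecules`, `n_excluded`.
#' @export
combinatorial_patterns <- function(status) {
  status <- as.matrix(status)
  status[status == "no_call"] <- NA
  if (is.null(colnames(status))) {
    colnames(status) <- paste0("gene", seq_len(ncol(status)))
  }
  complete <- rowSums(is.na(status)) == 0L
  pat <- apply(status[complete, , drop = FALSE], 1, paste, collapse = ",")
  counts <- sort(table(pat), decreasing = TRUE)
  structure(list(genes = colnames(status),
                 possible = 2L^ncol(status),
                 counts = setNames(as.integer(counts), names(counts)),
                 n_molecules = sum(complete),
                 n_excluded = sum(!complete)),
            class = "pattern_table")
}

#' @export
print.pattern_table <- function(x, ...) {
  cat(sprintf("<pattern_table> %d observed of %d possible patterns over %s (%d molecules, %d excluded)\n",
              length(x$counts), x$possible, paste(x$genes, collapse = "/"),
              x$n_molecules, x$n_excluded))
  invisible(x)
}

#' Distance-binned correlation of paired GpC methylation scores
#'
#' For every within-molecule pair of called GpC sites, bins the pair by
#' site distance and computes the Pearson correlation of the paired scores
#' pooled over molecules (both pair orders included, making the statistic
#' symmetric). The periodic decay of this correlogram reflects the
#' nucleosome repeat length.
#'
#' @param scores Per-site score table (`read_id`, `position`, `score`).
#' @param max_distance Largest pair distance considered (default 500 bp).
#' @param bin Bin width in bp (default 10).
#' @param min_pairs Minimum unordered pairs per bin (default 100); bins below
#'   it report `NA`.
#' @return Data frame `dist_lo`, `dist_hi`, `dist_mid`, `n_pairs`,
#'   `correlation`.
#' @export
score_autocorrelation <- function(scores, max_distance = 500L, bin = 10L,
                                  min_pairs = 100L) {
  scores <- scores[!is.na(scores$score), , drop = FALSE]
  parts <- lapply(split(scores, scores$read_id), function(df) {
    n <- nrow(df)
    if (n < 2L) return(NULL)
    df <- df[order(df$position), , drop = FALSE]
    d <- outer(df$position, df$position, "-")
    keep <- which(d > 0 & d <= max_distance, arr.ind = TRUE)
    if (nrow(keep) == 0L) return(NULL)
    data.table(d = d[keep],
               s1 = df$score[keep[, 1]],
               s2 = df$score[keep[, 2]])
  })
  pairs <- data.table::rbindlist(parts)
  bins <- data.frame(dist_lo = seq(0L, max_distance - bin, by = bin))
  bins$dist_hi <- bins$dist_lo + bin
  bins$dist_mid <- bins$dist_lo + bin / 2
  bins$n_pairs <- 0L
  bins$correlation <- NA_real_
  if (nrow(pairs) == 0L) return(bins)
  # duplicate with swapped order so the correlation is symmetric in pair order
  pairs <- rbind(pairs, pairs[, .(d, s1 = s2, s2 = s1)])
  pairs[, bin_i := pmin(d %/% bin, nrow(bins) - 1L)]
  stats_ <- pairs[, .(n = .N %/% 2L,
                      cc = if (var(s1) > 0 && var(s2) > 0) cor(s1, s2)
                           else NA_real_),
                  by = bin_i]
  bins$n_pairs[stats_$bin_i + 1L] <- stats_$n
  ok <- stats_$n >= min_pairs
  bins$correlation[stats_$bin_i[ok] + 1L] <- stats_$cc[ok]
  bins
}

#' Cluster molecules by promoter-window occupancy profile
#'
#' Bins per-base occupancy indicator vectors to fixed-width mean features and
#' partitions molecules by k-means; clusters are relabeled in decreasing
#' openness (1 minus mean occupancy), so cluster 1 is the most open.
#'
#' @param occupancy Numeric matrix (molecules x bases) of 0/1 occupancy over
#'   a common window; all molecules must fully cover it.
#' @param k Number of clusters (default 3: closed, narrow open, wide open).
#' @param bin Feature bin width in bp (default 10).
#' @param nstart k-means restarts (default 20).
#' @param seed Optional seed for the k-means initialization.
#' @return List with `labels` (per-molecule cluster), `profiles` (k x bins
#'   mean-occupancy matrix), `openness` (per-cluster), `sizes`.
#' @export
cluster_openness <- function(occupancy, k = 3L, bin = 10L, nstart = 20L,
                             seed = NULL) {
  occupancy <- as.matrix(occupancy)
  if (k > nrow(occupancy)) stop("k exceeds the number of molecules")
  grp <- (seq_len(ncol(occupancy)) - 1L) %/% bin
  feat <- vapply(split(seq_len(ncol(occupancy)), grp),
                 function(ix) rowMeans(occupancy[, ix, drop = FALSE]),
                 numeric(nrow(occupancy)))
  feat <- matrix(feat, nrow = nrow(occupancy))
  if (!is.null(seed)) set.seed(seed)
  km <- kmeans(feat, centers = k, nstart = nstart)
  openness <- 1 - rowMeans(km$centers)
  ord <- order(openness, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  list(labels = relabel[km$cluster],
       profiles = km$centers[ord, , drop = FALSE],
       openness = openness[ord],
       sizes = as.integer(table(factor(relabel[km$cluster], levels = seq_len(k)))))
}

#' Complete-nucleosome counts per molecule
#'
#' @param paths List of `nucleosome_path` objects.
#' @return List with `counts` (per molecule, truncated calls excluded),
#'   `median`, `max`.
#' @export
nucleosomes_per_molecule <- function(paths) {
  stopifnot(length(paths) >= 1L)
  counts <- vapply(paths, function(p) {
    sum(!(p$nucleosomes$truncated_start | p$nucleosomes$truncated_end))
  }, integer(1))
  list(counts = counts, median = median(counts), max = max(counts))
}
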