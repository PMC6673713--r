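`%||%` <- function(x, y) if (is.null(x)) y else x

#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney AUC: the probability that a randomly drawn positive scores
#' higher than a randomly drawn negative, with ties counted half.
#'
#' @param scores Numeric score vector.
#' @param labels Logical (or 0/1) vector, `TRUE` = positive class.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be represented")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# reverse complement of a plain DNA character string (ACGT only)
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# number of GpC dinucleotides ("GC") in a sequence
count_gpc <- function(kmer) {
  m <- gregexpr("GC", kmer, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

# trapezoid integral on an equally spaced grid
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# 0-based positions of GpC cytosines within [start, end) of a reference string.
# On the forward strand the methylated C is the C of "GC"; on the reverse
# strand the same dinucleotide (GpC is its own reverse complement) carries its
# C opposite the forward G, one base to the left.
gpc_sites <- function(refseq, start, end, strand = "+") {
  stopifnot(start >= 0, end <= nchar(refseq), end > start)
  sub <- substr(refseq, start + 1L, end)
  m <- gregexpr("GC", sub, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  g_pos <- start + as.integer(m) - 1L  # 0-based forward-strand G
  if (strand == "+") g_pos + 1L else g_pos
}
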