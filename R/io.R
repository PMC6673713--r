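# Readers and writers for the pipeline's plain-text formats: event-alignment
# TSV (nanopolish eventalign dialect), reference FASTA, BED-like annotation
# and interval files, bedGraph tracks, score/model tables, YAML configuration.
# All intervals are 0-based half-open internally and on disk; missing values
# are written as ".".

#' Default run configuration
#'
#' Thresholds and tolerances of the pipeline: the site-score cutoff (0.5),
#' region/peak geometry (pair distance < 100 bp, length >= 100 bp, peak
#' factor 1.5), promoter window (-500/+100 around the TSS), minimum
#' coverages, EM settings, the event likelihood filter, and the seed.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(score_cutoff = 0.5,
       max_pair_gap = 100L,
       region_min_length = 100L,
       peak_factor = 1.5,
       promoter_upstream = 500L,
       promoter_downstream = 100L,
       min_cov = 5L,
       min_pos_events = 20L,
       max_events_per_kmer = 10L,
       min_scores = 100L,
       log_filter = -10,
       sigma_eps = 1e-3,
       em_tol = 1e-6,
       em_max_iter = 500L,
       em_restarts = 3L,
       score_shape = 2.1486,
       seed = 1L)
}

#' Read a YAML run configuration
#'
#' Values present in the file override [default_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0L) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(base, user)
  stopifnot(cfg$max_pair_gap > 0, cfg$region_min_length > 0,
            cfg$peak_factor > 0, cfg$min_cov > 0)
  cfg
}

#' Read an event-alignment table
#'
#' Tab-separated `nanopolish eventalign` dialect with a header; the columns
#' `contig`, `position`, `reference_kmer`, `read_name` and
#' `event_level_mean` are required (extra columns are ignored; an optional
#' `strand` column is kept). Rows with an unparseable position or event level
#' are skipped with a warning.
#'
#' @param path TSV file path.
#' @return Data frame `read_id`, `chrom`, `position` (0-based 6-mer start),
#'   `kmer`, `event_level`, `strand`.
#' @export
read_eventalign <- function(path) {
  required <- c("contig", "position", "reference_kmer", "read_name",
                "event_level_mean")
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  missing <- setdiff(required, names(dt))
  if (length(missing) > 0L) {
    stop("event-alignment table lacks required columns: ",
         paste(missing, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(dt$position))
  lev <- suppressWarnings(as.numeric(dt$event_level_mean))
  bad <- is.na(pos) | is.na(lev)
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) skipped in ", path)
  }
  out <- data.frame(read_id = dt$read_name[!bad], chrom = dt$contig[!bad],
                    position = pos[!bad], kmer = dt$reference_kmer[!bad],
                    event_level = lev[!bad],
                    strand = if ("strand" %in% names(dt)) dt$strand[!bad]
                             else "+")
  out
}

#' Write an event-alignment table
#'
#' @param events Data frame as returned by [read_eventalign()].
#' @param path Output TSV path.
#' @export
write_eventalign <- function(events, path) {
  out <- data.frame(contig = events$chrom, position = events$position,
                    reference_kmer = events$kmer, read_name = events$read_id,
                    event_level_mean = events$event_level,
                    strand = events$strand %||% "+")
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a gene annotation BED
#'
#' Six-column headerless BED (`chrom`, `start`, `end`, `gene_id`, `score`,
#' `strand`, 0-based half-open). The TSS is `start` on the forward strand and
#' `end - 1` on the reverse strand.
#'
#' @param path BED file path.
#' @return Data frame `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
read_annotation <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 6L) stop("annotation BED needs 6 columns")
  names(dt)[1:6] <- c("chrom", "start", "end", "gene_id", "score", "strand")
  if (!all(dt$strand %in% c("+", "-"))) {
    stop("unknown strand symbol in annotation: ",
         paste(setdiff(unique(dt$strand), c("+", "-")), collapse = ", "))
  }
  if (anyDuplicated(dt$gene_id)) {
    stop("duplicate gene id(s): ",
         paste(unique(dt$gene_id[duplicated(dt$gene_id)]), collapse = ", "))
  }
  data.frame(gene_id = dt$gene_id, chrom = dt$chrom, start = dt$start,
             end = dt$end, strand = dt$strand,
             tss = ifelse(dt$strand == "+", dt$start, dt$end - 1L))
}

#' Read a reference FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of chromosome sequences (uppercase).
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` plus any further columns supplied, sorted
#' within chromosome, headerless and tab-separated; `NA` becomes ".".
#'
#' @param intervals Data frame with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @param columns Extra columns to keep after the first three, in order.
#' @export
write_bed <- function(intervals, path,
                      columns = setdiff(names(intervals),
                                        c("chrom", "start", "end"))) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  out <- intervals[order(intervals$chrom, intervals$start, intervals$end),
                   c("chrom", "start", "end", columns), drop = FALSE]
  fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE, na = ".")
  invisible(path)
}

#' Read a BED-like interval file
#'
#' @param path BED path (headerless, tab-separated).
#' @param col_names Names for the columns present.
#' @return Data frame.
#' @export
read_bed <- function(path, col_names = c("chrom", "start", "end")) {
  dt <- fread(path, sep = "\t", header = FALSE, na.strings = ".")
  names(dt)[seq_along(col_names)] <- col_names
  setDF(dt)
  dt
}

#' Write a bedGraph track
#'
#' @param track A `nucleosome_track` (see [nucleosome_track()]).
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  write_bed(track_bedgraph(track), path, columns = "value")
}

#' Write a tab-separated table with "." for missing values
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  fwrite(x, path, sep = "\t", quote = FALSE, na = ".")
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, na.strings = ".")
  setDF(dt)
  dt
}

#' Write a trained model table
#'
#' @param models A `kmer_model_set`.
#' @param path Output TSV path.
#' @export
write_model_table <- function(models, path) {
  write_tsv(as.data.frame(models), path)
}

#' Read a trained model table back into a model set
#'
#' @param path TSV written by [write_model_table()].
#' @return A `kmer_model_set`.
#' @export
read_model_table <- function(path) {
  df <- read_tsv(path)
  models <- lapply(seq_len(nrow(df)), function(i) {
    kmer_model(df$kmer[i], df$mu0[i], df$sigma0[i], df$rho[i], df$mu1[i],
               df$sigma1[i], df$mu2[i], df$sigma2[i],
               n_neg = df$n_neg[i], n_pos = df$n_pos[i])
  })
  structure(list(models = setNames(models, df$kmer),
                 untrained = data.frame(kmer = character(0),
                                        reason = character(0))),
            class = "kmer_model_set")
}

# short stable content hash (djb2 over the YAML rendering) for manifests
config_hash <- function(config) {
  bytes <- utf8ToInt(yaml::as.yaml(config[order(names(config))]))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Write a run manifest
#'
#' Records the package version, configuration hash, and seed of a pipeline
#' run for reproducibility.
#'
#' @param path Output YAML path.
#' @param config Configuration list.
#' @param seed Integer seed of the run.
#' @export
write_manifest <- function(path, config, seed) {
  yaml::write_yaml(list(package = "nucfoot",
                        version = as.character(packageVersion("nucfoot")),
                        config_hash = config_hash(config),
                        seed = as.integer(seed)),
                   path)
  invisible(path)
}
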