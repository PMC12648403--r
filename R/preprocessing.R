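# ENCODE-style dataset construction: one-hot encoding, positive window
# extraction with random shifts, bottom-5% signal filtering, upstream
# negatives, log10(1+x) signal transform, and PCM-based per-base binary
# labeling. Coordinates are 0-based half-open (BED convention) throughout.

#' One-hot encode a DNA sequence
#'
#' `A=[1,0,0,0], C=[0,1,0,0], G=[0,0,1,0], T=[0,0,0,1]`; `N` encodes as an
#' all-zero row. Case-insensitive.
#'
#' @param sequence Character scalar over `{A,C,G,T,N}` (or a
#'   `Biostrings::DNAString`).
#' @return `L x 4` binary matrix with columns A, C, G, T.
#' @export
one_hot <- function(sequence) {
  s <- toupper(as.character(sequence))
  letters <- strsplit(s, "")[[1]]
  idx <- match(letters, c("A", "C", "G", "T", "N"))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("invalid character '", letters[bad], "' at position ", bad)
  }
  m <- matrix(0, length(letters), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  keep <- idx <= 4L
  m[cbind(which(keep), idx[keep])] <- 1
  m
}

#' Transform a raw binding signal value
#'
#' `log10(1 + x)`: monotone, maps 0 to 0, compresses the heavy right tail of
#' ChIP-seq coverage.
#'
#' @param x Nonnegative numeric vector.
#' @return Transformed values.
#' @export
transform_signal <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) stop("signal values must be finite and >= 0")
  log10(1 + x)
}

# fetch [start, end) (0-based half-open) from a named genome
genome_fetch <- function(genome, chrom, start, end) {
  seqs <- if (methods::is(genome, "DNAStringSet")) {
    as.character(genome[[chrom]])
  } else {
    genome[[chrom]]
  }
  substr(seqs, start + 1L, end)
}

genome_len <- function(genome, chrom) {
  if (methods::is(genome, "DNAStringSet")) {
    Biostrings::width(genome)[match(chrom, names(genome))]
  } else {
    nchar(genome[[chrom]])
  }
}

#' Sentinel for an example dropped during extraction
#' @param reason Character drop reason.
#' @return Object of class `skipped_example`.
#' @export
skipped_example <- function(reason) {
  structure(list(reason = reason), class = "skipped_example")
}

#' Test whether an extraction result was skipped
#' @param x Result of [extract_positive()] or [make_negative()].
#' @return Logical.
#' @export
is_skipped <- function(x) inherits(x, "skipped_example")

#' Extract a positive training example around a peak
#'
#' Takes a `length`-bp window centered on the peak summit plus a uniform
#' random integer shift (default -100..100 bp, noise injection), together
#' with the per-base signal slice. Windows that would leave the chromosome
#' are skipped and reported in the dataset drop report.
#'
#' @param peak One-row data.frame with `chrom`, `peak_position` (0-based),
#'   `signal_value`.
#' @param genome Named list of chromosome strings or a
#'   `Biostrings::DNAStringSet`.
#' @param signal Named list of per-base numeric signal vectors (position i =
#'   0-based coordinate i-1); may be `NULL` for sequence-only examples.
#' @param length Window length in bp (default 1000).
#' @param shift_range Integer range of the random shift (default c(-100, 100)).
#' @return A `labeled_example` list (sequence, onehot, signal,
#'   signal_transformed, is_positive, chrom, start, summit_signal), or a
#'   `skipped_example` carrying the drop reason.
#' @export
extract_positive <- function(peak, genome, signal = NULL, length = 1000L,
                             shift_range = c(-100L, 100L)) {
  shift <- if (shift_range[1] == shift_range[2]) shift_range[1] else
    sample(shift_range[1]:shift_range[2], 1L)
  center <- peak$peak_position + shift
  start <- center - length %/% 2L
  end <- start + length
  L <- genome_len(genome, peak$chrom)
  if (start < 0L || end > L) {
    return(skipped_example("window_out_of_bounds"))
  }
  seqc <- genome_fetch(genome, peak$chrom, start, end)
  sig <- if (!is.null(signal)) signal[[peak$chrom]][(start + 1L):end] else NULL
  structure(list(sequence = seqc, onehot = one_hot(seqc),
                 signal = sig,
                 signal_transformed = if (!is.null(sig)) transform_signal(sig) else NULL,
                 is_positive = TRUE, chrom = peak$chrom, start = start,
                 summit_signal = peak$signal_value),
            class = "labeled_example")
}

#' Drop the lowest-signal examples
#'
#' Removes the `floor(fraction * n)` examples with the smallest summit
#' signal (bottom 5% by default), keeping the original order otherwise; ties
#' at the cutoff drop the earliest examples.
#'
#' @param examples List of `labeled_example`s with `summit_signal`.
#' @param fraction Fraction to drop (default 0.05).
#' @return Filtered list.
#' @export
filter_low_signal <- function(examples, fraction = 0.05) {
  n <- length(examples)
  k <- floor(fraction * n)
  if (n == 0L || k == 0L) return(examples)
  vals <- vapply(examples, function(e) e$summit_signal, numeric(1))
  drop <- order(vals, seq_len(n))[seq_len(k)]   # ties: earliest dropped first
  examples[-drop]
}

#' Construct an upstream negative example
#'
#' A `length`-bp window centered `offset` bp upstream of the peak summit;
#' skipped if out of bounds or overlapping any peak interval.
#'
#' @inheritParams extract_positive
#' @param peaks_all data.frame of all peak intervals (`chrom`, `start`,
#'   `end`) the negative must not overlap.
#' @param offset Upstream distance in bp (default 3000).
#' @return A `labeled_example`, or a `skipped_example` carrying the drop
#'   reason.
#' @export
make_negative <- function(peak, genome, signal = NULL, peaks_all = NULL,
                          length = 1000L, offset = 3000L) {
  center <- peak$peak_position - offset
  start <- center - length %/% 2L
  end <- start + length
  if (start < 0L || end > genome_len(genome, peak$chrom)) {
    return(skipped_example("window_out_of_bounds"))
  }
  if (!is.null(peaks_all)) {
    same <- peaks_all[peaks_all$chrom == peak$chrom, , drop = FALSE]
    if (nrow(same) > 0 && any(pmax(same$start, start) < pmin(same$end, end))) {
      return(skipped_example("overlaps_peak"))
    }
  }
  seqc <- genome_fetch(genome, peak$chrom, start, end)
  sig <- if (!is.null(signal)) signal[[peak$chrom]][(start + 1L):end] else NULL
  structure(list(sequence = seqc, onehot = one_hot(seqc),
                 signal = sig,
                 signal_transformed = if (!is.null(sig)) transform_signal(sig) else NULL,
                 is_positive = FALSE, chrom = peak$chrom, start = start,
                 summit_signal = peak$signal_value),
            class = "labeled_example")
}

# position weight (log-odds) matrix from a count matrix: pseudocount 1,
# uniform background 0.25; rows = positions, cols = A,C,G,T
pcm_to_logodds <- function(pcm, pseudocount = 1, background = rep(0.25, 4)) {
  pcm <- as.matrix(pcm)
  if (ncol(pcm) != 4L || nrow(pcm) < 1L || any(pcm < 0) || any(!is.finite(pcm))) {
    stop("PCM must be a w x 4 matrix of nonnegative counts")
  }
  p <- (pcm + pseudocount) / (rowSums(pcm) + 4 * pseudocount)
  log2(sweep(p, 2, background, "/"))
}

revcomp_matrix <- function(m) m[rev(seq_len(nrow(m))), 4:1, drop = FALSE]

# score every width-w window of a one-hot matrix against a log-odds matrix
scan_scores <- function(onehot, lo) {
  w <- nrow(lo)
  L <- nrow(onehot)
  n <- L - w + 1L
  s <- numeric(n)
  for (j in seq_len(w)) {
    s <- s + onehot[j:(n + j - 1L), , drop = FALSE] %*% lo[j, ]
  }
  as.numeric(s)
}

#' Per-base binary labels from a position count matrix
#'
#' Converts the PCM to log-odds weights (pseudocount 1, uniform background),
#' scans both strands, and labels 1 every base covered by a window whose
#' score reaches `threshold_fraction` of the maximum attainable score.
#'
#' @param sequence Character DNA sequence (or one-hot matrix).
#' @param pcm `w x 4` nonnegative count matrix (rows = positions).
#' @param threshold_fraction Fraction of the maximum log-odds score required
#'   (default 0.8).
#' @return Integer vector of 0/1 labels, one per base.
#' @export
label_binary <- function(sequence, pcm, threshold_fraction = 0.8) {
  onehot <- if (is.matrix(sequence)) sequence else one_hot(sequence)
  lo <- pcm_to_logodds(pcm)
  w <- nrow(lo)
  if (w > nrow(onehot)) stop("PCM wider than sequence")
  max_score <- sum(apply(lo, 1, max))
  thr <- threshold_fraction * max_score
  lab <- integer(nrow(onehot))
  for (mat in list(lo, revcomp_matrix(lo))) {
    sc <- scan_scores(onehot, mat)
    hit <- which(sc >= thr)
    for (h in hit) lab[h:(h + w - 1L)] <- 1L
  }
  lab
}

#' Build a labeled dataset from genome, peaks and signal
#'
#' Runs the full extraction pipeline: one positive per peak (random shift),
#' bottom-fraction signal filtering, one upstream negative attempted per
#' surviving peak, per-base labels (binary task: PCM match labeling for
#' positives, all-zero for negatives; signal task: log10(1+signal)), and a
#' drop report of skipped windows.
#'
#' @param genome Named list of chromosome strings or `DNAStringSet`.
#' @param peaks data.frame with `chrom`, `start`, `end`, `peak_position`,
#'   `signal_value`.
#' @param signal Named list of per-base signal vectors (required for the
#'   signal task).
#' @param task `"binary"` or `"signal"`.
#' @param pcm Count matrix for binary labeling.
#' @param length Window length (defaults: 500 binary, 1000 signal).
#' @param shift_range,neg_offset,filter_fraction,threshold_fraction Pipeline
#'   parameters (see the step functions).
#' @param seed RNG seed controlling the shifts.
#' @return Object of class `chip_dataset`: list of examples (each with
#'   `onehot` and `label`), plus `drop_report` and bookkeeping fields.
#' @export
build_dataset <- function(genome, peaks, signal = NULL,
                          task = c("signal", "binary"), pcm = NULL,
                          length = NULL, shift_range = c(-100L, 100L),
                          neg_offset = 3000L, filter_fraction = 0.05,
                          threshold_fraction = 0.8, seed = 1L) {
  task <- match.arg(task)
  if (is.null(length)) length <- if (task == "binary") 500L else 1000L
  if (task == "binary" && is.null(pcm)) stop("binary task requires a PCM")
  if (task == "signal" && is.null(signal)) stop("signal task requires a signal track")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  drops <- c(window_out_of_bounds = 0L, overlaps_peak = 0L)
  positives <- list()
  for (i in seq_len(nrow(peaks))) {
    ex <- extract_positive(peaks[i, ], genome, signal, length, shift_range)
    if (is_skipped(ex)) {
      drops[ex$reason] <- drops[ex$reason] + 1L
    } else {
      positives[[length(positives) + 1L]] <- ex
      attr(positives[[length(positives)]], "peak_row") <- i
    }
  }
  positives <- filter_low_signal(positives, filter_fraction)
  negatives <- list()
  for (ex in positives) {
    i <- attr(ex, "peak_row")
    ng <- make_negative(peaks[i, ], genome, signal, peaks, length, neg_offset)
    if (is_skipped(ng)) {
      drops[ng$reason] <- drops[ng$reason] + 1L
    } else {
      negatives[[length(negatives) + 1L]] <- ng
    }
  }
  examples <- c(positives, negatives)
  for (j in seq_along(examples)) {
    ex <- examples[[j]]
    examples[[j]]$label <- if (task == "signal") {
      ex$signal_transformed
    } else if (ex$is_positive) {
      label_binary(ex$onehot, pcm, threshold_fraction)
    } else {
      integer(nrow(ex$onehot))
    }
  }
  structure(list(examples = examples, task = task, length = length,
                 n_positive = length(positives), n_negative = length(negatives),
                 drop_report = data.frame(reason = names(drops),
                                          count = as.integer(drops))),
            class = "chip_dataset")
}

#' Read peak intervals from a BED or narrowPeak file
#'
#' BED columns beyond the standard ones are tolerated; for 10-column
#' narrowPeak input the summit offset (column 10) and signalValue are used,
#' otherwise the interval midpoint and score stand in.
#'
#' @param path BED/narrowPeak file.
#' @return data.frame with `chrom`, `start`, `end`, `peak_position`,
#'   `signal_value` (0-based half-open).
#' @export
read_peaks <- function(path) {
  ncols <- length(utils::read.table(path, nrows = 1L, sep = "\t"))
  gr <- if (ncols == 10L) {
    rtracklayer::import(path, format = "BED",
                        extraCols = c(signalValue = "numeric",
                                      pValue = "numeric", qValue = "numeric",
                                      peak = "integer"))
  } else {
    rtracklayer::import(path, format = "BED")
  }
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  summit <- if (!is.null(gr$peak) && all(gr$peak >= 0)) start0 + gr$peak
            else (start0 + end0) %/% 2L
  sv <- if (!is.null(gr$signalValue)) gr$signalValue
        else if (!is.null(gr$score)) as.numeric(gr$score) else 0
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = start0, end = end0, peak_position = summit,
             signal_value = sv, stringsAsFactors = FALSE)
}

#' Read a bedGraph signal track as per-base vectors
#'
#' @param path bedGraph file.
#' @param seqlengths Named integer vector of chromosome lengths.
#' @return Named list of per-base numeric vectors.
#' @export
read_signal_track <- function(path, seqlengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- list()
  for (chrom in names(seqlengths)) {
    v <- numeric(seqlengths[[chrom]])
    sub <- gr[GenomicRanges::seqnames(gr) == chrom]
    if (length(sub)) {
      for (i in seq_along(sub)) {
        v[GenomicRanges::start(sub)[i]:GenomicRanges::end(sub)[i]] <- sub$score[i]
      }
    }
    out[[chrom]] <- v
  }
  out
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)
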