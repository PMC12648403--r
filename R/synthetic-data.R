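# Planted-motif ChIP-seq simulator: an i.i.d. background genome with PWM
# motif instances planted at non-overlapping sites, a smooth Gaussian
# occupancy profile per site plus Gaussian noise, matched BED peak records,
# and full ground truth. Every stage of the package can be exercised against
# these fixtures without external downloads.

#' Build a PWM from a consensus string
#'
#' Each column places `info_strength` probability on the consensus base and
#' spreads the remainder uniformly over the other three; `info_strength = 1`
#' gives a deterministic motif (2 bits/position), `0.25` a uniform one
#' (0 bits).
#'
#' @param consensus Character string over `{A,C,G,T}`.
#' @param info_strength Probability mass on the consensus base, in (0, 1].
#' @return `w x 4` probability matrix (rows = positions, cols = A,C,G,T).
#' @export
pwm_from_consensus <- function(consensus, info_strength = 0.9) {
  if (info_strength <= 0 || info_strength > 1) {
    stop("info_strength must be in (0, 1]")
  }
  letters <- strsplit(toupper(consensus), "")[[1]]
  idx <- match(letters, c("A", "C", "G", "T"))
  if (anyNA(idx)) stop("consensus must use only A, C, G, T")
  w <- length(idx)
  m <- matrix((1 - info_strength) / 3, w, 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_len(w), idx)] <- info_strength
  m
}

#' Configure the planted-motif simulator
#'
#' Defaults describe the standard study conditions used throughout the test
#' suite: a 2 Mb uniform-background genome with 300 planted sites of an 8 bp
#' motif at `info_strength` 0.9, Gaussian occupancy peaks (amplitude 10,
#' width 50 bp, noise sd 0.5), and an optional cofactor motif at a fixed
#' start-to-start offset (40 bp) from each primary site.
#'
#' @param genome_length Genome size in bp.
#' @param base_freqs Background base frequencies (A,C,G,T), must sum to 1.
#' @param primary_pwm `w x 4` probability matrix of the planted motif.
#' @param cofactor_pwm Optional cofactor motif PWM; `NULL` disables cofactor
#'   planting.
#' @param n_sites Number of primary sites.
#' @param amplitude,peak_width Gaussian occupancy profile: height and sd (bp).
#' @param noise_sd Additive Gaussian noise sd (clipped at 0).
#' @param cofactor_offset Start-to-start distance (bp) from primary to
#'   cofactor site.
#' @param cofactor_orientations Strands sampled for cofactor instances.
#' @param peak_halfwidth Half-width of emitted BED peak records.
#' @param min_site_gap Minimum distance between primary site centers.
#' @param chrom Chromosome name of the simulated sequence.
#' @param seed RNG seed; fixed seed gives byte-identical outputs.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 2e6, base_freqs = rep(0.25, 4),
                       primary_pwm = pwm_from_consensus("TGACTCAG", 0.9),
                       cofactor_pwm = NULL, n_sites = 300L,
                       amplitude = 10, peak_width = 50, noise_sd = 0.5,
                       cofactor_offset = 40L,
                       cofactor_orientations = c("+", "-"),
                       peak_halfwidth = 100L, min_site_gap = 2000L,
                       chrom = "chrS", seed = 1L) {
  stopifnot(abs(sum(base_freqs) - 1) < 1e-9)
  check_pwm <- function(m) {
    if (any(abs(rowSums(m) - 1) > 1e-9)) stop("PWM rows must sum to 1")
  }
  check_pwm(primary_pwm)
  if (!is.null(cofactor_pwm)) check_pwm(cofactor_pwm)
  margin <- 4500L + peak_halfwidth  # room for 1000 bp windows and upstream negatives
  if (n_sites * min_site_gap + 2 * margin > genome_length) {
    stop("n_sites x min_site_gap does not fit in genome_length")
  }
  structure(list(genome_length = as.integer(genome_length),
                 base_freqs = base_freqs, primary_pwm = primary_pwm,
                 cofactor_pwm = cofactor_pwm, n_sites = as.integer(n_sites),
                 amplitude = amplitude, peak_width = peak_width,
                 noise_sd = noise_sd,
                 cofactor_offset = as.integer(cofactor_offset),
                 cofactor_orientations = cofactor_orientations,
                 peak_halfwidth = as.integer(peak_halfwidth),
                 min_site_gap = as.integer(min_site_gap),
                 chrom = chrom, seed = as.integer(seed)),
            class = "sim_config")
}

sample_pwm_instance <- function(pwm) {
  paste(vapply(seq_len(nrow(pwm)), function(i) {
    sample(c("A", "C", "G", "T"), 1L, prob = pwm[i, ])
  }, character(1)), collapse = "")
}

revcomp_string <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Simulate a ChIP-seq-like dataset with planted ground truth
#'
#' Samples an i.i.d. background genome, plants non-overlapping primary motif
#' instances (strand chosen uniformly; reverse-complemented on `-`), plants
#' optional cofactor instances at the configured start-to-start offset,
#' accumulates a Gaussian occupancy profile per site, adds clipped Gaussian
#' noise, and emits one BED peak record per primary site.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `peaks.bed`, `signal.bedGraph` and `ground_truth.tsv` there.
#' @return List with `genome` (`DNAStringSet`), `signal` (named list with a
#'   per-base vector), `peaks` (data.frame as [read_peaks()] returns),
#'   `ground_truth` (data.frame: site, motif, start, strand, instance) and
#'   `config`.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  L <- config$genome_length
  bases <- c("A", "C", "G", "T")
  genome_chars <- sample(bases, L, replace = TRUE, prob = config$base_freqs)

  w <- nrow(config$primary_pwm)
  margin <- 4500L + config$peak_halfwidth
  centers <- integer(0)
  tries <- 0L
  while (length(centers) < config$n_sites) {
    tries <- tries + 1L
    if (tries > 10L * config$n_sites) {
      stop("could not place ", config$n_sites, " non-overlapping sites")
    }
    cand <- sample.int(L - 2L * margin, 1L) + margin
    if (all(abs(cand - centers) >= config$min_site_gap)) {
      centers <- c(centers, cand)
    }
  }
  centers <- sort(centers)

  truth <- list()
  plant <- function(start0, pwm, strand, motif_id, site_id) {
    inst <- sample_pwm_instance(pwm)
    planted <- if (strand == "-") revcomp_string(inst) else inst
    genome_chars[(start0 + 1L):(start0 + nchar(planted))] <<-
      strsplit(planted, "")[[1]]
    truth[[length(truth) + 1L]] <<- data.frame(
      site = site_id, motif = motif_id, start = start0, strand = strand,
      instance = planted, stringsAsFactors = FALSE)
  }
  for (s in seq_along(centers)) {
    start0 <- centers[s] - w %/% 2L           # 0-based motif start
    strand <- sample(c("+", "-"), 1L)
    plant(start0, config$primary_pwm, strand, "primary", s)
    if (!is.null(config$cofactor_pwm)) {
      co_start <- start0 + config$cofactor_offset
      co_strand <- sample(config$cofactor_orientations, 1L)
      plant(co_start, config$cofactor_pwm, co_strand, "cofactor", s)
    }
  }
  truth <- do.call(rbind, truth)

  signal <- numeric(L)
  half_support <- ceiling(4 * config$peak_width)
  for (cen in centers) {
    lo <- max(1L, cen - half_support)
    hi <- min(L, cen + half_support)
    d <- (lo:hi) - 1L - cen          # vector index i holds coordinate i-1
    signal[lo:hi] <- signal[lo:hi] +
      config$amplitude * exp(-(d / config$peak_width)^2 / 2)
  }
  if (config$noise_sd > 0) {
    signal <- signal + stats::rnorm(L, 0, config$noise_sd)
  }
  signal <- pmax(signal, 0)

  peaks <- data.frame(
    chrom = config$chrom,
    start = centers - config$peak_halfwidth,
    end = centers + config$peak_halfwidth,
    peak_position = centers,
    signal_value = signal[centers + 1L],
    stringsAsFactors = FALSE)

  genome_str <- paste(genome_chars, collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(genome_str, config$chrom))
  result <- list(genome = genome,
                 signal = stats::setNames(list(signal), config$chrom),
                 peaks = peaks, ground_truth = truth, config = config)
  if (!is.null(out_dir)) write_simulation(result, out_dir)
  result
}

#' Write a simulated dataset to FASTA/BED/bedGraph/TSV
#'
#' @param sim Result of [simulate_dataset()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(out_dir, "genome.fa"))
  pk <- sim$peaks
  utils::write.table(
    data.frame(pk$chrom, pk$start, pk$end, paste0("site", seq_len(nrow(pk))),
               sprintf("%.4f", pk$signal_value), "."),
    file.path(out_dir, "peaks.bed"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  chrom <- names(sim$signal)[1]
  v <- sim$signal[[chrom]]
  utils::write.table(
    data.frame(chrom, seq_along(v) - 1L, seq_along(v), sprintf("%.4f", v)),
    file.path(out_dir, "signal.bedGraph"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$ground_truth,
                     file.path(out_dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
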