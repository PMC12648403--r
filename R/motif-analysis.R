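# Motif representation analytics: filter-activation PFM extraction from the
# first layer of a trained model, information content, MEME minimal-format
# IO, reproducible-detection matrices with permutation q-values, an internal
# PWM scanner with exact score-distribution p-values, and motif-pair
# minimum-distance distributions by strand orientation.

#' Highest-signal window of a per-base prediction
#'
#' The half-open window of length `w` maximizing the summed prediction;
#' earliest window on ties.
#'
#' @param prediction Numeric vector.
#' @param w Window length (default 100).
#' @return Integer `c(start, end)`, 0-based half-open.
#' @export
top_signal_window <- function(prediction, w = 100L) {
  L <- length(prediction)
  if (L < w) stop("prediction length ", L, " shorter than window ", w)
  sums <- cumsum(prediction)
  win <- sums[w:L] - c(0, sums[seq_len(L - w)])
  s <- which.max(win) - 1L          # first maximum = earliest window
  c(start = s, end = s + w)
}

# activations of the model's first (quanvolutional or classical) layer
first_layer_activations <- function(model, onehot) {
  cfg <- model$config
  if (cfg$first_layer == "quantum") {
    qconv1_fwd(onehot, cfg$qconv, model$params$first)$y
  } else {
    conv1d_same_fwd(onehot, model$params$first$W, model$params$first$b,
                    cfg$qconv$k_target)$y
  }
}

#' Collect maximally activating subsequences per first-layer filter
#'
#' For each example, predictions locate the `w_region`-bp window with the
#' highest predicted binding; within that window each filter's
#' activation-maximizing position is mapped back to its `k`-bp input window
#' (the QConv1 'same'-padding convention: output position p covers input
#' `[p - floor((k-1)/2), p + ceil((k-1)/2)]`), and the subsequence is
#' collected. Windows clipped by the sequence boundary are discarded.
#'
#' @param model A trained `quanv_model`.
#' @param examples List of examples with `sequence` and `onehot` fields.
#' @param w_region Width of the top-signal region (default 100).
#' @param k Subsequence length (default the 16 bp receptive field).
#' @return List (one character vector of `k`-mers per filter).
#' @export
max_activation_subsequences <- function(model, examples, w_region = 100L,
                                        k = 16L) {
  nf <- model$config$channels[1]
  left <- (k - 1L) %/% 2L
  out <- replicate(nf, character(0), simplify = FALSE)
  tabs <- if (model$config$first_layer == "quantum") {
    qconv_tables(model$config$qconv, model$params$first$theta)
  } else NULL
  for (ex in examples) {
    pred <- forward_model(model, ex$onehot, tabs = tabs)
    win <- top_signal_window(pred, w_region)
    act <- first_layer_activations(model, ex$onehot)
    rows <- (win[["start"]] + 1L):win[["end"]]
    L <- nrow(ex$onehot)
    for (f in seq_len(nf)) {
      p <- rows[which.max(act[rows, f])]
      s <- p - left
      e <- s + k - 1L
      if (s >= 1L && e <= L) {
        out[[f]] <- c(out[[f]], substr(ex$sequence, s, e))
      }
    }
  }
  out
}

#' Build a position frequency matrix from aligned subsequences
#'
#' @param subsequences Nonempty character vector of equal-length sequences.
#' @param k Expected width (default 16).
#' @return Object of class `pfm`: `m` (`k x 4` row-stochastic matrix),
#'   `support` (number of sequences).
#' @export
build_pfm <- function(subsequences, k = 16L) {
  if (length(subsequences) == 0L) stop("no subsequences")
  if (any(nchar(subsequences) != k)) stop("subsequences must all have length ", k)
  m <- matrix(0, k, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (s in subsequences) {
    oh <- one_hot(s)
    m <- m + oh
  }
  counts <- rowSums(m)
  if (any(counts == 0)) stop("position with no A/C/G/T observations")
  m <- m / counts
  structure(list(m = m, support = length(subsequences)), class = "pfm")
}

#' Information content of a PFM in bits
#'
#' `IC = -sum_ij b_j log2(b_j) + sum_ij m_ij log2(m_ij)` with the convention
#' `0 log2 0 = 0`. Under a uniform background the IC of a width-w PFM lies
#' in `[0, 2w]`: 0 for a uniform matrix, `2w` for a deterministic one.
#'
#' @param pfm A [build_pfm()] object or bare `w x 4` row-stochastic matrix.
#' @param background Length-4 base frequencies (default uniform).
#' @return IC in bits.
#' @export
information_content <- function(pfm, background = rep(0.25, 4)) {
  m <- if (inherits(pfm, "pfm")) pfm$m else as.matrix(pfm)
  if (any(abs(rowSums(m) - 1) > 1e-9) || any(m < 0)) {
    stop("PFM rows must be probability vectors")
  }
  if (abs(sum(background) - 1) > 1e-9 || any(background <= 0)) {
    stop("background must be a positive probability vector")
  }
  xlogx <- function(p) ifelse(p > 0, p * log2(p), 0)
  -nrow(m) * sum(xlogx(background)) + sum(xlogx(m))
}

#' Write PFMs in MEME minimal motif format
#'
#' @param pfms List of [build_pfm()] objects (names become motif ids).
#' @param path Output file.
#' @param background Background letter frequencies.
#' @return `path`, invisibly.
#' @export
export_meme <- function(pfms, path, background = rep(0.25, 4)) {
  if (is.null(names(pfms))) names(pfms) <- paste0("filter_", seq_along(pfms))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", c("A", "C", "G", "T"), background),
                     collapse = " "), ""), con)
  for (nm in names(pfms)) {
    p <- pfms[[nm]]
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      nrow(p$m), p$support), con)
    writeLines(apply(p$m, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MEME minimal motif file
#'
#' @param path MEME file written by [export_meme()] (or compatible).
#' @return Named list of `pfm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "MOTIF")) {
      nm <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      i <- i + 1L
      while (!grepl("^letter-probability matrix", lines[i])) i <- i + 1L
      hdr <- lines[i]
      w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", hdr))
      ns <- if (grepl("nsites=", hdr)) {
        as.integer(sub(".*nsites= *([0-9]+).*", "\\1", hdr))
      } else 0L
      rows <- lines[(i + 1L):(i + w)]
      m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
      colnames(m) <- c("A", "C", "G", "T")
      out[[nm]] <- structure(list(m = m, support = ns), class = "pfm")
      i <- i + w
    }
    i <- i + 1L
  }
  out
}

# best alignment (shifts both ways, forward and reverse-complement) of two
# row-stochastic matrices by Pearson correlation of overlapping cells
motif_match_score <- function(pfm, ref, min_overlap = 4L) {
  m <- if (inherits(pfm, "pfm")) pfm$m else pfm
  r <- if (inherits(ref, "pfm")) ref$m else ref
  best <- list(score = -Inf, shift = 0L, strand = "+")
  for (strand in c("+", "-")) {
    rr <- if (strand == "-") revcomp_matrix(r) else r
    for (shift in (-(nrow(rr) - min_overlap)):(nrow(m) - min_overlap)) {
      i1 <- max(1L, 1L + shift); i2 <- min(nrow(m), nrow(rr) + shift)
      if (i2 - i1 + 1L < min_overlap) next
      a <- m[i1:i2, , drop = FALSE]
      b <- rr[(i1 - shift):(i2 - shift), , drop = FALSE]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      sc <- stats::cor(as.vector(a), as.vector(b))
      if (sc > best$score) best <- list(score = sc, shift = shift, strand = strand)
    }
  }
  best
}

#' Detect reference motifs among extracted PFMs
#'
#' For each reference motif, the observed statistic is the best
#' column-correlation alignment score over all PFMs (shifts and reverse
#' complement allowed). Significance comes from a positional-permutation
#' null (rows of every PFM shuffled), with Benjamini-Hochberg adjustment
#' across references; `q < q_threshold` counts as detection.
#'
#' @param pfms List of `pfm` objects (e.g. the 64 filter PFMs).
#' @param references Named list of reference motifs (`pfm` or matrices).
#' @param q_threshold Detection threshold on the BH-adjusted q-value
#'   (default 0.1).
#' @param n_perm Permutation draws (default 100).
#' @param min_overlap Minimum aligned columns.
#' @return data.frame: `ref`, `score`, `best_pfm`, `p`, `q`, `detected`.
#' @export
motif_detections <- function(pfms, references, q_threshold = 0.1,
                             n_perm = 100L, min_overlap = 4L) {
  obs <- lapply(names(references), function(nm) {
    scores <- vapply(pfms, function(p) {
      motif_match_score(p, references[[nm]], min_overlap)$score
    }, numeric(1))
    list(ref = nm, score = max(scores), best_pfm = which.max(scores))
  })
  null_max <- matrix(0, n_perm, length(references))
  for (b in seq_len(n_perm)) {
    shuffled <- lapply(pfms, function(p) {
      m <- if (inherits(p, "pfm")) p$m else p
      m[sample.int(nrow(m)), , drop = FALSE]
    })
    null_max[b, ] <- vapply(seq_along(references), function(j) {
      max(vapply(shuffled, function(m) {
        motif_match_score(m, references[[j]], min_overlap)$score
      }, numeric(1)))
    }, numeric(1))
  }
  p <- vapply(seq_along(obs), function(j) {
    (1 + sum(null_max[, j] >= obs[[j]]$score)) / (n_perm + 1)
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(ref = vapply(obs, `[[`, character(1), "ref"),
             score = vapply(obs, `[[`, numeric(1), "score"),
             best_pfm = vapply(obs, `[[`, integer(1), "best_pfm"),
             p = p, q = q, detected = q < q_threshold,
             stringsAsFactors = FALSE)
}

#' Reproducible-detection binary matrix
#'
#' An entry is 1 iff the reference motif was matched in at least
#' `min_trials` of `n_trials` independent training trials for that
#' condition (default: 4 of 5).
#'
#' @param matches data.frame with columns `ref`, `condition`, `trial`, one
#'   row per successful per-trial match.
#' @param n_trials Number of trials run per condition (default 5).
#' @param min_trials Reproducibility threshold (default 4).
#' @param refs,conditions Optional row/column universes (defaults: observed).
#' @return Binary matrix, rows = reference motifs, columns = conditions.
#' @export
detection_matrix <- function(matches, n_trials = 5L, min_trials = 4L,
                             refs = NULL, conditions = NULL) {
  if (min_trials > n_trials) stop("min_trials must be <= n_trials")
  if (nrow(matches) > 0 &&
      (any(matches$trial < 1L) || any(matches$trial > n_trials))) {
    stop("trial index out of range 1..", n_trials)
  }
  if (is.null(refs)) refs <- sort(unique(matches$ref))
  if (is.null(conditions)) conditions <- sort(unique(matches$condition))
  D <- matrix(0L, length(refs), length(conditions),
              dimnames = list(refs, conditions))
  if (nrow(matches) > 0) {
    key <- unique(matches[, c("ref", "condition", "trial")])
    tab <- stats::aggregate(trial ~ ref + condition, data = key, FUN = length)
    for (i in seq_len(nrow(tab))) {
      if (tab$trial[i] >= min_trials) D[tab$ref[i], tab$condition[i]] <- 1L
    }
  }
  D
}

#' Functional-similarity correlation and Ward clustering of conditions
#'
#' Pearson correlation between detection-vector columns; conditions with
#' constant detection vectors yield undefined correlations, reported as
#' `NA` and treated as zero similarity for clustering. Hierarchical
#' clustering uses Ward linkage on `1 - correlation` distances.
#'
#' @param detection Binary matrix from [detection_matrix()] (>= 2 columns).
#' @return List with `correlation` (matrix, possibly with NA),
#'   `constant_conditions`, `hclust`, and `order` (dendrogram leaf order).
#' @export
similarity_and_cluster <- function(detection) {
  if (ncol(detection) < 2L) stop("need at least 2 conditions")
  sds <- apply(detection, 2, stats::sd)
  corr <- suppressWarnings(stats::cor(detection))
  filled <- corr
  filled[is.na(filled)] <- 0
  diag(filled) <- 1
  hc <- stats::hclust(stats::as.dist(1 - filled), method = "ward.D2")
  list(correlation = corr, constant_conditions = colnames(detection)[sds == 0],
       hclust = hc, order = colnames(detection)[hc$order])
}

# log-odds weights of a probability PWM with small pseudocount
pwm_to_logodds <- function(pwm, background = rep(0.25, 4), pseudocount = 1e-3) {
  m <- if (inherits(pwm, "pfm")) pwm$m else as.matrix(pwm)
  p <- (m + pseudocount) / (1 + 4 * pseudocount)
  log2(sweep(p, 2, background, "/"))
}

# exact p-values of integer-discretized log-odds scores under the background
# model, by dynamic programming over the per-position score distributions
score_pvalue_table <- function(lo, background, granularity = 1e-3) {
  w <- nrow(lo)
  rng <- sum(apply(lo, 1, max) - apply(lo, 1, min))
  delta <- max(rng * granularity, 1e-12)
  iw <- round(sweep(lo, 1, apply(lo, 1, min)) / delta)  # nonneg integers
  max_total <- sum(apply(iw, 1, max))
  probs <- numeric(max_total + 1L)
  probs[1] <- 1
  for (i in seq_len(w)) {
    nxt <- numeric(max_total + 1L)
    for (j in 1:4) {
      s <- iw[i, j]
      idx <- which(probs > 0)
      nxt[idx + s] <- nxt[idx + s] + probs[idx] * background[j]
    }
    probs <- nxt
  }
  surv <- rev(cumsum(rev(probs)))   # surv[s+1] = P(total >= s)
  list(iw = iw, delta = delta, offset = sum(apply(lo, 1, min)), surv = surv)
}

#' Scan a sequence with a PWM, exact p-values, both strands
#'
#' Log-odds scoring (pseudocount 1e-3) against the background model; window
#' p-values come from the exact distribution of the discretized score under
#' the background (dynamic programming, granularity 1e-3 of the total score
#' range). Both strands are scanned; minus-strand matches are reported on
#' the forward coordinate axis.
#'
#' @param sequence Character DNA sequence.
#' @param pwm Probability PWM (`pfm` or `w x 4` matrix).
#' @param p_threshold Report matches with `p <= p_threshold` (default 1e-4).
#' @param background Base frequencies (default uniform).
#' @return data.frame: `start` (0-based), `strand`, `score` (log-odds,
#'   bits), `p`.
#' @export
pwm_scan <- function(sequence, pwm, p_threshold = 1e-4,
                     background = rep(0.25, 4)) {
  onehot <- if (is.matrix(sequence)) sequence else one_hot(sequence)
  lo <- pwm_to_logodds(pwm, background)
  w <- nrow(lo)
  if (w > nrow(onehot)) stop("PWM wider than sequence")
  hits <- list()
  for (strand in c("+", "-")) {
    mat <- if (strand == "-") revcomp_matrix(lo) else lo
    tab <- score_pvalue_table(mat, background)
    iscores <- as.integer(round(scan_scores(onehot, tab$iw)))
    pvals <- tab$surv[pmin(iscores, length(tab$surv) - 1L) + 1L]
    keep <- which(pvals <= p_threshold)
    if (length(keep)) {
      hits[[strand]] <- data.frame(
        start = keep - 1L, strand = strand,
        score = iscores[keep] * tab$delta + tab$offset,
        p = pvals[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0), p = numeric(0)))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

#' Scan many sequences, keeping sequence ids
#'
#' @param sequences Named character vector (e.g. peak sequences).
#' @inheritParams pwm_scan
#' @return data.frame as [pwm_scan()] plus a `peak` column.
#' @export
scan_sequences <- function(sequences, pwm, p_threshold = 1e-4,
                           background = rep(0.25, 4)) {
  rows <- lapply(names(sequences), function(id) {
    h <- pwm_scan(sequences[[id]], pwm, p_threshold, background)
    if (nrow(h)) cbind(peak = id, h) else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(peak = character(0), start = integer(0),
                      strand = character(0), score = numeric(0),
                      p = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Minimum motif-pair distances per strand orientation
#'
#' For every peak containing matches of both motifs and every orientation
#' pair (strand of A, strand of B), the minimum start-to-start distance
#' `|pos_A - pos_B|` is recorded; peaks lacking either motif contribute
#' nothing.
#'
#' @param matches_a,matches_b Match tables from [scan_sequences()] (columns
#'   `peak`, `start`, `strand`).
#' @return data.frame: `peak`, `orientation` (one of `++`, `+-`, `-+`,
#'   `--`), `distance`.
#' @export
min_distance_distribution <- function(matches_a, matches_b) {
  peaks <- intersect(unique(matches_a$peak), unique(matches_b$peak))
  rows <- list()
  for (pk in peaks) {
    a <- matches_a[matches_a$peak == pk, ]
    b <- matches_b[matches_b$peak == pk, ]
    for (sa in c("+", "-")) {
      for (sb in c("+", "-")) {
        ai <- a$start[a$strand == sa]
        bi <- b$start[b$strand == sb]
        if (length(ai) == 0L || length(bi) == 0L) next
        d <- min(abs(outer(ai, bi, "-")))
        rows[[length(rows) + 1L]] <- data.frame(
          peak = pk, orientation = paste0(sa, sb), distance = d,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(peak = character(0), orientation = character(0),
                      distance = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Extract per-filter PFMs from a trained model
#'
#' The full filter-activation pipeline: top-signal windows, per-filter
#' maximally activating 16 bp subsequences, and one PFM per filter (filters
#' with no collected subsequence are dropped).
#'
#' @param model A trained `quanv_model`.
#' @param examples Examples to mine (typically the test split).
#' @param w_region,k See [max_activation_subsequences()].
#' @return Named list of `pfm` objects (`filter_<i>`).
#' @export
extract_filter_pfms <- function(model, examples, w_region = 100L, k = 16L) {
  subs <- max_activation_subsequences(model, examples, w_region, k)
  names(subs) <- paste0("filter_", seq_along(subs))
  subs <- subs[vapply(subs, length, integer(1)) > 0]
  lapply(subs, build_pfm, k = k)
}
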