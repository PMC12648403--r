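test_that("top-signal window finds spikes and breaks ties to the earliest", {
  p <- numeric(300); p[201] <- 5
  w <- top_signal_window(p, 100)
  expect_true(w[["start"]] <= 200 && 200 < w[["end"]])
  expect_equal(unname(top_signal_window(rep(1, 300), 100)), c(0, 100))
  two <- numeric(300); two[51] <- 3; two[251] <- 3
  w2 <- top_signal_window(two, 100)
  expect_true(w2[["start"]] <= 50 && 50 < w2[["end"]])
  expect_error(top_signal_window(numeric(50), 100), "shorter")
})

test_that("PFM construction counts position-wise letter frequencies", {
  pf <- build_pfm(rep(strrep("A", 16), 10))
  expect_equal(unname(pf$m[, "A"]), rep(1, 16))
  expect_equal(pf$support, 10)
  pf3 <- build_pfm(c(paste0("A", strrep("G", 3)), paste0("A", strrep("G", 3)),
                     paste0("C", strrep("G", 3))), k = 4)
  expect_equal(unname(pf3$m[1, ]), c(2 / 3, 1 / 3, 0, 0))
  expect_error(build_pfm(character(0)), "no subsequences")
  expect_error(build_pfm(c("ACGT", "ACG"), k = 4), "length")
})

test_that("information content matches the closed forms", {
  uni <- matrix(0.25, 16, 4)
  expect_equal(information_content(uni), 0)
  det <- matrix(0, 16, 4); det[, 2] <- 1
  expect_equal(information_content(det), 32)
  one_det <- matrix(0.25, 16, 4); one_det[7, ] <- c(1, 0, 0, 0)
  expect_equal(information_content(one_det), 2)
  # bounds under uniform background
  set.seed(1)
  for (i in 1:20) {
    m <- matrix(rgamma(64, 1), 16, 4); m <- m / rowSums(m)
    ic <- information_content(m)
    expect_true(ic >= -1e-9 && ic <= 32 + 1e-9)
  }
  expect_error(information_content(matrix(1, 4, 4)), "probability")
})

test_that("MEME export writes one block per PFM and round-trips", {
  set.seed(2)
  pfms <- lapply(1:64, function(i) {
    m <- matrix(rgamma(64, 1), 16, 4); m <- m / rowSums(m)
    colnames(m) <- c("A", "C", "G", "T")
    structure(list(m = m, support = 10 + i), class = "pfm")
  })
  names(pfms) <- paste0("filter_", 1:64)
  path <- tempfile(fileext = ".meme")
  export_meme(pfms, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "MOTIF")), 64)
  expect_true(any(grepl("^A 0.25000 C 0.25000 G 0.25000 T 0.25000$", lines)))
  back <- read_meme(path)
  expect_equal(names(back), names(pfms))
  for (i in c(1, 33, 64)) {
    expect_lt(max(abs(back[[i]]$m - pfms[[i]]$m)), 1e-6)
    expect_equal(back[[i]]$support, pfms[[i]]$support)
  }
})

test_that("detection requires reproducible matches in >= 4 of 5 trials", {
  matches <- data.frame(
    ref = c(rep("M1", 4), rep("M2", 3), rep("M3", 5)),
    condition = "TF_A",
    trial = c(1:4, 1:3, 1:5))
  D <- detection_matrix(matches)
  expect_equal(D["M1", "TF_A"], 1L)
  expect_equal(D["M2", "TF_A"], 0L)
  expect_equal(D["M3", "TF_A"], 1L)
  all_hits <- expand.grid(ref = c("X", "Y"), condition = c("c1", "c2"),
                          trial = 1:5, stringsAsFactors = FALSE)
  expect_true(all(detection_matrix(all_hits) == 1L))
  bad <- data.frame(ref = "M", condition = "c", trial = 6)
  expect_error(detection_matrix(bad), "out of range")
})

test_that("similarity clustering recovers planted blocks", {
  set.seed(3)
  base1 <- rbinom(40, 1, 0.5)
  base2 <- rbinom(40, 1, 0.5)
  flip <- function(v, k) { i <- sample(40, k); v[i] <- 1 - v[i]; v }
  D <- cbind(a1 = base1, a2 = flip(base1, 2),
             b1 = base2, b2 = flip(base2, 2))
  sc <- similarity_and_cluster(D)
  expect_equal(unname(sc$correlation["a1", "a1"]), 1)
  grp <- cutree(sc$hclust, 2)
  expect_equal(grp[["a1"]], grp[["a2"]])
  expect_equal(grp[["b1"]], grp[["b2"]])
  expect_false(grp[["a1"]] == grp[["b1"]])
  expect_equal(unname(similarity_and_cluster(cbind(x = c(1, 0), y = c(0, 1)))
                      $correlation["x", "y"]), -1)
  # constant columns are flagged and their correlations reported missing
  sc2 <- similarity_and_cluster(cbind(c1 = c(1, 1, 1), c2 = c(1, 0, 1),
                                      c3 = c(0, 1, 0)))
  expect_equal(sc2$constant_conditions, "c1")
  expect_true(is.na(sc2$correlation["c1", "c2"]))
})

test_that("PWM scanning recovers planted instances on both strands", {
  set.seed(4)
  pwm <- pwm_from_consensus("TGACTCAGGT", 0.95)
  bg <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  planted <- paste0(substr(bg, 1, 100), "TGACTCAGGT", substr(bg, 111, 400))
  hits <- pwm_scan(planted, pwm, p_threshold = 1e-4)
  expect_true(any(hits$start == 100 & hits$strand == "+"))

  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit("TGACTCAGGT", "")[[1]]), collapse = ""))
  planted_rc <- paste0(substr(bg, 1, 100), rc, substr(bg, 111, 400))
  hits_rc <- pwm_scan(planted_rc, pwm, p_threshold = 1e-4)
  expect_true(any(hits_rc$start == 100 & hits_rc$strand == "-"))

  expect_equal(nrow(pwm_scan(planted, pwm, p_threshold = 0)), 0)
})

test_that("scan p-values are calibrated on pure background", {
  set.seed(5)
  # heterogeneous columns give a dense score distribution, so the attained
  # p-value at the cutoff sits close to the nominal threshold
  pwm <- matrix(rgamma(40, 1), 10, 4)
  pwm <- pwm / rowSums(pwm)
  colnames(pwm) <- c("A", "C", "G", "T")
  L <- 20000
  bg <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  thr <- 1e-3
  hits <- pwm_scan(bg, pwm, p_threshold = thr)
  npos <- L - 10 + 1
  expected <- thr * npos * 2
  expect_lt(abs(nrow(hits) - expected), 3 * sqrt(expected) + 1)
})

test_that("minimum distances are tabulated per orientation pair", {
  a <- data.frame(peak = "p1", start = 50, strand = "+")
  b <- data.frame(peak = "p1", start = 86, strand = "+")
  d <- min_distance_distribution(a, b)
  expect_equal(d$distance, 36)
  expect_equal(d$orientation, "++")
  same <- min_distance_distribution(a, data.frame(peak = "p1", start = 50,
                                                  strand = "-"))
  expect_equal(same$distance, 0)
  expect_equal(same$orientation, "+-")
  none <- min_distance_distribution(a, data.frame(peak = "p2", start = 10,
                                                  strand = "+"))
  expect_equal(nrow(none), 0)
})

test_that("cofactor spacing planted at 40 bp is recovered as the histogram mode", {
  cfg <- sim_config(genome_length = 200000, n_sites = 60, min_site_gap = 1500,
                    primary_pwm = pwm_from_consensus("TGACTCAG", 0.95),
                    cofactor_pwm = pwm_from_consensus("CCACGTGG", 0.95),
                    cofactor_offset = 40, seed = 19)
  sim <- simulate_dataset(cfg)
  seqs <- vapply(seq_len(nrow(sim$peaks)), function(i) {
    as.character(Biostrings::subseq(sim$genome[[1]],
                                    sim$peaks$start[i] + 1L, sim$peaks$end[i]))
  }, character(1))
  names(seqs) <- paste0("peak", seq_along(seqs))
  ma <- scan_sequences(seqs, cfg$primary_pwm, p_threshold = 1e-4)
  mb <- scan_sequences(seqs, cfg$cofactor_pwm, p_threshold = 1e-4)
  d <- min_distance_distribution(ma, mb)
  expect_gt(nrow(d), 10)
  mode_d <- as.integer(names(sort(table(d$distance), decreasing = TRUE))[1])
  expect_equal(mode_d, 40L)
})

test_that("a rigged filter recovers exactly its planted 16 bp input window", {
  set.seed(6)
  motif <- "ACGTACGTTTGGCCAA"
  L <- 250
  cfg <- model_config(task = "binary", input_length = L,
                      first_layer = "classical",
                      qconv = qconv_config(n_qubits = 2, k_target = 16),
                      channels = c(3L, 4L, 5L), pools = c(5L, 5L, 5L),
                      kernels = c(conv2 = 5L, conv3 = 5L, bottleneck = 3L,
                                  decoder = 3L),
                      dec_channels = 3L)
  m <- build_model(cfg)
  # filter 1 = exact indicator of `motif`; constant head -> window [0, 100)
  W <- matrix(0, 16 * 4, 3)
  oh <- one_hot(motif)
  for (j in 1:16) W[(j - 1) * 4 + which(oh[j, ] == 1), 1] <- 1
  m$params$first$W <- W
  m$params$first$b[] <- 0
  m$params$head$W[] <- 0
  m$params$head$b[] <- 0

  base <- sample(c("A", "C", "G", "T"), L, TRUE)
  base[41:56] <- strsplit(motif, "")[[1]]
  seqc <- paste(base, collapse = "")
  ex <- list(sequence = seqc, onehot = one_hot(seqc))
  subs <- max_activation_subsequences(m, list(ex), w_region = 100, k = 16)
  expect_length(subs, 3)
  expect_equal(subs[[1]], motif)
  expect_true(all(nchar(unlist(subs)) == 16))
})

test_that("filter PFM extraction yields one 16-wide PFM per filter", {
  set.seed(7)
  cfg <- model_config(task = "signal", input_length = 250,
                      qconv = qconv_config(n_qubits = 2, n_layers = 1),
                      channels = c(5L, 6L, 8L), pools = c(5L, 5L, 5L),
                      kernels = c(conv2 = 5L, conv3 = 5L, bottleneck = 3L,
                                  decoder = 3L),
                      dec_channels = 4L)
  m <- build_model(cfg)
  exs <- lapply(1:3, function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = "")
    list(sequence = s, onehot = one_hot(s))
  })
  pfms <- extract_filter_pfms(m, exs)
  expect_equal(length(pfms), 5)
  for (p in pfms) {
    expect_equal(nrow(p$m), 16)
    expect_equal(rowSums(p$m), rep(1, 16), tolerance = 1e-9)
  }
})
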