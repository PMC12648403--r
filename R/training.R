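# Losses, the optimization loop (AdamW, early stopping on a validation
# carve-out), nested down-sampling, and cross-cell fine-tuning.

#' Training configuration
#'
#' @param lr AdamW learning rate (default 1e-3).
#' @param weight_decay Decoupled weight decay (default 1e-2).
#' @param max_epochs Maximum epochs (default 40).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement (default 6; must be < `max_epochs`).
#' @param split Training fraction of the 80/20 train/test partition.
#' @param val_fraction Fraction of the training split carved out to monitor
#'   early stopping (default 0.1).
#' @param batch_size Minibatch size (default 16).
#' @param neg_pos_ratio `r` of the hard-negative-mining loss (default 3).
#' @param seed RNG seed controlling the partition, shuffling and
#'   initialization; identical seeds give identical partitions across
#'   compared models.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, weight_decay = 1e-2, max_epochs = 40L,
                         patience = 6L, split = 0.8, val_fraction = 0.1,
                         batch_size = 16L, neg_pos_ratio = 3, seed = 1L) {
  if (!(split > 0 && split < 1)) stop("split fraction must be in (0, 1)")
  if (patience >= max_epochs) stop("patience must be < max_epochs")
  structure(list(lr = lr, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), split = split,
                 val_fraction = val_fraction,
                 batch_size = as.integer(batch_size),
                 neg_pos_ratio = neg_pos_ratio, seed = as.integer(seed)),
            class = "train_config")
}

#' Hard negative mining loss
#'
#' Per-base binary cross-entropy where every positive base is kept but only
#' the `min(r * n_pos, n_neg)` highest-loss negative bases contribute (top 1%
#' of negatives when a sequence has no positive base), countering the
#' extreme base-level class imbalance. Predictions are clamped at 1e-7.
#'
#' @param pred Predicted probabilities in (0, 1).
#' @param labels Binary labels.
#' @param r Negative:positive retention ratio (default 3); `Inf` keeps all
#'   negatives, recovering plain mean BCE.
#' @return Scalar loss (>= 0).
#' @export
hard_negative_mining_loss <- function(pred, labels, r = 3) {
  hnm_loss_grad(pred, labels, r)$loss
}

# loss + gradient wrt pred in one pass
hnm_loss_grad <- function(pred, labels, r = 3) {
  if (length(pred) != length(labels)) stop("pred/label length mismatch")
  eps <- 1e-7
  p <- pmin(pmax(pred, eps), 1 - eps)
  y <- as.numeric(labels)
  bce <- -(y * log(p) + (1 - y) * log(1 - p))
  pos <- which(y == 1)
  neg <- which(y == 0)
  keep_neg <- if (length(pos) == 0L) {
    neg[order(bce[neg], decreasing = TRUE)][seq_len(max(1L, ceiling(0.01 * length(neg))))]
  } else if (is.infinite(r)) {
    neg
  } else {
    k <- min(floor(r * length(pos)), length(neg))
    neg[order(bce[neg], decreasing = TRUE)][seq_len(k)]
  }
  kept <- c(pos, keep_neg)
  n <- length(kept)
  grad <- numeric(length(pred))
  grad[kept] <- (-(y[kept] / p[kept]) + (1 - y[kept]) / (1 - p[kept])) / n
  # clamped predictions carry no gradient
  grad[pred < eps | pred > 1 - eps] <- 0
  list(loss = mean(bce[kept]), grad = grad)
}

#' Root mean squared error loss
#'
#' @param pred,target Equal-length finite numeric vectors.
#' @return `sqrt(mean((pred - target)^2))`.
#' @export
rmse_loss <- function(pred, target) {
  if (length(pred) != length(target)) stop("pred/target length mismatch")
  if (any(!is.finite(pred)) || any(!is.finite(target))) stop("inputs must be finite")
  sqrt(mean((pred - target)^2))
}

rmse_loss_grad <- function(pred, target) {
  n <- length(pred)
  rmse <- sqrt(mean((pred - target)^2))
  grad <- if (rmse > 0) (pred - target) / (n * rmse) else numeric(n)
  list(loss = rmse, grad = grad)
}

example_loss_grad <- function(task, pred, label, r) {
  if (task == "binary") hnm_loss_grad(pred, label, r)
  else rmse_loss_grad(pred, label)
}

dataset_loss <- function(model, dataset, idx, r, tabs = NULL) {
  mean(vapply(idx, function(i) {
    ex <- dataset$examples[[i]]
    pred <- forward_model(model, ex$onehot, tabs = tabs)
    example_loss_grad(dataset$task, pred, ex$label, r)$loss
  }, numeric(1)))
}

#' Train a model
#'
#' Splits the dataset 80/20 into train/test with the configured seed, carves
#' a validation fraction out of the training split to monitor early stopping,
#' and optimizes all weights -- including the PQC rotation angles -- with
#' AdamW on minibatch gradients (hard-negative-mining loss for the binary
#' task, RMSE for signal). Training stops at `max_epochs` or after
#' `patience` epochs without validation improvement; the weights with the
#' best validation loss are returned.
#'
#' @param model A [build_model()] model.
#' @param dataset A [build_dataset()] `chip_dataset` whose task matches.
#' @param config A [train_config()].
#' @param epochs Optional override of `config$max_epochs`.
#' @param restore_best Restore the best-validation weights at the end
#'   (default TRUE); `FALSE` keeps the final-epoch weights, as used for
#'   fixed-epoch smoke runs where early stopping is disabled.
#' @return Object of class `quanv_fit`: `model` (best weights), `history`
#'   (per-epoch train/validation loss), `split` (train/val/test indices),
#'   `config`.
#' @export
train <- function(model, dataset, config = train_config(), epochs = NULL,
                  restore_best = TRUE) {
  if (model$config$task != dataset$task) {
    stop("model task ", model$config$task, " does not match dataset task ",
         dataset$task)
  }
  max_epochs <- if (is.null(epochs)) config$max_epochs else as.integer(epochs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  n <- length(dataset$examples)
  perm <- sample.int(n)
  n_train_all <- floor(config$split * n)
  train_all <- perm[seq_len(n_train_all)]
  test_idx <- perm[(n_train_all + 1L):n]
  n_val <- max(1L, floor(config$val_fraction * n_train_all))
  val_idx <- train_all[seq_len(n_val)]
  train_idx <- train_all[(n_val + 1L):n_train_all]

  quantum <- model$config$first_layer == "quantum"
  opt <- adamw_init(model$params)
  step <- 0L
  best <- list(loss = Inf, params = model$params)
  bad_epochs <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  r <- config$neg_pos_ratio
  for (epoch in seq_len(max_epochs)) {
    order_ep <- sample(train_idx)
    batches <- split(order_ep, ceiling(seq_along(order_ep) / config$batch_size))
    ep_loss <- 0
    for (b in batches) {
      tabs_g <- if (quantum) {
        qconv_tables(model$config$qconv, model$params$first$theta,
                     gradients = TRUE)
      } else NULL
      grads <- NULL
      for (i in b) {
        ex <- dataset$examples[[i]]
        fw <- forward_model(model, ex$onehot, want_cache = TRUE, tabs = tabs_g)
        lg <- example_loss_grad(dataset$task, fw$pred, ex$label, r)
        if (!is.finite(lg$loss)) {
          stop("training diverged: non-finite loss at epoch ", epoch)
        }
        ep_loss <- ep_loss + lg$loss
        g <- backward_model(model, ex$onehot, fw, lg$grad, tabs_grad = tabs_g)
        grads <- if (is.null(grads)) g else acc_grads(grads, g)
      }
      grads <- scale_grads(grads, 1 / length(b))
      step <- step + 1L
      upd <- adamw_update(model$params, grads, opt, lr = config$lr,
                          weight_decay = config$weight_decay, step = step)
      model$params <- upd$params
      opt <- upd$state
    }
    tabs <- if (quantum) {
      qconv_tables(model$config$qconv, model$params$first$theta)
    } else NULL
    val_loss <- dataset_loss(model, dataset, val_idx, r, tabs)
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = ep_loss / length(train_idx),
                                val_loss = val_loss))
    if (val_loss < best$loss - 1e-12) {
      best <- list(loss = val_loss, params = model$params)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= config$patience) break
    }
  }
  if (restore_best) model$params <- best$params
  structure(list(model = model, history = history,
                 split = list(train = train_idx, val = val_idx, test = test_idx),
                 config = config),
            class = "quanv_fit")
}

#' Nested down-sampling of a peak set
#'
#' Draws one random permutation and takes prefixes, so every smaller subset
#' is strictly contained in every larger one -- the design that lets a common
#' test set compare models across training sizes.
#'
#' @param peaks data.frame of peaks.
#' @param sizes Ascending subset sizes; maximum must not exceed `nrow(peaks)`.
#' @param seed RNG seed for the permutation.
#' @return Named list of peak data.frames, one per size.
#' @export
downsample_nested <- function(peaks, sizes, seed = 1L) {
  n <- nrow(peaks)
  if (any(diff(sizes) < 0)) stop("sizes must be ascending")
  if (max(sizes) > n) stop("size ", max(sizes), " exceeds peak count ", n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm <- sample.int(n)
  out <- lapply(sizes, function(s) peaks[perm[seq_len(s)], , drop = FALSE])
  names(out) <- as.character(sizes)
  out
}

#' Default down-sampling ladder
#'
#' The standard size ladder 250, 500, 750, 1000, 1500, 3000, 6000, 12000,
#' 24000 capped by -- and ending with -- the full peak count.
#'
#' @param n_peaks Total available peaks.
#' @return Integer vector of subset sizes.
#' @export
downsample_ladder <- function(n_peaks) {
  ladder <- c(250L, 500L, 750L, 1000L, 1500L, 3000L, 6000L, 12000L, 24000L)
  c(ladder[ladder < n_peaks], n_peaks)
}

#' Fine-tune a pretrained model on a target dataset
#'
#' Continues optimization of all weights (including the PQC angles) from a
#' pretrained checkpoint; the source fit is recorded as provenance. With
#' `epochs = 0` the weights are returned unchanged.
#'
#' @param fit A `quanv_fit` (or bare `quanv_model`) to start from.
#' @param dataset Target `chip_dataset`; its task must match the model.
#' @param config A [train_config()] for the fine-tuning phase.
#' @param epochs Number of fine-tuning epochs.
#' @param source_id Optional provenance label stored on the result.
#' @return A `quanv_fit` with attribute `source` carrying the provenance.
#' @export
fine_tune <- function(fit, dataset, config = train_config(), epochs = 5L,
                      source_id = NULL) {
  model <- if (inherits(fit, "quanv_fit")) fit$model else fit
  if (!inherits(model, "quanv_model")) stop("fit must be a quanv_fit or quanv_model")
  if (epochs == 0L) {
    out <- structure(list(model = model, history = NULL, split = NULL,
                          config = config), class = "quanv_fit")
    attr(out, "source") <- source_id
    return(out)
  }
  out <- train(model, dataset, config, epochs = epochs)
  attr(out, "source") <- source_id
  out
}

#' Paired cross-cell versus self-cell comparison harness
#'
#' For each trial: fine-tune a source-pretrained model on the target data
#' (cross) and train a fresh model on the target data alone (self), score
#' both on the target test split with `metric`, and return the paired
#' scores.
#'
#' @param pretrained A `quanv_fit` trained on source data.
#' @param target_dataset Target `chip_dataset`.
#' @param config Base [train_config()]; each trial t uses `seed + t`.
#' @param metric Function `(model, dataset, test_idx) -> scalar score`.
#' @param n_trials Number of paired trials.
#' @param epochs Training epochs per trial.
#' @return data.frame with columns `trial`, `cross`, `self`.
#' @export
cross_self_harness <- function(pretrained, target_dataset, config,
                               metric, n_trials = 3L, epochs = 3L) {
  rows <- lapply(seq_len(n_trials), function(t) {
    cfg <- config; cfg$seed <- config$seed + t
    cross_fit <- fine_tune(pretrained, target_dataset, cfg, epochs = epochs)
    fresh <- build_model(pretrained$model$config)
    self_fit <- train(fresh, target_dataset, cfg, epochs = epochs)
    data.frame(trial = t,
               cross = metric(cross_fit$model, target_dataset, cross_fit$split$test),
               self = metric(self_fit$model, target_dataset, self_fit$split$test))
  })
  do.call(rbind, rows)
}
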