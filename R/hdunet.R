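# Hierarchically dense (HD) 3D U-Net, written against the package's own
# convolution kernels (no deep-learning framework exists in this stack).
# Architecture contract:
#  * dense convolution block: two 3x3x3 conv+ReLU layers, each layer's
#    input the concatenation of all previous feature maps in the block;
#    the block output concatenates input and both layers' features;
#  * dense down-sampling: a stride-2 conv+ReLU AND a 2x max-pool of the
#    incoming features, concatenated;
#  * up-sampling: 2x nearest-neighbour upsample, conv+ReLU, then
#    concatenation of the same-level encoder features;
#  * 1x1x1 head convolution to one channel with a ReLU (nonnegative dose).

#' Model configuration
#'
#' @param n_levels number of resolution levels (input dims must be
#'   divisible by `2^(n_levels - 1)`).
#' @param base_features stem output channels.
#' @param growth_features channels added by each dense conv layer.
#' @param input_channels,output_channels fixed at 2 (CT, PB) and 1 (MC).
#' @export
model_config <- function(n_levels = 4, base_features = 16,
                         growth_features = 16,
                         input_channels = 2, output_channels = 1) {
  stopifnot(n_levels >= 2, base_features >= 1, growth_features >= 1)
  list(n_levels = as.integer(n_levels),
       base = as.integer(base_features),
       growth = as.integer(growth_features),
       in_ch = as.integer(input_channels),
       out_ch = as.integer(output_channels))
}

#' Training configuration
#'
#' Defaults follow the training protocol: Adam at initial learning rate
#' 1e-3, multiplied by 0.1 when the validation loss fails to improve for
#' 10 epochs, early stopping after 15 epochs without improvement, at most
#' 500 epochs, batch size 4, MSE loss, 3-fold cross-validation.
#'
#' @param initial_lr,lr_decay_factor,lr_patience plateau schedule.
#' @param early_stop_patience,max_epochs stopping rule.
#' @param batch_size samples per Adam step (gradient accumulation).
#' @param n_folds cross-validation folds.
#' @param warmup_steps Adam steps over which the learning rate ramps
#'   linearly from 0 (guards the narrow desk-scale nets against early
#'   ReLU collapse; the recorded lr is the post-warm-up schedule value).
#' @param head_leak fraction of the output gradient passed through
#'   saturated (zero) head voxels when the target wants them positive;
#'   revives a dying ReLU head.  0 disables.
#' @param seed master seed; fold training derives sub-seeds from it.
#' @export
train_config <- function(initial_lr = 1e-3, lr_decay_factor = 0.1,
                         lr_patience = 10, early_stop_patience = 15,
                         max_epochs = 500, batch_size = 4, n_folds = 3,
                         warmup_steps = 10, head_leak = 0.05,
                         seed = 1) {
  stopifnot(lr_patience > 0, early_stop_patience > 0, max_epochs > 0,
            batch_size > 0, n_folds >= 2,
            lr_decay_factor > 0, lr_decay_factor < 1, head_leak >= 0)
  list(initial_lr = initial_lr, lr_decay_factor = lr_decay_factor,
       lr_patience = as.integer(lr_patience),
       early_stop_patience = as.integer(early_stop_patience),
       max_epochs = as.integer(max_epochs),
       batch_size = as.integer(batch_size),
       n_folds = as.integer(n_folds),
       warmup_steps = as.integer(warmup_steps),
       head_leak = head_leak,
       seed = as.integer(seed))
}

cat4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1:3], da[4] + db[4]))
}

take_ch <- function(x, idx) x[, , , idx, drop = FALSE]

relu <- function(x) {
  x[x < 0] <- 0
  x
}

new_conv_param <- function(c_in, c_out, k) {
  fan_in <- k^3 * c_in
  ## small positive bias keeps ReLU units alive on sparse nonnegative inputs
  list(w = matrix(rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)), fan_in, c_out),
       b = rep(0.01, c_out), k = as.integer(k), c_in = as.integer(c_in))
}

#' Build an HD U-Net
#'
#' Constructs all weights (He-normal initialization, deterministic given
#' `seed`) and the channel bookkeeping for the configured depth/width.
#'
#' @param config a [model_config].
#' @param seed integer weight-initialization seed.
#' @return an object of class `hdunet` with `$params` and `$config`.
#' @export
build_model <- function(config = model_config(), seed = 1) {
  L <- config$n_levels; g <- config$growth
  with_seed(seed, {
    P <- list()
    P$stem <- new_conv_param(config$in_ch, config$base, 3)
    ch <- config$base
    enc_ch <- integer(L)
    for (l in seq_len(L)) {
      P[[paste0("enc", l, "_f1")]] <- new_conv_param(ch, g, 3)
      P[[paste0("enc", l, "_f2")]] <- new_conv_param(ch + g, g, 3)
      ch <- ch + 2 * g
      enc_ch[l] <- ch
      if (l < L) {
        P[[paste0("down", l)]] <- new_conv_param(ch, g, 3)
        ch <- ch + g
      }
    }
    comp <- config$base + g
    ch <- enc_ch[L]
    for (l in rev(seq_len(L - 1))) {
      P[[paste0("up", l)]] <- new_conv_param(ch, comp, 3)
      ch <- comp + enc_ch[l]
      P[[paste0("dec", l, "_f1")]] <- new_conv_param(ch, g, 3)
      P[[paste0("dec", l, "_f2")]] <- new_conv_param(ch + g, g, 3)
      ch <- ch + 2 * g
    }
    P$head <- new_conv_param(ch, config$out_ch, 1)
    ## near-zero head weights + positive bias keep the ReLU head alive and
    ## start the output at a small constant dose (standard regression init)
    P$head$w <- P$head$w * 0.1
    P$head$b[] <- 0.1
    structure(list(params = P, config = config, enc_ch = enc_ch),
              class = "hdunet")
  })
}

#' @export
print.hdunet <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(p) length(p$w) + length(p$b), 0))
  cat(sprintf("hdunet: %d levels, base %d, growth %d, %d parameters\n",
              x$config$n_levels, x$config$base, x$config$growth, n_par))
  invisible(x)
}

conv_f <- function(x, p, stride = 1L)
  .conv3d_fwd(x, dim(x), p$w, p$b, p$k, stride)
conv_b <- function(x, p, gout, stride = 1L)
  .conv3d_bwd(x, dim(x), p$w, gout, p$k, stride)

dense_fwd <- function(P, prefix, x) {
  r1 <- relu(conv_f(x, P[[paste0(prefix, "_f1")]]))
  x1 <- cat4(x, r1)
  r2 <- relu(conv_f(x1, P[[paste0(prefix, "_f2")]]))
  list(out = cat4(x1, r2), x = x, x1 = x1, r1 = r1, r2 = r2)
}

dense_bwd <- function(P, Genv, prefix, cache, gout) {
  c_x <- dim(cache$x)[4]; c_x1 <- dim(cache$x1)[4]
  g_x1 <- take_ch(gout, seq_len(c_x1))
  g_r2 <- take_ch(gout, (c_x1 + 1):dim(gout)[4])
  b2 <- conv_b(cache$x1, P[[paste0(prefix, "_f2")]], g_r2 * (cache$r2 > 0))
  assign(paste0(prefix, "_f2"), b2, envir = Genv)
  g_x1 <- g_x1 + b2$gx
  g_x <- take_ch(g_x1, seq_len(c_x))
  g_r1 <- take_ch(g_x1, (c_x + 1):c_x1)
  b1 <- conv_b(cache$x, P[[paste0(prefix, "_f1")]], g_r1 * (cache$r1 > 0))
  assign(paste0(prefix, "_f1"), b1, envir = Genv)
  g_x + b1$gx
}

#' Forward pass of the HD U-Net
#'
#' @param model an `hdunet`.
#' @param x input array `(D, H, W, 2)`: normalized CT and PB dose.
#' @param want_cache keep activations for a backward pass.
#' @return with `want_cache = FALSE`, the output array `(D, H, W, 1)`;
#'   otherwise a list `(y, cache)`.
#' @export
hdunet_forward <- function(model, x, want_cache = FALSE) {
  cfg <- model$config; L <- cfg$n_levels; P <- model$params
  d <- dim(x)
  if (length(d) != 4 || d[4] != cfg$in_ch)
    stop("input must be (D,H,W,", cfg$in_ch, ")")
  if (any(d[1:3] %% 2^(L - 1) != 0))
    stop("spatial dims ", paste(d[1:3], collapse = "x"),
         " not divisible by 2^(n_levels-1) = ", 2^(L - 1))
  cache <- list()
  a0 <- conv_f(x, P$stem)
  t <- relu(a0)
  cache$stem <- list(x = x, r = t)
  enc <- vector("list", L)
  for (l in seq_len(L)) {
    db <- dense_fwd(P, paste0("enc", l), t)
    cache[[paste0("enc", l)]] <- db
    enc[[l]] <- db$out
    if (l < L) {
      p <- P[[paste0("down", l)]]
      r <- relu(conv_f(db$out, p, stride = 2L))
      mp <- .maxpool_fwd(db$out, dim(db$out))
      cache[[paste0("down", l)]] <- list(x = db$out, r = r, argmax = mp$argmax)
      t <- cat4(r, mp$out)
    }
  }
  u <- enc[[L]]
  for (l in rev(seq_len(L - 1))) {
    u2 <- .upsample_fwd(u, dim(u))
    r <- relu(conv_f(u2, P[[paste0("up", l)]]))
    cache[[paste0("up", l)]] <- list(u2 = u2, r = r, u_dim = dim(u))
    db <- dense_fwd(P, paste0("dec", l), cat4(r, enc[[l]]))
    cache[[paste0("dec", l)]] <- db
    u <- db$out
  }
  a <- conv_f(u, P$head)
  y <- relu(a)
  cache$head <- list(x = u, r = y)
  if (want_cache) list(y = y, cache = cache) else y
}

## Backward pass; returns gradients keyed like params (list(gw, gb) each).
hdunet_backward <- function(model, cache, g_y) {
  cfg <- model$config; L <- cfg$n_levels; P <- model$params
  Genv <- new.env(parent = emptyenv())
  assign("head", conv_b(cache$head$x, P$head, g_y * (cache$head$r > 0)),
         envir = Genv)
  g_u <- get("head", envir = Genv)$gx
  g_enc <- vector("list", L)
  for (l in seq_len(L - 1)) {
    g_cat <- dense_bwd(P, Genv, paste0("dec", l),
                       cache[[paste0("dec", l)]], g_u)
    up <- cache[[paste0("up", l)]]
    comp <- dim(up$r)[4]
    g_r <- take_ch(g_cat, seq_len(comp))
    g_skip <- take_ch(g_cat, (comp + 1):dim(g_cat)[4])
    g_enc[[l]] <- if (is.null(g_enc[[l]])) g_skip else g_enc[[l]] + g_skip
    ub <- conv_b(up$u2, P[[paste0("up", l)]], g_r * (up$r > 0))
    assign(paste0("up", l), ub, envir = Genv)
    g_u <- .upsample_bwd(ub$gx, dim(up$u2))
  }
  g_enc[[L]] <- if (is.null(g_enc[[L]])) g_u else g_enc[[L]] + g_u
  g_t <- NULL
  for (l in rev(seq_len(L))) {
    g_out <- g_enc[[l]]
    if (l < L) {
      dn <- cache[[paste0("down", l)]]
      gch <- dim(dn$r)[4]
      g_r <- take_ch(g_t, seq_len(gch))
      g_mp <- take_ch(g_t, (gch + 1):dim(g_t)[4])
      db <- conv_b(dn$x, P[[paste0("down", l)]], g_r * (dn$r > 0), stride = 2L)
      assign(paste0("down", l), db, envir = Genv)
      g_out <- g_out + db$gx + .maxpool_bwd(dn$argmax, g_mp, dim(dn$x))
    }
    g_t <- dense_bwd(P, Genv, paste0("enc", l),
                     cache[[paste0("enc", l)]], g_out)
  }
  assign("stem", conv_b(cache$stem$x, P$stem, g_t * (cache$stem$r > 0)),
         envir = Genv)
  grads <- as.list(Genv)
  lapply(grads, function(g) list(gw = g$gw, gb = g$gb))
}

## ---------------------------------------------------------------------------
## Training
## ---------------------------------------------------------------------------

sample_input <- function(s) {
  d <- dim(s$ct_norm)
  array(c(s$ct_norm, s$pb_norm), c(d, 2L))
}

sample_target <- function(s) {
  d <- dim(s$mc_norm)
  array(s$mc_norm, c(d, 1L))
}

adam_init <- function(params) {
  lapply(params, function(p) list(mw = p$w * 0, vw = p$w * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$gw
    s$vw <- beta2 * s$vw + (1 - beta2) * g$gw^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$gb
    s$vb <- beta2 * s$vb + (1 - beta2) * g$gb^2
    params[[nm]]$w <- params[[nm]]$w - lr * (s$mw / c1) / (sqrt(s$vw / c2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

#' Plan-level cross-validation folds
#'
#' Partitions samples into `n_folds` folds at the plan level: all beams of
#' one plan land in the same fold, fold sizes (in plans) differ by at most
#' one, and the assignment is deterministic given `seed`.
#'
#' @param plan_ids character vector, one plan id per sample.
#' @param n_folds number of folds.
#' @param seed integer.
#' @return integer vector of fold assignments (1..n_folds) per sample.
#' @export
split_folds <- function(plan_ids, n_folds = 3, seed = 1) {
  plans <- unique(plan_ids)
  if (length(plans) < n_folds)
    stop("fewer plans (", length(plans), ") than folds (", n_folds, ")")
  shuffled <- with_seed(seed, sample(plans))
  fold_of_plan <- setNames(rep(seq_len(n_folds), length.out = length(plans)),
                           shuffled)
  unname(fold_of_plan[plan_ids])
}

mse_loss <- function(y, target) mean((y - target)^2)

#' Train one cross-validation fold
#'
#' Minimizes voxelwise MSE between the network output and the normalized
#' MC dose with Adam (gradient accumulation to `batch_size`).  The
#' learning rate is multiplied by `lr_decay_factor` when the validation
#' loss fails to improve for `lr_patience` epochs; training stops after
#' `early_stop_patience` epochs without improvement or at `max_epochs`,
#' and the weights from the best validation epoch are returned.
#' Validation samples should be un-augmented.
#'
#' @param train_samples,val_samples lists of `canonical_sample`s with
#'   `mc_norm` present.
#' @param train_cfg a [train_config]; `model_cfg` a [model_config].
#' @param seed fold-specific seed (derive from the master seed + fold).
#' @param verbose print per-epoch losses.
#' @return list with `model` (best weights) and `history` (data.frame:
#'   epoch, train_loss, val_loss, lr).
#' @export
train_fold <- function(train_samples, val_samples, train_cfg = train_config(),
                       model_cfg = model_config(), seed = 1, verbose = FALSE) {
  model <- build_model(model_cfg, seed = seed)
  state <- adam_init(model$params)
  lr <- train_cfg$initial_lr
  best_val <- Inf; best_params <- model$params
  bad_lr <- 0L; bad_stop <- 0L; t_step <- 0L
  history <- data.frame()
  n <- length(train_samples)
  val_mse <- function() {
    mean(vapply(val_samples, function(s) {
      mse_loss(hdunet_forward(model, sample_input(s)), sample_target(s))
    }, 0))
  }
  with_seed(derive_seed(seed, 777L), {
    for (epoch in seq_len(train_cfg$max_epochs)) {
      ord <- sample(n)
      ep_loss <- 0
      for (start in seq(1, n, by = train_cfg$batch_size)) {
        idx <- ord[start:min(start + train_cfg$batch_size - 1L, n)]
        acc <- NULL
        for (i in idx) {
          s <- train_samples[[i]]
          x <- sample_input(s); target <- sample_target(s)
          fw <- hdunet_forward(model, x, want_cache = TRUE)
          loss <- mse_loss(fw$y, target)
          if (!is.finite(loss))
            stop("NaN/Inf training loss at epoch ", epoch, ", lr ", lr,
                 ", sample ", i)
          ep_loss <- ep_loss + loss / n
          g_y <- 2 * (fw$y - target) / (length(target) * length(idx))
          if (train_cfg$head_leak > 0) {
            ## dying-ReLU protection: saturated head voxels whose target
            ## is above zero get a reduced upward gradient instead of none
            revive <- fw$cache$head$r <= 0 & g_y < 0
            if (any(revive)) {
              fw$cache$head$r[revive] <- .Machine$double.eps
              g_y[revive] <- train_cfg$head_leak * g_y[revive]
            }
          }
          g <- hdunet_backward(model, fw$cache, g_y)
          acc <- if (is.null(acc)) g else
            Map(function(a, b) list(gw = a$gw + b$gw, gb = a$gb + b$gb),
                acc, g[names(acc)])
        }
        t_step <- t_step + 1L
        lr_eff <- if (train_cfg$warmup_steps > 0)
          lr * min(1, t_step / train_cfg$warmup_steps) else lr
        upd <- adam_step(model$params, acc, state, lr_eff, t_step)
        model$params <- upd$params; state <- upd$state
      }
      vl <- val_mse()
      history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                           val_loss = vl, lr = lr))
      if (verbose)
        message(sprintf("epoch %3d  train %.3e  val %.3e  lr %.1e",
                        epoch, ep_loss, vl, lr))
      if (is.finite(vl) && vl < best_val - 1e-12) {
        best_val <- vl; best_params <- model$params
        bad_lr <- 0L; bad_stop <- 0L
      } else {
        bad_lr <- bad_lr + 1L; bad_stop <- bad_stop + 1L
      }
      if (bad_stop >= train_cfg$early_stop_patience) break
      if (bad_lr >= train_cfg$lr_patience) {
        lr <- lr * train_cfg$lr_decay_factor
        bad_lr <- 0L
      }
    }
  })
  model$params <- best_params
  list(model = model, history = history, best_val = best_val)
}

#' Train the full fold ensemble
#'
#' Splits samples into `n_folds` plan-level folds, trains one network per
#' fold (training on the other folds, validating un-augmented on the
#' held-out fold), optionally zoom-augmenting each fold's training set.
#'
#' @param samples list of canonical samples (un-augmented).
#' @param plan_ids plan id per sample.
#' @param train_cfg,model_cfg configurations.
#' @param zoom_factors augmentation factors for the training folds
#'   (`NULL` or empty = none).
#' @param verbose print progress.
#' @return a `fold_ensemble`: list of trained models plus histories.
#' @export
train_ensemble <- function(samples, plan_ids, train_cfg = train_config(),
                           model_cfg = model_config(),
                           zoom_factors = NULL, verbose = FALSE) {
  folds <- split_folds(plan_ids, train_cfg$n_folds, seed = train_cfg$seed)
  models <- list(); histories <- list()
  for (f in seq_len(train_cfg$n_folds)) {
    tr <- samples[folds != f]
    va <- samples[folds == f]
    if (length(zoom_factors)) tr <- augment_training_set(tr, zoom_factors)
    fit <- train_fold(tr, va, train_cfg, model_cfg,
                      seed = derive_seed(train_cfg$seed, f), verbose = verbose)
    models[[f]] <- fit$model
    histories[[f]] <- fit$history
  }
  structure(list(models = models, histories = histories, folds = folds,
                 train_cfg = train_cfg, model_cfg = model_cfg),
            class = "fold_ensemble")
}

#' Fold-averaged inference
#'
#' Arithmetic mean of the fold models' outputs for one canonical sample;
#' nonnegative by the ReLU head.
#'
#' @param ensemble a `fold_ensemble` (or list with `$models`).
#' @param sample a `canonical_sample`.
#' @return 3D array: converted dose in PB-max units on the tensor lattice.
#' @export
predict_ensemble <- function(ensemble, sample) {
  x <- sample_input(sample)
  outs <- lapply(ensemble$models, function(m) hdunet_forward(m, x))
  y <- Reduce(`+`, outs) / length(outs)
  array(y, dim = dim(y)[1:3])
}
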