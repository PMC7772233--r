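#' Configure training
#'
#' @param epochs Number of passes over the labeled set (or over the
#'   unlabeled set when training unlabeled-only).
#' @param labeled_batch,unlabeled_batch Slices per optimization step drawn
#'   from each domain.
#' @param learning_rate Positive step size.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param seed Integer seed; together with the data it fully determines the
#'   fitted parameters.
#' @param checkpoint_dir Optional directory; when set, the final checkpoint
#'   and the per-step training log are written there.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 24L, labeled_batch = 8L,
                         unlabeled_batch = 8L, learning_rate = 2e-3,
                         optimizer = c("adam", "sgd"), seed = 1L,
                         checkpoint_dir = NULL) {
  if (epochs < 1L) stopf("epochs must be >= 1")
  if (labeled_batch < 1L || unlabeled_batch < 1L)
    stopf("batch sizes must be >= 1")
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  structure(list(epochs = as.integer(epochs),
                 labeled_batch = as.integer(labeled_batch),
                 unlabeled_batch = as.integer(unlabeled_batch),
                 learning_rate = as.numeric(learning_rate),
                 optimizer = match.arg(optimizer),
                 seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

# Coerce volumes / lists of volumes / lists of slice samples to a flat list
# of slice samples.
as_slice_samples <- function(x) {
  if (is.null(x)) return(list())
  if (inherits(x, "labeled_volume")) return(volume_to_samples(x))
  if (inherits(x, "slice_sample")) return(list(x))
  if (is.list(x)) {
    out <- list()
    for (el in x) out <- c(out, as_slice_samples(el))
    return(out)
  }
  stopf("cannot interpret object of class '%s' as slice samples", class(x)[1])
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * (state$m[[nm]] %||% 0) + (1 - beta1) * g
    state$v[[nm]] <- beta2 * (state$v[[nm]] %||% 0) + (1 - beta2) * g * g
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

#' Fit the thickness-agnostic semi-supervised segmentation model
#'
#' Trains the encoder-decoder on labeled thick-slice samples and, when
#' provided, unlabeled thin-slice samples. Each optimization step draws one
#' labeled batch and one unlabeled batch, evaluates the combined objective
#' (supervised cross-entropy plus `lambda` times the divergence-to-uniform
#' loss), and applies one optimizer update. With no unlabeled data or
#' `lambda = 0` this degenerates to purely supervised training; with no
#' labeled data and `lambda > 0` it trains on the unlabeled objective alone
#' (which collapses predictions — useful only as an ablation arm). One epoch
#' is one pass over the labeled set; unlabeled batches cycle with
#' reshuffling. The run is fully reproducible given the seeds in `model`
#' and `control`.
#'
#' @param labeled Labeled slice samples: a list of `slice_sample`s, a
#'   [labeled_volume()] with mask, or a list of such volumes. May be empty
#'   only if `unlabeled` is nonempty and `loss$lambda > 0`.
#' @param unlabeled Unlabeled slice samples (labels, if present, are
#'   ignored), same accepted shapes; or `NULL`.
#' @param model A [model_config()] or a prebuilt [build_model()] result.
#' @param loss A [loss_config()].
#' @param control A [train_config()].
#' @return An object of class `thinseg`: list with `model` (trained
#'   `thinseg_model`), `history` (one row per step: `step`, `loss_s`,
#'   `loss_t`, `lambda_eff`, `total`), `loss`, `control`, and counts.
#' @seealso [predict.thinseg()], [evaluate_volumes()], [run_ablation()]
#' @export
thinseg <- function(labeled, unlabeled = NULL, model = model_config(),
                    loss = loss_config(), control = train_config()) {
  lab <- as_slice_samples(labeled)
  unl <- as_slice_samples(unlabeled)
  nL <- length(lab)
  nU <- length(unl)
  if (nL == 0L && nU == 0L)
    stopf("no training data: both labeled and unlabeled sets are empty")
  if (nL == 0L && loss$lambda == 0)
    stopf("labeled set is empty and lambda = 0: nothing to optimize")
  for (s in lab)
    if (is.null(s$label))
      stopf("labeled sample (volume '%s', slice %d) has no label",
            s$volume_id, s$slice_index)
  if (inherits(model, "model_config")) model <- build_model(model)
  if (!inherits(model, "thinseg_model"))
    stopf("model must be a model_config or thinseg_model")

  use_unl <- nU > 0L && loss$lambda > 0
  spe <- if (nL > 0L) ceiling(nL / control$labeled_batch)
         else ceiling(nU / control$unlabeled_batch)
  total_steps <- control$epochs * spe
  warm_steps <- max(1, loss$warmup * total_steps)

  params <- model$params
  state <- new.env(parent = emptyenv())
  state$m <- list()
  state$v <- list()
  hist <- vector("list", total_steps)

  with_seed(control$seed, {
    step <- 0L
    upool <- integer(0)
    next_unl <- function(k) {
      out <- integer(0)
      while (length(out) < k) {
        if (!length(upool)) upool <<- sample.int(nU)
        take <- min(k - length(out), length(upool))
        out <- c(out, upool[seq_len(take)])
        upool <<- upool[-seq_len(take)]
      }
      out
    }
    for (ep in seq_len(control$epochs)) {
      lorder <- if (nL > 0L) sample.int(nL) else integer(0)
      uorder_only <- if (nL == 0L) sample.int(nU) else integer(0)
      for (sb in seq_len(spe)) {
        step <- step + 1L
        lam <- loss$lambda * min(1, step / warm_steps)
        grads <- list()
        addg <- function(gg, w) {
          for (nm in names(gg))
            grads[[nm]] <<- gacc(grads[[nm]], gg[[nm]] * w)
        }
        ls_val <- NA_real_
        lt_val <- NA_real_
        stride <- encoder_downsample(model$config)
        # forward on a stride-multiple canvas; losses and gradients live on
        # the original region only
        fwd_pad <- function(image) {
          pp <- pad_to_multiple(image, stride)
          fw <- forward_net(model_with(model, params), pp$x)
          list(fw = fw, H = pp$H, W = pp$W,
               p = softmax_hw(fw$logits)[seq_len(pp$H), seq_len(pp$W), ,
                                         drop = FALSE])
        }
        bwd_pad <- function(r, gz, w) {
          full <- array(0, dim(r$fw$logits))
          full[seq_len(r$H), seq_len(r$W), ] <- gz
          addg(net_backward(r$fw$tape, r$fw$logits_id, full), w)
        }
        if (nL > 0L) {
          idx <- lorder[((sb - 1L) * control$labeled_batch + 1L):
                          min(sb * control$labeled_batch, nL)]
          ls_val <- 0
          for (i in idx) {
            r <- fwd_pad(lab[[i]]$image)
            ls_val <- ls_val + supervised_loss(r$p, lab[[i]]$label)
            bwd_pad(r, grad_supervised_logits(r$p, lab[[i]]$label),
                    1 / length(idx))
          }
          ls_val <- ls_val / length(idx)
        }
        if (use_unl) {
          uidx <- if (nL > 0L) next_unl(control$unlabeled_batch)
                  else uorder_only[((sb - 1L) * control$unlabeled_batch + 1L):
                                     min(sb * control$unlabeled_batch, nU)]
          lt_val <- 0
          for (i in uidx) {
            r <- fwd_pad(unl[[i]]$image)
            lt_val <- lt_val + target_loss(r$p, loss$divergence)
            if (lam > 0)
              bwd_pad(r, grad_target_logits(r$p, loss$divergence),
                      lam / length(uidx))
          }
          lt_val <- lt_val / length(uidx)
        }
        # global-norm gradient clipping guards rare unstable steps
        gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), 1)))
        if (is.finite(gn) && gn > 5)
          grads <- lapply(grads, function(g) g * (5 / gn))
        if (control$optimizer == "adam") {
          up <- adam_update(params, grads, state, control$learning_rate, step)
          params <- up$params
        } else {
          for (nm in names(grads))
            params[[nm]] <- params[[nm]] - control$learning_rate * grads[[nm]]
        }
        hist[[step]] <- data.frame(
          step = step, loss_s = ls_val, loss_t = lt_val, lambda_eff = lam,
          total = (if (is.na(ls_val)) 0 else ls_val) +
                  (if (is.na(lt_val)) 0 else lam * lt_val))
      }
    }
  })

  model$params <- params
  fit <- structure(list(
    model = model,
    history = do.call(rbind, hist),
    loss = loss,
    control = control,
    n_labeled = nL,
    n_unlabeled = nU
  ), class = "thinseg")

  if (!is.null(control$checkpoint_dir)) {
    dir.create(control$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    fit$checkpoint <- file.path(control$checkpoint_dir, "model.rds")
    save_checkpoint(model, fit$checkpoint)
    utils::write.csv(fit$history,
                     file.path(control$checkpoint_dir, "training_log.csv"),
                     row.names = FALSE)
  }
  fit
}

# Cheap re-skinning of a model with updated parameters.
model_with <- function(model, params) {
  model$params <- params
  model
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized file holding the model configuration
#' and all parameter arrays.
#'
#' @param model A `thinseg_model` or fitted `thinseg` object.
#' @param path Destination file.
#' @return `path` (save) or a `thinseg_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "thinseg")) model <- model$model
  saveRDS(list(format = "thinseg-checkpoint", version = 1L,
               config = model$config, params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("no such checkpoint: '%s'", path)
  ck <- readRDS(path)
  if (!identical(ck$format, "thinseg-checkpoint"))
    stopf("'%s' is not a thinseg checkpoint", path)
  structure(list(config = ck$config, params = ck$params),
            class = "thinseg_model")
}

#' Predict the segmentation of a whole volume
#'
#' Runs the trained model slice by slice (the volume is normalized first if
#' it has not been), takes the per-pixel argmax over classes, and restacks
#' the slices into a mask carrying the source volume's spacing and tags.
#'
#' @param object A fitted [thinseg()] object (or a bare `thinseg_model`).
#' @param volume A [labeled_volume()].
#' @param type `"mask"` to return the volume with the predicted mask
#'   attached, `"prob"` to return the stacked `(slices, H, W, C)`
#'   probability array.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.thinseg <- function(object, volume, type = c("mask", "prob"), ...) {
  predict_volume(object$model, volume, type = match.arg(type))
}

#' @rdname predict.thinseg
#' @export
predict_volume <- function(object, volume, type = c("mask", "prob")) {
  type <- match.arg(type)
  model <- if (inherits(object, "thinseg")) object$model else object
  if (!inherits(volume, "labeled_volume"))
    stopf("volume must be a labeled_volume")
  if (is.null(volume$norm)) volume <- normalize_volume(volume)
  samples <- volume_to_samples(volume)
  probs <- lapply(samples, function(s) model_forward(model, s$image))
  if (type == "prob") {
    d <- dim(probs[[1]])
    out <- array(0, c(length(probs), d))
    for (i in seq_along(probs)) out[i, , , ] <- probs[[i]]
    return(out)
  }
  planes <- lapply(probs, function(p) {
    am <- p[, , 1]
    cls <- matrix(0L, nrow(am), ncol(am))
    for (cc in seq_len(dim(p)[3])[-1]) {
      better <- p[, , cc] > am
      cls[better] <- cc - 1L
      am[better] <- p[, , cc][better]
    }
    cls
  })
  volume$mask <- stack_slices(planes)
  volume
}

## ---- S3 surface --------------------------------------------------------

#' @export
print.thinseg <- function(x, ...) {
  h <- x$history
  cat(sprintf("Semi-supervised segmentation fit (%s encoder, %s divergence, lambda = %g)\n",
              x$model$config$encoder, x$loss$divergence$name, x$loss$lambda))
  cat(sprintf("  %d labeled + %d unlabeled slices, %d steps\n",
              x$n_labeled, x$n_unlabeled, nrow(h)))
  last <- h[nrow(h), ]
  cat(sprintf("  final losses: supervised %s, unlabeled %s, total %.4f\n",
              formatC(last$loss_s, digits = 4, format = "f"),
              formatC(last$loss_t, digits = 4, format = "f"), last$total))
  invisible(x)
}

#' @export
summary.thinseg <- function(object, ...) {
  h <- object$history
  sm <- list(
    config = object$model$config,
    loss = object$loss,
    control = object$control,
    steps = nrow(h),
    n_labeled = object$n_labeled,
    n_unlabeled = object$n_unlabeled,
    final = h[nrow(h), ],
    loss_quartiles = stats::quantile(h$total, c(0, .25, .5, .75, 1)))
  class(sm) <- "summary.thinseg"
  sm
}

#' @export
print.summary.thinseg <- function(x, ...) {
  cat(sprintf("thinseg fit: encoder %s, C = %d classes, %d steps\n",
              x$config$encoder, x$config$num_classes, x$steps))
  cat(sprintf("  data: %d labeled, %d unlabeled slices\n",
              x$n_labeled, x$n_unlabeled))
  cat(sprintf("  objective: %s divergence, lambda = %g (warm-up %.0f%%)\n",
              x$loss$divergence$name, x$loss$lambda, 100 * x$loss$warmup))
  cat("  total-loss quartiles over training:\n")
  print(round(x$loss_quartiles, 4))
  invisible(x)
}

#' @export
coef.thinseg <- function(object, ...) {
  unlist(object$model$params)
}

#' @export
plot.thinseg <- function(x, ...) {
  h <- x$history
  graphics::plot(h$step, h$total, type = "l", xlab = "step", ylab = "loss",
                 main = "Training losses", ...)
  if (!all(is.na(h$loss_s)))
    graphics::lines(h$step, h$loss_s, col = "steelblue")
  if (!all(is.na(h$loss_t)))
    graphics::lines(h$step, h$loss_t, col = "firebrick")
  graphics::legend("topright", bty = "n",
                   legend = c("total", "supervised", "unlabeled"),
                   col = c("black", "steelblue", "firebrick"), lty = 1)
  invisible(x)
}
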