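#' Divergence choice for the unlabeled-domain objective
#'
#' The unlabeled objective is the negated f-divergence between the per-pixel
#' predicted class distribution and the uniform distribution `U = 1/C`. Two
#' generator functions are supported: `f(x) = x log x` (KL divergence, with
#' `f(0) = 0` by the standard limit) and the Pearson chi-square divergence
#' `f(x) = x^2 - 1` (so `f(0) = -1` by direct evaluation). Both satisfy
#' `f(1) = 0`, so the divergence vanishes exactly at uniform predictions.
#'
#' @param name `"pearson_chi2"` or `"kl"`.
#' @return An object of class `divergence_kind` with fields `name` and the
#'   vectorized generator `f`.
#' @export
divergence_kind <- function(name = c("pearson_chi2", "kl")) {
  name <- match.arg(name)
  f <- if (name == "kl") {
    function(x) ifelse(x > 0, x * log(pmax(x, 1e-300)), 0)
  } else {
    function(x) x^2 - 1
  }
  structure(list(name = name, f = f), class = "divergence_kind")
}

as_divergence <- function(kind) {
  if (inherits(kind, "divergence_kind")) kind else divergence_kind(kind)
}

#' Configure the combined loss
#'
#' The training objective is `L = L_S(p_s, y_s) + lambda * L_T(p_t)`:
#' supervised cross-entropy on labeled (thick-slice) predictions plus a
#' weighted divergence-to-uniform term on unlabeled (thin-slice)
#' predictions. `lambda` ramps up linearly over the first `warmup` fraction
#' of training steps, since entropy-type regularizers destabilize early
#' training at full strength.
#'
#' @param lambda Nonnegative weight of the unlabeled term.
#' @param divergence `"pearson_chi2"`, `"kl"`, or a [divergence_kind()].
#' @param num_classes Class count `C >= 2`.
#' @param warmup Fraction of total steps over which `lambda` ramps from 0.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(lambda = 0.1, divergence = "pearson_chi2",
                        num_classes = 2L, warmup = 0.1) {
  if (lambda < 0) stopf("lambda must be >= 0")
  if (num_classes < 2L) stopf("num_classes must be >= 2")
  structure(list(lambda = as.numeric(lambda),
                 divergence = as_divergence(divergence),
                 num_classes = as.integer(num_classes),
                 warmup = as.numeric(warmup)),
            class = "loss_config")
}

check_prob_map <- function(p) {
  if (length(dim(p)) != 3L)
    stopf("probability map must be an H x W x C array")
  invisible(p)
}

#' Supervised cross-entropy loss
#'
#' Mean over all pixels of `-log p` at the true class (one-hot labels).
#' Probabilities are clamped at `1e-12` inside the log, so exact zeros at a
#' true class yield a large finite penalty rather than an error.
#'
#' @param p `H x W x C` probability map.
#' @param y `H x W` integer label map with values in `[0, C)`.
#' @return Nonnegative scalar.
#' @export
supervised_loss <- function(p, y) {
  check_prob_map(p)
  d <- dim(p)
  y <- as.integer(y)
  if (length(y) != d[1] * d[2])
    stopf("label map size does not match probability map")
  if (any(y < 0L | y >= d[3]))
    stopf("labels must lie in [0, %d)", d[3])
  npix <- d[1] * d[2]
  pt <- p[seq_len(npix) + y * npix]
  -mean(log(pmax(pt, 1e-12)))
}

#' Divergence-to-uniform loss on unlabeled predictions
#'
#' Per pixel, the negated f-divergence from the uniform distribution:
#' `-(1/C) * sum_c f(C * p_c)`, averaged over pixels. It is 0 iff every
#' pixel predicts the uniform distribution and is negative otherwise, so
#' minimizing it pushes predictions away from the decision boundary toward
#' confident one-hot assignments. For the Pearson chi-square generator it is
#' bounded below by `-(C - 1)` (attained at one-hot pixels).
#'
#' @param p `H x W x C` probability map.
#' @param kind Divergence name or [divergence_kind()].
#' @return Scalar `<= 0`.
#' @export
target_loss <- function(p, kind = "pearson_chi2") {
  check_prob_map(p)
  kind <- as_divergence(kind)
  C <- dim(p)[3]
  -sum(kind$f(C * p)) / (C * dim(p)[1] * dim(p)[2])
}

#' Combined semi-supervised objective
#'
#' `supervised_loss(p_s, y_s) + lambda * target_loss(p_t, kind)`. With
#' `lambda = 0` (or no unlabeled predictions) this reduces exactly to the
#' supervised loss.
#'
#' @param p_s,y_s Labeled-domain probability map and label map.
#' @param p_t Unlabeled-domain probability map, or `NULL`.
#' @param config A [loss_config()].
#' @return Scalar loss value.
#' @export
total_loss <- function(p_s, y_s, p_t, config = loss_config()) {
  ls <- supervised_loss(p_s, y_s)
  if (config$lambda == 0 || is.null(p_t)) return(ls)
  ls + config$lambda * target_loss(p_t, config$divergence)
}

#' Closed-form binary gradient references
#'
#' The printed binary-case derivatives of the divergence-to-uniform loss
#' with respect to the foreground probability: `log(1 - p) - log(p)` for KL
#' and `2 - 4p` for Pearson chi-square. Both vanish at `p = 0.5`; the KL
#' form is unbounded as `p` approaches 0 or 1 while the chi-square form is
#' bounded by 2 in absolute value — the gradient-imbalance argument for
#' preferring chi-square. These are qualitative references for analysis and
#' tests; training backpropagates through [target_loss()] itself.
#'
#' @param p Probabilities in `[0, 1]` (exactly 0/1 allowed only for
#'   chi-square; for KL they signal an unbounded gradient via a warning and
#'   infinite values).
#' @param kind Divergence name or [divergence_kind()].
#' @return Numeric vector of reference gradients.
#' @export
binary_gradient_reference <- function(p, kind = "pearson_chi2") {
  kind <- as_divergence(kind)
  if (any(p < 0 | p > 1)) stopf("p must lie in [0, 1]")
  if (kind$name == "pearson_chi2") return(2 - 4 * p)
  out <- suppressWarnings(log(1 - p) - log(p))
  if (any(p == 0 | p == 1))
    warning("KL reference gradient is unbounded at p = 0 or p = 1",
            call. = FALSE)
  out
}

## ---- gradients used by the trainer ------------------------------------

# d supervised_loss / d logits for softmax outputs: (p - onehot(y)) / npix.
grad_supervised_logits <- function(p, y) {
  d <- dim(p)
  npix <- d[1] * d[2]
  g <- p
  idx <- seq_len(npix) + as.integer(y) * npix
  g[idx] <- g[idx] - 1
  g / npix
}

# d [lambda-free] target_loss / d logits, by chain rule through softmax.
# dL/dp_c = -(1/npix) * f'(C p_c); dL/dz_i = p_i * (g_i - sum_c p_c g_c).
grad_target_logits <- function(p, kind) {
  kind <- as_divergence(kind)
  d <- dim(p)
  npix <- d[1] * d[2]
  gp <- if (kind$name == "pearson_chi2") {
    -(2 * d[3] * p) / npix
  } else {
    -(log(pmax(d[3] * p, 1e-12)) + 1) / npix
  }
  s <- gp[, , 1] * p[, , 1]
  for (cc in seq_len(d[3])[-1]) s <- s + gp[, , cc] * p[, , cc]
  p * (gp - array(s, d))
}
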