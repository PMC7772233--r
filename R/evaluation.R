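#' Dice overlap coefficient
#'
#' `2|A intersect B| / (|A| + |B|)` between two binary masks of identical
#' shape. Two empty masks agree perfectly and score 1; an empty mask against
#' a nonempty one scores 0. Symmetric in its arguments.
#'
#' @param a,b Binary (logical or 0/1) arrays of identical shape.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stopf("dice: mask shapes differ")
  a <- a != 0
  b <- b != 0
  sa <- sum(a)
  sb <- sum(b)
  if (sa + sb == 0L) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Evaluate a model on labeled volumes
#'
#' Predicts each volume slice-wise and reports per-volume Dice plus group
#' means by modality and domain, in the layout of a thick / thin / mixed
#' benchmark table. Group means are volume-level (each volume weighted
#' equally); a slice-pooled aggregation (mean of per-slice Dice over all
#' slices in the group) is reported alongside, since the two conventions
#' can differ.
#'
#' @param object A fitted [thinseg()] object or `thinseg_model`.
#' @param volumes List of [labeled_volume()]s, each carrying ground truth.
#' @return An object of class `dice_report`: `per_volume` (volume_id,
#'   modality, domain, dice), `group_means` (modality x thick/thin/mixed,
#'   volume-level), and `slice_pooled` (same layout, slice-level).
#' @export
evaluate_volumes <- function(object, volumes) {
  if (inherits(volumes, "labeled_volume")) volumes <- list(volumes)
  missing_truth <- vapply(volumes, function(v) is.null(v$mask), TRUE)
  if (any(missing_truth))
    stopf("ground truth missing for volume(s): %s",
          paste(vapply(volumes[missing_truth], `[[`, "", "volume_id"),
                collapse = ", "))
  rows <- lapply(volumes, function(v) {
    pred <- predict_volume(object, v)
    sd_ <- vapply(seq_len(dim(v$mask)[1]), function(i)
      dice(v$mask[i, , ], pred$mask[i, , ]), 1)
    data.frame(volume_id = v$volume_id, modality = v$modality,
               domain = v$domain, dice = dice(v$mask, pred$mask),
               slice_dice_sum = sum(sd_), n_slices = length(sd_),
               stringsAsFactors = FALSE)
  })
  per_volume <- do.call(rbind, rows)
  dice_report(per_volume)
}

# Build a dice_report from a per-volume table (with slice sums for the
# slice-pooled aggregation).
dice_report <- function(per_volume) {
  gm <- list()
  sp <- list()
  for (mod in sort(unique(per_volume$modality))) {
    for (dom in c("thick", "thin", "mixed")) {
      sel <- per_volume$modality == mod &
        (if (dom == "mixed") TRUE else per_volume$domain == dom)
      if (!any(sel)) next
      gm[[length(gm) + 1L]] <- data.frame(
        modality = mod, domain = dom,
        dice = mean(per_volume$dice[sel]), n = sum(sel),
        stringsAsFactors = FALSE)
      sp[[length(sp) + 1L]] <- data.frame(
        modality = mod, domain = dom,
        dice = sum(per_volume$slice_dice_sum[sel]) /
          sum(per_volume$n_slices[sel]),
        n = sum(per_volume$n_slices[sel]),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    per_volume = per_volume[, c("volume_id", "modality", "domain", "dice")],
    group_means = do.call(rbind, gm),
    slice_pooled = do.call(rbind, sp),
    mean_dice = mean(per_volume$dice)
  ), class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("Dice report over %d volumes (mean Dice %.4f)\n",
              nrow(x$per_volume), x$mean_dice))
  g <- x$group_means
  for (mod in unique(g$modality)) {
    row <- function(dom) {
      v <- g$dice[g$modality == mod & g$domain == dom]
      if (length(v)) sprintf("%.4f", v) else "  -   "
    }
    cat(sprintf("  %-6s thick %s  thin %s  mixed %s\n",
                mod, row("thick"), row("thin"), row("mixed")))
  }
  invisible(x)
}

# Mean Dice of a report restricted by domain/modality (NULL = no filter).
report_mean <- function(report, domain = NULL, modality = NULL) {
  pv <- report$per_volume
  sel <- rep(TRUE, nrow(pv))
  if (!is.null(domain)) sel <- sel & pv$domain == domain
  if (!is.null(modality)) sel <- sel & pv$modality == modality
  mean(pv$dice[sel])
}

#' Evaluate a model on a cohort manifest split
#'
#' Reads the split's volumes (falling back to the hidden ground-truth table
#' for volumes whose masks were withheld from the manifest) and calls
#' [evaluate_volumes()].
#'
#' @param object Fitted [thinseg()] object or `thinseg_model`.
#' @param manifest A manifest `data.frame` from [read_manifest()] /
#'   [make_cohort()], or a path to one.
#' @param split Which split to evaluate (default `"test"`).
#' @return A `dice_report`.
#' @export
evaluate_manifest <- function(object, manifest, split = "test") {
  manifest <- ensure_manifest(manifest)
  dirn <- attr(manifest, "dir")
  rows <- which(manifest$split == split)
  if (!length(rows)) stopf("manifest has no '%s' split", split)
  hidden <- hidden_truth_table(dirn)
  vols <- lapply(rows, function(i) {
    v <- manifest_volume(manifest, i)
    if (is.null(v$mask)) {
      hp <- hidden$mask_path[match(v$volume_id, hidden$volume_id)]
      if (!is.na(hp)) {
        m <- RNifti::readNifti(file.path(dirn, hp))
        v$mask <- array(as.integer(aperm(as.array(m), c(3, 2, 1)) != 0),
                        dim(v$intensity))
      }
    }
    v
  })
  evaluate_volumes(object, vols)
}

ensure_manifest <- function(manifest) {
  if (is.character(manifest)) return(read_manifest(manifest))
  if (is.null(attr(manifest, "dir"))) {
    p <- attr(manifest, "path")
    if (!is.null(p)) attr(manifest, "dir") <- dirname(normalizePath(p))
    else stopf("manifest lacks a directory attribute; pass the CSV path")
  }
  manifest
}

hidden_truth_table <- function(dirn) {
  hp <- file.path(dirn, "hidden_truth", "hidden_truth.csv")
  if (file.exists(hp))
    utils::read.csv(hp, stringsAsFactors = FALSE, colClasses = "character")
  else data.frame(volume_id = character(), mask_path = character())
}

#' Three-experiment ablation harness
#'
#' Trains and evaluates the three regimes of the semi-supervised design on
#' one cohort with identical architecture and initialization seed:
#' Experiment 1 uses labeled thick-slice volumes only (`lambda = 0`);
#' Experiment 2 uses unlabeled thin-slice volumes only (the
#' divergence-to-uniform objective alone, which collapses predictions);
#' Experiment 3 combines both. Test-set Dice reports are returned
#' side-by-side.
#'
#' @param manifest Cohort manifest (`data.frame` or path).
#' @param model A [model_config()]; the same config (hence identical
#'   initialization) is used for all three experiments.
#' @param loss A [loss_config()] for Experiment 3 (Experiment 1 zeroes
#'   `lambda`; Experiment 2 uses it unchanged).
#' @param control A [train_config()].
#' @return An object of class `thinseg_ablation`: per-experiment fits and
#'   `dice_report`s plus a comparison table.
#' @export
run_ablation <- function(manifest, model = model_config(),
                         loss = loss_config(), control = train_config()) {
  manifest <- ensure_manifest(manifest)
  data <- load_training_data(manifest)
  loss1 <- loss
  loss1$lambda <- 0
  # Exp 2 has no labeled set, so its epoch is a pass over the (larger)
  # unlabeled set; scale its epoch count to match Exp 1/3's total steps.
  nL <- sum(vapply(data$labeled, function(v) dim(v$intensity)[1], 1L))
  nU <- sum(vapply(data$unlabeled, function(v) dim(v$intensity)[1], 1L))
  control2 <- control
  if (nL > 0L && nU > 0L) {
    steps3 <- control$epochs * ceiling(nL / control$labeled_batch)
    control2$epochs <- max(1L, as.integer(round(
      steps3 / ceiling(nU / control$unlabeled_batch))))
  }
  exps <- list(
    exp1 = thinseg(data$labeled, NULL, model, loss1, control),
    exp2 = thinseg(list(), data$unlabeled, model, loss, control2),
    exp3 = thinseg(data$labeled, data$unlabeled, model, loss, control))
  reports <- lapply(exps, evaluate_manifest, manifest = manifest)
  tab <- ablation_table(reports)
  structure(list(fits = exps, reports = reports, table = tab),
            class = "thinseg_ablation")
}

# Normalized training samples from a manifest: labeled thick + unlabeled thin.
load_training_data <- function(manifest) {
  manifest <- ensure_manifest(manifest)
  get_split <- function(split, with_mask) {
    rows <- which(manifest$split == split)
    lapply(rows, function(i)
      normalize_volume(manifest_volume(manifest, i, with_mask = with_mask)))
  }
  list(labeled = get_split("train_labeled", TRUE),
       unlabeled = get_split("train_unlabeled", FALSE))
}

# Side-by-side Dice table: one row per experiment, columns modality x
# thick/thin/mixed.
ablation_table <- function(reports) {
  rows <- lapply(names(reports), function(nm) {
    g <- reports[[nm]]$group_means
    out <- data.frame(exp = nm, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(g)))
      out[[paste(g$modality[i], g$domain[i], sep = "_")]] <- g$dice[i]
    out$thick <- report_mean(reports[[nm]], domain = "thick")
    out$thin <- report_mean(reports[[nm]], domain = "thin")
    out$mixed <- reports[[nm]]$mean_dice
    out
  })
  nms <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(nms, names(r))) r[[nm]] <- NA_real_
    r[nms]
  })
  do.call(rbind, rows)
}

#' @export
print.thinseg_ablation <- function(x, ...) {
  cat("Ablation: thick-only (exp1) / thin-only (exp2) / combined (exp3)\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(v) sprintf("%.4f", v))
  print(tab, row.names = FALSE)
  invisible(x)
}
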