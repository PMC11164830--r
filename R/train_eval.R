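# Training with patient-level splits, evaluation metrics (aMSE, aPCC, NGPC,
# ACC, AUC, AUPRC), the loss-component ablation runner, and tumor-vs-normal
# differential gene ranking.

#' Patient-level split specification
#'
#' Samples are assigned to train/validation/test by their `patient_id`, so
#' no patient contributes spots to more than one set.
#'
#' @param train_patients,val_patients,test_patients disjoint character
#'   vectors of patient ids.
#' @param seed integer recorded with the split.
#' @return list with class `split_spec`.
#' @export
split_spec <- function(train_patients, val_patients = character(0),
                       test_patients = character(0), seed = NA_integer_) {
  all <- c(train_patients, val_patients, test_patients)
  if (anyDuplicated(all)) {
    stop("patient(s) assigned to more than one set: ",
         paste(unique(all[duplicated(all)]), collapse = ", "))
  }
  if (length(train_patients) == 0L) stop("training set has no patients")
  structure(list(train_patients = train_patients, val_patients = val_patients,
                 test_patients = test_patients, seed = seed),
            class = "split_spec")
}

#' Random patient-level split
#'
#' @param patient_ids character vector of distinct patient ids.
#' @param n_val,n_test number of validation / test patients.
#' @param seed RNG seed for the assignment.
#' @return a [split_spec()].
#' @export
random_patient_split <- function(patient_ids, n_val = 1L, n_test = 1L,
                                 seed = 1L) {
  patient_ids <- unique(patient_ids)
  if (length(patient_ids) < n_val + n_test + 1L) {
    stop("need at least ", n_val + n_test + 1L, " patients")
  }
  set.seed(seed)
  perm <- sample(patient_ids)
  split_spec(train_patients = perm[seq_len(length(perm) - n_val - n_test)],
             val_patients = if (n_val) perm[length(perm) - n_test - seq_len(n_val) + 1L] else character(0),
             test_patients = if (n_test) perm[length(perm) - seq_len(n_test) + 1L] else character(0),
             seed = seed)
}

split_role <- function(patient_id, split) {
  if (patient_id %in% split$train_patients) return("train")
  if (patient_id %in% split$val_patients) return("val")
  if (patient_id %in% split$test_patients) return("test")
  NA_character_
}

#' Training hyperparameters
#'
#' @param epochs number of passes over the training spots.
#' @param batch_size spots per mini-batch (under a positive spatial weight,
#'   batches are built from sampled central spots plus their grid neighbors
#'   so the spatial term is computable; `batch_size` then bounds the batch).
#' @param lr Adam learning rate.
#' @param m number of target genes for [partition_genes()].
#' @param window_px,out_size_px patch geometry, see [extract_patches()].
#' @param scale,pseudocount expression normalization, see
#'   [normalize_expression()].
#' @param partition_layer rank genes for the target set on the
#'   `"normalized"` (default) or `"raw"` layer.
#' @param spatial_reduce gene reduction inside the spatial loss, see
#'   [loss_spatial()].
#' @param augment apply random flips / 90-degree rotations to training
#'   patches.
#' @param early_stop_patience stop after this many epochs without
#'   improvement of validation aPCC (default `Inf` = never).
#' @param select_best keep the parameters from the best validation epoch
#'   (when a validation set exists).
#' @param seed RNG seed for weight initialization and batch order.
#' @return list with class `train_config`.
#' @export
train_config <- function(epochs = 10L, batch_size = 64L, lr = 5e-3, m = 250L,
                         window_px = 150L, out_size_px = 224L, scale = 10000,
                         pseudocount = 1,
                         partition_layer = c("normalized", "raw"),
                         spatial_reduce = c("mean", "sum"), augment = FALSE,
                         early_stop_patience = Inf, select_best = TRUE,
                         seed = 1L) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, m = as.integer(m), window_px = as.integer(window_px),
                 out_size_px = as.integer(out_size_px), scale = scale,
                 pseudocount = pseudocount,
                 partition_layer = match.arg(partition_layer),
                 spatial_reduce = match.arg(spatial_reduce),
                 augment = isTRUE(augment),
                 early_stop_patience = early_stop_patience,
                 select_best = isTRUE(select_best), seed = as.integer(seed)),
            class = "train_config")
}

# ---------------------------------------------------------------------------
# dataset preparation (QC -> normalization -> patches -> partition), with all
# statistics (gene filter, channel stats, gene ranking) computed on the
# training split only

#' Prepare a cohort for training and evaluation
#'
#' Runs the full preprocessing pipeline: patch extraction with boundary
#' exclusion, spot QC, gene QC (detection counted on training spots only,
#' applied cohort-wide), expression normalization, patch standardization
#' with training-split channel statistics, target/non-target gene
#' partitioning on the training split, and neighbor-graph construction.
#'
#' @param samples list of [st_sample()] with raw counts; all samples must
#'   share one gene universe.
#' @param split a [split_spec()] covering every sample's patient.
#' @param thresholds a [qc_thresholds()].
#' @param config a [train_config()] (patch geometry, normalization, m).
#' @return list with class `sg_dataset`.
#' @export
prepare_dataset <- function(samples, split, thresholds = qc_thresholds(),
                            config = train_config()) {
  roles <- vapply(samples, function(s) split_role(s$patient_id, split),
                  character(1))
  if (anyNA(roles)) {
    stop("sample(s) with patient not assigned in the split: ",
         paste(vapply(samples[is.na(roles)], `[[`, "", "sample_id"),
               collapse = ", "))
  }
  if (!any(roles == "train")) stop("no training samples")
  gene_universe <- colnames(samples[[1]]$expression)
  entries <- lapply(samples, function(s) {
    if (!identical(colnames(s$expression), gene_universe)) {
      stop("samples do not share one gene universe (", s$sample_id, ")")
    }
    ex <- extract_patches(s, config$window_px, config$out_size_px)
    keep <- qc_filter_spots(s, thresholds, boundary_mask = ex$boundary_mask)
    keep_ids <- names(keep)[keep]
    if (length(keep_ids) == 0L) {
      message("sample ", s$sample_id, ": no spots survive QC")
    }
    list(sample = s, keep_ids = keep_ids, patches = ex$patches,
         boundary_mask = ex$boundary_mask)
  })

  train_idx <- which(roles == "train")
  train_counts <- do.call(rbind, lapply(entries[train_idx], function(e) {
    e$sample$expression[e$keep_ids, , drop = FALSE]
  }))
  if (nrow(train_counts) == 0L) stop("training split is empty after QC")
  gene_keep <- qc_filter_genes(
    expression_matrix(train_counts, gene_universe,
                      make.unique(rownames(train_counts)), "raw_counts"),
    thresholds)
  gene_names <- gene_universe[gene_keep]
  if (length(gene_names) == 0L) stop("no genes survive QC")

  entries <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    counts <- e$sample$expression[e$keep_ids, gene_names, drop = FALSE]
    counts <- expression_matrix(counts, gene_names, e$keep_ids, "raw_counts")
    norm <- if (length(e$keep_ids)) {
      normalize_expression(counts, config$scale, config$pseudocount)
    }
    patch_keep <- match(e$keep_ids, e$patches$spot_ids)
    patches <- e$patches
    patches$patches <- patches$patches[patch_keep, , , , drop = FALSE]
    patches$spot_ids <- e$keep_ids
    spots <- e$sample$spots[match(e$keep_ids, e$sample$spots$spot_id), ,
                            drop = FALSE]
    class(spots) <- c("spot_table", "data.frame")
    list(sample_id = e$sample$sample_id, patient_id = e$sample$patient_id,
         role = roles[i], spots = spots, counts = counts, expr = norm,
         patches = patches, labels = spots$annotation,
         graph = build_neighbor_graph(spots),
         latent = e$sample$latent, boundary_mask = e$boundary_mask)
  })

  train_entries <- entries[roles == "train"]
  raw_train <- abind_patches(lapply(train_entries, function(e) e$patches))
  stats <- channel_stats(raw_train)
  if (any(stats$sd <= 0)) stop("degenerate image channel in training split")
  entries <- lapply(entries, function(e) {
    if (nrow(e$spots)) {
      e$patches <- normalize_patches(e$patches, stats$mean, stats$sd)
    }
    e
  })

  part_expr <- do.call(rbind, lapply(train_entries, function(e) {
    if (config$partition_layer == "normalized") unclass(e$expr) else
      unclass(e$counts)
  }))
  colnames(part_expr) <- gene_names
  part_expr <- expression_matrix(part_expr, gene_names,
                                 make.unique(rownames(part_expr)),
                                 if (config$partition_layer == "normalized")
                                   "normalized" else "raw_counts")
  m <- min(config$m, length(gene_names))
  partition <- partition_genes(part_expr, m)

  structure(list(entries = entries, gene_names = gene_names,
                 channel_stats = stats, partition = partition, split = split,
                 thresholds = thresholds, config = config),
            class = "sg_dataset")
}

abind_patches <- function(patch_sets) {
  arrs <- lapply(patch_sets, `[[`, "patches")
  keep <- vapply(arrs, function(a) dim(a)[1] > 0L, logical(1))
  arrs <- arrs[keep]
  n <- vapply(arrs, function(a) dim(a)[1], integer(1))
  S <- dim(arrs[[1]])[2]
  out <- array(0, c(sum(n), S, S, 3L))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , , ] <- a
    at <- at + dim(a)[1]
  }
  ps <- patch_sets[[which(keep)[1]]]
  ps$patches <- out
  ps$spot_ids <- unlist(lapply(patch_sets[keep], `[[`, "spot_ids"))
  ps
}

dataset_entries <- function(dataset, role) {
  Filter(function(e) e$role == role && nrow(e$spots) > 0L, dataset$entries)
}

# ---------------------------------------------------------------------------
# training

augment_batch <- function(a) {
  # random horizontal/vertical flips and 90-degree rotations, per batch
  if (runif(1) < 0.5) a <- a[, dim(a)[2]:1, , , drop = FALSE]
  if (runif(1) < 0.5) a <- a[, , dim(a)[3]:1, , drop = FALSE]
  if (runif(1) < 0.5) a <- aperm(a, c(1L, 3L, 2L, 4L))
  a
}

make_batches <- function(entry, config, weights) {
  n <- nrow(entry$spots)
  ord <- sample.int(n)
  if (weights$gamma_spat > 0) {
    # neighborhood batching: sampled central spots plus their neighbors, so
    # the spatial term always has in-batch pairs
    centrals_per <- max(1L, config$batch_size %/% 4L)
    starts <- split(ord, ceiling(seq_along(ord) / centrals_per))
    lapply(starts, function(centrals) {
      sort(unique(c(centrals, unlist(entry$graph$neighbors[centrals]))))
    })
  } else {
    split(ord, ceiling(seq_along(ord) / config$batch_size))
  }
}

#' Train the multi-task model
#'
#' Optimizes the composite loss (primary + weighted auxiliary, tumor, and
#' spatial terms) with Adam over mini-batches. When a validation split is
#' present the model from the epoch with the best validation target-gene
#' aPCC is kept.
#'
#' @param x list of raw [st_sample()] (with `split` given) or a prepared
#'   [prepare_dataset()] result.
#' @param split a [split_spec()] (ignored when `x` is already prepared).
#' @param mconfig a [model_config()]; `m`/`n_nontarget` are filled from the
#'   gene partition.
#' @param weights a [loss_weights()]. A positive spatial weight requires an
#'   annotation on every training spot.
#' @param config a [train_config()].
#' @param thresholds QC thresholds used when `x` is a raw sample list.
#' @param warm_start optional `sg_checkpoint` to initialize parameters from
#'   (its architecture and gene partition must match).
#' @return list with class `sg_checkpoint`: trained `model`, `partition`,
#'   `gene_names`, `channel_stats`, `weights`, `config`, per-epoch loss
#'   `history`, and the `split`.
#' @export
train_model <- function(x, split = NULL, mconfig = model_config(),
                        weights = loss_weights(), config = train_config(),
                        thresholds = qc_thresholds(), warm_start = NULL) {
  weights <- as_loss_weights(weights)
  dataset <- if (inherits(x, "sg_dataset")) x else
    prepare_dataset(x, split, thresholds, config)
  train_entries <- dataset_entries(dataset, "train")
  if (length(train_entries) == 0L) stop("empty training split")
  val_entries <- dataset_entries(dataset, "val")

  if (weights$gamma_spat > 0 &&
      any(vapply(train_entries, function(e) anyNA(e$labels), logical(1)))) {
    stop("a positive spatial weight requires annotations for all training spots")
  }
  has_tumor_labels <- !any(vapply(train_entries, function(e) anyNA(e$labels),
                                  logical(1)))
  if (weights$beta_tmr > 0 && !has_tumor_labels) {
    stop("a positive tumor weight requires annotations for all training spots")
  }

  part <- dataset$partition
  set.seed(config$seed)
  if (is.null(warm_start)) {
    mconfig$m <- part$m
    mconfig$n_nontarget <- length(part$nontarget_idx)
    train_expr <- do.call(rbind, lapply(train_entries, function(e) unclass(e$expr)))
    model <- spotgene_model(
      mconfig,
      target_bias = colMeans(train_expr[, part$target_idx, drop = FALSE]),
      nontarget_bias = colMeans(train_expr[, part$nontarget_idx, drop = FALSE]))
  } else {
    check_checkpoint_compat(warm_start, part)
    model <- warm_start$model
  }

  opt <- adam_state(model$params)
  step <- 0L
  history <- data.frame()
  best <- list(val = -Inf, params = model$params, epoch = 0L)
  stale <- 0L

  for (epoch in seq_len(config$epochs)) {
    comp_sum <- c(primary = 0, auxiliary = 0, tumor = 0, spatial = 0)
    n_batches <- 0L
    for (e in sample(train_entries)) {
      for (idx in make_batches(e, config, weights)) {
        a <- e$patches$patches[idx, , , , drop = FALSE]
        if (config$augment) a <- augment_batch(a)
        X <- patches_to_batch(a)
        fw <- nn_forward(model, X, dim(a)[2], keep_cache = TRUE)
        model <- fw$model
        g_t <- unclass(e$expr)[idx, part$target_idx, drop = FALSE]
        g_n <- unclass(e$expr)[idx, part$nontarget_idx, drop = FALSE]
        y <- e$labels[idx]

        comp <- list(primary = loss_primary(g_t, fw$g_hat_target),
                     auxiliary = loss_auxiliary(g_n, fw$g_hat_nontarget),
                     tumor = if (has_tumor_labels)
                       loss_tumor(y, fw$y_hat) else 0,
                     spatial = if (weights$gamma_spat > 0)
                       loss_spatial(fw$g_hat_target, y, e$graph,
                                    spot_index = idx,
                                    reduce = config$spatial_reduce) else 0)

        d_t <- t(grad_loss_mse(g_t, fw$g_hat_target))
        if (weights$gamma_spat > 0) {
          d_t <- d_t + weights$gamma_spat *
            t(grad_loss_spatial(fw$g_hat_target, y, e$graph, spot_index = idx,
                                reduce = config$spatial_reduce))
        }
        d_n <- weights$lambda_aux * t(grad_loss_mse(g_n, fw$g_hat_nontarget))
        d_s <- if (weights$beta_tmr > 0 && has_tumor_labels) {
          matrix(weights$beta_tmr * grad_loss_tumor_score(y, fw$y_hat),
                 nrow = 1L)
        } else matrix(0, 1L, length(idx))

        grads <- nn_backward(model, fw$cache, d_t, d_n, d_s)
        step <- step + 1L
        upd <- adam_step(model$params, grads, opt, config$lr, step)
        model$params <- upd$params
        opt <- upd$state
        comp_sum <- comp_sum + unlist(comp)
        n_batches <- n_batches + 1L
      }
    }
    comp_mean <- comp_sum / n_batches
    val_apcc <- NA_real_
    if (length(val_entries)) {
      val_apcc <- mean_target_apcc(model, val_entries, part)
      if (val_apcc > best$val) {
        best <- list(val = val_apcc, params = model$params, epoch = epoch)
        stale <- 0L
      } else stale <- stale + 1L
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss_primary = comp_mean[["primary"]],
      loss_auxiliary = comp_mean[["auxiliary"]],
      loss_tumor = comp_mean[["tumor"]],
      loss_spatial = comp_mean[["spatial"]],
      loss_total = loss_total(as.list(comp_mean), weights),
      val_apcc_target = val_apcc))
    if (stale >= config$early_stop_patience) break
  }

  if (length(val_entries) && config$select_best && best$epoch > 0L) {
    model$params <- best$params
  }
  structure(list(model = model, partition = part,
                 gene_names = dataset$gene_names,
                 channel_stats = dataset$channel_stats, weights = weights,
                 config = config, thresholds = dataset$thresholds,
                 split = dataset$split, history = history,
                 best_val_apcc = if (length(val_entries)) best$val else NA_real_),
            class = "sg_checkpoint")
}

check_checkpoint_compat <- function(ckpt, partition) {
  if (ckpt$partition$m != partition$m ||
      !identical(ckpt$partition$target_genes, partition$target_genes)) {
    stop("checkpoint is incompatible with this dataset: ",
         "gene partitions differ (m = ", ckpt$partition$m, " vs ",
         partition$m, ")")
  }
}

# forward a prepared entry in bounded chunks
forward_entry <- function(model, entry, chunk = 256L) {
  n <- nrow(entry$spots)
  out_t <- NULL; out_n <- NULL; out_y <- numeric(0)
  for (idx in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    a <- entry$patches$patches[idx, , , , drop = FALSE]
    fw <- nn_forward(model, patches_to_batch(a), dim(a)[2])
    out_t <- rbind(out_t, fw$g_hat_target)
    out_n <- rbind(out_n, fw$g_hat_nontarget)
    out_y <- c(out_y, fw$y_hat)
  }
  list(g_hat_target = out_t, g_hat_nontarget = out_n, y_hat = out_y)
}

mean_target_apcc <- function(model, entries, part) {
  g_true <- do.call(rbind, lapply(entries, function(e)
    unclass(e$expr)[, part$target_idx, drop = FALSE]))
  g_hat <- do.call(rbind, lapply(entries, function(e)
    forward_entry(model, e)$g_hat_target))
  mean(per_gene_pcc(g_true, g_hat, quiet = TRUE))
}

# ---------------------------------------------------------------------------
# metrics

#' Per-gene Pearson correlation
#'
#' Correlation across spots, one value per gene. Genes with zero variance in
#' either truth or prediction get 0 (and are reported via `message()`), so
#' averages keep a fixed denominator.
#'
#' @param g_true,g_hat N x m matrices (N >= 2).
#' @param quiet suppress the zero-variance message.
#' @return numeric m-vector in `[-1, 1]`.
#' @export
per_gene_pcc <- function(g_true, g_hat, quiet = FALSE) {
  g_true <- as.matrix(g_true); g_hat <- as.matrix(g_hat)
  stopifnot(identical(dim(g_true), dim(g_hat)))
  if (nrow(g_true) < 2L) stop("need at least 2 spots for a correlation")
  sd_t <- apply(g_true, 2L, sd)
  sd_h <- apply(g_hat, 2L, sd)
  flat <- sd_t == 0 | sd_h == 0
  out <- numeric(ncol(g_true))
  if (any(!flat)) {
    out[!flat] <- vapply(which(!flat), function(j) cor(g_true[, j], g_hat[, j]),
                         numeric(1))
  }
  if (any(flat) && !quiet) {
    message(sum(flat), " gene(s) with zero variance assigned PCC = 0")
  }
  out
}

#' Area under the ROC curve
#'
#' @param y binary labels; `p` predicted probabilities/scores.
#' @param p scores.
#' @return AUC, or NA (with a warning) when only one class is present.
#' @export
auc_score <- function(y, p) {
  if (length(unique(y)) < 2L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = p, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision: scores sorted decreasingly, AP = sum over positives of
#' precision at each positive's rank, divided by the number of positives.
#' Ties are handled by grouping tied scores into one threshold step and
#' using the interpolating precision of the whole group.
#'
#' @param y binary labels; `p` scores.
#' @return AUPRC, or NA (with a warning) when only one class is present.
#' @export
auprc_score <- function(y, p) {
  if (length(unique(y)) < 2L) {
    warning("AUPRC undefined: only one class present")
    return(NA_real_)
  }
  thr <- sort(unique(p), decreasing = TRUE)
  npos <- sum(y == 1)
  tp_prev <- 0; fp_prev <- 0; ap <- 0
  for (t in thr) {
    sel <- p >= t
    tp <- sum(y[sel] == 1); fp <- sum(y[sel] == 0)
    if (tp > tp_prev) {
      ap <- ap + (tp - tp_prev) / npos * tp / (tp + fp)
    }
    tp_prev <- tp; fp_prev <- fp
  }
  ap
}

metrics_from_predictions <- function(g_true_t, g_hat_t, g_true_n, g_hat_n,
                                     y, y_hat, acc_threshold = 0.5) {
  pcc_t <- per_gene_pcc(g_true_t, g_hat_t, quiet = TRUE)
  pcc_n <- if (!is.null(g_true_n) && ncol(g_true_n) > 0L) {
    per_gene_pcc(g_true_n, g_hat_n, quiet = TRUE)
  } else numeric(0)
  have_y <- !is.null(y) && !anyNA(y)
  structure(list(
    amse_target = mean((g_true_t - g_hat_t)^2),
    apcc_target = mean(pcc_t),
    amse_nontarget = if (length(pcc_n)) mean((g_true_n - g_hat_n)^2) else NA_real_,
    apcc_nontarget = if (length(pcc_n)) mean(pcc_n) else NA_real_,
    ngpc = sum(pcc_t > 0),
    ngpc_nontarget = if (length(pcc_n)) sum(pcc_n > 0) else NA_integer_,
    per_gene_pcc = pcc_t,
    per_gene_pcc_nontarget = pcc_n,
    acc = if (have_y) mean((y_hat >= acc_threshold) == (y == 1)) else NA_real_,
    auc = if (have_y) auc_score(y, y_hat) else NA_real_,
    auprc = if (have_y) auprc_score(y, y_hat) else NA_real_),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report>\n",
                     "  target genes:     aMSE %.4f  aPCC %.4f  NGPC %d\n",
                     "  non-target genes: aMSE %s  aPCC %s\n",
                     "  annotation:       ACC %s  AUC %s  AUPRC %s\n"),
              x$amse_target, x$apcc_target, x$ngpc,
              fmt_or_na(x$amse_nontarget), fmt_or_na(x$apcc_nontarget),
              fmt_or_na(x$acc), fmt_or_na(x$auc), fmt_or_na(x$auprc)))
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)

#' Evaluate a trained model
#'
#' Pools spots over the requested samples, runs the model, and reports aMSE
#' (mean squared error over spots and genes, same reduction as the training
#' losses), aPCC (mean per-gene Pearson correlation), NGPC (number of target
#' genes with positive correlation), and — when annotations are available —
#' ACC at threshold 0.5, AUC, and AUPRC of the tumor head.
#'
#' @param checkpoint an `sg_checkpoint` from [train_model()].
#' @param x a prepared [prepare_dataset()] result (evaluates the entries
#'   with the given `role`) or a list of raw [st_sample()] objects, which
#'   are preprocessed with the checkpoint's frozen gene set, channel
#'   statistics, and thresholds.
#' @param role which split entries to evaluate when `x` is a dataset.
#' @return an `eval_report` (see [metrics_from_predictions()] fields).
#' @export
evaluate_model <- function(checkpoint, x, role = "test") {
  entries <- if (inherits(x, "sg_dataset")) {
    dataset_entries(x, role)
  } else {
    lapply(x, function(s) prepare_eval_entry(checkpoint, s))
  }
  if (length(entries) == 0L) stop("no samples to evaluate")
  part <- checkpoint$partition
  g_true_t <- NULL; g_true_n <- NULL; g_hat_t <- NULL; g_hat_n <- NULL
  y <- numeric(0); y_hat <- numeric(0)
  for (e in entries) {
    fw <- forward_entry(checkpoint$model, e)
    g_true_t <- rbind(g_true_t, unclass(e$expr)[, part$target_idx, drop = FALSE])
    g_true_n <- rbind(g_true_n, unclass(e$expr)[, part$nontarget_idx, drop = FALSE])
    g_hat_t <- rbind(g_hat_t, fw$g_hat_target)
    g_hat_n <- rbind(g_hat_n, fw$g_hat_nontarget)
    y <- c(y, e$labels)
    y_hat <- c(y_hat, fw$y_hat)
  }
  rep <- metrics_from_predictions(g_true_t, g_hat_t, g_true_n, g_hat_n,
                                  if (anyNA(y)) NULL else y, y_hat)
  rep$n_spots <- nrow(g_true_t)
  rep$target_genes <- part$target_genes
  rep$nontarget_genes <- part$nontarget_genes
  rep
}

# preprocess one raw sample with a checkpoint's frozen statistics
prepare_eval_entry <- function(checkpoint, sample) {
  cfg <- checkpoint$config
  ex <- extract_patches(sample, cfg$window_px, cfg$out_size_px)
  keep <- qc_filter_spots(sample, checkpoint$thresholds,
                          boundary_mask = ex$boundary_mask)
  keep_ids <- names(keep)[keep]
  missing <- setdiff(checkpoint$gene_names, colnames(sample$expression))
  if (length(missing)) {
    stop("sample lacks gene(s) the model was trained on: ",
         paste(head(missing, 5L), collapse = ", "))
  }
  counts <- expression_matrix(
    sample$expression[keep_ids, checkpoint$gene_names, drop = FALSE],
    checkpoint$gene_names, keep_ids, "raw_counts")
  patches <- ex$patches
  sel <- match(keep_ids, patches$spot_ids)
  patches$patches <- patches$patches[sel, , , , drop = FALSE]
  patches$spot_ids <- keep_ids
  patches <- normalize_patches(patches, checkpoint$channel_stats$mean,
                               checkpoint$channel_stats$sd)
  spots <- sample$spots[match(keep_ids, sample$spots$spot_id), , drop = FALSE]
  class(spots) <- c("spot_table", "data.frame")
  list(sample_id = sample$sample_id, patient_id = sample$patient_id,
       role = "eval", spots = spots, counts = counts,
       expr = normalize_expression(counts, cfg$scale, cfg$pseudocount),
       patches = patches, labels = spots$annotation,
       graph = build_neighbor_graph(spots), latent = sample$latent)
}

#' Predict on a slide without expression data
#'
#' Inference path: given only an image and spot coordinates, extracts and
#' normalizes patches with the checkpoint's stored channel statistics and
#' returns predicted target genes, non-target genes, and tumor
#' probabilities for every spot whose patch window stays inside the slide.
#'
#' @param checkpoint an `sg_checkpoint`.
#' @param image image array or path.
#' @param spots a [spot_table()] (annotation may be NA).
#' @return list: `spot_ids`, `g_hat_target`, `g_hat_nontarget`, `y_hat`,
#'   `boundary_mask`.
#' @export
predict_sample <- function(checkpoint, image, spots) {
  cfg <- checkpoint$config
  dummy <- st_sample("predict", "predict", image, spots,
                     expression_matrix(matrix(0, nrow(spots), 1L,
                                              dimnames = list(spots$spot_id, "dummy")),
                                       layer = "raw_counts"))
  ex <- extract_patches(dummy, cfg$window_px, cfg$out_size_px)
  patches <- normalize_patches(ex$patches, checkpoint$channel_stats$mean,
                               checkpoint$channel_stats$sd)
  fw <- forward_entry(checkpoint$model,
                      list(spots = spots[match(patches$spot_ids, spots$spot_id), ],
                           patches = patches))
  list(spot_ids = patches$spot_ids, g_hat_target = fw$g_hat_target,
       g_hat_nontarget = fw$g_hat_nontarget, y_hat = fw$y_hat,
       boundary_mask = ex$boundary_mask,
       target_genes = checkpoint$partition$target_genes,
       nontarget_genes = checkpoint$partition$nontarget_genes)
}

# ---------------------------------------------------------------------------
# ablation and differential ranking

ABLATION_VARIANTS <- list(
  random        = NULL,                 # untrained
  prim          = c(0, 0, 0),
  w_aux         = c(1, 0, 0),
  w_tmr         = c(0, 1, 0),
  w_spat        = c(0, 0, 1),
  full_base     = c(1, 1, 0),
  full_spat     = c(1, 1, 1)
)

#' Run the loss-component ablation
#'
#' Trains and evaluates one model per variant: `random` (initialized, never
#' trained), `prim` (primary loss only), `w_aux`, `w_tmr`, `w_spat` (one
#' auxiliary term each), `full_base` (auxiliary + tumor), and `full_spat`
#' (all terms). Non-zero weights are taken from `base_weights`.
#'
#' @param samples list of raw [st_sample()].
#' @param split a [split_spec()].
#' @param config a [train_config()]; `config$seed` is offset by each seed.
#' @param base_weights a [loss_weights()] giving the magnitudes used when a
#'   term is switched on.
#' @param seeds integer vector; each variant is run once per seed.
#' @param thresholds QC thresholds.
#' @param variants subset of variant names to run.
#' @param out_tsv optional path; the table is also written as TSV.
#' @return data.frame with one row per (variant, seed) and the evaluation
#'   metrics on the test split.
#' @export
run_ablation <- function(samples, split, config = train_config(),
                         base_weights = loss_weights(1, 1, 1), seeds = 1L,
                         thresholds = qc_thresholds(),
                         variants = names(ABLATION_VARIANTS),
                         out_tsv = NULL) {
  variants <- match.arg(variants, names(ABLATION_VARIANTS), several.ok = TRUE)
  dataset <- prepare_dataset(samples, split, thresholds, config)
  rows <- list()
  for (seed in seeds) {
    cfg <- config
    cfg$seed <- as.integer(config$seed + seed - 1L)
    for (v in variants) {
      toggles <- ABLATION_VARIANTS[[v]]
      if (is.null(toggles)) {
        set.seed(cfg$seed)
        part <- dataset$partition
        mcfg <- model_config()
        mcfg$m <- part$m
        mcfg$n_nontarget <- length(part$nontarget_idx)
        ckpt <- structure(list(model = spotgene_model(mcfg), partition = part,
                               gene_names = dataset$gene_names,
                               channel_stats = dataset$channel_stats,
                               weights = loss_weights(0, 0, 0), config = cfg,
                               thresholds = dataset$thresholds,
                               split = dataset$split,
                               history = data.frame()),
                          class = "sg_checkpoint")
      } else {
        w <- loss_weights(toggles[1] * base_weights$lambda_aux,
                          toggles[2] * base_weights$beta_tmr,
                          toggles[3] * base_weights$gamma_spat)
        ckpt <- train_model(dataset, weights = w, config = cfg)
      }
      rep <- evaluate_model(ckpt, dataset, role = "test")
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, seed = cfg$seed,
        amse_target = rep$amse_target, apcc_target = rep$apcc_target,
        amse_nontarget = rep$amse_nontarget,
        apcc_nontarget = rep$apcc_nontarget, ngpc = rep$ngpc,
        acc = rep$acc, auc = rep$auc, auprc = rep$auprc)
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(out_tsv)) write_tsv_full(tab, out_tsv)
  tab
}

#' Rank genes by tumor-vs-normal mean expression difference
#'
#' For each gene, computes the mean expression in tumor spots and in normal
#' spots; genes are ranked by the absolute difference (descending, ties
#' broken by gene name) and the top k are returned with signed differences.
#'
#' @param expr normalized N x m [expression_matrix()] (columns named).
#' @param annotations N binary labels (both classes must be present).
#' @param k number of genes to return.
#' @return data.frame: `gene`, `mean_tumor`, `mean_normal`, `difference`
#'   (tumor minus normal), `abs_difference`, ordered by rank.
#' @export
differential_gene_ranking <- function(expr, annotations, k = 5L) {
  expr <- as.matrix(expr)
  stopifnot(nrow(expr) == length(annotations))
  if (!all(annotations %in% c(0, 1))) stop("annotations must be binary")
  if (length(unique(annotations)) < 2L) {
    stop("both tumor and normal spots are required")
  }
  mu_t <- colMeans(expr[annotations == 1, , drop = FALSE])
  mu_n <- colMeans(expr[annotations == 0, , drop = FALSE])
  d <- mu_t - mu_n
  ord <- order(-abs(d), colnames(expr), method = "radix")
  top <- ord[seq_len(min(k, ncol(expr)))]
  data.frame(gene = colnames(expr)[top], mean_tumor = unname(mu_t[top]),
             mean_normal = unname(mu_n[top]), difference = unname(d[top]),
             abs_difference = unname(abs(d[top])))
}

# ---------------------------------------------------------------------------
# checkpoint persistence

#' Save / load a model checkpoint
#'
#' The checkpoint (weights, model config, gene partition, image channel
#' statistics, loss weights, history) is stored with `saveRDS`; a JSON
#' sidecar (`<path>.json`) mirrors all non-weight metadata.
#'
#' @param checkpoint an `sg_checkpoint`.
#' @param path destination `.rds` path.
#' @return `path` (`save_checkpoint`) / the checkpoint (`load_checkpoint`).
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  meta <- list(
    backbone = checkpoint$model$config$backbone,
    m = checkpoint$partition$m,
    n_nontarget = length(checkpoint$partition$nontarget_idx),
    target_genes = checkpoint$partition$target_genes,
    channel_mean = checkpoint$channel_stats$mean,
    channel_sd = checkpoint$channel_stats$sd,
    loss_weights = unclass(checkpoint$weights),
    train_config = unclass(checkpoint$config),
    best_val_apcc = checkpoint$best_val_apcc)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
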