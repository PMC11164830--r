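test_that("per-gene correlation matches a textbook Pearson brute force", {
  set.seed(10)
  g <- matrix(rnorm(40), 10, 4)
  h <- matrix(rnorm(40), 10, 4)
  pcc <- per_gene_pcc(g, h)
  for (j in 1:4) expect_equal(pcc[j], bf_pearson(g[, j], h[, j]),
                              tolerance = 1e-12)
  expect_equal(per_gene_pcc(g, g), rep(1, 4))
  expect_equal(per_gene_pcc(g, -g + 3), rep(-1, 4))
  expect_error(per_gene_pcc(g[1, , drop = FALSE], h[1, , drop = FALSE]),
               "2 spots")
})

test_that("zero-variance genes are assigned correlation 0", {
  g <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  h <- cbind(a = c(0, 1, 2), b = c(2, 2, 2))
  expect_message(pcc <- per_gene_pcc(g, h), "zero variance")
  expect_identical(pcc, c(0, 0))
})

test_that("AUPRC matches a brute-force threshold enumeration", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(6:30, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y <- c(0, 1, y[-(1:2)])
    p <- round(runif(n), 2)  # rounded scores exercise tie handling
    expect_equal(auprc_score(y, p), bf_auprc(y, p), tolerance = 1e-12)
  }
  expect_equal(auprc_score(c(0, 1), c(0.1, 0.9)), 1)
  expect_warning(v <- auprc_score(c(1, 1), c(0.2, 0.8)), "one class")
  expect_true(is.na(v))
  expect_warning(a <- auc_score(c(0, 0), c(0.2, 0.8)), "one class")
  expect_true(is.na(a))
})

test_that("a perfect predictor attains the ideal metric vector", {
  set.seed(14)
  m <- 6
  g <- matrix(rnorm(20 * m), 20, m)
  gn <- matrix(rnorm(20 * 3), 20, 3)
  y <- rbinom(20, 1, 0.5); y[1:2] <- c(0, 1)
  rep <- spotgene:::metrics_from_predictions(g, g, gn, gn, y, y)
  expect_equal(rep$amse_target, 0)
  expect_equal(rep$apcc_target, 1)
  expect_equal(rep$ngpc, m)
  expect_equal(rep$acc, 1)
  expect_equal(rep$auc, 1)
  expect_equal(rep$auprc, 1)
  expect_equal(rep$ngpc, sum(rep$per_gene_pcc > 0))  # recount
})

test_that("label-shuffled scores give chance-level AUC", {
  set.seed(15)
  y <- rbinom(400, 1, 0.5)
  p <- runif(400)  # independent of y
  expect_lt(abs(auc_score(y, p) - 0.5), 0.1)
})

test_that("differential ranking orders genes by |tumor - normal| difference", {
  ann <- c(1, 1, 0, 0)
  expr <- cbind(big = c(5, 5, 1, 1),      # diff +4
                small = c(3, 3, 2, 2),    # diff +1
                down = c(1, 1, 3.5, 3.5)) # diff -2.5
  r <- differential_gene_ranking(expr, ann, k = 3)
  expect_identical(r$gene, c("big", "down", "small"))
  expect_equal(r$difference, c(4, -2.5, 1))
  expect_error(differential_gene_ranking(expr, c(1, 1, 1, 1)), "both")
  # ties broken lexicographically
  tied <- cbind(zb = c(2, 2, 1, 1), za = c(3, 3, 2, 2))
  expect_identical(differential_gene_ranking(tied, ann, k = 2)$gene,
                   c("za", "zb"))
})

test_that("differential ranking matches a brute-force sort on random data", {
  set.seed(16)
  expr <- matrix(rnorm(30 * 20), 30, 20,
                 dimnames = list(NULL, sprintf("g%02d", 1:20)))
  ann <- rep(c(1, 0), 15)
  r <- differential_gene_ranking(expr, ann, k = 20)
  d <- colMeans(expr[ann == 1, ]) - colMeans(expr[ann == 0, ])
  oracle <- names(sort(-abs(d)))
  expect_identical(r$gene, oracle)
  expect_equal(r$abs_difference, unname(abs(d)[oracle]))
})

test_that("split construction enforces patient disjointness", {
  expect_error(split_spec("A", "A", "B"), "more than one")
  sp <- random_patient_split(c("A", "B", "C", "D"), seed = 3)
  expect_length(sp$train_patients, 2)
  expect_length(intersect(sp$train_patients,
                          c(sp$val_patients, sp$test_patients)), 0)
  expect_error(random_patient_split(c("A", "B"), n_val = 1, n_test = 1),
               "at least 3")
})

cohort_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ch <- small_cohort(seed = 55, n_patients = 3, sections = 1)
      split <- split_spec("P1", "P2", "P3")
      ds <- prepare_dataset(ch$samples, split, sim_thresholds(),
                            sim_train_config())
      cache <<- list(ch = ch, split = split, ds = ds)
    }
    cache
  }
})

abind_arrays <- function(arrs) {
  n <- vapply(arrs, function(a) dim(a)[1], integer(1))
  out <- array(0, c(sum(n), dim(arrs[[1]])[-1]))
  at <- 0
  for (a in arrs) { out[at + seq_len(dim(a)[1]), , , ] <- a; at <- at + dim(a)[1] }
  out
}

test_that("dataset statistics come from the training split only", {
  fx <- cohort_fixture()
  ds <- fx$ds
  train_entries <- Filter(function(e) e$role == "train", ds$entries)
  raw <- lapply(fx$ch$samples, function(s) {
    if (s$patient_id != "P1") return(NULL)
    ex <- extract_patches(s, 16, 16)
    keep <- qc_filter_spots(s, sim_thresholds(), ex$boundary_mask)
    ex$patches$patches[match(names(keep)[keep], ex$patches$spot_ids), , , ,
                       drop = FALSE] / 255
  })
  raw <- raw[!vapply(raw, is.null, logical(1))]
  pix <- abind_arrays(raw)
  for (ch in 1:3) {
    expect_equal(ds$channel_stats$mean[ch], mean(pix[, , , ch]),
                 tolerance = 1e-12)
  }
  # partition ranked on training spots only: recompute from train entries
  train_norm <- do.call(rbind, lapply(train_entries, function(e) unclass(e$expr)))
  oracle <- colnames(train_norm)[order(-colMeans(train_norm),
                                       colnames(train_norm))][1:ds$partition$m]
  expect_setequal(ds$partition$target_genes, oracle)
})

test_that("training produces a full history and supports warm start", {
  fx <- cohort_fixture()
  tc <- sim_train_config(epochs = 5, seed = 2)
  ck <- train_model(fx$ds, weights = loss_weights(1, 1, 1), config = tc)
  expect_equal(nrow(ck$history), 5)
  expect_true(all(c("loss_primary", "loss_auxiliary", "loss_tumor",
                    "loss_spatial") %in% names(ck$history)))
  expect_true(all(ck$history$loss_spatial >= 0))
  # warm start with 0 epochs evaluates identically to the checkpoint
  tc0 <- sim_train_config(epochs = 0, seed = 2)
  ck0 <- train_model(fx$ds, weights = loss_weights(1, 1, 1), config = tc0,
                     warm_start = ck)
  r1 <- evaluate_model(ck, fx$ds, role = "test")
  r0 <- evaluate_model(ck0, fx$ds, role = "test")
  expect_identical(r1$amse_target, r0$amse_target)
  expect_identical(r1$per_gene_pcc, r0$per_gene_pcc)
})

test_that("missing annotations are rejected when the spatial term is on", {
  fx <- cohort_fixture()
  samples <- fx$ch$samples
  samples[[1]]$spots$annotation[5] <- NA
  expect_error(train_model(samples, fx$split, weights = loss_weights(1, 1, 1),
                           config = sim_train_config(epochs = 1),
                           thresholds = sim_thresholds()),
               "annotations")
})

test_that("the total training loss decreases when overfitting one batch", {
  fx <- cohort_fixture()
  # restrict to a slice of the training sample so one batch covers it
  sm <- fx$ch$samples[[1]]
  keep <- which(sm$spots$array_row <= 3)
  sm$spots <- sm$spots[keep, ]
  class(sm$spots) <- c("spot_table", "data.frame")
  sm$expression <- sm$expression[keep, , drop = FALSE]
  attr(sm$expression, "layer") <- "raw_counts"
  tc <- sim_train_config(epochs = 12, seed = 3)
  ck <- train_model(list(sm), split_spec("P1"), weights = loss_weights(0, 0, 0),
                    config = tc, thresholds = sim_thresholds())
  expect_lt(ck$history$loss_total[12], ck$history$loss_total[1])
})

test_that("checkpoints round-trip and reject incompatible warm starts", {
  fx <- cohort_fixture()
  tc <- sim_train_config(epochs = 1, seed = 4)
  ck <- train_model(fx$ds, weights = loss_weights(0, 0, 0), config = tc)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_checkpoint(path)
  expect_identical(back$model$params, ck$model$params)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$m, ck$partition$m)
  # incompatible m
  tc2 <- sim_train_config(epochs = 1, m = 3, seed = 4)
  ds2 <- prepare_dataset(fx$ch$samples, fx$split, sim_thresholds(), tc2)
  expect_error(train_model(ds2, config = tc2, warm_start = ck),
               "incompatible")
})

test_that("evaluation of raw held-out samples uses frozen statistics", {
  fx <- cohort_fixture()
  tc <- sim_train_config(epochs = 2, seed = 6)
  ck <- train_model(fx$ds, weights = loss_weights(1, 1, 0), config = tc)
  test_samples <- Filter(function(s) s$patient_id == "P3", fx$ch$samples)
  r_raw <- evaluate_model(ck, test_samples)
  r_ds <- evaluate_model(ck, fx$ds, role = "test")
  expect_equal(r_raw$amse_target, r_ds$amse_target, tolerance = 1e-10)
  expect_equal(r_raw$auc, r_ds$auc, tolerance = 1e-10)
})

test_that("the ablation runner produces one row per variant and seed", {
  fx <- cohort_fixture()
  tc <- sim_train_config(epochs = 1, seed = 9)
  tab <- run_ablation(fx$ch$samples, fx$split, config = tc,
                      thresholds = sim_thresholds(),
                      variants = c("random", "prim", "full_spat"))
  expect_equal(nrow(tab), 3)
  expect_setequal(tab$variant, c("random", "prim", "full_spat"))
  expect_true(all(is.finite(tab$amse_target)))
})
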