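# Fixture builders and independent brute-force oracles shared by the tests.
# Everything is generated in code; no binary fixtures.

# deterministic image whose pixel values encode position, so crop geometry
# can be checked exactly: value = (row0 * 7 + col0 * 3 + channel) mod 256
coord_image <- function(H, W) {
  img <- array(0, c(H, W, 3L))
  for (ch in 1:3) {
    img[, , ch] <- outer(0:(H - 1L), 0:(W - 1L),
                         function(r, c) (r * 7 + c * 3 + ch) %% 256)
  }
  img
}

# small hand-built sample: spots on a grid, coordinate-encoded image
tiny_sample <- function(n_row = 2L, n_col = 2L, n_genes = 6L, img_side = 300L,
                        spacing = 60L, offset = 80L, annotation = NULL,
                        counts = NULL, sample_id = "tiny", patient_id = "pt1") {
  grid <- expand.grid(array_row = seq_len(n_row), array_col = seq_len(n_col))
  n <- nrow(grid)
  ids <- sprintf("%s_s%d", sample_id, seq_len(n))
  if (is.null(annotation)) annotation <- rep_len(c(1L, 0L), n)
  spots <- data.frame(spot_id = ids,
                      pixel_x = offset + (grid$array_col - 1L) * spacing,
                      pixel_y = offset + (grid$array_row - 1L) * spacing,
                      array_row = grid$array_row, array_col = grid$array_col,
                      annotation = annotation)
  if (is.null(counts)) {
    counts <- matrix(seq_len(n * n_genes) %% 7L, n, n_genes)
  }
  genes <- sprintf("G%02d", seq_len(n_genes))
  st_sample(sample_id, patient_id, coord_image(img_side, img_side),
            spot_table(spots),
            expression_matrix(counts, genes, ids, "raw_counts"))
}

# write a sample as the TSV trio read_st_sample() expects; returns the paths
write_sample_files <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, "image.png")
  img <- spotgene::load_image(sample$image) / 255
  EBImage::writeImage(EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color"),
                      img_path, type = "png", bits.per.sample = 8L)
  spots_path <- file.path(dir, "spots.tsv")
  write.table(as.data.frame(sample$spots), spots_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  counts_path <- file.path(dir, "counts.tsv")
  df <- data.frame(spot_id = rownames(sample$expression), sample$expression,
                   check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(image = img_path, spots = spots_path, counts = counts_path)
}

# ---------------------------------------------------------------------------
# explicit-loop loss oracles (independent of the vectorized implementations)

bf_mse_loss <- function(g, ghat) {
  s <- 0
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
    s <- s + (g[i, j] - ghat[i, j])^2
  }
  s / (nrow(g) * ncol(g))
}

bf_xent_loss <- function(y, p, eps = 1e-7) {
  s <- 0
  for (i in seq_along(y)) {
    pi <- min(max(p[i], eps), 1 - eps)
    s <- s - (y[i] * log(pi) + (1 - y[i]) * log(1 - pi))
  }
  s / length(y)
}

# spatial loss by explicit scan over ordered (central, neighbor) pairs with
# equal labels; rows/cols give each batch row's grid position
bf_spatial_loss <- function(preds, labels, rows, cols, reduce = "mean") {
  B <- nrow(preds); K <- 0L; s <- 0
  for (i in seq_len(B)) for (j in seq_len(B)) {
    if (i == j) next
    if (abs(rows[i] - rows[j]) <= 1 && abs(cols[i] - cols[j]) <= 1 &&
        labels[i] == labels[j]) {
      K <- K + 1L
      d2 <- (preds[i, ] - preds[j, ])^2
      s <- s + if (reduce == "mean") mean(d2) else sum(d2)
    }
  }
  if (K == 0L) 0 else s / K
}

bf_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# neighbor lists by brute-force pairwise scan
bf_neighbors <- function(rows, cols) {
  n <- length(rows)
  lapply(seq_len(n), function(i) {
    out <- integer(0)
    for (j in seq_len(n)) {
      if (i != j && abs(rows[i] - rows[j]) <= 1 && abs(cols[i] - cols[j]) <= 1) {
        out <- c(out, j)
      }
    }
    out
  })
}

# average precision by explicit per-threshold precision/recall enumeration
bf_auprc <- function(y, p) {
  ths <- sort(unique(p), decreasing = TRUE)
  npos <- sum(y == 1)
  prev_rec <- 0; ap <- 0
  for (t in ths) {
    tp <- sum(y == 1 & p >= t); fp <- sum(y == 0 & p >= t)
    rec <- tp / npos; prec <- tp / (tp + fp)
    if (rec > prev_rec) ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# ---------------------------------------------------------------------------
# QC fixture: 10 x 10 grid of spots with planted spot- and gene-level
# violations of the default thresholds (200/20000 UMIs, 5% mito, 200
# detected genes, 3 spots per gene)

qc_fixture <- function() {
  n_spots <- 100L
  n_genes <- 250L
  genes <- c("MT-CO1", sprintf("G%03d", seq_len(n_genes - 1L)))
  counts <- matrix(0L, n_spots, n_genes)
  # baseline spots: genes 2..241 with count 2, genes 246..250 with count 1
  # -> 245 detected, 485 UMIs, 0% mito (column 1 is the mitochondrial gene)
  counts[, 2:241] <- 2L
  counts[, 246:250] <- 1L
  # keep the mitochondrial gene and column 242 detected in a few clean spots
  counts[20:23, 1] <- 1L                                 # mito ~ 1/486 ~ 0.2%
  counts[13:15, 242] <- 1L
  # gene-level plants on otherwise-zero columns:
  counts[10:12, 243] <- 1L                               # detected in 3 spots
  counts[10:11, 244] <- 1L                               # detected in 2 spots
  # column 245 stays all-zero
  # planted spot violations (rows reset first) and a boundary spot (5):
  counts[1, ] <- 0L; counts[1, 2:151] <- 1L              # 150 UMIs (< 200)
  counts[2, ] <- 0L; counts[2, 2:201] <- 100L            # 200 genes x 100
  counts[2, 202] <- 1L                                   # -> 20001 (> 20000)
  counts[3, 1] <- 30L                                    # mito 30/515 ~ 5.8%
  counts[4, ] <- 0L; counts[4, 2:200] <- 3L              # 199 genes (< 200)
  counts[5, ] <- 0L; counts[5, 2:201] <- 1L              # exactly 200 UMIs,
                                                         # 200 genes, 0% mito
  grid <- expand.grid(array_row = 1:10, array_col = 1:10)
  ids <- sprintf("qc_s%03d", seq_len(n_spots))
  spots <- spot_table(data.frame(
    spot_id = ids, pixel_x = 40 + 20 * (grid$array_col - 1L),
    pixel_y = 40 + 20 * (grid$array_row - 1L),
    array_row = grid$array_row, array_col = grid$array_col,
    annotation = rep_len(c(0L, 1L), n_spots)))
  sample <- st_sample("qcfix", "qcpt", array(128, c(260, 260, 3L)), spots,
                      expression_matrix(counts, genes, ids, "raw_counts"))
  list(sample = sample,
       bad_spots = ids[1:4],
       boundary_pass_spot = ids[5],
       genes_excluded = c(genes[244], genes[245]),
       gene_detected_3 = genes[243])
}

# small simulated cohort for pipeline-level tests (8x8 grids, 16px patches)
small_cohort <- function(seed = 11L, n_patients = 3L, sections = 1L) {
  cfg <- sim_config(n_rows = 8L, n_cols = 8L, patch_px = 16L, n_genes = 20L,
                    n_coupled = 6L, tumor_blob_count = 2L,
                    tumor_blob_radius = 2.5, seed = seed)
  list(config = cfg,
       samples = simulate_cohort(cfg, n_patients = n_patients,
                                 sections_per_patient = sections))
}

# QC thresholds scaled to the simulator's small gene panels
sim_thresholds <- function() {
  qc_thresholds(min_umi = 50L, max_umi = 50000L, min_genes_per_spot = 5L,
                min_spots_per_gene = 3L)
}

sim_train_config <- function(m = 6L, ...) {
  train_config(window_px = 16L, out_size_px = 16L, m = m, batch_size = 32L,
               ...)
}
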