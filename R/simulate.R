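# Synthetic paired histology / spatial-transcriptomics generator.
#
# The generator emulates the statistical structure the model assumes, not
# tissue realism: grid-arranged spots, spatially clustered (blob-shaped)
# tumor annotations, patch morphology coupled to the tumor state and to a
# continuous per-spot intensity covariate, and overdispersed
# negative-binomial counts with dropout.

#' Simulator configuration
#'
#' @param n_rows,n_cols spot grid dimensions.
#' @param patch_px patch window side in pixels; spots are spaced exactly
#'   `patch_px` apart so patches are disjoint, with a margin so no default
#'   window exits the slide.
#' @param n_genes total number of genes.
#' @param n_coupled number of genes whose negative-binomial mean depends on
#'   the latent tumor/normal state (the rest are decoys with one shared
#'   mean).
#' @param tumor_blob_count,tumor_blob_radius number and radius (grid units)
#'   of the disc-shaped tumor regions whose union defines the annotation.
#' @param nb_mean_normal,nb_mean_tumor negative-binomial means of coupled
#'   genes in normal / tumor spots; scalars or length-`n_coupled` vectors.
#'   Decoy genes use `nb_mean_normal[1]`.
#' @param coupling_direction per-coupled-gene +1 (up in tumor) or -1 (means
#'   swapped). Default alternates so that half the coupled genes are up and
#'   half down in tumor, keeping per-spot library size balanced across
#'   states (a single direction would couple library size — and through
#'   total-count normalization every decoy gene — to the tumor state).
#' @param nb_dispersion negative-binomial size parameter (variance
#'   `mu + mu^2 / size`; larger = closer to Poisson).
#' @param image_signal_strength 0..1 gain on every image-expression
#'   coupling: at 0 the patch pixel distribution is independent of the
#'   latent state and of the intensity covariate.
#' @param intensity_effect log-fold change on odd-indexed coupled genes per
#'   unit of the per-spot continuous intensity covariate.
#' @param dropout_rate probability that a drawn count is zeroed.
#' @param seed RNG seed; the whole sample is deterministic given the config.
#' @return list with class `sim_config`.
#' @export
sim_config <- function(n_rows = 16L, n_cols = 16L, patch_px = 32L,
                       n_genes = 50L, n_coupled = 10L, tumor_blob_count = 3L,
                       tumor_blob_radius = 3.5, nb_mean_normal = 5,
                       nb_mean_tumor = 15, coupling_direction = NULL,
                       nb_dispersion = 2, image_signal_strength = 0.8,
                       intensity_effect = 0.5, dropout_rate = 0.02,
                       seed = 1L) {
  stopifnot(n_coupled <= n_genes, nb_dispersion > 0,
            all(nb_mean_normal > 0), all(nb_mean_tumor > 0),
            image_signal_strength >= 0, image_signal_strength <= 1,
            dropout_rate >= 0, dropout_rate < 1)
  if (is.null(coupling_direction)) {
    coupling_direction <- rep_len(c(1, -1), n_coupled)
  }
  stopifnot(length(coupling_direction) == n_coupled,
            all(coupling_direction %in% c(-1, 1)))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 patch_px = as.integer(patch_px), n_genes = as.integer(n_genes),
                 n_coupled = as.integer(n_coupled),
                 tumor_blob_count = as.integer(tumor_blob_count),
                 tumor_blob_radius = tumor_blob_radius,
                 nb_mean_normal = nb_mean_normal,
                 nb_mean_tumor = nb_mean_tumor,
                 coupling_direction = coupling_direction,
                 nb_dispersion = nb_dispersion,
                 image_signal_strength = image_signal_strength,
                 intensity_effect = intensity_effect,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "sim_config")
}

sim_gene_names <- function(config) {
  c(sprintf("CPL%03d", seq_len(config$n_coupled)),
    sprintf("DCY%03d", seq_len(config$n_genes - config$n_coupled)))
}

# per-gene NB mean matrix (2 x n_genes: rows normal/tumor)
sim_mean_table <- function(config) {
  mu_n <- rep_len(config$nb_mean_normal, config$n_coupled)
  mu_t <- rep_len(config$nb_mean_tumor, config$n_coupled)
  swap <- config$coupling_direction < 0
  tmp <- mu_n[swap]; mu_n[swap] <- mu_t[swap]; mu_t[swap] <- tmp
  decoy <- rep(config$nb_mean_normal[1], config$n_genes - config$n_coupled)
  rbind(normal = c(mu_n, decoy), tumor = c(mu_t, decoy))
}

#' Simulate one paired histology / expression sample
#'
#' Generates (1) an `n_rows` x `n_cols` spot grid with disjoint patches,
#' (2) a spatially clustered binary annotation from a union of disc-shaped
#' tumor blobs, (3) a rendered slide whose per-patch mean intensity and
#' noise scale shift with the tumor state and a continuous per-spot
#' covariate (both scaled by `image_signal_strength`), and (4)
#' negative-binomial counts whose means depend on the state for coupled
#' genes, with dropout. The ground-truth latent table (state + covariate)
#' is attached as `$latent`.
#'
#' @param config a [sim_config()].
#' @param sample_id,patient_id identifiers.
#' @param gene_mean_factor optional per-gene multiplicative effect (used by
#'   [simulate_cohort()] for patient-level batch effects).
#' @param reseed set the RNG to `config$seed` first (default TRUE; the
#'   cohort generator seeds once and disables this).
#' @return an [st_sample()] with raw counts and in-memory image.
#' @export
simulate_sample <- function(config = sim_config(), sample_id = "sim1",
                            patient_id = "patient1", gene_mean_factor = NULL,
                            reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (reseed) set.seed(config$seed)
  p <- config$patch_px
  nr <- config$n_rows; nc <- config$n_cols
  if (config$tumor_blob_radius > max(nr, nc)) {
    stop("grid too small for the requested tumor blobs")
  }
  grid <- expand.grid(array_row = seq_len(nr), array_col = seq_len(nc))
  n <- nrow(grid)
  # centers at multiples of patch_px; windows [c - p/2, c + p/2) are disjoint
  # and stay inside the (p * (nr + 1)) x (p * (nc + 1)) slide
  pixel_y <- p * grid$array_row
  pixel_x <- p * grid$array_col

  centers <- cbind(runif(config$tumor_blob_count, 1, nr),
                   runif(config$tumor_blob_count, 1, nc))
  tumor <- rep(FALSE, n)
  for (b in seq_len(config$tumor_blob_count)) {
    d2 <- (grid$array_row - centers[b, 1])^2 + (grid$array_col - centers[b, 2])^2
    tumor <- tumor | d2 <= config$tumor_blob_radius^2
  }
  z <- rnorm(n)   # continuous intensity covariate

  img <- render_slide(config, grid, pixel_x, pixel_y, tumor, z)
  counts <- draw_counts(config, tumor, z, gene_mean_factor)
  spot_ids <- sprintf("%s_r%02dc%02d", sample_id, grid$array_row, grid$array_col)
  rownames(counts) <- spot_ids

  spots <- spot_table(data.frame(
    spot_id = spot_ids, pixel_x = pixel_x, pixel_y = pixel_y,
    array_row = grid$array_row, array_col = grid$array_col,
    annotation = as.integer(tumor)))
  latent <- data.frame(spot_id = spot_ids, tumor_state = as.integer(tumor),
                       intensity = z)
  st_sample(sample_id, patient_id, img, spots,
            expression_matrix(counts, sim_gene_names(config), spot_ids,
                              "raw_counts"),
            latent = latent)
}

# H&E-like rendering: pinkish background noise; tumor patches darker and
# grainier; the covariate shifts patch brightness
render_slide <- function(config, grid, pixel_x, pixel_y, tumor, z) {
  p <- config$patch_px
  H <- p * (config$n_rows + 1L); W <- p * (config$n_cols + 1L)
  base <- c(225, 195, 215)   # background RGB
  s <- config$image_signal_strength
  img <- array(0, c(H, W, 3L))
  for (ch in 1:3) {
    img[, , ch] <- base[ch] + matrix(rnorm(H * W, sd = 8), H, W)
  }
  tumor_shift <- c(-50, -65, -35) * s   # toward hematoxylin purple
  half <- p %/% 2L
  for (i in seq_len(nrow(grid))) {
    rows <- (pixel_y[i] - half + 1L):(pixel_y[i] - half + p)
    cols <- (pixel_x[i] - half + 1L):(pixel_x[i] - half + p)
    noise_sd <- 8 * (1 + 0.6 * s * tumor[i])
    for (ch in 1:3) {
      shift <- tumor[i] * tumor_shift[ch] + 15 * s * z[i]
      img[rows, cols, ch] <- base[ch] + shift +
        matrix(rnorm(p * p, sd = noise_sd), p, p)
    }
  }
  pmax(pmin(round(img), 255), 0)
}

draw_counts <- function(config, tumor, z, gene_mean_factor = NULL) {
  n <- length(tumor)
  means <- sim_mean_table(config)
  mu <- means[tumor + 1L, , drop = FALSE]   # n x n_genes
  # the covariate modulates odd-indexed coupled genes
  mod <- seq_len(config$n_coupled)[seq_len(config$n_coupled) %% 2L == 1L]
  if (length(mod)) {
    mu[, mod] <- mu[, mod] * exp(config$intensity_effect * z)
  }
  if (!is.null(gene_mean_factor)) {
    stopifnot(length(gene_mean_factor) == config$n_genes)
    mu <- sweep(mu, 2L, gene_mean_factor, `*`)
  }
  counts <- matrix(rnbinom(n * config$n_genes, mu = as.vector(mu),
                           size = config$nb_dispersion),
                   n, config$n_genes)
  if (config$dropout_rate > 0) {
    counts[matrix(runif(length(counts)) < config$dropout_rate,
                  n, config$n_genes)] <- 0L
  }
  colnames(counts) <- sim_gene_names(config)
  counts
}

#' Simulate a multi-patient cohort
#'
#' Each patient receives a lognormal per-gene random effect on the
#' negative-binomial means (a simple patient-level batch effect); all
#' sections of a patient share the effect, and every section gets its own
#' blob layout, image, and counts.
#'
#' @param config a [sim_config()]; `config$seed` seeds the whole cohort.
#' @param n_patients number of patients (>= 3 recommended so
#'   train/validation/test splits are possible).
#' @param sections_per_patient tissue sections per patient.
#' @param patient_effect_sd standard deviation of the per-patient log-normal
#'   gene effect (0 = identical patients).
#' @return list of [st_sample()]; `sample_id` is `P<i>_S<j>` and
#'   `patient_id` is `P<i>`.
#' @export
simulate_cohort <- function(config = sim_config(), n_patients = 3L,
                            sections_per_patient = 2L,
                            patient_effect_sd = 0.15) {
  set.seed(config$seed)
  samples <- list()
  for (pt in seq_len(n_patients)) {
    effect <- exp(rnorm(config$n_genes, sd = patient_effect_sd))
    for (sec in seq_len(sections_per_patient)) {
      samples[[length(samples) + 1L]] <- simulate_sample(
        config, sample_id = sprintf("P%d_S%d", pt, sec),
        patient_id = sprintf("P%d", pt), gene_mean_factor = effect,
        reseed = FALSE)
    }
  }
  samples
}
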