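# Data model and I/O for paired histology / spatial-expression samples.
#
# Conventions used throughout:
#   * pixel coordinates are 0-based, x = column, y = row;
#   * images are numeric H x W x 3 arrays on the 0..255 (8-bit) scale;
#   * a crop of width w centred at c covers the half-open pixel interval
#     [c - floor(w/2), c - floor(w/2) + w).

SPOT_COLUMNS <- c("spot_id", "pixel_x", "pixel_y", "array_row", "array_col",
                  "annotation")

#' Validate and construct a spot table
#'
#' A spot table holds, per capture spot: an identifier, the patch-centre
#' pixel coordinates on the slide (0-based, x = column, y = row), the integer
#' grid (array) coordinates, and an optional binary pathological annotation
#' (1 = tumor, 0 = normal, NA = unannotated).
#'
#' @param df data.frame with columns `spot_id`, `pixel_x`, `pixel_y`,
#'   `array_row`, `array_col`, `annotation`.
#' @return The validated data.frame with class `spot_table`.
#' @export
spot_table <- function(df) {
  missing_cols <- setdiff(SPOT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("spot table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$spot_id <- as.character(df$spot_id)
  if (anyDuplicated(df$spot_id)) {
    stop("duplicate spot_id(s): ",
         paste(unique(df$spot_id[duplicated(df$spot_id)]), collapse = ", "))
  }
  key <- paste(df$array_row, df$array_col)
  if (anyDuplicated(key)) {
    stop("duplicate (array_row, array_col) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  px <- c(df$pixel_x, df$pixel_y)
  if (any(!is.finite(px)) || any(px < 0)) {
    stop("pixel coordinates must be finite and non-negative")
  }
  ann <- df$annotation
  if (!all(is.na(ann) | ann %in% c(0, 1))) {
    stop("annotation must be 0, 1 or NA")
  }
  df <- as.data.frame(df)[, SPOT_COLUMNS]
  rownames(df) <- NULL
  class(df) <- c("spot_table", "data.frame")
  df
}

#' Construct an expression matrix
#'
#' Wraps an N (spots) x M (genes) numeric matrix with gene/spot names and a
#' layer tag (`"raw_counts"` or `"normalized"`).
#'
#' @param values numeric N x M matrix.
#' @param gene_names character vector of M unique gene names.
#' @param spot_ids character vector of N spot ids.
#' @param layer `"raw_counts"` or `"normalized"`.
#' @return numeric matrix with dimnames and a `layer` attribute.
#' @export
expression_matrix <- function(values, gene_names = colnames(values),
                              spot_ids = rownames(values),
                              layer = c("raw_counts", "normalized")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (is.null(gene_names) || is.null(spot_ids)) {
    stop("gene_names and spot_ids are required")
  }
  if (anyDuplicated(gene_names)) stop("gene names must be unique")
  if (length(gene_names) != ncol(values) || length(spot_ids) != nrow(values)) {
    stop("dimnames do not match matrix dimensions")
  }
  if (layer == "raw_counts" && any(values < 0, na.rm = TRUE)) {
    stop("raw counts must be non-negative")
  }
  dimnames(values) <- list(as.character(spot_ids), as.character(gene_names))
  attr(values, "layer") <- layer
  values
}

expr_layer <- function(x) attr(x, "layer") %||% "raw_counts"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a spatial-transcriptomics sample
#'
#' Bundles one tissue section: the slide image (array or file path), the spot
#' table, and the spots x genes expression matrix. Spot order in the table
#' and the matrix must agree.
#'
#' @param sample_id,patient_id identifiers; `patient_id` must be non-empty
#'   (patient-level data splits depend on it).
#' @param image H x W x 3 numeric array (0..255) or a path to an image file.
#' @param spots a [spot_table()].
#' @param expression an [expression_matrix()] whose rows match `spots$spot_id`.
#' @param latent optional data.frame of simulator ground truth.
#' @return list with class `st_sample`.
#' @export
st_sample <- function(sample_id, patient_id, image, spots, expression,
                      latent = NULL) {
  if (!nzchar(patient_id)) stop("patient_id must be non-empty")
  spots <- spot_table(spots)
  if (!identical(rownames(expression), spots$spot_id)) {
    bad <- union(setdiff(rownames(expression), spots$spot_id),
                 setdiff(spots$spot_id, rownames(expression)))
    stop("spot ids in expression matrix do not match spot table; offenders: ",
         paste(head(bad, 10L), collapse = ", "))
  }
  structure(list(sample_id = sample_id, patient_id = patient_id,
                 image = image, spots = spots, expression = expression,
                 latent = latent),
            class = "st_sample")
}

#' @export
print.st_sample <- function(x, ...) {
  cat(sprintf("<st_sample> %s (patient %s): %d spots x %d genes, layer=%s\n",
              x$sample_id, x$patient_id, nrow(x$spots), ncol(x$expression),
              expr_layer(x$expression)))
  invisible(x)
}

n_spots <- function(sample) nrow(sample$spots)

# ---------------------------------------------------------------------------
# reading

sniff_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return(",")
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a spot table from TSV/CSV
#'
#' @param path file with header columns `spot_id`, `pixel_x`, `pixel_y`,
#'   `array_row`, `array_col`, `annotation`. Delimiter is taken from the file
#'   extension (`.csv` = comma) or sniffed from the header line.
#' @return a [spot_table()].
#' @export
read_spot_table <- function(path) {
  df <- read.delim(path, sep = sniff_delim(path), header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  spot_table(df)
}

read_counts <- function(counts_path) {
  if (grepl("\\.mtx$", counts_path, ignore.case = TRUE)) {
    dir <- dirname(counts_path)
    genes_path <- file.path(dir, "genes.txt")
    spots_path <- file.path(dir, "spots.txt")
    for (p in c(genes_path, spots_path)) {
      if (!file.exists(p)) stop("MatrixMarket counts need sidecar file: ", p)
    }
    m <- as.matrix(Matrix::readMM(counts_path))
    genes <- readLines(genes_path)
    spots <- readLines(spots_path)
    if (nrow(m) != length(spots) || ncol(m) != length(genes)) {
      stop("MatrixMarket dimensions do not match genes.txt/spots.txt")
    }
    expression_matrix(m, genes, spots, layer = "raw_counts")
  } else {
    df <- read.delim(counts_path, sep = sniff_delim(counts_path), header = TRUE,
                     row.names = 1L, check.names = FALSE)
    expression_matrix(as.matrix(df), colnames(df), rownames(df),
                      layer = "raw_counts")
  }
}

#' Load a slide image as an 8-bit RGB array
#'
#' @param image H x W x 3 array (returned unchanged) or path to a
#'   PNG/TIFF/JPEG file.
#' @return numeric H x W x 3 array on the 0..255 scale.
#' @export
load_image <- function(image) {
  if (is.array(image)) {
    if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
      stop("image must be an H x W x 3 array")
    }
    return(image)
  }
  if (!file.exists(image)) stop("cannot read image: ", image)
  img <- EBImage::readImage(image)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  # EBImage stores (x, y, channel) on a 0..1 scale; return (row, col, channel)
  a <- aperm(a, c(2L, 1L, 3L))
  round(a * 255)
}

#' Read one sample from image + spot table + counts files
#'
#' @param image_path slide image (PNG/TIFF/JPEG).
#' @param spots_path spot table TSV/CSV.
#' @param counts_path spots x genes counts as TSV/CSV (header = gene names,
#'   first column = spot ids) or MatrixMarket `.mtx` with `genes.txt` and
#'   `spots.txt` next to it.
#' @param sample_id,patient_id identifiers (default: file stem / sample_id).
#' @return an [st_sample()] carrying raw counts, with counts rows aligned to
#'   the spot-table order.
#' @export
read_st_sample <- function(image_path, spots_path, counts_path,
                           sample_id = tools::file_path_sans_ext(basename(image_path)),
                           patient_id = sample_id) {
  spots <- read_spot_table(spots_path)
  counts <- read_counts(counts_path)
  missing_in_counts <- setdiff(spots$spot_id, rownames(counts))
  extra_in_counts <- setdiff(rownames(counts), spots$spot_id)
  if (length(missing_in_counts) || length(extra_in_counts)) {
    stop("spot ids disagree between spot table and counts; missing in counts: [",
         paste(head(missing_in_counts, 10L), collapse = ", "),
         "]; not in spot table: [",
         paste(head(extra_in_counts, 10L), collapse = ", "), "]")
  }
  counts <- expression_matrix(counts[spots$spot_id, , drop = FALSE],
                              layer = "raw_counts")
  st_sample(sample_id, patient_id, load_image(image_path), spots, counts)
}

# ---------------------------------------------------------------------------
# patches

#' Extract per-spot square patches from the slide image
#'
#' For each spot, crops the axis-aligned `window_px` square centred at
#' (`pixel_x`, `pixel_y`) using the half-open convention
#' `[c - floor(w/2), c - floor(w/2) + w)` per axis, then resizes to
#' `out_size_px` (bilinear). Spots whose window exits the image are excluded
#' (never padded) and flagged in `boundary_mask`.
#'
#' @param sample an [st_sample()] with a loadable image.
#' @param window_px crop side in pixels (default 150, the patch scale at x20
#'   magnification where a spot covers roughly 150 x 150 pixels).
#' @param out_size_px output side in pixels (default 224, the standard CNN
#'   input size).
#' @return list with `patches` (a `patch_set`: N x S x S x 3 array of raw
#'   0..255 values plus spot ids) and `boundary_mask` (logical per input
#'   spot, TRUE = excluded).
#' @export
extract_patches <- function(sample, window_px = 150L, out_size_px = 224L) {
  stopifnot(window_px >= 1L, out_size_px >= 1L)
  img <- load_image(sample$image)
  H <- dim(img)[1]; W <- dim(img)[2]
  w <- as.integer(window_px)
  x0 <- floor(sample$spots$pixel_x) - (w %/% 2L)
  y0 <- floor(sample$spots$pixel_y) - (w %/% 2L)
  excluded <- x0 < 0L | y0 < 0L | (x0 + w) > W | (y0 + w) > H
  names(excluded) <- sample$spots$spot_id
  keep <- which(!excluded)
  if (length(keep) == 0L) {
    stop("no spots retained: every patch window exits the image")
  }
  S <- as.integer(out_size_px)
  patches <- array(0, c(length(keep), S, S, 3L))
  for (k in seq_along(keep)) {
    i <- keep[k]
    crop <- img[(y0[i] + 1L):(y0[i] + w), (x0[i] + 1L):(x0[i] + w), ,
                drop = FALSE]
    if (w == S) {
      patches[k, , , ] <- crop
    } else {
      patches[k, , , ] <- resize_patch(crop, S)
    }
  }
  ps <- structure(list(patches = patches,
                       spot_ids = sample$spots$spot_id[keep],
                       window_px = w, out_size_px = S,
                       normalized = FALSE),
                  class = "patch_set")
  list(patches = ps, boundary_mask = excluded)
}

# bilinear resize of one H x W x 3 patch to side S
resize_patch <- function(crop, S) {
  out <- EBImage::resize(EBImage::Image(aperm(crop, c(2L, 1L, 3L)) / 255,
                                        colormode = "Color"),
                         w = S, h = S)
  aperm(EBImage::imageData(out), c(2L, 1L, 3L)) * 255
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches, %dpx (window %dpx), %s\n",
              dim(x$patches)[1], x$out_size_px, x$window_px,
              if (isTRUE(x$normalized)) "normalized" else "raw 0..255"))
  invisible(x)
}

#' Per-channel mean and standard deviation of a patch set
#'
#' Computed on the 0..1 (pixel/255) scale, over all pixels of all patches.
#' Intended to be run on the training split only; the statistics are stored
#' in the model checkpoint and reused for validation/test patches.
#'
#' @param patches a `patch_set` of raw patches.
#' @return list with numeric `mean` and `sd`, each length 3.
#' @export
channel_stats <- function(patches) {
  stopifnot(inherits(patches, "patch_set"), !isTRUE(patches$normalized))
  x <- patches$patches / 255
  m <- apply(x, 4L, mean)
  s <- apply(x, 4L, sd)
  list(mean = m, sd = s)
}

#' Standardize patches channel-wise
#'
#' Applies `((raw / 255) - mean) / sd` per channel, the usual image
#' standardization for CNN input.
#'
#' @param patches a raw `patch_set`.
#' @param channel_mean,channel_sd length-3 numeric vectors (training-split
#'   statistics on the 0..1 scale).
#' @return a `patch_set` with `normalized = TRUE`.
#' @export
normalize_patches <- function(patches, channel_mean, channel_sd) {
  stopifnot(inherits(patches, "patch_set"))
  if (isTRUE(patches$normalized)) stop("patches are already normalized")
  stopifnot(length(channel_mean) == 3L, length(channel_sd) == 3L)
  if (any(channel_sd <= 0)) {
    stop("degenerate channel: standard deviation must be > 0 in every channel")
  }
  x <- patches$patches / 255
  for (c in 1:3) {
    x[, , , c] <- (x[, , , c] - channel_mean[c]) / channel_sd[c]
  }
  patches$patches <- x
  patches$normalized <- TRUE
  patches$channel_mean <- channel_mean
  patches$channel_sd <- channel_sd
  patches
}

# ---------------------------------------------------------------------------
# writing

#' Write per-spot predictions to TSV
#'
#' One row per spot; columns are the predicted genes followed by
#' `tumor_prob`. Values are written at full float precision so the table
#' round-trips losslessly.
#'
#' @param spot_ids N spot ids.
#' @param gene_names m gene names (non-empty).
#' @param predicted N x m matrix of predicted expression.
#' @param tumor_prob N-vector of tumor probabilities.
#' @param out_path output TSV path.
#' @return `out_path`, invisibly.
#' @export
write_predictions <- function(spot_ids, gene_names, predicted, tumor_prob,
                              out_path) {
  predicted <- as.matrix(predicted)
  if (length(gene_names) == 0L) stop("gene_names must be non-empty")
  if (nrow(predicted) != length(spot_ids) ||
      ncol(predicted) != length(gene_names) ||
      length(tumor_prob) != length(spot_ids)) {
    stop("shape mismatch between spot_ids, gene_names, predicted, tumor_prob")
  }
  df <- data.frame(spot_id = spot_ids, predicted, check.names = FALSE)
  names(df)[-1L] <- gene_names
  df$tumor_prob <- tumor_prob
  write_tsv_full(df, out_path)
  invisible(out_path)
}

# full-precision TSV writer shared by all outputs
write_tsv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    if (all(x == round(x), na.rm = TRUE)) x else sprintf("%.17g", x)
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read back a predictions TSV
#'
#' @param path file written by [write_predictions()].
#' @return list with `spot_ids`, `gene_names`, `predicted`, `tumor_prob`.
#' @export
read_predictions <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  genes <- setdiff(names(df), c("spot_id", "tumor_prob"))
  list(spot_ids = as.character(df$spot_id), gene_names = genes,
       predicted = as.matrix(df[, genes, drop = FALSE]),
       tumor_prob = df$tumor_prob)
}

#' Write a sample to disk in the formats this package reads
#'
#' Writes `image.png`, `spots.tsv`, counts (TSV or MatrixMarket trio) and a
#' small `meta.json` into `dir`. [read_st_sample()] on the written files
#' round-trips counts exactly and coordinates at float precision.
#'
#' @param sample an [st_sample()] with raw counts and an in-memory image.
#' @param dir output directory (created if needed).
#' @param counts_format `"tsv"` or `"mtx"`.
#' @return `dir`, invisibly.
#' @export
write_st_sample <- function(sample, dir, counts_format = c("tsv", "mtx")) {
  counts_format <- match.arg(counts_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img <- load_image(sample$image) / 255
  EBImage::writeImage(EBImage::Image(aperm(img, c(2L, 1L, 3L)),
                                     colormode = "Color"),
                      file.path(dir, "image.png"), type = "png", bits.per.sample = 8L)
  write_tsv_full(as.data.frame(sample$spots), file.path(dir, "spots.tsv"))
  counts <- sample$expression
  if (counts_format == "tsv") {
    df <- data.frame(spot_id = rownames(counts), counts, check.names = FALSE)
    write_tsv_full(df, file.path(dir, "counts.tsv"))
  } else {
    Matrix::writeMM(Matrix::Matrix(unclass(counts), sparse = TRUE),
                    file.path(dir, "counts.mtx"))
    writeLines(colnames(counts), file.path(dir, "genes.txt"))
    writeLines(rownames(counts), file.path(dir, "spots.txt"))
  }
  meta <- list(sample_id = sample$sample_id, patient_id = sample$patient_id,
               counts_format = counts_format)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  if (!is.null(sample$latent)) {
    write_tsv_full(sample$latent, file.path(dir, "latent.tsv"))
  }
  invisible(dir)
}

#' Read a directory of samples written by [write_st_sample()]
#'
#' @param dir directory whose subdirectories each hold one sample.
#' @return list of [st_sample()] objects.
#' @export
read_st_cohort <- function(dir) {
  sample_dirs <- list.dirs(dir, recursive = FALSE)
  sample_dirs <- sample_dirs[file.exists(file.path(sample_dirs, "meta.json"))]
  if (length(sample_dirs) == 0L) stop("no samples (meta.json) found under ", dir)
  lapply(sample_dirs, function(d) {
    meta <- jsonlite::read_json(file.path(d, "meta.json"))
    counts_path <- if (identical(meta$counts_format, "mtx")) {
      file.path(d, "counts.mtx")
    } else file.path(d, "counts.tsv")
    s <- read_st_sample(file.path(d, "image.png"), file.path(d, "spots.tsv"),
                        counts_path, sample_id = meta$sample_id,
                        patient_id = meta$patient_id)
    latent_path <- file.path(d, "latent.tsv")
    if (file.exists(latent_path)) {
      s$latent <- read.delim(latent_path, sep = "\t", stringsAsFactors = FALSE)
    }
    s
  })
}
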