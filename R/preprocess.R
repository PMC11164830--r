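# Quality control, expression normalization, gene partitioning, and the
# 3x3 grid neighbor graph.

#' Quality-control thresholds
#'
#' Defaults follow the standard spot/gene filters for spatial
#' transcriptomics: spots with fewer than 200 UMIs, more than 20 000 UMIs,
#' over 5% mitochondrial counts, or fewer than 200 detected genes are
#' excluded ("fewer"/"more" are strict, so the bounds themselves are kept);
#' genes detected in fewer than 3 spots are excluded.
#'
#' @param min_umi,max_umi inclusive bounds on per-spot total UMIs.
#' @param max_mito_frac maximum fraction of counts on mitochondrial genes.
#' @param min_genes_per_spot minimum number of genes with count > 0.
#' @param min_spots_per_gene minimum number of spots in which a gene has
#'   count > 0.
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @return list with class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_umi = 200L, max_umi = 20000L,
                          max_mito_frac = 0.05, min_genes_per_spot = 200L,
                          min_spots_per_gene = 3L, mito_prefix = "MT-") {
  stopifnot(min_umi < max_umi, max_mito_frac >= 0, max_mito_frac <= 1)
  structure(list(min_umi = min_umi, max_umi = max_umi,
                 max_mito_frac = max_mito_frac,
                 min_genes_per_spot = min_genes_per_spot,
                 min_spots_per_gene = min_spots_per_gene,
                 mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

#' Per-spot QC statistics
#'
#' @param counts raw-count [expression_matrix()].
#' @param mito_prefix mitochondrial gene-name prefix.
#' @return data.frame with `spot_id`, `total_umi`, `mito_frac`,
#'   `detected_genes`.
#' @export
qc_spot_stats <- function(counts, mito_prefix = "MT-") {
  total <- rowSums(counts)
  is_mito <- startsWith(colnames(counts), mito_prefix)
  mito <- if (any(is_mito)) rowSums(counts[, is_mito, drop = FALSE]) else 0
  data.frame(spot_id = rownames(counts),
             total_umi = unname(total),
             mito_frac = unname(ifelse(total > 0, mito / total, 0)),
             detected_genes = unname(rowSums(counts > 0)))
}

#' Spot-level QC filter
#'
#' Keeps a spot iff its total UMI count lies in `[min_umi, max_umi]`, its
#' mitochondrial fraction is at most `max_mito_frac`, it has at least
#' `min_genes_per_spot` detected genes, and it is not boundary-excluded.
#'
#' @param sample an [st_sample()] with raw counts.
#' @param thresholds a [qc_thresholds()].
#' @param boundary_mask optional logical per spot (TRUE = patch window exits
#'   the slide, see [extract_patches()]).
#' @return named logical vector, TRUE = keep.
#' @export
qc_filter_spots <- function(sample, thresholds = qc_thresholds(),
                            boundary_mask = NULL) {
  counts <- sample$expression
  if (expr_layer(counts) != "raw_counts") {
    stop("spot QC needs the raw-count layer")
  }
  stats <- qc_spot_stats(counts, thresholds$mito_prefix)
  keep <- stats$total_umi >= thresholds$min_umi &
    stats$total_umi <= thresholds$max_umi &
    stats$mito_frac <= thresholds$max_mito_frac &
    stats$detected_genes >= thresholds$min_genes_per_spot
  if (!is.null(boundary_mask)) {
    keep <- keep & !boundary_mask[stats$spot_id]
  }
  setNames(keep, stats$spot_id)
}

#' Gene-level QC filter
#'
#' Keeps a gene iff it is detected (count > 0) in at least
#' `min_spots_per_gene` spots. Run after spot QC so detection reflects
#' retained spots only.
#'
#' @param counts raw-count [expression_matrix()] (spot-filtered).
#' @param thresholds a [qc_thresholds()].
#' @return named logical vector over genes, TRUE = keep.
#' @export
qc_filter_genes <- function(counts, thresholds = qc_thresholds()) {
  if (expr_layer(counts) != "raw_counts") {
    stop("gene QC needs the raw-count layer")
  }
  keep <- colSums(counts > 0) >= thresholds$min_spots_per_gene
  setNames(keep, colnames(counts))
}

#' Library-size normalization with log transform
#'
#' `out[i, j] = ln(pseudocount + scale * counts[i, j] / total_i)`: counts are
#' divided by the per-spot total, multiplied by a scale factor (default
#' 10 000), and log-transformed after adding a pseudocount so zeros map to
#' `ln(pseudocount)` (0 with the default pseudocount of 1).
#'
#' @param counts raw-count [expression_matrix()].
#' @param scale scale factor (counts per `scale` total).
#' @param pseudocount added before the log.
#' @return [expression_matrix()] with layer `"normalized"` and the spot
#'   totals stored in attribute `spot_totals` (so the transform is
#'   invertible).
#' @export
normalize_expression <- function(counts, scale = 10000, pseudocount = 1) {
  if (expr_layer(counts) != "raw_counts") {
    stop("normalize_expression expects raw counts")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- rowSums(counts)
  if (any(total == 0)) {
    stop("spot(s) with zero total counts: run spot QC before normalization")
  }
  out <- log(pseudocount + scale * counts / total)
  out <- expression_matrix(out, colnames(counts), rownames(counts),
                           layer = "normalized")
  attr(out, "spot_totals") <- total
  attr(out, "scale") <- scale
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Partition genes into target and non-target sets
#'
#' Target genes are the `m` genes with the largest mean expression across the
#' (training) spots; all remaining genes form the non-target (auxiliary) set.
#' Ties are broken by gene name so the partition is deterministic.
#'
#' @param expr expression matrix (normalized layer by convention; any layer
#'   accepted, recorded in the result).
#' @param m number of target genes (default 250).
#' @return list with class `gene_partition`: integer `target_idx`,
#'   `nontarget_idx` (column indices into `expr`), `m`, and the
#'   corresponding gene names.
#' @export
partition_genes <- function(expr, m = 250L) {
  M <- ncol(expr)
  if (m > M) stop("m (", m, ") exceeds number of genes (", M, ")")
  mu <- colMeans(expr)
  ord <- order(-mu, colnames(expr), method = "radix")
  target <- sort(ord[seq_len(m)])
  structure(list(target_idx = target,
                 nontarget_idx = setdiff(seq_len(M), target),
                 m = as.integer(m),
                 target_genes = colnames(expr)[target],
                 nontarget_genes = colnames(expr)[setdiff(seq_len(M), target)],
                 ranking_layer = expr_layer(expr)),
            class = "gene_partition")
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf("<gene_partition> %d target / %d non-target genes (ranked on %s layer)\n",
              x$m, length(x$nontarget_idx), x$ranking_layer))
  invisible(x)
}

#' Build the 3x3-window neighbor graph over spots
#'
#' Two spots are neighbors iff their grid coordinates differ by at most 1 in
#' each of row and column (and they are distinct) — the eight surrounding
#' positions of a 3x3 window. Missing grid positions simply yield fewer
#' neighbors.
#'
#' @param spots a [spot_table()] (or data.frame with `array_row`,
#'   `array_col`, `spot_id`).
#' @return list with class `neighbor_graph`: `neighbors` (per spot, integer
#'   indices of its neighbors) and `spot_ids`.
#' @export
build_neighbor_graph <- function(spots) {
  key <- paste(spots$array_row, spots$array_col)
  if (anyDuplicated(key)) stop("duplicate array coordinates")
  pos <- new.env(hash = TRUE, size = nrow(spots))
  for (i in seq_len(nrow(spots))) assign(key[i], i, envir = pos)
  offsets <- expand.grid(dr = -1:1, dc = -1:1)
  offsets <- offsets[!(offsets$dr == 0 & offsets$dc == 0), ]
  nbrs <- lapply(seq_len(nrow(spots)), function(i) {
    ks <- paste(spots$array_row[i] + offsets$dr, spots$array_col[i] + offsets$dc)
    idx <- unlist(lapply(ks, function(k) {
      if (exists(k, envir = pos, inherits = FALSE)) get(k, envir = pos) else NULL
    }))
    sort(as.integer(idx %||% integer(0)))
  })
  structure(list(neighbors = nbrs, spot_ids = spots$spot_id),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("<neighbor_graph> %d spots, degree %d..%d (mean %.2f)\n",
              length(deg), min(deg), max(deg), mean(deg)))
  invisible(x)
}

#' Per-spot QC report
#'
#' @param sample an [st_sample()] with raw counts.
#' @param thresholds a [qc_thresholds()].
#' @param boundary_mask optional logical exclusion mask from
#'   [extract_patches()].
#' @return data.frame with per-spot statistics, individual pass flags and an
#'   overall `pass` column.
#' @export
qc_report <- function(sample, thresholds = qc_thresholds(),
                      boundary_mask = NULL) {
  stats <- qc_spot_stats(sample$expression, thresholds$mito_prefix)
  stats$pass_umi <- stats$total_umi >= thresholds$min_umi &
    stats$total_umi <= thresholds$max_umi
  stats$pass_mito <- stats$mito_frac <= thresholds$max_mito_frac
  stats$pass_genes <- stats$detected_genes >= thresholds$min_genes_per_spot
  stats$pass_boundary <- if (is.null(boundary_mask)) TRUE else
    !boundary_mask[stats$spot_id]
  stats$pass <- stats$pass_umi & stats$pass_mito & stats$pass_genes &
    stats$pass_boundary
  stats
}
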