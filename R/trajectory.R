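#' Bin features along pseudotime
#'
#' Cells of one cell type are library-size normalized
#' (`log1p(count / libsize * 1e4)`), assigned to `n_bins` uniform pseudotime
#' bins on [0, 1] (`[i/n, (i+1)/n)`, last bin closed), and averaged per bin.
#' Bins containing no cells are filled by linear interpolation between
#' their neighbours (leading/trailing empties carry the nearest value).
#' With `scale = "z"` (default) each feature's profile is then z-scored
#' across bins; zero-variance profiles become all zeros.
#'
#' @param counts a `stim_counts`.
#' @param cells cell annotations.
#' @param cell_type cell type to profile (all its time points pooled:
#'   pseudotime spans the activation trajectory).
#' @param n_bins number of bins (>= 2; default 100).
#' @param features optional subset of feature ids.
#' @param scale `"z"` for z-scored profiles, `"raw"` for the interpolated
#'   bin means.
#' @param smooth_width width of a centred moving average applied to each
#'   profile after interpolation and before any z-scoring (1 disables).
#'   Bin profiles built from a few thousand cells are thin (tens of cells
#'   per bin); mild smoothing recovers the stability that very large
#'   datasets get for free.
#' @return a `stim_profiles` object: list with `values` (feature x bin
#'   matrix), `cell_type`, `n_bins`, `scale`, `feature_mean` (overall mean
#'   normalized signal per feature, used for background matching), and
#'   `bin_cells` (cells per bin).
#' @export
bin_pseudotime <- function(counts, cells, cell_type, n_bins = 100,
                           features = NULL, scale = c("z", "raw"),
                           smooth_width = 5) {
  scale <- match.arg(scale)
  if (n_bins < 2) abort("n_bins must be >= 2")
  cells <- check_cells(cells)
  sub <- cells[cells$cell_type == cell_type, ]
  if (nrow(sub) == 0) abort(sprintf("no cells of type %s", cell_type))
  m <- counts$counts[, sub$cell_id, drop = FALSE]
  if (!is.null(features)) m <- m[features, , drop = FALSE]
  lib <- Matrix::colSums(m)
  lib[lib == 0] <- 1
  norm <- m %*% Matrix::Diagonal(x = 1e4 / lib)
  norm@x <- log1p(norm@x)
  bin <- pmin(floor(sub$pseudotime * n_bins), n_bins - 1L) + 1L
  bin_cells <- tabulate(bin, nbins = n_bins)
  if (mean(bin_cells == 0) > 0.5) {
    warn("more than 50% of pseudotime bins are empty; features dropped")
    return(structure(list(values = matrix(0, 0, n_bins),
                          cell_type = cell_type, n_bins = n_bins,
                          scale = scale, feature_mean = numeric(0),
                          bin_cells = bin_cells),
                     class = "stim_profiles"))
  }
  agg <- norm %*% sparseMatrix(i = seq_along(bin), j = bin, x = 1,
                               dims = c(length(bin), n_bins))
  agg <- as.matrix(agg)
  vals <- sweep(agg, 2, pmax(bin_cells, 1), `/`)
  # interpolate empty bins from filled neighbours
  empty <- bin_cells == 0
  if (any(empty)) {
    filled <- which(!empty)
    vals <- t(apply(vals, 1, function(v) {
      approx(filled, v[filled], xout = seq_len(n_bins), rule = 2)$y
    }))
  }
  if (smooth_width > 1) {
    vals <- t(apply(vals, 1, smooth_ma, width = smooth_width))
  }
  feature_mean <- rowMeans(vals)
  if (scale == "z") {
    mu <- rowMeans(vals)
    s <- apply(vals, 1, sd)
    # zero-variance convention, with a tolerance absorbing float accumulation
    zero <- s <= 1e-10 * pmax(abs(mu), 1)
    vals <- (vals - mu) / ifelse(zero, 1, s)
    vals[zero, ] <- 0
  }
  rownames(vals) <- rownames(m)
  structure(list(values = vals, cell_type = cell_type, n_bins = n_bins,
                 scale = scale, feature_mean = feature_mean,
                 bin_cells = bin_cells),
            class = "stim_profiles")
}

#' @export
print.stim_profiles <- function(x, ...) {
  cat(sprintf("<stim_profiles> %d features x %d bins (%s, %s)\n",
              nrow(x$values), x$n_bins, x$cell_type, x$scale))
  invisible(x)
}

#' Long-format view of binned profiles
#'
#' @param profiles a `stim_profiles`.
#' @return tibble(`feature_id`, `cell_type`, `bin`, `value`).
#' @export
profile_tbl <- function(profiles) {
  v <- profiles$values
  tibble(feature_id = rep(rownames(v), times = ncol(v)),
         cell_type = profiles$cell_type,
         bin = rep(seq_len(ncol(v)), each = nrow(v)),
         value = as.vector(v))
}

#' Select highly variable response genes
#'
#' Genes with `|log2FC| > log2(fc_threshold)` and `q < q_threshold` in at
#' least one differential contrast (the "FC > 2 DEG" gate).
#'
#' @param diff_results row-bound [response_de()] results over contrasts.
#' @param fc_threshold linear fold-change threshold (default 2).
#' @param q_threshold BH q cutoff (default 0.05).
#' @return character vector of gene ids.
#' @export
select_variable_degs <- function(diff_results, fc_threshold = 2,
                                 q_threshold = 0.05) {
  if (nrow(diff_results) == 0) return(character(0))
  hits <- diff_results[abs(diff_results$lfc) > log2(fc_threshold) &
                       diff_results$q < q_threshold, ]
  unique(hits$feature_id)
}

#' Cluster genes into temporal modules
#'
#' Concatenates each gene's z-scored bin profile across the three cell
#' types (length `3 * n_bins`) and runs k-means with `n_start` restarts
#' under a fixed seed. Genes missing a profile in any cell type are dropped
#' with a message.
#'
#' @param profiles_by_celltype list of three `stim_profiles` (z-scored),
#'   one per cell type.
#' @param genes optional subset of gene ids to cluster (e.g. from
#'   [select_variable_degs()]).
#' @param k number of clusters (default 15).
#' @param n_start k-means restarts (default 20).
#' @param seed RNG seed for the restarts.
#' @return a `stim_modules` object: list with `assignment`
#'   (tibble `gene_id`, `cluster`), `centers` (k x 3 n_bins matrix),
#'   `k`, `n_bins`, `cell_types`.
#' @export
cluster_modules <- function(profiles_by_celltype, genes = NULL, k = 15,
                            n_start = 20, seed = 1) {
  mats <- lapply(profiles_by_celltype, function(p) p$values)
  shared <- Reduce(intersect, lapply(mats, rownames))
  if (!is.null(genes)) {
    missing <- setdiff(genes, shared)
    if (length(missing) > 0) {
      inform(sprintf("%d gene(s) lack a profile in some cell type; dropped",
                     length(missing)))
    }
    shared <- intersect(genes, shared)
  }
  if (k > length(shared)) abort("k exceeds the number of genes")
  X <- do.call(cbind, lapply(mats, function(m) m[shared, , drop = FALSE]))
  set.seed(seed)
  km <- kmeans(X, centers = k, nstart = n_start, iter.max = 100)
  structure(list(
    assignment = tibble(gene_id = shared, cluster = unname(km$cluster)),
    centers = km$centers, k = k,
    n_bins = ncol(mats[[1]]),
    cell_types = vapply(profiles_by_celltype, function(p) p$cell_type,
                        character(1)),
    tot_withinss = km$tot.withinss),
    class = "stim_modules")
}

#' @export
print.stim_modules <- function(x, ...) {
  cat(sprintf("<stim_modules> %d genes in %d clusters\n",
              nrow(x$assignment), x$k))
  invisible(x)
}

#' Gene activity scores from peak accessibility
#'
#' Per cell and gene, the sum of counts over peaks overlapping the promoter
#' window `[tss - promoter_bp, tss + promoter_bp]` (1-based, clipped at 1)
#' and, when `body = TRUE` and the gene table carries an `end` column, the
#' gene span. Overlap means any shared base under the package conventions
#' (peaks 0-based half-open, window 1-based inclusive).
#'
#' @param peak_counts a `stim_counts` of peaks.
#' @param peaks tibble(`peak_id`, `chrom`, `start`, `end`).
#' @param genes tibble(`gene_id`, `chrom`, `tss`, optionally `end`).
#' @param promoter_bp promoter half-width (default 2000).
#' @param body include the gene body (requires an `end` column).
#' @return a `stim_counts` of derived gene activity scores (genes x cells).
#' @export
gene_activity_score <- function(peak_counts, peaks, genes,
                                promoter_bp = 2000, body = FALSE) {
  if (body && !"end" %in% names(genes)) {
    abort("body = TRUE requires an `end` column in `genes`")
  }
  win_lo <- pmax(1, genes$tss - promoter_bp)
  win_hi <- genes$tss + promoter_bp
  if (body) {
    win_lo <- pmin(win_lo, pmax(1, genes$tss))
    win_hi <- pmax(win_hi, genes$end)
  }
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(win_lo, win_hi))
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gene_gr, peak_gr))
  A <- sparseMatrix(i = S4Vectors_from(hits), j = S4Vectors_to(hits), x = 1,
                    dims = c(nrow(genes), nrow(peaks)))
  m <- peak_counts$counts[peaks$peak_id, , drop = FALSE]
  scores <- A %*% m
  rownames(scores) <- genes$gene_id
  colnames(scores) <- colnames(m)
  new_stim_counts(methods::as(scores, "CsparseMatrix"))
}

# tiny wrappers keep the S4Vectors dependency implicit via GenomicRanges
S4Vectors_from <- function(hits) methods::slot(hits, "from")
S4Vectors_to <- function(hits) methods::slot(hits, "to")

#' Expression-accessibility concordance along pseudotime
#'
#' Computes the lagged cross-correlation between a gene's activity
#' (accessibility) profile and its expression profile over shifts
#' `s in [-max_lag, max_lag]`, where the reported `lag` maximizes
#' `cor(activity[t], expression[t - s])`: a negative lag means chromatin
#' leads expression. Classes: `"priming"` when `lag <= -lag_min`;
#' `"memory"` when the expression pulse has decayed (its maximum lies
#' before the tail window and the tail mean is below `tail_level`) while
#' activity stays above `tail_level` over the final `tail_window` bins;
#' otherwise `"concordant"`. Priming is checked first. Profiles may be
#' smoothed by a centred moving average of width `smooth_width` first.
#'
#' @param expr_profile,activity_profile equal-length z-scored numeric
#'   vectors (one gene, one cell type).
#' @param max_lag maximum shift searched (bins).
#' @param lag_min minimum lead (bins) to call priming (default 5).
#' @param tail_window,tail_level memory rule: tail length (bins) and level
#'   (SD units).
#' @param smooth_width moving-average width (1 disables smoothing).
#' @return tibble(`lag`, `r_max`, `class`, `tail_expression`,
#'   `tail_activity`).
#' @export
concordance <- function(expr_profile, activity_profile, max_lag = 20,
                        lag_min = 5, tail_window = 20, tail_level = 0.5,
                        smooth_width = 5) {
  stopifnot(length(expr_profile) == length(activity_profile))
  e <- smooth_ma(expr_profile, smooth_width)
  a <- smooth_ma(activity_profile, smooth_width)
  n <- length(e)
  if (max_lag >= n - 1) abort("max_lag must be smaller than the profile length")
  shifts <- -max_lag:max_lag
  lag_cor <- function(x_full, y_full, s) {
    m <- length(x_full)
    if (s >= 0) {
      x <- x_full[(1 + s):m]; y <- y_full[1:(m - s)]
    } else {
      x <- x_full[1:(m + s)]; y <- y_full[(1 - s):m]
    }
    if (sd(x) == 0 || sd(y) == 0) return(0)
    cor(x, y)
  }
  cc <- vapply(shifts, function(s) lag_cor(a, e, s), numeric(1))
  lag <- shifts[which.max(cc)]
  tail_ix <- (n - tail_window + 1):n
  tail_e <- mean(e[tail_ix])
  tail_a <- mean(a[tail_ix])
  decayed <- which.max(e) < min(tail_ix) && tail_e < tail_level
  cls <- if (lag <= -lag_min) "priming"
         else if (decayed && tail_a > tail_level) "memory"
         else "concordant"
  tibble(lag = lag, r_max = lag_cor(a, e, lag), class = cls,
         tail_expression = tail_e, tail_activity = tail_a)
}

smooth_ma <- function(x, width) {
  if (width <= 1) return(x)
  k <- rep(1 / width, width)
  as.vector(stats::filter(x, k, sides = 2)) |>
    (\(v) { v[is.na(v)] <- x[is.na(v)]; v })()
}
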