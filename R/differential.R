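#' Stimulation-response differential expression (pseudobulk, paired)
#'
#' Per feature, a paired linear model of the log2(CPM+1) pseudobulk across
#' donors observed at both time points of one cell type (time as fixed
#' effect, donor as blocking factor; with two time points this is the
#' paired t-test). Two-sided p; BH q across features.
#'
#' `da_peaks()` is the identical estimator applied to peak pseudobulk: one
#' code path, two entry points.
#'
#' @param pb a `stim_pseudobulk` (genes for `response_de`, peaks for
#'   `da_peaks`).
#' @param cell_type cell type analysed.
#' @param time_pair length-2 character, reference first
#'   (default `c("0h", "1h")`); the log2 fold change is `time_pair[2]`
#'   minus `time_pair[1]`.
#' @return tibble(`feature_id`, `cell_type`, `contrast`, `lfc`, `p`, `q`).
#' @export
response_de <- function(pb, cell_type, time_pair = c("0h", "1h")) {
  de_paired(pb, cell_type, time_pair)
}

#' @rdname response_de
#' @export
da_peaks <- function(pb, cell_type, time_pair = c("0h", "1h")) {
  de_paired(pb, cell_type, time_pair)
}

de_paired <- function(pb, cell_type, time_pair) {
  stopifnot(length(time_pair) == 2)
  A <- pb_matrix(pb, cell_type, time_pair[1], "log2cpm")
  B <- pb_matrix(pb, cell_type, time_pair[2], "log2cpm")
  donors <- intersect(rownames(A), rownames(B))
  if (length(donors) < 3) {
    abort("paired differential test requires >= 3 donors at both times")
  }
  D <- B[donors, , drop = FALSE] - A[donors, , drop = FALSE]
  n <- length(donors)
  lfc <- colMeans(D)
  s <- apply(D, 2, sd)
  tstat <- lfc / (s / sqrt(n))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  p[s == 0 & lfc == 0] <- 1            # no signal, no variance
  p[s == 0 & lfc != 0] <- 0            # exact constant shift
  tibble(feature_id = colnames(D), cell_type = cell_type,
         contrast = paste(time_pair[2], "vs", time_pair[1]),
         lfc = unname(lfc), p = unname(p),
         q = unname(p.adjust(p, method = "BH")))
}

#' Peak presence and stimulation specificity
#'
#' A peak is *present* in a context when at least `min_cell_fraction` of
#' that context's cells carry a nonzero count, and *stimulation-specific*
#' in a cell type when absent at 0h but present at 1h or 6h.
#'
#' @param peak_counts a `stim_counts` of peaks.
#' @param cells cell annotations.
#' @param min_cell_fraction presence threshold, strictly inside (0, 1).
#' @return tibble(`peak_id`, `cell_type`, `present_0h`, `present_1h`,
#'   `present_6h`, `stimulation_specific`).
#' @export
peak_presence <- function(peak_counts, cells, min_cell_fraction = 0.02) {
  if (min_cell_fraction <= 0 || min_cell_fraction >= 1) {
    abort("min_cell_fraction must lie strictly inside (0, 1)")
  }
  cells <- check_cells(cells)
  m <- peak_counts$counts
  out <- list()
  for (ct in unique(cells$cell_type)) {
    pres <- sapply(stim_times(), function(tm) {
      ids <- cells$cell_id[cells$cell_type == ct & cells$time == tm]
      if (length(ids) == 0) return(rep(NA, nrow(m)))
      frac <- rowSums(m[, ids, drop = FALSE] > 0) / length(ids)
      frac >= min_cell_fraction
    })
    out[[ct]] <- tibble(
      peak_id = rownames(m), cell_type = ct,
      present_0h = pres[, "0h"], present_1h = pres[, "1h"],
      present_6h = pres[, "6h"],
      stimulation_specific = !pres[, "0h"] &
        (pres[, "1h"] | pres[, "6h"]))
  }
  dplyr::bind_rows(out)
}

#' Gene-set enrichment by Fisher's exact test
#'
#' Fold enrichment is the hit rate inside the set over the hit rate outside
#' it: `(|hit n set| / |set|) / (|hit \ set| / |background \ set|)`; the
#' p-value is the two-sided Fisher exact test on the 2x2 table.
#'
#' @param hit_genes,set_genes,background_genes character vectors; both
#'   `hit_genes` and `set_genes` must be subsets of `background_genes`.
#' @return tibble(`fold`, `odds_ratio`, `p`, `n_hit_in_set`, `n_set`,
#'   `n_hit`, `n_background`).
#' @export
geneset_enrichment <- function(hit_genes, set_genes, background_genes) {
  if (length(set_genes) == 0 || length(background_genes) == 0) {
    abort("set and background must be non-empty")
  }
  if (!all(set_genes %in% background_genes) ||
      !all(hit_genes %in% background_genes)) {
    abort("hits and set must be subsets of the background")
  }
  hit <- unique(hit_genes)
  set <- unique(set_genes)
  bg <- unique(background_genes)
  a <- length(intersect(hit, set))
  b <- length(set) - a
  c_ <- length(setdiff(hit, set))
  d <- length(setdiff(bg, set)) - c_
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
  ft <- fisher.test(tab)
  fold <- (a / length(set)) / (c_ / (length(bg) - length(set)))
  tibble(fold = fold, odds_ratio = unname(ft$estimate), p = ft$p.value,
         n_hit_in_set = a, n_set = length(set), n_hit = length(hit),
         n_background = length(bg))
}

#' Case-control differential expression per context
#'
#' Per gene and context, a linear model of log2(CPM+1) pseudobulk on case
#' status plus optional donor covariates; BH q per context. Zero-variance
#' genes get p = 1. A rank-deficient design (confounded covariate) is an
#' error.
#'
#' Use [activity_dependent_de()] on results from several contexts to flag
#' genes whose case-control DE appears only under stimulation.
#'
#' @param pb a `stim_pseudobulk`.
#' @param case_labels tibble(`donor_id`, `status`) with status in
#'   {case, control}.
#' @param cell_type,time the context analysed.
#' @param covariates optional donor-level covariate matrix
#'   (rownames = donor ids).
#' @return tibble(`feature_id`, `cell_type`, `time`, `lfc`, `p`, `q`).
#' @export
case_control_de <- function(pb, case_labels, cell_type, time,
                            covariates = NULL) {
  Y <- pb_matrix(pb, cell_type, time, "log2cpm")
  donors <- intersect(rownames(Y), case_labels$donor_id)
  status <- case_labels$status[match(donors, case_labels$donor_id)]
  if (min(table(status)) < 3) abort("need >= 3 donors per arm")
  Y <- Y[donors, , drop = FALSE]
  X <- cbind(1, status == "case")
  colnames(X) <- c("(Intercept)", "case")
  if (!is.null(covariates)) X <- cbind(X, covariates[donors, , drop = FALSE])
  if (qr(X)$rank < ncol(X)) {
    abort("design is rank deficient (confounded covariate)")
  }
  n <- nrow(X)
  df <- n - ncol(X)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * XtXi["case", "case"])
  lfc <- B["case", ]
  tstat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pt(-abs(tstat), df)
  p[se == 0] <- 1                        # zero-variance gene
  tibble(feature_id = colnames(Y), cell_type = cell_type, time = time,
         lfc = unname(lfc), p = unname(p),
         q = p.adjust(p, method = "BH"))
}

#' @rdname case_control_de
#' @param de_results row-bound [case_control_de()] results covering 0h and
#'   at least one stimulated time of each cell type.
#' @param q_threshold significance cutoff (default 0.05).
#' @return for `activity_dependent_de()`: tibble(`feature_id`, `cell_type`,
#'   `de_stimulated`, `de_baseline`, `activity_dependent`).
#' @export
activity_dependent_de <- function(de_results, q_threshold = 0.05) {
  de_results |>
    group_by(.data$feature_id, .data$cell_type) |>
    summarise(
      de_stimulated = any(.data$q < q_threshold & .data$time != "0h"),
      de_baseline = any(.data$q < q_threshold & .data$time == "0h"),
      .groups = "drop") |>
    mutate(activity_dependent = .data$de_stimulated & !.data$de_baseline)
}
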