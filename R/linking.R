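#' Link peaks to genes by co-activation across metacells
#'
#' Cells of one cell type are ordered by pseudotime and aggregated into
#' `n_metacells` equal-size contiguous metacells. For every candidate pair
#' (peak interval within `window_bp` of the gene TSS), the Pearson
#' correlation between the log1p-CPM metacell vectors is computed, with a
#' p-value from the t approximation and BH q across all candidate pairs of
#' the cell type.
#'
#' @param expr_counts,peak_counts `stim_counts` over the same cells.
#' @param cells cell annotations.
#' @param genes tibble(`gene_id`, `chrom`, `tss`).
#' @param peaks tibble(`peak_id`, `chrom`, `start`, `end`).
#' @param cell_type cell type analysed.
#' @param window_bp linking window around the TSS (default 250 kb).
#' @param n_metacells number of metacells (>= 5; default 50).
#' @return tibble(`peak_id`, `gene_id`, `cell_type`, `r`, `p`, `q`,
#'   `significant`).
#' @export
link_peaks <- function(expr_counts, peak_counts, cells, genes, peaks,
                       cell_type, window_bp = 2.5e5, n_metacells = 50) {
  if (n_metacells < 5) abort("n_metacells must be >= 5")
  cells <- check_cells(cells)
  sub <- cells[cells$cell_type == cell_type, ]
  sub <- sub[order(sub$pseudotime), ]
  if (nrow(sub) < n_metacells) abort("fewer cells than metacells")
  grp <- ceiling(seq_len(nrow(sub)) / (nrow(sub) / n_metacells))
  grp <- pmin(grp, n_metacells)
  E <- metacell_log1p_cpm(expr_counts$counts[, sub$cell_id, drop = FALSE], grp,
                          n_metacells)
  P <- metacell_log1p_cpm(peak_counts$counts[, sub$cell_id, drop = FALSE], grp,
                          n_metacells)
  cand <- candidate_pairs(genes, peaks, window_bp)
  if (nrow(cand) == 0) {
    return(tibble(peak_id = character(), gene_id = character(),
                  cell_type = character(), r = double(), p = double(),
                  q = double(), significant = logical()))
  }
  Es <- scale_rows(E)
  Ps <- scale_rows(P)
  m <- n_metacells
  r <- rowSums(Ps[cand$peak_id, , drop = FALSE] *
               Es[cand$gene_id, , drop = FALSE]) / (m - 1)
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((m - 2) / pmax(1e-12, 1 - r^2))
  p <- 2 * pt(-abs(tstat), df = m - 2)
  q <- p.adjust(p, method = "BH")
  tibble(peak_id = cand$peak_id, gene_id = cand$gene_id,
         cell_type = cell_type, r = r, p = p, q = q,
         significant = q < 0.05)
}

metacell_log1p_cpm <- function(m, grp, n_groups) {
  agg <- m %*% sparseMatrix(i = seq_along(grp), j = grp, x = 1,
                            dims = c(length(grp), n_groups))
  agg <- as.matrix(agg)
  lib <- colSums(agg)
  lib[lib == 0] <- 1
  log1p(sweep(agg, 2, 1e6 / lib, `*`))
}

# rows standardized to mean 0, SD 1 (zero-variance rows stay 0)
scale_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  out <- (m - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}

# peak-gene pairs with the peak interval within window_bp of the TSS
candidate_pairs <- function(genes, peaks, window_bp) {
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1, genes$tss - window_bp), genes$tss + window_bp))
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1, peaks$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gene_gr, peak_gr))
  tibble(gene_id = genes$gene_id[S4Vectors_from(hits)],
         peak_id = peaks$peak_id[S4Vectors_to(hits)])
}

#' Activity-by-contact enhancer-gene scores
#'
#' For each gene and time point, candidate enhancers are the peaks within
#' `candidate_window_bp` of the TSS; activity `A` is the mean CPM
#' accessibility of the peak at that time (averaged over donors and cell
#' types unless one is given), and contact `C` is the summed contact
#' frequency between the bins containing the peak midpoint and the TSS,
#' plus `pseudocount`. The ABC score is `A*C / sum(A*C)` over the gene's
#' candidates; per gene the scores sum to 1 whenever any candidate has
#' `A*C > 0`. Genes without candidates are omitted with a message.
#'
#' @param pb_peaks a `stim_pseudobulk` of peaks.
#' @param peaks,genes feature tables as in [link_peaks()].
#' @param contacts tibble from [read_contacts()] / [simulate_contacts()];
#'   anchor order is ignored (symmetric lookup).
#' @param time time point scored.
#' @param cell_type optional cell type restriction for the activity.
#' @param candidate_window_bp candidate window (default 500 kb).
#' @param pseudocount added to contact frequencies (default 0.1).
#' @return tibble(`gene_id`, `peak_id`, `time`, `activity`, `contact`,
#'   `score`).
#' @export
abc_scores <- function(pb_peaks, peaks, genes, contacts, time,
                       cell_type = NULL, candidate_window_bp = 5e5,
                       pseudocount = 0.1) {
  ctx <- pb_peaks$contexts[pb_peaks$contexts$time == time, ]
  if (!is.null(cell_type)) ctx <- ctx[ctx$cell_type == cell_type, ]
  if (nrow(ctx) == 0) abort(sprintf("no pseudobulk context at time %s", time))
  # mean linear-scale CPM activity per peak at this time
  act <- rowMeans(do.call(cbind, lapply(seq_len(nrow(ctx)), function(i) {
    colMeans(2^pb_matrix(pb_peaks, ctx$cell_type[i], ctx$time[i],
                         "log2cpm") - 1)
  })))
  cand <- candidate_pairs(genes, peaks, candidate_window_bp)
  no_cand <- setdiff(genes$gene_id, cand$gene_id)
  if (length(no_cand) > 0) {
    inform(sprintf("%d gene(s) have no candidate peaks; omitted",
                   length(no_cand)))
  }
  if (nrow(cand) == 0) {
    return(tibble(gene_id = character(), peak_id = character(),
                  time = character(), activity = double(),
                  contact = double(), score = double()))
  }
  ct <- contacts[contacts$time == time, ]
  mid <- (peaks$start + peaks$end) / 2
  names(mid) <- peaks$peak_id
  tss <- stats::setNames(genes$tss, genes$gene_id)
  gchr <- stats::setNames(genes$chrom, genes$gene_id)
  cand$contact <- contact_freq(ct, gchr[cand$gene_id], tss[cand$gene_id],
                               mid[cand$peak_id]) + pseudocount
  cand$activity <- unname(act[cand$peak_id])
  cand$time <- time
  cand |>
    group_by(.data$gene_id) |>
    mutate(score = {
      ac <- .data$activity * .data$contact
      if (sum(ac) > 0) ac / sum(ac) else 0
    }) |>
    ungroup() |>
    select("gene_id", "peak_id", "time", "activity", "contact", "score")
}

# symmetric contact lookup: summed freq of records whose anchor bins contain
# the two query points (either orientation)
contact_freq <- function(ct, chrom, pos_a, pos_b) {
  if (nrow(ct) == 0) return(rep(0, length(pos_a)))
  # match by containment using IRanges overlaps on both orientations
  q_a <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos_a, pos_a))
  q_b <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos_b, pos_b))
  r_a <- GenomicRanges::GRanges(ct$chrom_a,
                                IRanges::IRanges(ct$start_a + 1, ct$end_a))
  r_b <- GenomicRanges::GRanges(ct$chrom_b,
                                IRanges::IRanges(ct$start_b + 1, ct$end_b))
  out <- rep(0, length(pos_a))
  matches <- character(0)
  for (orient in 1:2) {
    ra <- if (orient == 1) r_a else r_b
    rb <- if (orient == 1) r_b else r_a
    ha <- suppressWarnings(GenomicRanges::findOverlaps(q_a, ra))
    hb <- suppressWarnings(GenomicRanges::findOverlaps(q_b, rb))
    pa <- paste(S4Vectors_from(ha), S4Vectors_to(ha))
    pb <- paste(S4Vectors_from(hb), S4Vectors_to(hb))
    matches <- c(matches, intersect(pa, pb))
  }
  matches <- unique(matches)   # a record is counted once per query pair
  if (length(matches) > 0) {
    ij <- do.call(rbind, strsplit(matches, " "))
    i <- as.integer(ij[, 1])
    j <- as.integer(ij[, 2])
    contrib <- tapply(ct$freq[j], i, sum)
    out[as.integer(names(contrib))] <- as.vector(contrib)
  }
  out
}

#' Overlap enrichment between co-activation links and ABC pairs
#'
#' Builds the 2x2 table {linked, not} x {ABC >= threshold, not} over the
#' candidate peak-gene universe (the pairs present in `abc`), and reports
#' the overlap fraction among linked pairs, the fold enrichment (as in
#' [geneset_enrichment()]) and the two-sided Fisher exact p.
#'
#' @param linked output of [link_peaks()].
#' @param abc output of [abc_scores()].
#' @param score_threshold ABC score cutoff (default 0.02).
#' @return tibble(`overlap_fraction`, `fold`, `odds_ratio`, `p`,
#'   `n_linked`, `n_abc`, `n_universe`).
#' @export
overlap_enrichment <- function(linked, abc, score_threshold = 0.02) {
  if (nrow(abc) == 0 || nrow(linked) == 0) {
    abort("linked and abc universes must be non-empty")
  }
  uni <- dplyr::distinct(abc[, c("peak_id", "gene_id")])
  abc_pos <- abc |>
    group_by(.data$peak_id, .data$gene_id) |>
    summarise(abc_hit = any(.data$score >= score_threshold),
              .groups = "drop")
  uni <- dplyr::left_join(uni, abc_pos, by = c("peak_id", "gene_id"))
  link_sig <- dplyr::distinct(linked[linked$significant,
                                     c("peak_id", "gene_id")])
  link_sig$linked <- TRUE
  uni <- dplyr::left_join(uni, link_sig, by = c("peak_id", "gene_id"))
  uni$linked[is.na(uni$linked)] <- FALSE
  a <- sum(uni$linked & uni$abc_hit)
  b <- sum(uni$linked & !uni$abc_hit)
  c_ <- sum(!uni$linked & uni$abc_hit)
  d <- sum(!uni$linked & !uni$abc_hit)
  ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
  n_link <- a + b
  fold <- if (n_link > 0 && (c_ + d) > 0 && c_ > 0) {
    (a / n_link) / (c_ / (c_ + d))
  } else NA_real_
  tibble(overlap_fraction = if (n_link > 0) a / n_link else NA_real_,
         fold = fold, odds_ratio = unname(ft$estimate), p = ft$p.value,
         n_linked = n_link, n_abc = a + c_, n_universe = nrow(uni))
}
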