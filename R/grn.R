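#' TF motif activity along pseudotime
#'
#' A simplified motif-deviation score. For each TF, the raw activity per
#' pseudotime bin is the mean raw (interpolated, non-z-scored) binned
#' accessibility over the TF's motif peaks. The background is
#' `n_background` random peak sets of the same size, matched on overall
#' mean accessibility by decile-stratified sampling; the reported activity
#' is the per-bin z-score against that background (background SD of 0 gives
#' z = 0). TFs with fewer than 5 assigned peaks are dropped with a message.
#'
#' @param peak_profiles a `stim_profiles` of peaks with `scale = "raw"`
#'   (from [bin_pseudotime()]).
#' @param motif_map tibble(`tf`, `peak_id`).
#' @param n_background number of matched background sets (default 100).
#' @param seed RNG seed for background sampling.
#' @return a `stim_motif_activity` object: list with `z` (TF x bin matrix),
#'   `cell_type`, `n_bins`.
#' @export
motif_activity <- function(peak_profiles, motif_map, n_background = 100,
                           seed = 1) {
  if (peak_profiles$scale != "raw") {
    abort("motif_activity needs raw-scale peak profiles (scale = 'raw')")
  }
  vals <- peak_profiles$values
  peak_mean <- peak_profiles$feature_mean
  decile <- cut(rank(peak_mean, ties.method = "first"),
                breaks = 10, labels = FALSE)
  names(decile) <- rownames(vals)
  by_decile <- split(rownames(vals), decile)
  set.seed(seed)
  tfs <- unique(motif_map$tf)
  zrows <- list()
  for (tf in tfs) {
    ids <- intersect(motif_map$peak_id[motif_map$tf == tf], rownames(vals))
    if (length(ids) < 5) {
      inform(sprintf("TF %s has < 5 assigned peaks; dropped", tf))
      next
    }
    raw <- colMeans(vals[ids, , drop = FALSE])
    dcount <- table(decile[ids])
    bg <- matrix(0, n_background, ncol(vals))
    for (b in seq_len(n_background)) {
      draw <- unlist(lapply(names(dcount), function(d) {
        pool <- by_decile[[d]]
        pool[sample.int(length(pool), dcount[[d]],
                        replace = dcount[[d]] > length(pool))]
      }), use.names = FALSE)
      bg[b, ] <- colMeans(vals[draw, , drop = FALSE])
    }
    mu <- colMeans(bg)
    s <- apply(bg, 2, sd)
    z <- ifelse(s > 0, (raw - mu) / s, 0)
    zrows[[tf]] <- z
  }
  if (length(zrows) == 0) abort("no TF retained (all < 5 peaks)")
  structure(list(z = do.call(rbind, zrows),
                 cell_type = peak_profiles$cell_type,
                 n_bins = peak_profiles$n_bins),
            class = "stim_motif_activity")
}

#' @export
print.stim_motif_activity <- function(x, ...) {
  cat(sprintf("<stim_motif_activity> %d TFs x %d bins (%s)\n",
              nrow(x$z), x$n_bins, x$cell_type))
  invisible(x)
}

#' Call early / late response TF regulators
#'
#' A TF is called for a phase when (a) its motif peaks are enriched among
#' the up-regulated differentially accessible peaks of the phase's contrast
#' (1h vs 0h for early, 6h vs 0h for late; Fisher exact over the tested
#' peak universe, BH `q < 0.05`) and (b) the TF gene itself is
#' differentially expressed in the same contrast (`q < 0.05`). Both gates
#' are required.
#'
#' @param da_results [da_peaks()] results for the phase contrast.
#' @param motif_map tibble(`tf`, `peak_id`).
#' @param tf_de [response_de()] results for the same contrast, containing
#'   the TF gene ids in `feature_id`.
#' @param phase `"early"` or `"late"` (annotation only; the contrast is
#'   carried by the inputs).
#' @param tf_genes optional named character mapping tf -> gene id when TF
#'   names differ from gene ids (default: identity).
#' @return tibble(`tf`, `cell_type`, `phase`, `odds_ratio`, `p`, `q`,
#'   `tf_de_q`, `called`).
#' @export
call_response_tfs <- function(da_results, motif_map, tf_de,
                              phase = c("early", "late"), tf_genes = NULL) {
  phase <- match.arg(phase)
  universe <- unique(da_results$feature_id)
  up_da <- unique(da_results$feature_id[da_results$q < 0.05 &
                                        da_results$lfc > 0])
  tfs <- unique(motif_map$tf)
  rows <- lapply(tfs, function(tf) {
    ids <- intersect(motif_map$peak_id[motif_map$tf == tf], universe)
    a <- length(intersect(ids, up_da))
    b <- length(ids) - a
    c_ <- length(up_da) - a
    d <- length(universe) - length(up_da) - b
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                      alternative = "greater")
    gene <- if (!is.null(tf_genes)) tf_genes[[tf]] else tf
    de_q <- tf_de$q[match(gene, tf_de$feature_id)]
    tibble(tf = tf, cell_type = da_results$cell_type[1], phase = phase,
           odds_ratio = unname(ft$estimate), p = ft$p.value,
           tf_de_q = ifelse(length(de_q) == 0, NA_real_, de_q))
  })
  out <- dplyr::bind_rows(rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$called <- out$q < 0.05 & !is.na(out$tf_de_q) & out$tf_de_q < 0.05
  out[, c("tf", "cell_type", "phase", "odds_ratio", "p", "q", "tf_de_q",
          "called")]
}

#' Infer TF-target regulatory edges over pseudotime
#'
#' For each candidate TF-gene pair -- the TF must have a motif in at least
#' one peak significantly linked to the gene (the candidacy gate), and the
#' gene must be differentially expressed in some condition -- computes the
#' Pearson correlation between the TF's motif-activity z profile and the
#' gene's binned expression profile, with significance from a circular-shift
#' permutation null (random cyclic rotations of the gene profile, seeded),
#' which respects the autocorrelation of bin profiles. BH q per cell type.
#'
#' @param activity a `stim_motif_activity`.
#' @param gene_profiles a z-scored `stim_profiles` of genes, same cell type
#'   and bin count.
#' @param linked_pairs [link_peaks()] output (significant rows are used).
#' @param motif_map tibble(`tf`, `peak_id`).
#' @param de_genes character vector of DE gene ids (targets are restricted
#'   to these).
#' @param n_perm number of random shifts (default 1000).
#' @param seed RNG seed.
#' @return tibble(`tf`, `target`, `cell_type`, `r`, `p`, `q`,
#'   `significant`).
#' @export
infer_grn <- function(activity, gene_profiles, linked_pairs, motif_map,
                      de_genes, n_perm = 1000, seed = 1) {
  stopifnot(activity$n_bins == gene_profiles$n_bins)
  n <- activity$n_bins
  links <- linked_pairs[linked_pairs$significant, c("peak_id", "gene_id")]
  cand <- dplyr::inner_join(motif_map, links, by = "peak_id",
                            relationship = "many-to-many")
  cand <- dplyr::distinct(cand[, c("tf", "gene_id")])
  cand <- cand[cand$gene_id %in% de_genes &
               cand$gene_id %in% rownames(gene_profiles$values) &
               cand$tf %in% rownames(activity$z), ]
  if (nrow(cand) == 0) {
    return(tibble(tf = character(), target = character(),
                  cell_type = character(), r = double(), p = double(),
                  q = double(), significant = logical()))
  }
  set.seed(seed)
  shift_draws <- matrix(sample.int(n - 1L, nrow(cand) * n_perm,
                                   replace = TRUE),
                        nrow(cand), n_perm)
  r_obs <- numeric(nrow(cand))
  p_perm <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- activity$z[cand$tf[i], ]
    g <- gene_profiles$values[cand$gene_id[i], ]
    cc <- circular_cors(a, g)            # cor at every cyclic shift of g
    r_obs[i] <- cc[1]
    perm <- cc[shift_draws[i, ] + 1L]
    p_perm[i] <- (1 + sum(abs(perm) >= abs(cc[1]))) / (n_perm + 1)
  }
  out <- tibble(tf = cand$tf, target = cand$gene_id,
                cell_type = activity$cell_type, r = r_obs, p = p_perm)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < 0.05
  out
}

# Pearson correlation of a with every cyclic rotation of g, via FFT
# (index k+1 = g rotated left by k bins)
circular_cors <- function(a, g) {
  n <- length(a)
  sa <- sd(a) * sqrt((n - 1) / n)
  sg <- sd(g) * sqrt((n - 1) / n)
  if (sa == 0 || sg == 0) return(rep(0, n))
  az <- (a - mean(a)) / sa
  gz <- (g - mean(g)) / sg
  cc <- Re(stats::fft(stats::fft(az) * Conj(stats::fft(gz)),
                      inverse = TRUE)) / n
  pmin(1, pmax(-1, cc / n))
}

#' TF-target enrichment for a risk-gene set
#'
#' Per TF (and cell type), Fisher's exact test of its significant targets
#' against a risk-gene list over a background gene universe; BH q across
#' TF x cell-type rows. TFs with no targets are skipped with a message.
#'
#' @param grn_edges [infer_grn()] output.
#' @param risk_genes character vector, subset of `background`.
#' @param background character vector of candidate target genes.
#' @return tibble(`tf`, `cell_type`, `n_targets`, `odds_ratio`, `p`, `q`).
#' @export
target_enrichment <- function(grn_edges, risk_genes, background) {
  if (!all(risk_genes %in% background)) {
    abort("risk_genes must be a subset of background")
  }
  groups <- dplyr::distinct(grn_edges[, c("tf", "cell_type")])
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    sub <- grn_edges[grn_edges$tf == groups$tf[i] &
                     grn_edges$cell_type == groups$cell_type[i] &
                     grn_edges$significant, ]
    targets <- intersect(unique(sub$target), background)
    if (length(targets) == 0) {
      inform(sprintf("TF %s has no significant targets; skipped",
                     groups$tf[i]))
      next
    }
    a <- length(intersect(targets, risk_genes))
    b <- length(targets) - a
    c_ <- length(setdiff(risk_genes, targets))
    d <- length(background) - a - b - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    rows[[length(rows) + 1]] <- tibble(
      tf = groups$tf[i], cell_type = groups$cell_type[i],
      n_targets = length(targets), odds_ratio = unname(ft$estimate),
      p = ft$p.value)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out$q <- p.adjust(out$p, method = "BH")
  out
}

#' Export a TF-target subnetwork as an edge list
#'
#' Filters significant GRN edges to a chosen TF set and target gene list
#' (e.g. selected regulators x risk genes).
#'
#' @param grn_edges [infer_grn()] output.
#' @param tfs,targets optional filters (NULL keeps all).
#' @return edge-list tibble sorted by |r|.
#' @export
grn_subnetwork <- function(grn_edges, tfs = NULL, targets = NULL) {
  out <- grn_edges[grn_edges$significant, ]
  if (!is.null(tfs)) out <- out[out$tf %in% tfs, ]
  if (!is.null(targets)) out <- out[out$target %in% targets, ]
  dplyr::arrange(out, dplyr::desc(abs(.data$r)))
}
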