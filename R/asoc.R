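#' Pool allelic counts across heterozygous donors
#'
#' Sums ref/alt read counts over heterozygous donors per (SNP, context) and
#' applies the coverage filters: pooled total >= `min_total` and number of
#' contributing het donors >= `min_donors`.
#'
#' @param allele_counts tibble(`snp_id`, `donor_id`, `cell_type`, `time`,
#'   `ref_count`, `alt_count`), optionally `peak_id` (carried through).
#' @param min_total minimum pooled read total (default 20).
#' @param min_donors minimum het donors (default 2).
#' @return tibble(`snp_id`, [`peak_id`,] `cell_type`, `time`, `ref_count`,
#'   `alt_count`, `n_donors`, `total`).
#' @export
aggregate_allele_counts <- function(allele_counts, min_total = 20,
                                    min_donors = 2) {
  if (min_total < 0 || min_donors < 0) abort("thresholds must be >= 0")
  keys <- intersect(c("snp_id", "peak_id", "cell_type", "time"),
                    names(allele_counts))
  out <- allele_counts |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(ref_count = sum(.data$ref_count),
              alt_count = sum(.data$alt_count),
              n_donors = dplyr::n_distinct(.data$donor_id),
              .groups = "drop") |>
    mutate(total = .data$ref_count + .data$alt_count)
  out[out$total >= min_total & out$n_donors >= min_donors, ]
}

#' Allele-specific open chromatin test
#'
#' Exact two-sided binomial test of the pooled alt count against
#' `Binomial(total, p0)`. For the symmetric null `p0 = 0.5` the two-sided
#' p-value has the closed form `min(1, 2 * P(X <= min(alt, ref)))`, which
#' equals the minimum-likelihood two-sided tail sum; for `p0 != 0.5` the
#' minimum-likelihood definition (as in `binom.test`) is used. BH q per
#' context; significant means `q < 0.05`.
#'
#' @param pooled output of [aggregate_allele_counts()].
#' @param p0 null alt-allele fraction (default 0.5; a fixed reference-bias
#'   prior can be supplied).
#' @return the input with added `alt_fraction`, `p`, `q`, `significant`.
#' @export
asoc_test <- function(pooled, p0 = 0.5) {
  if (any(pooled$total < 1)) abort("pooled totals must be >= 1")
  n <- pooled$total
  k <- pooled$alt_count
  if (p0 == 0.5) {
    p <- pmin(1, 2 * pbinom(pmin(k, n - k), n, 0.5))
  } else {
    p <- vapply(seq_along(n), function(i) {
      stats::binom.test(k[i], n[i], p = p0)$p.value
    }, numeric(1))
  }
  pooled$alt_fraction <- k / n
  pooled$p <- p
  pooled <- pooled |>
    group_by(.data$cell_type, .data$time) |>
    mutate(q = p.adjust(.data$p, method = "BH")) |>
    ungroup()
  pooled$significant <- pooled$q < 0.05
  pooled
}

#' Concordance between ASoC allelic ratios and caQTL effect sizes
#'
#' For SNP-context pairs present in both result sets (alleles aligned so
#' the caQTL effect allele is the alt allele; a flipped input is aligned by
#' negating beta), reports the Pearson correlation between the pooled log
#' allelic ratio `log(alt/ref)` and the caQTL beta, the zero-intercept
#' regression slope, and the sign concordance among pairs significant in
#' both analyses.
#'
#' @param asoc_results [asoc_test()] output.
#' @param caqtl_results caQTL tibble with `snp_id`, `cell_type`, `time`,
#'   `beta` and (optionally) `ref`/`alt` allele columns plus `significant`.
#' @param min_shared minimum number of shared pairs (default 10).
#' @return tibble(`r`, `slope`, `sign_concordance`, `n_pairs`,
#'   `n_both_significant`).
#' @export
caqtl_concordance <- function(asoc_results, caqtl_results, min_shared = 10) {
  joined <- dplyr::inner_join(
    asoc_results, caqtl_results,
    by = c("snp_id", "cell_type", "time"), suffix = c("_asoc", "_caqtl"))
  joined <- joined[joined$ref_count > 0 & joined$alt_count > 0, ]
  if (nrow(joined) < min_shared) {
    abort(sprintf("only %d shared SNP-context pairs (need >= %d)",
                  nrow(joined), min_shared))
  }
  beta <- joined$beta
  if (all(c("ref_asoc", "alt_asoc", "ref_caqtl", "alt_caqtl") %in%
          names(joined))) {
    flip <- joined$ref_caqtl == joined$alt_asoc &
      joined$alt_caqtl == joined$ref_asoc
    beta <- ifelse(flip, -beta, beta)
  }
  x <- log(joined$alt_count / joined$ref_count)
  sig_cols <- intersect(c("significant_asoc", "significant_caqtl"),
                        names(joined))
  both_sig <- if (length(sig_cols) == 2) {
    joined[[sig_cols[1]]] & joined[[sig_cols[2]]]
  } else rep(TRUE, nrow(joined))
  tibble(r = cor(x, beta),
         slope = sum(x * beta) / sum(x^2),
         sign_concordance = if (any(both_sig)) {
           mean(sign(x[both_sig]) == sign(beta[both_sig]))
         } else NA_real_,
         n_pairs = nrow(joined),
         n_both_significant = sum(both_sig))
}

#' Intersect GWAS index SNPs with ASoC through LD proxies
#'
#' For each GWAS index SNP, the proxy set contains the index itself plus
#' every SNP whose dosage r-squared with the index exceeds `r2_threshold`
#' (strict, following the r^2 > 0.8 convention). A locus is flagged
#' "ASoC-explained" in a context when any proxy is significant ASoC there.
#' The summary contrasts loci explained at baseline (0h) with loci explained
#' in any stimulated context.
#'
#' @param asoc_results [asoc_test()] output.
#' @param index_snps character vector of GWAS index SNP ids.
#' @param genotypes a `stim_genotypes` (for dosage LD).
#' @param r2_threshold proxy threshold (default 0.8).
#' @return a list with `loci` (tibble: `index_snp`, `cell_type`, `time`,
#'   `flagged`, `supporting_snps`) and `summary` (tibble: `index_snp`,
#'   `explained_0h`, `explained_stimulated`).
#' @export
gwas_ld_intersect <- function(asoc_results, index_snps, genotypes,
                              r2_threshold = 0.8) {
  if (r2_threshold <= 0 || r2_threshold > 1) {
    abort("r2_threshold must lie in (0, 1]")
  }
  dos <- genotypes$dosage
  sig <- asoc_results[asoc_results$significant, ]
  loci <- list()
  for (idx in index_snps) {
    if (!idx %in% colnames(dos)) {
      inform(sprintf("index SNP %s absent from genotypes; skipped", idx))
      next
    }
    r2 <- suppressWarnings(cor(dos[, idx], dos))[1, ]^2
    r2[idx] <- 1
    proxies <- colnames(dos)[!is.na(r2) & r2 > r2_threshold]
    proxies <- union(proxies, idx)       # self-proxy always counts
    hits <- sig[sig$snp_id %in% proxies, ]
    ctx <- dplyr::distinct(asoc_results[, c("cell_type", "time")])
    for (i in seq_len(nrow(ctx))) {
      sup <- hits$snp_id[hits$cell_type == ctx$cell_type[i] &
                         hits$time == ctx$time[i]]
      loci[[length(loci) + 1]] <- tibble(
        index_snp = idx, cell_type = ctx$cell_type[i], time = ctx$time[i],
        flagged = length(sup) > 0,
        supporting_snps = paste(sup, collapse = ","))
    }
  }
  loci <- dplyr::bind_rows(loci)
  summary <- loci |>
    group_by(.data$index_snp) |>
    summarise(explained_0h = any(.data$flagged & .data$time == "0h"),
              explained_stimulated = any(.data$flagged & .data$time != "0h"),
              .groups = "drop")
  list(loci = loci, summary = summary)
}
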