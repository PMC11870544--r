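#' Build per-context donor pseudobulk
#'
#' Sums counts per donor within each (cell type, time) context, normalizes
#' to log2(CPM + 1), and applies a rank-based inverse-normal transform
#' (rankit, \eqn{\Phi^{-1}((r - 0.5)/n)}) per feature across donors within
#' the context. Donors contributing fewer than `min_cells` cells to a
#' context are excluded there and recorded.
#'
#' @param counts a `stim_counts` (features x cells).
#' @param cells cell annotation tibble (`cell_id`, `donor_id`, `cell_type`,
#'   `time`, and `pseudotime`).
#' @param min_cells minimum cells per donor and context (>= 1).
#' @return a `stim_pseudobulk` object: list with `contexts` (tibble),
#'   and per-context entries `log2cpm` and `int` (donor x feature matrices),
#'   plus `cell_counts` and `excluded` bookkeeping tibbles.
#' @export
pseudobulk <- function(counts, cells, min_cells = 10) {
  if (min_cells < 1) abort("min_cells must be >= 1")
  cells <- check_cells(cells)
  m <- counts$counts
  cells <- cells[cells$cell_id %in% colnames(m), ]
  ctx_tab <- dplyr::distinct(cells[, c("cell_type", "time")])
  ctx_tab <- dplyr::arrange(ctx_tab, .data$cell_type, .data$time)
  mats <- list()
  counts_tab <- list()
  excluded <- list()
  for (i in seq_len(nrow(ctx_tab))) {
    ct <- ctx_tab$cell_type[i]
    tm <- ctx_tab$time[i]
    sub <- cells[cells$cell_type == ct & cells$time == tm, ]
    ncell <- table(sub$donor_id)
    keep_donors <- names(ncell)[ncell >= min_cells]
    drop_donors <- setdiff(names(ncell), keep_donors)
    if (length(drop_donors) > 0) {
      excluded[[length(excluded) + 1]] <-
        tibble(cell_type = ct, time = tm, donor_id = drop_donors,
               n_cells = as.integer(ncell[drop_donors]))
    }
    sub <- sub[sub$donor_id %in% keep_donors, ]
    groups <- factor(sub$donor_id, levels = sort(keep_donors))
    msub <- m[, sub$cell_id, drop = FALSE]
    agg <- msub %*% sparseMatrix(i = seq_len(ncol(msub)),
                                 j = as.integer(groups), x = 1,
                                 dims = c(ncol(msub), nlevels(groups)))
    agg <- t(as.matrix(agg))            # donors x features
    rownames(agg) <- levels(groups)
    colnames(agg) <- rownames(m)
    lib <- rowSums(agg)
    lib[lib == 0] <- 1
    log2cpm <- log2(agg / lib * 1e6 + 1)
    int <- apply(log2cpm, 2, inverse_normal_transform)
    rownames(int) <- rownames(log2cpm)
    lab <- context_label(ct, tm)
    mats[[lab]] <- list(log2cpm = log2cpm, int = int)
    counts_tab[[length(counts_tab) + 1]] <-
      tibble(cell_type = ct, time = tm, donor_id = levels(groups),
             n_cells = as.integer(ncell[levels(groups)]))
  }
  structure(list(contexts = ctx_tab, mats = mats,
                 cell_counts = dplyr::bind_rows(counts_tab),
                 excluded = if (length(excluded)) dplyr::bind_rows(excluded)
                            else tibble(cell_type = character(),
                                        time = character(),
                                        donor_id = character(),
                                        n_cells = integer()),
                 min_cells = min_cells),
            class = "stim_pseudobulk")
}

#' @export
print.stim_pseudobulk <- function(x, ...) {
  cat(sprintf("<stim_pseudobulk> %d contexts, %d features\n",
              nrow(x$contexts), ncol(x$mats[[1]]$log2cpm)))
  invisible(x)
}

#' Rank-based inverse-normal transform
#'
#' Maps values to normal quantiles by rank: \eqn{\Phi^{-1}((r - 0.5)/n)}.
#' Ties get average ranks.
#'
#' @param x numeric vector.
#' @return transformed vector (mean approximately 0, SD approximately 1).
#' @export
inverse_normal_transform <- function(x) {
  qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

# pull the donor x feature matrix of one context, with existence check
pb_matrix <- function(pb, cell_type, time, scale = c("int", "log2cpm")) {
  scale <- match.arg(scale)
  lab <- context_label(cell_type, time)
  if (!lab %in% names(pb$mats)) {
    abort(sprintf("context %s not present in pseudobulk", lab))
  }
  pb$mats[[lab]][[scale]]
}

#' Map cis QTL per context by ordinary least squares
#'
#' For each feature and context, regresses the inverse-normal pseudobulk on
#' dosage plus covariates for every cis SNP (window from [cis_window()]:
#' default half-width 100 kb around a gene TSS, 25 kb around a peak). The
#' lead SNP is the minimum nominal p; the feature-level p is Bonferroni
#' (`min(1, p_lead * n_cis)`), and q is BH across features within each
#' context. A feature is an eGene/cPeak when `q < 0.05`.
#'
#' Covariates default to the top `n_geno_pc` genotype PCs plus the top
#' `n_pheno_pc` phenotype (expression/accessibility) PCs of the context.
#' Monomorphic cis SNPs are skipped; a covariate collinear with a tested
#' dosage raises a rank-deficiency error.
#'
#' @param pb a `stim_pseudobulk`.
#' @param genotypes a `stim_genotypes`.
#' @param features tibble of gene (`gene_id`, `chrom`, `tss`) or peak
#'   (`peak_id`, `chrom`, `start`, `end`) records.
#' @param kind `"gene"` or `"peak"` (sets the id column and default window).
#' @param cis_bp cis half-width in bp; default 1e5 for genes, 2.5e4 for
#'   peaks.
#' @param contexts optional tibble(`cell_type`, `time`) subset.
#' @param n_geno_pc,n_pheno_pc numbers of genotype / phenotype PCs used as
#'   covariates (0 disables).
#' @param covariates optional extra donor-level covariate matrix
#'   (rownames = donor ids).
#' @param keep `"lead"` (default) returns one row per feature-context;
#'   `"all"` returns every cis SNP tested (q is only defined on leads).
#' @return tibble: `feature_id`, `cell_type`, `time`, `snp_id`, `beta`,
#'   `se`, `p_nominal`, `n_cis`, `lead`, `p_feature`, `q`, `significant`.
#' @export
map_qtl <- function(pb, genotypes, features, kind = c("gene", "peak"),
                    cis_bp = NULL, contexts = NULL,
                    n_geno_pc = 3, n_pheno_pc = 5, covariates = NULL,
                    keep = c("lead", "all")) {
  kind <- match.arg(kind)
  keep <- match.arg(keep)
  id_col <- if (kind == "gene") "gene_id" else "peak_id"
  if (is.null(cis_bp)) cis_bp <- if (kind == "gene") 1e5 else 2.5e4
  feats <- cis_window(features, cis_bp)
  if (is.null(contexts)) contexts <- pb$contexts
  geno_pcs <- genotype_pcs(genotypes, n_geno_pc)
  out <- vector("list", nrow(contexts))
  for (i in seq_len(nrow(contexts))) {
    ct <- contexts$cell_type[i]
    tm <- contexts$time[i]
    Y <- pb_matrix(pb, ct, tm, "int")
    donors <- intersect(rownames(Y), rownames(genotypes$dosage))
    if (length(donors) < 10) {
      abort(sprintf("context %s retains fewer than 10 donors",
                    context_label(ct, tm)))
    }
    Y <- Y[donors, , drop = FALSE]
    G <- genotypes$dosage[donors, , drop = FALSE]
    C <- cbind(`(Intercept)` = rep(1, length(donors)))
    if (n_geno_pc > 0) C <- cbind(C, geno_pcs[donors, , drop = FALSE])
    if (n_pheno_pc > 0) {
      k <- min(n_pheno_pc, nrow(Y) - 1, ncol(Y))
      pc <- prcomp(Y, center = TRUE, scale. = FALSE)$x[, seq_len(k),
                                                       drop = FALSE]
      colnames(pc) <- paste0("phenoPC", seq_len(k))
      C <- cbind(C, pc)
    }
    if (!is.null(covariates)) C <- cbind(C, covariates[donors, , drop = FALSE])
    if (qr(C)$rank < ncol(C)) abort("covariate matrix is rank deficient")
    res <- qtl_ols_context(Y, G, C, feats, id_col, genotypes$snps)
    if (nrow(res) > 0) {
      res$cell_type <- ct
      res$time <- tm
      out[[i]] <- res
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(res)
  leads <- res[res$lead, ]
  leads <- leads |>
    group_by(.data$cell_type, .data$time) |>
    mutate(q = p.adjust(.data$p_feature, method = "BH")) |>
    ungroup()
  leads$significant <- leads$q < 0.05
  if (keep == "lead") {
    return(dplyr::arrange(leads, .data$cell_type, .data$time,
                          .data$feature_id))
  }
  res <- dplyr::left_join(
    res, leads[, c("feature_id", "cell_type", "time", "snp_id", "q",
                   "significant")],
    by = c("feature_id", "cell_type", "time", "snp_id"))
  dplyr::arrange(res, .data$cell_type, .data$time, .data$feature_id,
                 .data$p_nominal)
}

genotype_pcs <- function(genotypes, n_pc) {
  if (n_pc <= 0) return(NULL)
  X <- genotypes$dosage
  keep <- apply(X, 2, sd) > 0
  k <- min(n_pc, nrow(X) - 1, sum(keep))
  pc <- prcomp(X[, keep, drop = FALSE], center = TRUE,
               scale. = TRUE)$x[, seq_len(k), drop = FALSE]
  colnames(pc) <- paste0("genoPC", seq_len(k))
  pc
}

# one context: residualized OLS per feature over its cis SNPs
qtl_ols_context <- function(Y, G, C, feats, id_col, snps) {
  n <- nrow(Y)
  qC <- qr(C)
  Yr <- qr.resid(qC, Y)
  Gr <- qr.resid(qC, G)
  g_ss <- colSums(Gr^2)
  g_raw_var <- apply(G, 2, var)
  df <- n - ncol(C) - 1
  if (df < 1) abort("not enough donors for the covariate set")
  rows <- vector("list", nrow(feats))
  for (f in seq_len(nrow(feats))) {
    fid <- feats[[id_col]][f]
    if (!fid %in% colnames(Yr)) next
    cis <- cis_snp_ids(feats[f, ], snps)
    cis <- cis[cis %in% colnames(Gr)]
    if (length(cis) == 0) {
      inform(sprintf("feature %s has no cis SNPs; skipped", fid))
      next
    }
    poly <- g_ss[cis] > 1e-10
    if (any(!poly & g_raw_var[cis] > 1e-10)) {
      abort("rank deficiency: a covariate is collinear with a tested dosage")
    }
    cis <- cis[poly]
    if (length(cis) == 0) next
    y <- Yr[, fid]
    gss <- g_ss[cis]
    beta <- as.vector(crossprod(Gr[, cis, drop = FALSE], y)) / gss
    rss <- sum(y^2) - beta^2 * gss
    rss[rss < 0] <- 0
    se <- sqrt(rss / df / gss)
    tstat <- beta / se
    pval <- 2 * pt(-abs(tstat), df)
    lead <- which.min(pval)
    rows[[f]] <- tibble(
      feature_id = fid, snp_id = cis, beta = beta, se = se,
      p_nominal = pval, n_cis = length(cis),
      lead = seq_along(cis) == lead,
      p_feature = pmin(1, pval * length(cis)))
  }
  dplyr::bind_rows(rows)
}

#' Dynamic (genotype-by-time interaction) QTL test
#'
#' Stacks a feature's inverse-normal pseudobulk across the three time points
#' of one cell type and fits the linear mixed model
#' `y ~ G * time + (1 | donor)` (donor random intercept absorbing
#' non-genetic differences between lines; \pkg{lmerTest} fit with
#' Satterthwaite degrees of freedom). Wald tests are reported for the two
#' interaction contrasts (1h-0h and 6h-0h) and jointly (2 df). When the
#' donor variance component collapses to the boundary the model is refit by
#' OLS with a note. BH q-values are computed per cell type and contrast; a
#' feature is classified `dynamic` when either contrast has `q < 0.05`.
#'
#' @param pb a `stim_pseudobulk` containing all three time points of
#'   `cell_type`.
#' @param genotypes a `stim_genotypes`.
#' @param lead_snps tibble(`feature_id`, `snp_id`): the SNP tested per
#'   feature (typically lead eQTL/caQTL, or the union over contexts).
#' @param cell_type cell type analysed.
#' @param covariates optional donor-level covariate matrix.
#' @return tibble with interaction effects, per-contrast Wald p and q, the
#'   joint 2-df p, and `class` (`"dynamic"`/`"static"`).
#' @export
dynamic_qtl <- function(pb, genotypes, lead_snps, cell_type,
                        covariates = NULL) {
  times <- stim_times()
  mats <- lapply(times, function(tm) pb_matrix(pb, cell_type, tm, "int"))
  names(mats) <- times
  donors <- Reduce(intersect, c(lapply(mats, rownames),
                                list(rownames(genotypes$dosage))))
  if (length(donors) < 10) abort("fewer than 10 donors shared across times")
  rows <- vector("list", nrow(lead_snps))
  n_singular <- 0L
  for (i in seq_len(nrow(lead_snps))) {
    fid <- lead_snps$feature_id[i]
    snp <- lead_snps$snp_id[i]
    if (!fid %in% colnames(mats[[1]]) ||
        !snp %in% colnames(genotypes$dosage)) next
    df <- dplyr::bind_rows(lapply(times, function(tm) {
      tibble(y = mats[[tm]][donors, fid], donor = donors, time = tm)
    }))
    df$time <- factor(df$time, levels = times)
    df$G <- genotypes$dosage[df$donor, snp]
    if (var(df$G) < 1e-10) next
    if (!is.null(covariates)) {
      cv <- covariates[df$donor, , drop = FALSE]
      colnames(cv) <- paste0("cv", seq_len(ncol(cv)))
      df <- dplyr::bind_cols(df, as_tibble(cv))
      form <- as.formula(paste("y ~ G * time +",
                               paste(colnames(cv), collapse = " + "),
                               "+ (1 | donor)"))
    } else {
      form <- y ~ G * time + (1 | donor)
    }
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = df,
                     control = lme4::lmerControl(check.conv.singular =
                       lme4::.makeCC(action = "ignore", tol = 1e-4)))))
    res <- if (lme4::isSingular(fit, tol = 1e-4)) {
      n_singular <- n_singular + 1L
      wald_ols(form, df)
    } else {
      wald_lmm(fit)
    }
    rows[[i]] <- tibble(feature_id = fid, cell_type = cell_type,
                        snp_id = snp,
                        beta_gxt_1h = res$b[1], p_1h = res$p[1],
                        beta_gxt_6h = res$b[2], p_6h = res$p[2],
                        p_joint = res$p_joint)
  }
  if (n_singular > 0) {
    inform(sprintf("%d feature(s) had a boundary donor variance; refit as OLS",
                   n_singular))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$q_1h <- p.adjust(out$p_1h, method = "BH")
  out$q_6h <- p.adjust(out$p_6h, method = "BH")
  out$q_joint <- p.adjust(out$p_joint, method = "BH")
  out$class <- ifelse(out$q_1h < 0.05 | out$q_6h < 0.05, "dynamic", "static")
  out
}

# Satterthwaite Wald tests on the two interaction terms of a lmerTest fit
wald_lmm <- function(fit) {
  cf <- summary(fit)$coefficients
  ix <- grep("^G:time", rownames(cf))
  L <- matrix(0, 2, nrow(cf))
  L[1, ix[1]] <- 1
  L[2, ix[2]] <- 1
  joint <- lmerTest::contest(fit, L, joint = TRUE)
  list(b = cf[ix, "Estimate"], p = cf[ix, "Pr(>|t|)"],
       p_joint = joint[["Pr(>F)"]])
}

# OLS fallback when the random intercept is at the boundary
wald_ols <- function(form, df) {
  form_fix <- lme4::nobars(form)
  fit <- lm(form_fix, data = df)
  cf <- summary(fit)$coefficients
  ix <- grep("^G:time", rownames(cf))
  red <- lm(stats::update(form_fix, . ~ . - G:time), data = df)
  an <- stats::anova(red, fit)
  list(b = cf[ix, "Estimate"], p = cf[ix, "Pr(>|t|)"],
       p_joint = an[["Pr(>F)"]][2])
}

#' Storey's pi1 estimate of the non-null fraction
#'
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (n (1 - \lambda))} over a
#' lambda grid, smoothed with a cubic spline and evaluated at the largest
#' lambda; \eqn{\pi_1 = 1 - \hat\pi_0}, clipped to [0, 1].
#'
#' @param pvalues numeric p-values in [0, 1]; at least 50 required.
#' @param lambda evaluation grid (default 0.05 to 0.9 by 0.05).
#' @return tibble with `pi1`, `pi0`, `n`, `lambda_max`.
#' @export
pi1 <- function(pvalues, lambda = seq(0.05, 0.9, by = 0.05)) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) < 50) abort("pi1 needs at least 50 p-values")
  if (any(pvalues < 0 | pvalues > 1)) abort("p-values must lie in [0, 1]")
  pi0_grid <- vapply(lambda, function(l) mean(pvalues > l) / (1 - l),
                     numeric(1))
  fit <- smooth.spline(lambda, pi0_grid, df = 3)
  pi0 <- predict(fit, x = max(lambda))$y
  pi0 <- min(max(pi0, 0), 1)
  tibble(pi1 = 1 - pi0, pi0 = pi0, n = length(pvalues),
         lambda_max = max(lambda))
}

#' Effect-size concordance between two QTL result sets
#'
#' Matches results on (feature, SNP and optionally context), aligns effect
#' alleles (flipping the second beta where ref/alt are swapped), and
#' reports the sign-agreement fraction, the zero-intercept regression slope
#' of `beta_b` on `beta_a`, and the Pearson correlation.
#'
#' @param qtl_a,qtl_b QTL tibbles with `feature_id`, `snp_id`, `beta`, and
#'   optionally `ref`/`alt` columns and `cell_type`/`time`.
#' @param match_on join keys (default feature, snp and any shared context
#'   columns).
#' @return tibble with `sign_concordance`, `slope`, `r`, `n_pairs`.
#' @export
qtl_concordance <- function(qtl_a, qtl_b,
                            match_on = intersect(
                              c("feature_id", "snp_id", "cell_type", "time"),
                              intersect(names(qtl_a), names(qtl_b)))) {
  joined <- dplyr::inner_join(qtl_a, qtl_b, by = match_on,
                              suffix = c("_a", "_b"))
  if (nrow(joined) == 0) abort("no overlapping (feature, SNP) pairs")
  beta_b <- joined$beta_b
  if (all(c("ref_a", "alt_a", "ref_b", "alt_b") %in% names(joined))) {
    same <- joined$ref_a == joined$ref_b & joined$alt_a == joined$alt_b
    flipped <- joined$ref_a == joined$alt_b & joined$alt_a == joined$ref_b
    keep <- same | flipped
    if (!all(keep)) {
      warn(sprintf("%d pairs dropped: alleles do not match",
                   sum(!keep)))
    }
    joined <- joined[keep, ]
    beta_b <- ifelse(flipped[keep], -joined$beta_b, joined$beta_b)
  }
  a <- joined$beta_a
  tibble(sign_concordance = mean(sign(a) == sign(beta_b)),
         slope = sum(a * beta_b) / sum(a^2),
         r = cor(a, beta_b),
         n_pairs = nrow(joined))
}

#' Cross-context sharing of QTL signals
#'
#' For every ordered pair of contexts, reports the fraction of context A's
#' significant features whose lead SNP replicates in context B (nominal
#' p < 0.05 with the same sign) and Storey's pi1 of A's lead SNPs evaluated
#' on B's p-values.
#'
#' @param qtl_by_context lead-level QTL tibble over >= 2 contexts (from
#'   [map_qtl()], `keep = "lead"`), plus matching all-SNP results in
#'   `lookup` used to evaluate A's leads in B.
#' @param lookup tibble with `feature_id`, `snp_id`, `cell_type`, `time`,
#'   `beta`, `p_nominal` covering all contexts (e.g. [map_qtl()] with
#'   `keep = "all"`).
#' @return tibble(`context_a`, `context_b`, `n_significant`, `replication`,
#'   `pi1`).
#' @export
sharing_matrix <- function(qtl_by_context, lookup = qtl_by_context) {
  ctx <- dplyr::distinct(qtl_by_context[, c("cell_type", "time")])
  if (nrow(ctx) < 2) abort("sharing_matrix needs >= 2 contexts")
  out <- list()
  for (i in seq_len(nrow(ctx))) for (j in seq_len(nrow(ctx))) {
    if (i == j) next
    a <- qtl_by_context[qtl_by_context$cell_type == ctx$cell_type[i] &
                        qtl_by_context$time == ctx$time[i] &
                        qtl_by_context$significant, ]
    b <- lookup[lookup$cell_type == ctx$cell_type[j] &
                lookup$time == ctx$time[j], ]
    m <- dplyr::inner_join(a, b, by = c("feature_id", "snp_id"),
                           suffix = c("_a", "_b"))
    rep_frac <- if (nrow(m) == 0) NA_real_ else
      mean(m$p_nominal_b < 0.05 & sign(m$beta_a) == sign(m$beta_b))
    p1 <- if (nrow(m) >= 50) pi1(m$p_nominal_b)$pi1 else NA_real_
    out[[length(out) + 1]] <- tibble(
      context_a = context_label(ctx$cell_type[i], ctx$time[i]),
      context_b = context_label(ctx$cell_type[j], ctx$time[j]),
      n_significant = nrow(a), replication = rep_frac, pi1 = p1)
  }
  dplyr::bind_rows(out)
}
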