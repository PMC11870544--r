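#' Build molecular-trait prediction models
#'
#' One single-SNP model per significant feature-context: for genes the lead
#' eQTL SNP with weight = standardized effect (`beta * sd(dosage)`, the
#' phenotype being inverse-normal and hence unit variance); for peaks the
#' universe is the union of cPeaks with a caQTL or a significant ASoC
#' variant, and the weight SNP is whichever of the two has the smaller
#' p-value (ASoC weight = pooled log allelic ratio). Traits failing the
#' quality gate `|weight|/se >= quality_z` (where an se is available) are
#' dropped.
#'
#' @param qtl_results lead-level [map_qtl()] output (`keep = "lead"`).
#' @param genotypes a `stim_genotypes` (for dosage SDs).
#' @param kind `"gene"` or `"peak"`.
#' @param asoc_results optional [asoc_test()] output with a `peak_id`
#'   column (peaks only).
#' @param q_threshold significance gate on the QTL side (default 0.05).
#' @param quality_z weight quality gate (default 2; QTL leads at q < 0.05
#'   virtually always pass).
#' @return tibble(`trait_id`, `feature_id`, `cell_type`, `time`, `group`,
#'   `snp_id`, `weight`, `source`).
#' @export
build_trait_models <- function(qtl_results, genotypes,
                               kind = c("gene", "peak"),
                               asoc_results = NULL, q_threshold = 0.05,
                               quality_z = 2) {
  kind <- match.arg(kind)
  sdg <- apply(genotypes$dosage, 2, sd)
  qtl <- qtl_results[qtl_results$q < q_threshold, ]
  qtl <- qtl[abs(qtl$beta) / qtl$se >= quality_z, ]
  models <- tibble(
    feature_id = qtl$feature_id, cell_type = qtl$cell_type,
    time = qtl$time, snp_id = qtl$snp_id,
    weight = qtl$beta * unname(sdg[qtl$snp_id]),
    p = qtl$p_nominal, source = if (kind == "gene") "eqtl" else "caqtl")
  if (kind == "peak" && !is.null(asoc_results)) {
    asoc <- asoc_results[asoc_results$significant, ]
    if (nrow(asoc) > 0) {
      if (!"peak_id" %in% names(asoc)) {
        abort("asoc_results must carry a peak_id column to enter peak models")
      }
      am <- tibble(
        feature_id = asoc$peak_id, cell_type = asoc$cell_type,
        time = asoc$time, snp_id = asoc$snp_id,
        weight = unname(log(pmax(asoc$alt_count, 0.5) /
                              pmax(asoc$ref_count, 0.5))),
        p = asoc$p, source = "asoc")
      models <- dplyr::bind_rows(models, am)
    }
  }
  if (nrow(models) == 0) {
    return(tibble(trait_id = character(), feature_id = character(),
                  cell_type = character(), time = character(),
                  group = character(), snp_id = character(),
                  weight = double(), source = character()))
  }
  # top variant per feature-context, by p-value, across sources
  models <- models |>
    group_by(.data$feature_id, .data$cell_type, .data$time) |>
    slice_min(.data$p, n = 1, with_ties = FALSE) |>
    ungroup()
  models$trait_id <- paste(models$feature_id,
                           context_label(models$cell_type, models$time),
                           sep = "|")
  if (anyDuplicated(models$trait_id)) abort("duplicate trait ids")
  models$group <- kind
  models[, c("trait_id", "feature_id", "cell_type", "time", "group",
             "snp_id", "weight", "source")]
}

#' Impute trait association z-scores from GWAS summary statistics
#'
#' Standard TWAS imputation: `z_trait = (w' z) / sqrt(w' R w)` over the
#' trait's weight SNPs within their LD block. For a single-SNP weight this
#' reduces to `sign(w) * z_snp`. Traits whose weight SNPs span blocks or
#' with non-positive `w'Rw` are dropped with a message.
#'
#' @param trait_models [build_trait_models()] output (one or more rows per
#'   trait).
#' @param gwas a `stim_gwas`.
#' @return tibble(`trait_id`, `group`, `block`, `z`, plus weight metadata
#'   for downstream augmentation).
#' @export
impute_trait_z <- function(trait_models, gwas) {
  snp_block <- stats::setNames(gwas$snp$block, gwas$snp$snp_id)
  z_snp <- stats::setNames(gwas$snp$z, gwas$snp$snp_id)
  out <- list()
  for (tid in unique(trait_models$trait_id)) {
    tm <- trait_models[trait_models$trait_id == tid, ]
    if (!all(tm$snp_id %in% names(snp_block))) {
      inform(sprintf("trait %s has weight SNPs outside the GWAS panel", tid))
      next
    }
    blocks <- unique(snp_block[tm$snp_id])
    if (length(blocks) > 1) {
      inform(sprintf("trait %s spans LD blocks; dropped", tid))
      next
    }
    R <- gwas$blocks[[blocks]]$R
    ids <- gwas$blocks[[blocks]]$snp_id
    w <- stats::setNames(rep(0, length(ids)), ids)
    w[tm$snp_id] <- tm$weight
    wRw <- as.numeric(t(w) %*% R %*% w)
    if (wRw <= 0) {
      inform(sprintf("trait %s has non-positive w'Rw; dropped", tid))
      next
    }
    out[[length(out) + 1]] <- tibble(
      trait_id = tid, group = tm$group[1], block = blocks,
      z = sum(w * z_snp[ids]) / sqrt(wRw))
  }
  dplyr::bind_rows(out)
}

#' Augment an LD block with imputed traits
#'
#' Builds the joint correlation matrix over the block's SNPs plus its
#' traits: trait-SNP correlation is `w'R_col / sqrt(w'Rw)` and trait-trait
#' correlation follows from the same bilinear form.
#'
#' @param block one element of `gwas$blocks`.
#' @param trait_models weight rows for traits in this block.
#' @param trait_z imputed z rows ([impute_trait_z()]) for this block.
#' @param z_snp named SNP z-scores.
#' @return list(`z`, `R`, `groups`, `variable`) ready for
#'   [finemap_block()].
#' @export
augment_block <- function(block, trait_models, trait_z, z_snp) {
  ids <- block$snp_id
  R <- block$R
  tids <- trait_z$trait_id
  k <- length(tids)
  W <- matrix(0, length(ids), k, dimnames = list(ids, tids))
  for (tid in tids) {
    tm <- trait_models[trait_models$trait_id == tid, ]
    W[tm$snp_id, tid] <- tm$weight
  }
  denom <- sqrt(pmax(diag(t(W) %*% R %*% W), 1e-12))
  cross <- R %*% W %*% diag(1 / denom, k, k)     # SNP x trait correlations
  tt <- diag(1 / denom, k, k) %*% (t(W) %*% R %*% W) %*% diag(1 / denom, k, k)
  Ra <- rbind(cbind(R, cross), cbind(t(cross), tt))
  vars <- c(ids, tids)
  dimnames(Ra) <- list(vars, vars)
  groups <- c(rep("snp", length(ids)), trait_z$group)
  z <- c(z_snp[ids], stats::setNames(trait_z$z, tids))
  list(z = z, R = Ra, groups = groups, variable = vars)
}

#' Fine-map one block by Bayesian single-effect regression
#'
#' Summary-statistic fine-mapping over a block's variables (SNPs and
#' imputed molecular traits). Each of `L` single-effect components assigns,
#' per variable, a Bayes factor for a normal effect prior with the
#' variable's group variance `sigma2[group]`; inclusion weights are
#' proportional to the prior odds times the Bayes factor,
#' `pi[group]/(1 - pi[group]) * BF`, with an explicit null option of
#' weight 1, so a component may contain *no* effect (blocks without signal
#' keep near-prior PIPs). Components are residualized against each other
#' and iterated to convergence. `PIP = 1 - prod(1 - alpha_l)`.
#'
#' With `L = 1` this is the exact posterior over causal configurations of
#' size at most one under independent Bernoulli(`pi`) inclusion; larger `L`
#' uses the iterative variational scheme.
#'
#' @param z named z-score vector.
#' @param R variable correlation matrix (unit diagonal).
#' @param groups character group label per variable (e.g. `"snp"`,
#'   `"gene"`, `"peak"`).
#' @param pi named per-variable prior inclusion probability by group.
#' @param sigma2 named prior effect variance (z-score scale) by group.
#' @param L number of single-effect components (default 1).
#' @param tol convergence tolerance on the maximum PIP change.
#' @param max_iter iteration cap (warn and return last iterate beyond it).
#' @return a `stim_finemap_block` list: `pip` (named), `alpha` (L x p),
#'   `mu`, `s2` (posterior moments per component), `groups`, `converged`,
#'   `n_iter`, `lbf` (per-variable log Bayes factors of the first
#'   component).
#' @export
finemap_block <- function(z, R, groups, pi, sigma2, L = 1, tol = 1e-6,
                          max_iter = 200) {
  p <- length(z)
  stopifnot(nrow(R) == p, length(groups) == p, L >= 1)
  prior_pi <- pmin(pmax(unname(pi[groups]), 1e-12), 1 - 1e-12)
  log_odds <- log(prior_pi) - log1p(-prior_pi)
  s2_g <- unname(sigma2[groups])
  alpha <- matrix(0, L, p)
  mu <- matrix(0, L, p)
  b <- rep(0, p)                       # sum over components of alpha*mu
  converged <- FALSE
  it <- 0
  post_var <- s2_g / (s2_g + 1)        # posterior variance given inclusion
  lbf1 <- NULL
  repeat {
    it <- it + 1
    pip_old <- 1 - apply(1 - alpha, 2, prod)
    for (l in seq_len(L)) {
      b_l <- alpha[l, ] * mu[l, ]
      r <- z - as.vector(R %*% (b - b_l))
      lbf <- 0.5 * log(1 / (1 + s2_g)) + 0.5 * r^2 * s2_g / (1 + s2_g)
      w <- log_odds + lbf              # null option has log-weight 0
      mx <- max(w, 0)
      we <- exp(w - mx)
      alpha[l, ] <- we / (sum(we) + exp(-mx))
      mu[l, ] <- post_var * r
      b <- b - b_l + alpha[l, ] * mu[l, ]
      if (l == 1) lbf1 <- lbf
    }
    pip <- 1 - apply(1 - alpha, 2, prod)
    if (max(abs(pip - pip_old)) < tol || L == 1) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) {
      warn("finemap_block did not converge; returning last iterate")
      break
    }
  }
  s2_mat <- matrix(rep(post_var, each = L), L, p)
  structure(list(
    pip = stats::setNames(1 - apply(1 - alpha, 2, prod), names(z)),
    alpha = alpha, mu = mu, s2 = s2_mat, groups = groups,
    converged = converged, n_iter = it, lbf = lbf1),
    class = "stim_finemap_block")
}

#' Estimate group priors by expectation-maximization across blocks
#'
#' Alternates fine-mapping every block (E-step, [finemap_block()]) with
#' closed-form prior updates (M-step): `pi_k` is the mean PIP over the
#' group's variables and `sigma2_k` the PIP-weighted posterior second
#' moment of the effects. Groups absent from all blocks keep their initial
#' prior. Reports the per-group priors, the enrichment of each trait group
#' over SNPs (`pi_k / pi_snp`), and final per-variable PIPs.
#'
#' @param blocks list of blocks, each a list with `z`, `R`, `groups` (and
#'   optionally `variable` names).
#' @param init_pi,init_sigma2 named starting values per group.
#' @param L components per block (default 1).
#' @param max_iter EM iteration cap (default 100).
#' @param tol relative-change convergence tolerance on the priors.
#' @return a `stim_finemap` object: list with `pi`, `sigma2`, `enrichment`,
#'   `pips` (tibble: block, variable, group, pip, ev2 = PIP-weighted second
#'   moment), `n_iter`, `converged`, `history`.
#' @export
em_group_priors <- function(blocks, init_pi, init_sigma2, L = 1,
                            max_iter = 100, tol = 1e-4) {
  if (length(blocks) < 10) abort("em_group_priors needs >= 10 blocks")
  groups_all <- unique(unlist(lapply(blocks, function(b) b$groups)))
  pi_k <- init_pi[groups_all]
  s2_k <- init_sigma2[groups_all]
  if (anyNA(pi_k) || anyNA(s2_k)) {
    abort("init_pi / init_sigma2 must cover every group present")
  }
  n_k <- table(factor(unlist(lapply(blocks, function(b) b$groups)),
                      levels = groups_all))
  history <- list()
  converged <- FALSE
  fits <- NULL
  for (it in seq_len(max_iter)) {
    fits <- lapply(blocks, function(b) {
      finemap_block(b$z, b$R, b$groups, pi = pi_k, sigma2 = s2_k, L = L)
    })
    pip_sum <- stats::setNames(rep(0, length(groups_all)), groups_all)
    m2_sum <- pip_sum
    for (f in fits) {
      w <- f$alpha * (f$mu^2 + f$s2)        # component-wise second moments
      for (g in groups_all) {
        sel <- f$groups == g
        if (!any(sel)) next
        pip_sum[g] <- pip_sum[g] + sum(f$pip[sel])
        m2_sum[g] <- m2_sum[g] + sum(w[, sel, drop = FALSE])
      }
    }
    pi_new <- pmin(pmax(pip_sum / as.numeric(n_k[groups_all]), 1e-8),
                   1 - 1e-8)
    s2_new <- ifelse(pip_sum > 1e-8, m2_sum / pip_sum, s2_k)
    s2_new <- pmax(s2_new, 1e-4)
    delta <- max(abs(log(pi_new / pi_k)), abs(log(s2_new / s2_k)))
    history[[it]] <- tibble(iter = it, group = groups_all,
                            pi = unname(pi_new), sigma2 = unname(s2_new))
    pi_k <- pi_new
    s2_k <- s2_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  pips <- purrr::imap(fits, function(f, i) {
    ev2 <- colSums(f$alpha * (f$mu^2 + f$s2))
    tibble(block = i, variable = names(f$pip), group = f$groups,
           pip = unname(f$pip), ev2 = unname(ev2))
  }) |> dplyr::bind_rows()
  enr <- if ("snp" %in% groups_all) pi_k / pi_k[["snp"]] else
    stats::setNames(rep(NA_real_, length(pi_k)), names(pi_k))
  structure(list(pi = pi_k, sigma2 = s2_k, enrichment = enr, pips = pips,
                 n_iter = length(history), converged = converged,
                 history = dplyr::bind_rows(history)),
            class = "stim_finemap")
}

#' @export
print.stim_finemap <- function(x, ...) {
  cat(sprintf("<stim_finemap> %d variables, %d EM iterations (%s)\n",
              nrow(x$pips), x$n_iter,
              if (x$converged) "converged" else "not converged"))
  for (g in names(x$pi)) {
    cat(sprintf("  %-6s pi = %.4g, sigma2 = %.3g, enrichment = %.3g\n",
                g, x$pi[[g]], x$sigma2[[g]], x$enrichment[[g]]))
  }
  invisible(x)
}

#' Partition trait heritability across variable groups
#'
#' Each variable's expected causal variance contribution on the z-score
#' scale is `PIP * E[b^2 | inclusion]`; with standardized (unit-variance)
#' variables this is proportional to its share of the GWAS heritability
#' implied by the model. Shares are reported as percentages of the total
#' over all variables, per group (optionally split by context when the
#' `pips` table carries trait ids of the form `feature|celltype_time`).
#'
#' @param fit a `stim_finemap` from [em_group_priors()].
#' @param by_context also split trait groups by context parsed from the
#'   trait id (default FALSE).
#' @return tibble(`group`, [`context`,] `h2_share`, `h2_pct`).
#' @export
heritability_partition <- function(fit, by_context = FALSE) {
  pips <- fit$pips
  contrib <- pips$pip * pips$ev2
  total <- sum(contrib)
  if (total <= 0) {
    return(tibble(group = unique(pips$group), h2_share = 0, h2_pct = 0))
  }
  pips$contrib <- contrib
  if (by_context) {
    pips$context <- ifelse(grepl("\\|", pips$variable),
                           sub("^.*\\|", "", pips$variable), NA_character_)
    out <- pips |>
      group_by(.data$group, .data$context) |>
      summarise(h2_share = sum(.data$contrib) / total, .groups = "drop")
  } else {
    out <- pips |>
      group_by(.data$group) |>
      summarise(h2_share = sum(.data$contrib) / total, .groups = "drop")
  }
  out$h2_pct <- 100 * out$h2_share
  out
}

#' Aggregate trait PIPs into gene PIPs and classify dynamics
#'
#' The gene PIP is the sum of the gene's per-context trait PIPs (also
#' reported capped at 1). A gene is `dynamic` when the summed PIP of the
#' stimulated contexts (1h + 6h) exceeds the 0h PIP by at least
#' `dynamic_margin` (default 0.5), else `static`. Confidence strata follow
#' the capped PIP: `high` above 0.8, `plausible` in (0.5, 0.8], else
#' `low`.
#'
#' @param trait_pips tibble with `feature_id`, `time`, `pip` (one row per
#'   trait; e.g. the gene-group rows of `fit$pips` joined back to trait
#'   metadata).
#' @param dynamic_margin the stimulated-minus-baseline PIP margin
#'   (default 0.5).
#' @return tibble(`feature_id`, `pip_0h`, `pip_1h`, `pip_6h`, `gene_pip`,
#'   `gene_pip_capped`, `class`, `confidence`).
#' @export
aggregate_gene_pip <- function(trait_pips, dynamic_margin = 0.5) {
  stopifnot(all(c("feature_id", "time", "pip") %in% names(trait_pips)))
  wide <- trait_pips |>
    group_by(.data$feature_id, .data$time) |>
    summarise(pip = sum(.data$pip), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "time", values_from = "pip",
                       names_prefix = "pip_", values_fill = 0)
  for (cn in paste0("pip_", stim_times())) {
    if (!cn %in% names(wide)) wide[[cn]] <- 0
  }
  wide$gene_pip <- wide$pip_0h + wide$pip_1h + wide$pip_6h
  wide$gene_pip_capped <- pmin(1, wide$gene_pip)
  margin <- (wide$pip_1h + wide$pip_6h) - wide$pip_0h
  wide$class <- ifelse(margin >= dynamic_margin - 1e-9, "dynamic", "static")
  wide$confidence <- dplyr::case_when(
    wide$gene_pip_capped > 0.8 ~ "high",
    wide$gene_pip_capped > 0.5 ~ "plausible",
    TRUE ~ "low")
  wide[, c("feature_id", "pip_0h", "pip_1h", "pip_6h", "gene_pip",
           "gene_pip_capped", "class", "confidence")]
}

#' Link causal cPeaks to putative target genes
#'
#' Union of four evidence channels per cPeak: co-activation linkage
#' (significant [link_peaks()] pair), the peak's top variant being an eQTL
#' for the gene at FDR < `eqtl_fdr`, the gene's TSS (or span, when an `end`
#' column exists) overlapping the peak, and an ABC score above
#' `abc_threshold`. Evidence multiplicity is reported.
#'
#' @param cpeak_models peak trait models ([build_trait_models()] rows), one
#'   per cPeak-context, carrying the top variant in `snp_id`.
#' @param linked [link_peaks()] output.
#' @param eqtl lead-level eQTL results (with `q`).
#' @param abc [abc_scores()] output.
#' @param peaks,genes feature tables.
#' @param eqtl_fdr eQTL evidence threshold (default 0.2).
#' @param abc_threshold ABC evidence threshold (default 0.02).
#' @return tibble(`peak_id`, `gene_id`, `evidence`, `n_evidence`).
#' @export
link_cpeak_targets <- function(cpeak_models, linked, eqtl, abc, peaks, genes,
                               eqtl_fdr = 0.2, abc_threshold = 0.02) {
  cp <- unique(cpeak_models$feature_id)
  ev <- list()
  add_ev <- function(peak_id, gene_id, tag) {
    tibble(peak_id = peak_id, gene_id = gene_id, tag = tag)
  }
  co <- linked[linked$significant & linked$peak_id %in% cp, ]
  if (nrow(co) > 0) {
    ev[[length(ev) + 1]] <- add_ev(co$peak_id, co$gene_id, "coactivation")
  }
  eq <- eqtl[eqtl$q < eqtl_fdr, c("feature_id", "snp_id")]
  eq_hit <- dplyr::inner_join(
    dplyr::distinct(cpeak_models[, c("feature_id", "snp_id")]),
    eq, by = "snp_id", suffix = c("_peak", "_gene"),
    relationship = "many-to-many")
  if (nrow(eq_hit) > 0) {
    ev[[length(ev) + 1]] <- add_ev(eq_hit$feature_id_peak,
                                   eq_hit$feature_id_gene, "eqtl")
  }
  pk <- peaks[peaks$peak_id %in% cp, ]
  if (nrow(pk) > 0) {
    g_lo <- if ("end" %in% names(genes)) pmin(genes$tss, genes$tss) else
      genes$tss
    g_hi <- if ("end" %in% names(genes)) pmax(genes$tss, genes$end) else
      genes$tss
    gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                      IRanges::IRanges(g_lo, g_hi))
    peak_gr <- GenomicRanges::GRanges(pk$chrom,
                                      IRanges::IRanges(pk$start + 1, pk$end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(peak_gr, gene_gr))
    if (length(S4Vectors_from(hits)) > 0) {
      ev[[length(ev) + 1]] <- add_ev(pk$peak_id[S4Vectors_from(hits)],
                                     genes$gene_id[S4Vectors_to(hits)],
                                     "overlap")
    }
  }
  ab <- abc[abc$score >= abc_threshold & abc$peak_id %in% cp, ]
  if (nrow(ab) > 0) {
    ev[[length(ev) + 1]] <- add_ev(ab$peak_id, ab$gene_id, "abc")
  }
  if (length(ev) == 0) {
    return(tibble(peak_id = character(), gene_id = character(),
                  evidence = character(), n_evidence = integer()))
  }
  dplyr::bind_rows(ev) |>
    dplyr::distinct() |>
    group_by(.data$peak_id, .data$gene_id) |>
    summarise(evidence = paste(sort(unique(.data$tag)), collapse = ","),
              n_evidence = dplyr::n_distinct(.data$tag), .groups = "drop")
}
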