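#' Specify a synthetic stimulation multiomic experiment
#'
#' Defines the full generative design: genome layout (SNPs, gene TSSs, peak
#' intervals on one synthetic chromosome), donor genotype structure (MAF
#' range, AR(1) LD within blocks), the single-cell count model (negative
#' binomial with lognormal size factors and donor random intercepts),
#' temporal expression modules along pseudotime, and the planted effects
#' (QTL, allelic imbalance, GWAS, case-control shifts) recovered by the
#' downstream estimators.
#'
#' Default scale is a "desk" preset: 24 donors, 2,000 SNPs, 600 genes,
#' 800 peaks and 30 cells per donor and context. Pseudotime is *drawn*
#' per time point (Beta(2,8), Beta(5,5), Beta(8,2) for 0/1/6 h), not
#' inferred: trajectory inference is out of scope and downstream stages
#' consume pseudotime as given.
#'
#' @param n_donors,n_snps,n_genes,n_peaks,cells_per_donor_context design
#'   sizes (all >= 1).
#' @param cell_types,times contexts to generate cells for (defaults: all 9).
#' @param maf_range range of simulated minor allele frequencies.
#' @param ld_block_size,ld_rho SNPs per LD block and the AR(1) correlation
#'   of the latent Gaussian haplotype copula within a block (|rho| < 1).
#' @param nb_dispersion negative-binomial dispersion phi
#'   (variance = mu + phi mu^2); 0 gives Poisson counts.
#' @param donor_sd SD of the per-donor, per-feature random intercept on the
#'   natural-log scale.
#' @param size_factor_sd SD of the lognormal per-cell size factor (log scale).
#' @param base_log_mean_range range of per-feature baseline log means
#'   (natural log of expected counts per cell).
#' @param module_spec tibble with columns `module`, `shape`
#'   (one of `"flat"`, `"early"`, `"late"`, `"priming"`), `n_genes`.
#'   Remaining genes are flat. `"priming"` genes follow the late shape while
#'   their matched peak follows the same shape advanced by `priming_lead`.
#' @param module_amplitude log-scale amplitude of the temporal shapes.
#' @param priming_lead pseudotime lead of chromatin over expression for
#'   priming modules (fraction of the [0,1] axis).
#' @param pseudotime_beta named list of Beta(a, b) parameters per time point.
#' @param qtl_spec,caqtl_spec planted genetic effects:
#'   tibble(`feature_id`, `snp_id`, `cell_type`, `time`, `beta`), beta on the
#'   natural-log scale of the count mean per alt dosage. See [plant_qtl()].
#' @param asoc_spec tibble(`snp_id`, `peak_id`) of heterozygous sites inside
#'   peaks at which allelic reads are emitted; defaults to all caQTL SNPs of
#'   `caqtl_spec`.
#' @param asoc_kappa coupling between the colocated caQTL effect and the
#'   allelic ratio: `logit(p_alt) = kappa * beta_context`.
#' @param asoc_depth mean read depth per heterozygous donor, SNP and context.
#' @param case_spec optional list with `n_cases`, `de_genes`, `lfc` (log2)
#'   and `contexts` (tibble cell_type/time) for case-control shifts.
#' @param seed integer seed that fully determines every generated object
#'   (R's default Mersenne-Twister stream, one stream per generator call).
#' @return a `sim_design` list, including laid-out `snps`, `genes` and
#'   `peaks` tibbles (genes carry their `module`, peaks carry `module` and
#'   the `linked_gene` whose TSS is nearest).
#' @export
sim_design <- function(n_donors = 24, n_snps = 2000, n_genes = 600,
                       n_peaks = 800, cells_per_donor_context = 30,
                       cell_types = stim_cell_types(), times = stim_times(),
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 20, ld_rho = 0.5,
                       nb_dispersion = 0.5, donor_sd = 0.3,
                       size_factor_sd = 0.3,
                       base_log_mean_range = log(c(0.5, 5)),
                       module_spec = NULL,
                       module_amplitude = 1.5, priming_lead = 0.1,
                       pseudotime_beta = list(`0h` = c(2, 8), `1h` = c(5, 5),
                                              `6h` = c(8, 2)),
                       qtl_spec = NULL, caqtl_spec = NULL, asoc_spec = NULL,
                       asoc_kappa = 1, asoc_depth = 30,
                       case_spec = NULL, seed = 1L) {
  stopifnot(n_donors >= 1, n_snps >= 1, n_genes >= 1, n_peaks >= 1,
            cells_per_donor_context >= 1, abs(ld_rho) < 1,
            nb_dispersion >= 0, donor_sd >= 0)
  if (is.null(module_spec)) module_spec <- default_module_spec(n_genes)
  snp_spacing <- 3000
  genome_bp <- n_snps * snp_spacing
  snps <- tibble(
    snp_id = sprintf("rs%05d", seq_len(n_snps)),
    chrom = "chr1",
    pos = as.integer(seq_len(n_snps) * snp_spacing),
    ref = "A", alt = "G",
    block = (seq_len(n_snps) - 1L) %/% ld_block_size + 1L)
  # MAFs are part of the layout: fixed by the design seed, independent of
  # later generator calls
  old_seed <- .get_random_seed()
  set.seed(seed)
  snps$maf <- runif(n_snps, maf_range[1], maf_range[2])
  genes <- tibble(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    chrom = "chr1",
    tss = as.integer(round(seq_len(n_genes) * genome_bp / (n_genes + 1))),
    strand = "+")
  peak_mid <- round(seq_len(n_peaks) * genome_bp / (n_peaks + 1))
  peaks <- tibble(
    peak_id = sprintf("peak%04d", seq_len(n_peaks)),
    chrom = "chr1",
    start = as.integer(peak_mid - 250),
    end = as.integer(peak_mid + 250))
  genes$module <- assign_modules(n_genes, module_spec)
  peaks <- link_peaks_to_modules(peaks, genes)
  .restore_random_seed(old_seed)
  structure(list(
    n_donors = n_donors, n_snps = n_snps, n_genes = n_genes,
    n_peaks = n_peaks, cells_per_donor_context = cells_per_donor_context,
    cell_types = cell_types, times = times,
    maf_range = maf_range, ld_block_size = ld_block_size, ld_rho = ld_rho,
    nb_dispersion = nb_dispersion, donor_sd = donor_sd,
    size_factor_sd = size_factor_sd,
    base_log_mean_range = base_log_mean_range,
    module_spec = module_spec, module_amplitude = module_amplitude,
    priming_lead = priming_lead, pseudotime_beta = pseudotime_beta,
    snps = snps, genes = genes, peaks = peaks,
    qtl_spec = qtl_spec, caqtl_spec = caqtl_spec, asoc_spec = asoc_spec,
    asoc_kappa = asoc_kappa, asoc_depth = asoc_depth,
    case_spec = case_spec,
    donors = sprintf("donor%03d", seq_len(n_donors)),
    seed = as.integer(seed)), class = "sim_design")
}

.get_random_seed <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_random_seed <- function(old_seed) {
  if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(paste0("<sim_design> %d donors, %d SNPs, %d genes, %d peaks, ",
                     "%d cells/donor/context, seed %d\n"),
              x$n_donors, x$n_snps, x$n_genes, x$n_peaks,
              x$cells_per_donor_context, x$seed))
  invisible(x)
}

#' @rdname sim_design
#' @param n_genes_total total genes available when sizing the default
#'   modules (each module gets `min(60, n_genes_total %/% 10)` genes).
#' @export
default_module_spec <- function(n_genes_total = 600) {
  n <- min(60L, n_genes_total %/% 10L)
  if (n < 1) {
    return(tibble(module = character(), shape = character(),
                  n_genes = integer()))
  }
  tibble(module = c("early", "late", "priming"),
         shape = c("early", "late", "priming"),
         n_genes = rep(n, 3))
}

assign_modules <- function(n_genes, module_spec) {
  module <- rep("flat", n_genes)
  if (is.null(module_spec) || nrow(module_spec) == 0) return(module)
  if (sum(module_spec$n_genes) > n_genes) {
    abort("module_spec assigns more genes than exist")
  }
  at <- 1L
  for (i in seq_len(nrow(module_spec))) {
    module[at:(at + module_spec$n_genes[i] - 1L)] <- module_spec$module[i]
    at <- at + module_spec$n_genes[i]
  }
  module
}

# each module gene claims its nearest peak; that peak inherits the module
# (priming modules put the *early-shifted* shape on the peak)
link_peaks_to_modules <- function(peaks, genes) {
  peaks$module <- "flat"
  peaks$linked_gene <- NA_character_
  mid <- (peaks$start + peaks$end) / 2
  mod_genes <- which(genes$module != "flat")
  claimed <- rep(FALSE, nrow(peaks))
  for (g in mod_genes) {
    d <- abs(mid - genes$tss[g])
    d[claimed] <- Inf
    j <- which.min(d)
    peaks$module[j] <- genes$module[g]
    peaks$linked_gene[j] <- genes$gene_id[g]
    claimed[j] <- TRUE
  }
  peaks
}

# temporal shape on the natural-log scale, as a function of pseudotime
shape_value <- function(shape, pt, lead = 0) {
  t <- pt + lead
  switch(shape,
    flat = rep(0, length(pt)),
    early = exp(-((t - 0.25) / 0.12)^2),
    late = stats::plogis((t - 0.6) / 0.08),
    priming = stats::plogis((t - 0.6) / 0.08),
    down = 1 - stats::plogis((t - 0.4) / 0.12),
    abort(sprintf("unknown module shape '%s'", shape)))
}

# shape used for a *peak* of a module: priming peaks lead their gene
peak_shape_value <- function(module, pt, priming_lead) {
  if (module == "priming") shape_value("late", pt, lead = priming_lead)
  else shape_value(module, pt)
}

#' Plant cis QTL effects into a design
#'
#' Picks, for each requested feature, the nearest sufficiently common SNP
#' and returns the expanded effect table suitable for `qtl_spec` /
#' `caqtl_spec`. `beta_by_time` gives the effect at each time point
#' (a constant produces a static QTL; differing values a dynamic one).
#'
#' @param design a [sim_design()].
#' @param feature_ids gene or peak ids to receive an effect.
#' @param kind `"gene"` or `"peak"`.
#' @param beta_by_time named numeric, e.g. `c("0h" = 0, "1h" = 0, "6h" = .8)`,
#'   or a single number applied to all time points. May also be a function
#'   of the feature index returning such a vector, for per-feature effects.
#' @param cell_types cell types in which the effect is active.
#' @param min_maf minimum MAF of the chosen SNP.
#' @return tibble(`feature_id`, `snp_id`, `cell_type`, `time`, `beta`).
#' @export
plant_qtl <- function(design, feature_ids, kind = c("gene", "peak"),
                      beta_by_time, cell_types = design$cell_types,
                      min_maf = 0.2) {
  kind <- match.arg(kind)
  feats <- if (kind == "gene") design$genes else design$peaks
  id_col <- if (kind == "gene") "gene_id" else "peak_id"
  pos <- if (kind == "gene") feats$tss else (feats$start + feats$end) / 2
  ok <- design$snps$maf >= min_maf
  if (!any(ok)) abort("no SNP satisfies min_maf")
  rows <- purrr::imap(feature_ids, function(fid, i) {
    j <- match(fid, feats[[id_col]])
    if (is.na(j)) abort(sprintf("unknown %s '%s'", kind, fid))
    snp <- design$snps$snp_id[ok][which.min(abs(design$snps$pos[ok] - pos[j]))]
    b <- if (is.function(beta_by_time)) beta_by_time(i) else beta_by_time
    if (length(b) == 1 && is.null(names(b))) {
      b <- stats::setNames(rep(b, length(design$times)), design$times)
    }
    tidyr::expand_grid(feature_id = fid, snp_id = snp,
                       cell_type = cell_types, time = names(b)) |>
      mutate(beta = unname(b[.data$time]))
  })
  dplyr::bind_rows(rows)
}

#' Simulate donor genotypes under Hardy-Weinberg with block LD
#'
#' Two latent Gaussian haplotypes per donor follow an AR(1) process with
#' parameter `ld_rho` within each LD block; thresholding each haplotype at
#' the SNP's allele-frequency quantile yields alleles, and their sum the
#' dosage. Marginally each SNP is Hardy-Weinberg at its MAF; jointly,
#' neighbouring SNPs are correlated through the Gaussian copula.
#'
#' @param design a [sim_design()].
#' @param seed RNG seed (defaults to the design seed).
#' @return a `stim_genotypes` object (see [read_genotypes()]).
#' @export
simulate_genotypes <- function(design, seed = design$seed) {
  set.seed(seed)
  n_hap <- 2L * design$n_donors
  p <- design$n_snps
  z <- matrix(rnorm(n_hap * p), n_hap, p)
  rho <- design$ld_rho
  if (rho != 0) {
    blk <- design$snps$block
    scale <- sqrt(1 - rho^2)
    for (j in 2:p) {
      if (blk[j] == blk[j - 1]) z[, j] <- rho * z[, j - 1] + scale * z[, j]
    }
  }
  thr <- qnorm(design$snps$maf)
  alleles <- sweep(z, 2, thr, `<`)
  dos <- alleles[seq(1, n_hap, 2), , drop = FALSE] +
    alleles[seq(2, n_hap, 2), , drop = FALSE]
  dos <- matrix(as.numeric(dos), nrow = design$n_donors,
                dimnames = list(design$donors, design$snps$snp_id))
  new_stim_genotypes(dos, design$snps)
}

#' Simulate cell annotations with drawn pseudotime
#'
#' One row per cell: `cells_per_donor_context` cells for every donor and
#' context in the design, with pseudotime drawn from the per-time-point
#' Beta distributions so that activation advances with time in expectation.
#'
#' @inheritParams simulate_genotypes
#' @return tibble(`cell_id`, `donor_id`, `cell_type`, `time`, `pseudotime`).
#' @export
simulate_cells <- function(design, seed = design$seed) {
  set.seed(seed + 1L)
  grid <- tidyr::expand_grid(donor_id = design$donors,
                             cell_type = design$cell_types,
                             time = design$times)
  k <- design$cells_per_donor_context
  cells <- tidyr::uncount(grid, k)
  ab <- do.call(rbind, design$pseudotime_beta[cells$time])
  cells$pseudotime <- rbeta(nrow(cells), ab[, 1], ab[, 2])
  cells$cell_id <- sprintf("cell%07d", seq_len(nrow(cells)))
  check_cells(cells[, c("cell_id", "donor_id", "cell_type", "time",
                        "pseudotime")])
}

# shared NB count engine for genes and peaks
simulate_counts <- function(genotypes, cells, design, features, id_col,
                            modules, shapes_fun, effects, seed,
                            case_labels = NULL, case_shift = NULL) {
  set.seed(seed)
  n_feat <- nrow(features)
  n_cell <- nrow(cells)
  mu0 <- runif(n_feat, design$base_log_mean_range[1],
               design$base_log_mean_range[2])
  u <- matrix(rnorm(design$n_donors * n_feat, sd = design$donor_sd),
              design$n_donors, n_feat,
              dimnames = list(design$donors, features[[id_col]]))
  s <- rlnorm(n_cell, 0, design$size_factor_sd)
  donor_idx <- match(cells$donor_id, design$donors)
  # per-module temporal contribution, shared across member features
  mod_levels <- unique(modules)
  mod_eta <- vapply(mod_levels, function(m) {
    design$module_amplitude * shapes_fun(m, cells$pseudotime)
  }, numeric(n_cell))
  colnames(mod_eta) <- mod_levels
  eff_by_feat <- if (is.null(effects) || nrow(effects) == 0) list() else
    split(effects, effects$feature_id)
  if (!is.null(effects) && nrow(effects) > 0) {
    bad <- setdiff(effects$feature_id, features[[id_col]])
    bad2 <- setdiff(effects$snp_id, colnames(genotypes$dosage))
    if (length(bad) > 0 || length(bad2) > 0) {
      abort("planted effect refers to unknown feature or SNP")
    }
  }
  ctx <- context_label(cells$cell_type, cells$time)
  size <- if (design$nb_dispersion > 0) 1 / design$nb_dispersion else Inf
  out <- matrix(0L, n_feat, n_cell,
                dimnames = list(features[[id_col]], cells$cell_id))
  for (g in seq_len(n_feat)) {
    eta <- mu0[g] + mod_eta[, modules[g]] + u[donor_idx, g]
    fx <- eff_by_feat[[features[[id_col]][g]]]
    if (!is.null(fx)) {
      for (r in seq_len(nrow(fx))) {
        mask <- ctx == context_label(fx$cell_type[r], fx$time[r])
        if (any(mask)) {
          eta[mask] <- eta[mask] +
            fx$beta[r] * genotypes$dosage[donor_idx[mask], fx$snp_id[r]]
        }
      }
    }
    if (!is.null(case_shift) && features[[id_col]][g] %in% case_shift$ids) {
      mask <- case_shift$cell_mask
      eta[mask] <- eta[mask] + case_shift$lfc_ln
    }
    mu <- s * exp(eta)
    out[g, ] <- if (is.finite(size)) rnbinom(n_cell, mu = mu, size = size)
                else rpois(n_cell, mu)
  }
  new_stim_counts(methods::as(Matrix::Matrix(out, sparse = TRUE),
                              "CsparseMatrix"))
}

#' Simulate single-cell gene expression counts
#'
#' Counts for cell \eqn{i} and gene \eqn{g} are negative binomial with mean
#' \eqn{s_i \exp(\mu_g + m_g(\mathrm{pt}_i) + u_{d(i),g} +
#' \sum \beta\,G)} and dispersion `nb_dispersion`: lognormal size factor,
#' per-module temporal shape, donor random intercept, and any planted QTL
#' effects active in the cell's context.
#'
#' @param genotypes from [simulate_genotypes()].
#' @param cells from [simulate_cells()].
#' @inheritParams simulate_genotypes
#' @return list with `counts` (a `stim_counts`, genes x cells) and `truth`
#'   (gene modules, planted QTL table, case labels if any).
#' @export
simulate_expression <- function(genotypes, cells, design,
                                seed = design$seed) {
  case_shift <- NULL
  labels <- NULL
  if (!is.null(design$case_spec)) {
    labels <- simulate_case_labels(design)
    cs <- design$case_spec
    ctxs <- context_label(cs$contexts$cell_type, cs$contexts$time)
    case_donors <- labels$donor_id[labels$status == "case"]
    case_shift <- list(
      ids = cs$de_genes,
      lfc_ln = cs$lfc * log(2),
      cell_mask = cells$donor_id %in% case_donors &
        context_label(cells$cell_type, cells$time) %in% ctxs)
  }
  counts <- simulate_counts(
    genotypes, cells, design, design$genes, "gene_id",
    design$genes$module, function(m, pt) shape_value(m, pt),
    design$qtl_spec, seed = seed + 2L, case_shift = case_shift)
  list(counts = counts,
       truth = list(modules = design$genes[, c("gene_id", "module")],
                    qtl = design$qtl_spec, case_labels = labels,
                    case_spec = design$case_spec))
}

#' Simulate single-cell chromatin accessibility counts
#'
#' Same generative family as [simulate_expression()], on peaks. Peaks of a
#' `"priming"` module follow the gene's late temporal shape advanced by
#' `priming_lead` pseudotime, so chromatin opens before the linked gene's
#' expression rises. Planted caQTL shift peak means by `beta * dosage`.
#'
#' @inheritParams simulate_expression
#' @return list with `counts` (peaks x cells) and `truth` (peak modules and
#'   planted caQTL table).
#' @export
simulate_accessibility <- function(genotypes, cells, design,
                                   seed = design$seed) {
  counts <- simulate_counts(
    genotypes, cells, design, design$peaks, "peak_id",
    design$peaks$module,
    function(m, pt) peak_shape_value(m, pt, design$priming_lead),
    design$caqtl_spec, seed = seed + 3L)
  list(counts = counts,
       truth = list(modules = design$peaks[, c("peak_id", "module",
                                               "linked_gene")],
                    caqtl = design$caqtl_spec))
}

#' Simulate allelic read counts at heterozygous SNPs inside peaks
#'
#' For every SNP of `asoc_spec` (default: every planted caQTL SNP, taken to
#' sit inside its peak), each donor heterozygous at the SNP emits, per
#' context, a Poisson total read count proportional to that donor's peak
#' pseudobulk count (mean `asoc_depth`), and an alt count that is binomial
#' with `logit(p) = asoc_kappa * beta_context` of the colocated caQTL.
#' Homozygous donors emit no rows; zero-read rows are dropped.
#'
#' @param genotypes from [simulate_genotypes()].
#' @param peak_counts `stim_counts` from [simulate_accessibility()].
#' @param cells cell annotations.
#' @inheritParams simulate_genotypes
#' @return tibble(`snp_id`, `peak_id`, `donor_id`, `cell_type`, `time`,
#'   `ref_count`, `alt_count`).
#' @export
simulate_allele_counts <- function(genotypes, peak_counts, cells, design,
                                   seed = design$seed) {
  spec <- design$asoc_spec
  if (is.null(spec)) {
    if (is.null(design$caqtl_spec)) {
      abort("design has neither asoc_spec nor caqtl_spec")
    }
    spec <- dplyr::distinct(design$caqtl_spec[, c("feature_id", "snp_id")])
    spec <- tibble(snp_id = spec$snp_id, peak_id = spec$feature_id)
  }
  set.seed(seed + 4L)
  pb <- pseudobulk_raw_sums(peak_counts, cells, unique(spec$peak_id))
  betas <- design$caqtl_spec
  rows <- purrr::pmap(spec, function(snp_id, peak_id, ...) {
    het <- design$donors[genotypes$dosage[, snp_id] == 1]
    if (length(het) == 0) return(NULL)
    tab <- pb[pb$peak_id == peak_id & pb$donor_id %in% het, ]
    if (nrow(tab) == 0) return(NULL)
    depth_scale <- design$asoc_depth / max(mean(tab$total), 1e-9)
    b <- rep(0, nrow(tab))
    if (!is.null(betas)) {
      bx <- betas[betas$feature_id == peak_id & betas$snp_id == snp_id, ]
      if (nrow(bx) > 0) {
        key <- context_label(tab$cell_type, tab$time)
        bkey <- context_label(bx$cell_type, bx$time)
        m <- match(key, bkey)
        b <- ifelse(is.na(m), 0, bx$beta[m])
      }
    }
    n <- rpois(nrow(tab), depth_scale * tab$total)
    alt <- rbinom(nrow(tab), n, stats::plogis(design$asoc_kappa * b))
    keep <- n > 0
    tibble(snp_id = snp_id, peak_id = peak_id, donor_id = tab$donor_id[keep],
           cell_type = tab$cell_type[keep], time = tab$time[keep],
           ref_count = n[keep] - alt[keep], alt_count = alt[keep])
  })
  dplyr::bind_rows(rows)
}

# raw per-donor-context sums for a subset of features
pseudobulk_raw_sums <- function(counts, cells, feature_ids) {
  m <- counts$counts[feature_ids, , drop = FALSE]
  key <- paste(cells$donor_id, cells$cell_type, cells$time, sep = "\r")
  groups <- factor(key)
  agg <- m %*% sparseMatrix(i = seq_len(ncol(m)),
                            j = as.integer(groups), x = 1,
                            dims = c(ncol(m), nlevels(groups)))
  parts <- do.call(rbind, strsplit(levels(groups), "\r", fixed = TRUE))
  tibble(peak_id = rep(feature_ids, times = nlevels(groups)),
         donor_id = rep(parts[, 1], each = length(feature_ids)),
         cell_type = rep(parts[, 2], each = length(feature_ids)),
         time = rep(parts[, 3], each = length(feature_ids)),
         total = as.vector(as.matrix(agg)))
}

#' Simulate GWAS summary statistics under block LD
#'
#' Per LD block with correlation `R`, draws
#' \eqn{z = \sqrt{n}\, R\, b + \varepsilon}, \eqn{\varepsilon \sim N(0, R)},
#' where `b` holds per-SNP standardized effects (from planted causal traits
#' and/or direct SNP effects). `R` is the empirical dosage correlation of
#' the block (ridge-regularized if singular).
#'
#' @param genotypes from [simulate_genotypes()].
#' @param design the design (supplies the block layout).
#' @param snp_effects tibble(`snp_id`, `b`) of standardized per-SNP effects;
#'   missing SNPs have effect 0.
#' @param n_gwas GWAS sample size.
#' @param seed RNG seed.
#' @return a `stim_gwas` object.
#' @export
simulate_gwas <- function(genotypes, design, snp_effects = NULL,
                          n_gwas = 50000, seed = design$seed) {
  set.seed(seed + 5L)
  snps <- design$snps
  b <- stats::setNames(rep(0, nrow(snps)), snps$snp_id)
  if (!is.null(snp_effects) && nrow(snp_effects) > 0) {
    b[snp_effects$snp_id] <- snp_effects$b
  }
  blocks <- list()
  z_all <- numeric(0)
  for (bl in split(snps$snp_id, snps$block)) {
    X <- genotypes$dosage[, bl, drop = FALSE]
    R <- suppressWarnings(cor(X))
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch)) {
      R <- R + diag(0.01, nrow(R))
      R <- stats::cov2cor(R)
      ch <- chol(R)
      inform("singular LD block: applied ridge jitter")
    }
    z <- sqrt(n_gwas) * as.vector(R %*% b[bl]) +
      as.vector(crossprod(ch, rnorm(length(bl))))
    names(z) <- bl
    blocks[[length(blocks) + 1]] <- list(snp_id = bl, R = R)
    z_all <- c(z_all, z)
  }
  names(blocks) <- as.character(seq_along(blocks))
  snp_tab <- tibble(snp_id = names(z_all), z = unname(z_all),
                    block = rep(names(blocks),
                                vapply(blocks, function(x) length(x$snp_id),
                                       integer(1))))
  new_stim_gwas(snp_tab, n_gwas, blocks)
}

#' Simulate case/control donor labels
#'
#' Deterministic under the design seed. The case-status expression shift
#' itself is applied by [simulate_expression()] when the design carries a
#' `case_spec`.
#'
#' @inheritParams simulate_genotypes
#' @return tibble(`donor_id`, `status`) with `status` in {case, control}.
#' @export
simulate_case_labels <- function(design, seed = design$seed) {
  cs <- design$case_spec
  if (is.null(cs)) abort("design has no case_spec")
  if (cs$n_cases > design$n_donors) {
    abort("n_cases exceeds the number of donors")
  }
  set.seed(seed + 6L)
  cases <- sample(design$donors, cs$n_cases)
  tibble(donor_id = design$donors,
         status = ifelse(design$donors %in% cases, "case", "control"))
}

#' Simulate a TF motif-to-peak assignment map
#'
#' Response TFs receive `n_peaks_per_tf` peaks drawn mostly
#' (`purity` fraction) from the peaks of their module; null TFs draw
#' uniformly from all peaks. Motif scanning itself is out of scope: this
#' map is what a scanner would produce.
#'
#' @param design a [sim_design()].
#' @param tf_spec tibble(`tf`, `module`) where module is a peak module name
#'   or `"null"`.
#' @param n_peaks_per_tf motif peaks per TF.
#' @param purity fraction of a response TF's peaks drawn from its module.
#' @param seed RNG seed.
#' @return tibble(`tf`, `peak_id`).
#' @export
simulate_motif_map <- function(design, tf_spec, n_peaks_per_tf = 50,
                               purity = 0.8, seed = design$seed) {
  set.seed(seed + 7L)
  rows <- purrr::pmap(tf_spec, function(tf, module, ...) {
    if (module == "null") {
      ids <- sample(design$peaks$peak_id, n_peaks_per_tf)
    } else {
      own <- design$peaks$peak_id[design$peaks$module == module]
      n_own <- min(length(own), round(purity * n_peaks_per_tf))
      ids <- c(sample(own, n_own),
               sample(setdiff(design$peaks$peak_id, own),
                      n_peaks_per_tf - n_own))
    }
    tibble(tf = tf, peak_id = ids)
  })
  dplyr::bind_rows(rows)
}

#' Simulate a promoter-capture contact map
#'
#' Emits one bedpe-like record per (gene TSS bin, peak bin) pair within
#' `window_bp`, per time point, with frequency decaying exponentially in
#' distance times lognormal noise.
#'
#' @param design a [sim_design()].
#' @param window_bp maximum TSS-peak distance.
#' @param bin_bp contact bin size.
#' @param decay_bp exponential distance-decay scale.
#' @param seed RNG seed.
#' @return tibble in the [read_contacts()] layout.
#' @export
simulate_contacts <- function(design, window_bp = 5e5, bin_bp = 5000,
                              decay_bp = 1e5, seed = design$seed) {
  set.seed(seed + 8L)
  mid <- (design$peaks$start + design$peaks$end) / 2
  rows <- purrr::map(seq_len(nrow(design$genes)), function(g) {
    tss <- design$genes$tss[g]
    j <- which(abs(mid - tss) <= window_bp)
    if (length(j) == 0) return(NULL)
    d <- abs(mid[j] - tss)
    tibble(peak_bin = floor(mid[j] / bin_bp), tss_bin = floor(tss / bin_bp),
           dist = d)
  })
  tab <- dplyr::distinct(dplyr::bind_rows(rows))
  out <- purrr::map(design$times, function(tm) {
    tibble(chrom_a = "chr1",
           start_a = tab$tss_bin * bin_bp, end_a = (tab$tss_bin + 1) * bin_bp,
           chrom_b = "chr1",
           start_b = tab$peak_bin * bin_bp,
           end_b = (tab$peak_bin + 1) * bin_bp,
           freq = exp(-tab$dist / decay_bp) *
             rlnorm(nrow(tab), 0, 0.3),
           time = tm)
  })
  dplyr::bind_rows(out)
}

#' Generate a complete synthetic dataset
#'
#' Orchestrates all generators and optionally writes every input format to
#' disk (MTX + sidecars, genotype TSV, BED, cell TSV, allelic-count TSV)
#' together with a `truth.json` record of the planted parameters.
#'
#' @param design a [sim_design()].
#' @param dir optional output directory.
#' @param seed RNG seed (defaults to the design seed).
#' @return list with `genotypes`, `cells`, `expression`, `accessibility`,
#'   `allele_counts` (NULL when nothing is planted) and `truth`.
#' @export
simulate_dataset <- function(design, dir = NULL, seed = design$seed) {
  geno <- simulate_genotypes(design, seed)
  cells <- simulate_cells(design, seed)
  expr <- simulate_expression(geno, cells, design, seed)
  atac <- simulate_accessibility(geno, cells, design, seed)
  ac <- if (!is.null(design$caqtl_spec) || !is.null(design$asoc_spec)) {
    simulate_allele_counts(geno, atac$counts, cells, design, seed)
  } else NULL
  truth <- list(expression = expr$truth, accessibility = atac$truth,
                asoc_kappa = design$asoc_kappa)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_count_matrix(expr$counts, file.path(dir, "rna"))
    write_count_matrix(atac$counts, file.path(dir, "atac"))
    write_genotypes(geno, file.path(dir, "genotypes.tsv"))
    write_bed(design$peaks, file.path(dir, "peaks.bed"))
    readr::write_tsv(design$genes, file.path(dir, "genes.tsv"))
    readr::write_tsv(cells, file.path(dir, "cells.tsv"))
    if (!is.null(ac)) readr::write_tsv(ac, file.path(dir, "allele_counts.tsv"))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(truth, file.path(dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
  }
  list(genotypes = geno, cells = cells, expression = expr,
       accessibility = atac, allele_counts = ac, truth = truth)
}

#' Simulate fine-mapping blocks with group structure
#'
#' Builds summary-statistic LD blocks at the *variable* level: `n_snps`
#' SNPs under AR(1) LD plus molecular traits (gene and peak groups), each
#' trait predicted by a single SNP weight (+-1), so the augmented
#' correlation matrix is exact. Each variable is causal independently with
#' its group's prior probability; causal effects on the z scale are
#' `N(0, sigma2_group)`; then `z = R b + N(0, R)`.
#'
#' @param n_blocks number of blocks.
#' @param n_snps,n_gene_traits,n_peak_traits variables per block.
#' @param pi named prior inclusion probabilities per group
#'   (`snp`, `gene`, `peak`).
#' @param sigma2 named prior effect variances per group (z-score scale).
#' @param rho AR(1) LD among SNPs.
#' @param seed RNG seed.
#' @return list of `blocks` (each: `z`, `R`, `groups`, `variable`,
#'   `causal` logical truth) suitable for [finemap_block()] /
#'   [em_group_priors()].
#' @export
simulate_trait_blocks <- function(n_blocks, n_snps = 20, n_gene_traits = 4,
                                  n_peak_traits = 0,
                                  pi = c(snp = 0.002, gene = 0.06,
                                         peak = 0.06),
                                  sigma2 = c(snp = 25, gene = 25, peak = 25),
                                  rho = 0.5, seed = 1) {
  set.seed(seed)
  R_snp <- rho^abs(outer(seq_len(n_snps), seq_len(n_snps), `-`))
  lapply(seq_len(n_blocks), function(bi) {
    n_tr <- n_gene_traits + n_peak_traits
    groups <- c(rep("snp", n_snps), rep("gene", n_gene_traits),
                rep("peak", n_peak_traits))
    # each trait is a +-1-weighted copy of a distinct SNP where possible
    w_snp <- if (n_tr > 0) sample(n_snps, n_tr, replace = n_tr > n_snps)
             else integer(0)
    w_sign <- sample(c(-1, 1), n_tr, replace = TRUE)
    p <- n_snps + n_tr
    R <- diag(p)
    R[seq_len(n_snps), seq_len(n_snps)] <- R_snp
    if (n_tr > 0) {
      for (t in seq_len(n_tr)) {
        rcol <- w_sign[t] * R_snp[, w_snp[t]]
        R[seq_len(n_snps), n_snps + t] <- rcol
        R[n_snps + t, seq_len(n_snps)] <- rcol
      }
      if (n_tr > 1) {
        for (a in seq_len(n_tr - 1)) for (b2 in (a + 1):n_tr) {
          v <- w_sign[a] * w_sign[b2] * R_snp[w_snp[a], w_snp[b2]]
          R[n_snps + a, n_snps + b2] <- v
          R[n_snps + b2, n_snps + a] <- v
        }
      }
    }
    causal <- runif(p) < pi[groups]
    b <- ifelse(causal, rnorm(p, 0, sqrt(sigma2[groups])), 0)
    ch <- chol(R + diag(1e-8, p))
    z <- as.vector(R %*% b) + as.vector(crossprod(ch, rnorm(p)))
    variable <- c(sprintf("b%04d_snp%02d", bi, seq_len(n_snps)),
                  if (n_tr > 0) sprintf("b%04d_trait%02d", bi, seq_len(n_tr)))
    list(z = stats::setNames(z, variable), R = R, groups = groups,
         variable = variable, causal = causal,
         weight_snp = w_snp, weight_sign = w_sign)
  })
}
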