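test_that("genotypes follow Hardy-Weinberg marginals and AR(1) copula LD", {
  d <- sim_design(n_donors = 5000, n_snps = 40, n_genes = 2, n_peaks = 2,
                  cells_per_donor_context = 1, maf_range = c(0.5, 0.5),
                  ld_rho = 0, seed = 4)
  g <- simulate_genotypes(d)
  expect_lt(abs(mean(g$dosage) - 1), 0.02)          # 2 * maf at maf .5
  r_adj <- cor(g$dosage[, 1], g$dosage[, 2])
  expect_lt(abs(r_adj), 0.05)                       # independence at rho 0

  # Monte-Carlo copula oracle for the rho = 0.9 dosage correlation
  d9 <- sim_design(n_donors = 5000, n_snps = 4, n_genes = 2, n_peaks = 2,
                   cells_per_donor_context = 1, maf_range = c(0.3, 0.3),
                   ld_rho = 0.9, seed = 4)
  g9 <- simulate_genotypes(d9)
  set.seed(99)
  n_mc <- 2e5
  z1 <- rnorm(n_mc)
  z2 <- 0.9 * z1 + sqrt(1 - 0.81) * rnorm(n_mc)
  thr <- qnorm(0.3)
  h1 <- z1 < thr
  h2 <- z2 < thr
  # dosage correlation equals haplotype allele correlation for iid haplotypes
  r_oracle <- cor(h1, h2)
  r_sim <- mean(sapply(1:3, function(j) cor(g9$dosage[, j], g9$dosage[, j + 1])))
  expect_lt(abs(r_sim - r_oracle), 0.03)
})

test_that("cell annotations have the right size, ordering and determinism", {
  d <- sim_design(n_donors = 24, n_snps = 10, n_genes = 2, n_peaks = 2,
                  cells_per_donor_context = 50, seed = 8)
  cells <- simulate_cells(d)
  expect_equal(nrow(cells), 24 * 9 * 50)
  m0 <- mean(cells$pseudotime[cells$time == "0h"])
  m6 <- mean(cells$pseudotime[cells$time == "6h"])
  expect_gt(m6, m0)                                  # Beta means 0.8 vs 0.2
  expect_identical(cells, simulate_cells(d))         # same seed, same table
})

test_that("expression counts match the NB mean identity and plant effects per context", {
  # beta = 0, flat modules, no donor effect: mean count = exp(mu) * E[s]
  d <- sim_design(n_donors = 50, n_snps = 10, n_genes = 40, n_peaks = 2,
                  cells_per_donor_context = 25, cell_types = "GABA",
                  donor_sd = 0, size_factor_sd = 0.3,
                  module_spec = tibble::tibble(module = character(),
                                               shape = character(),
                                               n_genes = integer()),
                  seed = 12)
  g <- simulate_genotypes(d)
  cells <- simulate_cells(d)
  ex <- simulate_expression(g, cells, d)
  # recover mu by rerunning the generator's own RNG draw
  set.seed(d$seed + 2L)
  mu <- runif(40, d$base_log_mean_range[1], d$base_log_mean_range[2])
  expected <- exp(mu) * exp(0.3^2 / 2)               # lognormal mean
  observed <- Matrix::rowMeans(ex$counts$counts)
  n_cells <- ncol(ex$counts$counts)
  phi <- d$nb_dispersion
  se <- sqrt(expected * (1 + expected * (phi + 0.3^2 + phi * 0.3^2)) / n_cells)
  expect_true(all(abs(observed - expected) < 3.5 * se))

  # Poisson limit: dispersion 0 gives variance ~ mean
  dp <- sim_design(n_donors = 50, n_snps = 10, n_genes = 20, n_peaks = 2,
                   cells_per_donor_context = 40, cell_types = "GABA",
                   donor_sd = 0, size_factor_sd = 0, nb_dispersion = 0,
                   module_spec = tibble::tibble(module = character(),
                                                shape = character(),
                                                n_genes = integer()),
                   seed = 13)
  gp <- simulate_genotypes(dp)
  cp <- simulate_cells(dp)
  exp_p <- simulate_expression(gp, cp, dp)
  m <- as.matrix(exp_p$counts$counts)
  ratio <- apply(m, 1, var) / rowMeans(m)
  expect_lt(abs(median(ratio) - 1), 0.1)

  # a QTL planted only in npglut 1h shows there and not at 0h
  dq <- sim_design(n_donors = 200, n_snps = 50, n_genes = 10, n_peaks = 2,
                   cells_per_donor_context = 20, cell_types = "npglut",
                   module_spec = tibble::tibble(module = character(),
                                                shape = character(),
                                                n_genes = integer()),
                   seed = 14)
  dq$qtl_spec <- plant_qtl(dq, "gene0003", "gene",
                           beta_by_time = c(`0h` = 0, `1h` = 0.5, `6h` = 0),
                           cell_types = "npglut")
  gq <- simulate_genotypes(dq)
  cq <- simulate_cells(dq)
  exq <- simulate_expression(gq, cq, dq)
  pb <- pseudobulk(exq$counts, cq, min_cells = 3)
  snp <- dq$qtl_spec$snp_id[1]
  eff <- sapply(c("0h", "1h"), function(tm) {
    Y <- stimqtl:::pb_matrix(pb, "npglut", tm, "int")
    dose <- gq$dosage[rownames(Y), snp]
    fit <- summary(lm(Y[, "gene0003"] ~ dose))$coefficients["dose", ]
    fit[c("Estimate", "Std. Error")]
  })
  expect_lt(abs(eff["Estimate", "0h"]), 3 * eff["Std. Error", "0h"])
  expect_gt(eff["Estimate", "1h"], 3 * eff["Std. Error", "1h"])

  # unknown feature in the effect table is a config error
  dq$qtl_spec$feature_id <- "nonexistent"
  expect_error(simulate_expression(gq, cq, dq), "unknown feature")
})

test_that("accessibility priming peaks lead their genes and null caQTL are calibrated", {
  ms <- tibble::tibble(module = "priming", shape = "priming", n_genes = 30L)
  d <- sim_design(n_donors = 30, n_snps = 20, n_genes = 120, n_peaks = 150,
                  cells_per_donor_context = 60, cell_types = "GABA",
                  module_spec = ms, seed = 15)
  g <- simulate_genotypes(d)
  cells <- simulate_cells(d)
  ex <- simulate_expression(g, cells, d)
  at <- simulate_accessibility(g, cells, d)
  pm <- d$peaks[d$peaks$module == "priming", ]
  # chromatin is already elevated at 1h while expression is not:
  # compare mean counts at 1h vs 0h for peaks and their genes
  cid <- function(tm) cells$cell_id[cells$time == tm]
  peak_ratio <- mean(Matrix::rowMeans(at$counts$counts[pm$peak_id, cid("1h")])) /
    mean(Matrix::rowMeans(at$counts$counts[pm$peak_id, cid("0h")]))
  gene_ratio <- mean(Matrix::rowMeans(ex$counts$counts[pm$linked_gene, cid("1h")])) /
    mean(Matrix::rowMeans(ex$counts$counts[pm$linked_gene, cid("0h")]))
  expect_gt(peak_ratio, gene_ratio * 1.15)

  # null genotype associations on donor pseudobulk are uniform
  pb <- pseudobulk(at$counts, cells, min_cells = 3)
  Y <- stimqtl:::pb_matrix(pb, "GABA", "0h", "int")
  dose <- g$dosage[rownames(Y), 1]
  pvals <- apply(Y[, 1:120], 2, function(y)
    summary(lm(y ~ dose))$coefficients[2, 4])
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("allelic counts couple to caQTL effects and only het donors emit rows", {
  d <- sim_design(n_donors = 60, n_snps = 200, n_genes = 5, n_peaks = 60,
                  cells_per_donor_context = 30, cell_types = "GABA",
                  module_spec = tibble::tibble(module = character(),
                                               shape = character(),
                                               n_genes = integer()),
                  asoc_kappa = 1, asoc_depth = 60, seed = 16)
  # half null, half with kappa*beta = logit(0.7)
  b <- log(0.7 / 0.3)
  ids <- sprintf("peak%04d", 1:40)
  d$caqtl_spec <- dplyr::bind_rows(
    purrr::list_rbind(lapply(1:20, function(i)
      plant_qtl(d, ids[i], "peak", beta_by_time = 0, cell_types = "GABA"))),
    purrr::list_rbind(lapply(21:40, function(i)
      plant_qtl(d, ids[i], "peak", beta_by_time = b, cell_types = "GABA"))))
  g <- simulate_genotypes(d)
  cells <- simulate_cells(d)
  at <- simulate_accessibility(g, cells, d)
  ac <- simulate_allele_counts(g, at$counts, cells, d)

  # het-only contract
  het <- g$dosage[cbind(ac$donor_id, ac$snp_id)]
  expect_true(all(het == 1))
  expect_true(all(ac$ref_count + ac$alt_count >= 1))

  null_snps <- unique(d$caqtl_spec$snp_id[d$caqtl_spec$beta == 0])
  alt_null <- with(ac[ac$snp_id %in% null_snps, ],
                   sum(alt_count) / sum(alt_count + ref_count))
  expect_lt(abs(alt_null - 0.5), 0.01)
  sig_snps <- setdiff(unique(d$caqtl_spec$snp_id), null_snps)
  alt_sig <- with(ac[ac$snp_id %in% sig_snps, ],
                  sum(alt_count) / sum(alt_count + ref_count))
  expect_lt(abs(alt_sig - 0.7), 0.02)
})

test_that("GWAS z-scores are null-calibrated, track sqrt(n) b, and are deterministic", {
  d <- sim_design(n_donors = 400, n_snps = 400, n_genes = 2, n_peaks = 2,
                  cells_per_donor_context = 1, ld_rho = 0, seed = 17)
  g <- simulate_genotypes(d)
  gw_null <- simulate_gwas(g, d, n_gwas = 10000)
  expect_lt(abs(mean(gw_null$snp$z)), 0.1)
  expect_lt(abs(sd(gw_null$snp$z) - 1), 0.1)
  expect_identical(simulate_gwas(g, d, n_gwas = 10000)$snp$z, gw_null$snp$z)

  # single causal SNP with b = 0.05, independent LD: E[z] = sqrt(n) b = 5
  eff <- tibble::tibble(snp_id = "rs00007", b = 0.05)
  zs <- sapply(1:40, function(i)
    simulate_gwas(g, d, snp_effects = eff, n_gwas = 1e4,
                  seed = 1000 + i)$snp$z)
  z_caus <- mean(zs[7, ])
  expect_lt(abs(z_caus - 5), 3 * 1 / sqrt(40) + 0.4)  # LD leakage is small at rho 0
  far <- mean(abs(rowMeans(zs)[-(1:40)]))
  expect_lt(far, 0.5)
})

test_that("case labels are sized, deterministic, and shift only the planted contexts", {
  d <- sim_design(n_donors = 100, n_snps = 10, n_genes = 60, n_peaks = 2,
                  cells_per_donor_context = 15, cell_types = "npglut",
                  module_spec = tibble::tibble(module = character(),
                                               shape = character(),
                                               n_genes = integer()),
                  case_spec = list(
                    n_cases = 28,
                    de_genes = sprintf("gene%04d", 1:10),
                    lfc = 1,
                    contexts = tibble::tibble(cell_type = "npglut",
                                              time = "6h")),
                  seed = 18)
  labels <- simulate_case_labels(d)
  expect_equal(sum(labels$status == "case"), 28)
  expect_identical(labels, simulate_case_labels(d))

  g <- simulate_genotypes(d)
  cells <- simulate_cells(d)
  ex <- simulate_expression(g, cells, d)
  pb <- pseudobulk(ex$counts, cells, min_cells = 3)
  de0 <- case_control_de(pb, labels, "npglut", "0h")
  de6 <- case_control_de(pb, labels, "npglut", "6h")
  planted <- sprintf("gene%04d", 1:10)
  expect_gt(min(abs(de6$lfc[de6$feature_id %in% planted])), 0.5)
  expect_true(all(de6$q[de6$feature_id %in% planted] < 0.05))
  expect_gt(mean(de0$p[de0$feature_id %in% planted] > 0.05), 0.8)
})
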