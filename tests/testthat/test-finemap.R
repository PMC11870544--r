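test_that("trait models pick the top variant by p and honour the union rule", {
  qtl <- tibble::tibble(
    feature_id = c("pk1", "pk2", "pk3"),
    cell_type = "GABA", time = "0h",
    snp_id = c("sA", "sB", "sC"),
    beta = c(0.5, 0.4, 0.3), se = c(0.05, 0.05, 0.2),
    p_nominal = c(1e-8, 1e-6, 0.2), n_cis = 10, lead = TRUE,
    p_feature = c(1e-7, 1e-5, 1), q = c(1e-6, 1e-4, 0.9),
    significant = c(TRUE, TRUE, FALSE))
  set.seed(100)
  g <- toy_genotypes(matrix(rbinom(40 * 5, 2, 0.4), 40, 5,
                            dimnames = list(NULL, c("sA", "sB", "sC", "sD",
                                                    "sE"))))
  asoc <- tibble::tibble(
    snp_id = c("sD", "sE"), peak_id = c("pk1", "pk4"),
    cell_type = "GABA", time = "0h",
    ref_count = c(40, 10), alt_count = c(80, 40),
    p = c(1e-4, 1e-5), q = c(1e-3, 1e-4), significant = TRUE)

  models <- build_trait_models(qtl, g, kind = "peak", asoc_results = asoc)
  # pk1: caQTL p 1e-8 beats ASoC p 1e-4
  expect_equal(models$snp_id[models$feature_id == "pk1"], "sA")
  expect_equal(models$source[models$feature_id == "pk1"], "caqtl")
  # pk4 has only ASoC: union rule admits it with the ASoC variant
  expect_equal(models$snp_id[models$feature_id == "pk4"], "sE")
  expect_equal(models$source[models$feature_id == "pk4"], "asoc")
  expect_equal(models$weight[models$feature_id == "pk4"], log(40 / 10))
  # pk3 fails the q gate: no trait in that context
  expect_false("pk3" %in% models$feature_id)
  # gene weights are the standardized lead effect
  gm <- build_trait_models(dplyr::mutate(qtl, feature_id = c("g1", "g2", "g3")),
                           g, kind = "gene")
  expect_equal(gm$weight[gm$feature_id == "g1"],
               0.5 * sd(g$dosage[, "sA"]))
})

test_that("trait z imputation reduces correctly for single and multi-SNP weights", {
  R <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("s1", "s2"),
                                                    c("s1", "s2")))
  gwas <- stimqtl:::new_stim_gwas(
    tibble::tibble(snp_id = c("s1", "s2"), z = c(4.2, 1.0), block = "1"),
    n_gwas = 1e4, blocks = list(`1` = list(snp_id = c("s1", "s2"), R = R)))
  single <- tibble::tibble(trait_id = "t1", feature_id = "f",
                           cell_type = "GABA", time = "0h", group = "gene",
                           snp_id = "s1", weight = 0.7, source = "eqtl")
  expect_equal(impute_trait_z(single, gwas)$z, 4.2)
  neg <- dplyr::mutate(single, weight = -0.7)
  expect_equal(impute_trait_z(neg, gwas)$z, -4.2)

  # two-SNP weight: direct matrix arithmetic oracle
  multi <- dplyr::bind_rows(single,
                            dplyr::mutate(single, snp_id = "s2",
                                          weight = 0.3))
  w <- c(0.7, 0.3)
  oracle <- sum(w * c(4.2, 1.0)) / sqrt(drop(t(w) %*% R %*% w))
  expect_equal(impute_trait_z(multi, gwas)$z, oracle)

  # augmented correlation: trait-SNP column follows w'R_col / sqrt(w'Rw)
  tz <- impute_trait_z(multi, gwas)
  aug <- augment_block(gwas$blocks[["1"]], multi, tz,
                       stats::setNames(gwas$snp$z, gwas$snp$snp_id))
  expect_equal(unname(aug$R["s1", "t1"]),
               drop(R["s1", ] %*% w) / sqrt(drop(t(w) %*% R %*% w)))
  expect_equal(unname(aug$R["t1", "t1"]), 1)
  expect_true(isSymmetric(aug$R))
})

test_that("finemap_block matches exact enumeration and handles null and duplicate cases", {
  pri <- c(snp = 0.01, gene = 0.15)
  s2 <- c(snp = 25, gene = 25)

  # two independent variables, strong vs null z
  z <- stats::setNames(c(6, 0), c("v1", "v2"))
  R <- diag(2)
  fm <- finemap_block(z, R, c("gene", "gene"), pri, s2, L = 1)
  oracle <- enumerate_single_effect_pip(z, R, c("gene", "gene"), pri, s2)
  expect_lt(0.5 * sum(abs(fm$pip - oracle)), 1e-10)
  expect_gt(fm$pip[["v1"]], 0.95)

  # all-null z: PIPs stay near the prior level
  z0 <- stats::setNames(rep(0, 5), paste0("n", 1:5))
  fm0 <- finemap_block(z0, diag(5), rep("snp", 5), pri, s2, L = 1)
  expect_true(all(fm0$pip <= pri[["snp"]] + 1e-6))

  # duplicate variable (r = 1) with a strong signal splits the PIP evenly
  Rd <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  zd <- stats::setNames(c(6, 6), c("a", "b"))
  fmd <- finemap_block(zd, Rd, c("snp", "snp"), pri, s2, L = 1)
  expect_equal(unname(fmd$pip["a"]), unname(fmd$pip["b"]))
  expect_lt(abs(sum(fmd$pip) - fmd$pip[["a"]] * 2), 1e-12)

  # random correlated blocks against the enumeration oracle
  set.seed(101)
  worst <- 0
  for (i in 1:25) {
    p <- sample(3:12, 1)
    A <- matrix(rnorm(p * p), p)
    R <- cov2cor(crossprod(A) + diag(p) * 0.5)
    groups <- sample(c("snp", "gene"), p, TRUE)
    b <- rep(0, p)
    b[sample(p, 1)] <- rnorm(1, 0, 5)
    zz <- as.vector(R %*% b) + as.vector(crossprod(chol(R), rnorm(p)))
    names(zz) <- paste0("v", seq_len(p))
    dimnames(R) <- list(names(zz), names(zz))
    fmi <- finemap_block(zz, R, groups, pri, s2, L = 1)
    tv <- 0.5 * sum(abs(fmi$pip -
                          enumerate_single_effect_pip(zz, R, groups, pri, s2)))
    worst <- max(worst, tv)
  }
  expect_lt(worst, 1e-10)

  # tidiers expose the per-variable table
  td <- tidy(fm)
  expect_equal(td$variable, c("v1", "v2"))
  expect_equal(glance(fm)$converged, TRUE)
})

test_that("EM group priors recover planted enrichment and fix empty groups", {
  blocks <- simulate_trait_blocks(120, n_snps = 15, n_gene_traits = 3,
                                  pi = c(snp = 0.004, gene = 0.08,
                                         peak = 0.08),
                                  sigma2 = c(snp = 36, gene = 36, peak = 36),
                                  seed = 102)
  fit <- em_group_priors(blocks, init_pi = c(snp = 0.01, gene = 0.01),
                         init_sigma2 = c(snp = 16, gene = 16), L = 1)
  expect_gt(fit$enrichment[["gene"]], 4)     # planted ratio 20
  expect_lt(fit$enrichment[["gene"]], 80)
  expect_equal(fit$enrichment[["snp"]], 1)
  expect_true(all(tidy(fit)$pip >= 0 & tidy(fit)$pip <= 1))

  # scaling all z magnitudes up raises the fitted effect variance
  blocks2 <- lapply(blocks, function(b) { b$z <- b$z * 2; b })
  fit2 <- em_group_priors(blocks2, init_pi = c(snp = 0.01, gene = 0.01),
                          init_sigma2 = c(snp = 16, gene = 16), L = 1)
  expect_gt(fit2$sigma2[["gene"]], fit$sigma2[["gene"]])

  expect_error(em_group_priors(blocks[1:5], c(snp = .01, gene = .01),
                               c(snp = 16, gene = 16)), ">= 10 blocks")
})

test_that("heritability partition is exact in the degenerate case and null", {
  # a single causal trait explaining all signal takes ~100% of its group
  z <- stats::setNames(c(8, 0.1, -0.2), c("g|GABA_0h", "s1", "s2"))
  fm <- finemap_block(z, diag(3), c("gene", "snp", "snp"),
                      pi = c(gene = 0.1, snp = 0.01),
                      sigma2 = c(gene = 30, snp = 30), L = 1)
  fit <- structure(list(
    pips = tibble::tibble(block = 1, variable = names(z),
                          group = c("gene", "snp", "snp"),
                          pip = unname(fm$pip),
                          ev2 = colSums(fm$alpha * (fm$mu^2 + fm$s2))),
    pi = c(gene = 0.1, snp = 0.01), sigma2 = c(gene = 30, snp = 30),
    enrichment = c(gene = 10, snp = 1), n_iter = 1, converged = TRUE),
    class = "stim_finemap")
  h2 <- heritability_partition(fit)
  expect_gt(h2$h2_pct[h2$group == "gene"], 99)

  h2c <- heritability_partition(fit, by_context = TRUE)
  expect_equal(h2c$context[h2c$group == "gene"], "GABA_0h")

  # null fit: zero shares
  fit0 <- fit
  fit0$pips$pip <- 0
  expect_true(all(heritability_partition(fit0)$h2_pct == 0))
})

test_that("gene PIP aggregation and the dynamic rule are exact pure functions", {
  pips <- tibble::tibble(
    feature_id = c("gA", "gA", "gA", "gB", "gB", "gB", "gC"),
    time = c("0h", "1h", "6h", "0h", "1h", "6h", "1h"),
    pip = c(0.1, 0.4, 0.3, 0.6, 0.1, 0.1, 0.85))
  gp <- aggregate_gene_pip(pips)
  a <- gp[gp$feature_id == "gA", ]
  # 0.4 + 0.3 - 0.1 = 0.6 >= 0.5: dynamic; gene PIP sums to 0.8
  expect_equal(a$gene_pip, 0.8)
  expect_equal(a$class, "dynamic")
  expect_equal(a$confidence, "plausible")
  b <- gp[gp$feature_id == "gB", ]
  # (0.1 + 0.1) - 0.6 < 0.5: static
  expect_equal(b$class, "static")
  cc <- gp[gp$feature_id == "gC", ]
  expect_equal(cc$gene_pip, 0.85)
  expect_equal(cc$confidence, "high")
  expect_equal(cc$class, "dynamic")            # 0.85 - 0 >= 0.5

  # capping and the boundary of the margin
  edge <- aggregate_gene_pip(tibble::tibble(
    feature_id = c("e", "e"), time = c("1h", "6h"), pip = c(0.75, 0.75)))
  expect_equal(edge$gene_pip, 1.5)
  expect_equal(edge$gene_pip_capped, 1)
  exact <- aggregate_gene_pip(tibble::tibble(
    feature_id = c("x", "x"), time = c("0h", "6h"), pip = c(0.2, 0.7)))
  expect_equal(exact$class, "dynamic")         # margin exactly 0.5
})

test_that("cPeak target linking unions the four evidence channels", {
  cp <- tibble::tibble(trait_id = "pk1|GABA_0h", feature_id = "pk1",
                       cell_type = "GABA", time = "0h", group = "peak",
                       snp_id = "sX", weight = 1, source = "caqtl")
  peaks <- tibble::tibble(peak_id = "pk1", chrom = "chr1",
                          start = 1000L, end = 1500L)
  genes <- tibble::tibble(gene_id = c("gIn", "gNear", "gFar"),
                          chrom = "chr1", tss = c(1200L, 5000L, 900000L))
  linked <- tibble::tibble(peak_id = "pk1", gene_id = "gNear",
                           significant = TRUE)
  eqtl <- tibble::tibble(feature_id = "gNear", cell_type = "GABA",
                         time = "0h", snp_id = "sX", q = 0.1)
  abc <- tibble::tibble(gene_id = "gNear", peak_id = "pk1", time = "0h",
                        activity = 1, contact = 1, score = 0.5)
  res <- link_cpeak_targets(cp, linked, eqtl, abc, peaks, genes)
  near <- res[res$gene_id == "gNear", ]
  expect_equal(near$n_evidence, 3L)
  expect_true(grepl("abc", near$evidence) & grepl("coactivation", near$evidence) &
                grepl("eqtl", near$evidence))
  # the overlapping gene is tagged by overlap alone
  gin <- res[res$gene_id == "gIn", ]
  expect_equal(gin$evidence, "overlap")
  expect_false("gFar" %in% res$gene_id)

  # eQTL above the FDR gate is not evidence
  res2 <- link_cpeak_targets(cp, linked, dplyr::mutate(eqtl, q = 0.5),
                             abc, peaks, genes)
  expect_false(grepl("eqtl", res2$evidence[res2$gene_id == "gNear"]))
})
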