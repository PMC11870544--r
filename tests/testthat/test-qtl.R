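make_tiny_pb <- function(seed = 30, n_donors = 40, n_genes = 25,
                         cell_types = "GABA", qtl_spec = NULL,
                         cells_per = 15, donor_sd = 0.3) {
  d <- sim_design(n_donors = n_donors, n_snps = 100, n_genes = n_genes,
                  n_peaks = 2, cells_per_donor_context = cells_per,
                  cell_types = cell_types, donor_sd = donor_sd,
                  module_spec = tibble::tibble(module = character(),
                                               shape = character(),
                                               n_genes = integer()),
                  seed = seed)
  d$qtl_spec <- qtl_spec
  g <- simulate_genotypes(d)
  cells <- simulate_cells(d)
  ex <- simulate_expression(g, cells, d)
  list(design = d, genotypes = g, cells = cells, counts = ex$counts,
       pb = pseudobulk(ex$counts, cells, min_cells = 3))
}

test_that("pseudobulk sums counts per donor and inverse-normal matches the rankit table", {
  counts <- stimqtl:::new_stim_counts(methods::as(Matrix::Matrix(
    matrix(c(3, 5, 0, 2, 7, 1), nrow = 1,
           dimnames = list("g1", paste0("c", 1:6))), sparse = TRUE),
    "CsparseMatrix"))
  cells <- tibble::tibble(cell_id = paste0("c", 1:6),
                          donor_id = rep(c("d1", "d2", "d3"), each = 2),
                          cell_type = "GABA", time = "0h",
                          pseudotime = 0.5)
  pb <- pseudobulk(counts, cells, min_cells = 1)
  # d1 summed 3 + 5 = 8 of library 8 -> log2(1e6 + 1)
  lc <- stimqtl:::pb_matrix(pb, "GABA", "0h", "log2cpm")
  expect_equal(unname(lc["d1", "g1"]), log2(1e6 + 1))

  # rankit mapping for n = 5 against the closed-form table
  x <- c(0.3, -1, 2, 0.7, 0.31)
  expect_equal(inverse_normal_transform(x),
               qnorm((c(2, 1, 5, 4, 3) - 0.5) / 5))

  # min_cells exclusion is recorded
  cells2 <- cells
  cells2$donor_id <- c("d1", "d1", "d1", "d2", "d2", "d3")
  pb2 <- pseudobulk(counts, cells2, min_cells = 2)
  expect_equal(pb2$excluded$donor_id, "d3")
  expect_false("d3" %in% rownames(stimqtl:::pb_matrix(pb2, "GABA", "0h")))

  expect_error(pseudobulk(counts, cells, min_cells = 0), "min_cells")
})

test_that("map_qtl recovers planted effects and is calibrated under the null", {
  qtl <- purrr::list_rbind(lapply(1:10, function(i)
    plant_qtl(sim_design(n_donors = 40, n_snps = 100, n_genes = 25,
                         n_peaks = 2, cell_types = "GABA", seed = 30,
                         module_spec = tibble::tibble(module = character(),
                                                      shape = character(),
                                                      n_genes = integer())),
              sprintf("gene%04d", i), "gene", beta_by_time = 0.9,
              cell_types = "GABA")))
  fx <- make_tiny_pb(seed = 30, qtl_spec = qtl)
  res <- map_qtl(fx$pb, fx$genotypes, fx$design$genes, "gene",
                 n_geno_pc = 0, n_pheno_pc = 0)
  res0 <- res[res$time == "0h", ]
  planted <- sprintf("gene%04d", 1:10)
  expect_gt(mean(res0$significant[res0$feature_id %in% planted]), 0.7)
  expect_equal(res0$q, bh_brute(res0$p_feature), tolerance = 1e-12)
  # feature-level p is Bonferroni of the lead
  expect_equal(res0$p_feature,
               pmin(1, res0$p_nominal * res0$n_cis))

  # global null: eGene rate at q < .05 stays near zero
  fx0 <- make_tiny_pb(seed = 31)
  null_res <- map_qtl(fx0$pb, fx0$genotypes, fx0$design$genes, "gene",
                      n_geno_pc = 0, n_pheno_pc = 0)
  expect_lt(mean(null_res$significant), 0.05 + 0.05)

  # a covariate equal to a tested dosage raises a rank-deficiency error
  bad_cov <- fx$genotypes$dosage[, fx$design$qtl_spec$snp_id[1], drop = FALSE]
  colnames(bad_cov) <- "cov1"
  expect_error(map_qtl(fx$pb, fx$genotypes, fx$design$genes, "gene",
                       n_geno_pc = 0, n_pheno_pc = 0, covariates = bad_cov),
               "rank deficiency")
})

test_that("dynamic_qtl flags planted interactions, not static effects, and falls back on boundary fits", {
  ids <- sprintf("gene%04d", 1:20)
  d0 <- sim_design(n_donors = 60, n_snps = 100, n_genes = 25, n_peaks = 2,
                   cell_types = "GABA", seed = 33,
                   module_spec = tibble::tibble(module = character(),
                                                shape = character(),
                                                n_genes = integer()))
  spec <- dplyr::bind_rows(
    purrr::list_rbind(lapply(1:10, function(i)
      plant_qtl(d0, ids[i], "gene",
                beta_by_time = c(`0h` = 0, `1h` = 0, `6h` = 1),
                cell_types = "GABA"))),
    purrr::list_rbind(lapply(11:20, function(i)
      plant_qtl(d0, ids[i], "gene", beta_by_time = 0.8,
                cell_types = "GABA"))))
  fx <- make_tiny_pb(seed = 33, n_donors = 60, qtl_spec = spec)
  leads <- dplyr::distinct(spec[, c("feature_id", "snp_id")])
  dyn <- dynamic_qtl(fx$pb, fx$genotypes, leads, "GABA")
  expect_gt(mean(dyn$class[dyn$feature_id %in% ids[1:10]] == "dynamic"), 0.7)
  expect_lt(mean(dyn$class[dyn$feature_id %in% ids[11:20]] == "dynamic"), 0.3)
  expect_true(all(dyn$q_1h >= dyn$p_1h - 1e-12))

  # donor_sd = 0 drives the variance component to the boundary -> OLS note
  fx0 <- make_tiny_pb(seed = 34, n_donors = 30, donor_sd = 0)
  leads0 <- tibble::tibble(feature_id = sprintf("gene%04d", 1:5),
                           snp_id = fx0$design$snps$snp_id[1:5])
  expect_message(dynamic_qtl(fx0$pb, fx0$genotypes, leads0, "GABA"),
                 "boundary")
})

test_that("pi1 recovers mixtures and rejects unstable inputs", {
  set.seed(40)
  expect_lt(pi1(runif(5000))$pi1, 0.03)
  mix <- c(rbeta(1500, 0.1, 1), runif(3500))
  expect_lt(abs(pi1(mix)$pi1 - 0.3), 0.05)
  expect_equal(pi1(rep(1e-9, 100))$pi1, 1)
  expect_error(pi1(runif(10)), "at least 50")
  expect_error(pi1(c(runif(60), 2)), "0, 1")
})

test_that("qtl_concordance is exact on identity and invariant to allele flips", {
  a <- tibble::tibble(feature_id = paste0("f", 1:50), snp_id = paste0("s", 1:50),
                      ref = "A", alt = "G", beta = rnorm(50))
  ident <- qtl_concordance(a, a)
  expect_equal(ident$sign_concordance, 1)
  expect_equal(ident$slope, 1)
  expect_equal(ident$r, 1)

  # noisy copy: zero-intercept slope close to 1
  set.seed(41)
  b <- a
  b$beta <- a$beta + rnorm(50, 0, 0.05)
  expect_lt(abs(qtl_concordance(a, b)$slope - 1), 0.05)

  # allele-flipped duplicate realigns exactly
  fl <- a
  fl$ref <- "G"
  fl$alt <- "A"
  fl$beta <- -a$beta
  flipped <- qtl_concordance(a, fl)
  expect_equal(flipped$slope, 1)
  expect_equal(flipped$r, 1)

  expect_error(qtl_concordance(a, dplyr::mutate(a, snp_id = paste0("x", snp_id))),
               "no overlapping")
})

test_that("sharing_matrix reflects planted cross-context structure", {
  lead <- tidyr::expand_grid(feature_id = paste0("f", 1:30),
                             cell_type = c("GABA", "npglut"), time = "0h")
  lead$snp_id <- paste0("s", match(lead$feature_id, paste0("f", 1:30)))
  lead$beta <- rep(rnorm(30), each = 2)
  lead$p_nominal <- 1e-6
  lead$significant <- TRUE
  sm <- sharing_matrix(lead)
  expect_true(all(sm$replication == 1))
  expect_equal(nrow(sm), 2)

  # independent null contexts: replication about .025 (sign gate halves 5%)
  set.seed(42)
  null_lead <- tidyr::expand_grid(feature_id = paste0("f", 1:400),
                                  cell_type = c("GABA", "npglut"),
                                  time = "0h")
  null_lead$snp_id <- paste0("s", match(null_lead$feature_id,
                                        paste0("f", 1:400)))
  null_lead$beta <- rnorm(nrow(null_lead))
  null_lead$p_nominal <- runif(nrow(null_lead))
  null_lead$significant <- null_lead$cell_type == "GABA"  # A sig, B null
  sm0 <- sharing_matrix(null_lead)
  rep_ab <- sm0$replication[sm0$context_a == "GABA_0h"]
  expect_lt(abs(rep_ab - 0.025), 0.03)
})
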