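#' Read a sparse count matrix with feature and barcode sidecars
#'
#' Loads a MatrixMarket coordinate file together with its feature and
#' barcode TSVs (the layout emitted by the common single-cell pipelines and
#' by [write_count_matrix()]). Counts must be non-negative integers.
#'
#' @param mtx_path path to a MatrixMarket `.mtx` file (features x cells).
#' @param features_path TSV without header; first column is the feature id
#'   (additional columns are kept as `feature_meta`).
#' @param barcodes_path TSV without header; single column of cell barcodes.
#' @return a `stim_counts` object: a list with `counts` (a
#'   `Matrix::dgCMatrix`, features in rows, cells in columns, dimnames set),
#'   `features` (character) and `cells` (character).
#' @export
read_count_matrix <- function(mtx_path, features_path, barcodes_path) {
  m <- Matrix::readMM(mtx_path)
  if (length(m@x) > 0 && (any(m@x < 0) || any(m@x != round(m@x)))) {
    abort("count matrix contains negative or non-integer entries")
  }
  feats <- readr::read_tsv(features_path, col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE)
  cells <- readr::read_tsv(barcodes_path, col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE)
  if (nrow(feats) != nrow(m) || nrow(cells) != ncol(m)) {
    abort(sprintf(
      "dimension mismatch: matrix is %d x %d but %d features / %d barcodes",
      nrow(m), ncol(m), nrow(feats), nrow(cells)))
  }
  counts <- methods::as(m, "CsparseMatrix")
  dimnames(counts) <- list(as.character(feats[[1]]), as.character(cells[[1]]))
  new_stim_counts(counts)
}

new_stim_counts <- function(counts) {
  structure(
    list(counts = counts, features = rownames(counts), cells = colnames(counts)),
    class = "stim_counts")
}

#' @export
print.stim_counts <- function(x, ...) {
  cat(sprintf("<stim_counts> %d features x %d cells (%.1f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' Write a count matrix as MTX plus TSV sidecars
#'
#' Exact inverse of [read_count_matrix()] on valid data.
#'
#' @param x a `stim_counts` object or a sparse/dense integer matrix
#'   (features x cells) with dimnames.
#' @param dir output directory; `matrix.mtx`, `features.tsv` and
#'   `barcodes.tsv` are created inside it.
#' @return invisibly, the three file paths.
#' @export
write_count_matrix <- function(x, dir) {
  counts <- if (inherits(x, "stim_counts")) x$counts else x
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"), paths[1])
  readr::write_tsv(tibble(id = rownames(counts)), paths[2], col_names = FALSE)
  readr::write_tsv(tibble(id = colnames(counts)), paths[3], col_names = FALSE)
  invisible(paths)
}

#' Read donor genotypes from a minimal VCF or the TSV dosage dialect
#'
#' Two on-disk forms are supported. A VCF (detected by a `.vcf` extension or
#' a `##fileformat=VCF` first line) is parsed with \pkg{vcfR}; only the GT
#' field is used and alleles are counted, so `0/1` and `1|0` both give
#' dosage 1. The TSV dialect has header
#' `snp_id chrom pos ref alt <donor ids...>` with dosage entries in
#' `{0, 1, 2}`. Missing genotypes (`./.` or `NA`) are rejected unless
#' `impute_missing = TRUE`, in which case they are replaced by the SNP's
#' mean dosage.
#'
#' @param path input file.
#' @param impute_missing replace missing dosages by the per-SNP mean
#'   (default `FALSE`: missing entries are an error).
#' @return a `stim_genotypes` object: list with `dosage` (donors x SNPs
#'   numeric matrix with dimnames), `snps` (tibble: `snp_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `maf`) and `donors` (character). `maf` is the
#'   folded empirical allele frequency, in (0, 0.5].
#' @export
read_genotypes <- function(path, impute_missing = FALSE) {
  first <- readLines(path, n = 1L)
  if (grepl("\\.vcf(\\.gz)?$", path) || grepl("^##fileformat=VCF", first)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    dos <- gt_to_dosage(gt)
    snps <- tibble(snp_id = fix$ID, chrom = fix$CHROM,
                   pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT)
    donors <- colnames(gt)
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("snp_id", "chrom", "pos", "ref", "alt")
    if (!all(need %in% names(tab))) {
      abort("genotype TSV must start with columns snp_id chrom pos ref alt")
    }
    donors <- setdiff(names(tab), need)
    dos <- t(as.matrix(tab[, donors, drop = FALSE]))
    bad <- !(dos %in% c(0, 1, 2) | is.na(dos))
    if (any(bad)) abort("genotype entries must be 0, 1, 2 or missing")
    snps <- tab[, need]
    snps$pos <- as.integer(snps$pos)
  }
  if (anyNA(dos)) {
    if (!impute_missing) {
      abort("missing genotypes found; set impute_missing = TRUE to mean-impute")
    }
    for (j in which(colSums(is.na(dos)) > 0)) {
      dos[is.na(dos[, j]), j] <- mean(dos[, j], na.rm = TRUE)
    }
  }
  dimnames(dos) <- list(donors, snps$snp_id)
  af <- unname(colMeans(dos)) / 2
  snps$maf <- pmin(af, 1 - af)
  new_stim_genotypes(dos, snps)
}

# GT strings -> dosage matrix (SNPs x donors in, donors x SNPs out)
gt_to_dosage <- function(gt) {
  parse1 <- function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (!all(alleles %in% c("0", "1"))) {
      abort(sprintf("unsupported GT entry '%s' (biallelic 0/1 only)", g))
    }
    sum(alleles == "1")
  }
  out <- vapply(seq_len(ncol(gt)), function(j) {
    vapply(gt[, j], parse1, numeric(1), USE.NAMES = FALSE)
  }, numeric(nrow(gt)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(gt))
  t(matrix(out, nrow = nrow(gt), dimnames = list(rownames(gt), colnames(gt))))
}

new_stim_genotypes <- function(dosage, snps) {
  stopifnot(nrow(snps) == ncol(dosage))
  structure(list(dosage = dosage, snps = snps, donors = rownames(dosage)),
            class = "stim_genotypes")
}

#' @export
print.stim_genotypes <- function(x, ...) {
  cat(sprintf("<stim_genotypes> %d donors x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Write genotypes in the TSV dosage dialect
#'
#' @param genotypes a `stim_genotypes` object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_genotypes <- function(genotypes, path) {
  tab <- dplyr::bind_cols(
    genotypes$snps[, c("snp_id", "chrom", "pos", "ref", "alt")],
    as_tibble(t(genotypes$dosage)))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Read peak intervals from a BED file
#'
#' Intervals keep the BED convention: 0-based, half-open. When the file has
#' no name column, ids are synthesized as `"chrom:start-end"`.
#'
#' @param path a BED3+ file.
#' @return tibble with `peak_id`, `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  start0 <- GenomicRanges::start(gr) - 1L
  end <- GenomicRanges::end(gr)
  if (any(start0 >= end)) abort("BED intervals must satisfy start < end")
  nm <- gr$name
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (is.null(nm) || all(is.na(nm))) {
    nm <- sprintf("%s:%d-%d", chrom, start0, end)
  }
  tibble(peak_id = nm, chrom = chrom, start = start0, end = end)
}

#' Write peak intervals as BED4
#'
#' @param peaks tibble with `peak_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(all(c("peak_id", "chrom", "start", "end") %in% names(peaks)))
  if (any(peaks$start >= peaks$end)) {
    abort("BED intervals must satisfy start < end")
  }
  readr::write_tsv(peaks[, c("chrom", "start", "end", "peak_id")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a contact map (bedpe-like TSV)
#'
#' Columns: `chrom_a start_a end_a chrom_b start_b end_b freq time`.
#' Lookups through [abc_scores()] are symmetric in the two anchors.
#'
#' @param path input TSV with header.
#' @return tibble of contact records.
#' @export
read_contacts <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b",
            "freq", "time")
  if (!all(need %in% names(tab))) {
    abort("contact TSV must have columns chrom_a..end_b, freq, time")
  }
  if (any(tab$freq < 0)) abort("contact frequencies must be non-negative")
  tab
}

#' Cis windows around genes and peaks
#'
#' For a gene the window is `[tss - w, tss + w]`; for a peak it is the
#' interval extended by `w` on both sides. Windows are 1-based inclusive in
#' SNP coordinates (the peak's BED start is converted once, here) and are
#' clipped at position 1. A SNP is *cis* to the feature iff its `pos` lies
#' inside the window on the same chromosome.
#'
#' @param features tibble of features: needs `chrom` plus either `tss`
#'   (genes) or `start`/`end` (peaks, 0-based half-open).
#' @param half_width_bp window half-width in bp (> 0 required for peaks'
#'   extension to make sense; 0 is allowed and gives a degenerate window).
#' @return the input tibble with added `window_lo`, `window_hi` columns.
#' @export
cis_window <- function(features, half_width_bp) {
  if (half_width_bp < 0) abort("half_width_bp must be >= 0")
  w <- half_width_bp
  if ("tss" %in% names(features)) {
    lo <- features$tss - w
    hi <- features$tss + w
  } else if (all(c("start", "end") %in% names(features))) {
    lo <- features$start + 1 - w
    hi <- features$end + w
  } else {
    abort("features need a tss column (genes) or start/end columns (peaks)")
  }
  features$window_lo <- pmax(1, lo)
  features$window_hi <- hi
  features
}

# cis SNP indices for one feature row (already carrying window_lo/hi)
cis_snp_ids <- function(feature_row, snps) {
  snps$snp_id[snps$chrom == feature_row$chrom &
              snps$pos >= feature_row$window_lo &
              snps$pos <= feature_row$window_hi]
}

#' Read GWAS summary statistics plus LD blocks
#'
#' `path_z` is a TSV with columns `snp_id`, `z`, `block` and an `n` column
#' (the GWAS sample size, constant). `path_ld` is a long-format TSV with
#' columns `block`, `snp_a`, `snp_b`, `r` giving each block's correlation
#' matrix (upper triangle is enough; symmetry and unit diagonal are filled
#' in).
#'
#' @param path_z,path_ld input TSV paths.
#' @return a `stim_gwas` object: list with `snp` (tibble: snp_id, z, block),
#'   `n_gwas`, and `blocks` (named list of lists with `snp_id` and `R`).
#' @export
read_gwas <- function(path_z, path_ld) {
  zt <- readr::read_tsv(path_z, show_col_types = FALSE, progress = FALSE)
  ld <- readr::read_tsv(path_ld, show_col_types = FALSE, progress = FALSE)
  blocks <- lapply(split(zt$snp_id, zt$block), function(ids) {
    R <- diag(length(ids))
    dimnames(R) <- list(ids, ids)
    list(snp_id = ids, R = R)
  })
  for (i in seq_len(nrow(ld))) {
    b <- as.character(ld$block[i])
    R <- blocks[[b]]$R
    R[ld$snp_a[i], ld$snp_b[i]] <- ld$r[i]
    R[ld$snp_b[i], ld$snp_a[i]] <- ld$r[i]
    blocks[[b]]$R <- R
  }
  new_stim_gwas(zt[, c("snp_id", "z", "block")], unique(zt$n)[1], blocks)
}

new_stim_gwas <- function(snp, n_gwas, blocks) {
  structure(list(snp = snp, n_gwas = n_gwas, blocks = blocks),
            class = "stim_gwas")
}

#' Write GWAS summary statistics plus LD blocks
#'
#' Inverse of [read_gwas()].
#'
#' @param gwas a `stim_gwas` object.
#' @param path_z,path_ld output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_gwas <- function(gwas, path_z, path_ld) {
  zt <- gwas$snp
  zt$n <- gwas$n_gwas
  readr::write_tsv(zt, path_z)
  ld <- purrr::imap(gwas$blocks, function(b, nm) {
    R <- b$R
    idx <- which(upper.tri(R) & abs(R) > 1e-12, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    tibble(block = nm, snp_a = b$snp_id[idx[, 1]],
           snp_b = b$snp_id[idx[, 2]], r = R[idx])
  })
  ld <- dplyr::bind_rows(ld)
  if (nrow(ld) == 0) ld <- tibble(block = character(), snp_a = character(),
                                  snp_b = character(), r = double())
  readr::write_tsv(ld, path_ld)
  invisible(c(path_z, path_ld))
}

#' @export
print.stim_gwas <- function(x, ...) {
  cat(sprintf("<stim_gwas> %d SNPs in %d LD blocks, n = %s\n",
              nrow(x$snp), length(x$blocks), format(x$n_gwas)))
  invisible(x)
}
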