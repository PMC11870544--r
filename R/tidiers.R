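#' Tidy a module clustering
#'
#' @param x a `stim_modules` from [cluster_modules()].
#' @param ... unused.
#' @return the gene-to-cluster assignment tibble.
#' @export
tidy.stim_modules <- function(x, ...) x$assignment

#' @rdname tidy.stim_modules
#' @return for `glance()`: one-row tibble with `k`, `n_genes`,
#'   `tot_withinss`, and the smallest/largest cluster sizes.
#' @export
glance.stim_modules <- function(x, ...) {
  sizes <- table(x$assignment$cluster)
  tibble(k = x$k, n_genes = nrow(x$assignment),
         tot_withinss = x$tot_withinss,
         min_cluster = as.integer(min(sizes)),
         max_cluster = as.integer(max(sizes)))
}

#' Tidy a fitted group-prior fine-mapping model
#'
#' @param x a `stim_finemap` from [em_group_priors()].
#' @param ... unused.
#' @return per-variable tibble (`block`, `variable`, `group`, `pip`,
#'   `ev2`).
#' @export
tidy.stim_finemap <- function(x, ...) x$pips

#' @rdname tidy.stim_finemap
#' @return for `glance()`: one row per group with the fitted prior
#'   inclusion probability, prior effect variance, enrichment over SNPs,
#'   and EM diagnostics.
#' @export
glance.stim_finemap <- function(x, ...) {
  tibble(group = names(x$pi), pi = unname(x$pi),
         sigma2 = unname(x$sigma2), enrichment = unname(x$enrichment),
         n_iter = x$n_iter, converged = x$converged)
}

#' Tidy a single fine-mapped block
#'
#' @param x a `stim_finemap_block` from [finemap_block()].
#' @param ... unused.
#' @return tibble(`variable`, `group`, `pip`, `lbf`).
#' @export
tidy.stim_finemap_block <- function(x, ...) {
  tibble(variable = names(x$pip), group = x$groups,
         pip = unname(x$pip), lbf = unname(x$lbf))
}

#' @rdname tidy.stim_finemap_block
#' @export
glance.stim_finemap_block <- function(x, ...) {
  tibble(n_variables = length(x$pip), n_iter = x$n_iter,
         converged = x$converged, max_pip = max(x$pip))
}
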