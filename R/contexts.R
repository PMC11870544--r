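#' Cellular contexts of the stimulation design
#'
#' The experimental design crosses three iPSC-derived neuronal cell types
#' (GABAergic, NEFM- glutamatergic "nmglut", NEFM+ glutamatergic "npglut")
#' with three time points of KCl depolarization (0, 1 and 6 hours), giving
#' nine "contexts". All per-context analyses (pseudobulk, QTL mapping, ASoC,
#' differential tests) are keyed on the `(cell_type, time)` pair.
#'
#' @return `contexts()` returns a 9-row tibble with columns `cell_type`,
#'   `time` and `context` (the `"<cell_type>_<time>"` label).
#' @export
#' @examples
#' contexts()
contexts <- function() {
  grid <- expand.grid(time = stim_times(), cell_type = stim_cell_types(),
                      stringsAsFactors = FALSE)
  tibble(
    cell_type = grid$cell_type,
    time = grid$time,
    context = context_label(grid$cell_type, grid$time)
  )
}

#' @rdname contexts
#' @export
stim_cell_types <- function() c("GABA", "nmglut", "npglut")

#' @rdname contexts
#' @export
stim_times <- function() c("0h", "1h", "6h")

#' @rdname contexts
#' @param cell_type,time character vectors (recycled).
#' @export
context_label <- function(cell_type, time) paste(cell_type, time, sep = "_")

# validate a cells annotation tibble; returns it with checked columns
check_cells <- function(cells) {
  need <- c("cell_id", "donor_id", "cell_type", "time", "pseudotime")
  missing <- setdiff(need, names(cells))
  if (length(missing) > 0) {
    abort(paste0("cell annotation is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad_ct <- setdiff(unique(cells$cell_type), stim_cell_types())
  bad_t <- setdiff(unique(cells$time), stim_times())
  if (length(bad_ct) > 0 || length(bad_t) > 0) {
    abort("cell annotation contains unknown cell types or time points")
  }
  if (anyNA(cells$pseudotime) ||
      any(cells$pseudotime < 0 | cells$pseudotime > 1)) {
    abort("pseudotime must be defined for every cell and lie in [0, 1]")
  }
  cells
}
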