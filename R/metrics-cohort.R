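#' Compute global network metrics for every subject in a cohort
#'
#' Adds the raw measures (`C_raw`, `Q`, `L_raw`, `E`) and the
#' null-normalized measures (`gamma`, `lambda`, `sigma`) to a cohort tibble
#' with a `connectome` list-column. Each subject's null ensemble gets its
#' own seed derived from `seed` and the subject's position, so results do
#' not depend on evaluation order.
#'
#' @param cohort Tibble with columns `subject_id` and `connectome` (list of
#'   connectivity matrices), e.g. from [generate_cohort()].
#' @param n_null Null networks per subject for the normalization
#'   (reference analysis: 1000; default here 100).
#' @param swaps_per_edge Swap attempts per edge in each null network.
#' @param n_restarts Louvain restarts for modularity.
#' @param seed Integer seed fanned out per subject.
#' @param keep_connectome Keep the `connectome` list-column in the output?
#' @param normalize Compute the null-normalized measures? Disable for toy
#'   graphs where the null ensemble has no triangles (gamma undefined).
#' @return The cohort tibble with metric columns appended (class
#'   `tractnet_metrics`).
#' @export
compute_network_metrics <- function(cohort, n_null = 100,
                                    swaps_per_edge = 10, n_restarts = 20,
                                    seed = 1, keep_connectome = FALSE,
                                    normalize = TRUE) {
  stopifnot(is.data.frame(cohort), "connectome" %in% names(cohort))
  rows <- purrr::imap(cohort$connectome, function(w, i) {
    s <- subject_seed(seed, i)
    raw <- network_metrics(w, n_restarts = n_restarts, seed = s)
    if (!normalize) return(raw)
    norm <- normalize_metrics(w, n_null = n_null,
                              swaps_per_edge = swaps_per_edge, seed = s,
                              raw = raw)
    dplyr::bind_cols(raw, norm)
  })
  out <- dplyr::bind_cols(
    cohort[setdiff(names(cohort),
                   c("connectome", "n_edges", "total_strength"))],
    dplyr::bind_rows(rows)
  )
  if (keep_connectome) out$connectome <- cohort$connectome
  class(out) <- c("tractnet_metrics", setdiff(class(out), "tractnet_cohort"))
  out
}

#' Write / read a cohort metrics table
#'
#' Plain CSV with one row per subject (`subject_id`, covariates, raw and
#' normalized measures).
#'
#' @param metrics Metrics tibble from [compute_network_metrics()].
#' @param path File path.
#' @export
write_metrics_csv <- function(metrics, path) {
  readr::write_csv(dplyr::select(metrics, -dplyr::any_of("connectome")), path)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if ("group" %in% names(out)) {
    out$group <- factor(out$group, levels = c("control", "patient"))
  }
  class(out) <- c("tractnet_metrics", class(out))
  out
}
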