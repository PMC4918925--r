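#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy group-comparison results
#'
#' @param x A `tractnet_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return Plain tibble, one row per measure.
#' @export
tidy.tractnet_comparison <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "tractnet_comparison")
  out
}

#' @rdname tidy.tractnet_comparison
#' @export
glance.tractnet_comparison <- function(x, ...) {
  grp <- attr(x, "groups")
  tibble::tibble(
    n_measures = nrow(x),
    n_significant = sum(x$q < 0.05),
    n_perm = attr(x, "n_perm"),
    n_control = unname(grp["control"]),
    n_patient = unname(grp["patient"])
  )
}

#' Tidy partial-correlation results
#'
#' @param x A `tractnet_correlation` from [correlate_measures()].
#' @param ... Unused.
#' @return Plain tibble, one row per measure-covariate pair.
#' @export
tidy.tractnet_correlation <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "tractnet_correlation")
  out
}

#' @rdname tidy.tractnet_correlation
#' @export
glance.tractnet_correlation <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_significant = sum(x$q < 0.05),
    n = x$n[1],
    controls = paste(attr(x, "controls"), collapse = ", ")
  )
}

#' Tidy a full cohort analysis
#'
#' @param x A `tractnet_analysis` from [analyze_cohort()].
#' @param which `"group"` or `"correlation"`.
#' @param ... Unused.
#' @export
tidy.tractnet_analysis <- function(x, which = c("group", "correlation"),
                                   ...) {
  which <- match.arg(which)
  if (which == "group") tidy(x$group_comparisons) else tidy(x$correlations)
}

#' @rdname tidy.tractnet_analysis
#' @export
glance.tractnet_analysis <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$group_comparisons),
    dplyr::rename_with(glance(x$correlations),
                       function(nm) paste0("corr_", nm))
  )
}
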