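#' Two-sample permutation test on group means
#'
#' Statistic: difference of group means (first level minus second). The
#' two-sided p-value uses the add-one convention,
#' `p = (1 + #{|diff_perm| >= |diff_obs|}) / (1 + n_perm)`, so p is never
#' exactly 0. Group labels are permuted uniformly at random.
#'
#' @param values Numeric vector of per-subject values.
#' @param groups Vector/factor of two group labels, both with >= 2 subjects.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Optional integer seed.
#' @return List with `difference` (observed mean difference), `p`, and the
#'   group means.
#' @export
permutation_test <- function(values, groups, n_perm = 10000, seed = NULL) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("both groups need at least 2 subjects", call. = FALSE)
  }
  if (length(values) != length(groups) || anyNA(values)) {
    stop("values and groups must align and be complete", call. = FALSE)
  }
  g1 <- groups == levels(groups)[1]
  n1 <- sum(g1)
  obs <- mean(values[g1]) - mean(values[!g1])
  if (stats::var(values) == 0) {
    return(list(difference = 0, p = 1,
                mean_1 = mean(values[g1]), mean_2 = mean(values[!g1])))
  }
  run <- function() {
    total <- sum(values)
    n <- length(values)
    n2 <- n - n1
    vapply(seq_len(n_perm), function(b) {
      s1 <- sum(values[sample.int(n, n1)])
      s1 / n1 - (total - s1) / n2
    }, numeric(1))
  }
  perm <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (1 + n_perm)
  list(difference = obs, p = p,
       mean_1 = mean(values[g1]), mean_2 = mean(values[!g1]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over `p.adjust(method = "BH")`, the step-up false discovery
#' rate control with monotonicity enforcement.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Vector of q-values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p <= 0 | p > 1)) stop("p-values must be in (0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Partial correlation with covariate residualization
#'
#' Residualizes `x` and `y` on an intercept plus the covariate columns by
#' least squares, correlates the residuals, and tests
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k` degrees of
#' freedom (two-sided), `k` = number of covariates. With no covariates this
#' reduces to the plain Pearson correlation and its usual t-test.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix/data frame of confounds, one
#'   row per subject; must be full rank.
#' @return List with `r`, `p`, `df`, and `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have the same length", call. = FALSE)
  k <- 0
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) {
      stop("covariates must have one row per subject", call. = FALSE)
    }
    k <- ncol(covariates)
    design <- cbind(`(intercept)` = 1, covariates)
    qr_d <- qr(design)
    if (qr_d$rank < ncol(design)) {
      dropped <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
      stop("covariate matrix is rank deficient; collinear column(s): ",
           paste(dropped, collapse = ", "), call. = FALSE)
    }
    x <- qr.resid(qr_d, x)
    y <- qr.resid(qr_d, y)
  } else {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  if (n <= k + 2) stop("need n > k + 2 subjects", call. = FALSE)
  r <- cor(x, y)
  df <- n - 2 - k
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), df), df = df, n = n)
}

#' Group comparison of global network measures
#'
#' Runs one two-sample permutation test per measure and applies
#' Benjamini-Hochberg FDR correction across the family of measures.
#'
#' @param metrics Metrics tibble (one row per subject) with a `group`
#'   column, e.g. from [compute_network_metrics()].
#' @param measures Character vector of measure columns to test (default:
#'   the five reported global measures).
#' @param n_perm Permutations per test.
#' @param seed Integer seed.
#' @return Tibble of class `tractnet_comparison`: one row per measure with
#'   group means/sds, observed difference (control minus patient), `p`, `q`.
#' @export
compare_groups <- function(metrics,
                           measures = c("gamma", "Q", "lambda", "E", "sigma"),
                           n_perm = 10000, seed = 1) {
  stopifnot("group" %in% names(metrics))
  missing_m <- setdiff(measures, names(metrics))
  if (length(missing_m)) {
    stop("measures not in metrics table: ", paste(missing_m, collapse = ", "),
         call. = FALSE)
  }
  grp <- factor(metrics$group, levels = c("control", "patient"))
  rows <- purrr::imap(setNames(measures, measures), function(msr, nm) {
    v <- metrics[[msr]]
    pt_res <- permutation_test(v, grp, n_perm = n_perm,
                               seed = subject_seed(seed, match(nm, measures)))
    tibble::tibble(
      measure = nm,
      mean_control = mean(v[grp == "control"]),
      sd_control = sd(v[grp == "control"]),
      mean_patient = mean(v[grp == "patient"]),
      sd_patient = sd(v[grp == "patient"]),
      difference = pt_res$difference,
      p = pt_res$p
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q <- bh_fdr(out$p)
  attr(out, "n_perm") <- n_perm
  attr(out, "groups") <- table(grp)
  attr(out, "subject_values") <-
    dplyr::select(tibble::as_tibble(metrics),
                  dplyr::any_of(c("subject_id", "group", measures)))
  class(out) <- c("tractnet_comparison", class(out))
  out
}

#' Partial correlations between network measures and glucose covariates
#'
#' For each glucose covariate, correlates every network measure with the
#' covariate after residualizing both on the confounds (default: age, sex,
#' number of connections, total connection strength), with BH-FDR applied
#' within each covariate's family of measures.
#'
#' @param metrics Metrics tibble with measure, covariate and confound
#'   columns.
#' @param covariates Glucose covariate columns (default HbA1c and FPG).
#' @param measures Measure columns to correlate.
#' @param controls Confound columns to residualize on.
#' @param subset Optional logical vector selecting subjects (e.g.
#'   `metrics$group == "patient"`); default all subjects.
#' @return Tibble of class `tractnet_correlation`: one row per
#'   measure-covariate pair with partial `r`, `p`, `q`, `n`.
#' @export
correlate_measures <- function(metrics,
                               covariates = c("hba1c", "fpg"),
                               measures = c("gamma", "Q", "lambda", "E",
                                            "sigma"),
                               controls = c("age", "sex", "n_edges",
                                            "total_strength"),
                               subset = NULL) {
  need <- c(covariates, measures, controls)
  missing_c <- setdiff(need, names(metrics))
  if (length(missing_c)) {
    stop("columns not in metrics table: ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(subset)) metrics <- metrics[subset, , drop = FALSE]
  cmat <- as.matrix(metrics[, controls, drop = FALSE])
  out <- purrr::map_dfr(covariates, function(cv) {
    fam <- purrr::map_dfr(measures, function(msr) {
      pc <- partial_correlation(metrics[[msr]], metrics[[cv]],
                                covariates = cmat)
      tibble::tibble(measure = msr, covariate = cv,
                     r = pc$r, p = pc$p, n = pc$n)
    })
    fam$q <- bh_fdr(fam$p)
    fam
  })
  attr(out, "controls") <- controls
  attr(out, "subject_values") <-
    dplyr::select(tibble::as_tibble(metrics),
                  dplyr::any_of(c("subject_id", "group", covariates,
                                  measures, controls)))
  class(out) <- c("tractnet_correlation", class(out))
  out
}

#' Full statistical analysis of a cohort metrics table
#'
#' Group permutation tests (FDR across the five global measures) plus
#' covariate-adjusted partial correlations of each measure with HbA1c and
#' FPG (FDR within each glucose variable's family).
#'
#' @inheritParams compare_groups
#' @inheritParams correlate_measures
#' @param records Optional separate subject-records table to join on
#'   `subject_id` (errors on unmatched ids); by default `metrics` already
#'   carries the covariates.
#' @return List of class `tractnet_analysis` with elements
#'   `group_comparisons` and `correlations`.
#' @export
analyze_cohort <- function(metrics, records = NULL,
                           measures = c("gamma", "Q", "lambda", "E", "sigma"),
                           n_perm = 10000, seed = 1, subset = NULL) {
  if (!is.null(records)) {
    unmatched <- c(setdiff(metrics$subject_id, records$subject_id),
                   setdiff(records$subject_id, metrics$subject_id))
    if (length(unmatched)) {
      stop("subject ids do not match between metrics and records: ",
           paste(unique(unmatched), collapse = ", "), call. = FALSE)
    }
    metrics <- dplyr::inner_join(
      metrics, records,
      by = intersect(names(metrics), names(records)))
  }
  res <- list(
    group_comparisons = compare_groups(metrics, measures = measures,
                                       n_perm = n_perm, seed = seed),
    correlations = correlate_measures(metrics, measures = measures,
                                      subset = subset)
  )
  class(res) <- "tractnet_analysis"
  res
}

#' @export
print.tractnet_analysis <- function(x, ...) {
  cat("Structural network analysis\n\nGroup comparisons:\n")
  print(tibble::as_tibble(x$group_comparisons), ...)
  cat("\nPartial correlations (controlling ",
      paste(attr(x$correlations, "controls"), collapse = ", "), "):\n",
      sep = "")
  print(tibble::as_tibble(x$correlations), ...)
  invisible(x)
}
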