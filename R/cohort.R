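#' Synthetic cohort configuration
#'
#' Parameters of the synthetic two-group cohort generator. Each subject's
#' connectome is a Watts-Strogatz-style weighted graph: a ring lattice with
#' `lattice_degree` neighbours per node, each edge rewired to a random
#' shortcut with a group-specific probability; edge weights are integer
#' synthetic streamline counts (log-normal), thresholded at
#' `min_streamlines`, converted to fiber densities (count / total count) and
#' multiplied by the group weight scale. The default shortcut probabilities
#' and weight scales are calibrated (see [calibrate_shortcut_prob()] and
#' [calibrate_weight_scale()]) so that the control and patient ensembles
#' have normalized path length near 1.41 and 1.52 and global efficiency
#' near 0.63e-3 and 0.59e-3 respectively, with integration lower in the
#' patient group and segregation parameters equal by construction.
#'
#' @param n_per_group Subjects per group (default 20).
#' @param n_nodes Network nodes / brain regions (default 144).
#' @param lattice_degree Even number of ring-lattice neighbours per node.
#' @param shortcut_prob_control,shortcut_prob_patient Per-edge rewiring
#'   probability for each group (patient lower: fewer shortcuts, longer
#'   paths).
#' @param weight_scale_control,weight_scale_patient Multiplier applied to
#'   fiber-density weights per group (patient lower: lower efficiency).
#' @param weight_dispersion Log-normal sigma of the synthetic streamline
#'   counts (0 = deterministic counts).
#' @param count_meanlog Log-normal meanlog of the streamline counts; the
#'   default `log(30)` gives whole-brain totals in the tens of thousands.
#' @param min_streamlines Minimum streamline count for an edge to survive
#'   (default 3).
#' @param age_range Two-element numeric; ages drawn uniformly (default
#'   50-59 years, emulating a tightly matched middle-aged cohort).
#' @param male_fraction Fraction of males per group (default 0.45, i.e. 9
#'   of 20).
#' @param cov_corr Named list describing the glucose covariates. Each entry
#'   has `measure` (currently `"E"`), `r` (target correlation with that
#'   measure across the cohort), `mean` and `sd` (units: % for HbA1c,
#'   mmol/L for FPG).
#' @param seed Default integer seed used by [generate_cohort()].
#' @return A list of class `tractnet_config`.
#' @export
cohort_config <- function(n_per_group = 20,
                          n_nodes = 144,
                          lattice_degree = 12,
                          shortcut_prob_control = 0.043,
                          shortcut_prob_patient = 0.0305,
                          weight_scale_control = 1.156,
                          weight_scale_patient = 1.123,
                          weight_dispersion = 1.0,
                          count_meanlog = log(30),
                          min_streamlines = 3,
                          age_range = c(50, 59),
                          male_fraction = 0.45,
                          cov_corr = list(
                            hba1c = list(measure = "E", r = -0.53,
                                         mean = 8.3, sd = 2.5),
                            fpg = list(measure = "E", r = -0.41,
                                       mean = 7.6, sd = 2.5)
                          ),
                          seed = 20160623) {
  cfg <- list(
    n_per_group = n_per_group, n_nodes = n_nodes,
    lattice_degree = lattice_degree,
    shortcut_prob_control = shortcut_prob_control,
    shortcut_prob_patient = shortcut_prob_patient,
    weight_scale_control = weight_scale_control,
    weight_scale_patient = weight_scale_patient,
    weight_dispersion = weight_dispersion,
    count_meanlog = count_meanlog,
    min_streamlines = min_streamlines,
    age_range = age_range, male_fraction = male_fraction,
    cov_corr = cov_corr, seed = seed
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "tractnet_config")
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
    if (lattice_degree %% 2 != 0) {
      stop("lattice_degree must be even", call. = FALSE)
    }
    if (n_nodes < lattice_degree + 1) {
      stop("degenerate config: n_nodes (", n_nodes,
           ") must exceed lattice_degree (", lattice_degree, ")",
           call. = FALSE)
    }
    for (p in c(shortcut_prob_control, shortcut_prob_patient)) {
      if (p < 0 || p > 1) stop("shortcut probabilities must be in [0, 1]",
                               call. = FALSE)
    }
    if (weight_scale_control <= 0 || weight_scale_patient <= 0) {
      stop("weight scales must be positive", call. = FALSE)
    }
    if (weight_dispersion < 0) stop("weight_dispersion must be >= 0",
                                    call. = FALSE)
    if (length(age_range) != 2 || age_range[1] > age_range[2]) {
      stop("age_range must be c(lo, hi)", call. = FALSE)
    }
  })
  invisible(cfg)
}

# One Watts-Strogatz-style weighted connectome. Ring lattice of
# `lattice_degree` neighbours, each edge independently rewired (keeping its
# first endpoint) with probability p; log-normal integer streamline counts;
# counts below min_streamlines dropped; fiber density = count / total count
# (total taken before thresholding) times the group scale.
generate_connectome <- function(n_nodes, lattice_degree, shortcut_prob,
                                weight_scale, weight_dispersion,
                                count_meanlog, min_streamlines) {
  half <- lattice_degree / 2
  from <- rep(seq_len(n_nodes), half)
  to <- from + rep(seq_len(half), each = n_nodes)
  to <- ((to - 1) %% n_nodes) + 1
  m <- length(from)

  adj <- matrix(FALSE, n_nodes, n_nodes)
  adj[cbind(from, to)] <- TRUE
  adj[cbind(to, from)] <- TRUE

  rewire_flag <- runif(m) < shortcut_prob
  for (e in which(rewire_flag)) {
    a <- from[e]; b <- to[e]
    candidates <- which(!adj[a, ])
    candidates <- candidates[candidates != a]
    if (length(candidates) == 0) next
    d <- candidates[sample.int(length(candidates), 1)]
    adj[a, b] <- adj[b, a] <- FALSE
    adj[a, d] <- adj[d, a] <- TRUE
    to[e] <- d
  }

  counts <- round(rlnorm(m, meanlog = count_meanlog, sdlog = weight_dispersion))
  total <- sum(counts)
  counts[counts < min_streamlines] <- 0
  w <- matrix(0, n_nodes, n_nodes)
  dens <- if (total > 0) counts / total * weight_scale else counts * 0
  w[cbind(from, to)] <- dens
  w[cbind(to, from)] <- dens
  rownames(w) <- colnames(w) <- paste0("R", seq_len(n_nodes))
  w
}

#' Generate a synthetic two-group cohort
#'
#' Produces a cohort tibble with one row per subject: group, demographic
#' covariates, glucose covariates, and the subject's connectome in the
#' `connectome` list-column. Connectomes are group-specific Watts-Strogatz
#' weighted graphs (see [cohort_config()]); glucose covariates are injected
#' by [generate_covariate()] against each subject's global efficiency at the
#' configured target correlations, orthogonalized to the confounds (age,
#' sex, edge count, total strength) that the downstream partial-correlation
#' analysis controls.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`. The same config and
#'   seed always reproduce the identical cohort.
#' @return Tibble of class `tractnet_cohort` with columns `subject_id`,
#'   `group` (factor control/patient), `age`, `sex` (0/1, 1 = male),
#'   `hba1c`, `fpg`, `n_edges`, `total_strength`, `connectome` (list of
#'   matrices).
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_cohort_config(config)
  withr::with_seed(as.integer(seed), generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_per_group
  groups <- rep(c("control", "patient"), each = n)
  ids <- c(sprintf("C%02d", seq_len(n)), sprintf("P%02d", seq_len(n)))

  mats <- vector("list", 2 * n)
  for (i in seq_along(groups)) {
    patient <- groups[i] == "patient"
    mats[[i]] <- generate_connectome(
      n_nodes = cfg$n_nodes, lattice_degree = cfg$lattice_degree,
      shortcut_prob = if (patient) cfg$shortcut_prob_patient
                      else cfg$shortcut_prob_control,
      weight_scale = if (patient) cfg$weight_scale_patient
                     else cfg$weight_scale_control,
      weight_dispersion = cfg$weight_dispersion,
      count_meanlog = cfg$count_meanlog,
      min_streamlines = cfg$min_streamlines
    )
  }

  age <- runif(2 * n, cfg$age_range[1], cfg$age_range[2])
  n_male <- round(cfg$male_fraction * n)
  sex <- as.vector(vapply(1:2, function(g) {
    sample(c(rep(1L, n_male), rep(0L, n - n_male)))
  }, integer(n)))

  eff <- vapply(mats, global_efficiency, numeric(1))
  ne <- vapply(mats, n_edges, numeric(1))
  ts <- vapply(mats, total_strength, numeric(1))
  controls <- cbind(age = age, sex = sex, n_edges = ne, total_strength = ts)

  cov_values <- lapply(cfg$cov_corr, function(cc) {
    metric <- switch(cc$measure,
      E = eff,
      n_edges = ne,
      total_strength = ts,
      stop("unsupported cov_corr measure: ", cc$measure, call. = FALSE)
    )
    if (stats::var(metric) == 0) {
      # degenerate (noise-free) cohorts: no metric variation to correlate
      # with, draw the covariate independently at the requested scale
      g <- rnorm(length(metric))
      return(cc$mean + cc$sd * (g - mean(g)) / sd(g))
    }
    generate_covariate(metric, target_r = cc$r, mean = cc$mean, sd = cc$sd,
                       controls = controls)
  })

  out <- tibble::tibble(
    subject_id = ids,
    group = factor(groups, levels = c("control", "patient")),
    age = age,
    sex = sex,
    hba1c = cov_values$hba1c,
    fpg = cov_values$fpg,
    n_edges = ne,
    total_strength = ts,
    connectome = mats
  )
  class(out) <- c("tractnet_cohort", class(out))
  out
}

#' Generate a covariate with a target correlation to a metric
#'
#' Builds `covariate = r * z(metric) + sqrt(1 - r^2) * z(noise)` so the
#' population correlation with `metric` equals `target_r`, then rescales to
#' the requested mean and sd. When `controls` is supplied, both the metric
#' and the noise are first residualized on the controls, so the *partial*
#' correlation given those controls is what is targeted (and the covariate
#' is orthogonal to the controls by construction).
#'
#' @param metric Numeric vector of per-subject metric values (>= 3, not
#'   constant).
#' @param target_r Target correlation, `|target_r| < 1`.
#' @param mean,sd Output location and scale (sample-exact).
#' @param seed Optional integer seed for the noise; otherwise the current
#'   RNG state is used.
#' @param controls Optional numeric matrix of confounds (one row per
#'   subject) to orthogonalize against.
#' @return Numeric covariate vector, same length as `metric`.
#' @export
generate_covariate <- function(metric, target_r, mean = 0, sd = 1,
                               seed = NULL, controls = NULL) {
  n <- length(metric)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  if (abs(target_r) >= 1) stop("|target_r| must be < 1", call. = FALSE)
  if (stats::var(metric) == 0) {
    stop("metric values have zero variance", call. = FALSE)
  }
  noise <- if (is.null(seed)) rnorm(n) else withr::with_seed(seed, rnorm(n))

  resid_on <- function(v) {
    if (is.null(controls)) return(v - base::mean(v))
    stats::lm.fit(cbind(1, controls), v)$residuals
  }
  zm <- resid_on(metric)
  if (stats::var(zm) == 0) {
    stop("metric is collinear with the controls", call. = FALSE)
  }
  zm <- zm / stats::sd(zm)
  ze <- resid_on(noise)
  ze <- ze / stats::sd(ze)
  g <- target_r * zm + sqrt(1 - target_r^2) * ze
  mean + sd * (g - base::mean(g)) / stats::sd(g)
}

#' Analytic weight-scale calibration
#'
#' Global efficiency is linear in the weights (`E(s*w) = s*E(w)`), so the
#' scale that moves a network's efficiency to a target value is simply
#' `s = target_E / E(w)`.
#'
#' @param w Base connectivity matrix (must have nonzero efficiency). A list
#'   of matrices is also accepted: the ensemble mean efficiency is used.
#' @param target_E Desired global efficiency (> 0).
#' @return Positive scale factor.
#' @export
calibrate_weight_scale <- function(w, target_E) {
  if (target_E <= 0) stop("target_E must be positive", call. = FALSE)
  e <- if (is.list(w)) mean(vapply(w, global_efficiency, numeric(1)))
       else global_efficiency(w)
  if (e == 0) stop("base network has zero efficiency; cannot calibrate",
                   call. = FALSE)
  target_E / e
}

# Coarse independent oracle used by the shortcut-probability calibration:
# Floyd-Warshall distances (vectorized R) and a plain R edge-swap null.
# Deliberately a separate code path from the Dijkstra/C++ pipeline so the
# calibration is not self-confirming.
floyd_warshall_dist <- function(w) {
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  n <- nrow(d)
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

edge_swap_null_r <- function(w, swaps_per_edge = 10) {
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  m <- nrow(idx)
  if (m < 2) return(w)
  ei <- idx[, 1]; ej <- idx[, 2]
  for (t in seq_len(swaps_per_edge * m)) {
    e <- sample.int(m, 2)
    a <- ei[e[1]]; b <- ej[e[1]]; c <- ei[e[2]]; d <- ej[e[2]]
    if (runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
    if (a == c || a == d || b == c || b == d) next
    if (w[a, d] > 0 || w[c, b] > 0) next
    w1 <- w[a, b]; w2 <- w[c, d]
    w[a, b] <- w[b, a] <- 0; w[c, d] <- w[d, c] <- 0
    w[a, d] <- w[d, a] <- w1; w[c, b] <- w[b, c] <- w2
    ei[e[1]] <- min(a, d); ej[e[1]] <- max(a, d)
    ei[e[2]] <- min(c, b); ej[e[2]] <- max(c, b)
  }
  w
}

oracle_lambda <- function(w, n_null, swaps_per_edge = 10) {
  lraw_of <- function(m) {
    d <- floyd_warshall_dist(m)
    off <- d[row(d) != col(d)]
    mean(off[is.finite(off)])
  }
  l_raw <- lraw_of(w)
  l_null <- vapply(seq_len(n_null), function(b) {
    lraw_of(edge_swap_null_r(w, swaps_per_edge))
  }, numeric(1))
  l_raw / mean(l_null)
}

#' Calibrate the shortcut probability to a target normalized path length
#'
#' Bisection over the Watts-Strogatz rewiring probability until the
#' ensemble mean normalized path length (lambda) of a probe ensemble
#' matches `target_lambda`. Lambda is evaluated with a deliberately
#' independent coarse oracle (Floyd-Warshall distances, plain R edge-swap
#' nulls) rather than the production metric path, so a calibrated default
#' can be validated against the pipeline afterwards. Lambda decreases
#' monotonically in the shortcut probability: a fully random graph has
#' lambda near 1, a pure lattice the maximum.
#'
#' @param target_lambda Target normalized path length (>= 1 in practice).
#' @param config A [cohort_config()]; its topology fields (nodes, lattice
#'   degree, weights) define the ensemble being calibrated.
#' @param n_null Null networks per probe graph (oracle normalization).
#' @param n_probe Probe graphs per bisection step.
#' @param tol Absolute tolerance on the ensemble mean lambda.
#' @param max_iter Bisection iteration cap.
#' @param seed Seed for the probe ensembles.
#' @return The calibrated shortcut probability.
#' @export
calibrate_shortcut_prob <- function(target_lambda, config = cohort_config(),
                                    n_null = 50, n_probe = 10, tol = 0.02,
                                    max_iter = 12, seed = 1) {
  probe_lambda <- function(p) {
    withr::with_seed(seed, {
      mean(vapply(seq_len(n_probe), function(i) {
        w <- generate_connectome(
          config$n_nodes, config$lattice_degree, p, 1,
          config$weight_dispersion, config$count_meanlog,
          config$min_streamlines)
        oracle_lambda(w, n_null = n_null)
      }, numeric(1)))
    })
  }
  lam_hi <- probe_lambda(1)  # most random -> smallest lambda
  lam_lo <- probe_lambda(0)  # lattice -> largest lambda
  if (target_lambda > lam_lo + tol || target_lambda < lam_hi - tol) {
    stop(sprintf(
      "target lambda %.3f unreachable: achievable range is [%.3f, %.3f]",
      target_lambda, lam_hi, lam_lo), call. = FALSE)
  }
  lo <- 0; hi <- 1
  p <- 0.5
  for (it in seq_len(max_iter)) {
    p <- (lo + hi) / 2
    lam <- probe_lambda(p)
    if (abs(lam - target_lambda) < tol) break
    if (lam > target_lambda) lo <- p else hi <- p
  }
  p
}
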