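# Synthetic matched two-layer expression data with a known sparse
# miRNA -> mRNA regulatory network, a Cox outcome and heavy censoring,
# emulating (at desk scale) a matched tumor cohort with ~100 samples,
# a large mRNA layer, a small miRNA layer and ~80% censoring.

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. The defaults describe the
#' package's reference study condition: 100 samples, 300 transcripts,
#' 30 miRNAs, 5 disjoint targets per miRNA, regulation strength a = 1 against
#' noise sd 1 (true-pair correlation -1/sqrt(2)), 3 prognostic miRNAs each
#' with coefficient 1 plus their first target transcript with coefficient
#' -0.5, exponential baseline hazard 0.1, 80% censoring, and a noisy target
#' prediction source listing 80% of true edges, 1% of non-edges and omitting
#' 10% of miRNAs entirely.
#'
#' @param n samples; @param p1 mRNAs; @param p2 miRNAs.
#' @param targets_per_mirna true targets of each miRNA (disjoint sets).
#' @param n_prognostic number of prognostic miRNAs.
#' @param a regulation strength (>= 0); @param sigma residual sd (> 0).
#' @param beta_mirna,beta_mrna true coefficients of prognostic miRNAs and of
#'   each prognostic miRNA's first target transcript (the latter entered
#'   with a negative sign so both effects act in the same direction).
#' @param hazard_scale exponential baseline hazard rate.
#' @param censor_frac target expected censored fraction in \[0, 1).
#' @param sensitivity probability that a true edge is listed in the
#'   prediction table; @param fp_rate listing probability for non-edges.
#' @param mirna_dropout fraction of miRNAs absent from the prediction source
#'   (exercises the correlation-only fallback).
#' @param seed mandatory RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n = 100, p1 = 300, p2 = 30, targets_per_mirna = 5,
                       n_prognostic = 3, a = 1, sigma = 1, beta_mirna = 1,
                       beta_mrna = 0.5, hazard_scale = 0.1,
                       censor_frac = 0.8, sensitivity = 0.8, fp_rate = 0.01,
                       mirna_dropout = 0.1, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(n >= 1, p1 >= 1, p2 >= 1, targets_per_mirna >= 0,
            n_prognostic >= 0, n_prognostic <= p2, a >= 0, sigma > 0,
            hazard_scale > 0, censor_frac >= 0, censor_frac < 1,
            sensitivity >= 0, sensitivity <= 1, fp_rate >= 0, fp_rate <= 1,
            mirna_dropout >= 0, mirna_dropout <= 1)
  if (targets_per_mirna * p2 > p1)
    stop("infeasible network: ", targets_per_mirna, " targets x ", p2,
         " miRNAs exceeds ", p1, " mRNAs")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a ground-truth regulatory network
#'
#' Assigns each miRNA a disjoint random set of target mRNAs, and designates
#' `n_prognostic` miRNAs (preferring those with targets) as prognostic,
#' together with their first target transcript.
#'
#' @param p1,p2,targets_per_mirna,n_prognostic,seed see [sim_config()].
#' @param beta_mirna,beta_mrna true coefficient magnitudes.
#' @return a `network_truth`: `targets` (list per miRNA of mRNA indices),
#'   `edges` (two-column matrix mrna/mirna index), `beta` (true coefficient
#'   vector over \[p1 mRNAs; p2 miRNAs\]), `prognostic_mirnas`.
#' @export
simulate_network <- function(p1, p2, targets_per_mirna, n_prognostic = 0,
                             beta_mirna = 1, beta_mrna = 0.5, seed) {
  if (targets_per_mirna * p2 > p1)
    stop("infeasible network: cannot draw ", targets_per_mirna,
         " disjoint targets for each of ", p2, " miRNAs from ", p1, " mRNAs")
  set.seed(seed)
  pool <- sample.int(p1)
  targets <- vector("list", p2)
  for (j in seq_len(p2)) {
    take <- seq_len(targets_per_mirna) + (j - 1) * targets_per_mirna
    targets[[j]] <- if (targets_per_mirna > 0) sort(pool[take]) else integer()
  }
  edges <- do.call(rbind, lapply(seq_len(p2), function(j)
    if (length(targets[[j]])) cbind(mrna = targets[[j]], mirna = j)))
  if (is.null(edges)) edges <- cbind(mrna = integer(), mirna = integer())
  beta <- numeric(p1 + p2)
  prog <- integer()
  if (n_prognostic > 0) {
    with_targets <- which(lengths(targets) > 0)
    cand <- if (length(with_targets) >= n_prognostic) with_targets
            else seq_len(p2)
    prog <- sort(sample(cand, n_prognostic))
    beta[p1 + prog] <- beta_mirna
    for (j in prog)
      if (length(targets[[j]])) beta[targets[[j]][1]] <- -beta_mrna
  }
  structure(list(targets = targets, edges = edges, beta = beta,
                 prognostic_mirnas = prog, p1 = p1, p2 = p2, seed = seed),
            class = "network_truth")
}

#' Simulate matched two-layer expression
#'
#' Each miRNA is standard normal across samples; each regulated mRNA equals
#' -a * (its regulator) + sigma * noise, so a true pair has expected Pearson
#' correlation -a / sqrt(a^2 + sigma^2); unregulated mRNAs are pure noise.
#'
#' @param n samples; @param network a [simulate_network()] truth.
#' @param a regulation strength; @param sigma noise sd; @param seed RNG seed.
#' @return list with `x_mrna` (p1 x n) and `x_mirna` (p2 x n), rownames
#'   `mRNA0001`... / `miR001`..., colnames `S001`...
#' @export
simulate_expression <- function(n, network, a = 1, sigma = 1, seed) {
  stopifnot(inherits(network, "network_truth"), a >= 0, sigma > 0)
  set.seed(seed)
  p1 <- network$p1; p2 <- network$p2
  x_mirna <- matrix(stats::rnorm(p2 * n), p2, n)
  x_mrna <- matrix(stats::rnorm(p1 * n, sd = sigma), p1, n)
  for (j in seq_len(p2)) {
    tg <- network$targets[[j]]
    if (length(tg))
      x_mrna[tg, ] <- x_mrna[tg, ] - a * rep(x_mirna[j, ], each = length(tg))
  }
  samp <- sprintf("S%03d", seq_len(n))
  dimnames(x_mrna) <- list(sprintf("mRNA%04d", seq_len(p1)), samp)
  dimnames(x_mirna) <- list(sprintf("miR%03d", seq_len(p2)), samp)
  list(x_mrna = x_mrna, x_mirna = x_mirna)
}

#' Simulate a right-censored Cox outcome
#'
#' Event times are drawn by inverse transform from an exponential baseline
#' with hazard `hazard_scale * exp(x' beta)`. Censoring times are uniform on
#' (0, c_max) with c_max solved numerically so that the expected censored
#' fraction (given the realized linear predictors) equals `censor_frac`;
#' censoring is independent of the covariates.
#'
#' @param X feature x sample matrix of the concatenated layers (mRNAs then
#'   miRNAs), or a precomputed linear predictor via `eta`.
#' @param beta true coefficient vector aligned to the rows of `X`.
#' @param hazard_scale baseline hazard rate.
#' @param censor_frac target expected censored fraction in \[0, 1).
#' @param seed RNG seed.
#' @param eta optional linear predictor overriding `X`/`beta`.
#' @return list with `time`, `status`, the latent `event_time`, `eta`, and
#'   the calibrated `c_max` (`Inf` when `censor_frac = 0`).
#' @export
simulate_survival <- function(X = NULL, beta = NULL, hazard_scale = 0.1,
                              censor_frac = 0.8, seed, eta = NULL) {
  if (is.null(eta)) eta <- as.vector(crossprod(X, beta))
  n <- length(eta)
  rate <- hazard_scale * exp(eta)
  set.seed(seed)
  event_time <- stats::rexp(n, rate = rate)
  if (censor_frac == 0) {
    cens_time <- rep(Inf, n)
    c_max <- Inf
  } else {
    # expected censored fraction under C ~ U(0, cm), T_i ~ Exp(rate_i):
    # mean_i (1/cm) * integral_0^cm exp(-rate_i c) dc
    expected_cens <- function(cm)
      mean((1 - exp(-rate * cm)) / (rate * cm))
    c_max <- stats::uniroot(function(cm) expected_cens(cm) - censor_frac,
                            lower = 1e-9, upper = 1e9,
                            extendInt = "downX", tol = 1e-10)$root
    cens_time <- stats::runif(n, 0, c_max)
  }
  status <- as.integer(event_time <= cens_time)
  list(time = pmin(event_time, cens_time), status = status,
       event_time = event_time, eta = eta, c_max = c_max)
}

#' Simulate a noisy target-prediction table
#'
#' Each true network edge is listed with probability `sensitivity`;
#' non-edges are listed with probability `fp_rate`. Listed pairs receive a
#' prediction p-value uniform on (0, 0.05), mirroring sources that only
#' retain pairs below that threshold. A fraction `mirna_dropout` of miRNAs
#' is removed from the source entirely (absent from its covered set), so
#' that the fused graph falls back to correlation evidence for them.
#'
#' @param network a [simulate_network()] truth.
#' @param sensitivity,fp_rate,mirna_dropout rates in \[0, 1\].
#' @param seed RNG seed.
#' @return a [target_predictions()] table with `source_label = "synthetic"`.
#' @export
simulate_target_predictions <- function(network, sensitivity = 0.8,
                                        fp_rate = 0.01, mirna_dropout = 0,
                                        seed) {
  stopifnot(inherits(network, "network_truth"))
  set.seed(seed)
  p1 <- network$p1; p2 <- network$p2
  mrna_ids <- sprintf("mRNA%04d", seq_len(p1))
  mirna_ids <- sprintf("miR%03d", seq_len(p2))
  n_drop <- round(mirna_dropout * p2)
  dropped <- if (n_drop > 0) sort(sample.int(p2, n_drop)) else integer()
  covered_mirnas <- mirna_ids[setdiff(seq_len(p2), dropped)]
  is_edge <- matrix(FALSE, p1, p2)
  if (nrow(network$edges)) is_edge[network$edges] <- TRUE
  keep_cols <- setdiff(seq_len(p2), dropped)
  rec <- list()
  for (j in keep_cols) {
    tr <- which(is_edge[, j])
    tr <- tr[stats::runif(length(tr)) < sensitivity]
    fp <- which(!is_edge[, j])
    fp <- fp[stats::runif(length(fp)) < fp_rate]
    rows <- c(tr, fp)
    if (length(rows))
      rec[[length(rec) + 1]] <- data.frame(
        mirna_id = mirna_ids[j], transcript_id = mrna_ids[rows],
        p_value = stats::runif(length(rows), 0, 0.05))
  }
  records <- if (length(rec)) do.call(rbind, rec) else
    data.frame(mirna_id = character(), transcript_id = character(),
               p_value = numeric())
  target_predictions(records, source_label = "synthetic",
                     covered_mirnas = covered_mirnas,
                     covered_mrnas = mrna_ids)
}

#' Generate a complete synthetic two-layer survival dataset
#'
#' Composes the network, expression, survival and target-prediction
#' generators under one master seed (sub-seeds are derived deterministically
#' from it) and optionally writes all on-disk artifacts: expression TSVs,
#' clinical TSV, prediction TSV and a ground-truth JSON.
#'
#' @param config a [sim_config()].
#' @param dir output directory, or `NULL` to skip writing.
#' @return a `synthetic_dataset`: `x_mrna`, `x_mirna`, `time`, `status`,
#'   `sample_ids`, `predictions`, `truth` (network, beta, latent pieces) and
#'   the echoed `config`.
#' @export
simulate_fusion_data <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sd0 <- config$seed
  network <- simulate_network(config$p1, config$p2, config$targets_per_mirna,
                              config$n_prognostic, config$beta_mirna,
                              config$beta_mrna, seed = sd0)
  expr <- simulate_expression(config$n, network, config$a, config$sigma,
                              seed = sd0 + 1)
  X <- rbind(expr$x_mrna, expr$x_mirna)
  surv <- simulate_survival(X, network$beta, config$hazard_scale,
                            config$censor_frac, seed = sd0 + 2)
  preds <- simulate_target_predictions(network, config$sensitivity,
                                       config$fp_rate, config$mirna_dropout,
                                       seed = sd0 + 3)
  out <- structure(list(
    x_mrna = expr$x_mrna, x_mirna = expr$x_mirna,
    time = surv$time, status = surv$status,
    sample_ids = colnames(expr$x_mrna), predictions = preds,
    truth = list(network = network, beta = network$beta,
                 event_time = surv$event_time, eta = surv$eta,
                 c_max = surv$c_max),
    config = config), class = "synthetic_dataset")
  if (!is.null(dir)) write_synthetic_dataset(out, dir)
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic two-layer survival dataset\n")
  cat("  n = ", length(x$time), " samples, ", nrow(x$x_mrna), " mRNAs, ",
      nrow(x$x_mirna), " miRNAs\n", sep = "")
  cat("  events: ", sum(x$status), " / censored: ", sum(1 - x$status),
      "\n", sep = "")
  cat("  true edges: ", nrow(x$truth$network$edges), "; prognostic miRNAs: ",
      paste(sprintf("miR%03d", x$truth$network$prognostic_mirnas),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
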