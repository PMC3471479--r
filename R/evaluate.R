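#' Reverse Kaplan-Meier estimate of the censoring distribution
#'
#' Kaplan-Meier estimator with the roles of events and censorings swapped:
#' censorings are the "events" of the censoring process G. At tied times the
#' survival events precede the censorings in the risk-set bookkeeping, i.e.
#' the multiplicative factor at time u is 1 - c_u / (r_u - d_u) with r_u
#' subjects at risk, d_u events and c_u censorings at u. G_hat(0) = 1 and
#' G_hat is nonincreasing.
#'
#' @param time,status survival outcome (status 1 = event, 0 = censored).
#' @return a `censkm` object: knot times, right-continuous survival values.
#' @export
censoring_km <- function(time, status) {
  if (length(time) < 1) stop("empty outcome")
  if (!all(status %in% c(0, 1))) stop("status must be 0 or 1")
  ut <- sort(unique(time))
  r <- vapply(ut, function(u) sum(time >= u), numeric(1))
  d <- vapply(ut, function(u) sum(time == u & status == 1), numeric(1))
  cc <- vapply(ut, function(u) sum(time == u & status == 0), numeric(1))
  fac <- ifelse(cc == 0, 1, 1 - cc / (r - d))
  structure(list(time = ut, surv = cumprod(fac), n = length(time)),
            class = "censkm")
}

#' Evaluate a censoring survival curve
#'
#' @param ck a [censoring_km()] object.
#' @param t evaluation times.
#' @param left if `TRUE`, return the left limit G_hat(t-) instead of the
#'   right-continuous value G_hat(t).
#' @return censoring survival probabilities.
#' @export
cens_surv <- function(ck, t, left = FALSE) {
  stopifnot(inherits(ck, "censkm"))
  idx <- if (left) findInterval(t, ck$time, left.open = TRUE)
         else findInterval(t, ck$time)
  c(1, ck$surv)[idx + 1]
}

#' @export
print.censkm <- function(x, ...) {
  cat("Censoring survival (reverse Kaplan-Meier), n = ", x$n, ", ",
      length(x$time), " knots, G(max t) = ",
      format(x$surv[length(x$surv)], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Default evaluation grid and horizon
#'
#' Time grid 0 and the distinct event times up to tau, where tau is the
#' largest event time at which the censoring survival estimate is positive.
#'
#' @param time,status evaluation outcome.
#' @param ck optional precomputed [censoring_km()].
#' @return list with `grid` and `tau`.
#' @export
pec_grid <- function(time, status, ck = censoring_km(time, status)) {
  et <- sort(unique(time[status == 1]))
  ok <- cens_surv(ck, et) > 0
  if (!any(ok)) stop("censoring survival vanishes before the first event")
  tau <- max(et[ok])
  list(grid = c(0, et[et <= tau]), tau = tau)
}

#' IPCW prediction error curve (time-resolved Brier score)
#'
#' Empirical Brier score of predicted event-free probabilities against the
#' observed status, reweighted for censoring by the inverse of the censoring
#' survival estimate:
#' PEC(t) = 1/n * sum_i \[ r_hat(t|x_i)^2 1(t_i <= t, d_i = 1) / G(t_i-) +
#' (1 - r_hat(t|x_i))^2 1(t_i > t) / G(t) \].
#' Subjects censored before t contribute nothing (their status at t is
#' unknown). Event-time weights use the left limit G(t_i-).
#'
#' @param sp matrix of predicted survival probabilities, n samples x
#'   length(grid) time points.
#' @param time,status outcome of the evaluated samples.
#' @param grid ordered evaluation times; default [pec_grid()].
#' @param ck censoring estimate used for the weights; default computed from
#'   the evaluated samples themselves.
#' @param estimator label stored on the curve.
#' @param left_limit use G(t_i-) for event terms (default); `FALSE` evaluates
#'   G at t_i itself.
#' @return a `pec` object: `time`, `value`, `estimator`, `tau`.
#' @export
prediction_error_curve <- function(sp, time, status, grid = NULL,
                                   ck = censoring_km(time, status),
                                   estimator = "apparent",
                                   left_limit = TRUE) {
  n <- length(time)
  if (is.null(grid)) grid <- pec_grid(time, status, ck)$grid
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  sp <- as.matrix(sp)
  if (nrow(sp) != n || ncol(sp) != length(grid))
    stop("'sp' must be an n x length(grid) matrix of survival probabilities")
  Gi <- cens_surv(ck, time, left = left_limit)
  Gt <- cens_surv(ck, grid)
  vals <- numeric(length(grid))
  for (k in seq_along(grid)) {
    t <- grid[k]
    i1 <- time <= t & status == 1
    i2 <- time > t
    if (any(i1 & Gi == 0))
      stop("censoring weight G(t-) is zero for an observed event; ",
           "choose a smaller evaluation horizon tau")
    if (any(i2) && Gt[k] == 0)
      stop("censoring weight G(", format(t), ") is zero while subjects are ",
           "still at risk; choose a smaller evaluation horizon tau")
    acc <- numeric(n)
    acc[i1] <- sp[i1, k]^2 / Gi[i1]
    acc[i2] <- acc[i2] + (1 - sp[i2, k])^2 / Gt[k]
    vals[k] <- sum(acc) / n
  }
  structure(list(time = grid, value = vals, estimator = estimator,
                 tau = max(grid)), class = "pec")
}

#' @export
print.pec <- function(x, ...) {
  cat("Prediction error curve [", x$estimator, "]: ", length(x$time),
      " time points on [", format(min(x$time)), ", ", format(x$tau),
      "], IPEC = ", format(ipec(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.pec <- function(x, add = FALSE, col = 1, ...) {
  if (!add)
    plot(x$time, x$value, type = "s", xlab = "time",
         ylab = "prediction error", col = col, ...)
  else graphics::lines(x$time, x$value, type = "s", col = col, ...)
  invisible(x)
}

#' Integrated prediction error curve (IPEC)
#'
#' Exact integral of the right-continuous step function over \[grid start,
#' tau\].
#'
#' @param curve a `pec` object (or list with `time`, `value`).
#' @param tau upper integration limit; default the curve's recorded horizon.
#' @return nonnegative scalar.
#' @export
ipec <- function(curve, tau = NULL) {
  if (is.null(tau)) tau <- curve$tau
  tt <- curve$time; vv <- curve$value
  hi <- if (!is.null(curve$tau)) max(curve$tau, max(tt)) else max(tt)
  if (tau < tt[1] || tau > hi)
    stop("'tau' outside the curve's range [", format(tt[1]), ", ",
         format(hi), "]")
  keep <- tt <= tau
  tt <- tt[keep]; vv <- vv[keep]
  sum(vv * (c(tt[-1], tau) - tt))
}

#' Prediction error curve of the Kaplan-Meier reference
#'
#' The covariate-free reference predictor: every subject is assigned the
#' Kaplan-Meier survival estimate of the evaluation data itself.
#'
#' @inheritParams prediction_error_curve
#' @return a `pec` object labelled `"km_reference"`.
#' @export
km_reference_curve <- function(time, status, grid = NULL,
                               ck = censoring_km(time, status)) {
  if (is.null(grid)) grid <- pec_grid(time, status, ck)$grid
  fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  S <- .step_eval(fit$time, fit$surv, grid, 1)
  sp <- matrix(S, length(time), length(grid), byrow = TRUE)
  out <- prediction_error_curve(sp, time, status, grid, ck,
                                estimator = "km_reference")
  out
}

#' Trainer closure for bootstrap evaluation
#'
#' Packages a [coxfuse()] configuration into a function
#' `function(x_mrna, x_mirna, time, status)` suitable for
#' [bootstrap_632()]. With `rebuild_graph = TRUE` the fusion graph is
#' reassembled from the training (in-bag) samples of every call, so that the
#' correlation tests never see evaluation data; `predictions` must then be
#' supplied. Otherwise a fixed prebuilt `graph` (or none) is used.
#'
#' @param steps,penalty,cf,graph,escalate,weight_mode see [coxfuse()].
#' @param rebuild_graph reassemble the graph from each training set.
#' @param predictions [target_predictions()] used when rebuilding.
#' @param graph_args further arguments to [fusion_graph()] when rebuilding.
#' @return a trainer function returning a `coxfuse` fit.
#' @export
coxfuse_trainer <- function(steps = 100, penalty = NULL, cf = 0.9,
                            graph = NULL, escalate = TRUE,
                            weight_mode = "linear", rebuild_graph = FALSE,
                            predictions = NULL, graph_args = list()) {
  force(steps); force(penalty); force(cf); force(graph)
  function(x_mrna, x_mirna, time, status) {
    g <- graph
    if (rebuild_graph)
      g <- do.call(fusion_graph,
                   c(list(mrna = x_mrna, mirna = x_mirna,
                          predictions = predictions), graph_args))
    coxfuse(x_mrna, x_mirna, time, status, steps = steps, penalty = penalty,
            graph = g, cf = cf, escalate = escalate,
            weight_mode = weight_mode)
  }
}

#' .632 bootstrap estimation of the prediction error curve and IPEC
#'
#' Draws `B` bootstrap samples of size n with replacement. The apparent
#' curve is the full-data model evaluated on the full data. For each
#' replicate b, a model is trained on the in-bag samples and evaluated on
#' the out-of-bag samples (censoring weights estimated from the out-of-bag
#' samples themselves), and the .632 curve is the pointwise combination
#' 0.368 * apparent + 0.632 * oob_b, integrated to IPEC_b over \[0, tau\].
#' Replicates whose out-of-bag set carries no event, or whose training
#' fails, are redrawn (recorded in the redraw log). Fully deterministic
#' under `seed`.
#'
#' @param x_mrna,x_mirna expression matrices (features x samples).
#' @param time,status outcome.
#' @param trainer fitting closure, see [coxfuse_trainer()].
#' @param B number of bootstrap replicates.
#' @param seed RNG seed.
#' @param grid,tau evaluation grid and horizon; default from the full data.
#' @param max_retries redraw attempts per replicate before aborting.
#' @return a `boot632` object: `apparent` curve, `curves` (B x grid matrix
#'   of .632 values), `ipecs` (length B), `selected` (per-replicate selected
#'   feature sets), `redraws` log, `grid`, `tau`, `seed`, and the full-data
#'   `model`.
#' @export
bootstrap_632 <- function(x_mrna, x_mirna = NULL, time, status, trainer,
                          B = 50, seed = 1, grid = NULL, tau = NULL,
                          max_retries = 20) {
  if (B < 1) stop("'B' must be >= 1")
  n <- length(time)
  ck_full <- censoring_km(time, status)
  if (is.null(grid)) {
    pg <- pec_grid(time, status, ck_full)
    grid <- pg$grid
    if (is.null(tau)) tau <- pg$tau
  }
  if (is.null(tau)) tau <- max(grid)

  model <- trainer(x_mrna, x_mirna, time, status)
  sp_full <- predict(model, x_mrna, x_mirna, type = "survival", times = grid)
  apparent <- prediction_error_curve(sp_full, time, status, grid, ck_full,
                                     estimator = "apparent")

  curves <- matrix(NA_real_, B, length(grid))
  oob_curves <- matrix(NA_real_, B, length(grid))
  ipecs <- numeric(B)
  selected <- vector("list", B)
  redraws <- data.frame(replicate = integer(), attempt = integer(),
                        reason = character())
  set.seed(seed)
  for (b in seq_len(B)) {
    ok <- FALSE
    for (attempt in seq_len(max_retries)) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      reason <- NULL
      if (length(oob) == 0 || sum(status[oob]) == 0) {
        reason <- "no out-of-bag events"
      } else if (sum(status[idx]) == 0) {
        reason <- "no in-bag events"
      } else {
        fit_b <- tryCatch(
          trainer(x_mrna[, idx, drop = FALSE],
                  if (!is.null(x_mirna)) x_mirna[, idx, drop = FALSE],
                  time[idx], status[idx]),
          error = function(e) e)
        if (inherits(fit_b, "error")) {
          reason <- paste("trainer:", conditionMessage(fit_b))
        } else {
          sp_oob <- predict(fit_b, x_mrna[, oob, drop = FALSE],
                            if (!is.null(x_mirna)) x_mirna[, oob, drop = FALSE],
                            type = "survival", times = grid)
          oob_curve <- tryCatch(
            prediction_error_curve(sp_oob, time[oob], status[oob], grid,
                                   censoring_km(time[oob], status[oob]),
                                   estimator = "oob"),
            error = function(e) e)
          if (inherits(oob_curve, "error")) {
            reason <- paste("evaluation:", conditionMessage(oob_curve))
          } else {
            oob_curves[b, ] <- oob_curve$value
            curves[b, ] <- 0.368 * apparent$value + 0.632 * oob_curve$value
            ipecs[b] <- ipec(list(time = grid, value = curves[b, ],
                                  tau = tau), tau)
            selected[[b]] <- unique(fit_b$selection$feature)
            ok <- TRUE
          }
        }
      }
      if (ok) break
      redraws <- rbind(redraws, data.frame(replicate = b, attempt = attempt,
                                           reason = reason))
      message("bootstrap replicate ", b, " redrawn (", reason, ")")
    }
    if (!ok) stop("bootstrap replicate ", b, " failed after ", max_retries,
                  " attempts")
  }
  structure(list(apparent = apparent, curves = curves,
                 oob_curves = oob_curves, ipecs = ipecs,
                 selected = selected, redraws = redraws, grid = grid,
                 tau = tau, B = B, seed = seed, model = model),
            class = "boot632")
}

#' @export
print.boot632 <- function(x, ...) {
  cat(".632 bootstrap evaluation: B = ", x$B, ", tau = ", format(x$tau),
      "\n", sep = "")
  cat("  IPEC median ", format(stats::median(x$ipecs), digits = 4),
      " (IQR ", format(stats::IQR(x$ipecs), digits = 4), ")\n", sep = "")
  if (nrow(x$redraws)) cat("  ", nrow(x$redraws), " redraw(s)\n", sep = "")
  invisible(x)
}

#' @export
plot.boot632 <- function(x, ...) {
  mean632 <- colMeans(x$curves)
  plot(x$grid, mean632, type = "s", xlab = "time", ylab = "prediction error",
       ylim = range(0, mean632, x$apparent$value), ...)
  graphics::lines(x$apparent$time, x$apparent$value, type = "s", col = "grey50")
  graphics::legend("bottomright", c(".632 (mean over B)", "apparent"),
                   col = c(1, "grey50"), lty = 1, bty = "n")
  invisible(x)
}

#' Paired one-sided Wilcoxon comparison of IPEC distributions
#'
#' Tests whether model A's bootstrap IPECs are systematically smaller than
#' model B's (paired signed-rank test on the same bootstrap samples, zero
#' differences dropped; exact null distribution for B <= 25, otherwise the
#' normal approximation with continuity correction).
#'
#' @param ipecs_a,ipecs_b equal-length IPEC vectors from the same bootstrap
#'   samples.
#' @param alternative `"less"` (A smaller, default), `"greater"`, or
#'   `"two.sided"`.
#' @return list with `p_value`, `median_a`, `median_b`, `iqr_a`, `iqr_b`,
#'   `alternative`, `n`.
#' @export
compare_ipecs <- function(ipecs_a, ipecs_b, alternative = "less") {
  if (length(ipecs_a) != length(ipecs_b))
    stop("IPEC vectors must be paired (equal length)")
  d <- ipecs_a - ipecs_b
  if (all(d == 0)) {
    warning("all paired IPEC differences are zero; p = 1")
    p <- 1
  } else {
    nz <- sum(d != 0)
    p <- suppressWarnings(stats::wilcox.test(
      ipecs_a, ipecs_b, paired = TRUE, alternative = alternative,
      exact = nz <= 25, correct = TRUE))$p.value
  }
  list(p_value = p,
       median_a = stats::median(ipecs_a), median_b = stats::median(ipecs_b),
       iqr_a = stats::IQR(ipecs_a), iqr_b = stats::IQR(ipecs_b),
       alternative = alternative, n = length(ipecs_a))
}

#' Bootstrap selection-stability counts
#'
#' For every feature, the number of bootstrap replicates in which it was
#' selected at least once, ranked descending (ties by feature id). Features
#' never selected are absent.
#'
#' @param boot a [bootstrap_632()] result.
#' @param top_k return at most this many rows.
#' @return data.frame with columns `feature`, `layer`, `count`.
#' @export
selection_counts <- function(boot, top_k = Inf) {
  stopifnot(inherits(boot, "boot632"))
  feats <- unlist(boot$selected)
  if (length(feats) == 0)
    return(data.frame(feature = character(), layer = character(),
                      count = integer()))
  cnt <- sort(table(feats), decreasing = TRUE)
  out <- data.frame(feature = names(cnt),
                    layer = boot$model$layer[
                      match(names(cnt), boot$model$feature_ids)],
                    count = as.integer(cnt))
  out <- out[order(-out$count, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}
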