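# Componentwise likelihood-based Cox boosting with optional graph guidance.
#
# Internal representation: samples are kept in input order; the risk-set
# bookkeeping precomputes, for every distinct event time, an indicator row
# over samples (Breslow handling of ties: every subject with t_i >= t_e is
# at risk, each of the d_e tied events contributes one -log S0 term).

.risk_structure <- function(time, status) {
  et <- sort(unique(time[status == 1]))
  if (length(et) == 0) stop("no events in the data (all observations censored)")
  d <- vapply(et, function(e) sum(time == e & status == 1), numeric(1))
  R <- outer(et, time, "<=") * 1  # d x n risk-set indicator
  list(event_times = et, d = d, R = R, event_rows = which(status == 1),
       n = length(time))
}

# score U_j and observed Fisher information F_j of the Cox partial
# log-likelihood w.r.t. a new coefficient gamma_j at gamma = 0, offset fixed;
# vectorized over all columns of X.
.score_info_all <- function(X, w, rs) {
  wX <- X * w
  S0 <- as.vector(rs$R %*% w)
  M1 <- (rs$R %*% wX) / S0
  M2 <- (rs$R %*% (wX * X)) / S0
  U <- colSums(X[rs$event_rows, , drop = FALSE]) - colSums(rs$d * M1)
  Fi <- colSums(rs$d * (M2 - M1 * M1))
  list(U = U, info = Fi)
}

# Breslow partial log-likelihood at linear predictor eta
.cox_pl <- function(eta, rs) {
  S0 <- as.vector(rs$R %*% exp(eta))
  sum(eta[rs$event_rows]) - sum(rs$d * log(S0))
}

#' Cox partial-likelihood score and information for one candidate covariate
#'
#' First derivative U and observed Fisher information F of the Cox partial
#' log-likelihood with respect to a single new coefficient gamma at
#' gamma = 0, holding the linear predictor `offset` fixed. Ties are handled
#' by the Breslow approximation. These are the ingredients of one
#' componentwise boosting update: gamma_hat = U / (F + lambda).
#'
#' @param x covariate vector over samples.
#' @param time,status observed times (>= 0) and event indicators (1 = event,
#'   0 = censored); at least one event required.
#' @param offset per-sample linear predictor held fixed, default 0.
#' @return list with elements `U` and `info`.
#' @export
cox_score_info <- function(x, time, status, offset = NULL) {
  check_surv(time, status)
  if (length(x) != length(time)) stop("length mismatch between x and time")
  if (is.null(offset)) offset <- numeric(length(time))
  if (length(offset) != length(time)) stop("offset length mismatch")
  rs <- .risk_structure(time, status)
  si <- .score_info_all(matrix(as.numeric(x), ncol = 1), exp(offset), rs)
  list(U = si$U[[1]], info = si$info[[1]])
}

check_surv <- function(time, status) {
  if (length(time) != length(status)) stop("time/status length mismatch")
  if (anyNA(time) || anyNA(status)) stop("time/status contain NA")
  if (any(time < 0)) stop("negative survival times")
  if (!all(status %in% c(0, 1))) stop("status must be 0 (censored) or 1 (event)")
  if (sum(status) < 1) stop("at least one event is required")
  invisible(NULL)
}

#' Fit a graph-guided componentwise Cox boosting model
#'
#' Componentwise likelihood-based boosting for the Cox proportional hazards
#' model. Starting from beta = 0, each of `steps` boosting steps computes,
#' for every covariate j, the penalized one-parameter update
#' gamma_j = U_j / (F_j + lambda_j) at the current linear predictor, selects
#' the covariate maximizing the penalized score statistic
#' U_j^2 / (F_j + lambda_j) (ties broken towards the lowest feature index),
#' and adds gamma to its coefficient. This yields sparse fits with implicit
#' feature selection.
#'
#' With a [fusion_graph()] supplied, the penalty schedule becomes adaptive:
#' the selected feature's penalty is escalated ([penalty_escalate()]) and,
#' whenever the selected feature is an mRNA, the penalties of miRNAs
#' connected to it are relaxed in proportion to the edge weight
#' ([penalty_relax()]), making regulator miRNAs of prognostic transcripts
#' more likely to enter the model in later steps. The graph is directed
#' (mRNA -> miRNA): selecting a miRNA triggers no relaxation. With
#' `cf = 1` the graph machinery is inert and the fit is identical to the
#' plain model.
#'
#' Features are standardized internally to mean 0 / variance 1 (training
#' statistics are stored and reused by [predict.coxfuse()]), so that a
#' common initial penalty is meaningful across covariates and layers.
#'
#' @param x_mrna mRNA expression, features x samples, rownames = transcript
#'   ids.
#' @param x_mirna miRNA expression, features x samples, or `NULL` for a
#'   single-layer fit.
#' @param time,status survival outcome aligned with the sample columns.
#' @param steps number of boosting steps M (>= 0).
#' @param penalty common initial penalty lambda for all covariates; default
#'   `9 * sum(status)`.
#' @param graph optional [fusion_graph()]; rows/cols must match the feature
#'   ids of the two layers.
#' @param cf stepsize modification factor in (0, 1], default 0.9 (only used
#'   with a graph).
#' @param escalate apply penalty escalation to selected features (graph mode
#'   only), default `TRUE`.
#' @param criterion `"score"` (penalized score statistic, default) or
#'   `"plgain"` (exact penalized partial-log-likelihood gain; O(n p) per
#'   covariate and step, intended for small p).
#' @param weight_mode edge-weight modulation for relaxation, see
#'   [penalty_relax()].
#' @param standardize standardize features internally (default `TRUE`).
#' @return an object of class `coxfuse` with components `coefficients`
#'   (on the standardized scale), `selection` (per-step trace), `penalties`
#'   (final per-feature penalties), `baseline` (Breslow cumulative baseline
#'   hazard), `center`/`scale`, layer bookkeeping and the call.
#' @seealso [predict.coxfuse()], [bootstrap_632()], [cv_coxfuse()]
#' @export
coxfuse <- function(x_mrna, x_mirna = NULL, time, status, steps = 100,
                    penalty = NULL, graph = NULL, cf = 0.9, escalate = TRUE,
                    criterion = c("score", "plgain"),
                    weight_mode = "linear", standardize = TRUE) {
  criterion <- match.arg(criterion)
  check_expression(x_mrna, "x_mrna")
  if (!is.null(x_mirna)) check_expression(x_mirna, "x_mirna")
  check_surv(time, status)
  if (length(steps) != 1 || steps < 0 || steps != round(steps))
    stop("'steps' must be a nonnegative integer")
  check_cf(cf)
  n <- length(time)
  if (ncol(x_mrna) != n || (!is.null(x_mirna) && ncol(x_mirna) != n))
    stop("expression matrices and survival outcome have mismatched samples")
  if (!is.null(x_mirna) && !is.null(colnames(x_mrna)) &&
      !is.null(colnames(x_mirna)) &&
      !identical(colnames(x_mrna), colnames(x_mirna)))
    stop("sample identifiers of the two layers are not aligned")

  p1 <- nrow(x_mrna)
  p2 <- if (is.null(x_mirna)) 0L else nrow(x_mirna)
  ids <- c(rownames(x_mrna), if (p2) rownames(x_mirna))
  if (anyDuplicated(ids))
    stop("feature identifiers must be unique across both layers")
  layer <- rep(c("mrna", "mirna"), c(p1, p2))
  X <- t(if (p2) rbind(x_mrna, x_mirna) else x_mrna)  # n x p

  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    if (any(scl == 0))
      stop("zero-variance feature(s): ",
           paste(utils::head(ids[scl == 0], 5), collapse = ", "))
    X <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  } else {
    ctr <- rep(0, p1 + p2); scl <- rep(1, p1 + p2)
  }

  if (is.null(penalty)) penalty <- 9 * sum(status)
  if (penalty <= 0) stop("'penalty' must be positive")

  adj <- NULL
  if (!is.null(graph)) {
    if (!inherits(graph, "fusion_graph")) stop("'graph' must be a fusion_graph")
    if (p2 == 0) stop("graph-guided fitting needs a miRNA layer")
    if (!setequal(graph$row_ids, rownames(x_mrna)) ||
        !setequal(graph$col_ids, rownames(x_mirna)))
      stop("graph identifiers do not match the expression feature ids")
    W <- graph$W[rownames(x_mrna), rownames(x_mirna), drop = FALSE]
    adj <- lapply(seq_len(p1), function(i) {
      j <- which(W[i, ] > 0)
      list(idx = p1 + j, w = unname(W[i, j]))
    })
  }

  rs <- .risk_structure(time, status)
  p <- p1 + p2
  beta <- stats::setNames(numeric(p), ids)
  lambda <- rep(penalty, p)
  eta <- numeric(n)
  trace <- vector("list", steps)
  stopped_early <- FALSE

  k <- 0L
  while (k < steps) {
    k <- k + 1L
    si <- .score_info_all(X, exp(eta), rs)
    denom <- si$info + lambda
    gamma <- si$U / denom
    stat <- si$U * gamma  # U^2 / (F + lambda)
    if (all(si$U == 0)) {
      message("boosting stopped early at step ", k,
              ": no covariate carries score")
      stopped_early <- TRUE
      k <- k - 1L
      break
    }
    if (criterion == "plgain") {
      pl0 <- .cox_pl(eta, rs)
      stat <- vapply(seq_len(p), function(j) {
        .cox_pl(eta + gamma[j] * X[, j], rs) - pl0 -
          0.5 * lambda[j] * gamma[j]^2
      }, numeric(1))
    }
    j <- which.max(stat)  # first maximum = lowest index on ties
    beta[j] <- beta[j] + gamma[j]
    eta <- eta + gamma[j] * X[, j]
    if (!is.null(adj) && cf < 1) {
      if (escalate) lambda[j] <- penalty_escalate(lambda[j], si$info[j], cf)
      if (j <= p1 && length(adj[[j]]$idx)) {
        tgt <- adj[[j]]$idx
        lambda[tgt] <- penalty_relax(lambda[tgt], si$info[tgt], adj[[j]]$w,
                                     cf, weight_mode)
      }
    }
    trace[[k]] <- data.frame(step = k, feature = ids[j], index = j,
                             layer = layer[j], gamma = gamma[j],
                             score_stat = stat[j])
  }
  selection <- if (k > 0) do.call(rbind, trace[seq_len(k)]) else
    data.frame(step = integer(), feature = character(), index = integer(),
               layer = character(), gamma = numeric(), score_stat = numeric())

  # Breslow cumulative baseline hazard at the fitted linear predictor
  S0 <- as.vector(rs$R %*% exp(eta))
  H0 <- cumsum(rs$d / S0)

  structure(list(
    coefficients = beta, selection = selection,
    penalties = stats::setNames(lambda, ids),
    baseline = list(time = rs$event_times, cumhaz = H0),
    center = stats::setNames(ctr, ids), scale = stats::setNames(scl, ids),
    linear_predictors = eta, time = time, status = status,
    feature_ids = ids, layer = layer, p1 = p1, p2 = p2, n = n,
    config = list(steps = steps, steps_done = k, penalty = penalty, cf = cf,
                  graph = !is.null(graph), escalate = escalate,
                  criterion = criterion, weight_mode = weight_mode,
                  standardize = standardize, stopped_early = stopped_early),
    call = match.call()), class = "coxfuse")
}

#' Breslow estimator of the cumulative baseline hazard
#'
#' H0_hat(t) = sum over event times t_e <= t of d_e / sum_{i at risk} exp(eta_i),
#' a right-continuous nondecreasing step function with H0_hat(0) = 0. At
#' eta = 0 this reduces to the Nelson-Aalen estimator.
#'
#' @param object a fitted [coxfuse()] model (uses its stored training data),
#'   or `NULL` to supply `eta`, `time`, `status` directly.
#' @param eta,time,status training linear predictors and outcome (used when
#'   `object` is `NULL`).
#' @return list with `time` (ordered distinct event times) and `cumhaz`.
#' @export
breslow_cumhaz <- function(object = NULL, eta = NULL, time = NULL,
                           status = NULL) {
  if (!is.null(object)) {
    stopifnot(inherits(object, "coxfuse"))
    return(object$baseline)
  }
  check_surv(time, status)
  rs <- .risk_structure(time, status)
  S0 <- as.vector(rs$R %*% exp(eta))
  list(time = rs$event_times, cumhaz = cumsum(rs$d / S0))
}

# evaluate a right-continuous step function given knots/values, f(t<knot1)=init
.step_eval <- function(knots, values, t, init) {
  idx <- findInterval(t, knots)
  c(init, values)[idx + 1]
}
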