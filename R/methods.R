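#' @export
print.coxfuse <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("Componentwise Cox boosting fit",
      if (x$config$graph) " (graph-guided)", "\n", sep = "")
  cat("  n = ", x$n, " (", sum(x$status), " events), p = ",
      x$p1 + x$p2, " (", x$p1, " mRNA + ", x$p2, " miRNA)\n", sep = "")
  cat("  steps = ", x$config$steps_done, ", initial penalty = ",
      format(x$config$penalty), ", cf = ", x$config$cf, "\n", sep = "")
  cat("  nonzero coefficients: ", nz, "\n", sep = "")
  invisible(x)
}

#' @export
summary.coxfuse <- function(object, ...) {
  nz <- object$coefficients[object$coefficients != 0]
  sel <- object$selection
  picks <- table(sel$feature)
  out <- data.frame(
    feature = names(nz),
    layer = object$layer[match(names(nz), object$feature_ids)],
    coefficient = unname(nz),
    times_selected = as.integer(picks[names(nz)]))
  out <- out[order(-abs(out$coefficient)), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(coefficients = out, n = object$n,
                 events = sum(object$status),
                 layers = table(factor(out$layer, c("mrna", "mirna"))),
                 config = object$config),
            class = "summary.coxfuse")
}

#' @export
print.summary.coxfuse <- function(x, ...) {
  cat("Cox boosting model: ", nrow(x$coefficients),
      " selected features (", x$layers[["mrna"]], " mRNA, ",
      x$layers[["mirna"]], " miRNA); n = ", x$n, ", events = ", x$events,
      "\n\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
coef.coxfuse <- function(object, nonzero = FALSE, ...) {
  if (nonzero) object$coefficients[object$coefficients != 0]
  else object$coefficients
}

#' Predictions from a fitted Cox boosting model
#'
#' @param object a [coxfuse()] fit.
#' @param x_mrna,x_mirna new expression data (features x samples) carrying
#'   the training feature ids; `NULL` reuses the training data.
#' @param type `"lp"` (linear predictor, standardized training scale),
#'   `"risk"` (exp(lp)), or `"survival"` for predicted event-free
#'   probabilities r_hat(t|x) = exp(-H0(t) * exp(lp)) at the given `times`.
#' @param times evaluation time points (required for `type = "survival"`).
#' @param ... unused.
#' @return vector of lp/risk values, or an n x length(times) matrix of
#'   survival probabilities in (0, 1\], nonincreasing along each row.
#' @export
predict.coxfuse <- function(object, x_mrna = NULL, x_mirna = NULL,
                            type = c("lp", "risk", "survival"),
                            times = NULL, ...) {
  type <- match.arg(type)
  if (is.null(x_mrna) && is.null(x_mirna)) {
    eta <- object$linear_predictors
  } else {
    Xn <- if (object$p2 > 0) {
      if (is.null(x_mirna)) stop("model was fitted with a miRNA layer; ",
                                 "supply 'x_mirna'")
      rbind(x_mrna, x_mirna)
    } else x_mrna
    missing_ids <- setdiff(object$feature_ids, rownames(Xn))
    if (length(missing_ids))
      stop("new data lacks feature(s): ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    unknown <- setdiff(rownames(Xn), object$feature_ids)
    if (length(unknown))
      stop("unknown feature id(s) in new data: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    Xn <- t(Xn[object$feature_ids, , drop = FALSE])
    Xn <- sweep(sweep(Xn, 2L, object$center), 2L, object$scale, "/")
    eta <- as.vector(Xn %*% object$coefficients)
  }
  if (type == "lp") return(eta)
  if (type == "risk") return(exp(eta))
  if (is.null(times)) stop("'times' is required for survival predictions")
  H0 <- .step_eval(object$baseline$time, object$baseline$cumhaz, times, 0)
  exp(-outer(exp(eta), H0))
}

#' Coefficient build-up of a boosting fit
#'
#' Plots the coefficient paths over boosting steps for all features that
#' entered the model, coloured by layer.
#'
#' @param x a [coxfuse()] fit.
#' @param ... passed to `matplot`.
#' @export
plot.coxfuse <- function(x, ...) {
  sel <- x$selection
  if (nrow(sel) == 0) {
    plot(0, 0, type = "n", xlab = "boosting step", ylab = "coefficient",
         main = "Empty selection trace")
    return(invisible(x))
  }
  feats <- unique(sel$feature)
  M <- x$config$steps_done
  path <- matrix(0, M + 1, length(feats), dimnames = list(NULL, feats))
  for (k in seq_len(M)) {
    path[k + 1, ] <- path[k, ]
    path[k + 1, sel$feature[k]] <- path[k + 1, sel$feature[k]] + sel$gamma[k]
  }
  lay <- x$layer[match(feats, x$feature_ids)]
  graphics::matplot(0:M, path, type = "l", lty = 1,
                    col = ifelse(lay == "mrna", "grey40", "firebrick"),
                    xlab = "boosting step", ylab = "coefficient (standardized)",
                    ...)
  graphics::legend("topleft", legend = c("mRNA", "miRNA"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Cross-validated choice of the number of boosting steps
#'
#' K-fold cross-validation of the held-out Cox partial log-likelihood along
#' the boosting path: for each fold the model is trained on the remaining
#' folds up to `steps_max` steps, the left-out fold's partial log-likelihood
#' is evaluated at every step of the path, and the step count maximizing the
#' summed held-out likelihood over folds is returned. Folds are stratified
#' by event status so that every fold contains events.
#'
#' @inheritParams coxfuse
#' @param folds number of folds K >= 2.
#' @param steps_max largest step count explored.
#' @param seed RNG seed for the fold assignment (deterministic result).
#' @param ... further arguments passed to [coxfuse()] (penalty, graph, cf,
#'   ...).
#' @return list with `steps` (the chosen M*), `cvl` (summed held-out partial
#'   log-likelihood for M = 0..steps_max) and `fold` (per-sample assignment).
#' @export
cv_coxfuse <- function(x_mrna, x_mirna = NULL, time, status, folds = 5,
                       steps_max = 100, seed = 1, ...) {
  check_surv(time, status)
  if (folds < 2) stop("'folds' must be >= 2")
  n <- length(time)
  if (sum(status) < folds)
    stop("too few events (", sum(status), ") for ", folds, " folds")
  set.seed(seed)
  fold <- integer(n)
  for (grp in list(which(status == 1), which(status == 0)))
    fold[grp] <- sample(rep_len(seq_len(folds), length(grp)))
  cvl <- numeric(steps_max + 1)
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- coxfuse(x_mrna[, tr, drop = FALSE],
                   if (!is.null(x_mirna)) x_mirna[, tr, drop = FALSE],
                   time[tr], status[tr], steps = steps_max, ...)
    Xte <- if (!is.null(x_mirna))
      rbind(x_mrna[, !tr, drop = FALSE], x_mirna[, !tr, drop = FALSE])
    else x_mrna[, !tr, drop = FALSE]
    Xte <- t(Xte[fit$feature_ids, , drop = FALSE])
    Xte <- sweep(sweep(Xte, 2L, fit$center), 2L, fit$scale, "/")
    if (sum(status[!tr]) == 0)
      stop("fold ", f, " contains no events; use fewer folds")
    rs_te <- .risk_structure(time[!tr], status[!tr])
    eta <- numeric(sum(!tr))
    cvl[1] <- cvl[1] + .cox_pl(eta, rs_te)
    sel <- fit$selection
    for (m in seq_len(steps_max)) {
      if (m <= nrow(sel))
        eta <- eta + sel$gamma[m] * Xte[, sel$index[m]]
      cvl[m + 1] <- cvl[m + 1] + .cox_pl(eta, rs_te)
    }
  }
  list(steps = which.max(cvl) - 1L, cvl = cvl, fold = fold, seed = seed)
}
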