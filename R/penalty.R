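#' Penalty escalation after selection
#'
#' When a covariate is selected in a boosting step its penalty is raised to
#' lambda_new = (1/c_f - 1) * F + lambda / c_f, where F is the covariate's
#' Fisher information at the current offset. The one-step stepsize factor
#' nu = F / (F + lambda) then satisfies nu_new = c_f * nu_old exactly, i.e.
#' each re-selection shrinks the feature's future step size by c_f.
#'
#' @param lambda current penalty (or vector of penalties), > 0.
#' @param info Fisher information F of the feature(s), > 0.
#' @param cf stepsize modification factor in (0, 1].
#' @return updated penalty value(s).
#' @export
penalty_escalate <- function(lambda, info, cf) {
  check_cf(cf)
  if (cf == 1) return(lambda)
  (1 / cf - 1) * info + lambda / cf
}

#' Penalty relaxation of graph-connected miRNAs
#'
#' When an mRNA is selected, every miRNA connected to it with edge weight w
#' gets its penalty lowered. With shrinkage fraction s = lambda / (F + lambda)
#' and edge-modulated factor c_w, the update sets
#' lambda_new = F * (s * c_w) / (1 - s * c_w), so that s_new = c_w * s_old
#' exactly -- the mirror of [penalty_escalate()]'s contract. The modulation is
#' `"linear"`: c_w = 1 - w * (1 - c_f) (no effect at w = 0, full c_f at
#' w = 1), or `"power"`: c_w = c_f^w.
#'
#' @param lambda current penalties of the connected miRNAs.
#' @param info their Fisher informations at the current offset.
#' @param w edge weights in \[0, 1\] (same length).
#' @param cf stepsize modification factor in (0, 1].
#' @param weight_mode `"linear"` (default) or `"power"`.
#' @return updated penalties.
#' @export
penalty_relax <- function(lambda, info, w, cf, weight_mode = "linear") {
  check_cf(cf)
  if (any(w < 0 | w > 1)) stop("edge weights must lie in [0, 1]")
  cw <- switch(weight_mode,
               linear = 1 - w * (1 - cf),
               power = cf^w,
               stop("unknown weight_mode '", weight_mode, "'"))
  out <- lambda
  act <- cw < 1  # no-op edges (w = 0 or cf = 1) are left untouched exactly
  if (any(act)) {
    s_new <- (lambda[act] / (info[act] + lambda[act])) * cw[act]
    out[act] <- info[act] * s_new / (1 - s_new)
  }
  out
}

check_cf <- function(cf) {
  if (!is.numeric(cf) || length(cf) != 1 || cf <= 0 || cf > 1)
    stop("'cf' must be a single value in (0, 1]")
  invisible(cf)
}
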