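test_that("score and information match hand computation and finite differences", {
  # two subjects, both events: U = 1 - 1/2, F = 1/4
  si <- cox_score_info(c(1, 0), time = c(1, 2), status = c(1, 1))
  expect_equal(si$U, 0.5)
  expect_equal(si$info, 0.25)
  # constant covariate carries no risk contrast
  si0 <- cox_score_info(rep(3, 8), time = 1:8,
                        status = c(1, 0, 1, 1, 0, 1, 0, 1),
                        offset = rnorm(8))
  expect_equal(si0$U, 0, tolerance = 1e-12)
  # random fixtures (with ties and offsets): finite-difference oracle, 1e-6
  for (seed in 1:5) {
    set.seed(seed)
    n <- 15
    sv <- fx_surv(n, seed = seed, ties = seed %% 2 == 0)
    x <- rnorm(n); off <- rnorm(n, sd = 0.5)
    si <- cox_score_info(x, sv$time, sv$status, offset = off)
    fd <- oracle_score_info_fd(x, sv$time, sv$status, offset = off)
    expect_equal(si$U, fd$U, tolerance = 1e-6)
    expect_equal(si$info, fd$info, tolerance = 1e-6)
  }
  expect_error(cox_score_info(1:3, time = 1:3, status = c(0, 0, 0)),
               "at least one event")
})

test_that("penalty escalation and relaxation satisfy their algebraic contracts", {
  expect_identical(penalty_escalate(9, 1, cf = 1), 9)
  lam <- penalty_escalate(9, 1, cf = 0.9)
  expect_equal(lam, 1 / 0.9 - 1 + 10)
  expect_equal(1 / (1 + lam), 0.09)              # nu: 0.1 -> 0.09
  expect_identical(penalty_relax(9, 1, w = 0, cf = 0.9), 9)
  lam2 <- penalty_relax(9, 1, w = 1, cf = 0.9)   # s: 0.9 -> 0.81
  expect_equal(lam2, 0.81 / 0.19)
  lam3 <- penalty_relax(9, 1, w = 0.5, cf = 0.9) # c_w = 0.95, s -> 0.855
  expect_equal(lam3 / (1 + lam3), 0.855)
  # repeated selection: nu decays geometrically, nu_k = cf^k * nu_0
  lam <- 42; Fi <- 2.3; cf <- 0.85
  nu0 <- Fi / (Fi + lam)
  for (k in 1:12) {
    lam <- penalty_escalate(lam, Fi, cf)
    expect_equal(Fi / (Fi + lam), cf^k * nu0, tolerance = 1e-10)
  }
})

test_that("boosting selects the covariate maximizing the penalized score", {
  ds <- fx_dataset(seed = 55, n = 60, p1 = 25, p2 = 5)
  fit <- coxfuse(ds$x_mrna, ds$x_mirna, ds$time, ds$status, steps = 1,
                 penalty = 50)
  # exhaustive recomputation of the selection criterion at step 1
  X <- rbind(ds$x_mrna, ds$x_mirna)
  Xs <- t(scale(t(X)))
  stat <- vapply(seq_len(nrow(Xs)), function(j) {
    si <- cox_score_info(Xs[j, ], ds$time, ds$status)
    si$U^2 / (si$info + 50)
  }, numeric(1))
  expect_equal(fit$selection$index, which.max(stat))
  # a lone informative feature is found by a single step
  set.seed(3)
  n <- 40
  sig <- rnorm(n)
  xm <- rbind(sig = sig, fx_expr(6, n, "noise", seed = 10))
  rownames(xm)[1] <- "signal"
  sv <- simulate_survival(eta = 1.5 * sig, censor_frac = 0.2, seed = 4)
  fit1 <- coxfuse(xm, NULL, sv$time, sv$status, steps = 1, penalty = 10)
  expect_equal(fit1$selection$feature, "signal")
})

test_that("degenerate boosting cases: huge penalty, ties, zero steps", {
  ds <- fx_dataset(seed = 55, n = 60, p1 = 25, p2 = 5)
  big <- coxfuse(ds$x_mrna, ds$x_mirna, ds$time, ds$status, steps = 1,
                 penalty = 1e12)
  expect_lt(abs(big$selection$gamma), 1e-9)
  # two identical columns: the lower index wins
  xm <- fx_expr(4, 30, "m", seed = 2)
  xm[3, ] <- xm[1, ]
  sv <- fx_surv(30, seed = 5)
  # make the duplicated pair the strongest candidate
  xm[1, ] <- xm[3, ] <- -sv$time + rnorm(30, sd = 0.1)
  fit <- coxfuse(xm, NULL, sv$time, sv$status, steps = 1, penalty = 5)
  expect_equal(fit$selection$index, 1L)
  # zero steps: initialization only
  f0 <- coxfuse(ds$x_mrna, ds$x_mirna, ds$time, ds$status, steps = 0)
  expect_true(all(coef(f0) == 0))
  expect_equal(nrow(f0$selection), 0L)
  expect_equal(predict(f0), rep(0, 60))
  # sparsity: at most M nonzero coefficients
  f7 <- coxfuse(ds$x_mrna, ds$x_mirna, ds$time, ds$status, steps = 7)
  expect_lte(sum(coef(f7) != 0), 7)
})

test_that("exact penalized-likelihood-gain criterion agrees on a clear signal", {
  set.seed(21)
  n <- 40
  sig <- rnorm(n)
  xm <- rbind(matrix(rnorm(3 * n), 3, n), sig)
  rownames(xm) <- c("n1", "n2", "n3", "signal")
  colnames(xm) <- sprintf("S%d", 1:n)
  sv <- simulate_survival(eta = 2 * sig, censor_frac = 0.2, seed = 22)
  f_score <- coxfuse(xm, NULL, sv$time, sv$status, steps = 3, penalty = 3)
  f_gain <- coxfuse(xm, NULL, sv$time, sv$status, steps = 3, penalty = 3,
                    criterion = "plgain")
  expect_identical(f_score$selection$feature, f_gain$selection$feature)
  # the first gain-criterion pick maximizes the exact penalized gain
  Xs <- t(scale(t(xm)))
  gains <- vapply(seq_len(nrow(Xs)), function(j) {
    si <- cox_score_info(Xs[j, ], sv$time, sv$status)
    gm <- si$U / (si$info + 3)
    oracle_pl(gm, Xs[j, ], sv$time, sv$status) -
      oracle_pl(0, Xs[j, ], sv$time, sv$status) - 0.5 * 3 * gm^2
  }, numeric(1))
  expect_equal(f_gain$selection$index[1], which.max(gains))
})

test_that("boosting path converges to the Cox MLE for a single covariate", {
  for (seed in 1:3) {
    set.seed(seed + 100)
    n <- 20
    x <- rnorm(n)
    sv <- simulate_survival(eta = 0.8 * x, censor_frac = 0.3,
                            seed = seed + 200)
    xm <- matrix(x, 1, n, dimnames = list("f1", sprintf("S%d", 1:n)))
    fit <- coxfuse(xm, NULL, sv$time, sv$status, steps = 500,
                   penalty = 0.01)
    xs <- (x - mean(x)) / sd(x)
    mle <- survival::coxph(survival::Surv(sv$time, sv$status) ~ xs,
                           ties = "breslow")
    expect_equal(unname(coef(fit)["f1"]), unname(coef(mle)),
                 tolerance = 1e-4)
  }
})

test_that("graph guidance with cf = 1 or zero weights is inert", {
  ds <- fx_dataset(seed = 55, n = 60, p1 = 25, p2 = 5)
  g <- fusion_graph(ds$x_mrna, ds$x_mirna, ds$predictions)
  plain <- coxfuse(ds$x_mrna, ds$x_mirna, ds$time, ds$status, steps = 20)
  neutral <- coxfuse(ds$x_mrna, ds$x_mirna, ds$time, ds$status, steps = 20,
                     graph = g, cf = 1)
  expect_identical(plain$coefficients, neutral$coefficients)
  expect_identical(plain$selection, neutral$selection)
  expect_identical(plain$penalties, neutral$penalties)
  # all-zero weights with escalation disabled: same thing at cf < 1
  g0 <- g; g0$W[] <- 0
  zero <- coxfuse(ds$x_mrna, ds$x_mirna, ds$time, ds$status, steps = 20,
                  graph = g0, cf = 0.9, escalate = FALSE)
  expect_identical(plain$selection, zero$selection)
})

test_that("graph guidance relaxes only miRNA penalties after mRNA picks", {
  ds <- fx_dataset(seed = 55, n = 60, p1 = 25, p2 = 5)
  g <- fusion_graph(ds$x_mrna, ds$x_mirna, ds$predictions)
  fit <- coxfuse(ds$x_mrna, ds$x_mirna, ds$time, ds$status, steps = 15,
                 graph = g, cf = 0.9)
  lam0 <- fit$config$penalty
  never_selected <- setdiff(fit$feature_ids, fit$selection$feature)
  mrna_ids <- fit$feature_ids[fit$layer == "mrna"]
  # unselected mRNAs never have their penalty touched (directed graph)
  expect_true(all(fit$penalties[intersect(never_selected, mrna_ids)] == lam0))
  # selected features were escalated above the common penalty
  expect_true(all(fit$penalties[unique(fit$selection$feature[
    fit$selection$layer == "mrna"])] > lam0))
})

test_that("fits are invariant to joint sample permutation", {
  ds <- fx_dataset(seed = 55, n = 60, p1 = 25, p2 = 5)
  set.seed(1)
  pi <- sample(60)
  f1 <- coxfuse(ds$x_mrna, ds$x_mirna, ds$time, ds$status, steps = 12)
  f2 <- coxfuse(ds$x_mrna[, pi], ds$x_mirna[, pi], ds$time[pi],
                ds$status[pi], steps = 12)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$baseline, f2$baseline, tolerance = 1e-10)
})

test_that("Breslow baseline hazard reduces to Nelson-Aalen at eta = 0", {
  bl <- breslow_cumhaz(eta = c(0, 0), time = c(1, 2), status = c(1, 1))
  expect_equal(bl$time, c(1, 2))
  expect_equal(bl$cumhaz, c(0.5, 1.5))
  ds <- fx_dataset(seed = 55, n = 60, p1 = 25, p2 = 5)
  fit <- coxfuse(ds$x_mrna, ds$x_mirna, ds$time, ds$status, steps = 10)
  expect_true(all(diff(fit$baseline$cumhaz) >= 0))
  expect_true(all(fit$baseline$cumhaz > 0))
})

test_that("survival predictions are proper, monotone and reconstructible", {
  ds <- fx_dataset(seed = 55, n = 60, p1 = 25, p2 = 5)
  fit <- coxfuse(ds$x_mrna, ds$x_mirna, ds$time, ds$status, steps = 10)
  tms <- c(0, sort(ds$time)[c(10, 30, 50)])
  sp <- predict(fit, ds$x_mrna, ds$x_mirna, type = "survival", times = tms)
  expect_equal(sp[, 1], rep(1, 60))           # H0(0) = 0
  expect_true(all(sp > 0 & sp <= 1))
  expect_true(all(apply(sp, 1, diff) <= 0))   # nonincreasing per sample
  # recomputation: sp = exp(-H0)^exp(eta)
  eta <- predict(fit, ds$x_mrna, ds$x_mirna, type = "lp")
  H0 <- c(0, vapply(tms[-1], function(t)
    max(0, fit$baseline$cumhaz[max(0, sum(fit$baseline$time <= t))]),
    numeric(1)))
  expect_equal(sp, exp(-outer(exp(eta), H0)), tolerance = 1e-12)
  # higher linear predictor implies pointwise lower survival
  hi <- which.max(eta); lo <- which.min(eta)
  expect_true(all(sp[hi, -1] < sp[lo, -1]))
  # a steps = 0 model predicts one shared curve
  f0 <- coxfuse(ds$x_mrna, ds$x_mirna, ds$time, ds$status, steps = 0)
  sp0 <- predict(f0, ds$x_mrna, ds$x_mirna, type = "survival", times = tms)
  expect_true(all(apply(sp0, 2, function(cc) length(unique(cc)) == 1)))
  expect_error(predict(fit, ds$x_mrna[-1, ], ds$x_mirna, type = "lp"),
               "lacks feature")
})

test_that("cross-validated step choice is deterministic and bounded", {
  ds <- fx_dataset(seed = 55, n = 60, p1 = 25, p2 = 5)
  cv1 <- cv_coxfuse(ds$x_mrna, ds$x_mirna, ds$time, ds$status, folds = 4,
                    steps_max = 15, seed = 9, penalty = 100)
  cv2 <- cv_coxfuse(ds$x_mrna, ds$x_mirna, ds$time, ds$status, folds = 4,
                    steps_max = 15, seed = 9, penalty = 100)
  expect_identical(cv1$steps, cv2$steps)
  expect_identical(cv1$cvl, cv2$cvl)
  expect_true(cv1$steps >= 0 && cv1$steps <= 15)
  # steps_max = 0 forces the null model
  cv0 <- cv_coxfuse(ds$x_mrna, ds$x_mirna, ds$time, ds$status, folds = 4,
                    steps_max = 0, seed = 9, penalty = 100)
  expect_identical(cv0$steps, 0L)
  # pure-noise features: the held-out likelihood prefers few steps
  xm <- fx_expr(30, 60, "n", seed = 77)
  sv <- fx_surv(60, seed = 78, censor = 0.3)
  cvn <- cv_coxfuse(xm, NULL, sv$time, sv$status, folds = 4, steps_max = 25,
                    seed = 9, penalty = 50)
  expect_lte(cvn$steps, 10)
})
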