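# In-code fixtures shared across test files.

# expression matrix with ids, features x samples
fx_expr <- function(p, n, prefix = "f", seed = 1, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(p * n, sd = sd), p, n,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(p)),
                              sprintf("S%03d", seq_len(n))))
  m
}

# small right-censored survival fixture with distinct or tied times
fx_surv <- function(n, seed = 1, censor = 0.4, ties = FALSE) {
  set.seed(seed)
  time <- rexp(n)
  if (ties) time <- round(time, 1) + 0.05
  status <- as.integer(runif(n) > censor)
  if (sum(status) == 0) status[1] <- 1L
  list(time = time, status = status)
}

# a 1-row pvalue_matrix from a scalar
fx_pm <- function(values, kind, rid = "m1", cid = "mi1") {
  pvalue_matrix(matrix(values, 1, dimnames = list(rid, cid)), kind)
}

# default small synthetic dataset, cached per seed within a test run
fx_dataset <- local({
  cache <- list()
  function(seed = 202, ...) {
    key <- paste0(seed, "/", paste(deparse(list(...)), collapse = ""))
    if (is.null(cache[[key]]))
      cache[[key]] <<- simulate_fusion_data(sim_config(seed = seed, ...))
    cache[[key]]
  }
})
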