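#' p-value matrix constructor
#'
#' Lightweight container for a p1 x p2 matrix of probabilities with mRNA
#' (transcript) row identifiers, miRNA column identifiers and a `kind` tag
#' recording the stage of the fusion pipeline the values belong to.
#'
#' @param values numeric matrix with entries in \[0, 1\]; dimnames give the
#'   feature identifiers.
#' @param kind one of `"correlation_raw"`, `"correlation_adjusted"`,
#'   `"prediction"`, `"combined"`.
#' @return a `pvalue_matrix`: the matrix with a `kind` attribute.
#' @export
pvalue_matrix <- function(values, kind = c("correlation_raw",
                                           "correlation_adjusted",
                                           "prediction", "combined")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (anyNA(values) || any(values < 0) || any(values > 1))
    stop("p-values must lie in [0, 1] and contain no NA")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry row (mRNA) and column (miRNA) identifiers")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("feature identifiers must be unique")
  structure(values, kind = kind, class = c("pvalue_matrix", "matrix"))
}

pm_kind <- function(x) attr(x, "kind")

#' Pearson correlation p-values between two expression layers
#'
#' For every (mRNA, miRNA) pair, tests H0: rho = 0 with the exact t-test
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom (two-sided).
#' Both matrices are features x samples and must share an identical, ordered
#' sample set.
#'
#' @param mrna,mirna numeric matrices, features as rows, samples as columns,
#'   with rownames (feature ids). If both carry column names they must agree
#'   exactly (same samples, same order).
#' @return a [pvalue_matrix()] of kind `"correlation_raw"` (p1 x p2).
#' @export
correlation_pvalues <- function(mrna, mirna) {
  check_expression(mrna, "mrna")
  check_expression(mirna, "mirna")
  n <- ncol(mrna)
  if (ncol(mirna) != n)
    stop("sample count mismatch: mrna has ", n, " samples, mirna has ",
         ncol(mirna))
  if (!is.null(colnames(mrna)) && !is.null(colnames(mirna)) &&
      !identical(colnames(mrna), colnames(mirna))) {
    bad <- union(setdiff(colnames(mrna), colnames(mirna)),
                 setdiff(colnames(mirna), colnames(mrna)))
    if (length(bad) == 0) bad <- "(same set, different order)"
    stop("sample identifiers are not aligned: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (n < 4) stop("need at least 4 shared samples, got ", n)
  check_nonzero_variance(mrna, "mrna")
  check_nonzero_variance(mirna, "mirna")
  r <- stats::cor(t(mrna), t(mirna))
  # exact test via the t transform; |r| = 1 maps to p = 0
  r2 <- pmin(r * r, 1)
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r2, 0))
  p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  p[!is.finite(tt)] <- 0
  p <- pmin(p, 1)
  dimnames(p) <- list(rownames(mrna), rownames(mirna))
  pvalue_matrix(p, "correlation_raw")
}

check_expression <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("'", what, "' must be a numeric matrix (features x samples)")
  if (is.null(rownames(x)))
    stop("'", what, "' must have feature identifiers as rownames")
  if (anyDuplicated(rownames(x)))
    stop("duplicated feature identifiers in '", what, "': ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyNA(x) || any(!is.finite(x)))
    stop("'", what, "' contains missing or non-finite values")
  invisible(x)
}

check_nonzero_variance <- function(x, what) {
  v <- apply(x, 1L, stats::sd)
  if (any(v == 0))
    stop("zero-variance feature(s) in '", what, "': ",
         paste(utils::head(rownames(x)[v == 0], 5), collapse = ", "))
  invisible(x)
}

#' Multiple-testing correction of a correlation p-value matrix
#'
#' Applies Benjamini-Hochberg over all p1 * p2 values jointly (one flattened
#' family), capping adjusted values at 1.
#'
#' @param P a [pvalue_matrix()] of kind `"correlation_raw"`.
#' @param method correction method; only `"BH"` is supported.
#' @return a [pvalue_matrix()] of kind `"correlation_adjusted"`.
#' @export
adjust_pvalues <- function(P, method = "BH") {
  if (!inherits(P, "pvalue_matrix") || pm_kind(P) != "correlation_raw")
    stop("'P' must be a pvalue_matrix of kind 'correlation_raw'")
  if (!identical(method, "BH"))
    stop("unknown method '", method, "'; supported methods: BH")
  adj <- matrix(stats::p.adjust(as.vector(P), method = "BH"),
                nrow = nrow(P), dimnames = dimnames(P))
  pvalue_matrix(pmin(adj, 1), "correlation_adjusted")
}

#' Stouffer combination of two p-value matrices
#'
#' Elementwise equal-weight Stouffer combination:
#' p_comb = 1 - Phi((Phi^-1(1 - p1) + Phi^-1(1 - p2)) / sqrt(2)).
#' Inputs are clamped to \[eps, 1 - eps\] before the normal quantile
#' transform so that boundary p-values (0 or 1) yield finite z-scores.
#'
#' @param p_a,p_b [pvalue_matrix()] objects of identical shape and identifiers.
#' @param eps clamping bound, default `1e-15`.
#' @return a [pvalue_matrix()] of kind `"combined"` with entries in (0, 1).
#' @export
stouffer_combine <- function(p_a, p_b, eps = 1e-15) {
  if (!identical(dim(p_a), dim(p_b)) ||
      !identical(dimnames(p_a), dimnames(p_b)))
    stop("shape or identifier mismatch between the two p-value matrices")
  za <- stats::qnorm(clamp01(unclass(p_a), eps), lower.tail = FALSE)
  zb <- stats::qnorm(clamp01(unclass(p_b), eps), lower.tail = FALSE)
  p <- stats::pnorm((za + zb) / sqrt(2), lower.tail = FALSE)
  p <- clamp01(p, eps)
  dimnames(p) <- dimnames(p_a)
  pvalue_matrix(p, "combined")
}

clamp01 <- function(x, eps) pmin(pmax(x, eps), 1 - eps)

#' Target prediction table
#'
#' Records of putative miRNA -> transcript regulatory pairs with a prediction
#' p-value, plus the identifier sets the source covers at all. Duplicate
#' (miRNA, transcript) pairs are resolved by keeping the minimum p-value.
#'
#' @param records data.frame with columns `mirna_id`, `transcript_id`,
#'   `p_value` (in \[0, 1\]).
#' @param source_label free-text provenance label.
#' @param covered_mirnas,covered_mrnas identifier sets the source covers;
#'   default: the ids appearing in `records`. Must be supersets of those.
#' @return a `target_predictions` object.
#' @export
target_predictions <- function(records, source_label = "unknown",
                               covered_mirnas = NULL, covered_mrnas = NULL) {
  req <- c("mirna_id", "transcript_id", "p_value")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    stop("'records' needs columns: ", paste(req, collapse = ", "))
  records <- records[req]
  records$mirna_id <- as.character(records$mirna_id)
  records$transcript_id <- as.character(records$transcript_id)
  if (nrow(records) > 0 &&
      (anyNA(records$p_value) || any(records$p_value < 0) ||
       any(records$p_value > 1)))
    stop("prediction p-values must lie in [0, 1]")
  if (nrow(records) > 0) {
    # keep the strongest (minimum-p) record per pair
    o <- order(records$mirna_id, records$transcript_id, records$p_value)
    records <- records[o, , drop = FALSE]
    key <- paste(records$mirna_id, records$transcript_id, sep = "\r")
    records <- records[!duplicated(key), , drop = FALSE]
    rownames(records) <- NULL
  }
  if (is.null(covered_mirnas)) covered_mirnas <- unique(records$mirna_id)
  if (is.null(covered_mrnas)) covered_mrnas <- unique(records$transcript_id)
  if (!all(records$mirna_id %in% covered_mirnas) ||
      !all(records$transcript_id %in% covered_mrnas))
    stop("covered identifier sets must contain all ids appearing in records")
  structure(list(records = records, source_label = source_label,
                 covered_mirnas = unique(as.character(covered_mirnas)),
                 covered_mrnas = unique(as.character(covered_mrnas))),
            class = "target_predictions")
}

#' @export
print.target_predictions <- function(x, ...) {
  cat("Target predictions [", x$source_label, "]: ", nrow(x$records),
      " pairs; coverage ", length(x$covered_mirnas), " miRNAs, ",
      length(x$covered_mrnas), " transcripts\n", sep = "")
  invisible(x)
}

#' Expand a target prediction table to a dense p-value matrix
#'
#' Listed pairs receive their prediction p-value; unlisted pairs whose miRNA
#' and transcript both appear in the source's covered sets receive p = 1.
#' Pairs with at least one feature absent from the source are flagged in the
#' coverage mask and bypass p-value combination entirely (the fused graph
#' falls back to the correlation p-value there).
#'
#' @param pred a [target_predictions()] table.
#' @param row_ids transcript identifiers (graph rows).
#' @param col_ids miRNA identifiers (graph columns).
#' @param strict if `TRUE`, prediction records whose ids are absent from
#'   `row_ids`/`col_ids` raise an error; otherwise they are dropped silently.
#' @return list with `p` (a [pvalue_matrix()] of kind `"prediction"`) and
#'   `mask` (logical matrix, `TRUE` where the pair is not covered).
#' @export
prediction_pvalue_matrix <- function(pred, row_ids, col_ids, strict = FALSE) {
  if (!inherits(pred, "target_predictions"))
    stop("'pred' must be a target_predictions object")
  row_ids <- as.character(row_ids); col_ids <- as.character(col_ids)
  p <- matrix(1, length(row_ids), length(col_ids),
              dimnames = list(row_ids, col_ids))
  rec <- pred$records
  if (nrow(rec) == 0) {
    warning("empty target prediction table: all pairs fall back to ",
            "correlation p-values")
    mask <- matrix(TRUE, length(row_ids), length(col_ids),
                   dimnames = dimnames(p))
    return(list(p = pvalue_matrix(p, "prediction"), mask = mask))
  }
  ri <- match(rec$transcript_id, row_ids)
  ci <- match(rec$mirna_id, col_ids)
  unmapped <- is.na(ri) | is.na(ci)
  if (any(unmapped) && strict)
    stop("prediction records with unmapped identifiers: ",
         paste(utils::head(paste(rec$mirna_id[unmapped],
                                 rec$transcript_id[unmapped], sep = "->"), 5),
               collapse = ", "))
  keep <- !unmapped
  p[cbind(ri[keep], ci[keep])] <- rec$p_value[keep]
  mask <- outer(!(row_ids %in% pred$covered_mrnas),
                !(col_ids %in% pred$covered_mirnas), "|")
  dimnames(mask) <- dimnames(p)
  list(p = pvalue_matrix(p, "prediction"), mask = mask)
}

#' Assemble the bipartite mRNA -> miRNA fusion graph
#'
#' Full fusion pipeline: Pearson correlation p-values for every
#' (mRNA, miRNA) pair, Benjamini-Hochberg correction over the whole family,
#' expansion of the target-prediction table to a dense matrix, Stouffer
#' combination on covered pairs, fallback to the adjusted correlation
#' p-value on uncovered pairs, and the weight transform w = 1 - p_comb.
#' The result is read as the adjacency matrix of a directed bipartite graph
#' with edges from mRNAs to miRNAs.
#'
#' @param mrna,mirna expression matrices (features x samples, shared ordered
#'   samples).
#' @param predictions a [target_predictions()] table, or `NULL` for a
#'   correlation-only graph (all pairs masked).
#' @param eps clamping bound for the Stouffer transform.
#' @param method multiple-testing correction, see [adjust_pvalues()].
#' @param weight_floor weights strictly below this value are set to zero
#'   (sparsification); the default 0 keeps all entries.
#' @param strict passed to [prediction_pvalue_matrix()].
#' @return a `fusion_graph`: list with `W` (p1 x p2 weight matrix in
#'   \[0, 1\]), `row_ids`, `col_ids`, the intermediate `p_cor_adj`, `p_pred`,
#'   `p_comb` matrices, the coverage `mask`, and `meta` (provenance).
#' @export
fusion_graph <- function(mrna, mirna, predictions = NULL, eps = 1e-15,
                         method = "BH", weight_floor = 0, strict = FALSE) {
  p_raw <- correlation_pvalues(mrna, mirna)
  p_adj <- adjust_pvalues(p_raw, method = method)
  if (is.null(predictions))
    predictions <- target_predictions(
      data.frame(mirna_id = character(), transcript_id = character(),
                 p_value = numeric()), source_label = "none")
  pm <- suppressWarnings(
    prediction_pvalue_matrix(predictions, rownames(mrna), rownames(mirna),
                             strict = strict))
  p_comb <- unclass(stouffer_combine(p_adj, pm$p, eps = eps))
  # uncovered pairs: combined evidence is the correlation evidence alone
  p_comb[pm$mask] <- unclass(p_adj)[pm$mask]
  W <- 1 - p_comb
  if (weight_floor > 0) W[W < weight_floor] <- 0
  structure(list(W = W, row_ids = rownames(mrna), col_ids = rownames(mirna),
                 p_cor_adj = p_adj, p_pred = pm$p,
                 p_comb = pvalue_matrix(p_comb, "combined"), mask = pm$mask,
                 meta = list(eps = eps, correction = method,
                             weight_floor = weight_floor,
                             prediction_source = predictions$source_label,
                             n_samples = ncol(mrna))),
            class = "fusion_graph")
}

#' @export
print.fusion_graph <- function(x, ...) {
  cat("Bipartite fusion graph (mRNA -> miRNA)\n")
  cat("  ", length(x$row_ids), " mRNAs x ", length(x$col_ids), " miRNAs; ",
      sum(x$mask), " correlation-only pairs\n", sep = "")
  cat("  prediction source: ", x$meta$prediction_source,
      "; correction: ", x$meta$correction, "\n", sep = "")
  qs <- stats::quantile(x$W, c(0, .5, .9, 1))
  cat(sprintf("  weights: min %.3f  median %.3f  q90 %.3f  max %.3f\n",
              qs[1], qs[2], qs[3], qs[4]))
  invisible(x)
}

#' Flatten a fusion graph to an edge table
#'
#' @param graph a [fusion_graph()].
#' @param weight_floor only edges with weight >= this value are returned.
#' @return data.frame with columns mrna_id, mirna_id, weight, p_cor_adj,
#'   p_pred, p_comb, masked.
#' @export
graph_edge_table <- function(graph, weight_floor = 0) {
  stopifnot(inherits(graph, "fusion_graph"))
  idx <- which(graph$W >= weight_floor, arr.ind = TRUE)
  out <- data.frame(
    mrna_id = graph$row_ids[idx[, 1]],
    mirna_id = graph$col_ids[idx[, 2]],
    weight = graph$W[idx],
    p_cor_adj = unclass(graph$p_cor_adj)[idx],
    p_pred = unclass(graph$p_pred)[idx],
    p_comb = unclass(graph$p_comb)[idx],
    masked = graph$mask[idx])
  out[order(-out$weight, out$mrna_id, out$mirna_id), , drop = FALSE]
}
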