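# Tab-separated on-disk formats: expression matrices (features x samples,
# first column feature id, header row sample ids), clinical tables
# (sample_id, time, status), target prediction tables and graph edge lists.
# One dialect: TSV, UTF-8, '.' decimal, no quoting.

#' Read an expression matrix
#'
#' @param path TSV file: first column feature ids, header row sample ids.
#' @param layer label stored on the matrix (`"mrna"` or `"mirna"`).
#' @param missing policy for missing values: `"error"` (default) or
#'   `"drop_feature"` (drop rows containing NA, with a warning).
#' @return numeric matrix features x samples with a `layer` attribute.
#' @export
read_expression <- function(path, layer = c("mrna", "mirna"),
                            missing = c("error", "drop_feature")) {
  layer <- match.arg(layer)
  missing <- match.arg(missing)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file needs an id column and >= 1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated feature identifier(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                   !is.na(m), arr.ind = TRUE)
    stop("non-numeric cell(s) in ", path, ", e.g. row ", bad[1, 1] + 1,
         " column ", bad[1, 2] + 1)
  }
  rownames(m) <- ids
  if (anyNA(m)) {
    if (missing == "error")
      stop("missing values in ", path, " (feature ",
           rownames(m)[which(rowSums(is.na(m)) > 0)[1]], ")")
    drop <- rowSums(is.na(m)) > 0
    warning("dropping ", sum(drop), " feature(s) with missing values")
    m <- m[!drop, , drop = FALSE]
  }
  structure(m, layer = layer)
}

#' Write an expression matrix
#'
#' @param x numeric matrix features x samples with dimnames.
#' @param path output TSV path.
#' @param id_column header name of the feature id column.
#' @export
write_expression <- function(x, path, id_column = "feature_id") {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical outcome table
#'
#' @param path TSV with columns `sample_id`, `time`, `status` (0/1).
#' @param samples optional sample ids (e.g. expression columns) to harmonize
#'   against; the intersection is taken with a warning unless `strict`.
#' @param strict error on any mismatch instead of intersecting.
#' @return list with `sample_id`, `time`, `status` in the harmonized order.
#' @export
read_clinical <- function(path, samples = NULL, strict = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("sample_id", "time", "status")
  if (!all(req %in% names(df)))
    stop("clinical file needs columns: ", paste(req, collapse = ", "))
  if (any(df$time < 0)) stop("negative times in clinical table")
  if (!all(df$status %in% c(0, 1))) stop("status must be 0 or 1")
  if (any(df$time == 0 & df$status == 1))
    warning("event(s) at time 0 in clinical table")
  if (!is.null(samples)) {
    if (strict && !setequal(df$sample_id, samples))
      stop("clinical and expression sample ids differ: ",
           paste(utils::head(union(setdiff(samples, df$sample_id),
                                   setdiff(df$sample_id, samples)), 5),
                 collapse = ", "))
    common <- intersect(samples, df$sample_id)
    if (length(common) < length(samples) ||
        length(common) < nrow(df))
      warning("restricting to ", length(common), " shared samples")
    df <- df[match(common, df$sample_id), , drop = FALSE]
  }
  message("clinical table: ", nrow(df), " samples, ", sum(df$status),
          " events, ", sum(df$status == 0), " censored")
  list(sample_id = df$sample_id, time = df$time, status = df$status)
}

#' Write a clinical outcome table
#' @param time,status,sample_id outcome vectors.
#' @param path output TSV path.
#' @export
write_clinical <- function(time, status, sample_id, path) {
  utils::write.table(data.frame(sample_id = sample_id, time = time,
                                status = status),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a target-prediction table
#'
#' Native format: TSV with columns `mirna_id`, `transcript_id`, `p_value`.
#' TargetScan-style flat files carry a conserved-targeting probability
#' `PCT` per pair instead; the per-pair p-value is then 1 - PCT.
#'
#' @param path input TSV.
#' @param format `"tsv"` (native) or `"targetscan"`.
#' @param source_label provenance label; defaults to the format name.
#' @return a [target_predictions()] table.
#' @export
read_predictions <- function(path, format = c("tsv", "targetscan"),
                             source_label = NULL) {
  format <- match.arg(format)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (format == "targetscan") {
    req <- c("mirna_id", "transcript_id", "PCT")
    if (!all(req %in% names(df)))
      stop("TargetScan file needs columns: ", paste(req, collapse = ", "))
    df$p_value <- 1 - df$PCT
  }
  if (is.null(source_label)) source_label <- format
  target_predictions(df[c("mirna_id", "transcript_id", "p_value")],
                     source_label = source_label)
}

#' Write a fusion graph as an edge list with provenance sidecar
#'
#' Writes a TSV edge list (`mrna_id`, `mirna_id`, `weight`, `p_cor_adj`,
#' `p_pred`, `p_comb`, `masked`) and a JSON sidecar (`<path>.json`) echoing
#' the graph's configuration.
#'
#' @param graph a [fusion_graph()].
#' @param path output TSV path.
#' @param weight_floor only write edges with weight >= this value.
#' @export
write_graph <- function(graph, path, weight_floor = 0) {
  et <- graph_edge_table(graph, weight_floor)
  utils::write.table(et, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(meta = graph$meta, p1 = length(graph$row_ids),
         p2 = length(graph$col_ids), weight_floor_written = weight_floor),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Stores the nonzero coefficients, selection trace, penalty state, Breslow
#' baseline hazard knots and values, standardization parameters and the
#' configuration echo, sufficient to reconstruct predictions.
#'
#' @param model a [coxfuse()] fit.
#' @param path output JSON path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "coxfuse"))
  nz <- model$coefficients[model$coefficients != 0]
  jsonlite::write_json(list(
    coefficients = as.list(nz),
    selection = model$selection,
    penalties = as.list(model$penalties[names(nz)]),
    baseline = model$baseline,
    center = as.list(model$center[names(nz)]),
    scale = as.list(model$scale[names(nz)]),
    n = model$n, events = sum(model$status),
    config = model$config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(ds$x_mrna, file.path(dir, "mrna.tsv"))
  write_expression(ds$x_mirna, file.path(dir, "mirna.tsv"))
  write_clinical(ds$time, ds$status, ds$sample_ids,
                 file.path(dir, "clinical.tsv"))
  utils::write.table(ds$predictions$records,
                     file.path(dir, "predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- unclass(ds$config)
  net <- ds$truth$network
  jsonlite::write_json(list(
    config = cfg, seed = cfg$seed,
    edges = as.data.frame(net$edges),
    beta = ds$truth$beta,
    prognostic_mirnas = net$prognostic_mirnas,
    covered_mirnas = ds$predictions$covered_mirnas),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
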