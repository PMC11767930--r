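# Readers and writers: HUMAnN3-style stratified pathabundance tables,
# generic feature tables, sample metadata, and fitted-model export.

read_tsv_checked <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2)
    stop(sprintf("'%s' has no data rows", path), call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(fields[[1]])
  bad <- which(vapply(fields, length, integer(1)) != n)
  if (length(bad))
    stop(sprintf("ragged row in '%s' at line %d (expected %d fields)",
                 path, bad[1], n), call. = FALSE)
  fields
}

#' Read a HUMAnN3-style stratified pathabundance table
#'
#' Parses a TSV whose first column holds feature ids and remaining columns
#' samples. Only stratified rows — ids of the form
#' \code{"pathway|taxon"} (taxon strings like \code{"g__X.s__Y"}) — are
#' retained; the pathway is split from the taxon at the first \code{"|"}.
#' Community-total (unstratified) rows are skipped, and
#' \code{UNMAPPED}/\code{UNINTEGRATED} rows are dropped by default.
#'
#' @param path TSV file path.
#' @param drop_unmapped drop rows whose pathway is UNMAPPED or UNINTEGRATED
#'   (default TRUE).
#' @param quiet suppress the skipped-row message.
#' @return long-format data frame with columns \code{pathway}, \code{taxon},
#'   \code{sample}, \code{abundance}.
#' @export
read_stratified_pathabundance <- function(path, drop_unmapped = TRUE,
                                          quiet = FALSE) {
  fields <- read_tsv_checked(path)
  header <- fields[[1]]
  samples <- header[-1]
  body <- fields[-1]
  ids <- vapply(body, `[`, character(1), 1L)
  stratified <- grepl("|", ids, fixed = TRUE)
  pathway_part <- sub("\\|.*$", "", ids)
  keep <- stratified
  if (drop_unmapped)
    keep <- keep & !(pathway_part %in% c("UNMAPPED", "UNINTEGRATED"))
  n_skipped <- sum(!keep)
  if (!any(keep))
    stop(sprintf("'%s' contains no stratified rows", path), call. = FALSE)
  if (n_skipped && !quiet)
    message(n_skipped, " unstratified or unmapped row(s) skipped")
  body <- body[keep]
  ids <- ids[keep]
  pathway <- sub("\\|.*$", "", ids)
  taxon <- sub("^[^|]*\\|", "", ids)
  vals <- do.call(rbind, lapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    v
  }))
  if (any(is.na(vals)))
    stop(sprintf("non-numeric abundance value in '%s'", path), call. = FALSE)
  data.frame(
    pathway = rep(pathway, each = length(samples)),
    taxon = rep(taxon, each = length(samples)),
    sample = rep(samples, times = length(ids)),
    abundance = as.numeric(t(vals)),
    stringsAsFactors = FALSE)
}

#' Read a generic feature table
#'
#' Reads a TSV with a leading id column and a numeric body, oriented
#' features-by-samples by default, and returns it samples x features.
#'
#' @param path TSV file path.
#' @param orientation \code{"features_by_samples"} (default: rows are
#'   features) or \code{"samples_by_features"}.
#' @return numeric matrix, samples in rows, with dimnames.
#' @export
read_feature_table <- function(path,
                               orientation = c("features_by_samples",
                                               "samples_by_features")) {
  orientation <- match.arg(orientation)
  fields <- read_tsv_checked(path)
  header <- fields[[1]][-1]
  body <- fields[-1]
  ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate row ids in '%s'", path), call. = FALSE)
  m <- matrix(NA_real_, length(ids), length(header),
              dimnames = list(ids, header))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (any(is.na(v)))
      stop(sprintf("non-numeric cell in '%s', row %d ('%s'), column %d",
                   path, i, ids[i], which(is.na(v))[1] + 1L), call. = FALSE)
    m[i, ] <- v
  }
  if (orientation == "features_by_samples") t(m) else m
}

#' Read a sample metadata table
#'
#' TSV with header columns \code{sample}, \code{subject} and optionally
#' \code{group}; extra columns are ignored with a notice.
#'
#' @param path TSV file path.
#' @param quiet suppress the extra-column notice.
#' @return data frame with columns \code{sample}, \code{subject} and, when
#'   present, \code{group}.
#' @export
read_metadata <- function(path, quiet = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!all(c("sample", "subject") %in% names(df)))
    stop(sprintf("'%s' must have 'sample' and 'subject' columns", path),
         call. = FALSE)
  if (anyDuplicated(df$sample))
    stop(sprintf("duplicate sample rows in '%s'", path), call. = FALSE)
  keep <- intersect(c("sample", "subject", "group"), names(df))
  extra <- setdiff(names(df), keep)
  if (length(extra) && !quiet)
    message("ignoring metadata column(s): ", paste(extra, collapse = ", "))
  df[keep]
}

write_factor_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(format(df, digits = 15, scientific = NA,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_factor_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a fitted model to text files
#'
#' Writes one TSV per mode (rows = feature ids, columns =
#' \code{factor_1..factor_R}), a weights TSV (component index, lambda,
#' sigma, block shares) for weighted models, and a \code{run_summary.json}
#' with the configuration, seed, iteration count and final error, so a run
#' can be reproduced. Files round-trip through [read_model()].
#'
#' @param model a fitted model.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_model <- function(model, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  weighted <- inherits(model, "cmtf_weighted_fit")
  mats <- list(samples = model$a, microbes = model$b, pathways = model$c,
               metabolites = if (weighted) model$v else model$d)
  files <- character(0)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (is.null(rownames(m)))
      rownames(m) <- paste0(sub("s$", "", nm), "_", seq_len(nrow(m)))
    if (is.null(colnames(m)))
      colnames(m) <- paste0("factor_", seq_len(ncol(m)))
    f <- file.path(outdir, paste0("factors_", nm, ".tsv"))
    write_factor_tsv(m, f)
    files <- c(files, f)
  }
  if (weighted) {
    shares <- block_weight_shares(model)
    wdf <- data.frame(factor = seq_len(model$R), lambda = model$lambda,
                      sigma = model$sigma,
                      tensor_share = shares[, "tensor"],
                      matrix_share = shares[, "matrix"], row.names = NULL)
    f <- file.path(outdir, "weights.tsv")
    utils::write.table(format(wdf, digits = 15, trim = TRUE), f,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  summary <- list(
    framework = if (weighted) "advanced" else "basic",
    R = model$R, n_iter = model$n_iter, converged = model$converged,
    final_rmse = if (length(model$rmse_trace))
      utils::tail(model$rmse_trace, 1) else NULL,
    objective = model$objective, config = model$config)
  f <- file.path(outdir, "run_summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(files, f))
}

#' Read back a model written by [write_model()]
#'
#' @param outdir directory written by [write_model()].
#' @return a \code{cmtf_fit} or \code{cmtf_weighted_fit} carrying the factor
#'   matrices and (for weighted models) the weight vectors.
#' @export
read_model <- function(outdir) {
  a <- read_factor_tsv(file.path(outdir, "factors_samples.tsv"))
  b <- read_factor_tsv(file.path(outdir, "factors_microbes.tsv"))
  c <- read_factor_tsv(file.path(outdir, "factors_pathways.tsv"))
  dm <- read_factor_tsv(file.path(outdir, "factors_metabolites.tsv"))
  wfile <- file.path(outdir, "weights.tsv")
  if (file.exists(wfile)) {
    w <- utils::read.delim(wfile)
    model <- new_weighted_model(a, b, c, dm, lambda = w$lambda,
                                sigma = w$sigma)
  } else {
    model <- structure(list(a = a, b = b, c = c, d = dm, R = ncol(a),
                            rmse_trace = numeric(0), converged = NA,
                            n_iter = NA_integer_),
                       class = "cmtf_fit")
  }
  model
}

#' Write a cross-validation table as TSV
#'
#' @param cv a \code{cmtf_cv} table from [cross_validate()].
#' @param path output file.
#' @export
write_cv_table <- function(cv, path) {
  out <- data.frame(R = cv$R, train_error = cv$train_error,
                    test_error = cv$test_error,
                    seed = attr(cv, "seed"), fraction = attr(cv, "fraction"))
  utils::write.table(format(out, digits = 10, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score plot of samples on two latent factors
#'
#' @param scores samples x 2 matrix (e.g. [project_top2()]) or a fitted
#'   model (projected automatically).
#' @param groups optional group labels used for coloring.
#' @param ... passed to [graphics::plot()].
#' @export
plot_scores <- function(scores, groups = NULL, ...) {
  if (inherits(scores, "cmtf_fit")) scores <- project_top2(scores)
  col <- if (is.null(groups)) 1 else as.integer(factor(groups)) + 1
  graphics::plot(scores[, 1], scores[, 2], col = col, pch = 19,
                 xlab = "latent factor 1", ylab = "latent factor 2", ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_len(nlevels(factor(groups))) + 1, pch = 19)
  invisible(NULL)
}

#' Horizontal bar plot of a biomarker ranking
#'
#' @param ranking a \code{biomarker_ranking} from [top_loadings()].
#' @param ... passed to [graphics::barplot()].
#' @export
plot_loadings <- function(ranking, ...) {
  graphics::barplot(rev(ranking$loading), names.arg = rev(ranking$feature),
                    horiz = TRUE, las = 1,
                    xlab = sprintf("loading (factor %d, %s)",
                                   attr(ranking, "factor"),
                                   attr(ranking, "mode")), ...)
  invisible(NULL)
}
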