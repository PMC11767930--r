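#' Construct a coupled tensor/matrix dataset
#'
#' Bundles the three-way abundance tensor (sample x microbe x pathway) and
#' the metabolite intensity matrix (sample x metabolite) that share the
#' sample mode, together with axis labels and optional per-sample group
#' labels.
#'
#' @param tensor 3-way numeric array, sample x microbe x pathway.
#' @param matrix numeric matrix, sample x metabolite.
#' @param sample_ids,microbe_ids,pathway_ids,metabolite_ids optional label
#'   vectors; defaults are generated. Must be duplicate-free and match the
#'   corresponding axis lengths.
#' @param groups optional per-sample category labels (character or factor)
#'   of length \code{nrow(matrix)}.
#' @return an object of class \code{coupled_dataset}.
#' @export
coupled_dataset <- function(tensor, matrix, sample_ids = NULL,
                            microbe_ids = NULL, pathway_ids = NULL,
                            metabolite_ids = NULL, groups = NULL) {
  check_tensor3(tensor)
  matrix <- as.matrix(matrix)
  if (!all(is.finite(matrix)))
    stop("'matrix' contains non-finite entries", call. = FALSE)
  d <- dim(tensor)
  if (nrow(matrix) != d[1])
    stop("tensor and matrix must share the sample mode (first dimension)",
         call. = FALSE)
  mk_ids <- function(ids, n, prefix, what) {
    if (is.null(ids)) ids <- paste0(prefix, seq_len(n))
    ids <- as.character(ids)
    if (length(ids) != n)
      stop(sprintf("%s labels have length %d, expected %d",
                   what, length(ids), n), call. = FALSE)
    if (anyDuplicated(ids))
      stop(sprintf("duplicate %s labels", what), call. = FALSE)
    ids
  }
  sample_ids     <- mk_ids(sample_ids, d[1], "sample_", "sample")
  microbe_ids    <- mk_ids(microbe_ids, d[2], "microbe_", "microbe")
  pathway_ids    <- mk_ids(pathway_ids, d[3], "pathway_", "pathway")
  metabolite_ids <- mk_ids(metabolite_ids, ncol(matrix), "metabolite_",
                           "metabolite")
  if (!is.null(groups)) {
    if (length(groups) != d[1])
      stop("'groups' must have one label per sample", call. = FALSE)
    groups <- as.character(groups)
  }
  dimnames(tensor) <- list(sample_ids, microbe_ids, pathway_ids)
  dimnames(matrix) <- list(sample_ids, metabolite_ids)
  structure(
    list(tensor = tensor, matrix = matrix,
         sample_ids = sample_ids, microbe_ids = microbe_ids,
         pathway_ids = pathway_ids, metabolite_ids = metabolite_ids,
         groups = groups),
    class = "coupled_dataset")
}

#' @export
print.coupled_dataset <- function(x, ...) {
  d <- dim(x$tensor)
  cat("Coupled dataset\n")
  cat(sprintf("  tensor: %d samples x %d microbes x %d pathways\n",
              d[1], d[2], d[3]))
  cat(sprintf("  matrix: %d samples x %d metabolites\n",
              nrow(x$matrix), ncol(x$matrix)))
  if (!is.null(x$groups))
    cat("  groups:", paste(names(table(x$groups)), table(x$groups),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.coupled_dataset <- function(x) {
  c(dim(x$tensor), ncol(x$matrix))
}
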