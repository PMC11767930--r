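# Preprocessing of stratified functional profiles and metabolite tables
# before they are assembled into the coupled tensor/matrix pair.

check_profile <- function(profile) {
  need <- c("pathway", "taxon", "sample", "abundance")
  if (!is.data.frame(profile) || !all(need %in% names(profile)))
    stop("a stratified profile needs columns pathway, taxon, sample, abundance",
         call. = FALSE)
  if (any(!is.finite(profile$abundance)))
    stop("abundances must be finite", call. = FALSE)
  if (any(profile$abundance < 0))
    stop("abundances must be non-negative", call. = FALSE)
  key <- paste(profile$pathway, profile$taxon, profile$sample, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (pathway, taxon, sample) records", call. = FALSE)
  invisible(profile)
}

#' Logstack scaling of a stratified functional profile
#'
#' For each (pathway, sample) cell, the total community abundance
#' \eqn{Y = \sum_t y_t} over the contributing taxa is log-transformed and the
#' taxon contributions are scaled linearly within that log total:
#' \deqn{y'_t = (y_t / Y) \cdot \log_{base}(1 + Y).}
#' Cells with zero total stay zero. Within-cell proportions are preserved and
#' the per-cell contributions sum to the log-transformed total.
#'
#' @param profile data frame with columns \code{pathway}, \code{taxon},
#'   \code{sample}, \code{abundance} (non-negative).
#' @param base logarithm base, default 10.
#' @return the profile with \code{abundance} replaced by its scaled value.
#' @export
logstack_scale <- function(profile, base = 10) {
  check_profile(profile)
  if (nrow(profile) == 0) return(profile)
  cell <- interaction(profile$pathway, profile$sample, drop = TRUE)
  total <- ave(profile$abundance, cell, FUN = sum)
  scaled <- ifelse(total > 0,
                   profile$abundance / total * log(1 + total, base = base),
                   0)
  profile$abundance <- scaled
  profile
}

#' Centered log-ratio transformation of a sample-by-feature matrix
#'
#' Applies, per sample (row), \eqn{x \to \log(x + pseudo) - mean(\log(x +
#' pseudo))}. Each output row sums to zero, mapping compositional intensities
#' to unconstrained coordinates.
#'
#' @param m numeric matrix, samples in rows; entries must be non-negative.
#' @param pseudo positive offset added before the log. Default: half the
#'   smallest non-zero entry of \code{m} when zeros are present, else 0.
#' @return matrix of the same shape with zero row means.
#' @export
clr_transform <- function(m, pseudo = NULL) {
  m <- as.matrix(m)
  if (any(!is.finite(m)))
    stop("intensities must be finite", call. = FALSE)
  if (any(m < 0))
    stop("intensities must be non-negative", call. = FALSE)
  if (is.null(pseudo)) {
    pseudo <- if (any(m == 0)) {
      pos <- m[m > 0]
      if (length(pos) == 0)
        stop("matrix is all zero; supply a positive 'pseudo'", call. = FALSE)
      min(pos) / 2
    } else 0
  }
  if (pseudo <= 0 && any(m == 0))
    stop("'pseudo' must be positive when zeros are present", call. = FALSE)
  lx <- log(m + pseudo)
  sweep(lx, 1, rowMeans(lx))
}

#' Average samples belonging to the same subject
#'
#' Replaces each subject's samples by their arithmetic mean, blockwise, with
#' subjects in sorted order. Used to align blocks profiled with unequal
#' per-subject sample counts before coupling on the shared mode.
#'
#' @param x a \code{coupled_dataset}, or a numeric matrix with samples in
#'   rows (row names = sample ids).
#' @param mapping named character vector: names are sample ids, values are
#'   subject ids. Every sample in \code{x} must appear.
#' @return object of the same type at the subject level.
#' @export
collapse_to_subjects <- function(x, mapping) UseMethod("collapse_to_subjects")

subject_of <- function(samples, mapping) {
  if (is.null(names(mapping)))
    stop("'mapping' must be a named vector (sample -> subject)", call. = FALSE)
  missing <- setdiff(samples, names(mapping))
  if (length(missing))
    stop("samples not present in the subject mapping: ",
         paste(missing, collapse = ", "), call. = FALSE)
  as.character(mapping[samples])
}

rows_to_subject_means <- function(m, subj) {
  subjects <- sort(unique(subj))
  out <- matrix(0, length(subjects), ncol(m),
                dimnames = list(subjects, colnames(m)))
  for (s in subjects)
    out[s, ] <- colMeans(m[subj == s, , drop = FALSE])
  out
}

#' @export
collapse_to_subjects.matrix <- function(x, mapping) {
  samples <- rownames(x)
  if (is.null(samples))
    stop("matrix must carry sample ids as row names", call. = FALSE)
  rows_to_subject_means(x, subject_of(samples, mapping))
}

#' @export
collapse_to_subjects.coupled_dataset <- function(x, mapping) {
  subj <- subject_of(x$sample_ids, mapping)
  subjects <- sort(unique(subj))
  d <- dim(x$tensor)
  t1 <- rows_to_subject_means(matricize(x$tensor, 1), subj)
  tensor <- fold(t1, 1, c(length(subjects), d[2], d[3]))
  mat <- rows_to_subject_means(x$matrix, subj)
  groups <- NULL
  if (!is.null(x$groups)) {
    groups <- vapply(subjects, function(s) {
      g <- unique(x$groups[subj == s])
      if (length(g) > 1)
        stop(sprintf("subject '%s' has conflicting group labels", s),
             call. = FALSE)
      g
    }, character(1))
  }
  coupled_dataset(tensor, mat, sample_ids = subjects,
                  microbe_ids = x$microbe_ids, pathway_ids = x$pathway_ids,
                  metabolite_ids = x$metabolite_ids, groups = groups)
}

#' Assemble a coupled dataset from a stratified profile and metabolite table
#'
#' Stacks the long-format stratified profile into the sample x microbe x
#' pathway tensor (absent triples become 0), joins it with the metabolite
#' matrix on the shared sample mode (inner join: ids present in both blocks,
#' sorted), and attaches group labels from the metadata. When the metadata
#' carries a subject column, both blocks are first averaged to the subject
#' level and the join is performed on subject ids.
#'
#' @param profile data frame with columns \code{pathway}, \code{taxon},
#'   \code{sample}, \code{abundance}.
#' @param metab numeric matrix samples x metabolites with sample row names
#'   and metabolite column names.
#' @param metadata optional data frame with columns \code{sample},
#'   optionally \code{subject} and \code{group}.
#' @param quiet suppress messages about dropped samples.
#' @return a \code{coupled_dataset}.
#' @export
assemble_coupled <- function(profile, metab, metadata = NULL, quiet = FALSE) {
  check_profile(profile)
  metab <- as.matrix(metab)
  if (is.null(rownames(metab)))
    stop("'metab' must carry sample ids as row names", call. = FALSE)
  if (anyDuplicated(colnames(metab)))
    stop("duplicate metabolite ids", call. = FALSE)
  if (anyDuplicated(rownames(metab)))
    stop("duplicate sample ids in the metabolite table", call. = FALSE)

  microbes <- sort(unique(profile$taxon))
  pathways <- sort(unique(profile$pathway))
  p_samples <- sort(unique(profile$sample))
  tensor <- array(0, dim = c(length(p_samples), length(microbes),
                             length(pathways)),
                  dimnames = list(p_samples, microbes, pathways))
  idx <- cbind(match(profile$sample, p_samples),
               match(profile$taxon, microbes),
               match(profile$pathway, pathways))
  tensor[idx] <- profile$abundance

  groups_map <- NULL
  if (!is.null(metadata)) {
    if (!"sample" %in% names(metadata))
      stop("metadata must have a 'sample' column", call. = FALSE)
    if ("subject" %in% names(metadata)) {
      mapping <- stats::setNames(as.character(metadata$subject),
                                 as.character(metadata$sample))
      keep_t <- p_samples %in% names(mapping)
      keep_m <- rownames(metab) %in% names(mapping)
      if (!quiet && (any(!keep_t) || any(!keep_m)))
        message("dropping ", sum(!keep_t) + sum(!keep_m),
                " sample(s) absent from the metadata")
      t1 <- rows_to_subject_means(
        matricize(tensor, 1)[keep_t, , drop = FALSE],
        subject_of(p_samples[keep_t], mapping))
      tensor <- fold(t1, 1, c(nrow(t1), length(microbes), length(pathways)))
      rownames(tensor) <- rownames(t1)
      metab <- collapse_to_subjects(metab[keep_m, , drop = FALSE], mapping)
      if ("group" %in% names(metadata)) {
        agg <- unique(data.frame(id = as.character(metadata$subject),
                                 group = as.character(metadata$group)))
        if (anyDuplicated(agg$id))
          stop("conflicting group labels within a subject", call. = FALSE)
        groups_map <- stats::setNames(agg$group, agg$id)
      }
    } else if ("group" %in% names(metadata)) {
      groups_map <- stats::setNames(as.character(metadata$group),
                                    as.character(metadata$sample))
    }
  }

  shared <- sort(intersect(rownames(tensor), rownames(metab)))
  if (length(shared) == 0)
    stop("the two blocks share no sample/subject ids", call. = FALSE)
  dropped <- setdiff(union(rownames(tensor), rownames(metab)), shared)
  if (length(dropped) && !quiet)
    message("dropping ids present in only one block: ",
            paste(dropped, collapse = ", "))
  tensor <- tensor[shared, , , drop = FALSE]
  metab <- metab[shared, , drop = FALSE]
  groups <- if (!is.null(groups_map)) unname(groups_map[shared]) else NULL
  coupled_dataset(tensor, metab, sample_ids = shared,
                  microbe_ids = microbes, pathway_ids = pathways,
                  metabolite_ids = colnames(metab), groups = groups)
}
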