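# Core containers: fingerprint matrices and activity tables.
#
# A fingerprint matrix is an N x M numeric matrix of non-negative feature
# counts with unique molecule ids as rownames (ECFC-style count fingerprints,
# typically folded to M = 1024 positions). An activity table maps a subset of
# those ids to activity-class labels; unlabeled molecules form the inactive
# background.

#' Construct a validated fingerprint matrix
#'
#' @param counts numeric matrix, one row per molecule, one column per folded
#'   fingerprint feature; all entries must be finite and non-negative. Bit
#'   fingerprints are accepted as counts in \{0, 1\}.
#' @param ids character vector of unique molecule identifiers; defaults to
#'   `rownames(counts)`.
#' @return an object of class `fingerprint_matrix` (a numeric matrix with
#'   molecule ids as rownames).
#' @details Every molecule must have at least one nonzero feature: a zero
#'   vector has no defined similarity under the association coefficients
#'   (all denominators vanish).
#' @export
fingerprint_matrix <- function(counts, ids = rownames(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(ids)) stop("molecule ids are required (rownames or `ids`)")
  ids <- as.character(ids)
  if (length(ids) != nrow(counts))
    stop("length(ids) must equal nrow(counts)")
  if (anyDuplicated(ids))
    stop("duplicate molecule id: ", ids[duplicated(ids)][1L])
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("negative or non-finite count at row %d (id '%s'), column %d",
                 bad[1L, 1L], ids[bad[1L, 1L]], bad[1L, 2L]))
  if (ncol(counts) < 1L) stop("fingerprint matrix needs at least one feature")
  zero <- rowSums(counts) == 0
  if (any(zero))
    stop("molecule '", ids[which(zero)[1L]], "' has an all-zero fingerprint")
  rownames(counts) <- ids
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("f%04d", seq_len(ncol(counts)))
  class(counts) <- c("fingerprint_matrix", class(counts))
  counts
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("fingerprint_matrix: %d molecules x %d features\n",
              nrow(x), ncol(x)))
  cat("ids: ", paste(head(rownames(x), 5L), collapse = ", "),
      if (nrow(x) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of molecules / features in a fingerprint matrix
#' @param x a `fingerprint_matrix`
#' @return integer count
#' @export
n_molecules <- function(x) nrow(x)

#' @rdname n_molecules
#' @export
n_features <- function(x) ncol(x)

field_sep <- function(format) switch(match.arg(format, c("csv", "tsv")),
                                     csv = ",", tsv = "\t")

#' Read a fingerprint matrix from CSV/TSV
#'
#' The canonical on-disk layout is a header row `id,f0001,...` followed by one
#' row per molecule: the id in the first column and M integer counts.
#'
#' @param path file path
#' @param format `"csv"` (default) or `"tsv"`
#' @return a validated [fingerprint_matrix()]
#' @export
read_fingerprints <- function(path, format = c("csv", "tsv")) {
  sep <- field_sep(format)
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(nf) < 2L) stop("fingerprint file has no data rows: ", path)
  if (length(unique(nf)) != 1L)
    stop("ragged fingerprint file (rows with differing field counts): ", path)
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("fingerprint file needs an id column plus features")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric feature column in ", path)
  rownames(m) <- ids
  fingerprint_matrix(m)
}

#' Write a fingerprint matrix to CSV/TSV
#' @param x a `fingerprint_matrix`
#' @param path output file path
#' @param format `"csv"` or `"tsv"`
#' @return `path`, invisibly
#' @export
write_fingerprints <- function(x, path, format = c("csv", "tsv")) {
  sep <- field_sep(format)
  df <- data.frame(id = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an activity table
#'
#' @param id character vector of molecule ids
#' @param class character vector of activity-class labels, parallel to `id`
#' @return an `activity_table` data frame with columns `id` and `class`
#' @export
activity_table <- function(id, class) {
  id <- as.character(id); class <- as.character(class)
  if (length(id) != length(class)) stop("id and class must be parallel")
  if (length(id) == 0L) stop("empty activity table")
  if (anyDuplicated(id)) stop("duplicate id in activity table: ",
                              id[duplicated(id)][1L])
  out <- data.frame(id = id, class = class, stringsAsFactors = FALSE)
  class(out) <- c("activity_table", "data.frame")
  out
}

#' Read an activity table (TSV, header `id<TAB>class`)
#' @param path file path
#' @return an [activity_table()]
#' @export
read_activity_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty activity file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("activity file has no rows: ", path)
  if (ncol(df) < 2L) stop("activity file needs two columns (id, class)")
  activity_table(df[[1L]], df[[2L]])
}

#' Write an activity table as TSV
#' @param x an `activity_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_activity_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Activity-class labels and sizes
#' @param x an `activity_table`
#' @return named integer vector: members per class, in order of appearance
#' @export
class_sizes <- function(x) {
  tab <- table(factor(x$class, levels = unique(x$class)))
  out <- as.integer(tab); names(out) <- names(tab)
  out
}

#' Members of one activity class
#' @param x an `activity_table`
#' @param label class label
#' @return character vector of molecule ids
#' @export
class_members <- function(x, label) {
  if (!label %in% x$class) stop("unknown activity class: ", label)
  x$id[x$class == label]
}

#' Cross-validate an activity table against a fingerprint matrix
#'
#' Checks that every labeled id exists in the fingerprint matrix and that
#' each class has at least `min_class_size` members (one reference plus at
#' least one retrievable active).
#'
#' @param x an `activity_table`
#' @param fps a `fingerprint_matrix`
#' @param min_class_size smallest acceptable class (default 2)
#' @param on_small `"error"` or `"warn"` for undersized classes
#' @return `x`, invisibly
#' @export
validate_activities <- function(x, fps, min_class_size = 2L,
                                on_small = c("error", "warn")) {
  on_small <- match.arg(on_small)
  unknown <- setdiff(x$id, rownames(fps))
  if (length(unknown) > 0L)
    stop("activity table references unknown molecule id: ", unknown[1L])
  sizes <- class_sizes(x)
  small <- sizes[sizes < min_class_size]
  if (length(small) > 0L) {
    msg <- paste0("activity class smaller than ", min_class_size, ": ",
                  paste(names(small), collapse = ", "))
    if (on_small == "error") stop(msg) else warning(msg)
  }
  invisible(x)
}
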