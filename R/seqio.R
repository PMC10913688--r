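#' Labelled promoter-window datasets
#'
#' A `m5c_dataset` is a data frame with columns `id`, `bases` and `label`
#' (1 = true 5mC site, 0 = spurious site). Sequences are fixed-alphabet
#' DNA strings; for model input they must all have the window length the
#' model was configured with (41 by default).
#'
#' @param id character vector of record identifiers.
#' @param bases character vector of DNA strings over `{A,C,G,T}` (plus `N`
#'   when `allow_n = TRUE`).
#' @param label integer/numeric vector of binary labels (0 or 1).
#' @param allow_n keep records containing `N`? When `FALSE` (default) any
#'   non-ACGT character is an error; when `TRUE`, `N` is tolerated and is
#'   encoded as an all-zero column by every encoder.
#' @return An object of class `m5c_dataset` (also a `data.frame`).
#' @examples
#' d <- m5c_dataset(c("a", "b"), c("ACGT", "TTTT"), c(1, 0))
#' dataset_summary(d)
#' @export
m5c_dataset <- function(id, bases, label, allow_n = FALSE) {
  id <- as.character(id)
  bases <- toupper(as.character(bases))
  if (length(id) != length(bases) || length(id) != length(label))
    stop("id, bases and label must have equal length")
  if (anyNA(label) || !all(label %in% c(0, 1)))
    stop("labels must be binary (0/1) with no missing values")
  validate_bases(bases, id, allow_n = allow_n)
  out <- data.frame(id = id, bases = bases, label = as.integer(label),
                    stringsAsFactors = FALSE)
  class(out) <- c("m5c_dataset", "data.frame")
  out
}

# alphabet check; names the offending record in the error
validate_bases <- function(bases, id, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, bases)
  if (any(bad)) {
    stop("sequence validation error: record '", id[which(bad)[1]],
         "' contains characters outside ",
         if (allow_n) "{A,C,G,T,N}" else "{A,C,G,T}")
  }
  invisible(TRUE)
}

#' Read a labelled FASTA file
#'
#' Reads a multi-record FASTA of fixed-length DNA windows. Labels come
#' either from a `|label=0` / `|label=1` suffix in each header, or from a
#' separate two-column tab-delimited file (`id<TAB>label`) given as
#' `labels`. Every record must resolve to a label.
#'
#' @param path path to the FASTA file.
#' @param labels optional path to a two-column TSV mapping record ids to
#'   binary labels. When supplied, header label tags are ignored.
#' @param allow_n see [m5c_dataset()].
#' @return A [m5c_dataset()] in file order.
#' @seealso [write_labeled_fasta()]
#' @export
read_labeled_fasta <- function(path, labels = NULL, allow_n = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("FASTA parse error in '", path,
                                            "': ", conditionMessage(e)))
  headers <- names(seqs)
  if (is.null(headers) || anyNA(headers))
    stop("FASTA parse error: records without headers in '", path, "'")
  bases <- as.character(seqs)
  if (!is.null(labels)) {
    ids <- sub("\\s.*$", "", headers)
    tab <- utils::read.table(labels, sep = "\t", header = FALSE,
                             colClasses = c("character", "integer"),
                             col.names = c("id", "label"))
    lab <- tab$label[match(ids, tab$id)]
    if (anyNA(lab))
      stop("labeling error: no label for record '", ids[which(is.na(lab))[1]],
           "' in ", labels)
  } else {
    ids <- sub("\\s*\\|label=[01]\\s*$", "", headers)
    ids <- sub("\\s.*$", "", ids)
    m <- regmatches(headers, regexpr("\\|label=[01]", headers))
    has <- grepl("\\|label=[01]", headers)
    if (!all(has))
      stop("labeling error: record '", ids[which(!has)[1]],
           "' has no |label= tag and no label file was given")
    lab <- as.integer(sub("\\|label=", "", m))
  }
  m5c_dataset(ids, bases, lab, allow_n = allow_n)
}

#' Write a labelled dataset as FASTA (plus optional label TSV)
#'
#' With `labels = NULL` the binary label is embedded in each FASTA header
#' as `id|label=0/1`; otherwise headers are bare ids and labels go to a
#' two-column TSV. A write-then-read round trip reproduces ids, bases and
#' labels exactly.
#'
#' @param data a [m5c_dataset()].
#' @param path output FASTA path.
#' @param labels optional output TSV path for `id<TAB>label` rows.
#' @return `path`, invisibly.
#' @export
write_labeled_fasta <- function(data, path, labels = NULL) {
  stopifnot(inherits(data, "m5c_dataset"))
  headers <- if (is.null(labels)) paste0(data$id, "|label=", data$label)
             else data$id
  x <- Biostrings::BStringSet(stats::setNames(data$bases, headers))
  Biostrings::writeXStringSet(x, filepath = path)
  if (!is.null(labels))
    utils::write.table(data.frame(data$id, data$label), labels, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# round-half-up, used for the per-class test allocation
round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/test split
#'
#' Partitions a labelled dataset into train and test sets so that each
#' class contributes `round(test_fraction * class size)` sequences
#' (round half up) to the test set — the 8:2 stratified scheme when
#' `test_fraction = 0.2`. Deterministic for a given `seed`.
#'
#' @param data a [m5c_dataset()] containing both classes.
#' @param test_fraction proportion of each class assigned to the test set,
#'   strictly between 0 and 1.
#' @param seed integer seed fixing the per-class sampling.
#' @return `list(train = , test = )` of [m5c_dataset()] objects; original
#'   record order is preserved within each part.
#' @examples
#' d <- generate_dataset(synthetic_spec(n_pos = 10, n_neg = 76, seed = 1))
#' sp <- stratified_split(d, 0.2, seed = 1)
#' vapply(sp, nrow, 1L)
#' @export
stratified_split <- function(data, test_fraction = 0.2, seed = 1) {
  stopifnot(inherits(data, "m5c_dataset"))
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must lie strictly between 0 and 1")
  set.seed(as.integer(seed))
  test_idx <- integer(0)
  for (cl in c(1L, 0L)) {
    idx <- which(data$label == cl)
    n_cl <- length(idx)
    n_test <- round_half_up(test_fraction * n_cl)
    if (n_cl == 0 || n_test < 1 || n_cl - n_test < 1)
      stop("split error: class ", cl, " too small (", n_cl,
           " records) to populate both partitions at test_fraction ",
           test_fraction)
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  test_idx <- sort(test_idx)
  subset_ds <- function(i) {
    out <- data[i, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("m5c_dataset", "data.frame")
    out
  }
  list(train = subset_ds(setdiff(seq_len(nrow(data)), test_idx)),
       test = subset_ds(test_idx))
}

#' Class counts and imbalance ratio of a dataset
#'
#' @param data a non-empty [m5c_dataset()].
#' @return `list(n_pos, n_neg, n, ratio)` where `ratio = n_neg / n_pos`
#'   (the negative:positive imbalance; errors when there are no
#'   positives).
#' @examples
#' imbalance_ratio(386773, 2923874) # ~7.6, the benchmark imbalance
#' @export
dataset_summary <- function(data) {
  stopifnot(inherits(data, "m5c_dataset"))
  if (nrow(data) == 0) stop("dataset is empty")
  n_pos <- sum(data$label == 1L)
  n_neg <- sum(data$label == 0L)
  list(n_pos = n_pos, n_neg = n_neg, n = n_pos + n_neg,
       ratio = imbalance_ratio(n_pos, n_neg))
}

#' @rdname dataset_summary
#' @param n_pos,n_neg positive / negative class counts.
#' @export
imbalance_ratio <- function(n_pos, n_neg) {
  if (n_pos <= 0) stop("ratio error: no positive samples (n_pos = 0)")
  n_neg / n_pos
}
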