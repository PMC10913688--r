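## Sequence encoders: one-hot (4 x L), nucleotide chemical property
## (NCP, 3 x L) and their row-wise merge (7 x L).

# columns in base order A, C, G, T
.ONEHOT <- diag(4)
dimnames(.ONEHOT) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))

# NCP per-nucleotide vectors: A (1,1,1), C (0,1,0), G (1,0,0), T (0,0,1)
.NCP <- matrix(c(1, 1, 1,
                 0, 1, 0,
                 1, 0, 0,
                 0, 0, 1), nrow = 3,
               dimnames = list(NULL, c("A", "C", "G", "T")))

.base_index <- function(bases, allow_n = FALSE) {
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  idx <- match(ch, c("A", "C", "G", "T"))
  if (anyNA(idx)) {
    if (!allow_n || any(ch[is.na(idx)] != "N"))
      stop("encoding error: sequence contains characters outside {A,C,G,T}",
           if (allow_n) " or N" else "")
  }
  idx
}

.encode_with <- function(map, bases, allow_n, scheme) {
  idx <- .base_index(bases, allow_n)
  map0 <- cbind(map, N = 0)          # all-zero column for N
  idx[is.na(idx)] <- 5L
  m <- map0[, idx, drop = FALSE]
  dimnames(m) <- NULL
  attr(m, "scheme") <- scheme
  m
}

#' One-hot encoding of a DNA window
#'
#' Each nucleotide becomes a 4-dimensional standard basis vector in the
#' order A, C, G, T: A is (1,0,0,0), C is (0,1,0,0), G is (0,0,1,0) and
#' T is (0,0,0,1). A 41-nt window yields a 4 x 41 matrix.
#'
#' @param bases a single DNA string (or a `m5c_dataset` row's `bases`).
#' @param allow_n encode `N` as an all-zero column instead of erroring.
#' @return numeric matrix with 4 rows and one column per position, with
#'   attribute `scheme = "onehot"`.
#' @examples
#' encode_onehot("ACGT") # 4 x 4 identity
#' @export
encode_onehot <- function(bases, allow_n = FALSE)
  .encode_with(.ONEHOT, toupper(bases), allow_n, "onehot")

#' Nucleotide-chemical-property (NCP) encoding
#'
#' Each nucleotide becomes a 3-dimensional binary vector reflecting ring
#' structure, functional group and hydrogen bonding: A (1,1,1), C (0,1,0),
#' G (1,0,0), T (0,0,1). A 41-nt window yields a 3 x 41 matrix.
#'
#' @inheritParams encode_onehot
#' @return numeric matrix with 3 rows, attribute `scheme = "ncp"`.
#' @export
encode_ncp <- function(bases, allow_n = FALSE)
  .encode_with(.NCP, toupper(bases), allow_n, "ncp")

#' Merge one-hot and NCP encodings into a 7-row feature matrix
#'
#' Stacks the 4-row one-hot matrix on top of the 3-row NCP matrix; for a
#' 41-nt window this is the 7 x 41 matrix the model consumes.
#'
#' @param a one-hot feature matrix (`scheme = "onehot"`).
#' @param b NCP feature matrix (`scheme = "ncp"`) of the same length.
#' @return numeric matrix with 7 rows, attribute `scheme = "merged"`;
#'   rows 1-4 equal `a`, rows 5-7 equal `b`.
#' @export
merge_encodings <- function(a, b) {
  if (!identical(attr(a, "scheme"), "onehot") ||
      !identical(attr(b, "scheme"), "ncp"))
    stop("merge error: expected a one-hot matrix and an NCP matrix")
  if (ncol(a) != ncol(b))
    stop("merge error: length mismatch (", ncol(a), " vs ", ncol(b), ")")
  m <- rbind(a, b)
  attr(m, "scheme") <- "merged"
  m
}

#' @rdname merge_encodings
#' @inheritParams encode_onehot
#' @export
encode_merged <- function(bases, allow_n = FALSE)
  merge_encodings(encode_onehot(bases, allow_n), encode_ncp(bases, allow_n))

#' Decode a one-hot (or merged) matrix back to its base string
#'
#' Takes the argmax over the 4 one-hot rows at each position. Encoding then
#' decoding any ACGT sequence is the identity.
#'
#' @param m a feature matrix from [encode_onehot()] or [encode_merged()].
#' @return a single DNA string.
#' @export
decode_onehot <- function(m) {
  top <- m[1:4, , drop = FALSE]
  paste(c("A", "C", "G", "T")[max.col(t(top), ties.method = "first")],
        collapse = "")
}

#' Encode every sequence of a dataset
#'
#' @param data a [m5c_dataset()] whose sequences all share one length.
#' @param scheme one of `"merged"` (7 rows, default), `"onehot"` (4) or
#'   `"ncp"` (3).
#' @param allow_n see [encode_onehot()].
#' @return numeric array of shape `rows x length x n`, with sequence ids as
#'   the third dimnames.
#' @export
encode_dataset <- function(data, scheme = c("merged", "onehot", "ncp"),
                           allow_n = FALSE) {
  stopifnot(inherits(data, "m5c_dataset"))
  scheme <- match.arg(scheme)
  lens <- nchar(data$bases)
  if (length(unique(lens)) != 1L)
    stop("encoding error: sequences have differing lengths")
  f <- switch(scheme, merged = encode_merged, onehot = encode_onehot,
              ncp = encode_ncp)
  L <- lens[1]
  rows <- switch(scheme, merged = 7L, onehot = 4L, ncp = 3L)
  out <- array(0, dim = c(rows, L, nrow(data)),
               dimnames = list(NULL, NULL, data$id))
  for (i in seq_len(nrow(data))) out[, , i] <- f(data$bases[i], allow_n)
  out
}
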