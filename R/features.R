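DNA_BASES <- c("A", "C", "G", "T")

# row-major over first base: AA AC AG AT CA ... TT
DINUCS <- paste0(rep(DNA_BASES, each = 4L), rep(DNA_BASES, 4L))

new_feature_matrix <- function(values, encoding, sequence_length = NA_integer_) {
  structure(values,
            encoding = encoding,
            sequence_length = sequence_length,
            class = c("promo_features", "matrix", "array"))
}

#' One-hot encode DNA sequences
#'
#' Each position becomes an indicator 4-block in the fixed column order
#' A, C, G, T; blocks are concatenated left to right (row-major over
#' positions), so an L-bp sequence maps to a length-4L row.
#'
#' @param sequences Character vector of equal-length ACGT sequences.
#' @return An `n x 4L` feature matrix with attributes `encoding = "onehot"`
#'   and `sequence_length = L`.
#' @export
#' @examples
#' one_hot_encode("ACGT")
one_hot_encode <- function(sequences) {
  lens <- unique(nchar(sequences))
  if (length(lens) != 1L) stop("sequences must share one length", call. = FALSE)
  L <- lens
  chars <- strsplit(sequences, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  idx <- match(flat, DNA_BASES)
  if (anyNA(idx)) {
    stop("invalid character(s) in sequence: ",
         paste(unique(flat[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  n <- length(sequences)
  out <- matrix(0, n, 4L * L)
  # column of the 1 for sample i, position p: 4*(p-1) + base
  pos <- rep(seq_len(L), times = n)
  row <- rep(seq_len(n), each = L)
  out[cbind(row, 4L * (pos - 1L) + idx)] <- 1
  colnames(out) <- paste0("p", rep(seq_len(L), each = 4L), "_",
                          rep(DNA_BASES, L))
  new_feature_matrix(out, "onehot", L)
}

#' Decode one-hot (or relaxed) matrices back to sequences
#'
#' Per-position argmax over the A, C, G, T columns; ties resolve to the
#' alphabetically first base. Accepts one `L x 4` matrix or an `n x 4L`
#' flattened batch.
#'
#' @param m Numeric matrix: `L x 4`, or `n x 4L` with `L` given.
#' @param L Sequence length for flattened input (inferred when `m` has a
#'   `sequence_length` attribute or 4 columns).
#' @return Character vector of decoded sequences.
#' @export
one_hot_decode <- function(m, L = NULL) {
  m <- unclass(m)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  if (ncol(m) == 4L) {
    # single sequence, positions as rows
    idx <- apply(m, 1L, which.max)
    return(paste(DNA_BASES[idx], collapse = ""))
  }
  L <- L %||% attr(m, "sequence_length")
  if (is.null(L) || is.na(L)) {
    if (ncol(m) %% 4L != 0L) stop("need 4 columns per position", call. = FALSE)
    L <- ncol(m) %/% 4L
  }
  if (ncol(m) != 4L * L) stop("shape error: expected ", 4L * L, " columns",
                              call. = FALSE)
  vapply(seq_len(nrow(m)), function(i) {
    mm <- matrix(m[i, ], ncol = 4L, byrow = TRUE)
    paste(DNA_BASES[apply(mm, 1L, which.max)], collapse = "")
  }, character(1))
}

#' Pseudo-dinucleotide composition parameters
#'
#' Bundles the correlation tier count `lambda`, the weight `w`, and a
#' standardized 16-row dinucleotide physical property table. The packaged
#' default table holds six average B-DNA base-pair step parameters (twist,
#' tilt, roll, shift, slide, rise); each column is standardized to mean 0,
#' sd 1 across the 16 dinucleotides. Any table with rownames AA..TT can be
#' substituted.
#'
#' @param lam Number of correlation tiers (lambda >= 0); default 3.
#' @param w Weight on the correlation block (> 0); default 0.05.
#' @param property_table 16 x P numeric matrix/data frame with dinucleotide
#'   rownames; default loads the packaged table.
#' @return An object of class `psednc_params`.
#' @export
psednc_params <- function(lam = 3L, w = 0.05, property_table = NULL) {
  if (is.null(property_table)) {
    path <- system.file("extdata", "dinucleotide_properties.csv",
                        package = "promoforge", mustWork = TRUE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    property_table <- as.matrix(df[, -1L, drop = FALSE])
    rownames(property_table) <- df[[1L]]
  }
  property_table <- as.matrix(property_table)
  if (nrow(property_table) != 16L ||
      !setequal(rownames(property_table), DINUCS)) {
    stop("property_table must have the 16 dinucleotides as rownames",
         call. = FALSE)
  }
  property_table <- property_table[DINUCS, , drop = FALSE]
  # population-sd standardization per column, the usual pseDNC convention
  property_table <- apply(property_table, 2L, function(v) {
    (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  })
  rownames(property_table) <- DINUCS
  stopifnot(lam >= 0, w > 0)
  structure(list(lam = as.integer(lam), w = w,
                 property_table = property_table),
            class = "psednc_params")
}

#' Pseudo-dinucleotide composition (pseDNC) features
#'
#' Encodes each sequence as a length `16 + lambda` vector: the first 16
#' components are weighted dinucleotide frequencies
#' `d_u = f_u / (1 + w * sum(theta))`, the last `lambda` are the sequence-
#' order terms `d_(16+j) = w * theta_j / (1 + w * sum(theta))`, where
#' `theta_j` is the mean correlation `Theta` between dinucleotides `j`
#' positions apart and `Theta` is the mean squared property difference over
#' the standardized property columns. Components sum to 1.
#'
#' @param sequences Character vector of ACGT sequences with length
#'   `>= lam + 2`.
#' @param params A [psednc_params()] object.
#' @return An `n x (16 + lam)` feature matrix (`encoding = "psednc"`).
#' @export
psednc <- function(sequences, params = psednc_params()) {
  lam <- params$lam
  w <- params$w
  pt <- params$property_table
  if (any(nchar(sequences) < lam + 2L)) {
    stop("sequence shorter than lam + 2 = ", lam + 2L, call. = FALSE)
  }
  out <- matrix(0, length(sequences), 16L + lam)
  for (i in seq_along(sequences)) {
    s <- sequences[i]
    L <- nchar(s)
    di <- paste0(substring(s, 1:(L - 1L), 1:(L - 1L)),
                 substring(s, 2:L, 2:L))
    idx <- match(di, DINUCS)
    if (anyNA(idx)) stop("invalid character in sequence ", i, call. = FALSE)
    f <- tabulate(idx, 16L) / (L - 1L)
    theta <- numeric(0)
    if (lam > 0L) {
      theta <- vapply(seq_len(lam), function(j) {
        ii <- idx[1:(L - 1L - j)]
        jj <- idx[(1L + j):(L - 1L)]
        mean(rowMeans((pt[ii, , drop = FALSE] - pt[jj, , drop = FALSE])^2))
      }, numeric(1))
    }
    denom <- 1 + w * sum(theta)
    out[i, ] <- c(f / denom, if (lam > 0L) w * theta / denom)
  }
  colnames(out) <- c(DINUCS, if (lam > 0L) paste0("theta", seq_len(lam)))
  new_feature_matrix(out, "psednc",
                     if (length(unique(nchar(sequences))) == 1L)
                       nchar(sequences[1L]) else NA_integer_)
}

#' Concatenate two feature matrices column-wise
#'
#' @param a,b Feature matrices with equal row counts.
#' @return A feature matrix with `encoding = "concat"`.
#' @export
concat_features <- function(a, b) {
  if (nrow(a) != nrow(b)) {
    stop("shape error: ", nrow(a), " vs ", nrow(b), " samples", call. = FALSE)
  }
  new_feature_matrix(cbind(unclass(a), unclass(b)), "concat",
                     attr(a, "sequence_length") %||% NA_integer_)
}

#' Encode sequences for a model
#'
#' Dispatches on the encoding name used at training time.
#'
#' @param sequences Character vector of DNA sequences.
#' @param encoding One of `"onehot"`, `"psednc"`, `"concat"`.
#' @param params [psednc_params()] for the pseDNC block.
#' @return A feature matrix.
#' @export
encode_sequences <- function(sequences, encoding = "onehot",
                             params = psednc_params()) {
  switch(encoding,
    onehot = one_hot_encode(sequences),
    psednc = psednc(sequences, params),
    concat = concat_features(one_hot_encode(sequences),
                             psednc(sequences, params)),
    stop("unknown encoding: ", encoding, call. = FALSE)
  )
}
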