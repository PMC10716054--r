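#' Position frequency matrix of an aligned fixed-length dataset
#'
#' @param x A [promoter_dataset()] (or character vector) of equal-length
#'   sequences.
#' @return An `L x 4` integer count matrix (columns A, C, G, T) of class
#'   `pfm` with attribute `n_sequences`.
#' @export
build_pfm <- function(x) {
  seqs <- if (is.data.frame(x)) x$sequence else as.character(x)
  if (length(seqs) == 0L) stop("empty dataset", call. = FALSE)
  lens <- unique(nchar(seqs))
  if (length(lens) != 1L) stop("sequences must share one length", call. = FALSE)
  L <- lens
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = L,
                  byrow = TRUE)
  counts <- vapply(DNA_BASES, function(b) colSums(chars == b), numeric(L))
  counts <- matrix(as.integer(counts), nrow = L,
                   dimnames = list(NULL, DNA_BASES))
  structure(counts, n_sequences = length(seqs), class = c("pfm", "matrix", "array"))
}

#' Information content (sequence logo heights)
#'
#' Per position, the information content is `R = 2 - H` bits, where `H` is
#' the Shannon entropy of the base frequencies; with the small-sample
#' correction enabled, `e_n = 3 / (2 * ln(2) * n)` is also subtracted and
#' the result floored at 0. Per-base bar heights are `frequency * R`.
#'
#' @param pfm A [build_pfm()] result.
#' @param small_sample_correction Apply the Schneider correction
#'   (default `FALSE`).
#' @return An `L x 4` matrix of bits, class `logo_matrix`.
#' @export
information_content <- function(pfm, small_sample_correction = FALSE) {
  n <- attr(pfm, "n_sequences")
  freq <- unclass(pfm) / n
  H <- apply(freq, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  R <- 2 - H
  if (small_sample_correction) R <- R - 3 / (2 * log(2) * n)
  R <- pmax(R, 0)
  structure(freq * R, class = c("logo_matrix", "matrix", "array"))
}

#' Consensus sequence of a PFM
#'
#' Per-position argmax base; ties resolve alphabetically (A < C < G < T).
#'
#' @param pfm A [build_pfm()] result.
#' @return A single consensus DNA string.
#' @export
consensus <- function(pfm) {
  m <- unclass(pfm)
  if (nrow(m) == 0L) stop("empty pfm", call. = FALSE)
  paste(DNA_BASES[apply(m, 1L, which.max)], collapse = "")
}

#' Export a PFM or logo matrix to CSV
#'
#' @param m A `pfm` or `logo_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logo_csv <- function(m, path) {
  df <- as.data.frame(unclass(m))
  df <- cbind(position = seq_len(nrow(df)), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot a sequence logo as stacked information bars
#'
#' Renders per-position, per-base information contributions as stacked bars
#' (a bar-style logo). Requires ggplot2.
#'
#' @param logo A [information_content()] result.
#' @return A ggplot object.
#' @export
plot_logo <- function(logo) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  m <- unclass(logo)
  df <- data.frame(
    position = rep(seq_len(nrow(m)), times = 4L),
    base = factor(rep(DNA_BASES, each = nrow(m)), levels = DNA_BASES),
    bits = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$bits,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                          G = "#F7B32B", T = "#D62839")) +
    ggplot2::labs(y = "information (bits)", x = "position") +
    ggplot2::theme_minimal()
}
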