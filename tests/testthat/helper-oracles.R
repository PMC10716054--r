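# Shared helpers: random sequence factories, stub scorers, and
# independent oracle implementations used to cross-check the package.

rand_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}

planted_motif_corpus <- function(n, motif = "TATAAT", offset = 39L,
                                 len = 50L, seed = 1L) {
  set.seed(seed)
  left <- rand_dna(n, offset - 1L)
  right <- rand_dna(n, len - offset + 1L - nchar(motif))
  promoter_dataset(sprintf("pm%05d", seq_len(n)),
                   paste0(left, motif, right))
}

# Independent pseDNC oracle: direct transcription of the defining
# formulas, sharing no code with the package implementation.
psednc_oracle <- function(s, lam, w, raw_table) {
  bases <- c("A", "C", "G", "T")
  dn <- paste0(rep(bases, each = 4), rep(bases, 4))
  # standardize each property column with the population sd
  pt <- apply(raw_table, 2, function(v) {
    (v - mean(v)) / sqrt(sum((v - mean(v))^2) / length(v))
  })
  rownames(pt) <- rownames(raw_table)
  L <- nchar(s)
  dimers <- substring(s, 1:(L - 1), 2:L)
  f <- vapply(dn, function(d) sum(dimers == d), numeric(1)) / (L - 1)
  Theta <- function(d1, d2) mean((pt[d1, ] - pt[d2, ])^2)
  theta <- numeric(lam)
  if (lam > 0) {
    for (j in seq_len(lam)) {
      m <- L - 1 - j
      theta[j] <- mean(vapply(seq_len(m), function(i) {
        Theta(dimers[i], dimers[i + j])
      }, numeric(1)))
    }
  }
  denom <- 1 + w * sum(theta)
  c(f / denom, if (lam > 0) w * theta / denom)
}

raw_property_table <- function() {
  path <- system.file("extdata", "dinucleotide_properties.csv",
                      package = "promoforge")
  df <- read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

# Brute-force binary metrics from raw label/call pairs (independent of
# binary_metrics): realize a confusion table as vectors and recount.
metrics_from_counts_oracle <- function(tp, tn, fp, fn) {
  truth <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
  call <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
  sn <- if (tp + fn > 0) sum(truth == 1 & call == 1) / sum(truth == 1) else NA
  sp <- if (tn + fp > 0) sum(truth == 0 & call == 0) / sum(truth == 0) else NA
  acc <- mean(truth == call)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) NA else (tp * tn - fp * fn) / sqrt(den)
  list(Sn = sn, Sp = sp, Acc = acc, MCC = mcc)
}

# A stub scorer is any function of a character vector of sequences.
stub_const <- function(value) function(seqs) rep(value, length(seqs))
stub_table <- function(map) function(seqs) unname(map[seqs])
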