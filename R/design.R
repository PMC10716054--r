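#' Constraints for sigma70 promoter generation
#'
#' Layout of every generated sequence (5' to 3'): random upstream pad,
#' the -35 hexamer, a random spacer of length drawn from
#' `spacer_lengths`, the -10 hexamer, and a fixed-length random
#' downstream pad (the discriminator region before the TSS). With the
#' defaults (50 bp total, 6-nt downstream pad) a 16-bp spacer leaves a
#' 16-nt upstream pad.
#'
#' @param minus35,minus10 Hexamer motifs (defaults TTGACA / TATAAT, the
#'   sigma70 consensus).
#' @param spacer_lengths Integer set of allowed spacer lengths
#'   (default 16:18).
#' @param downstream_length Pad after the -10 motif (default 6).
#' @param total_length Total sequence length (default 50).
#' @return A list of class `design_constraints`.
#' @export
design_constraints <- function(minus35 = "TTGACA", minus10 = "TATAAT",
                               spacer_lengths = 16:18,
                               downstream_length = 6L,
                               total_length = 50L) {
  minus35 <- toupper(minus35); minus10 <- toupper(minus10)
  if (grepl("[^ACGT]", minus35) || grepl("[^ACGT]", minus10)) {
    stop("motifs must be ACGT strings", call. = FALSE)
  }
  for (s in spacer_lengths) {
    up <- total_length - nchar(minus35) - s - nchar(minus10) -
      downstream_length
    if (up < 0L) stop("infeasible layout for spacer ", s, call. = FALSE)
  }
  structure(list(minus35 = minus35, minus10 = minus10,
                 spacer_lengths = as.integer(spacer_lengths),
                 downstream_length = as.integer(downstream_length),
                 total_length = as.integer(total_length)),
            class = "design_constraints")
}

#' Generate random promoters under sigma70 motif constraints
#'
#' Each sequence fixes the -35 and -10 hexamers, draws the spacer length
#' uniformly from the allowed set, and fills every free position i.i.d.
#' uniformly over A, C, G, T. Deterministic under `seed`.
#'
#' @param constraints A [design_constraints()].
#' @param n Number of sequences.
#' @param seed Integer RNG seed.
#' @return A [promoter_dataset()]; each record's spacer is recorded in
#'   the `spacer` attribute (integer vector).
#' @export
generate_constrained <- function(constraints = design_constraints(), n,
                                 seed = 1L) {
  set.seed(seed)
  cs <- constraints
  sp <- cs$spacer_lengths[sample.int(length(cs$spacer_lengths), n,
                                     replace = TRUE)]
  up_len <- cs$total_length - nchar(cs$minus35) - sp - nchar(cs$minus10) -
    cs$downstream_length
  rand_seg <- function(len) {
    if (len == 0L) return("")
    paste(DNA_BASES[sample.int(4L, len, replace = TRUE)], collapse = "")
  }
  seqs <- vapply(seq_len(n), function(i) {
    paste0(rand_seg(up_len[i]), cs$minus35, rand_seg(sp[i]), cs$minus10,
           rand_seg(cs$downstream_length))
  }, character(1))
  ds <- promoter_dataset(sprintf("nd%07d", seq_len(n)), seqs,
                         sigma_class = "sigma70", source = "ndesign")
  attr(ds, "spacer") <- sp
  ds
}

#' Check sequences against design constraints
#'
#' A sequence passes when it has the declared total length and contains
#' the -35 motif followed, after an allowed spacer length, by the -10
#' motif at the layout position implied by the downstream pad.
#'
#' @param sequences Character vector (or [promoter_dataset()]).
#' @param constraints A [design_constraints()].
#' @return Logical vector.
#' @export
check_constraints <- function(sequences, constraints = design_constraints()) {
  seqs <- if (is.data.frame(sequences)) sequences$sequence
          else as.character(sequences)
  cs <- constraints
  l35 <- nchar(cs$minus35); l10 <- nchar(cs$minus10)
  vapply(seqs, function(s) {
    if (nchar(s) != cs$total_length) return(FALSE)
    for (sp in cs$spacer_lengths) {
      p10 <- cs$total_length - cs$downstream_length - l10 + 1L
      p35 <- p10 - sp - l35
      if (p35 >= 1L &&
          substr(s, p35, p35 + l35 - 1L) == cs$minus35 &&
          substr(s, p10, p10 + l10 - 1L) == cs$minus10) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}

#' DRSAdesign screening cascade
#'
#' Filters candidate sequences to those predicted real
#' (`p_real > real_threshold`), then to those predicted strong
#' (`p_strong > strong_threshold`, default 0.9), ranks the survivors by
#' predicted activity (descending, ties broken lexicographically by
#' sequence) and keeps the top `top_k`.
#'
#' @param candidates Character vector of sequences, a
#'   [promoter_dataset()], or a `generation_batch`.
#' @param promor,promos,promoa Trained models (or scoring functions) for
#'   realness, strength, and activity.
#' @param real_threshold,strong_threshold Score cuts (defaults 0.5 and
#'   0.9).
#' @param top_k Maximum number of candidates returned (default 50).
#' @return Tibble with `sequence`, `p_real`, `p_strong`,
#'   `predicted_activity`, ranked best-first.
#' @export
drsa_screen <- function(candidates, promor, promos, promoa,
                        real_threshold = 0.5, strong_threshold = 0.9,
                        top_k = 50L) {
  seqs <- if (inherits(candidates, "generation_batch")) candidates$sequences
          else if (is.data.frame(candidates)) candidates$sequence
          else as.character(candidates)
  if (length(seqs) == 0L) stop("empty candidate list", call. = FALSE)
  p_real <- score_sequences(promor, seqs)
  keep <- p_real > real_threshold
  seqs2 <- seqs[keep]; p_real2 <- p_real[keep]
  if (length(seqs2) == 0L) {
    return(tibble::tibble(sequence = character(0), p_real = numeric(0),
                          p_strong = numeric(0),
                          predicted_activity = numeric(0)))
  }
  p_strong <- score_sequences(promos, seqs2)
  keep2 <- p_strong > strong_threshold
  seqs3 <- seqs2[keep2]
  if (length(seqs3) == 0L) {
    return(tibble::tibble(sequence = character(0), p_real = numeric(0),
                          p_strong = numeric(0),
                          predicted_activity = numeric(0)))
  }
  act <- score_sequences(promoa, seqs3)
  ord <- order(-act, seqs3)
  ord <- utils::head(ord, top_k)
  tibble::tibble(sequence = seqs3[ord], p_real = p_real2[keep2][ord],
                 p_strong = p_strong[keep2][ord],
                 predicted_activity = act[ord])
}

all_kmers <- function(k = 6L) {
  do.call(paste0, expand.grid(rep(list(DNA_BASES), k),
                              stringsAsFactors = FALSE)[, k:1, drop = FALSE])
}

#' Scan all 4^6 hexamers as candidate functional motifs
#'
#' For each of the 4096 6-mers, generates `n_contexts` constrained random
#' promoters with the variable 6-mer at `position_role` and `fixed_motif`
#' at the other role (fixed spacer, default 17 bp), scores every context
#' with the realness and strength models, and records the fraction of
#' contexts called real and strong (score > 0.5 each).
#'
#' @param position_role `"minus10"` (vary the -10, fix the -35) or
#'   `"minus35"`.
#' @param fixed_motif The conserved hexamer at the other role.
#' @param spacer Spacer length (default 17).
#' @param n_contexts Random contexts per 6-mer (default 100).
#' @param promor,promos Realness / strength scorers (models or
#'   functions).
#' @param seed Integer RNG seed.
#' @param threshold Score cut for both calls (default 0.5).
#' @return Tibble of 4096 rows: `kmer`, `position_role`, `n_contexts`,
#'   `fraction_real`, `fraction_strong`.
#' @export
scan_kmers <- function(position_role = c("minus10", "minus35"),
                       fixed_motif = "TTGACA", spacer = 17L,
                       n_contexts = 100L, promor, promos, seed = 1L,
                       threshold = 0.5) {
  position_role <- match.arg(position_role)
  fixed_motif <- toupper(fixed_motif)
  if (grepl("[^ACGT]", fixed_motif) || nchar(fixed_motif) != 6L) {
    stop("fixed_motif must be an ACGT 6-mer", call. = FALSE)
  }
  stopifnot(n_contexts >= 1L)
  kmers <- all_kmers(6L)
  n_total <- length(kmers) * n_contexts
  # lay out all contexts in one pass, then score in one batch per model
  set.seed(seed)
  frac_real <- numeric(length(kmers))
  frac_strong <- numeric(length(kmers))
  chunk <- 256L   # kmers per scoring batch keeps memory flat
  for (startk in seq(1L, length(kmers), by = chunk)) {
    kk <- kmers[startk:min(startk + chunk - 1L, length(kmers))]
    seqs <- unlist(lapply(kk, function(km) {
      cs <- if (position_role == "minus10") {
        design_constraints(minus35 = fixed_motif, minus10 = km,
                           spacer_lengths = spacer)
      } else {
        design_constraints(minus35 = km, minus10 = fixed_motif,
                           spacer_lengths = spacer)
      }
      generate_constrained(cs, n_contexts,
                           seed = sample.int(2^30, 1L))$sequence
    }))
    sr <- score_sequences(promor, seqs) > threshold
    ss <- score_sequences(promos, seqs) > threshold
    grp <- rep(seq_along(kk), each = n_contexts)
    jj <- startk + seq_along(kk) - 1L
    frac_real[jj] <- as.vector(rowsum(as.numeric(sr), grp)) / n_contexts
    frac_strong[jj] <- as.vector(rowsum(as.numeric(ss), grp)) / n_contexts
  }
  tibble::tibble(kmer = kmers, position_role = position_role,
                 n_contexts = as.integer(n_contexts),
                 fraction_real = frac_real, fraction_strong = frac_strong)
}

#' Summarize a 6-mer scan
#'
#' Reports the fraction of 6-mers whose realness fraction strictly
#' exceeds `chance_cut`, the fraction at exactly 100%, and the mean
#' strength fraction inside and outside the above-cut subset.
#'
#' @param reports A [scan_kmers()] tibble.
#' @param chance_cut Realness-fraction cut (default 0.5).
#' @return Named list of summary statistics.
#' @export
kmer_summary <- function(reports, chance_cut = 0.5) {
  if (nrow(reports) == 0L) stop("empty reports", call. = FALSE)
  above <- reports$fraction_real > chance_cut
  list(n_kmers = nrow(reports),
       fraction_above_cut = mean(above),
       fraction_at_100 = mean(reports$fraction_real == 1),
       mean_strong_above = if (any(above))
         mean(reports$fraction_strong[above]) else NA_real_,
       mean_strong_below = if (any(!above))
         mean(reports$fraction_strong[!above]) else NA_real_,
       chance_cut = chance_cut)
}

#' Stratify a 6-mer scan by an external binding-strength ranking
#'
#' Given a user-supplied table ranking -10 (or -35) hexamers by their
#' RNAP/sigma70 binding strength, reports — for the strongest-binding
#' and weakest-binding groups — the fraction of motifs whose realness
#' fraction exceeds `real_cut` and the group's mean strength fraction.
#'
#' @param reports A [scan_kmers()] tibble.
#' @param binding_table Data frame with columns `kmer` and `group`
#'   (values `"strongest"` / `"weakest"`).
#' @param real_cut Realness-fraction cut (default 0.95).
#' @return Tibble with one row per group.
#' @export
binding_table_comparison <- function(reports, binding_table,
                                     real_cut = 0.95) {
  missing_k <- setdiff(binding_table$kmer, reports$kmer)
  if (length(missing_k)) {
    stop("unknown motif(s) in binding table: ",
         paste(utils::head(missing_k, 5L), collapse = ", "), call. = FALSE)
  }
  groups <- unique(binding_table$group)
  rows <- lapply(groups, function(g) {
    kk <- binding_table$kmer[binding_table$group == g]
    if (length(kk) == 0L) stop("empty group: ", g, call. = FALSE)
    sub <- reports[match(kk, reports$kmer), ]
    tibble::tibble(group = g, n = length(kk),
                   fraction_real_above_cut = mean(sub$fraction_real >= real_cut),
                   fraction_real_below_half = mean(sub$fraction_real < 0.5),
                   mean_fraction_strong = mean(sub$fraction_strong))
  })
  do.call(rbind, rows)
}

#' Write screened candidates to FASTA plus a CSV score table
#'
#' @param candidates A [drsa_screen()] tibble.
#' @param fasta_path,csv_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_candidates <- function(candidates, fasta_path, csv_path) {
  ids <- sprintf("cand%04d", seq_len(nrow(candidates)))
  write_fasta(promoter_dataset(ids, candidates$sequence), fasta_path)
  utils::write.csv(cbind(id = ids, candidates), csv_path,
                   row.names = FALSE)
  invisible(c(fasta_path, csv_path))
}
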