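#' Construct a promoter sequence dataset
#'
#' A `promo_dataset` is a tibble with one row per promoter record and the
#' columns `id`, `sequence`, `strength_label` (`"strong"`, `"weak"` or
#' `"unknown"`), `realness_label` (`"real"`, `"fake"` or `"unknown"`),
#' `activity` (non-negative FI/OD600, `NA` when unmeasured), `sigma_class`
#' (`"sigma70"`, `"non_sigma70"` or `"unknown"`) and `source`. Sequences are
#' uppercase strings over the strict alphabet `A`, `C`, `G`, `T`; anything
#' else (including IUPAC ambiguity codes) is rejected at construction, since
#' both one-hot and pseDNC encodings are defined only on the four-letter
#' alphabet. When every sequence shares one length, it is recorded in the
#' `fixed_length` attribute.
#'
#' @param id Character vector of unique record identifiers.
#' @param sequence Character vector of DNA sequences (case-insensitive).
#' @param strength_label,realness_label,sigma_class Optional label vectors;
#'   recycled defaults are `"unknown"`.
#' @param activity Optional non-negative numeric vector (`NA` allowed).
#' @param source Optional provenance tag.
#'
#' @return A tibble of class `promo_dataset`.
#' @export
#' @examples
#' promoter_dataset(c("p1", "p2"), c("ACGT", "TTGA"))
promoter_dataset <- function(id, sequence,
                             strength_label = "unknown",
                             realness_label = "unknown",
                             activity = NA_real_,
                             sigma_class = "unknown",
                             source = "") {
  n <- length(sequence)
  id <- as.character(id)
  if (length(id) != n) stop("`id` and `sequence` lengths differ", call. = FALSE)
  x <- tibble::tibble(
    id = id,
    sequence = toupper(as.character(sequence)),
    strength_label = rep_len(as.character(strength_label), n),
    realness_label = rep_len(as.character(realness_label), n),
    activity = rep_len(as.numeric(activity), n),
    sigma_class = rep_len(as.character(sigma_class), n),
    source = rep_len(as.character(source), n)
  )
  class(x) <- c("promo_dataset", class(tibble::tibble()))
  validate_promo_dataset(x)
}

#' @rdname promoter_dataset
#' @param x Object to validate.
#' @export
validate_promo_dataset <- function(x) {
  stopifnot(is.data.frame(x))
  if (anyDuplicated(x$id)) {
    stop("duplicate record ids: ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- grepl("[^ACGT]", x$sequence)
  if (any(bad)) {
    stop("non-ACGT characters in sequence(s): ",
         paste(utils::head(x$id[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(x$activity) & x$activity < 0)) {
    i <- which(!is.na(x$activity) & x$activity < 0)[1L]
    stop("negative activity at row ", i, " (id ", x$id[i], ")", call. = FALSE)
  }
  lens <- unique(nchar(x$sequence))
  attr(x, "fixed_length") <- if (length(lens) == 1L) lens else NULL
  x
}

#' @rdname promoter_dataset
#' @export
fixed_length <- function(x) attr(x, "fixed_length")

#' @export
print.promo_dataset <- function(x, ...) {
  fl <- fixed_length(x)
  cat("<promo_dataset> ", nrow(x), " record(s)",
      if (!is.null(fl)) paste0(", fixed length ", fl, " bp"), "\n", sep = "")
  NextMethod()
}

#' Read promoter sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the strict ACGT alphabet;
#' FASTA headers become record ids (first whitespace-delimited token).
#'
#' @param path Path to a FASTA file.
#' @return A [promoter_dataset()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(seqs))
  ss <- toupper(as.character(seqs))
  bad <- grepl("[^ACGT]", ss)
  if (any(bad)) {
    stop("non-ACGT characters in FASTA entr",
         if (sum(bad) > 1L) "ies: " else "y: ",
         paste(utils::head(ids[bad], 5L), collapse = ", "), call. = FALSE)
  }
  promoter_dataset(ids, ss, source = basename(path))
}

#' Write a dataset to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param x A [promoter_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  s <- Biostrings::DNAStringSet(x$sequence)
  names(s) <- x$id
  Biostrings::writeXStringSet(s, path, width = 60L)
  invisible(path)
}

#' Read an activity table (CSV/TSV)
#'
#' Reads a delimited text table with a header row and builds a dataset.
#' Column roles are given through `columns`, a named list mapping the
#' dataset fields `sequence`, `id`, `activity`, `strength_label`,
#' `realness_label` and `sigma_class` to column names in the file; only
#' `sequence` is mandatory. Missing optional fields become
#' unknown/absent. Activities must be numeric and non-negative.
#'
#' @param path Path to a CSV (default) or TSV file.
#' @param columns Named list of column-name mappings; default expects
#'   columns named like the fields themselves.
#' @param sep Field separator; `","` or `"\t"`.
#' @return A [promoter_dataset()].
#' @export
read_activity_table <- function(path,
                                columns = list(sequence = "sequence"),
                                sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8")
  get_col <- function(field, default) {
    nm <- columns[[field]] %||% field
    if (nm %in% names(df)) df[[nm]] else default
  }
  seq_col <- columns[["sequence"]] %||% "sequence"
  if (!seq_col %in% names(df)) {
    stop("schema error: no sequence column `", seq_col, "` in ", path,
         call. = FALSE)
  }
  n <- nrow(df)
  act_raw <- get_col("activity", rep(NA, n))
  act <- suppressWarnings(as.numeric(act_raw))
  bad <- which(!is.na(act_raw) & act_raw != "" & is.na(act))
  if (length(bad)) {
    stop("non-numeric activity at row ", bad[1L], ": `", act_raw[bad[1L]],
         "`", call. = FALSE)
  }
  promoter_dataset(
    id = as.character(get_col("id", sprintf("row%d", seq_len(n)))),
    sequence = df[[seq_col]],
    strength_label = get_col("strength_label", "unknown"),
    realness_label = get_col("realness_label", "unknown"),
    activity = act,
    sigma_class = get_col("sigma_class", "unknown"),
    source = basename(path)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reduce records to 50-bp windows
#'
#' Extracts the 50-character substring starting at `start_offset` (1-based,
#' closed interval, forward strand) from every record, preserving labels and
#' activities. The default offset 11 takes characters 11-60 of an 81-mer,
#' i.e. the 50 nt ending immediately upstream of the TSS position
#' conventionally at 61 in RegulonDB 81-mers; it is exposed because the
#' -35/-10 motif distribution, not a fixed coordinate, motivates the cut.
#'
#' @param x A [promoter_dataset()].
#' @param start_offset 1-based window start (default 11).
#' @param width Window width (default 50).
#' @return A [promoter_dataset()] with `fixed_length = width`.
#' @export
window_to_50 <- function(x, start_offset = 11L, width = 50L) {
  stopifnot(start_offset >= 1L, width >= 1L)
  short <- nchar(x$sequence) < start_offset + width - 1L
  if (any(short)) {
    stop("window [", start_offset, ", ", start_offset + width - 1L,
         "] exceeds sequence bounds for id(s): ",
         paste(utils::head(x$id[short], 5L), collapse = ", "), call. = FALSE)
  }
  out <- x
  out$sequence <- substr(x$sequence, start_offset, start_offset + width - 1L)
  validate_promo_dataset(out)
}

#' Sample random fixed-width windows from each record
#'
#' Draws `n` contiguous windows per record, with the start position uniform
#' over all valid starts — the procedure used to turn 81-bp non-promoter
#' sequences into 50-bp negatives. Deterministic under `seed`.
#'
#' @param x A [promoter_dataset()].
#' @param n Windows per record.
#' @param width Window width (default 50).
#' @param seed Integer RNG seed.
#' @return A [promoter_dataset()] of `n * nrow(x)` records with ids
#'   suffixed `_w<j>`.
#' @export
sample_windows <- function(x, n, width = 50L, seed = 1L) {
  lens <- nchar(x$sequence)
  if (any(lens < width)) {
    stop("width ", width, " exceeds sequence length for id(s): ",
         paste(utils::head(x$id[lens < width], 5L), collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  rows <- rep(seq_len(nrow(x)), each = n)
  starts <- vapply(rows, function(i) sample.int(lens[i] - width + 1L, 1L),
                   integer(1))
  out <- x[rows, , drop = FALSE]
  out$id <- paste0(out$id, "_w", rep(seq_len(n), times = nrow(x)))
  out$sequence <- substr(out$sequence, starts, starts + width - 1L)
  validate_promo_dataset(out)
}

#' Extend promoters downstream using genomic context
#'
#' Each record's sequence must occur exactly once on the forward strand of
#' the supplied genome; it is then extended downstream (3' direction) to
#' `target_length` with the genomic sequence that follows it — the procedure
#' used to lengthen 50-bp promoters to 81-400 bp.
#'
#' @param x A [promoter_dataset()] of records to extend.
#' @param genome A [promoter_dataset()] holding genome (or contig) sequences.
#' @param target_length Desired final length (>= current lengths).
#' @return A [promoter_dataset()] with extended sequences.
#' @export
extend_promoter <- function(x, genome, target_length) {
  ext <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    s <- x$sequence[i]
    L <- nchar(s)
    if (target_length < L) {
      stop("target_length ", target_length, " is shorter than sequence ",
           x$id[i], " (", L, " bp)", call. = FALSE)
    }
    hits <- NULL
    for (g in seq_len(nrow(genome))) {
      m <- gregexpr(s, genome$sequence[g], fixed = TRUE)[[1L]]
      if (m[1L] != -1L) hits <- rbind(hits, cbind(g, m))
    }
    if (is.null(hits) || nrow(hits) != 1L) {
      stop("sequence ", x$id[i], " matches the genome ",
           if (is.null(hits)) 0L else nrow(hits),
           " times; need exactly one forward-strand match", call. = FALSE)
    }
    gseq <- genome$sequence[hits[1L, 1L]]
    end <- hits[1L, 2L] + target_length - 1L
    if (end > nchar(gseq)) {
      stop("extension of ", x$id[i], " runs past the genome end",
           call. = FALSE)
    }
    ext[i] <- substr(gseq, hits[1L, 2L], end)
  }
  out <- x
  out$sequence <- ext
  validate_promo_dataset(out)
}

#' Promoter activity from fluorescence and cell density
#'
#' Activity is fluorescence intensity normalized by culture optical density,
#' `FI / OD600`, in arbitrary units.
#'
#' @param fi Fluorescence intensity (>= 0).
#' @param od600 Optical density at 600 nm (> 0).
#' @return Numeric activity vector.
#' @export
normalize_activity <- function(fi, od600) {
  if (any(od600 <= 0)) stop("od600 must be > 0", call. = FALSE)
  if (any(fi < 0)) stop("fi must be >= 0", call. = FALSE)
  fi / od600
}

#' Call promoters active or inactive against a negative control
#'
#' A promoter is called active when its activity exceeds the negative
#' control by more than 20%, i.e. `activity > 1.2 * control`; equality is
#' inactive (strict inequality at the boundary).
#'
#' @param activity Numeric activity vector.
#' @param negative_control_activity Positive scalar control activity.
#' @return Character vector of `"active"` / `"inactive"`.
#' @export
call_active <- function(activity, negative_control_activity) {
  if (!is.numeric(negative_control_activity) ||
      length(negative_control_activity) != 1L ||
      negative_control_activity <= 0) {
    stop("negative_control_activity must be a positive scalar", call. = FALSE)
  }
  ifelse(activity > 1.2 * negative_control_activity, "active", "inactive")
}
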