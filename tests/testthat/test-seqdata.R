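test_that("FASTA reading, writing and round-tripping preserve records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "ACGTACGT", ">p2", "acgt"), f)
  ds <- read_fasta(f)
  expect_s3_class(ds, "promo_dataset")
  expect_equal(nrow(ds), 2L)
  expect_equal(ds$id, c("p1", "p2"))
  expect_equal(ds$sequence[2], "ACGT")   # lowercase normalized

  f2 <- withr::local_tempfile(fileext = ".fasta")
  ds50 <- promoter_dataset(c("a", "b"), c(strrep("ACGT", 30),
                                          strrep("TTGCA", 24)))
  write_fasta(ds50, f2)
  back <- read_fasta(f2)
  expect_equal(back$id, ds50$id)
  expect_equal(back$sequence, ds50$sequence)
})

test_that("ingest rejects ambiguity codes, duplicate ids and negatives", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "ACGT", ">bad", "ACNT"), f)
  expect_error(read_fasta(f), "bad")
  expect_error(promoter_dataset(c("x", "x"), c("ACGT", "ACGT")),
               "duplicate")
  expect_error(promoter_dataset("x", "ACGT", activity = -1),
               "negative activity")
})

test_that("activity tables parse with column mapping and validation", {
  f <- withr::local_tempfile(fileext = ".csv")
  n <- 200L
  df <- data.frame(name = sprintf("s%03d", 1:n),
                   seq = rand_dna(n, 50, seed = 4),
                   fi_od = rlnorm(n))
  write.csv(df, f, row.names = FALSE)
  ds <- read_activity_table(f, columns = list(sequence = "seq", id = "name",
                                              activity = "fi_od"))
  expect_equal(nrow(ds), n)
  expect_true(all(!is.na(ds$activity)))

  # missing optional activity column: absent, not an error
  ds2 <- read_activity_table(f, columns = list(sequence = "seq", id = "name"))
  expect_true(all(is.na(ds2$activity)))

  # schema and value errors
  expect_error(read_activity_table(f, columns = list(sequence = "nope")),
               "schema")
  df$fi_od[3] <- "abc"
  write.csv(df, f, row.names = FALSE)
  expect_error(
    read_activity_table(f, columns = list(sequence = "seq",
                                          activity = "fi_od")),
    "row 3")
  df$fi_od[3] <- -1
  write.csv(df, f, row.names = FALSE)
  expect_error(
    read_activity_table(f, columns = list(sequence = "seq",
                                          activity = "fi_od")),
    "negative")
})

test_that("window_to_50 cuts the stated 1-based closed interval", {
  s81 <- rand_dna(1, 81, seed = 7)
  ds <- promoter_dataset("r1", s81, strength_label = "strong",
                         activity = 3.5)
  w <- window_to_50(ds)
  expect_equal(fixed_length(w), 50L)
  expect_equal(w$sequence, substr(s81, 11, 60))
  expect_equal(w$strength_label, "strong")  # labels preserved
  expect_equal(w$activity, 3.5)

  ds50 <- promoter_dataset("r2", rand_dna(1, 50, seed = 8))
  expect_equal(window_to_50(ds50, start_offset = 1)$sequence, ds50$sequence)
  expect_error(window_to_50(ds, start_offset = 40), "bounds")
})

test_that("sample_windows draws uniform substrings deterministically", {
  ds <- promoter_dataset("np1", rand_dna(1, 81, seed = 10))
  w <- sample_windows(ds, n = 4, width = 50, seed = 2)
  expect_equal(nrow(w), 4L)
  expect_equal(fixed_length(w), 50L)
  for (s in w$sequence) expect_true(grepl(s, ds$sequence, fixed = TRUE))
  w2 <- sample_windows(ds, n = 4, width = 50, seed = 2)
  expect_identical(w$sequence, w2$sequence)
  expect_error(sample_windows(ds, n = 1, width = 100, seed = 1), "width")

  # start positions uniform over the 32 valid starts (chi-square)
  big <- sample_windows(ds, n = 10000, width = 50, seed = 5)
  starts <- vapply(big$sequence, function(s)
    regexpr(s, ds$sequence, fixed = TRUE)[[1]], numeric(1))
  tab <- tabulate(starts, 32)
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("windowing agrees with fixed-start sampling on the same start", {
  ds <- promoter_dataset("x", rand_dna(1, 81, seed = 11))
  # find a seeded draw starting at 11 and compare to the deterministic cut
  w <- sample_windows(ds, n = 200, width = 50, seed = 3)
  starts <- vapply(w$sequence, function(s)
    regexpr(s, ds$sequence, fixed = TRUE)[[1]], numeric(1))
  hit <- which(starts == 11)[1]
  expect_false(is.na(hit))
  expect_equal(w$sequence[hit], window_to_50(ds, 11)$sequence)
})

test_that("extend_promoter uses unique genomic context downstream", {
  genome_seq <- rand_dna(1, 500, seed = 12)
  genome <- promoter_dataset("chr", genome_seq)
  core <- substr(genome_seq, 101, 150)
  rec <- promoter_dataset("p", core)
  ext <- extend_promoter(rec, genome, 100)
  expect_equal(nchar(ext$sequence), 100L)
  expect_equal(substr(ext$sequence, 1, 50), core)
  expect_equal(ext$sequence, substr(genome_seq, 101, 200))
  expect_equal(extend_promoter(rec, genome, 50)$sequence, core)

  expect_error(extend_promoter(promoter_dataset("q", strrep("AC", 25)),
                               genome, 100), "exactly one")
})

test_that("activity normalization and active calls follow the 20% rule", {
  expect_equal(normalize_activity(1000, 2), 500)
  expect_equal(normalize_activity(0, 1.7), 0)
  expect_error(normalize_activity(10, 0), "od600")

  expect_equal(call_active(1.19 * 5, 5), "inactive")
  expect_equal(call_active(1.21 * 5, 5), "active")
  expect_equal(call_active(1.20 * 5, 5), "inactive")  # boundary is strict
  expect_error(call_active(1, 0), "positive")
})
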