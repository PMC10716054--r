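test_that("noise schedules satisfy their defining identities", {
  s1 <- make_schedule(1, 0.01, 0.01)
  expect_equal(s1$beta, 0.01)
  expect_equal(s1$alpha_bar, 0.99)
  s <- make_schedule(1000)
  expect_true(all(diff(s$alpha_bar) < 0))   # strictly decreasing
  expect_equal(s$alpha + s$beta, rep(1, 1000))
  expect_true(all(s$beta > 0 & s$beta < 1))
  expect_error(make_schedule(0), "T")
  expect_error(make_schedule(10, 0.5, 0.1), "beta")
})

test_that("forward diffusion follows the closed-form marginal", {
  sch <- make_schedule(1000)
  x0 <- encode_for_diffusion(rand_dna(1, 50, seed = 2))
  # tiny t: x_t stays within sqrt(beta_1)-scale noise of x0
  x1 <- forward_diffuse(x0, 1, sch, seed = 3)
  expect_lt(max(abs(x1 - sqrt(sch$alpha_bar[1]) * unclass(x0))),
            5 * sqrt(sch$beta[1]))
  # determinism
  expect_identical(forward_diffuse(x0, 500, sch, seed = 4),
                   forward_diffuse(x0, 500, sch, seed = 4))
  expect_error(forward_diffuse(x0, 0, sch), "range")
  expect_error(forward_diffuse(x0, 1001, sch), "range")

  # Monte-Carlo mean/variance identity at mid-schedule
  t <- 500L
  reps <- 4000L
  X0 <- unclass(x0)[rep(1, reps), ]
  xt <- forward_diffuse(X0, t, sch, seed = 5)
  ab <- sch$alpha_bar[t]
  z <- xt - sqrt(ab) * X0
  nel <- length(z)
  expect_lt(abs(mean(z)), 3 * sqrt((1 - ab) / nel))
  expect_lt(abs(var(as.vector(z)) - (1 - ab)),
            3 * (1 - ab) * sqrt(2 / nel))
})

test_that("diffusion training records checkpoints and reduces the loss", {
  ds <- planted_motif_corpus(300, seed = 8)
  sch <- make_schedule(50)
  cfg <- unet_config(channels = 8, seed = 2)
  m <- train_promodiff(ds, cfg, sch, epochs = 10, seed = 3,
                       batch_size = 100, learning_rate = 2e-3,
                       checkpoint_every = 2)
  expect_length(m$history, 10L)
  expect_lt(tail(m$history, 1), m$history[1])
  expect_equal(names(m$checkpoints), as.character(seq(2, 10, by = 2)))
  m2 <- train_promodiff(ds, cfg, sch, epochs = 10, seed = 3,
                        batch_size = 100, learning_rate = 2e-3,
                        checkpoint_every = 2)
  expect_identical(m$history, m2$history)
  expect_error(
    train_promodiff(promoter_dataset(c("a", "b"), c("ACGT", "ACGTAC")),
                    cfg, sch, epochs = 1),
    "fixed-length")

  # sampling: shape, alphabet, determinism, checkpoint lookup
  b <- sample_promoters(m, 25, seed = 4)
  expect_length(b$sequences, 25L)
  expect_true(all(nchar(b$sequences) == 50L))
  expect_false(any(grepl("[^ACGT]", b$sequences)))
  b2 <- sample_promoters(m, 25, seed = 4)
  expect_identical(b$sequences, b2$sequences)
  b_ck <- sample_promoters(m, 5, seed = 4, epoch = 4)
  expect_equal(b_ck$epoch, 4)
  expect_error(sample_promoters(m, 5, seed = 1, epoch = 3), "checkpoint")

  # checkpoints round-trip through the save container
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m3 <- load_model(f)
  expect_identical(sample_promoters(m3, 10, seed = 9)$sequences,
                   sample_promoters(m, 10, seed = 9)$sequences)
})

test_that("novelty reports count exact duplicates by the stated convention", {
  train <- promoter_dataset(c("a", "b", "c"),
                            c("ACGTA", "CCCCC", "GGGGG"))
  batch <- structure(list(sequences = c("ACGTA", "TTTTT", "TTTTT",
                                        "TTTTT", "AAAAA"),
                          epoch = 1, rpp = NULL),
                     class = "generation_batch")
  r <- novelty_report(batch, train)
  expect_equal(r$within_duplicates, 2L)   # repeats beyond first TTTTT
  expect_equal(r$cross_duplicates, 1L)
  r2 <- novelty_report(train$sequence, train)
  expect_equal(r2$cross_duplicates, 3L)
  r3 <- novelty_report(c("TTTTT", "AAAAA"), train)
  expect_equal(r3$cross_duplicates, 0L)
})

test_that("RPP is the above-threshold fraction under any scorer", {
  seqs <- rand_dna(10, 50, seed = 5)
  expect_equal(rpp(seqs, stub_const(1)), 1)
  expect_equal(rpp(seqs, stub_const(0)), 0)
  half <- function(ss) rep(c(0.9, 0.1), length.out = length(ss))
  expect_equal(rpp(seqs, half), 0.5)
  expect_error(rpp(character(0), stub_const(1)), "empty")
})

test_that("checkpoint RPP curves are reproducible and argmax-correct", {
  ds <- planted_motif_corpus(100, seed = 12)
  m <- train_promodiff(ds, unet_config(channels = 4, seed = 1),
                       make_schedule(10), epochs = 3, seed = 2,
                       batch_size = 100, checkpoint_every = 1)
  # favor later checkpoints via an epoch-blind scorer driven by a counter
  counter <- local({
    i <- 0
    function(ss) {
      i <<- i + 1
      c(rep(1, i), rep(0, length(ss) - i))
    }
  })
  cur <- checkpoint_rpp_curve(m, counter, n_per_epoch = 10, seed = 3)
  expect_equal(cur$epoch, 1:3)
  expect_equal(attr(cur, "best_epoch"), 3L)
  flat <- checkpoint_rpp_curve(m, stub_const(1), n_per_epoch = 10, seed = 3)
  expect_equal(flat$rpp, rep(1, 3))
  expect_identical(flat$rpp,
                   checkpoint_rpp_curve(m, stub_const(1), n_per_epoch = 10,
                                        seed = 3)$rpp)
  m0 <- m; m0$checkpoints <- list()
  expect_error(checkpoint_rpp_curve(m0, stub_const(1)), "checkpoint")
})
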