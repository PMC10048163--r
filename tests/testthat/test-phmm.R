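test_that("model building follows the match-column rule and counts", {
  # two identical ungapped rows "GGG": three match states, G-dominant
  hmm <- build_phmm(align_sequences(c(a = "GGG", b = "GGG")))
  expect_equal(hmm$m, 3L)
  expect_equal(unname(apply(hmm$match_emis, 1, which.max)), rep(3L, 3))

  # a 60%-gap column becomes insert states, excluded from m
  aln <- g4_alignment(tibble::tibble(
    seq_id = paste0("s", 1:5),
    aligned = c("GAG", "G-G", "G-G", "G-G", "GAG")))
  expect_equal(build_phmm(aln)$m, 2L)
  # at 40% gaps it stays a match column
  aln2 <- g4_alignment(tibble::tibble(
    seq_id = paste0("s", 1:5),
    aligned = c("GAG", "GAG", "GAG", "G-G", "G-G")))
  expect_equal(build_phmm(aln2)$m, 3L)

  expect_error(build_phmm(g4_alignment(tibble::tibble(
    seq_id = c("a", "b"), aligned = c("--", "--")))), "match-eligible")
})

test_that("emissions and transition groups are normalised", {
  for (seed in 1:5) {
    hmm <- build_phmm(random_alignment(5, 12, gap_prob = 0.2, seed = seed))
    expect_equal(rowSums(hmm$match_emis), rep(1, hmm$m), tolerance = 1e-9)
    expect_equal(rowSums(hmm$insert_emis), rep(1, hmm$m + 1), tolerance = 1e-9)
    tr <- hmm$trans
    for (k in seq_len(hmm$m + 1)) {
      expect_equal(tr$mm[k] + tr$mi[k] + tr$md[k], 1, tolerance = 1e-9)
      expect_equal(tr$im[k] + tr$ii[k], 1, tolerance = 1e-9)
      expect_true(tr$dm[k] + tr$dd[k] %in% c(0, 1) ||
                    abs(tr$dm[k] + tr$dd[k] - 1) < 1e-9)
    }
  }
})

test_that("forward log odds matches the single-state closed form", {
  hmm <- build_phmm(g4_alignment(tibble::tibble(
    seq_id = c("x", "y"), aligned = c("G", "G"))), pseudocount = 0)
  res <- forward_log_odds(hmm, "G")
  expect_equal(res$log_odds, log(4), tolerance = 1e-12)
  expect_equal(res$forward_loglik, 0, tolerance = 1e-12)
  v <- viterbi(hmm, "G")
  expect_equal(v$path, "M1")
  expect_equal(v$log_odds, log(4), tolerance = 1e-12)
  expect_error(forward_log_odds(hmm, ""), "empty")
  expect_error(viterbi(hmm, ""), "empty")
})

test_that("forward and Viterbi equal exhaustive path enumeration", {
  set.seed(11)
  for (trial in 1:12) {
    m_cols <- sample(2:3, 1)
    aln <- random_alignment(3, m_cols + sample(0:1, 1), gap_prob = 0.25,
                            seed = 100 + trial)
    hmm <- build_phmm(aln)
    if (hmm$m > 3) next
    for (len in 1:4) {
      seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      fwd <- forward_log_odds(hmm, seq)$forward_loglik
      expect_equal(fwd, log(enum_phmm(hmm, seq, "sum")), tolerance = 1e-9,
                   info = paste("forward", trial, seq))
      vit <- viterbi(hmm, seq)
      expect_equal(vit$viterbi_loglik, log(enum_phmm(hmm, seq, "max")),
                   tolerance = 1e-9, info = paste("viterbi", trial, seq))
    }
  }
})

test_that("Viterbi never exceeds forward and paths are structurally valid", {
  set.seed(21)
  for (trial in 1:25) {
    hmm <- build_phmm(random_alignment(4, sample(3:8, 1), gap_prob = 0.2,
                                       seed = 200 + trial))
    seq <- paste(sample(c("A", "C", "G", "T"), sample(2:10, 1),
                        replace = TRUE), collapse = "")
    f <- forward_log_odds(hmm, seq)$forward_loglik
    v <- viterbi(hmm, seq)
    expect_lte(v$viterbi_loglik, f + 1e-9)
    # emitted symbols = matches + inserts; nodes advance by matches + deletes
    states <- substr(v$path, 1, 1)
    expect_equal(sum(states %in% c("M", "I")), nchar(seq))
    expect_equal(sum(states %in% c("M", "D")), hmm$m)
  }
})

test_that("forward probabilities are proper over sequences of fixed length", {
  # summing P(seq | hmm) over all sequences of length m (no-indel model)
  hmm <- build_phmm(align_sequences(c(a = "GAG", b = "GAG", c = "GTG")))
  lens <- 3
  total <- 0
  alph <- c("A", "C", "G", "T")
  for (i in alph) for (j in alph) for (k in alph) {
    total <- total +
      exp(forward_log_odds(hmm, paste0(i, j, k))$forward_loglik)
  }
  expect_lte(total, 1 + 1e-9)
})

test_that("sampling is reproducible and matches trained emissions", {
  aln <- align_sequences(stats::setNames(rep("GGGAGGG", 6), paste0("m", 1:6)))
  hmm <- build_phmm(aln, pseudocount = 0)
  # a fully deterministic model generates identical sequences
  expect_equal(unique(sample_phmm(hmm, 10, seed = 3)), "GGGAGGG")
  expect_equal(sample_phmm(hmm, 5, seed = 9), sample_phmm(hmm, 5, seed = 9))

  # empirical base mix of samples from a noisier model within 3 sigma
  hmm2 <- build_phmm(align_sequences(c(a = "GGGAGGG", b = "GGGTGGG",
                                       c = "GGGAGGG", d = "GGGAGGG")),
                     pseudocount = 0)
  draws <- sample_phmm(hmm2, 2000, seed = 5)
  expect_true(all(nchar(draws) == 7))
  frac_a <- mean(substr(draws, 4, 4) == "A")
  p <- 3 / 4
  expect_lt(abs(frac_a - p), 3 * sqrt(p * (1 - p) / 2000))
})

test_that("JSON serialisation round-trips models losslessly", {
  for (seed in 1:3) {
    hmm <- build_phmm(random_alignment(4, 8, seed = seed))
    path <- withr::local_tempfile(fileext = ".json")
    write_phmm(hmm, path)
    back <- read_phmm(path)
    expect_equal(back$m, hmm$m)
    expect_equal(back$match_emis, hmm$match_emis, tolerance = 1e-12)
    expect_equal(back$insert_emis, hmm$insert_emis, tolerance = 1e-12)
    expect_equal(back$trans, hmm$trans, tolerance = 1e-12)
    # reloaded model scores identically
    s <- "GGGATGGG"
    expect_equal(forward_log_odds(back, s), forward_log_odds(hmm, s),
                 tolerance = 1e-12)
  }
  # corrupt schema errors out
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"version":"1.0","m":2}', bad)
  expect_error(read_phmm(bad), "schema")
  writeLines('{"version":"9.9"}', bad)
  expect_error(read_phmm(bad), "schema")
})

test_that("training on samples from a known model recovers match emissions", {
  truth <- build_phmm(align_sequences(c(a = "GGGAGGG", b = "GGGAGGG",
                                        c = "GGGTGGG", d = "GGGAGGG")),
                      pseudocount = 0)
  draws <- sample_phmm(truth, 2000, seed = 17)
  aln <- g4_alignment(tibble::tibble(seq_id = paste0("d", seq_along(draws)),
                                     aligned = draws))
  fit <- build_phmm(aln, pseudocount = 1)
  tv <- max(abs(fit$match_emis - truth$match_emis))
  expect_lt(tv, 0.05)
})
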