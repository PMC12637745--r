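test_that("temperature softmax matches closed forms and is shift-invariant", {
  expect_equal(temperature_softmax(c(5, 5, 5), 0.7), rep(1 / 3, 3))
  expect_equal(temperature_softmax(c(log(2), 0, 0), 1), c(0.5, 0.25, 0.25))
  # direct evaluation of exp(z/T) at T = 0.5
  expect_equal(temperature_softmax(c(1, 0), 0.5),
               c(exp(2) / (exp(2) + 1), 1 / (exp(2) + 1)),
               tolerance = 1e-12)
  z <- c(2.3, -1.1, 0.4)
  expect_equal(temperature_softmax(z + 100, 0.5),
               temperature_softmax(z, 0.5), tolerance = 1e-12)
  expect_error(temperature_softmax(c(1, 2), 0), "positive")
  expect_error(temperature_softmax(c(1, Inf), 1), "finite")
})

test_that("softmax entropy is non-decreasing in temperature", {
  withr::with_seed(7, {
    for (i in 1:20) {
      z <- rnorm(10, sd = 3)
      h <- vapply(c(0.2, 0.5, 1, 2, 5),
                  function(T) position_entropy(temperature_softmax(z, T)),
                  numeric(1))
      expect_true(all(diff(h) >= -1e-9))
    }
  })
})

test_that("top-k renormalization keeps the k largest and rescales", {
  expect_equal(topk_renormalize(c(0.5, 0.3, 0.2), 3), c(0.5, 0.3, 0.2))
  expect_equal(topk_renormalize(c(0.5, 0.3, 0.2), 2), c(0.625, 0.375))
  expect_equal(topk_renormalize(rep(0.1, 10), 4), rep(0.25, 4))
  expect_error(topk_renormalize(c(0.6, 0.4), 0), "positive")
  # stable tie-break: first occurrences win
  expect_equal(topk_renormalize(c(0.25, 0.25, 0.25, 0.25), 2), c(0.5, 0.5))
})

test_that("position entropy matches closed forms and the summation oracle", {
  expect_equal(position_entropy(c(1, 0, 0)), 0)
  expect_equal(position_entropy(rep(1 / 30, 30)), log2(30))
  expect_equal(position_entropy(c(0.5, 0.25, 0.25)), 1.5)
  withr::with_seed(3, {
    for (i in 1:50) {
      n <- sample(2:5, 1)
      p <- rgamma(n, 1)
      p <- p / sum(p)
      expect_equal(position_entropy(p), entropy_oracle(p), tolerance = 1e-12)
    }
  })
})

test_that("run entropy averages usable positions and honors exclusions", {
  # entropies 1 and 2 bits: (0.5,0.5) and uniform over 4
  probs <- list(c(" a" = 0.5, " b" = 0.5),
                c(" a" = 0.25, " b" = 0.25, " c" = 0.25, " d" = 0.25))
  r <- run_row("r1", probs, top_k = 4)
  es <- run_entropy(r$logprobs[[1]], k = 4)
  expect_equal(es$per_position, c(1, 2))
  expect_equal(es$run_mean, 1.5)
  expect_equal(es$positions_used, 2L)

  masked <- run_entropy(r$logprobs[[1]], k = 4, mask = c(FALSE, TRUE))
  expect_equal(masked$run_mean, 1)

  absent <- run_entropy(r$logprobs[[1]], k = 4, sampled_index = c(1L, NA))
  expect_equal(absent$run_mean, 1)

  expect_error(
    run_entropy(r$logprobs[[1]], k = 4, mask = c(TRUE, TRUE), run_id = "r1"),
    "empty run.*r1"
  )
})

test_that("per-position scores are invariant to logit shifts", {
  lp <- list(c(" a" = -0.3, " b" = -1.9, " c" = -2.5))
  shifted <- list(lp[[1]] + 7.7)
  for (post in c(TRUE, FALSE)) {
    expect_equal(
      run_entropy(lp, k = 3, logprobs_post_temperature = post,
                  temperature = 0.5)$run_mean,
      run_entropy(shifted, k = 3, logprobs_post_temperature = post,
                  temperature = 0.5)$run_mean,
      tolerance = 1e-12
    )
  }
})

test_that("internal repeatability hits its closed forms", {
  k <- 6
  uni <- dplyr::bind_rows(uniform_run("r1", k), uniform_run("r2", k))
  expect_equal(internal_repeatability(uni, mask_stopwords = FALSE)$score, 0)

  oh <- dplyr::bind_rows(onehot_run("r1", k), onehot_run("r2", k))
  expect_equal(internal_repeatability(oh, mask_stopwords = FALSE)$score, 1,
               tolerance = 1e-9)

  # run means 1 and 2 bits, k = 4: raw 1.5, score 0.25
  r1 <- run_row("r1", list(c(" a" = 0.5, " b" = 0.5)), top_k = 4)
  r2 <- run_row("r2", list(c(" a" = 0.25, " b" = 0.25, " c" = 0.25,
                             " d" = 0.25)), top_k = 4)
  res <- internal_repeatability(dplyr::bind_rows(r1, r2),
                                mask_stopwords = FALSE)
  expect_equal(res$raw, 1.5)
  expect_equal(res$score, 0.25)
})

test_that("internal reproducibility averages absolute pairwise differences", {
  k <- 4
  # P = 2 prompts with mean entropies 1 and 2 bits: raw 1, score 0.5
  p1 <- run_row("r1", list(c(" a" = 0.5, " b" = 0.5)), prompt = "p1",
                top_k = k)
  p2 <- run_row("r2", list(c(" a" = 0.25, " b" = 0.25, " c" = 0.25,
                             " d" = 0.25)), prompt = "p2", top_k = k)
  res <- internal_reproducibility(dplyr::bind_rows(p1, p2),
                                  mask_stopwords = FALSE)
  expect_equal(res$raw, 1)
  expect_equal(res$score, 0.5)

  # equal mean entropies: score exactly 1
  same <- dplyr::bind_rows(
    uniform_run("r1", k), uniform_run("r2", k, prompt = "p2"),
    uniform_run("r3", k, prompt = "p3")
  )
  expect_equal(internal_reproducibility(same, mask_stopwords = FALSE)$score, 1)

  # P = 3 with mean entropies (0, 0, log2 k): three pairs, mean (2/3) log2 k
  trio <- dplyr::bind_rows(
    onehot_run("r1", k), onehot_run("r2", k, prompt = "p2"),
    uniform_run("r3", k, prompt = "p3")
  )
  res3 <- internal_reproducibility(trio, mask_stopwords = FALSE)
  expect_equal(res3$raw, (2 / 3) * log2(k), tolerance = 1e-9)
  expect_equal(res3$score, 1 / 3, tolerance = 1e-9)

  expect_error(
    internal_reproducibility(uniform_run("r1", k), mask_stopwords = FALSE),
    "insufficient prompts"
  )
})

test_that("k = 1 run sets score 1 by continuity", {
  r <- run_row("r1", list(c(" a" = 1), c(" b" = 1)), top_k = 1)
  res <- internal_repeatability(dplyr::bind_rows(r), mask_stopwords = FALSE)
  expect_equal(res$score, 1)
})

test_that("internal scores stay in [0, 1] and ignore run order", {
  withr::with_seed(11, {
    for (i in 1:10) {
      k <- sample(2:8, 1)
      rows <- lapply(1:4, function(r) {
        probs <- lapply(1:3, function(j) {
          p <- rgamma(k, 0.5)
          p <- p / sum(p)
          stats::setNames(p, paste0(" t", seq_len(k)))
        })
        run_row(paste0("r", r), probs, top_k = k)
      })
      runs <- dplyr::bind_rows(rows)
      res <- internal_repeatability(runs, mask_stopwords = FALSE)
      expect_gte(res$score, 0)
      expect_lte(res$score, 1)
      perm <- runs[sample.int(nrow(runs)), ]
      expect_equal(internal_repeatability(perm, mask_stopwords = FALSE)$score,
                   res$score)
    }
  })
})

test_that("stopword positions are excluded from the entropy mean when masked", {
  # stopword position is uniform (high entropy), content position one-hot
  probs <- list(c(" the" = 0.5, " an" = 0.5), c(" meningitis" = 1))
  r <- run_row("rs", probs, top_k = 2)
  with_mask <- internal_repeatability(dplyr::bind_rows(r))
  without <- internal_repeatability(dplyr::bind_rows(r),
                                    mask_stopwords = FALSE)
  expect_equal(with_mask$raw, 0)
  expect_equal(without$raw, 0.5)
})
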