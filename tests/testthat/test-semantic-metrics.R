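test_that("cosine similarity handles identity, orthogonality, antipodes", {
  v <- c(0.3, -1.2, 4)
  expect_equal(cosine(v, v), 1)
  expect_equal(cosine(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine(c(1, 0), c(-1, 0)), -1)
  expect_equal(cosine(2 * v, 5 * v), 1) # scale invariance
  expect_error(cosine(c(0, 0), v), "zero-norm")
})

test_that("mean pairwise cosine equals the pair-enumeration oracle", {
  m <- rbind(c(1, 0), c(0, 1), c(-1, 0))
  expect_equal(mean_pairwise_cosine(m), -1 / 3)
  expect_equal(mean_pairwise_cosine(rbind(c(1, 2), c(2, 4), c(3, 6))), 1)
  expect_equal(mean_pairwise_cosine(rbind(c(1, 0), c(1, 1))),
               cosine(c(1, 0), c(1, 1)))
  withr::with_seed(5, {
    for (i in 1:20) {
      n <- sample(2:6, 1)
      m <- matrix(rnorm(n * 4), nrow = n)
      expect_equal(mean_pairwise_cosine(m), pairwise_cosine_oracle(m),
                   tolerance = 1e-12)
    }
  })
  expect_error(mean_pairwise_cosine(matrix(1, 1, 2)), "insufficient runs")
})

test_that("semantic repeatability rescales mean cosine to [0, 1]", {
  # identical texts: one embedding, score exactly 1
  fx <- text_runs(rep("fever and rash", 3),
                  rep(list(c(1, 2, 3)), 3))
  res <- semantic_repeatability(fx$runs, fx$backend)
  expect_equal(res$score, 1)
  expect_equal(res$raw, 1)

  # orthogonal pair: raw 0, score 0.5
  fx2 <- text_runs(c("fever rash", "headache stiffness"),
                   list(c(1, 0), c(0, 1)))
  res2 <- semantic_repeatability(fx2$runs, fx2$backend)
  expect_equal(res2$raw, 0)
  expect_equal(res2$score, 0.5)

  # three embeddings (1,0), (0,1), (-1,0): raw -1/3, score 1/3
  fx3 <- text_runs(c("alpha one", "beta two", "gamma three"),
                   list(c(1, 0), c(0, 1), c(-1, 0)))
  res3 <- semantic_repeatability(fx3$runs, fx3$backend)
  expect_equal(res3$raw, -1 / 3)
  expect_equal(res3$score, 1 / 3)
  expect_equal(res3$score, (res3$raw + 1) / 2) # exact rescaling contract

  expect_error(
    semantic_repeatability(fx3$runs[1, ], fx3$backend),
    "insufficient runs"
  )
})

test_that("stopword filtering happens before embedding", {
  # raw texts differ only in stopwords; filtered forms coincide, and the
  # lookup backend only knows the filtered form shared by both
  map <- list("fever rash" = c(2, 1))
  runs <- text_runs(c("the fever a rash", "fever the rash"),
                    list(c(9, 9), c(9, 9)))$runs
  res <- semantic_repeatability(runs, backend_lookup(map))
  expect_equal(res$score, 1)
  # with filtering off the raw texts are unknown to the backend
  expect_error(
    semantic_repeatability(runs, backend_lookup(map),
                           filter_stopwords = FALSE),
    "no embedding"
  )
  # all-stopword output cannot be scored
  sw_only <- text_runs(c("the an of", "and but or"),
                       list(c(1, 0), c(0, 1)))$runs
  expect_error(semantic_repeatability(sw_only, backend_lookup(map)),
               "empty filtered text")
})

test_that("prompt mean embeddings average runs coordinate-wise", {
  fx <- text_runs(rep("fever rash", 2), rep(list(c(0.3, 0.4)), 2))
  expect_equal(prompt_mean_embedding(fx$runs, fx$backend), c(0.3, 0.4))

  fx2 <- text_runs(c("one word", "two words"), list(c(1, 0), c(0, 1)))
  expect_equal(prompt_mean_embedding(fx2$runs, fx2$backend), c(0.5, 0.5))

  # antipodal cancellation: zero vector, flagged downstream
  fx3 <- text_runs(c("one word", "two words"), list(c(1, 0), c(-1, 0)))
  expect_equal(prompt_mean_embedding(fx3$runs, fx3$backend), c(0, 0))

  # normalize-then-mean variant
  fx4 <- text_runs(c("one word", "two words"), list(c(2, 0), c(0, 1)))
  expect_equal(
    prompt_mean_embedding(fx4$runs, fx4$backend,
                          l2_normalize_before_mean = TRUE),
    c(0.5, 0.5)
  )
})

test_that("semantic reproducibility compares prompt centroids", {
  mk_family <- function(vectors_by_prompt) {
    parts <- lapply(seq_along(vectors_by_prompt), function(p) {
      vs <- vectors_by_prompt[[p]]
      text_runs(paste0("prompt", p, " sentence ", seq_along(vs)), vs,
                prompt = paste0("p", p))
    })
    runs <- dplyr::bind_rows(lapply(parts, `[[`, "runs"))
    maps <- lapply(parts, function(x) environment(x$backend$embed)$map)
    list(runs = runs, backend = backend_lookup(do.call(c, maps)))
  }

  # identical centroids: score exactly 1
  fam <- mk_family(list(list(c(1, 1), c(1, 1)), list(c(2, 2), c(2, 2))))
  expect_equal(semantic_reproducibility(fam$runs, fam$backend)$score, 1)

  # orthogonal centroids: score 0.5
  fam2 <- mk_family(list(list(c(1, 0), c(1, 0)), list(c(0, 1), c(0, 1))))
  expect_equal(semantic_reproducibility(fam2$runs, fam2$backend)$score, 0.5)

  # centroids (1,0), (0,1), (-1,0): raw -1/3, score 1/3
  fam3 <- mk_family(list(list(c(1, 0)), list(c(0, 1)), list(c(-1, 0))))
  res3 <- semantic_reproducibility(fam3$runs, fam3$backend)
  expect_equal(res3$raw, -1 / 3)
  expect_equal(res3$score, 1 / 3)

  # zero-norm centroid names the prompt
  fam4 <- mk_family(list(list(c(1, 0), c(-1, 0)), list(c(0, 1))))
  expect_error(semantic_reproducibility(fam4$runs, fam4$backend),
               "zero-norm.*p1")

  expect_error(
    semantic_reproducibility(fam3$runs[fam3$runs$prompt_id == "p1", ],
                             fam3$backend),
    "insufficient prompts"
  )
})

test_that("positive rescaling of run embeddings leaves repeatability unchanged", {
  texts <- c("alpha one", "beta two", "gamma three")
  vs <- list(c(1, 2), c(-1, 1), c(3, 0.5))
  fx <- text_runs(texts, vs)
  scaled <- text_runs(texts, lapply(seq_along(vs), function(i) vs[[i]] * i * 2))
  expect_equal(
    semantic_repeatability(scaled$runs, scaled$backend)$score,
    semantic_repeatability(fx$runs, fx$backend)$score,
    tolerance = 1e-12
  )
})

test_that("backends cache deterministically and honor the plug-in contract", {
  b <- backend_mock_vmf(dim = 16, seed = 9)
  v1 <- embed_text(b, "a clinical sentence")
  v2 <- embed_text(b, "a clinical sentence")
  expect_identical(v1, v2)
  expect_equal(sqrt(sum(v1^2)), 1, tolerance = 1e-12)
  # distinct texts, distinct directions
  v3 <- embed_text(b, "another sentence")
  expect_gt(sum(abs(v1 - v3)), 1e-6)
  # a fresh backend with the same seed reproduces the embedding
  expect_identical(embed_text(backend_mock_vmf(16, 9), "a clinical sentence"),
                   v1)
  # registry round trip
  expect_identical(
    embed_text(embedding_backend("mock-vmf", dim = 16, seed = 9), "x"),
    embed_text(backend_mock_vmf(16, 9), "x")
  )
  expect_error(embedding_backend("nope"), "unknown embedding backend")
})
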