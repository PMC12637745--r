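# In-code fixtures: tiny run logs built from explicit per-position
# probability vectors, and lookup backends from explicit text -> vector
# maps. No files, no randomness unless a test seeds its own.

# One run row. `probs` is a list of named probability vectors (names are
# candidate tokens, first candidate is the sampled/generated token unless
# `sampled` says otherwise).
run_row <- function(run_id, probs, case = "c1", prompt = "p1",
                    model = "m1", temperature = 0.5, top_k = NULL,
                    sampled = NULL, dataset = NA_character_) {
  top_k <- top_k %||% max(vapply(probs, length, integer(1)))
  sampled <- sampled %||% rep(1L, length(probs))
  probs <- lapply(probs, function(p) {
    stopifnot(!is.null(names(p)))
    p[order(-p)]
  })
  tokens <- vapply(seq_along(probs), function(j) {
    if (is.na(sampled[[j]])) names(probs[[j]])[[1]]
    else names(probs[[j]])[[sampled[[j]]]]
  }, character(1))
  lps <- lapply(probs, function(p) log(p))
  tibble::tibble(
    run_id = run_id, case_id = case, prompt_id = prompt, model_id = model,
    temperature = temperature, top_k = as.integer(top_k),
    dataset_label = dataset,
    text = trimws(paste0(tokens, collapse = "")),
    tokens = list(tokens), logprobs = list(lps),
    sampled_index = list(as.integer(sampled))
  )
}

# A run whose positions all share one distribution.
uniform_run <- function(run_id, k, n_pos = 3, ...) {
  p <- stats::setNames(rep(1 / k, k), paste0(" tok", seq_len(k)))
  run_row(run_id, rep(list(p), n_pos), top_k = k, ...)
}

onehot_run <- function(run_id, k, n_pos = 3, ...) {
  p <- stats::setNames(c(1 - 1e-12 * (k - 1), rep(1e-12, k - 1)),
                       paste0(" tok", seq_len(k)))
  run_row(run_id, rep(list(p), n_pos), top_k = k, ...)
}

# Runs carrying given texts (one deterministic single-candidate position
# per word), plus a lookup backend embedding those texts (and their
# stopword-filtered forms) as the given vectors.
text_runs <- function(texts, vectors, case = "c1", prompt = "p1",
                      model = "m1", top_k = 5) {
  rows <- lapply(seq_along(texts), function(i) {
    toks <- paste0(" ", strsplit(texts[[i]], " ")[[1]])
    probs <- lapply(toks, function(tk) stats::setNames(1, tk))
    run_row(paste0("r", i, "-", case, "-", prompt), probs,
            case = case, prompt = prompt, model = model, top_k = top_k)
  })
  runs <- dplyr::bind_rows(rows)
  map <- list()
  for (i in seq_along(texts)) {
    map[[texts[[i]]]] <- vectors[[i]]
    filt <- filter_stopwords_text(texts[[i]])
    if (nzchar(filt) && is.null(map[[filt]])) map[[filt]] <- vectors[[i]]
  }
  list(runs = runs, backend = backend_lookup(map))
}

# Direct-summation entropy oracle, independent of position_entropy().
entropy_oracle <- function(p) {
  h <- 0
  for (v in p) if (v > 0) h <- h - v * log(v) / log(2)
  h
}

# Pair-enumeration cosine oracle, independent of mean_pairwise_cosine().
pairwise_cosine_oracle <- function(m) {
  n <- nrow(m)
  tot <- 0
  cnt <- 0
  for (r in seq_len(n - 1)) {
    for (s in (r + 1):n) {
      a <- m[r, ]; b <- m[s, ]
      tot <- tot + sum(a * b) / sqrt(sum(a^2) * sum(b^2))
      cnt <- cnt + 1
    }
  }
  tot / cnt
}
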