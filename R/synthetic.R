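#' Configuration for the synthetic run simulator
#'
#' The simulator stands in for the model-API layer: it emits run logs in
#' the exact dialect of [read_runs()] with *known* ground-truth
#' variability, so every score is testable by parameter recovery without
#' any model access. Two knobs control the two score families:
#'
#' * `dirichlet_alpha` — per-position token distributions are drawn from a
#'   symmetric Dirichlet over the vocabulary. Small `alpha` gives peaked,
#'   low-entropy distributions (internal repeatability near 1); large
#'   `alpha` approaches uniform (score near 0 when `top_k` spans the
#'   vocabulary).
#' * `vmf_kappa` — each run's embedding is drawn from a von Mises-Fisher
#'   distribution around a prompt-specific mean direction. Large `kappa`
#'   concentrates embeddings (semantic repeatability near 1); `kappa = 0`
#'   is uniform on the sphere (score near 0.5 in high dimension, where
#'   random directions are near-orthogonal).
#'
#' Prompt-level heterogeneity, the target of the reproducibility scores,
#' comes from `entropy_shift_per_prompt` (bits; prompt `p` uses
#' `alpha * 2^shift[p]`, a monotone knob rather than an exact entropy
#' inversion — realized mean entropies are recorded in the ground-truth
#' sidecar) and `prompt_direction_separation` (radians between consecutive
#' prompt mean directions in a fixed 2-plane). Zero shifts and zero
#' separation are the reproducibility null.
#'
#' Defaults mirror a full factorial evaluation study: `n_runs = 100`
#' repeated generations, `n_prompts = 5` reasoning prompts, `n_cases = 608`
#' clinical cases, `temperature = 0.5`, `top_k = 30`.
#'
#' @param vocab_size Synthetic vocabulary size (>= 2).
#' @param run_length Tokens per run.
#' @param n_runs Runs per case-prompt combination (`R`).
#' @param n_prompts Prompts per case (`P`).
#' @param n_cases Number of cases.
#' @param dirichlet_alpha Symmetric Dirichlet concentration (> 0).
#' @param entropy_shift_per_prompt Numeric, length `n_prompts` (a scalar is
#'   recycled); bits of entropy shift per prompt.
#' @param vmf_kappa von Mises-Fisher concentration (>= 0).
#' @param vmf_dim Embedding dimension (>= 2).
#' @param prompt_direction_separation Angle in radians (\[0, pi\]) between
#'   consecutive prompt mean directions.
#' @param stopword_fraction Fraction of the vocabulary drawn from the
#'   shipped stopword list, so stopword masking is exercised end to end.
#' @param temperature,top_k Generation parameters stamped into the log.
#' @param model_id,dataset_label Identifiers stamped into the log.
#' @param seed Master seed; every case-prompt combination derives its own
#'   substream, so enlarging `n_cases` never perturbs earlier cases.
#' @return A validated config list of class `"llmrr_synth_config"`.
#' @export
synth_config <- function(vocab_size = 100, run_length = 40, n_runs = 100,
                         n_prompts = 5, n_cases = 608, dirichlet_alpha = 0.05,
                         entropy_shift_per_prompt = 0, vmf_kappa = 300,
                         vmf_dim = 64, prompt_direction_separation = 0,
                         stopword_fraction = 0.2, temperature = 0.5,
                         top_k = 30, model_id = "synthetic-llm",
                         dataset_label = NA_character_, seed = 1) {
  shift <- rep_len(entropy_shift_per_prompt, n_prompts)
  cfg <- list(
    vocab_size = as.integer(vocab_size), run_length = as.integer(run_length),
    n_runs = as.integer(n_runs), n_prompts = as.integer(n_prompts),
    n_cases = as.integer(n_cases), dirichlet_alpha = dirichlet_alpha,
    entropy_shift_per_prompt = shift, vmf_kappa = vmf_kappa,
    vmf_dim = as.integer(vmf_dim),
    prompt_direction_separation = prompt_direction_separation,
    stopword_fraction = stopword_fraction, temperature = temperature,
    top_k = as.integer(top_k), model_id = model_id,
    dataset_label = dataset_label, seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      vocab_size >= 2, run_length >= 1, n_runs >= 1, n_prompts >= 1,
      n_cases >= 1, dirichlet_alpha > 0, vmf_kappa >= 0, vmf_dim >= 2,
      prompt_direction_separation >= 0, prompt_direction_separation <= pi,
      stopword_fraction >= 0, stopword_fraction < 1,
      temperature > 0, top_k >= 1
    )
  })
  structure(cfg, class = "llmrr_synth_config")
}

# Independent substream seed for one (case, prompt) cell; changing the
# number of cases or prompts never perturbs other cells' draws.
substream_seed <- function(master, case, prompt) {
  as.integer((as.double(master %% 65536) * 32749 +
                case * 131071 + prompt * 8191) %% 2147483647)
}

#' Draw one position's top-k candidate log-probabilities
#'
#' A probability vector over the vocabulary is drawn from a symmetric
#' Dirichlet(`alpha`) (via normalized gamma draws), sorted descending and
#' truncated to `top_k` candidates; the sampled token is drawn from the
#' truncated, renormalized distribution. Consumes the current RNG state.
#'
#' @param vocab_size Vocabulary size.
#' @param alpha Dirichlet concentration.
#' @param top_k Candidates to retain.
#' @param vocab Character vector of token strings, length `vocab_size`.
#' @return A list: `tokens` (candidate strings, descending by probability),
#'   `logprobs` (natural-log probabilities of the untruncated draw),
#'   `sampled_index` (1-based, within the candidates).
#' @export
sample_position_distribution <- function(vocab_size, alpha, top_k, vocab) {
  g <- rgamma(vocab_size, shape = alpha)
  if (sum(g) == 0) { # deep-underflow guard for extreme concentrations
    g[sample.int(vocab_size, 1)] <- 1
  }
  p <- g / sum(g)
  cand <- sample.int(vocab_size) # which token gets which mass
  ord <- order(p, decreasing = TRUE)
  keep <- ord[seq_len(min(top_k, vocab_size))]
  pk <- p[keep]
  idx <- sample.int(length(pk), 1, prob = pk)
  list(
    tokens = vocab[cand[keep]],
    logprobs = log(pmax(pk, 1e-300)),
    sampled_index = idx
  )
}

#' Draw from the von Mises-Fisher distribution on the unit sphere
#'
#' Wood's (1994) rejection scheme: the cosine `w` of the angle to the mean
#' direction is sampled via a beta envelope, a uniform direction is drawn
#' in the orthogonal complement, and the result is rotated onto
#' `mean_direction` by a Householder reflection. `kappa = 0` reduces to the
#' uniform distribution on the sphere. Consumes the current RNG state.
#'
#' @param n Number of draws.
#' @param mean_direction Unit vector (length `d >= 2`).
#' @param kappa Concentration (>= 0).
#' @return An `n x d` matrix of unit vectors.
#' @export
sample_vmf <- function(n, mean_direction, kappa) {
  d <- length(mean_direction)
  stopifnot(d >= 2, kappa >= 0,
            abs(sum(mean_direction^2) - 1) < 1e-8)
  out <- matrix(0, nrow = n, ncol = d)
  if (kappa == 0) {
    z <- matrix(rnorm(n * d), nrow = n)
    return(z / sqrt(rowSums(z^2)))
  }
  b <- (-2 * kappa + sqrt(4 * kappa^2 + (d - 1)^2)) / (d - 1)
  x0 <- (1 - b) / (1 + b)
  cc <- kappa * x0 + (d - 1) * log(1 - x0^2)
  # Householder reflection mapping e1 onto the mean direction
  e1 <- c(1, rep(0, d - 1))
  u <- e1 - mean_direction
  un <- sqrt(sum(u^2))
  reflect <- if (un < 1e-12) identity else {
    u <- u / un
    function(y) y - 2 * u * sum(u * y)
  }
  for (i in seq_len(n)) {
    repeat {
      z <- rbeta(1, (d - 1) / 2, (d - 1) / 2)
      w <- (1 - (1 + b) * z) / (1 - (1 - b) * z)
      if (kappa * w + (d - 1) * log(1 - x0 * w) - cc >= log(runif(1))) break
    }
    v <- rnorm(d - 1)
    v <- v / sqrt(sum(v^2))
    out[i, ] <- reflect(c(w, sqrt(max(1 - w^2, 0)) * v))
  }
  out
}

#' Simulate a synthetic experiment
#'
#' Generates the full factorial of `n_cases x n_prompts x n_runs` run
#' records described by a [synth_config()], together with a `"lookup"`
#' embedding backend mapping each run's (raw and stopword-filtered) text to
#' its von Mises-Fisher embedding, and a ground-truth sidecar for recovery
#' tests. Identical configs produce byte-identical logs.
#'
#' Synthetic tokens are pieces like `" tok0042"` (leading space, so the
#' text round-trips through whitespace-insensitive validation) with a
#' configurable fraction of real stopwords mixed into the vocabulary;
#' texts are the concatenated sampled tokens — deterministic functions of
#' the draw, which is all the embedding cache and masking tests need.
#'
#' @param config A [synth_config()].
#' @return A list with elements `runs` (run-log tibble), `backend`
#'   (`"lookup"` embedding backend), and `truth` (config echo, per-prompt
#'   mean directions, realized per-prompt mean entropies in bits, and the
#'   per-prompt effective Dirichlet alpha).
#' @export
simulate_runs <- function(config) {
  stopifnot(inherits(config, "llmrr_synth_config"))
  cfg <- config
  n_stop <- round(cfg$stopword_fraction * cfg$vocab_size)
  vocab <- paste0(" tok", formatC(seq_len(cfg$vocab_size), width = 4,
                                  flag = "0"))
  if (n_stop > 0) {
    sw <- rep_len(stopwords_en, n_stop)
    vocab[seq_len(n_stop)] <- paste0(" ", sw)
  }
  alpha_p <- cfg$dirichlet_alpha * 2^cfg$entropy_shift_per_prompt
  mu_p <- prompt_directions(cfg$n_prompts, cfg$vmf_dim,
                            cfg$prompt_direction_separation)

  emb_map <- new.env(parent = emptyenv())
  rows <- vector("list", cfg$n_cases * cfg$n_prompts)
  h_sum <- numeric(cfg$n_prompts)
  h_n <- numeric(cfg$n_prompts)
  cell <- 0L
  for (ca in seq_len(cfg$n_cases)) {
    for (pr in seq_len(cfg$n_prompts)) {
      cell <- cell + 1L
      res <- withr::with_seed(
        substream_seed(cfg$seed, ca, pr),
        simulate_cell(cfg, ca, pr, vocab, alpha_p[[pr]], mu_p[pr, ], emb_map)
      )
      rows[[cell]] <- res$runs
      h_sum[pr] <- h_sum[pr] + res$h_sum
      h_n[pr] <- h_n[pr] + res$h_n
    }
  }
  runs <- dplyr::bind_rows(rows)
  map <- as.list(emb_map)
  map <- map[sort(names(map))]
  list(
    runs = runs,
    backend = backend_lookup(map, name = "lookup-synthetic"),
    truth = list(
      config = unclass(cfg),
      prompt_mean_directions = mu_p,
      alpha_per_prompt = alpha_p,
      realized_mean_entropy_bits = h_sum / pmax(h_n, 1)
    )
  )
}

# One case-prompt cell: R runs plus their embeddings, inside the cell's
# own RNG substream. Returns the rows and the cell's entropy tally.
simulate_cell <- function(cfg, ca, pr, vocab, alpha, mu, emb_map) {
  emb <- sample_vmf(cfg$n_runs, mu, cfg$vmf_kappa)
  run_rows <- vector("list", cfg$n_runs)
  h_sum <- 0
  for (ri in seq_len(cfg$n_runs)) {
    toks <- character(cfg$run_length)
    lps <- vector("list", cfg$run_length)
    si <- integer(cfg$run_length)
    for (j in seq_len(cfg$run_length)) {
      pos <- sample_position_distribution(
        cfg$vocab_size, alpha, cfg$top_k, vocab)
      lp <- pos$logprobs
      names(lp) <- pos$tokens
      lps[[j]] <- lp
      si[[j]] <- pos$sampled_index
      toks[[j]] <- pos$tokens[[pos$sampled_index]]
      p <- topk_renormalize(exp(lp - max(lp)), cfg$top_k)
      h_sum <- h_sum + position_entropy(p)
    }
    text <- trimws(paste0(toks, collapse = ""))
    register_embedding(emb_map, text, emb[ri, ])
    filt <- filter_stopwords_text(text)
    if (nzchar(filt)) register_embedding(emb_map, filt, emb[ri, ])
    run_rows[[ri]] <- tibble(
      run_id = sprintf("case%04d-prompt%d-run%04d", ca, pr, ri),
      case_id = sprintf("case%04d", ca),
      prompt_id = sprintf("prompt%d", pr),
      model_id = cfg$model_id,
      temperature = cfg$temperature,
      top_k = cfg$top_k,
      dataset_label = cfg$dataset_label,
      text = text,
      tokens = list(toks),
      logprobs = list(lps),
      sampled_index = list(si)
    )
  }
  list(runs = dplyr::bind_rows(run_rows),
       h_sum = h_sum, h_n = cfg$n_runs * cfg$run_length)
}

# First registration wins: if two runs produce byte-identical text they
# must share one embedding (the cache contract), and determinism of the
# map then follows from generation order.
register_embedding <- function(env, text, vector) {
  if (!exists(text, envir = env, inherits = FALSE)) {
    assign(text, vector, envir = env)
  }
}

# Prompt mean directions: consecutive prompts separated by `angle` along a
# great circle in the plane of the first two coordinates.
prompt_directions <- function(n_prompts, dim, angle) {
  t(vapply(seq_len(n_prompts) - 1, function(j) {
    c(cos(j * angle), sin(j * angle), rep(0, dim - 2))
  }, numeric(dim)))
}

#' Experiment-plan bookkeeping
#'
#' Total generations of a full factorial design: `P x C x M x R` runs over
#' prompts, cases, models and repeats.
#'
#' @param n_prompts,n_cases,n_models,n_runs Positive integers.
#' @return A one-row tibble with the four factors and `total_generations`.
#' @examples
#' plan_experiment(n_prompts = 5, n_cases = 608, n_models = 3, n_runs = 100)
#' @export
plan_experiment <- function(n_prompts, n_cases, n_models, n_runs) {
  vals <- c(n_prompts = n_prompts, n_cases = n_cases,
            n_models = n_models, n_runs = n_runs)
  if (any(vals < 1) || any(vals != round(vals))) {
    abort("all plan factors must be positive integers")
  }
  tibble(
    n_prompts = as.integer(n_prompts), n_cases = as.integer(n_cases),
    n_models = as.integer(n_models), n_runs = as.integer(n_runs),
    total_generations = as.double(n_prompts) * n_cases * n_models * n_runs
  )
}
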