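#' Temperature-scaled softmax
#'
#' Converts a vector of logits into a probability distribution,
#' `exp(z/T) / sum(exp(z'/T))`, using max-subtraction for numerical
#' stability. Lower temperature concentrates probability mass on the top
#' logits; the distribution is invariant to adding a constant to all logits.
#'
#' @param logits Finite numeric vector.
#' @param temperature Positive scalar `T`. The `T = 0` (argmax) limit is not
#'   taken here; pass the one-hot distribution directly if you need it.
#' @return Numeric probability vector, positive and summing to 1.
#' @examples
#' temperature_softmax(c(log(2), 0, 0), 1) # 0.5, 0.25, 0.25
#' @export
temperature_softmax <- function(logits, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      !is.finite(temperature) || temperature <= 0) {
    abort("`temperature` must be a single positive number")
  }
  if (any(!is.finite(logits))) abort("`logits` must be finite")
  z <- logits / temperature
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Truncate a distribution to its top-k tokens and renormalize
#'
#' Retains the `k` largest probabilities (ties broken by original order, so
#' candidate lists already sorted by the provider stay stable) and rescales
#' them to sum to 1. With `k` at least the support size the distribution is
#' returned unchanged.
#'
#' @param probs Numeric probability vector (non-negative, summing to 1).
#' @param k Positive integer.
#' @return Renormalized numeric vector over the retained tokens, in their
#'   original order; its length is the effective support size
#'   `min(k, length(probs))`.
#' @examples
#' topk_renormalize(c(0.5, 0.3, 0.2), 2) # 0.625, 0.375
#' @export
topk_renormalize <- function(probs, k) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    abort("`k` must be a positive integer")
  }
  if (k >= length(probs)) {
    return(probs / sum(probs))
  }
  keep <- sort(head(order(probs, decreasing = TRUE), k))
  p <- probs[keep]
  p / sum(p)
}

#' Shannon entropy of a token distribution, in bits
#'
#' `-sum(p * log2(p))` with the `0 * log(0) = 0` convention. Zero for a
#' one-hot distribution; `log2(k)` for uniform over `k` tokens. Base 2 is
#' used throughout the package so that the internal scores, normalized by
#' `log2(k)`, span exactly \[0, 1\].
#'
#' @param probs Numeric probability vector.
#' @return Entropy in bits.
#' @examples
#' position_entropy(c(0.5, 0.25, 0.25)) # 1.5 bits
#' @export
position_entropy <- function(probs) {
  p <- probs[probs > 0]
  -sum(p * log2(p))
}

# Per-position distributions of one run from its logged candidate
# log-probabilities. When the log stores provider-normalized
# log-probabilities (the usual API case) the temperature is already baked
# in, so only exponentiation and top-k renormalization apply; when it
# stores raw logits the full temperature-scaled softmax pipeline runs.
position_distributions <- function(logprobs, k, logprobs_post_temperature,
                                   temperature) {
  lapply(logprobs, function(lp) {
    if (logprobs_post_temperature) {
      p <- exp(lp - max(lp))
      p <- p / sum(p)
    } else {
      p <- temperature_softmax(lp, temperature)
    }
    topk_renormalize(p, k)
  })
}

#' Per-position entropies and their run mean
#'
#' Computes the entropy (bits) of the top-k token distribution at every
#' usable position of one run, and their arithmetic mean. Positions are
#' excluded when masked (stopwords, see [stopword_position_mask()]) or when
#' the sampled token fell outside the logged top-k (`NA` in
#' `sampled_index`): a truncated distribution that does not even contain
#' its own sample would bias the entropy estimate.
#'
#' @param logprobs List of per-position numeric vectors of candidate
#'   log-probabilities, sorted non-increasing (one run's `logprobs` cell of
#'   a [run_log] tibble).
#' @param k Top-k truncation parameter.
#' @param mask Optional logical vector, `TRUE` to exclude a position.
#' @param sampled_index Optional integer vector; `NA` entries mark
#'   positions whose sample was outside the logged candidates (excluded).
#' @param logprobs_post_temperature If `TRUE` (the API-log default) the
#'   logged values are provider-normalized log-probabilities and are only
#'   exponentiated; if `FALSE` they are raw logits and the
#'   temperature-scaled softmax is applied first.
#' @param temperature Temperature for the raw-logit path.
#' @param run_id Identifier used in error messages.
#' @return A list of class `"entropy_summary"` with `per_position` (bits,
#'   usable positions only), `run_mean` (bits) and `positions_used`.
#' @export
run_entropy <- function(logprobs, k, mask = NULL, sampled_index = NULL,
                        logprobs_post_temperature = TRUE, temperature = NULL,
                        run_id = "<run>") {
  use <- rep(TRUE, length(logprobs))
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(logprobs))
    use <- use & !mask
  }
  if (!is.null(sampled_index)) {
    stopifnot(length(sampled_index) == length(logprobs))
    use <- use & !is.na(sampled_index)
  }
  if (!any(use)) {
    abort(paste0("empty run: no usable position in run `", run_id,
                 "` after exclusions"))
  }
  dists <- position_distributions(logprobs[use], k,
                                  logprobs_post_temperature, temperature)
  h <- vapply(dists, position_entropy, numeric(1))
  structure(
    list(per_position = h, run_mean = mean(h), positions_used = sum(use)),
    class = "entropy_summary"
  )
}

#' @export
print.entropy_summary <- function(x, ...) {
  cat(sprintf("<entropy_summary> mean %.4f bits over %d positions\n",
              x$run_mean, x$positions_used))
  invisible(x)
}

# 1 - raw / log2(k), clamped to [0, 1]. A single-candidate distribution
# (k = 1) is perfectly deterministic, so the score is 1 by continuity.
# Clamps larger than rounding noise indicate a logic error upstream.
entropy_score <- function(raw, k) {
  norm <- log2(k)
  clamp01(ifelse(norm == 0, 1, 1 - raw / ifelse(norm == 0, 1, norm)))
}

clamp01 <- function(x) {
  excess <- pmax(x - 1, -x, 0)
  if (any(excess > 1e-6)) {
    warn(sprintf("score clamped by %.3g; check inputs", max(excess)))
  }
  pmin(pmax(x, 0), 1)
}

# Mean per-run entropy H_r for every run, as an extra column on the log.
run_mean_entropies <- function(runs, k, stopwords, mask_stopwords,
                               logprobs_post_temperature) {
  h <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    mask <- if (mask_stopwords) {
      stopword_position_mask(runs$tokens[[i]], stopwords)
    }
    ki <- if (is.null(k)) runs$top_k[[i]] else k
    es <- run_entropy(
      runs$logprobs[[i]], ki, mask = mask,
      sampled_index = runs$sampled_index[[i]],
      logprobs_post_temperature = logprobs_post_temperature,
      temperature = runs$temperature[[i]], run_id = runs$run_id[[i]]
    )
    h[[i]] <- es$run_mean
  }
  dplyr::mutate(runs, .run_entropy = h)
}

#' Internal repeatability score
#'
#' Stability of the token-generating process across repeated runs under
#' identical conditions. For each run set, the per-run mean entropy `H_r`
#' (bits, over usable positions) is averaged over the `R` runs to give the
#' raw value, then rescaled: `score = 1 - raw / log2(k)`, clamped to
#' \[0, 1\]. Uniform top-k distributions everywhere give 0; one-hot
#' distributions give 1.
#'
#' @param runs A run-log tibble (see [run_log]); may hold many run sets.
#' @param k Top-k normalizer; defaults to each run set's logged `top_k`.
#' @param stopwords Stopword list used when `mask_stopwords = TRUE`.
#' @param mask_stopwords Exclude stopword token positions from the entropy
#'   average (default `TRUE`).
#' @param logprobs_post_temperature See [run_entropy()].
#' @return A tibble with one row per run set: the key columns, `n_runs`,
#'   `k`, `raw` (mean entropy, bits) and `score`.
#' @export
internal_repeatability <- function(runs, k = NULL,
                                   stopwords = stopwords_en,
                                   mask_stopwords = TRUE,
                                   logprobs_post_temperature = TRUE) {
  if (nrow(runs) == 0) abort("empty run log")
  runs <- run_mean_entropies(runs, k, stopwords, mask_stopwords,
                             logprobs_post_temperature)
  runs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(runset_keys))) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      k = if (is.null(k)) .data$top_k[[1]] else as.integer(k),
      raw = mean(.data$.run_entropy),
      .groups = "drop"
    ) |>
    dplyr::mutate(score = entropy_score(.data$raw, .data$k))
}

#' Internal reproducibility score
#'
#' Robustness of the token-generating process to changing the prompt. For
#' each prompt `p` of a family, the mean entropy over its runs gives
#' `Hbar(p)`; the raw value is the mean absolute difference of `Hbar` over
#' all `P(P-1)/2` prompt pairs, and `score = 1 - raw / log2(k)`, clamped.
#' Prompts with identical mean entropy — however high — score exactly 1:
#' the quantity measures *agreement across prompts*, not determinism.
#'
#' @inheritParams internal_repeatability
#' @return A tibble with one row per prompt family: the family key columns,
#'   `n_prompts`, `k`, `raw` (bits) and `score`.
#' @export
internal_reproducibility <- function(runs, k = NULL,
                                     stopwords = stopwords_en,
                                     mask_stopwords = TRUE,
                                     logprobs_post_temperature = TRUE) {
  fams <- prompt_families(runs)
  if (any(!fams$eligible)) {
    abort(paste0("insufficient prompts: reproducibility needs >= 2 prompts ",
                 "per family; offending case(s): ",
                 paste(fams$case_id[!fams$eligible], collapse = ", ")))
  }
  runs <- run_mean_entropies(runs, k, stopwords, mask_stopwords,
                             logprobs_post_temperature)
  per_prompt <- runs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(runset_keys))) |>
    dplyr::summarise(h_bar = mean(.data$.run_entropy),
                     k = if (is.null(k)) .data$top_k[[1]] else as.integer(k),
                     .groups = "drop")
  per_prompt |>
    dplyr::group_by(dplyr::across(dplyr::all_of(family_keys))) |>
    dplyr::summarise(
      n_prompts = dplyr::n(),
      k = .data$k[[1]],
      raw = mean_abs_pairwise_diff(.data$h_bar),
      .groups = "drop"
    ) |>
    dplyr::mutate(score = entropy_score(.data$raw, .data$k))
}

mean_abs_pairwise_diff <- function(x) {
  mean(as.numeric(stats::dist(matrix(x, ncol = 1), method = "manhattan")))
}
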