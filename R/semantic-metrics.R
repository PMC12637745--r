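#' Semantic repeatability score
#'
#' Consistency of output *meaning* across repeated runs under identical
#' conditions. Each run's text is stopword-filtered (by default), embedded
#' once (cached by exact filtered text), and the raw value is the mean
#' pairwise cosine similarity over the `R` run embeddings; the score
#' rescales it to \[0, 1\] as `(raw + 1) / 2`. Verbatim-identical runs
#' score exactly 1; mutually orthogonal embeddings score 0.5.
#'
#' @param runs A run-log tibble (see [run_log]); may hold many run sets,
#'   each needing at least 2 runs.
#' @param backend An embedding backend (see [embedding_backends]).
#' @param stopwords Stopword list used when `filter_stopwords = TRUE`.
#' @param filter_stopwords Remove stopwords from the text before embedding
#'   (default `TRUE`).
#' @return A tibble with one row per run set: the key columns, `n_runs`,
#'   `raw` (mean pairwise cosine) and `score`.
#' @export
semantic_repeatability <- function(runs, backend, stopwords = stopwords_en,
                                   filter_stopwords = TRUE) {
  if (nrow(runs) == 0) abort("empty run log")
  runs <- embed_runs(runs, backend, stopwords, filter_stopwords)
  runs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(runset_keys))) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      raw = mean_pairwise_cosine(do.call(rbind, .data$.embedding)),
      .groups = "drop"
    ) |>
    dplyr::mutate(score = (.data$raw + 1) / 2)
}

# Filter, embed and attach an .embedding list-column. Empty filtered text
# cannot be embedded meaningfully; fail loudly with the run ids.
embed_runs <- function(runs, backend, stopwords, filter_stopwords) {
  texts <- if (filter_stopwords) {
    filter_stopwords_text(runs$text, stopwords)
  } else {
    runs$text
  }
  empty <- !nzchar(texts)
  if (any(empty)) {
    abort(paste0("empty filtered text for run(s): ",
                 paste(runs$run_id[empty], collapse = ", ")))
  }
  emb <- embed_text(backend, texts)
  dplyr::mutate(runs,
                .embedding = lapply(seq_len(nrow(emb)), function(i) emb[i, ]))
}

#' Mean embedding of one run set
#'
#' Coordinate-wise arithmetic mean of the run embeddings — the
#' prompt-specific centroid the reproducibility score compares across
#' prompts. By default raw embeddings are averaged; set
#' `l2_normalize_before_mean = TRUE` for direction-only averaging (then the
#' centroid is the mean of unit vectors, which discounts magnitude).
#'
#' @param runs A run-log tibble holding a single run set (one prompt).
#' @inheritParams semantic_repeatability
#' @param l2_normalize_before_mean Normalize each embedding to unit length
#'   before averaging (default `FALSE`: average raw vectors).
#' @return A numeric vector of length `backend$dimension`. The mean can
#'   have zero norm under exact antipodal cancellation; that is flagged
#'   where the vector is later used in a cosine.
#' @export
prompt_mean_embedding <- function(runs, backend, stopwords = stopwords_en,
                                  filter_stopwords = TRUE,
                                  l2_normalize_before_mean = FALSE) {
  if (nrow(runs) == 0) abort("empty run set")
  runs <- embed_runs(runs, backend, stopwords, filter_stopwords)
  m <- do.call(rbind, runs$.embedding)
  if (l2_normalize_before_mean) {
    m <- m / sqrt(rowSums(m^2))
  }
  colMeans(m)
}

#' Semantic reproducibility score
#'
#' Consistency of output meaning across *different* prompts for the same
#' case, model and parameters. Each prompt's runs are embedded and averaged
#' into a prompt centroid ([prompt_mean_embedding()]); the raw value is the
#' mean pairwise cosine over the `P` centroids and the score is
#' `(raw + 1) / 2`.
#'
#' @inheritParams prompt_mean_embedding
#' @param runs A run-log tibble; every prompt family needs >= 2 prompts.
#' @return A tibble with one row per prompt family: the family key columns,
#'   `n_prompts`, `raw` and `score`.
#' @export
semantic_reproducibility <- function(runs, backend, stopwords = stopwords_en,
                                     filter_stopwords = TRUE,
                                     l2_normalize_before_mean = FALSE) {
  fams <- prompt_families(runs)
  if (any(!fams$eligible)) {
    abort(paste0("insufficient prompts: reproducibility needs >= 2 prompts ",
                 "per family; offending case(s): ",
                 paste(fams$case_id[!fams$eligible], collapse = ", ")))
  }
  runs <- embed_runs(runs, backend, stopwords, filter_stopwords)
  centroids <- runs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(runset_keys))) |>
    dplyr::summarise(.centroid = {
      m <- do.call(rbind, .data$.embedding)
      if (l2_normalize_before_mean) m <- m / sqrt(rowSums(m^2))
      list(colMeans(m))
    }, .groups = "drop")
  centroids |>
    dplyr::group_by(dplyr::across(dplyr::all_of(family_keys))) |>
    dplyr::summarise(
      n_prompts = dplyr::n(),
      raw = {
        m <- do.call(rbind, .data$.centroid)
        zero <- sqrt(rowSums(m^2)) == 0
        if (any(zero)) {
          abort(paste0("zero-norm mean embedding for prompt(s): ",
                       paste(.data$prompt_id[zero], collapse = ", ")))
        }
        mean_pairwise_cosine(m)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(score = (.data$raw + 1) / 2)
}
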