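#' Score every eligible unit of a run log
#'
#' The main entry point: computes the four scores for a whole run log in
#' one pass. Each run set (>= 2 runs) yields one *repeatability* row with
#' its semantic and internal scores; each prompt family (>= 2 prompts)
#' yields one *reproducibility* row (`prompt_id` is `NA` there, since the
#' score aggregates over prompts). Units too small to score are never
#' silently dropped: they are listed in the skip report available via
#' [skipped_units()].
#'
#' @param runs A run-log tibble (see [run_log]).
#' @param backend An embedding backend (see [embedding_backends]).
#' @param k Top-k entropy normalizer; default: each unit's logged `top_k`.
#' @param stopwords Stopword list.
#' @param filter_semantic Remove stopwords from text before embedding.
#' @param mask_internal Exclude stopword positions from entropy averaging.
#' @param logprobs_post_temperature See [run_entropy()].
#' @return A tibble of class `"llm_scores"` with columns `case_id`,
#'   `prompt_id`, `model_id`, `temperature`, `top_k`, `dataset_label`,
#'   `metric_kind` (`"repeatability"` or `"reproducibility"`), `semantic`
#'   and `internal` (both in \[0, 1\]). Attributes: `"skipped"` (tibble of
#'   ineligible units with reasons) and `"config"` (the full scoring
#'   configuration, stamped into files written by [write_scores()]).
#' @export
score_runs <- function(runs, backend, k = NULL, stopwords = stopwords_en,
                       filter_semantic = TRUE, mask_internal = TRUE,
                       logprobs_post_temperature = TRUE) {
  if (nrow(runs) == 0) abort("empty run log")
  sets <- run_sets(runs)
  fams <- prompt_families(runs)

  skipped <- dplyr::bind_rows(
    sets |>
      dplyr::filter(!.data$eligible) |>
      dplyr::mutate(unit = "run_set",
                    reason = paste0("needs >= 2 runs, has ", .data$n_runs)) |>
      dplyr::select(dplyr::all_of(c("unit", runset_keys, "reason"))),
    fams |>
      dplyr::filter(!.data$eligible) |>
      dplyr::mutate(unit = "prompt_family", prompt_id = NA_character_,
                    reason = paste0("needs >= 2 prompts, has ",
                                    .data$n_prompts)) |>
      dplyr::select(dplyr::all_of(c("unit", runset_keys, "reason")))
  )

  labels <- runs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(runset_keys))) |>
    dplyr::summarise(dataset_label = .data$dataset_label[[1]],
                     .groups = "drop")

  rpt_runs <- dplyr::semi_join(runs, dplyr::filter(sets, .data$eligible),
                               by = runset_keys)
  rpt <- NULL
  if (nrow(rpt_runs) > 0) {
    sem <- semantic_repeatability(rpt_runs, backend, stopwords,
                                  filter_stopwords = filter_semantic)
    int <- internal_repeatability(rpt_runs, k, stopwords,
                                  mask_stopwords = mask_internal,
                                  logprobs_post_temperature =
                                    logprobs_post_temperature)
    rpt <- sem |>
      dplyr::select(dplyr::all_of(runset_keys), semantic = "score") |>
      dplyr::left_join(
        dplyr::select(int, dplyr::all_of(runset_keys), internal = "score"),
        by = runset_keys
      ) |>
      dplyr::left_join(labels, by = runset_keys) |>
      dplyr::mutate(metric_kind = "repeatability")
  }

  fam_runs <- dplyr::semi_join(runs, dplyr::filter(fams, .data$eligible),
                               by = family_keys)
  rpd <- NULL
  if (nrow(fam_runs) > 0) {
    sem <- semantic_reproducibility(fam_runs, backend, stopwords,
                                    filter_stopwords = filter_semantic)
    int <- internal_reproducibility(fam_runs, k, stopwords,
                                    mask_stopwords = mask_internal,
                                    logprobs_post_temperature =
                                      logprobs_post_temperature)
    fam_labels <- labels |>
      dplyr::group_by(dplyr::across(dplyr::all_of(family_keys))) |>
      dplyr::summarise(dataset_label = .data$dataset_label[[1]],
                       .groups = "drop")
    rpd <- sem |>
      dplyr::select(dplyr::all_of(family_keys), semantic = "score") |>
      dplyr::left_join(
        dplyr::select(int, dplyr::all_of(family_keys), internal = "score"),
        by = family_keys
      ) |>
      dplyr::left_join(fam_labels, by = family_keys) |>
      dplyr::mutate(prompt_id = NA_character_,
                    metric_kind = "reproducibility")
  }

  out <- dplyr::bind_rows(rpt, rpd)
  if (nrow(out) == 0) abort("no eligible unit to score (see skip report)")
  out <- out |>
    dplyr::select(dplyr::all_of(c(
      "case_id", "prompt_id", "model_id", "temperature", "top_k",
      "dataset_label", "metric_kind", "semantic", "internal"
    ))) |>
    dplyr::arrange(.data$metric_kind, .data$case_id, .data$model_id,
                   .data$prompt_id)
  structure(
    out,
    skipped = skipped,
    config = list(
      package_version = as.character(packageVersion("llmrr")),
      backend = backend$name,
      k = if (is.null(k)) "per-unit top_k" else k,
      n_stopwords = length(stopwords),
      filter_semantic = filter_semantic,
      mask_internal = mask_internal,
      logprobs_post_temperature = logprobs_post_temperature
    ),
    class = c("llm_scores", class(out))
  )
}

#' Skip report of a scores table
#'
#' Units too small to score (run sets with a single run, families with a
#' single prompt), with reasons.
#'
#' @param scores A `"llm_scores"` tibble from [score_runs()].
#' @return A tibble; zero rows when nothing was skipped.
#' @export
skipped_units <- function(scores) {
  attr(scores, "skipped") %||% tibble()
}

#' Write a scores table to CSV
#'
#' The first line is a `#` comment embedding the scoring configuration and
#' package version as JSON; score columns are formatted with 10
#' significant digits so repeated runs produce byte-identical files.
#'
#' @param scores A `"llm_scores"` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  cfg <- attr(scores, "config") %||% list()
  header <- paste0("# llmrr ", jsonlite::toJSON(cfg, auto_unbox = TRUE))
  body <- scores |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(c("temperature", "semantic", "internal")),
      ~ formatC(.x, digits = 10, format = "g")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con, useBytes = TRUE)
  writeLines(readr::format_csv(body, na = ""), con, sep = "",
             useBytes = TRUE)
  invisible(path)
}

#' Read a scores table written by [write_scores()]
#'
#' @param path Path to the CSV.
#' @return A `"llm_scores"` tibble; the embedded configuration is restored
#'   into the `"config"` attribute.
#' @export
read_scores <- function(path) {
  first <- readLines(path, n = 1)
  cfg <- if (startsWith(first, "# llmrr ")) {
    jsonlite::fromJSON(sub("^# llmrr ", "", first))
  }
  out <- readr::read_csv(
    path, comment = "#", na = "",
    col_types = readr::cols(
      case_id = "c", prompt_id = "c", model_id = "c", temperature = "d",
      top_k = "i", dataset_label = "c", metric_kind = "c",
      semantic = "d", internal = "d", .default = "c"
    )
  )
  structure(out, config = cfg, class = c("llm_scores", class(out)))
}

#' Scatter plot of score pairs
#'
#' One point per scored unit in the (semantic, internal) plane, faceted by
#' metric kind — the package's basic diagnostic view of how consistency
#' distributes across cases.
#'
#' @param object A `"llm_scores"` tibble.
#' @param colour Column name to map to colour (default `"model_id"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot llm_scores
#' @export
autoplot.llm_scores <- function(object, colour = "model_id", ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$semantic, y = .data$internal,
    colour = .data[[colour]]
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric_kind)) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "semantic score", y = "internal score",
                  colour = colour) +
    ggplot2::theme_minimal()
}

#' Write group-comparison results to JSON
#'
#' Serializes a [compare_groups()] table (dropping the list-column of fit
#' objects but keeping group sizes and medians), stamped with the package
#' version and any scoring configuration carried by `scores_config`.
#'
#' @param comparison A tibble from [compare_groups()].
#' @param path Output path.
#' @param scores_config Optional configuration list to embed (e.g.
#'   `attr(scores, "config")`).
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path, scores_config = NULL) {
  tests <- lapply(comparison$test, function(t) {
    list(
      statistic = t$statistic, p_value = t$p_value,
      p_asymptotic = t$p_asymptotic, df = t$df, n_groups = t$n_groups,
      n_per_group = t$n_per_group, group_medians = t$group_medians,
      n_permutations = t$n_permutations, seed = t$seed,
      exhaustive = t$exhaustive
    )
  })
  names(tests) <- comparison$metric_kind
  out <- list(
    package_version = as.character(packageVersion("llmrr")),
    scores_config = scores_config,
    results = tests
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(10),
                       pretty = TRUE, na = "null")
  invisible(path)
}
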