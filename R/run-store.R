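#' @title Run logs as tibbles
#'
#' @description
#' A *run log* holds repeated generations from a language model, one row per
#' run, with the per-position top-k candidate log-probabilities the
#' completion APIs return. Columns:
#'
#' * `run_id`, `case_id`, `prompt_id`, `model_id` — opaque identifiers.
#' * `temperature`, `top_k` — the sampling parameters of the run.
#' * `dataset_label` — optional label (e.g. the case source); `NA` if absent.
#' * `text` — the generated output string.
#' * `tokens` — list-column; character vector of generated token pieces.
#' * `logprobs` — list-column; one numeric vector per position, named by
#'   candidate token, sorted non-increasing (the logged top-k candidates).
#' * `sampled_index` — list-column; integer vector giving, per position, the
#'   1-based index of the generated token among the candidates, or `NA` when
#'   the sampled token fell outside the logged top-k.
#'
#' The *repeatability* unit (a run set) is the group of rows sharing
#' `(case_id, prompt_id, model_id, temperature, top_k)`; the
#' *reproducibility* unit (a prompt family) drops `prompt_id`. Free-form
#' metadata never enters the grouping: repeatability is defined by the
#' sampling-relevant parameters only.
#'
#' @name run_log
#' @seealso [read_runs()], [write_runs()], [run_sets()], [prompt_families()]
NULL

runset_keys <- c("case_id", "prompt_id", "model_id", "temperature", "top_k")
family_keys <- c("case_id", "model_id", "temperature", "top_k")

#' Read a run log from JSON Lines
#'
#' Each line is one JSON object:
#' `{"run_id", "case_id", "prompt_id", "model_id",
#' "params": {"temperature", "top_k"}, "text", "tokens": [...],
#' "logprobs": [[{"token", "logprob"}, ...], ...], "sampled_index": [...]}`
#' with `sampled_index` 0-based (`null` when the sampled token was not among
#' the logged candidates) and an optional `"dataset_label"`. The dialect is
#' deliberately close to commercial completion-API responses so adapters
#' stay thin.
#'
#' @param path Path to a JSONL file (UTF-8).
#' @param validate Validate invariants after parsing (default `TRUE`).
#' @return A run-log tibble (see [run_log]); rows in file order.
#' @export
read_runs <- function(path, validate = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("run log not found: ", path))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) {
        abort(paste0("parse error at line ", i, " of ", path, ": ",
                     conditionMessage(e)))
      }
    )
    rows[[i]] <- tryCatch(
      parse_run_record(rec),
      error = function(e) {
        abort(paste0("invalid record at line ", i, " of ", path, ": ",
                     conditionMessage(e)))
      }
    )
  }
  runs <- dplyr::bind_rows(rows)
  if (validate) validate_runs(runs)
  runs
}

parse_run_record <- function(rec) {
  for (f in c("run_id", "case_id", "prompt_id", "model_id", "params",
              "text", "tokens", "logprobs")) {
    if (is.null(rec[[f]])) abort(paste0("missing field `", f, "`"))
  }
  tokens <- vapply(rec$tokens, as.character, character(1))
  lps <- lapply(rec$logprobs, function(pos) {
    lp <- vapply(pos, function(cand) as.numeric(cand$logprob), numeric(1))
    names(lp) <- vapply(pos, function(cand) as.character(cand$token),
                        character(1))
    lp
  })
  si <- rec$sampled_index %||% rep(list(NULL), length(lps))
  sampled <- vapply(si, function(x) {
    if (is.null(x)) NA_integer_ else as.integer(x) + 1L
  }, integer(1))
  tibble(
    run_id = as.character(rec$run_id),
    case_id = as.character(rec$case_id),
    prompt_id = as.character(rec$prompt_id),
    model_id = as.character(rec$model_id),
    temperature = as.numeric(rec$params$temperature),
    top_k = as.integer(rec$params$top_k),
    dataset_label = as.character(rec$dataset_label %||% NA_character_),
    text = as.character(rec$text),
    tokens = list(tokens),
    logprobs = list(lps),
    sampled_index = list(sampled)
  )
}

#' Write a run log to JSON Lines
#'
#' Inverse of [read_runs()]: log-probabilities are serialized with 17
#' significant digits so a write/read round trip reproduces the stored
#' doubles exactly.
#'
#' @param runs A run-log tibble (see [run_log]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_runs <- function(runs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(runs))) {
    rec <- list(
      run_id = runs$run_id[[i]],
      case_id = runs$case_id[[i]],
      prompt_id = runs$prompt_id[[i]],
      model_id = runs$model_id[[i]],
      params = list(temperature = runs$temperature[[i]],
                    top_k = runs$top_k[[i]]),
      text = runs$text[[i]],
      tokens = as.list(runs$tokens[[i]]),
      logprobs = lapply(runs$logprobs[[i]], function(lp) {
        unname(Map(function(tok, v) list(token = tok, logprob = v),
                   names(lp), as.list(unname(lp))))
      }),
      sampled_index = lapply(runs$sampled_index[[i]], function(x) {
        if (is.na(x)) NULL else x - 1L
      })
    )
    if (!is.na(runs$dataset_label[[i]])) {
      rec$dataset_label <- runs$dataset_label[[i]]
    }
    json <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17),
                             null = "null")
    writeLines(json, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Validate run-log invariants
#'
#' Checks, for every run: `tokens` and `logprobs` have equal length; every
#' candidate token is non-empty with a finite log-probability; candidates
#' are sorted non-increasing by log-probability; `sampled_index` is `NA` or
#' within the candidate range; `temperature > 0`, `top_k >= 1`, and no
#' logged position holds more than `top_k` candidates; the text equals the
#' concatenated tokens up to whitespace; and `run_id` is unique within each
#' run set. Positions whose sampled token fell outside the logged top-k are
#' legitimate (some APIs log this way) and are merely counted.
#'
#' @param runs A run-log tibble.
#' @return `runs`, invisibly. A warning reports the number of
#'   sampled-outside-top-k positions, if any; invariant violations abort
#'   with the offending `run_id` and field.
#' @export
validate_runs <- function(runs) {
  fail <- function(id, field, msg) {
    abort(paste0("run `", id, "`: invalid `", field, "`: ", msg))
  }
  n_absent <- 0L
  for (i in seq_len(nrow(runs))) {
    id <- runs$run_id[[i]]
    toks <- runs$tokens[[i]]
    lps <- runs$logprobs[[i]]
    si <- runs$sampled_index[[i]]
    if (!isTRUE(runs$temperature[[i]] > 0)) {
      fail(id, "temperature", "must be > 0")
    }
    if (!isTRUE(runs$top_k[[i]] >= 1)) fail(id, "top_k", "must be >= 1")
    if (length(toks) != length(lps)) {
      fail(id, "logprobs", sprintf(
        "length %d does not match %d tokens", length(lps), length(toks)))
    }
    if (length(si) != length(lps)) {
      fail(id, "sampled_index", "length does not match positions")
    }
    for (j in seq_along(lps)) {
      lp <- lps[[j]]
      if (length(lp) < 1) fail(id, "logprobs", paste0("position ", j, " empty"))
      if (length(lp) > runs$top_k[[i]]) {
        fail(id, "logprobs", paste0("position ", j, " has more than top_k (",
                                    runs$top_k[[i]], ") candidates"))
      }
      if (any(!nzchar(names(lp)))) {
        fail(id, "logprobs", paste0("empty candidate token at position ", j))
      }
      if (any(!is.finite(lp))) {
        fail(id, "logprobs", paste0("non-finite value at position ", j))
      }
      if (is.unsorted(-lp)) {
        fail(id, "logprobs", paste0("position ", j,
                                    " not sorted by descending logprob"))
      }
      if (is.na(si[[j]])) {
        n_absent <- n_absent + 1L
      } else if (si[[j]] < 1 || si[[j]] > length(lp)) {
        fail(id, "sampled_index", paste0("position ", j, " out of range"))
      }
    }
    squash <- function(x) gsub("[[:space:]]+", "", x)
    if (!identical(squash(runs$text[[i]]),
                   squash(paste0(toks, collapse = "")))) {
      fail(id, "text", "does not match concatenated tokens")
    }
  }
  dup <- runs |>
    dplyr::count(dplyr::across(dplyr::all_of(c(runset_keys, "run_id")))) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    fail(dup$run_id[[1]], "run_id", "duplicated within its run set")
  }
  if (n_absent > 0) {
    warn(paste0(n_absent, " position(s) have a sampled token outside the ",
                "logged top-k; they are excluded from entropy computation"))
  }
  invisible(runs)
}

#' Summarize run sets (repeatability units)
#'
#' One row per `(case_id, prompt_id, model_id, temperature, top_k)` group
#' with the run count and whether the group is eligible for repeatability
#' scoring (at least 2 runs).
#'
#' @param runs A run-log tibble.
#' @return A tibble with the key columns, `n_runs`, and `eligible`.
#' @export
run_sets <- function(runs) {
  runs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(runset_keys))) |>
    dplyr::summarise(n_runs = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(eligible = .data$n_runs >= 2)
}

#' Summarize prompt families (reproducibility units)
#'
#' One row per `(case_id, model_id, temperature, top_k)` group. Families
#' with a single prompt are returned but flagged ineligible: reproducibility
#' compares at least two prompts.
#'
#' @param runs A run-log tibble.
#' @return A tibble with the key columns, `n_prompts`, `n_runs`, and
#'   `eligible`.
#' @export
prompt_families <- function(runs) {
  runs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(family_keys))) |>
    dplyr::summarise(
      n_prompts = dplyr::n_distinct(.data$prompt_id),
      n_runs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(eligible = .data$n_prompts >= 2)
}
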