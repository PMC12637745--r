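#' Midranks
#'
#' Ranks 1..n with tied values receiving the average of the ranks they
#' span — the rank transform underlying the multivariate Kruskal-Wallis
#' test.
#'
#' @param values Numeric vector.
#' @return Numeric vector of midranks.
#' @examples
#' midranks(c(3, 1, 3)) # 2.5, 1, 2.5
#' @export
midranks <- function(values) {
  rank(values, ties.method = "average")
}

# Rank-transform the pooled sample once; permutations only relabel rows,
# so the centered rank matrix and the inverse pooled rank covariance are
# shared across all permuted statistics.
mkw_prepare <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  R <- apply(x, 2, midranks)
  if (is.null(dim(R))) R <- matrix(R, nrow = n)
  Rc <- sweep(R, 2, (n + 1) / 2)
  V <- crossprod(Rc) / (n - 1)
  Vi <- tryCatch(
    solve(V),
    error = function(e) {
      warn("singular pooled rank covariance (constant dimension?); using pseudo-inverse")
      MASS::ginv(V)
    }
  )
  list(Rc = Rc, Vi = Vi, n = n)
}

mkw_stat_prepared <- function(prep, gi) {
  Tj <- rowsum(prep$Rc, gi)
  nj <- tabulate(gi)
  nj <- nj[nj > 0]
  sum(rowSums((Tj %*% prep$Vi) * Tj) / nj)
}

#' Multivariate Kruskal-Wallis statistic
#'
#' The rank-MANOVA quadratic form: each dimension of the pooled sample is
#' midrank-transformed separately; with `t_j` the group mean rank vector
#' centered at the grand mean `(n+1)/2` and `V` the pooled rank covariance
#' (divisor `n - 1`), the statistic is `sum_j n_j t_j' V^{-1} t_j`. In one
#' dimension without ties this is exactly the Kruskal-Wallis H. It is
#' non-negative, invariant to strictly monotone per-dimension transforms,
#' and compared to a chi-square with `d * (groups - 1)` degrees of freedom
#' asymptotically — though inference in this package defaults to a
#' permutation null ([mkw_test()]).
#'
#' @param x Numeric matrix (or data frame) of points, one row per
#'   observation, `d` columns.
#' @param g Group labels, length `nrow(x)`, at least 2 groups.
#' @return The statistic (scalar, `>= 0`).
#' @export
mkw_statistic <- function(x, g) {
  x <- as.matrix(x)
  gi <- as.integer(factor(g))
  if (length(gi) != nrow(x)) abort("`g` must have one label per row of `x`")
  if (length(unique(gi)) < 2) abort("need >= 2 groups")
  if (nrow(x) < length(unique(gi))) {
    abort("need at least as many observations as groups")
  }
  mkw_stat_prepared(mkw_prepare(x), gi)
}

# All distinct assignments of the multiset of labels in gi to positions.
# Count is multinomial(n; n_1..n_K); guarded by the caller.
multiset_assignments <- function(gi) {
  K <- max(gi)
  rec <- function(counts, n_left) {
    if (n_left == 0) return(matrix(integer(0), nrow = 0, ncol = 1))
    parts <- list()
    for (j in seq_len(K)) {
      if (counts[j] > 0) {
        counts2 <- counts
        counts2[j] <- counts2[j] - 1L
        sub <- rec(counts2, n_left - 1L)
        parts[[length(parts) + 1]] <- rbind(
          matrix(j, nrow = 1, ncol = ncol(sub)), sub)
      }
    }
    do.call(cbind, parts)
  }
  rec(tabulate(gi, nbins = K), length(gi))
}

#' Multivariate Kruskal-Wallis permutation test
#'
#' Tests whether groups of `d`-dimensional score points differ in
#' distribution, using the rank-MANOVA statistic of [mkw_statistic()] with
#' a permutation null: group labels are shuffled uniformly and the p-value
#' is `(1 + #\{permuted >= observed\}) / (1 + n_permutations)`. The test is
#' two-sided by construction (any location difference inflates the
#' statistic), distribution-free, and valid under ties. An asymptotic
#' chi-square p-value (`d * (groups - 1)` df) is reported alongside for
#' reference. With `exhaustive = TRUE` all distinct label assignments are
#' enumerated instead (only sensible for small samples); the p-value is
#' then the exact proportion of assignments with a statistic at least the
#' observed one.
#'
#' @inheritParams mkw_statistic
#' @param n_permutations Number of label shuffles (ignored when
#'   `exhaustive = TRUE`); at least 99.
#' @param seed Integer seed for the permutation stream.
#' @param exhaustive Enumerate all distinct assignments (requires at most
#'   200,000 of them).
#' @return An object of class `"mkw_test"`: statistic, `p_value`,
#'   `p_asymptotic`, `df`, group sizes, per-group per-dimension medians,
#'   permutation count and seed. Supports [tidy()] and [glance()].
#' @export
mkw_test <- function(x, g, n_permutations = 9999, seed = 1,
                     exhaustive = FALSE) {
  x <- as.matrix(x)
  gi <- as.integer(factor(g))
  if (length(unique(gi)) < 2) abort("need >= 2 groups")
  if (nrow(x) < length(unique(gi))) {
    abort("need at least as many observations as groups")
  }
  if (!exhaustive && n_permutations < 99) {
    abort("`n_permutations` must be >= 99")
  }
  prep <- mkw_prepare(x)
  obs <- mkw_stat_prepared(prep, gi)
  tol <- 1e-9 * max(obs, 1)

  if (exhaustive) {
    nj <- tabulate(gi)
    n_assign <- round(exp(lgamma(length(gi) + 1) - sum(lgamma(nj + 1))))
    if (n_assign > 2e5) abort("too many assignments for exhaustive mode")
    assign_mat <- multiset_assignments(gi)
    stats <- apply(assign_mat, 2, function(gp) mkw_stat_prepared(prep, gp))
    p <- mean(stats >= obs - tol)
    n_perm <- ncol(assign_mat)
  } else {
    n <- nrow(x)
    count <- 0L
    withr::with_seed(seed, {
      for (b in seq_len(n_permutations)) {
        gp <- gi[sample.int(n)]
        if (mkw_stat_prepared(prep, gp) >= obs - tol) count <- count + 1L
      }
    })
    p <- (1 + count) / (1 + n_permutations)
    n_perm <- n_permutations
  }

  K <- length(unique(gi))
  df <- ncol(x) * (K - 1)
  med <- stats::aggregate(x, by = list(group = factor(g)), FUN = median)
  structure(
    list(
      statistic = obs,
      p_value = p,
      p_asymptotic = stats::pchisq(obs, df = df, lower.tail = FALSE),
      df = df,
      n_groups = K,
      n_per_group = tabulate(gi),
      group_medians = med,
      n_permutations = n_perm,
      seed = if (exhaustive) NA_integer_ else seed,
      exhaustive = exhaustive
    ),
    class = "mkw_test"
  )
}

#' @export
print.mkw_test <- function(x, ...) {
  cat("Multivariate Kruskal-Wallis permutation test\n")
  cat(sprintf("  statistic = %.4f, df = %d, groups = %d (n = %s)\n",
              x$statistic, x$df, x$n_groups,
              paste(x$n_per_group, collapse = "/")))
  cat(sprintf("  permutation p = %.4g (%s), asymptotic p = %.4g\n",
              x$p_value,
              if (x$exhaustive) "exhaustive" else
                paste0(x$n_permutations, " shuffles, seed ", x$seed),
              x$p_asymptotic))
  invisible(x)
}

#' Tidy a multivariate Kruskal-Wallis test result
#'
#' @param x An `"mkw_test"` object.
#' @param ... Unused.
#' @return A one-row tibble with the statistic, permutation and asymptotic
#'   p-values, degrees of freedom and permutation count.
#' @method tidy mkw_test
#' @export
tidy.mkw_test <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    p.value = x$p_value,
    p.asymptotic = x$p_asymptotic,
    df = x$df,
    n.groups = x$n_groups,
    n.permutations = x$n_permutations,
    method = "multivariate Kruskal-Wallis (permutation)"
  )
}

#' @rdname tidy.mkw_test
#' @method glance mkw_test
#' @export
glance.mkw_test <- function(x, ...) tidy(x)

#' Compare score groups with the multivariate Kruskal-Wallis test
#'
#' Runs [mkw_test()] on the bivariate `(semantic, internal)` points of a
#' scores table, grouped by a column such as `prompt_id`, `model_id`,
#' `dataset_label` or `label` (e.g. correct vs incorrect diagnosis),
#' separately for each `metric_kind` present. With `holm = TRUE` the
#' permutation p-values of the batch are Holm-adjusted; the default
#' reports per-comparison p-values unadjusted.
#'
#' @param scores A scores tibble (see [score_runs()]).
#' @param by Grouping column name (string).
#' @param n_permutations,seed,exhaustive Passed to [mkw_test()].
#' @param holm Holm-adjust p-values across the returned rows.
#' @return A tibble with one row per `metric_kind`: test summary columns
#'   plus a `test` list-column holding the full `"mkw_test"` objects.
#' @export
compare_groups <- function(scores, by, n_permutations = 9999, seed = 1,
                           exhaustive = FALSE, holm = FALSE) {
  if (!by %in% names(scores)) {
    abort(paste0("grouping column `", by, "` not found in scores"))
  }
  out <- scores |>
    dplyr::group_by(.data$metric_kind) |>
    dplyr::group_modify(function(d, key) {
      miss <- is.na(d[[by]])
      if (all(miss)) {
        # structurally inapplicable (e.g. prompt_id for reproducibility
        # rows, which aggregate over prompts): skip this metric kind
        return(tibble())
      }
      if (any(miss)) {
        abort(paste0("missing `", by, "` label for case(s): ",
                     paste(unique(d$case_id[miss]), collapse = ", ")))
      }
      lev <- unique(d[[by]])
      if (length(lev) < 2) {
        abort(paste0("need >= 2 levels of `", by, "` (metric_kind ",
                     key$metric_kind, ")"))
      }
      fit <- mkw_test(cbind(d$semantic, d$internal), d[[by]],
                      n_permutations = n_permutations, seed = seed,
                      exhaustive = exhaustive)
      dplyr::mutate(tidy(fit), test = list(fit))
    }) |>
    dplyr::ungroup()
  if (holm) {
    out$p.adjusted <- stats::p.adjust(out$p.value, method = "holm")
  }
  out
}

#' Null calibration of the permutation test
#'
#' Monte-Carlo estimate of the type-I error rate: both groups are drawn
#' from the same bivariate normal, the test is run, and the rejection rate
#' at `level` is returned. A well-calibrated test rejects close to `level`.
#'
#' @param n_replicates Number of simulated datasets.
#' @param n_per_group Observations per group (2 groups).
#' @param n_permutations Permutations per test.
#' @param level Nominal level.
#' @param seed Master seed; replicate `b` uses substream `seed + b`.
#' @return The rejection rate (scalar in \[0, 1\]).
#' @export
mkw_type1_error <- function(n_replicates = 1000, n_per_group = 30,
                            n_permutations = 999, level = 0.05, seed = 1) {
  g <- rep(1:2, each = n_per_group)
  rejections <- 0L
  for (b in seq_len(n_replicates)) {
    x <- withr::with_seed((seed + b) %% 2147483647,
                          matrix(rnorm(2 * 2 * n_per_group), ncol = 2))
    fit <- mkw_test(x, g, n_permutations = n_permutations,
                    seed = (seed + 2 * b) %% 2147483647)
    if (fit$p_value <= level) rejections <- rejections + 1L
  }
  rejections / n_replicates
}
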