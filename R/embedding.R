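#' @title Pluggable embedding backends
#'
#' @description
#' The semantic scores are agnostic to the embedding model: any function
#' mapping a text to a fixed-dimension vector can stand behind them. A
#' backend is an object with a `name`, a `dimension` and an `embed`
#' function; vectors are cached by exact input text, so repeated runs with
#' verbatim-identical output cost one embedding call and scores never depend
#' on call order or count.
#'
#' Two backends ship with the package:
#' * `"lookup"` — a fixed text-to-vector map (from a named list or a JSON
#'   file); used for fixtures and by the synthetic simulator.
#' * `"mock-vmf"` — a seeded deterministic mock that assigns every distinct
#'   text an independent uniform random direction on the unit sphere;
#'   useful for tests that need arbitrary text without any model download.
#'
#' Production embedding models (e.g. clinical sentence encoders) are
#' plugged in by registering a factory with [register_embedding_backend()];
#' the scoring functions only ever see the `embed` contract.
#'
#' @name embedding_backends
NULL

backend_registry <- new.env(parent = emptyenv())

#' Register an embedding backend factory
#'
#' @param name Backend name used with [embedding_backend()].
#' @param factory Function returning a backend object; typically a call to
#'   [new_embedding_backend()].
#' @return `name`, invisibly.
#' @export
register_embedding_backend <- function(name, factory) {
  stopifnot(is.character(name), length(name) == 1, is.function(factory))
  assign(name, factory, envir = backend_registry)
  invisible(name)
}

#' Resolve a registered embedding backend by name
#'
#' @param name Registered backend name (`"lookup"`, `"mock-vmf"`, or any
#'   name added with [register_embedding_backend()]).
#' @param ... Passed to the backend factory.
#' @return An object of class `"llm_embedding_backend"`.
#' @export
embedding_backend <- function(name, ...) {
  if (!exists(name, envir = backend_registry, inherits = FALSE)) {
    abort(paste0("unknown embedding backend `", name, "`; registered: ",
                 paste(ls(backend_registry), collapse = ", ")))
  }
  get(name, envir = backend_registry)(...)
}

#' Construct an embedding backend object
#'
#' @param name Identifier stamped into provenance metadata.
#' @param dimension Embedding dimension `d`.
#' @param embed Function taking one character string and returning a
#'   numeric vector of length `dimension`; must be deterministic.
#' @return An object of class `"llm_embedding_backend"`.
#' @export
new_embedding_backend <- function(name, dimension, embed) {
  structure(
    list(name = name, dimension = as.integer(dimension), embed = embed,
         cache = new.env(parent = emptyenv())),
    class = "llm_embedding_backend"
  )
}

#' @export
print.llm_embedding_backend <- function(x, ...) {
  cat(sprintf("<embedding backend '%s', d = %d, %d cached>\n",
              x$name, x$dimension, length(ls(x$cache))))
  invisible(x)
}

#' Embed texts through a backend, with caching
#'
#' @param backend An `"llm_embedding_backend"`.
#' @param texts Character vector.
#' @return Numeric matrix, one row per text, `backend$dimension` columns.
#' @export
embed_text <- function(backend, texts) {
  stopifnot(inherits(backend, "llm_embedding_backend"))
  out <- matrix(NA_real_, nrow = length(texts), ncol = backend$dimension)
  for (i in seq_along(texts)) {
    key <- texts[[i]]
    if (!exists(key, envir = backend$cache, inherits = FALSE)) {
      v <- as.numeric(backend$embed(key))
      if (length(v) != backend$dimension || any(!is.finite(v))) {
        abort(paste0("backend `", backend$name,
                     "` returned an invalid vector for text: ",
                     substr(key, 1, 50)))
      }
      assign(key, v, envir = backend$cache)
    }
    out[i, ] <- get(key, envir = backend$cache)
  }
  out
}

#' Lookup backend: a fixed text-to-vector map
#'
#' @param map Named list (or named numeric-vector list) mapping exact text
#'   to its embedding, or a matrix with rownames.
#' @param name Backend name for provenance.
#' @return A backend; embedding a text absent from the map is an error.
#' @export
backend_lookup <- function(map, name = "lookup") {
  if (is.matrix(map)) {
    map <- stats::setNames(lapply(seq_len(nrow(map)), function(i) map[i, ]),
                           rownames(map))
  }
  stopifnot(length(map) >= 1, !is.null(names(map)))
  d <- length(map[[1]])
  new_embedding_backend(name, d, function(text) {
    v <- map[[text]]
    if (is.null(v)) {
      abort(paste0("lookup backend has no embedding for text: ",
                   substr(text, 1, 60)))
    }
    v
  })
}

#' Lookup backend from a JSON map file
#'
#' @param path JSON file holding an object `{"text": [v1, v2, ...], ...}`.
#' @return A `"lookup"` backend.
#' @export
backend_lookup_from_json <- function(path) {
  backend_lookup(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

#' Seeded mock backend: one random unit direction per distinct text
#'
#' Deterministic for a fixed `seed`: the text is hashed to an RNG
#' substream, and a uniform direction on the `dim`-sphere is drawn. In high
#' dimension distinct texts embed nearly orthogonally, which makes this a
#' convenient worst-case (no shared meaning) stand-in for tests.
#'
#' @param dim Embedding dimension.
#' @param seed Integer master seed.
#' @return A `"mock-vmf"` backend.
#' @export
backend_mock_vmf <- function(dim = 64, seed = 1) {
  new_embedding_backend("mock-vmf", dim, function(text) {
    sub_seed <- (as.double(seed) * 69091 + string_hash(text)) %% 2147483647
    withr::with_seed(as.integer(sub_seed), {
      v <- rnorm(dim)
      v / sqrt(sum(v^2))
    })
  })
}

# Deterministic 31-bit string hash (polynomial rolling hash); stable across
# platforms, cheap, and collision-safe enough for RNG substreaming.
string_hash <- function(text) {
  codes <- utf8ToInt(enc2utf8(text))
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  h
}

register_embedding_backend("lookup", backend_lookup)
register_embedding_backend("mock-vmf", backend_mock_vmf)

#' Cosine similarity of two vectors
#'
#' @param a,b Numeric vectors of equal length with positive Euclidean norm.
#' @return `dot(a, b) / (|a| |b|)`, clamped to \[-1, 1\].
#' @export
cosine <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("cosine undefined for a zero-norm vector")
  min(max(sum(a * b) / (na * nb), -1), 1)
}

#' Mean pairwise cosine similarity
#'
#' Arithmetic mean of `cos(e_r, e_s)` over all unordered pairs of rows —
#' the raw semantic consistency of a set of embeddings.
#'
#' @param vectors Numeric matrix, one embedding per row (at least 2 rows,
#'   all with positive norm).
#' @return Scalar in \[-1, 1\].
#' @export
mean_pairwise_cosine <- function(vectors) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < 2) abort("insufficient runs: mean pairwise cosine needs >= 2 vectors")
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0)) {
    abort(paste0("zero-norm embedding at row ",
                 paste(which(norms == 0), collapse = ", ")))
  }
  u <- vectors / norms
  s <- tcrossprod(u)
  mean(pmin(pmax(s[upper.tri(s)], -1), 1))
}
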