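# Polynomial string hash over a large prime; stable across platforms and
# sessions (pure double arithmetic, all intermediates < 2^53).
HASH_PRIME <- 2147483629

hash_string <- function(s, seed = 0L) {
  b <- utf8ToInt(s)
  h <- (as.numeric(seed) %% HASH_PRIME)
  for (x in b) h <- (h * 131 + x) %% HASH_PRIME
  h
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Deterministic contextual mock embedder
#'
#' A stand-in for a pretrained protein language model, for testing and
#' synthetic benchmarks. Row `j` of the embedding is a seeded
#' pseudo-random function of the k-mer centred on residue `j`
#' (boundary-padded with `-`), so a point substitution perturbs every row
#' whose window covers the substituted position — mimicking the contextual
#' behaviour of a real language model, where a variation changes
#' representations beyond the varied residue. Identical (sequence, d, k,
#' seed) always yield bit-identical matrices.
#'
#' The defaults (d = 16, window k = 5) are calibrated so that the
#' synthetic regression tasks built on this embedder are genuinely
#' learnable by the smallest model configuration at realistic noise — the
#' property the recovery tests rely on; a real language model would use a
#' much larger d (e.g. 1280).
#'
#' @param d Embedding dimension (default 16).
#' @param k Odd context window width (default 5); `k = 1` makes the
#'   embedding strictly per-residue.
#' @param seed Integer seed folded into every row hash.
#' @return An embedder object usable with [embed_sequence()].
#' @examples
#' emb <- embedder_mock(d = 8, k = 3)
#' E <- embed_sequence(protein_sequence("p", "MATG"), emb)
#' dim(E)  # 4 x 8
#' @export
embedder_mock <- function(d = 16L, k = 5L, seed = 101L) {
  d <- as.integer(d); k <- as.integer(k)
  if (d < 1L) stop("d must be >= 1", call. = FALSE)
  if (k < 1L || k %% 2L == 0L) stop("k must be odd and >= 1", call. = FALSE)
  fn <- function(seq) {
    chars <- strsplit(seq$residues, "", fixed = TRUE)[[1L]]
    half <- (k - 1L) %/% 2L
    padded <- c(rep("-", half), chars, rep("-", half))
    L <- length(chars)
    E <- matrix(0, L, d)
    for (j in seq_len(L)) {
      kmer <- paste(padded[j:(j + k - 1L)], collapse = "")
      h <- hash_string(kmer, seed = seed)
      E[j, ] <- with_seed(h %% 2147483647, stats::rnorm(d))
    }
    E
  }
  new_embedder(name = sprintf("mock-d%d-k%d-s%d", d, k, seed),
               d = d, fn = fn, deterministic = TRUE, max_length = Inf)
}

#' Wrap a user-supplied embedding function as an embedder
#'
#' Adapter for external per-residue embedding providers (for instance a
#' pretrained transformer served from another process): `fn` receives a
#' `protein_sequence` and must return an `L x d` numeric matrix with one
#' row per residue, special begin/end tokens already stripped.
#'
#' @param fn Function of one `protein_sequence` argument.
#' @param d Output dimension.
#' @param name Identifier used in caches and provenance records.
#' @param deterministic Does `fn` always return the same matrix for the
#'   same sequence?
#' @param max_length Maximum sequence length `fn` supports.
#' @return An embedder object.
#' @export
embedder_custom <- function(fn, d, name = "custom", deterministic = FALSE,
                            max_length = Inf) {
  stopifnot(is.function(fn), d >= 1)
  new_embedder(name = name, d = as.integer(d), fn = fn,
               deterministic = isTRUE(deterministic), max_length = max_length)
}

new_embedder <- function(name, d, fn, deterministic, max_length) {
  structure(list(name = name, d = d, fn = fn,
                 deterministic = deterministic, max_length = max_length),
            class = "stabemb_embedder")
}

#' @export
print.stabemb_embedder <- function(x, ...) {
  cat(sprintf("Embedder '%s': d = %d, %s\n", x$name, x$d,
              if (x$deterministic) "deterministic" else "non-deterministic"))
  invisible(x)
}

#' Compute the per-residue embedding matrix of a sequence
#'
#' @param seq A `protein_sequence` (or residue string).
#' @param embedder An embedder from [embedder_mock()] or
#'   [embedder_custom()].
#' @param cache Optional cache from [embedding_cache()]; deterministic
#'   embedders are memoised on the residue string.
#' @return `L x d` numeric matrix, row `j` aligned to residue `j`.
#' @export
embed_sequence <- function(seq, embedder, cache = NULL) {
  seq <- as_protein_sequence(seq)
  stopifnot(inherits(embedder, "stabemb_embedder"))
  if (seq$length > embedder$max_length)
    stop("sequence '", seq$id, "' (", seq$length,
         " aa) exceeds the embedder's maximum length ", embedder$max_length,
         call. = FALSE)
  if (!is.null(cache) && embedder$deterministic) {
    hit <- cache_get(cache, embedder$name, seq$residues)
    if (!is.null(hit)) return(hit)
  }
  E <- embedder$fn(seq)
  if (!is.matrix(E) || nrow(E) != seq$length || ncol(E) != embedder$d)
    stop("embedder '", embedder$name, "' returned a ",
         paste(dim(E), collapse = "x"), " matrix; expected ",
         seq$length, "x", embedder$d, call. = FALSE)
  if (!all(is.finite(E)))
    stop("embedder returned non-finite values for '", seq$id, "'",
         call. = FALSE)
  if (!is.null(cache) && embedder$deterministic)
    cache_put(cache, embedder$name, seq$residues, E)
  E
}

#' Difference encoding of a variation
#'
#' Element-wise difference `D = Ewt - Evt` of the wild-type and variant
#' embedding matrices; the sole input of the prediction network. Exactly
#' antisymmetric: swapping the arguments flips the sign of every entry,
#' matching the thermodynamic reversibility of the target.
#'
#' @param ewt,evt `L x d` embedding matrices of wild-type and variant
#'   sequence. A shape mismatch signals an indel or misaligned rows and is
#'   an error.
#' @return `L x d` difference matrix.
#' @export
difference_encoding <- function(ewt, evt) {
  if (!is.matrix(ewt) || !is.matrix(evt) || !all(dim(ewt) == dim(evt)))
    stop("embedding matrices must have identical shape ",
         "(substitutions preserve length; indels are not supported)",
         call. = FALSE)
  ewt - evt
}

#' Create an embedding cache
#'
#' In-memory memoisation keyed by (embedder name, residue string), with an
#' optional on-disk layer holding one serialised matrix per sequence
#' (`<embedder>-<hash>.rds` files under `dir`; the residue string is
#' stored alongside the matrix and verified on load, so hash collisions
#' cannot return a wrong matrix). Cached matrices are bit-identical to
#' fresh computation for deterministic embedders.
#'
#' @param dir Optional directory for the on-disk layer; created if absent.
#' @return A cache object for [embed_sequence()].
#' @export
embedding_cache <- function(dir = NULL) {
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  structure(list(mem = new.env(parent = emptyenv()), dir = dir),
            class = "stabemb_cache")
}

cache_key <- function(embedder_name, residues)
  paste0(embedder_name, "::", residues)

cache_file <- function(cache, embedder_name, residues)
  file.path(cache$dir, sprintf("%s-%015.0f.rds",
                               gsub("[^A-Za-z0-9._-]", "_", embedder_name),
                               hash_string(residues)))

cache_get <- function(cache, embedder_name, residues) {
  key <- cache_key(embedder_name, residues)
  if (!is.null(cache$mem[[key]])) return(cache$mem[[key]])
  if (!is.null(cache$dir)) {
    f <- cache_file(cache, embedder_name, residues)
    if (file.exists(f)) {
      rec <- readRDS(f)
      if (identical(rec$residues, residues)) {
        cache$mem[[key]] <- rec$E
        return(rec$E)
      }
    }
  }
  NULL
}

cache_put <- function(cache, embedder_name, residues, E) {
  key <- cache_key(embedder_name, residues)
  cache$mem[[key]] <- E
  if (!is.null(cache$dir))
    saveRDS(list(residues = residues, E = E),
            cache_file(cache, embedder_name, residues))
  invisible(NULL)
}

#' Difference encoding of a variant directly from sequences
#'
#' Convenience wrapper: embeds the wild-type and the variant sequence and
#' returns `D = Ewt - Evt`.
#'
#' @inheritParams apply_variants
#' @inheritParams embed_sequence
#' @return `L x d` difference matrix.
#' @export
encode_variant <- function(seq, spec, embedder, cache = NULL) {
  seq <- as_protein_sequence(seq)
  if (is.character(spec)) spec <- parse_variant(spec)
  vseq <- apply_variants(seq, spec)
  difference_encoding(embed_sequence(seq, embedder, cache),
                      embed_sequence(vseq, embedder, cache))
}
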