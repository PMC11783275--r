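random_sequence <- function(len)
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")

random_spec <- function(chars, n_sites) {
  pos <- sort(sample(length(chars), n_sites))
  wt <- chars[pos]
  vt <- vapply(wt, function(a) sample(setdiff(AA_ALPHABET, a), 1L), "")
  variant_spec(wt, pos, vt)
}

#' Generate a seeded synthetic ddG regression task
#'
#' Emulates the structure of a curated stability dataset without any
#' external download: random protein sequences, random single- and
#' multi-point variations, and ground-truth ddG values produced by a
#' fixed linear functional of the variation's difference encoding,
#' `y = u . colMeans(D)`, rescaled to a realistic spread and perturbed by
#' Gaussian noise. Because the functional is linear in `D` and
#' `D(var -> wt) = -D(wt -> var)`, the noiseless ground truth is exactly
#' antisymmetric under direct/reverse exchange, mirroring thermodynamic
#' reversibility. Regeneration with the same seed is bit-identical.
#'
#' @param n_proteins Number of proteins (default 20).
#' @param n_variants Total number of variants, distributed evenly across
#'   proteins (default 500).
#' @param multi_point_fraction Fraction of variants carrying 2-5
#'   simultaneous substitutions (default 0.1).
#' @param noise_rel Noise standard deviation as a fraction of the
#'   noiseless target SD (default 0.1); ignored when `noise_sigma` is
#'   given.
#' @param noise_sigma Absolute noise SD in kcal/mol, overriding
#'   `noise_rel`.
#' @param length_range Sequence length range (default 50-80 residues).
#' @param target_sd Spread of the noiseless targets in kcal/mol (default
#'   1.5, a typical experimental ddG spread).
#' @param embedder Embedder defining the difference encodings the ground
#'   truth is built from (default: the deterministic mock).
#' @param seed Integer seed for all randomness.
#' @return A `stabemb_task`: `variants` (data frame `protein_id`,
#'   `variant`, `ddg`), `sequences`, the functional `u`, `noiseless`
#'   targets, `sigma`, `embedder` and `seed`.
#' @export
make_task <- function(n_proteins = 20L, n_variants = 500L,
                      multi_point_fraction = 0.1, noise_rel = 0.1,
                      noise_sigma = NULL, length_range = c(50L, 80L),
                      target_sd = 1.5, embedder = embedder_mock(),
                      seed = 1L) {
  stopifnot(n_proteins >= 1L, n_variants >= 1L,
            multi_point_fraction >= 0, multi_point_fraction <= 1,
            length_range[1L] >= 10L)
  with_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n_proteins,
                   replace = TRUE)
    ids <- sprintf("SYN%03d", seq_len(n_proteins))
    sequences <- stats::setNames(
      lapply(seq_len(n_proteins),
             function(i) protein_sequence(ids[i], random_sequence(lens[i]))),
      ids)

    pid <- ids[(seq_len(n_variants) - 1L) %% n_proteins + 1L]
    variant <- character(n_variants)
    for (i in seq_len(n_variants)) {
      chars <- strsplit(sequences[[pid[i]]]$residues, "", fixed = TRUE)[[1L]]
      multi <- stats::runif(1L) < multi_point_fraction
      n_sites <- if (multi) sample(2:5, 1L) else 1L
      variant[i] <- format_variant(random_spec(chars, n_sites))
    }

    u <- stats::rnorm(embedder$d)
    cache <- embedding_cache()
    y0 <- vapply(seq_len(n_variants), function(i) {
      D <- encode_variant(sequences[[pid[i]]], variant[i], embedder, cache)
      sum(u * colMeans(D))
    }, numeric(1L))
    if (stats::sd(y0) == 0)
      stop("degenerate task: noiseless targets have zero variance",
           call. = FALSE)
    scale <- target_sd / stats::sd(y0)
    u <- u * scale
    y0 <- y0 * scale
    sigma <- if (is.null(noise_sigma)) noise_rel * stats::sd(y0)
             else noise_sigma
    y <- y0 + stats::rnorm(n_variants, sd = sigma)

    structure(list(
      variants = data.frame(protein_id = pid, variant = variant, ddg = y,
                            stringsAsFactors = FALSE),
      sequences = sequences, u = u, noiseless = y0, sigma = sigma,
      embedder = embedder, seed = as.integer(seed)),
      class = "stabemb_task")
  })
}

#' @export
print.stabemb_task <- function(x, ...) {
  cat(sprintf(
    "Synthetic ddG task: %d variants on %d proteins (noise sd %.3f kcal/mol, seed %d)\n",
    nrow(x$variants), length(x$sequences), x$sigma, x$seed))
  invisible(x)
}

#' Ground-truth functional of a synthetic task
#'
#' Returns the task's noiseless predictor `(seq, spec) -> u . colMeans(D)`;
#' exactly antisymmetric by construction. Used to inject a perfect oracle
#' into evaluation pipelines.
#'
#' @param task A `stabemb_task`.
#' @return Function of `(seq, spec)` returning the noiseless ddG.
#' @export
task_truth <- function(task) {
  stopifnot(inherits(task, "stabemb_task"))
  cache <- embedding_cache()
  function(seq, spec) {
    D <- encode_variant(seq, spec, task$embedder, cache)
    sum(task$u * colMeans(D))
  }
}

#' Write a synthetic task to FASTA + TSV
#'
#' @param task A `stabemb_task`.
#' @param dir Output directory (created if absent); writes
#'   `sequences.fasta` and `variants.tsv`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_task <- function(task, dir) {
  stopifnot(inherits(task, "stabemb_task"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "sequences.fasta")
  tsv <- file.path(dir, "variants.tsv")
  write_fasta(task$sequences, fa)
  write_variants_tsv(task$variants, tsv)
  invisible(c(fasta = fa, variants = tsv))
}

#' Generate sequence families with controlled identity structure
#'
#' Produces `n_families` ancestor sequences and, for each, `members`
#' descendants obtained by point-mutating a fraction of the ancestor's
#' positions. Within-family identity stays high (about `1 - mut_rate`),
#' between-family identity stays near the random background — a fixture
#' for exercising homology-aware splitting at the 25% threshold.
#'
#' @param n_families Number of independent families.
#' @param members Sequences per family.
#' @param length Sequence length (default 120).
#' @param mut_rate Fraction of positions mutated per member (default
#'   0.3).
#' @param seed Integer seed.
#' @return Named list of `protein_sequence` objects (ids
#'   `FAM<i>_<j>`), with the family index attached as attribute
#'   `family`.
#' @export
make_dissimilar_families <- function(n_families, members, length = 120L,
                                     mut_rate = 0.3, seed = 1L) {
  stopifnot(n_families >= 1L, members >= 1L, length >= 20L,
            mut_rate >= 0, mut_rate < 1)
  with_seed(seed, {
    seqs <- list()
    fam <- integer(0)
    for (f in seq_len(n_families)) {
      anc <- strsplit(random_sequence(length), "", fixed = TRUE)[[1L]]
      for (j in seq_len(members)) {
        chars <- anc
        if (j > 1L && mut_rate > 0) {
          n_mut <- max(1L, round(mut_rate * length))
          pos <- sample(length, n_mut)
          chars[pos] <- vapply(chars[pos], function(a)
            sample(setdiff(AA_ALPHABET, a), 1L), "")
        }
        id <- sprintf("FAM%d_%d", f, j)
        seqs[[id]] <- protein_sequence(id, paste(chars, collapse = ""))
        fam <- c(fam, f)
      }
    }
    attr(seqs, "family") <- fam
    seqs
  })
}
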