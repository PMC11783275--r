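# Scoring used for identity computation: match +2, mismatch -1, gap
# opening 10, gap extension 0.5 (Needleman-Wunsch global alignment).
# Identity = identical aligned pairs / alignment length (gaps included).
IDENTITY_SCORING <- list(match = 2, mismatch = -1,
                         gap_opening = 10, gap_extension = 0.5)

identity_submat <- function() {
  letters <- c(AA_SEQ_ALPHABET, "B", "Z", "U", "*", "-", "+", ".")
  m <- matrix(IDENTITY_SCORING$mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- IDENTITY_SCORING$match
  m
}

#' Pairwise sequence identity
#'
#' Fraction of identical aligned residue pairs over the global alignment
#' length (gap columns included), from a Needleman-Wunsch alignment with
#' match +2, mismatch -1, affine gaps (opening 10, extension 0.5).
#' Symmetric; 1 for identical sequences.
#'
#' @param a,b `protein_sequence` objects or residue strings.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("ACDE", "ACDW")  # 0.75
#' @export
pairwise_identity <- function(a, b) {
  a <- as_protein_sequence(a, "a"); b <- as_protein_sequence(b, "b")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    substitutionMatrix = identity_submat(),
    gapOpening = IDENTITY_SCORING$gap_opening,
    gapExtension = IDENTITY_SCORING$gap_extension,
    type = "global")
  Biostrings::pid(aln, type = "PID1") / 100
}

# Symmetric identity matrix over a list of sequences.
identity_matrix <- function(seqs) {
  n <- length(seqs)
  M <- diag(1, n)
  ids <- vapply(seqs, function(s) s$id, "")
  dimnames(M) <- list(ids, ids)
  if (n >= 2L)
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n)
        M[i, j] <- M[j, i] <- pairwise_identity(seqs[[i]], seqs[[j]])
  M
}

#' Homology-aware fold assignment
#'
#' Splits proteins into `k` cross-validation folds so that (i) all
#' variations of one protein land in the same fold and (ii) no two
#' proteins in different folds share more than `threshold` sequence
#' identity. Proteins are first grouped into single-linkage clusters at
#' the identity threshold (the transitive closure of pairwise similarity,
#' so chains like A~B, B~C put A, B, C together even when A and C are
#' dissimilar); clusters are then assigned greedily, largest variation
#' load first, to the currently lightest fold, balancing the total
#' variation counts. The no-leak constraint is re-checked post hoc.
#'
#' @param seqs Named list of `protein_sequence` objects.
#' @param k Number of folds (>= 2).
#' @param threshold Identity threshold above which two proteins must
#'   share a fold (default 0.25).
#' @param counts Optional named vector of variation counts per protein
#'   id, used for balancing (default: 1 per protein).
#' @param seed Seed for the tie-breaking shuffle of equally loaded
#'   clusters; fixed seeds give identical assignments.
#' @param identities Optional precomputed identity matrix (as from
#'   internal computation), to skip alignment.
#' @return A `fold_assignment`: data frame `protein_id`, `fold`, with the
#'   cluster structure and identity matrix attached as attributes.
#' @export
homology_folds <- function(seqs, k = 5L, threshold = 0.25, counts = NULL,
                           seed = 1L, identities = NULL) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  ids <- vapply(seqs, function(s) s$id, "")
  names(seqs) <- ids
  if (is.null(counts)) counts <- stats::setNames(rep(1, length(ids)), ids)
  if (is.null(identities)) identities <- identity_matrix(seqs)

  # single-linkage clusters: proteins with identity >= threshold merge
  if (length(ids) == 1L) cl <- stats::setNames(1L, ids)
  else {
    hc <- stats::hclust(stats::as.dist(1 - identities), method = "single")
    cl <- stats::cutree(hc, h = 1 - threshold)
  }
  n_cl <- length(unique(cl))
  if (n_cl < k)
    stop("only ", n_cl, " single-linkage cluster(s) at identity threshold ",
         threshold, "; cannot build ", k, " leak-free folds", call. = FALSE)

  cl_load <- tapply(counts[ids], cl[ids], sum)
  ord <- with_seed(seed, {
    jitter <- stats::runif(length(cl_load))  # seeded tie-break
    order(-cl_load, jitter)
  })
  fold_of_cluster <- integer(length(cl_load))
  load <- numeric(k)
  for (ci in ord) {
    f <- which.min(load)
    fold_of_cluster[ci] <- f
    load[f] <- load[f] + cl_load[ci]
  }
  fold <- fold_of_cluster[cl[ids]]

  # post-hoc leak check
  for (i in seq_along(ids))
    for (j in seq_along(ids))
      if (i < j && fold[i] != fold[j] &&
          identities[i, j] > threshold)
        stop("leak: proteins ", ids[i], " and ", ids[j], " share ",
             round(100 * identities[i, j], 1), "% identity across folds",
             call. = FALSE)

  structure(data.frame(protein_id = ids, fold = fold,
                       stringsAsFactors = FALSE),
            class = c("fold_assignment", "data.frame"),
            clusters = cl, identities = identities, k = k,
            threshold = threshold)
}

#' Write / read a fold assignment TSV
#'
#' @param folds A `fold_assignment`.
#' @param path TSV file (`protein_id`, `fold`).
#' @return `path` (write) or a data frame (read).
#' @export
write_folds_tsv <- function(folds, path) {
  utils::write.table(as.data.frame(folds)[, c("protein_id", "fold")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_folds_tsv
#' @export
read_folds_tsv <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

#' Homology-aware k-fold cross-validation
#'
#' For each fold: trains the model on the remaining folds (with
#' reversibility augmentation by default) and evaluates on the held-out
#' fold's direct records, reporting PCC, RMSE and MAE per fold and their
#' mean and standard deviation across folds. Held-out proteins never
#' share more than `threshold` identity with any training protein.
#'
#' @inheritParams stabemb
#' @param k Number of folds.
#' @param threshold Identity threshold for the homology-aware split.
#' @param folds Optional precomputed `fold_assignment`.
#' @param predictor Optional function `(train_ds, test_variants,
#'   sequences) -> numeric` replacing the train+predict step; used for
#'   oracle injection in tests.
#' @return A `stabemb_cv` object: per-fold metrics, their mean/sd, and
#'   the fold assignment.
#' @export
stabemb_cv <- function(variants, sequences, k = 5L, threshold = 0.25,
                       embedder = embedder_mock(),
                       config = ddg_config("model0"),
                       control = stabemb_control(),
                       augment = TRUE, folds = NULL, predictor = NULL) {
  if (is.character(sequences) && length(sequences) == 1L)
    sequences <- read_fasta(sequences)
  ds <- stabemb_dataset(variants, sequences)
  prots <- unique(ds$records$protein_id)
  if (is.null(folds)) {
    counts <- table(ds$records$protein_id)
    folds <- homology_folds(sequences[prots], k = k, threshold = threshold,
                            counts = stats::setNames(as.numeric(counts),
                                                     names(counts)),
                            seed = control$seed)
  }
  if (!all(prots %in% folds$protein_id))
    stop("fold assignment does not cover every protein", call. = FALSE)
  k <- length(unique(folds$fold))

  per_fold <- vector("list", k)
  for (f in sort(unique(folds$fold))) {
    test_prots <- folds$protein_id[folds$fold == f]
    test_rows <- ds$records$protein_id %in% test_prots
    tr_var <- ds$records[!test_rows, c("protein_id", "variant", "ddg")]
    te_var <- ds$records[test_rows, c("protein_id", "variant", "ddg")]
    if (!nrow(te_var) || !nrow(tr_var)) next
    if (is.null(predictor)) {
      fit <- stabemb(tr_var, sequences, embedder = embedder,
                     config = config, control = control, augment = augment)
      pred <- predict(fit, te_var, sequences)$ddg_pred
    } else {
      pred <- predictor(tr_var, te_var, sequences)
    }
    per_fold[[f]] <- data.frame(
      fold = f, n = nrow(te_var),
      PCC = suppressWarnings(ddg_pcc(te_var$ddg, pred)),
      RMSE = ddg_rmse(te_var$ddg, pred),
      MAE = ddg_mae(te_var$ddg, pred))
  }
  per_fold <- do.call(rbind, per_fold)
  summ <- data.frame(
    statistic = c("PCC", "RMSE", "MAE"),
    mean = c(mean(per_fold$PCC), mean(per_fold$RMSE), mean(per_fold$MAE)),
    sd = c(stats::sd(per_fold$PCC), stats::sd(per_fold$RMSE),
           stats::sd(per_fold$MAE)))
  structure(list(per_fold = per_fold, summary = summ, folds = folds,
                 k = k, threshold = threshold),
            class = "stabemb_cv")
}

#' @export
print.stabemb_cv <- function(x, digits = 3L, ...) {
  cat(sprintf("%d-fold homology-aware cross-validation (identity <= %g%% across folds)\n",
              x$k, 100 * x$threshold))
  print(cbind(x$per_fold[, c("fold", "n")],
              round(x$per_fold[, c("PCC", "RMSE", "MAE")], digits)))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("%-5s %.*f +/- %.*f\n", x$summary$statistic[i], digits,
                x$summary$mean[i], digits, x$summary$sd[i]))
  invisible(x)
}
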