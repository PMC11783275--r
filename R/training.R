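#' Assemble a labeled variant dataset
#'
#' Binds a variant table to its sequences, validating that every variant
#' is applicable (positions in range, wild-type letters matching). Each
#' record carries the protein id (used for grouping in splits), the
#' sequence the variant applies to, the target ddG in kcal/mol (negative
#' = destabilizing) and a direction tag.
#'
#' @param variants Data frame with columns `protein_id`, `variant`,
#'   `ddg`, optional `direction` (defaults to `"direct"`).
#' @param sequences Named list of `protein_sequence` objects (or a FASTA
#'   path) covering every `protein_id`.
#' @return A `stabemb_dataset`: records data frame plus the sequence
#'   pool.
#' @export
stabemb_dataset <- function(variants, sequences) {
  if (is.character(sequences) && length(sequences) == 1L)
    sequences <- read_fasta(sequences)
  stopifnot(is.data.frame(variants))
  need <- c("protein_id", "variant", "ddg")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(variants$direction)) variants$direction <- "direct"
  absent <- setdiff(unique(variants$protein_id), names(sequences))
  if (length(absent))
    stop("no sequence for protein(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  rec <- data.frame(seq_id = variants$protein_id,
                    protein_id = variants$protein_id,
                    variant = variants$variant,
                    ddg = as.numeric(variants$ddg),
                    direction = variants$direction,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rec))) {
    spec <- parse_variant(rec$variant[i])
    apply_variants(sequences[[rec$seq_id[i]]], spec)  # errors if invalid
  }
  structure(list(records = rec, sequences = sequences),
            class = "stabemb_dataset")
}

#' @export
print.stabemb_dataset <- function(x, ...) {
  tab <- table(x$records$direction)
  cat(sprintf("Labeled dataset: %d records (%s) on %d proteins\n",
              nrow(x$records),
              paste(names(tab), tab, sep = " = ", collapse = ", "),
              length(unique(x$records$protein_id))))
  invisible(x)
}

#' Reversibility augmentation
#'
#' Doubles a dataset of direct variations by adding, for each record, its
#' thermodynamic reverse: the variant sequence becomes the wild type, the
#' substitutions are inverted and the target sign is switched
#' (ddG(A->B) = -ddG(B->A)). Reverse records keep their protein id so
#' grouped splits never separate a variation from its reverse.
#' Augmenting an already-augmented dataset is an error.
#'
#' @param ds A `stabemb_dataset` containing only direct records.
#' @return A `stabemb_dataset` with exactly `2N` records.
#' @export
augment_reverse <- function(ds) {
  stopifnot(inherits(ds, "stabemb_dataset"))
  if (any(ds$records$direction != "direct"))
    stop("dataset already contains reverse-tagged records; ",
         "reversibility augmentation must start from direct records only",
         call. = FALSE)
  n <- nrow(ds$records)
  if (n == 0L) return(ds)
  seqs <- ds$sequences
  add <- ds$records
  for (i in seq_len(n)) {
    r <- ds$records[i, ]
    rev <- reverse_variant(seqs[[r$seq_id]], parse_variant(r$variant))
    key <- paste0(r$protein_id, "|", r$variant)
    rev$seq$id <- key
    seqs[[key]] <- rev$seq
    add$seq_id[i] <- key
    add$variant[i] <- format_variant(rev$spec)
    add$ddg[i] <- -r$ddg
    add$direction[i] <- "reverse"
  }
  structure(list(records = rbind(ds$records, add), sequences = seqs),
            class = "stabemb_dataset")
}

#' Mean squared error
#'
#' The training loss: `MSE(y, y_hat) = mean((y - y_hat)^2)`.
#'
#' @param y,y_hat Equal-length numeric vectors, length >= 1.
#' @return Non-negative scalar; zero iff the vectors are identical.
#' @export
mse_loss <- function(y, y_hat) {
  if (length(y) == 0L) stop("empty input", call. = FALSE)
  if (length(y) != length(y_hat))
    stop("y and y_hat must have equal length", call. = FALSE)
  mean((y - y_hat)^2)
}

#' Training control parameters
#'
#' @param batch_size Minibatch size (default 128).
#' @param epochs Maximum number of epochs (default 500).
#' @param lr Adam learning rate (default 1e-4).
#' @param patience Early-stopping patience: training stops after this many
#'   epochs without improvement of the validation MSE; the parameters from
#'   the best epoch are returned (default 20).
#' @param val_fraction Fraction of training proteins (grouped, seeded)
#'   held out as the early-stopping validation subset (default 0.1).
#' @param seed Seed governing the validation split, shuffling and
#'   parameter initialisation; identical seeds give identical runs.
#' @param verbose Print per-epoch losses.
#' @return A `stabemb_control` list.
#' @export
stabemb_control <- function(batch_size = 128L, epochs = 500L, lr = 1e-4,
                            patience = 20L, val_fraction = 0.1, seed = 1L,
                            verbose = FALSE) {
  stopifnot(batch_size >= 1L, epochs >= 1L, lr > 0, patience >= 1L,
            val_fraction > 0, val_fraction < 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "stabemb_control")
}

# Difference matrices for every record of a dataset; one embedding per
# unique sequence thanks to the cache.
dataset_encode <- function(ds, embedder, cache = embedding_cache()) {
  lapply(seq_len(nrow(ds$records)), function(i) {
    r <- ds$records[i, ]
    encode_variant(ds$sequences[[r$seq_id]], r$variant, embedder, cache)
  })
}

#' Fit the ddG regression model
#'
#' The main fitting function. Encodes every variation as the difference
#' of wild-type and variant embedding matrices, optionally doubles the
#' data with reversibility augmentation, and trains the convolution +
#' transformer-encoder head by minimising the mean squared error with
#' Adam on minibatches. A protein-grouped validation subset drives early
#' stopping: the returned parameters are those of the epoch with minimum
#' validation MSE.
#'
#' @param variants Data frame (`protein_id`, `variant`, `ddg`) or a
#'   `stabemb_dataset`.
#' @param sequences Named list of `protein_sequence` objects or FASTA
#'   path; ignored when `variants` is already a dataset.
#' @param embedder Embedder producing per-residue matrices (default: the
#'   deterministic mock).
#' @param config Model configuration from [ddg_config()].
#' @param control Training control from [stabemb_control()].
#' @param augment Apply reversibility augmentation before training
#'   (default `TRUE`).
#' @param params Optional initial `ddg_params` (default: seeded random
#'   initialisation).
#' @return An object of class `stabemb` with the trained parameters, the
#'   per-epoch log, and everything needed by
#'   [predict.stabemb()].
#' @seealso [predict.stabemb()], [stabemb_cv()], [evaluate_predictions()]
#' @export
stabemb <- function(variants, sequences = NULL,
                    embedder = embedder_mock(),
                    config = ddg_config("model0"),
                    control = stabemb_control(),
                    augment = TRUE, params = NULL) {
  cl <- match.call()
  ds <- if (inherits(variants, "stabemb_dataset")) variants
        else stabemb_dataset(variants, sequences)
  if (augment) ds <- augment_reverse(ds)
  if (nrow(ds$records) == 0L) stop("empty dataset", call. = FALSE)

  cache <- embedding_cache()
  Dlist <- dataset_encode(ds, embedder, cache)
  y <- ds$records$ddg
  d <- embedder$d

  with_seed(control$seed, {
    # protein-grouped validation split for early stopping
    prots <- unique(ds$records$protein_id)
    n_val <- max(1L, round(control$val_fraction * length(prots)))
    if (n_val >= length(prots))
      stop("validation split would consume every protein; ",
           "lower val_fraction or supply more proteins", call. = FALSE)
    val_prots <- sample(prots, n_val)
    val_idx <- which(ds$records$protein_id %in% val_prots)
    tr_idx <- setdiff(seq_along(y), val_idx)
    if (!length(val_idx) || !length(tr_idx))
      stop("degenerate train/validation split", call. = FALSE)

    if (is.null(params)) params <- ddg_params_init(config, d,
                                                   seed = control$seed)
    check_params(params, config, d = d)
    opt <- adam_state_init(params, config$h)

    best <- list(params = params, val = Inf, epoch = 0L)
    wait <- 0L
    log <- vector("list", control$epochs)

    for (epoch in seq_len(control$epochs)) {
      ord <- sample(tr_idx)
      sse <- 0
      for (b0 in seq(1L, length(ord), by = control$batch_size)) {
        bi <- ord[b0:min(b0 + control$batch_size - 1L, length(ord))]
        B <- length(bi)
        gacc <- grad_zero(params, config$h)
        for (i in bi) {
          st <- ddg_forward(Dlist[[i]], params, config, keep = TRUE)
          resid <- st$y - y[i]
          sse <- sse + resid^2
          gacc <- grad_add(gacc,
                           ddg_backward(st, params, config,
                                        dy = 2 * resid / B),
                           config$h)
        }
        stp <- adam_step(params, gacc, opt, config$h, lr = control$lr)
        params <- stp$params
        opt <- stp$state
        if (!all(is.finite(params$wO)))
          stop("non-finite parameters at epoch ", epoch,
               " (training diverged; lower the learning rate)",
               call. = FALSE)
      }
      train_mse <- sse / length(tr_idx)
      val_pred <- vapply(val_idx, function(i)
        ddg_forward(Dlist[[i]], params, config), numeric(1L))
      val_mse <- mse_loss(y[val_idx], val_pred)
      if (!is.finite(val_mse))
        stop("non-finite validation loss at epoch ", epoch, call. = FALSE)
      log[[epoch]] <- data.frame(epoch = epoch, train_mse = train_mse,
                                 val_mse = val_mse)
      if (control$verbose)
        message(sprintf("epoch %4d  train %.4f  val %.4f", epoch,
                        train_mse, val_mse))
      if (val_mse < best$val) {
        best <- list(params = params, val = val_mse, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= control$patience) break
      }
    }
    log <- do.call(rbind, log[!vapply(log, is.null, TRUE)])

    fitted_all <- vapply(Dlist, function(D)
      ddg_forward(D, best$params, config), numeric(1L))

    structure(list(params = best$params, config = config,
                   control = control, embedder = embedder,
                   log = log, best_epoch = best$epoch,
                   best_val_mse = best$val,
                   augmented = augment,
                   records = ds$records,
                   fitted = fitted_all,
                   val_proteins = val_prots,
                   call = cl),
              class = "stabemb")
  })
}

#' @export
print.stabemb <- function(x, ...) {
  cat("ddG regression model (embedding-difference transformer head)\n")
  print(x$config)
  cat(sprintf("Trained on %d records (%d proteins%s); best epoch %d, validation MSE %.4f\n",
              nrow(x$records), length(unique(x$records$protein_id)),
              if (x$augmented) ", reversibility-augmented" else "",
              x$best_epoch, x$best_val_mse))
  invisible(x)
}

#' @export
#' @method summary stabemb
summary.stabemb <- function(object, ...) {
  res <- object$records$ddg - object$fitted
  out <- list(config = object$config,
              n_records = nrow(object$records),
              n_proteins = length(unique(object$records$protein_id)),
              augmented = object$augmented,
              epochs_run = nrow(object$log),
              best_epoch = object$best_epoch,
              best_val_mse = object$best_val_mse,
              train_rmse = sqrt(mean(res^2)),
              train_pcc = stats::cor(object$records$ddg, object$fitted))
  class(out) <- "summary.stabemb"
  out
}

#' @export
print.summary.stabemb <- function(x, ...) {
  print(x$config)
  cat(sprintf("Records: %d on %d proteins%s\n", x$n_records, x$n_proteins,
              if (x$augmented) " (reversibility-augmented)" else ""))
  cat(sprintf("Epochs run: %d (best %d, validation MSE %.4f)\n",
              x$epochs_run, x$best_epoch, x$best_val_mse))
  cat(sprintf("Training fit: PCC %.3f, RMSE %.3f kcal/mol\n",
              x$train_pcc, x$train_rmse))
  invisible(x)
}

#' @export
#' @method coef stabemb
coef.stabemb <- function(object, ...) object$params

#' @export
fitted.stabemb <- function(object, ...) object$fitted

#' @export
#' @method residuals stabemb
residuals.stabemb <- function(object, ...)
  object$records$ddg - object$fitted

#' Training-curve plot
#'
#' Train and validation MSE per epoch, with the selected (best) epoch
#' marked.
#'
#' @param x A fitted `stabemb` model.
#' @param ... Passed to [graphics::matplot()].
#' @export
#' @method plot stabemb
plot.stabemb <- function(x, ...) {
  graphics::matplot(x$log$epoch, cbind(x$log$train_mse, x$log$val_mse),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "MSE (kcal/mol)^2", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Predict ddG for new variants
#'
#' @param object Fitted `stabemb` model.
#' @param variants Data frame with `protein_id` and `variant` columns.
#' @param sequences Named list of `protein_sequence` objects or FASTA
#'   path covering every protein id.
#' @param reverse Additionally predict each reversed variant from the
#'   mutated sequence (direction tag `"reverse"`).
#' @param cache Optional [embedding_cache()].
#' @param ... Unused.
#' @return Data frame `protein_id`, `variant`, `direction`, `ddg_pred`
#'   (kcal/mol; negative = destabilizing), in input order, reverse rows
#'   appended.
#' @export
predict.stabemb <- function(object, variants, sequences, reverse = FALSE,
                            cache = embedding_cache(), ...) {
  if (is.character(sequences) && length(sequences) == 1L)
    sequences <- read_fasta(sequences)
  stopifnot(is.data.frame(variants),
            all(c("protein_id", "variant") %in% names(variants)))
  predict_one <- function(seq, spec) {
    D <- encode_variant(seq, spec, object$embedder, cache)
    ddg_forward(D, object$params, object$config)
  }
  n <- nrow(variants)
  out <- data.frame(protein_id = variants$protein_id,
                    variant = variants$variant,
                    direction = "direct",
                    ddg_pred = NA_real_, stringsAsFactors = FALSE)
  rev_rows <- if (reverse) out else NULL
  for (i in seq_len(n)) {
    seq <- sequences[[variants$protein_id[i]]]
    if (is.null(seq))
      stop("no sequence for protein '", variants$protein_id[i], "' (row ",
           i, ")", call. = FALSE)
    spec <- parse_variant(variants$variant[i])
    out$ddg_pred[i] <- predict_one(seq, spec)
    if (reverse) {
      rv <- reverse_variant(seq, spec)
      rev_rows$variant[i] <- format_variant(rv$spec)
      rev_rows$direction[i] <- "reverse"
      rev_rows$ddg_pred[i] <- predict_one(rv$seq, rv$spec)
    }
  }
  if (reverse) rbind(out, rev_rows) else out
}
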