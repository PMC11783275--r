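#' Pearson correlation coefficient
#'
#' @param e,p Equal-length numeric vectors (length >= 2), experimental
#'   and predicted ddG. A zero-variance input makes the correlation
#'   undefined; it is reported as `NA` with a warning, never coerced to 0.
#' @return Scalar in `[-1, 1]`, or `NA` when undefined.
#' @export
ddg_pcc <- function(e, p) {
  if (length(e) != length(p)) stop("unequal lengths", call. = FALSE)
  if (length(e) < 2L) stop("correlation needs at least 2 points",
                           call. = FALSE)
  if (stats::sd(e) == 0 || stats::sd(p) == 0) {
    warning("zero variance: correlation undefined, reported as NA",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(e, p)
}

#' Root mean square error
#'
#' @param e,p Equal-length numeric vectors, length >= 1.
#' @return `sqrt(mean((e - p)^2))`, in kcal/mol.
#' @export
ddg_rmse <- function(e, p) {
  if (length(e) == 0L) stop("empty input", call. = FALSE)
  if (length(e) != length(p)) stop("unequal lengths", call. = FALSE)
  sqrt(mean((e - p)^2))
}

#' Mean absolute error
#'
#' @param e,p Equal-length numeric vectors, length >= 1.
#' @return `mean(|e - p|)`, in kcal/mol.
#' @export
ddg_mae <- function(e, p) {
  if (length(e) == 0L) stop("empty input", call. = FALSE)
  if (length(e) != length(p)) stop("unequal lengths", call. = FALSE)
  mean(abs(e - p))
}

#' Direct/reverse prediction correlation
#'
#' Pearson correlation between the predictions for direct variations and
#' those for the corresponding reverse variations, aligned by variation.
#' A perfectly antisymmetric predictor gives -1.
#'
#' @param pdir,pinv Aligned prediction vectors for direct and reverse
#'   variations.
#' @return Scalar in `[-1, 1]`, `NA` when undefined.
#' @export
rd_r <- function(pdir, pinv) ddg_pcc(pdir, pinv)

#' Antisymmetry bias
#'
#' Mean deviation of a predictor from exact direct/reverse antisymmetry
#' (`pdir = -pinv`): `delta = sum(pdir_i + pinv_i) / (2N)`. Zero for an
#' exactly antisymmetric predictor; the sign indicates the direction of
#' the bias.
#'
#' @param pdir,pinv Aligned prediction vectors, length >= 1.
#' @return Scalar bias in kcal/mol.
#' @export
delta_bias <- function(pdir, pinv) {
  if (length(pdir) == 0L) stop("empty input", call. = FALSE)
  if (length(pdir) != length(pinv)) stop("unequal lengths", call. = FALSE)
  sum(pdir + pinv) / (2 * length(pdir))
}

# Pair key of a record: reverse records are keyed by their direct
# counterpart's variant string so direct/reverse pairs align.
pair_key <- function(protein_id, variant, direction) {
  v <- vapply(seq_along(variant), function(i) {
    if (direction[i] == "reverse") {
      s <- parse_variant(variant[i])
      format_variant(variant_spec(s$vt, s$pos, s$wt))
    } else variant[i]
  }, "")
  paste0(protein_id, "::", v)
}

#' Evaluate a set of ddG predictions
#'
#' Computes PCC, RMSE and MAE over (i) all records (Total), (ii) direct
#' records only and (iii) reverse records only, plus the two antisymmetry
#' statistics over direct/reverse pairs aligned by variation: the
#' direct/reverse correlation [rd_r()] and the antisymmetry bias
#' [delta_bias()]. When experimental values are missing for reverse
#' records they are filled with the negated direct targets
#' (reversibility). With no reverse records, the Reverse and Symmetry
#' entries are `NA` (absent), not zero.
#'
#' @param preds Data frame with columns `protein_id`, `variant`,
#'   `ddg_pred`, `ddg_exp`, and optionally `direction`
#'   (`"direct"`/`"reverse"`, default all direct).
#' @return A `stabemb_metrics` object: a 3 x 3 matrix of PCC/RMSE/MAE by
#'   Total/Direct/Reverse plus `rd_r` and `delta`.
#' @examples
#' df <- data.frame(protein_id = "p", variant = c("A2G", "G2A"),
#'                  direction = c("direct", "reverse"),
#'                  ddg_exp = c(-1.2, 1.2), ddg_pred = c(-1.0, 1.1))
#' evaluate_predictions(df)
#' @export
evaluate_predictions <- function(preds) {
  stopifnot(is.data.frame(preds))
  need <- c("protein_id", "variant", "ddg_pred", "ddg_exp")
  miss <- setdiff(need, names(preds))
  if (length(miss))
    stop("prediction table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(preds$direction)) preds$direction <- "direct"
  if (!all(preds$direction %in% c("direct", "reverse")))
    stop("direction must be 'direct' or 'reverse'", call. = FALSE)

  dir <- preds[preds$direction == "direct", , drop = FALSE]
  rev <- preds[preds$direction == "reverse", , drop = FALSE]

  # fill missing experimental reverse targets by reversibility
  if (nrow(rev) && anyNA(rev$ddg_exp)) {
    key_d <- pair_key(dir$protein_id, dir$variant, dir$direction)
    key_r <- pair_key(rev$protein_id, rev$variant, rev$direction)
    mi <- match(key_r, key_d)
    fill <- is.na(rev$ddg_exp) & !is.na(mi)
    rev$ddg_exp[fill] <- -dir$ddg_exp[mi[fill]]
  }

  block <- function(df) {
    if (!nrow(df) || anyNA(df$ddg_exp))
      return(c(PCC = NA_real_, RMSE = NA_real_, MAE = NA_real_))
    c(PCC = if (nrow(df) >= 2L) suppressWarnings(
        ddg_pcc(df$ddg_exp, df$ddg_pred)) else NA_real_,
      RMSE = ddg_rmse(df$ddg_exp, df$ddg_pred),
      MAE = ddg_mae(df$ddg_exp, df$ddg_pred))
  }
  tab <- rbind(Total = block(rbind(dir, rev)),
               Direct = block(dir),
               Reverse = block(rev))

  sym_r <- sym_d <- NA_real_
  n_pairs <- 0L
  if (nrow(dir) && nrow(rev)) {
    key_d <- pair_key(dir$protein_id, dir$variant, dir$direction)
    key_r <- pair_key(rev$protein_id, rev$variant, rev$direction)
    mi <- match(key_d, key_r)
    ok <- !is.na(mi)
    n_pairs <- sum(ok)
    if (n_pairs >= 1L) {
      pd <- dir$ddg_pred[ok]
      pv <- rev$ddg_pred[mi[ok]]
      sym_d <- delta_bias(pd, pv)
      if (n_pairs >= 2L) sym_r <- suppressWarnings(rd_r(pd, pv))
    }
  }

  structure(list(table = tab, rd_r = sym_r, delta = sym_d,
                 n_direct = nrow(dir), n_reverse = nrow(rev),
                 n_pairs = n_pairs),
            class = "stabemb_metrics")
}

#' @export
print.stabemb_metrics <- function(x, digits = 3L, ...) {
  cat(sprintf("ddG prediction metrics (%d direct, %d reverse records)\n",
              x$n_direct, x$n_reverse))
  print(round(x$table, digits))
  if (!is.na(x$rd_r) || !is.na(x$delta))
    cat(sprintf("Symmetry over %d pairs: r_d-r = %s, delta = %s kcal/mol\n",
                x$n_pairs,
                ifelse(is.na(x$rd_r), "NA", format(round(x$rd_r, digits))),
                ifelse(is.na(x$delta), "NA",
                       format(round(x$delta, digits)))))
  invisible(x)
}

#' @export
#' @method as.data.frame stabemb_metrics
as.data.frame.stabemb_metrics <- function(x, ...) {
  data.frame(partition = rownames(x$table),
             PCC = x$table[, "PCC"], RMSE = x$table[, "RMSE"],
             MAE = x$table[, "MAE"], row.names = NULL)
}

# Flat named-list view used by the JSON writers.
metrics_as_list <- function(x) {
  stopifnot(inherits(x, "stabemb_metrics"))
  out <- list()
  for (p in rownames(x$table))
    for (s in colnames(x$table))
      out[[paste0(tolower(p), "_", tolower(s))]] <- unname(x$table[p, s])
  out$rd_r <- x$rd_r
  out$delta <- x$delta
  out
}
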