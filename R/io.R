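CHECKPOINT_FORMAT <- 1L

embedder_descriptor <- function(embedder) {
  if (grepl("^mock-d\\d+-k\\d+-s\\d+$", embedder$name)) {
    n <- as.integer(strsplit(gsub("^mock-", "", embedder$name),
                             "[dks-]+")[[1L]][-1L])
    list(type = "mock", d = n[1L], k = n[2L], seed = n[3L])
  } else {
    list(type = "custom", name = embedder$name, d = embedder$d)
  }
}

#' Save a model checkpoint
#'
#' Writes configuration, every learnable tensor and an embedder
#' descriptor to a single JSON container (text, versioned). Mock
#' embedders are reconstructed on load; custom embedders must be supplied
#' again.
#'
#' @param object A fitted `stabemb` model, or a list with `params`,
#'   `config` and `embedder` fields.
#' @param path Output `.json` file.
#' @return `path`, invisibly.
#' @export
stabemb_save <- function(object, path) {
  stopifnot(!is.null(object$params), !is.null(object$config))
  ck <- list(
    format = CHECKPOINT_FORMAT,
    package_version = as.character(utils::packageVersion("stabemb")),
    config = list(m = object$config$m, w = object$config$w,
                  h = object$config$h, s = object$config$s,
                  attn_scale = object$config$attn_scale,
                  preset = object$config$preset),
    embedder = embedder_descriptor(object$embedder),
    d = object$params$d,
    params = lapply(
      object$params[setdiff(names(object$params), "d")],
      function(p) if (is.list(p)) lapply(p, unclass) else unclass(p))
  )
  jsonlite::write_json(ck, path, digits = NA, auto_unbox = TRUE,
                       matrix = "columnmajor")
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint written by [stabemb_save()].
#' @param embedder Required when the checkpoint references a custom
#'   embedder.
#' @return A `stabemb` object usable with [predict.stabemb()].
#' @export
stabemb_load <- function(path, embedder = NULL) {
  ck <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(ck$format) || ck$format[[1L]] > CHECKPOINT_FORMAT)
    stop("unsupported checkpoint format", call. = FALSE)
  pr <- ck$config$preset
  cfg <- ddg_config(preset = if (is.null(pr)) NULL else pr,
                    m = ck$config$m, w = ck$config$w, h = ck$config$h,
                    s = ck$config$s, attn_scale = ck$config$attn_scale)
  p <- ck$params
  num <- function(x) as.numeric(unlist(x))
  to_mat <- function(x) do.call(cbind, lapply(x, num))  # column-major
  params <- list(Wc = to_mat(p$Wc), bc = num(p$bc),
                 Aq = lapply(p$Aq, to_mat), Ak = lapply(p$Ak, to_mat),
                 Av = lapply(p$Av, to_mat), Ao = to_mat(p$Ao),
                 W1 = to_mat(p$W1), b1 = num(p$b1),
                 W2 = to_mat(p$W2), b2 = num(p$b2),
                 wO = num(p$wO), bO = num(p$bO),
                 d = as.integer(ck$d))
  class(params) <- "ddg_params"
  if (is.null(embedder)) {
    if (identical(ck$embedder$type, "mock"))
      embedder <- embedder_mock(ck$embedder$d, ck$embedder$k,
                                ck$embedder$seed)
    else
      stop("checkpoint references custom embedder '", ck$embedder$name,
           "'; pass it via the 'embedder' argument", call. = FALSE)
  }
  check_params(params, cfg, d = embedder$d)
  structure(list(params = params, config = cfg, embedder = embedder,
                 log = NULL, best_epoch = NA_integer_,
                 best_val_mse = NA_real_, augmented = NA,
                 records = NULL, fitted = NULL,
                 call = sys.call()),
            class = "stabemb")
}

# Provenance block attached to every CLI output.
provenance <- function(seed = NA_integer_, config = NULL) {
  cfg_json <- if (is.null(config)) "" else
    jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  list(package = "stabemb",
       version = as.character(utils::packageVersion("stabemb")),
       seed = seed,
       config_hash = sprintf("%015.0f", hash_string(as.character(cfg_json))))
}

#' Write predictions as TSV or JSON
#'
#' Both serialisations carry identical content: one record per variant
#' (`protein_id`, `variant`, `direction`, `ddg_pred`, plus any extra
#' columns); the JSON form adds a provenance header (package version,
#' seed, config hash) that the TSV form carries as `#`-comment lines.
#'
#' @param df Prediction data frame.
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @param prov Provenance list (from the calling run).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(df, path, format = c("tsv", "json"),
                              prov = provenance()) {
  format <- match.arg(format)
  if (format == "tsv") {
    hdr <- sprintf("# %s", paste(names(prov), unlist(prov), sep = "=",
                                 collapse = " "))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(list(provenance = prov, predictions = df), path,
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read predictions written by [write_predictions()]
#'
#' @param path TSV (possibly with `#` header) or JSON file.
#' @return Prediction data frame.
#' @export
read_predictions <- function(path) {
  if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path,
                                      simplifyVector = TRUE)$predictions)
  } else {
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  }
}
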