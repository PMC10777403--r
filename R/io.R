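# CSV dataset reading/writing, prediction output, and run manifests.

#' Read a dataset CSV
#'
#' Reads an RFC-4180 CSV with a header and validates its shape: ragged rows
#' and missing SMILES columns are reported with line numbers. Columns named
#' `bin_*` are treated as spectrum bins; character target cells with `<`
#' or `>` prefixes are kept verbatim for bounded-target parsing; empty
#' cells become missing targets (masked in the loss).
#'
#' @param path CSV path.
#' @param smiles_columns SMILES column name(s); default: every column named
#'   `smiles`, `rxn` or ending in `_smiles`, else the first column.
#' @param target_columns target columns; default: all remaining columns.
#' @param reaction logical per SMILES column (recycled).
#' @return a data.frame with attributes `smiles_columns`, `target_columns`,
#'   `reaction`, and `task_hint` (`"spectra"` when bin columns are present).
#' @export
read_dataset <- function(path, smiles_columns = NULL, target_columns = NULL,
                         reaction = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged CSV: line ", bad, " has ", nf[bad], " fields but the ",
         "header has ", nf[1], call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(smiles_columns)) {
    guess <- names(df)[tolower(names(df)) %in% c("smiles", "rxn", "reaction") |
                         grepl("_smiles$", tolower(names(df)))]
    smiles_columns <- if (length(guess) > 0L) guess else names(df)[1]
  }
  miss <- setdiff(smiles_columns, names(df))
  if (length(miss) > 0L)
    stop("missing SMILES column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(target_columns))
    target_columns <- setdiff(names(df), smiles_columns)
  for (sc in smiles_columns) {
    bad <- which(is.na(df[[sc]]) | !nzchar(trimws(df[[sc]])))
    if (length(bad) > 0L)
      stop("empty SMILES in column '", sc, "' at data row ", bad[1],
           call. = FALSE)
  }
  structure(df,
            smiles_columns = smiles_columns,
            target_columns = target_columns,
            reaction = rep_len(reaction, length(smiles_columns)),
            task_hint = if (any(grepl("^bin_", target_columns))) "spectra")
}

#' Write predictions next to their inputs
#'
#' Input columns are preserved; one prediction column is appended per task
#' (`<target>_pred`), with paired `<target>_unc` columns when an
#' uncertainty bundle is given. Values are written with full precision so a
#' round-trip read recovers them to better than 1e-6.
#'
#' @param data the input data.frame.
#' @param preds prediction data.frame/matrix from [predict.dmpnn()].
#' @param path output CSV path.
#' @param unc optional `uncertainty_bundle` aligned with `preds`.
#' @return the path, invisibly.
#' @export
write_predictions <- function(data, preds, path, unc = NULL) {
  preds <- as.data.frame(preds)
  out <- cbind(data, stats::setNames(preds, paste0(names(preds), "_pred")))
  if (!is.null(unc)) {
    u <- as.data.frame(as.matrix(unc$unc))
    names(u) <- paste0(names(preds), "_unc")
    out <- cbind(out, u)
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(format(out, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest for a fitted model
#'
#' Records the seed, training configuration, architecture, a hash of the
#' training data, and the package version — enough to rerun the fit
#' exactly.
#'
#' @param object a fitted `dmpnn`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
run_manifest <- function(object, path) {
  m <- list(
    package = "dmpnn",
    package_version = as.character(utils::packageVersion("dmpnn")),
    r_version = R.version.string,
    seed = object$control$seed,
    control = unclass(object$control),
    spec = unclass(object$spec),
    smiles_columns = object$smiles_columns,
    target_columns = object$target_columns,
    reaction = object$reaction,
    data_hash = object$data_hash,
    frozen = object$frozen,
    calibration = object$calibration %||% NULL)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
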