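#' Write a labeled matrix as TSV
#'
#' Tab-separated table with a header row of column labels and a first
#' column of row identifiers, at full float precision; the format all
#' chromcode outputs share.
#'
#' @param M Matrix with dimnames.
#' @param path Output path.
#' @param id_col Header of the identifier column.
#' @export
write_matrix_tsv <- function(M, path, id_col = "id") {
  M <- as.matrix(M)
  df <- data.frame(rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path.
#' @return Numeric matrix with row names from the first column.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1L, drop = FALSE])
  rownames(M) <- df[[1L]]
  M
}

#' Write all outputs of a factorization
#'
#' Emits `<prefix>.H.tsv` (codes x marks), `<prefix>.W.tsv`
#' (loci x codes), `<prefix>.assign.tsv` (hard code assignment with weight
#' and margin), `<prefix>.config.json` (the run configuration, if
#' supplied), and `<prefix>.log` (inputs, seed, reconstruction error and
#' sparsities).
#'
#' @param fit `chromcode_nmf` object.
#' @param prefix Output path prefix.
#' @param config Optional named list recorded as JSON next to the outputs.
#' @return Invisibly, the named vector of files written.
#' @export
write_factorization <- function(fit, prefix, config = NULL) {
  stopifnot(inherits(fit, "chromcode_nmf"))
  files <- c(H = paste0(prefix, ".H.tsv"),
             W = paste0(prefix, ".W.tsv"),
             assign = paste0(prefix, ".assign.tsv"),
             log = paste0(prefix, ".log"))
  write_matrix_tsv(fit$H, files["H"], id_col = "code")
  write_matrix_tsv(fit$W, files["W"], id_col = "locus")
  assign <- assign_codes(fit$W)
  utils::write.table(assign[, c("locus", "code_label", "weight", "margin")],
                     files["assign"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(config)) {
    files["config"] <- paste0(prefix, ".config.json")
    jsonlite::write_json(config, files["config"], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  log <- c(
    paste0("chromcode ", fit$mode, " mode"),
    paste0("rank c: ", fit$rank),
    paste0("loci: ", nrow(fit$W), ", columns: ", ncol(fit$H)),
    paste0("init: ", fit$init_method, ", l1_H: ", fit$l1_H,
           ", max_iter: ", fit$max_iter, ", tol: ", fit$tol),
    paste0("iterations run: ", fit$n_iter),
    paste0("reconstruction error (Frobenius): ",
           format(fit$reconstruction_error, digits = 10)),
    paste0("mean Hoyer sparsity of H rows: ",
           format(matrix_sparsity(fit$H), digits = 6)),
    paste0("mean Hoyer sparsity of W rows: ",
           format(suppressWarnings(matrix_sparsity(fit$W)), digits = 6)))
  writeLines(log, files["log"])
  invisible(files)
}
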