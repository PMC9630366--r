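#' Construct a per-comparison differential-expression table
#'
#' One injury-vs-control comparison's gene-level results: log2 fold-change,
#' adjusted p-value (absent for no-replicate datasets, whose DE calls come
#' from fold-change alone), and optional mean normalized expression in the
#' control and injury groups.
#'
#' @param comparison_id single string identifying the comparison.
#' @param records data frame with columns \code{gene_id}, \code{lfc}, and
#'   optionally \code{adj_p}, \code{expr_control}, \code{expr_injury}.
#' @param has_replicates logical; when \code{FALSE} the table must not carry
#'   adjusted p-values. Defaults to whether an \code{adj_p} column with any
#'   non-missing value is present.
#' @return An object of class \code{comparison_table}: a list with elements
#'   \code{comparison_id}, \code{records} (tibble keyed by unique
#'   \code{gene_id}), and \code{has_replicates}.
#' @export
comparison_table <- function(comparison_id, records, has_replicates = NULL) {
  stopifnot(is.character(comparison_id), length(comparison_id) == 1L,
            nzchar(comparison_id))
  records <- tibble::as_tibble(records)
  for (col in c("adj_p", "expr_control", "expr_injury")) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }
  records <- records[, c("gene_id", "lfc", "adj_p",
                         "expr_control", "expr_injury")]
  records$gene_id <- as.character(records$gene_id)
  for (col in c("lfc", "adj_p", "expr_control", "expr_injury")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  if (is.null(has_replicates)) has_replicates <- any(!is.na(records$adj_p))
  tab <- structure(
    list(comparison_id = comparison_id, records = records,
         has_replicates = isTRUE(has_replicates)),
    class = "comparison_table"
  )
  validate_comparison_table(tab)
}

validate_comparison_table <- function(tab) {
  rec <- tab$records
  if (any(is.na(rec$gene_id) | !nzchar(rec$gene_id))) {
    stop("comparison_table: empty gene_id in `", tab$comparison_id, "`",
         call. = FALSE)
  }
  dup <- unique(rec$gene_id[duplicated(rec$gene_id)])
  if (length(dup)) {
    stop("comparison_table: duplicate gene_id in `", tab$comparison_id,
         "`: ", paste(head(dup, 10L), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(rec$lfc))) {
    stop("comparison_table: non-finite lfc in `", tab$comparison_id, "`",
         call. = FALSE)
  }
  p <- rec$adj_p
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("comparison_table: adj_p outside [0, 1] in `", tab$comparison_id,
         "`", call. = FALSE)
  }
  if (!tab$has_replicates && any(!is.na(p))) {
    stop("comparison_table: no-replicate table `", tab$comparison_id,
         "` must not carry adj_p values", call. = FALSE)
  }
  ex <- c(rec$expr_control, rec$expr_injury)
  if (any(!is.na(ex) & ex < 0)) {
    stop("comparison_table: negative expression values in `",
         tab$comparison_id, "`", call. = FALSE)
  }
  tab
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("<comparison_table> %s: %d genes, %s\n", x$comparison_id,
              nrow(x$records),
              if (x$has_replicates) "replicated" else "no replicates"))
  print(x$records, n = 5)
  invisible(x)
}

#' Read a comparison table from TSV or CSV
#'
#' Expects a header with at least \code{gene} and \code{log2fc} columns;
#' \code{padj}, \code{expr_control} and \code{expr_injury} are optional.
#' A table without a \code{padj} column (or with an all-missing one) is
#' treated as a no-replicate dataset. Rows whose \code{log2fc} does not parse
#' as a finite number are dropped with a message reporting the count.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}; guessed from the
#'   file extension when omitted.
#' @param comparison_id identifier for the comparison; defaults to the file
#'   name without extension.
#' @return A \code{\link{comparison_table}}.
#' @export
read_comparison_table <- function(path, dialect = NULL, comparison_id = NULL) {
  if (!file.exists(path)) {
    stop("read_comparison_table: no such file: ", path, call. = FALSE)
  }
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  dialect <- match.arg(dialect, c("tsv", "csv"))
  reader <- if (dialect == "csv") readr::read_csv else readr::read_tsv
  raw <- reader(path, show_col_types = FALSE, progress = FALSE,
                col_types = readr::cols(.default = readr::col_character()))
  names(raw) <- tolower(names(raw))
  for (col in c("gene", "log2fc")) {
    if (!col %in% names(raw)) {
      stop("read_comparison_table: missing mandatory column `", col,
           "` in ", path, call. = FALSE)
    }
  }
  lfc <- suppressWarnings(as.numeric(raw$log2fc))
  bad <- !is.finite(lfc)
  if (any(bad)) {
    message("read_comparison_table: dropped ", sum(bad),
            " row(s) with unparseable log2fc from ", basename(path))
    raw <- raw[!bad, , drop = FALSE]
    lfc <- lfc[!bad]
  }
  num_or_na <- function(col) {
    if (col %in% names(raw)) suppressWarnings(as.numeric(raw[[col]]))
    else rep(NA_real_, nrow(raw))
  }
  rec <- tibble::tibble(
    gene_id = raw$gene, lfc = lfc,
    adj_p = num_or_na("padj"),
    expr_control = num_or_na("expr_control"),
    expr_injury = num_or_na("expr_injury")
  )
  if (is.null(comparison_id)) {
    comparison_id <- sub("\\.[^.]*$", "", basename(path))
  }
  comparison_table(comparison_id, rec)
}

#' Write a comparison table to TSV or CSV
#'
#' Inverse of \code{\link{read_comparison_table}}: the written file
#' round-trips to an identical table. The \code{padj} column is omitted for
#' no-replicate tables.
#'
#' @param tab a \code{\link{comparison_table}}.
#' @param path output path.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
write_comparison_table <- function(tab, path, dialect = "tsv") {
  stopifnot(inherits(tab, "comparison_table"))
  dialect <- match.arg(dialect, c("tsv", "csv"))
  out <- tab$records
  names(out)[names(out) == "gene_id"] <- "gene"
  names(out)[names(out) == "lfc"] <- "log2fc"
  names(out)[names(out) == "adj_p"] <- "padj"
  if (!tab$has_replicates) out$padj <- NULL
  if (dialect == "csv") readr::write_csv(out, path)
  else readr::write_tsv(out, path)
  invisible(path)
}

#' Harmonize gene identifiers against an alias map
#'
#' Cross-study integration mixes NCBI and Ensembl symbol vintages (e.g.
#' AXUD1 vs Csrnp1) and case drift (ATF3 vs Atf3). Every identifier is
#' matched case-insensitively against the alias map's synonyms and replaced
#' by the canonical symbol; identifiers not in the map keep their original
#' spelling. When two rows collapse onto one canonical symbol the row with
#' the larger |log2 fold-change| is kept and the drop is reported.
#'
#' @param tab a \code{\link{comparison_table}}.
#' @param alias_map named character vector, \code{synonym -> canonical}.
#'   Empty map is the identity.
#' @return A harmonized \code{\link{comparison_table}}.
#' @export
harmonize_gene_ids <- function(tab, alias_map = character()) {
  stopifnot(inherits(tab, "comparison_table"))
  if (length(alias_map) == 0L) return(tab)
  if (is.null(names(alias_map)) || any(!nzchar(names(alias_map)))) {
    stop("harmonize_gene_ids: alias_map must be a named vector", call. = FALSE)
  }
  rec <- tab$records
  idx <- match(tolower(rec$gene_id), tolower(names(alias_map)))
  rec$gene_id <- ifelse(is.na(idx), rec$gene_id,
                        unname(alias_map[idx]))
  if (anyDuplicated(rec$gene_id)) {
    first_pos <- match(rec$gene_id, rec$gene_id)  # first appearance order
    ord <- order(-abs(rec$lfc), rec$gene_id)
    rec_sorted <- rec[ord, , drop = FALSE]
    keep <- !duplicated(rec_sorted$gene_id)
    dropped <- rec_sorted$gene_id[!keep]
    message("harmonize_gene_ids: dropped ", length(dropped),
            " row(s) after alias collision (kept larger |lfc|): ",
            paste(unique(dropped), collapse = ", "))
    rec_kept <- rec_sorted[keep, , drop = FALSE]
    rec <- rec_kept[order(first_pos[ord][keep]), , drop = FALSE]
  }
  comparison_table(tab$comparison_id, rec, tab$has_replicates)
}
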