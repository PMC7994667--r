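# Dialect-aware tabular IO. All tables are plain TSV/CSV with a header;
# missing values are written as "NA" (empty fields also parse as missing).

# Sniff the separator from the header line: tab wins if present.
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

# MaxQuant flag columns recognized by the protein_groups dialect.
MAXQUANT_FLAG_COLS <- c(reverse = "Reverse",
                        contaminant = "Potential contaminant",
                        only_by_site = "Only identified by site")

#' Read an expression table into an ExpressionMatrix
#'
#' Reads a tab- or comma-separated table whose sample columns are matched to
#' a sample design. The `protein_groups` dialect additionally recognizes the
#' MaxQuant flag columns `Reverse`, `Potential contaminant` and
#' `Only identified by site`; flagged rows are retained but the flags are
#' carried as row attributes so the downstream filter can drop them.
#'
#' @param path file path.
#' @param dialect `"protein_groups"` or `"generic"`.
#' @param design sample design; every `design$sample_id` must be a column.
#' @param id_col name of the feature-id column (default: first column).
#' @param layer layer tag for the result.
#' @return [expression_matrix()] with rows in file order.
#' @export
read_expression_table <- function(path, dialect = c("generic", "protein_groups"),
                                  design, id_col = NULL, layer = "protein") {
  dialect <- match.arg(dialect)
  tab <- read_delim_auto(path)
  if (is.null(id_col)) id_col <- names(tab)[1]
  if (!id_col %in% names(tab)) stop("missing feature-id column: ", id_col)

  missing_samples <- setdiff(design$sample_id, names(tab))
  if (length(missing_samples) > 0) {
    stop("design sample column(s) absent from table: ",
         paste(missing_samples, collapse = ", "))
  }
  known <- c(id_col, design$sample_id,
             if (dialect == "protein_groups") unname(MAXQUANT_FLAG_COLS))
  orphan <- setdiff(names(tab), known)
  if (dialect == "protein_groups") {
    if (length(orphan) > 0) {
      warning("ignoring unrecognized column(s): ", paste(orphan, collapse = ", "))
    }
  } else if (length(orphan) > 0) {
    stop("table column(s) not present in design: ",
         paste(orphan, collapse = ", "))
  }

  ids <- as.character(tab[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicated feature id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  values <- as.matrix(tab[, design$sample_id, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids

  row_flags <- NULL
  if (dialect == "protein_groups") {
    row_flags <- data.frame(feature = ids, stringsAsFactors = FALSE)
    for (fl in names(MAXQUANT_FLAG_COLS)) {
      col <- MAXQUANT_FLAG_COLS[[fl]]
      row_flags[[fl]] <- if (col %in% names(tab)) {
        !is.na(tab[[col]]) & tab[[col]] == "+"
      } else FALSE
    }
  }
  expression_matrix(values, design, layer = layer, row_flags = row_flags)
}

#' Drop MaxQuant-flagged rows
#'
#' Removes rows flagged reverse, potential contaminant or only-identified-by
#' -site, per the standard MaxQuant post-processing policy.
#'
#' @param m ExpressionMatrix read with the `protein_groups` dialect.
#' @return filtered ExpressionMatrix.
#' @export
drop_flagged_rows <- function(m) {
  fl <- attr(m, "row_flags")
  if (is.null(fl)) return(m)
  keep <- !(fl$reverse | fl$contaminant | fl$only_by_site)
  out <- subset_matrix(m, features = keep)
  attr(out, "row_flags") <- fl[keep, , drop = FALSE]
  out
}

#' Read a MaxQuant-style phosphosite table
#'
#' Expects columns `protein`, `position`, `amino_acid`,
#' `localization_prob`, `multiplicity`, `sequence_window` plus one column
#' per design sample. One row per (site, multiplicity); positions are
#' 1-based and the sequence window is centered on the phosphosite.
#'
#' @param path file path.
#' @param design sample design.
#' @return data.frame of class `PhosphoSiteTable`: site metadata columns
#'   followed by per-sample log2 values; `site_id` is
#'   `<protein>_p<position>_m<multiplicity>`.
#' @export
read_phospho_table <- function(path, design) {
  tab <- read_delim_auto(path)
  required <- c("protein", "position", "amino_acid", "localization_prob",
                "multiplicity", "sequence_window")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("phospho table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  missing_samples <- setdiff(design$sample_id, names(tab))
  if (length(missing_samples) > 0) {
    stop("design sample column(s) absent from table: ",
         paste(missing_samples, collapse = ", "))
  }
  phospho_site_table(tab[required], as.matrix(tab[, design$sample_id]), design)
}

#' Construct a PhosphoSiteTable
#'
#' @param sites data.frame with columns `protein`, `position`,
#'   `amino_acid`, `localization_prob`, `multiplicity`, `sequence_window`.
#' @param values numeric matrix of per-sample log2 values (rows align with
#'   `sites`).
#' @param design sample design for the value columns.
#' @return `PhosphoSiteTable` data.frame.
#' @export
phospho_site_table <- function(sites, values, design) {
  win <- as.character(sites$sequence_window)
  len <- nchar(win)
  if (any(len %% 2 == 0)) stop("sequence windows must have odd length")
  center <- substr(win, (len + 1) / 2, (len + 1) / 2)
  if (any(!center %in% c("S", "T", "Y"))) {
    bad <- which(!center %in% c("S", "T", "Y"))[1]
    stop("window center residue must be S, T or Y (row ", bad,
         " has '", center[bad], "')")
  }
  if (!identical(center, as.character(sites$amino_acid))) {
    stop("window center residue does not match the amino_acid column")
  }
  p <- sites$localization_prob
  if (any(p < 0 | p > 1)) stop("localization probabilities must lie in [0, 1]")
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  colnames(values) <- design$sample_id
  out <- cbind(
    data.frame(site_id = sprintf("%s_p%d_m%d", sites$protein,
                                 as.integer(sites$position),
                                 as.integer(sites$multiplicity)),
               sites, stringsAsFactors = FALSE),
    as.data.frame(values))
  if (anyDuplicated(out$site_id)) stop("duplicated (site, multiplicity) rows")
  attr(out, "design") <- design
  class(out) <- c("PhosphoSiteTable", "data.frame")
  out
}

#' Convert a PhosphoSiteTable to an ExpressionMatrix of peptidoforms
#'
#' @param t PhosphoSiteTable.
#' @return ExpressionMatrix (layer `"phospho"`) keyed by `site_id`.
#' @export
phospho_values <- function(t) {
  design <- attr(t, "design")
  v <- as.matrix(t[, design$sample_id, drop = FALSE])
  rownames(v) <- t$site_id
  expression_matrix(v, design, layer = "phospho")
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, members... Duplicate members within a set are stored once.
#'
#' @param path GMT file.
#' @return named list of character member vectors, with a `descriptions`
#'   attribute; class `GeneSetCollection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short)) {
    stop("GMT line ", which(short)[1], " has fewer than 3 fields")
  }
  names_ <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names_)) {
    stop("duplicate set name: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- names_
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, "", 2L), names_)
  class(sets) <- "GeneSetCollection"
  sets
}

#' Write a tabular result to TSV
#'
#' Round-trip stable: writing and re-reading reproduces numeric values to
#' better than 1e-12 (values are serialized with 17 significant digits).
#'
#' @param result data.frame (e.g. a differential table or an overlap stat
#'   turned into a one-row table via [as.data.frame()]).
#' @param path output path.
#' @export
write_table <- function(result, path) {
  result <- as.data.frame(result)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  num <- vapply(result, is.numeric, TRUE)
  result[num] <- lapply(result[num], function(x) sprintf("%.17g", x))
  result[num] <- lapply(result[num], function(x) ifelse(x == "nan", "NA", x))
  write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  read_delim_auto(path)
}
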