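# Readers and writers for the tabular formats used throughout the package.
# Feature matrices are stored features x samples (genes or CpG loci on rows),
# as TSV with a header row of sample IDs and an `id` corner cell; missing
# values are written as "NA". Structured results are written as JSON.

#' Read a feature-by-sample matrix from TSV
#'
#' Expects tab-delimited text with one header row (corner label then sample
#' IDs) and one feature ID in the first column of every subsequent row.
#' Empty cells and the sentinel "NA" become missing values.
#'
#' @param path path to a TSV file.
#' @return Numeric matrix with feature row names and sample column names.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6 / 7, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' write_matrix(m, f)
#' all.equal(read_matrix(f), m)
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nfields <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nfields) == 0L) stop("empty file: ", path)
  bad <- which(nfields != nfields[1L])
  if (length(bad) > 0L) {
    stop("ragged row in ", path, ": line ", bad[1L] + 0L,
         " has ", nfields[bad[1L]], " fields, expected ", nfields[1L])
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          na.strings = c("NA", ""), check.names = FALSE,
                          colClasses = c("character", rep("numeric", nfields[1L] - 1L)),
                          comment.char = "")
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate feature IDs in ", path, ": ", paste(dup, collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' Inverse of [read_matrix()]: numbers are written with enough digits for an
#' exact double round trip, missing values as "NA".
#'
#' @param m numeric matrix with row and column names (0-row/0-column allowed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  if (!is.matrix(m)) stop("`m` must be a matrix")
  chr <- matrix("NA", nrow(m), ncol(m))
  ok <- !is.na(m)
  chr[ok] <- sprintf("%.17g", m[ok])
  header <- paste(c("id", colnames(m)), collapse = "\t")
  body <- if (nrow(m) > 0L) {
    apply(cbind(rownames(m), chr), 1L, paste, collapse = "\t")
  } else character(0)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a locus-to-gene mapping table
#'
#' Two-column TSV (header row, then locus ID and gene symbol per row), such
#' as a flattened CpG array annotation. Duplicate pairs are collapsed; one
#' locus may map to several genes and vice versa.
#'
#' @param path path to a two-column TSV.
#' @return `data.frame` with character columns `locus` and `gene`.
#' @export
read_locus_gene_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "")
  if (ncol(df) != 2L) {
    stop("locus-gene map must have exactly 2 columns, found ", ncol(df))
  }
  names(df) <- c("locus", "gene")
  if (nrow(df) == 0L) stop("locus-gene map is empty: ", path)
  dup <- duplicated(df)
  if (any(dup)) {
    omix_log("collapsed ", sum(dup), " duplicate locus-gene pairs")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read a clinical table
#'
#' TSV with one row per patient. Must contain an `ID` column; survival and
#' gold-standard columns (`time`, `event`, `stage`, `AFP`, `Ishak`, `braak`,
#' `risk`, ...) are cohort dependent and validated by [prepare_survival()].
#'
#' @param path path to a TSV file.
#' @return `data.frame` with one row per patient.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          na.strings = c("NA", ""), check.names = FALSE,
                          comment.char = "")
  if (!"ID" %in% names(df)) stop("clinical table must have an `ID` column")
  df$ID <- as.character(df$ID)
  dup <- unique(df$ID[duplicated(df$ID)])
  if (length(dup) > 0L) stop("duplicate patient IDs: ", paste(dup, collapse = ", "))
  df
}

#' Case-insensitive sample-ID intersection
#'
#' Matches IDs across data types after trimming whitespace and lowercasing,
#' reporting (not silently dropping) IDs found in only some inputs. Returns
#' the IDs spelled as in the first set.
#'
#' @param ... two or more character vectors of sample IDs.
#' @return Character vector of shared IDs, spelled as in the first argument.
#' @export
intersect_samples <- function(...) {
  sets <- list(...)
  if (length(sets) < 2L) stop("need at least two ID sets")
  keys <- lapply(sets, function(s) tolower(trimws(s)))
  shared <- Reduce(intersect, keys)
  for (i in seq_along(sets)) {
    only <- setdiff(keys[[i]], shared)
    if (length(only) > 0L) {
      omix_log("input ", i, ": ", length(only), " sample IDs absent elsewhere")
    }
  }
  sets[[1L]][match(shared, keys[[1L]])]
}
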