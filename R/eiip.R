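#' Load an EIIP residue-value table
#'
#' Reads a two-column text file mapping one-letter amino-acid codes to
#' electron-ion interaction potential (EIIP) values in Rydberg units.
#' Lines starting with `#` are comments.  The table must cover all 20
#' standard residues with finite values.
#'
#' @param path Path to a two-column (residue, value) text file.  When
#'   `NULL` (the default) the EIIP scale packaged with `ismftir` is used.
#' @return A named numeric vector of class `eiip_table` with one entry per
#'   residue and an attribute `table_mean`, the arithmetic mean of the 20
#'   standard-residue values (used to impute non-standard residues).
#' @export
#' @examples
#' tab <- eiip_table()
#' tab["A"]
eiip_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "eiip_amino_acids.tsv",
                        package = "ismftir", mustWork = TRUE)
  }
  raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("residue", "value"),
                           colClasses = c("character", "numeric"),
                           stringsAsFactors = FALSE)
  values <- stats::setNames(raw$value, toupper(raw$residue))
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  missing <- setdiff(standard, names(values))
  if (length(missing) > 0L) {
    stop("EIIP table is missing standard residues: ",
         paste(missing, collapse = ", "))
  }
  if (!all(is.finite(values))) stop("EIIP table contains non-finite values")
  structure(values, table_mean = mean(values[standard]),
            class = "eiip_table")
}

#' Construct a numeric molecular series
#'
#' The common container for EIIP-encoded proteins and ligand profiles:
#' an ordered sequence of real values attached to a molecule identifier.
#'
#' @param molecule_id Identifier string.
#' @param values Numeric vector, length >= 2, all finite.
#' @param source Either `"protein"` or `"ligand_profile"`.
#' @return An object of class `numeric_series`.
#' @export
numeric_series <- function(molecule_id, values,
                           source = c("protein", "ligand_profile")) {
  source <- match.arg(source)
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a numeric series needs at least 2 values")
  if (!all(is.finite(values))) stop("numeric series contains non-finite values")
  structure(list(molecule_id = as.character(molecule_id)[1L],
                 values = values, source = source),
            class = "numeric_series")
}

#' @export
print.numeric_series <- function(x, ...) {
  cat(sprintf("<numeric_series> %s (%s), length %d\n",
              x$molecule_id, x$source, length(x$values)))
  invisible(x)
}

#' @export
length.numeric_series <- function(x) length(x$values)

#' Encode a protein sequence as an EIIP series
#'
#' Replaces each residue of a primary-structure sequence by its EIIP
#' value, producing the numeric series that the informational spectrum is
#' computed from.
#'
#' @param sequence Amino-acid string (one-letter codes; case and
#'   whitespace are ignored).
#' @param table An [eiip_table()].
#' @param molecule_id Identifier carried on the result.
#' @param unknown_policy What to do with residues absent from the table
#'   (e.g. X, B, Z, U, O): `"table_mean"` (default) substitutes the table
#'   mean and warns; `"error"` aborts naming the offending position.
#' @return A [numeric_series()] with `source = "protein"` and the same
#'   length as the cleaned sequence.
#' @export
#' @examples
#' s <- encode_protein("MKVLAA", molecule_id = "toy")
#' s$values
encode_protein <- function(sequence, table = eiip_table(),
                           molecule_id = "protein",
                           unknown_policy = c("table_mean", "error")) {
  unknown_policy <- match.arg(unknown_policy)
  sequence <- gsub("[[:space:]]", "", sequence)
  if (!nzchar(sequence)) stop("empty sequence")
  chars <- strsplit(toupper(sequence), "")[[1]]
  values <- unname(unclass(table)[chars])
  unknown <- which(is.na(values))
  if (length(unknown) > 0L) {
    if (unknown_policy == "error") {
      stop(sprintf("unknown residue '%s' at position %d of '%s'",
                   chars[unknown[1L]], unknown[1L], molecule_id))
    }
    warning(sprintf(
      "%d non-standard residue(s) in '%s' replaced by the EIIP table mean",
      length(unknown), molecule_id))
    values[unknown] <- attr(table, "table_mean")
  }
  numeric_series(molecule_id, values, source = "protein")
}

#' Read a ligand numeric profile
#'
#' Ingests a precomputed small-molecule profile (one EIIP-like value per
#' position) from a two-column text file `index value`, indices
#' consecutive from 1.  Fields may be separated by whitespace or commas;
#' `#` lines are comments.
#'
#' @param path Path to the profile file.
#' @param molecule_id Identifier; defaults to the file name without
#'   extension.
#' @return A [numeric_series()] with `source = "ligand_profile"`.
#' @export
read_ligand_profile <- function(path, molecule_id = NULL) {
  if (is.null(molecule_id)) {
    molecule_id <- tools::file_path_sans_ext(basename(path))
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx_lines <- which(keep)
  if (length(idx_lines) < 2L) {
    stop("ligand profile needs at least 2 data rows: ", path)
  }
  fields <- strsplit(trimws(lines[idx_lines]), "[,\t ]+")
  parse_row <- function(i) {
    f <- fields[[i]]
    if (length(f) < 2L) {
      stop(sprintf("malformed profile row at line %d of '%s'",
                   idx_lines[i], path))
    }
    v <- suppressWarnings(as.numeric(f[1:2]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric value at line %d of '%s'",
                   idx_lines[i], path))
    }
    v
  }
  parsed <- vapply(seq_along(fields), parse_row, numeric(2))
  index <- parsed[1L, ]
  if (!isTRUE(all.equal(index, seq_along(index)))) {
    stop("profile indices must run consecutively from 1 in ", path)
  }
  numeric_series(molecule_id, parsed[2L, ], source = "ligand_profile")
}

#' Write a numeric series as a two-column profile file
#'
#' Inverse of [read_ligand_profile()]: emits `index<TAB>value` rows at
#' full double precision, so a write/read round trip reproduces the
#' values exactly.
#'
#' @param series A [numeric_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "numeric_series"))
  rows <- sprintf("%d\t%s", seq_along(series$values),
                  formatC(series$values, format = "g", digits = 17))
  writeLines(c(sprintf("# molecule_id: %s", series$molecule_id), rows), path)
  invisible(path)
}
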