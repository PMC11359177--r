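#' Read a FASTA proteome
#'
#' @param path FASTA file path.
#' @return A data frame with columns `id` (first whitespace token of the
#'   header) and `sequence` (uppercased, gaps and whitespace stripped).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
  dups <- unique(ids[duplicated(ids)])
  if (length(dups) > 0L) {
    stop("duplicate FASTA ids: ", paste(dups, collapse = ", "))
  }
  seqs <- gsub("[-.[:space:]]", "", toupper(as.character(set)))
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write FASTA records
#'
#' @param records Data frame with `id` and `sequence` columns (as
#'   returned by [read_fasta()]), or a named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  set <- Biostrings::AAStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Screen configuration
#'
#' @param target_frequency Normalized target frequency in (0, 0.5]; the
#'   filter keeps proteins whose cross-spectrum dominant peak falls at
#'   (the nearest grid bin to) this frequency.  Default 0.016, the
#'   ligand frequency commonly screened for.
#' @param tolerance_bins Allowed distance, in grid bins, between the
#'   dominant peak and the target bin (default 1; the target frequency is
#'   a rounded value, so one bin of slack is retained).
#' @param min_length Proteins shorter than this are skipped with a
#'   warning (default 8).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(target_frequency = 0.016, tolerance_bins = 1L,
                          min_length = 8L) {
  stopifnot(target_frequency > 0, target_frequency <= 0.5,
            tolerance_bins >= 0L, min_length >= 2L)
  structure(list(target_frequency = target_frequency,
                 tolerance_bins = as.integer(tolerance_bins),
                 min_length = as.integer(min_length)),
            class = "screen_config")
}

#' Screen a proteome against a ligand profile
#'
#' For each protein the EIIP series and the ligand profile are zero-padded
#' to a shared per-pair grid (`max(512, next power of two over the longer
#' series)`), their informational spectra multiplied, and the protein kept
#' when the dominant cross-spectrum peak lies within `tolerance_bins` of
#' the target frequency's nearest grid bin.  Hits are ranked by
#' cross-spectrum S/N (descending, id ascending on ties).
#'
#' @param records Proteome as a data frame with `id` and `sequence`
#'   (see [read_fasta()]) or a named character vector of sequences.
#' @param ligand A [numeric_series()] ligand profile.
#' @param cfg A [screen_config()].
#' @param table [eiip_table()] used for encoding.
#' @return A data frame of class `screen_hits` with columns
#'   `protein_id`, `length`, `n_fft`, `dominant_frequency`, `snr`, and an
#'   attribute `summary` giving counts screened / skipped / passed.
#' @export
screen_proteome <- function(records, ligand, cfg = screen_config(),
                            table = eiip_table()) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  stopifnot(nrow(records) >= 1L, inherits(ligand, "numeric_series"))
  lens <- nchar(records$sequence)
  skip <- lens < cfg$min_length
  if (any(skip)) {
    warning(sprintf("skipping %d record(s) shorter than %d residues",
                    sum(skip), cfg$min_length))
  }
  keep <- records[!skip, , drop = FALSE]
  if (nrow(keep) == 0L) stop("all records skipped (shorter than min_length)")

  ligand_cache <- new.env(parent = emptyenv())
  ligand_is <- function(n_fft) {
    key <- as.character(n_fft)
    if (is.null(ligand_cache[[key]])) {
      ligand_cache[[key]] <- informational_spectrum(ligand, n_fft)
    }
    ligand_cache[[key]]
  }

  n <- nrow(keep)
  out <- data.frame(protein_id = keep$id,
                    length = nchar(keep$sequence),
                    n_fft = integer(n),
                    dominant_frequency = numeric(n),
                    snr = numeric(n),
                    pass = logical(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    enc <- encode_protein(keep$sequence[i], table,
                          molecule_id = keep$id[i])
    n_fft <- default_n_fft(max(length(enc$values), length(ligand$values)))
    cs <- cross_spectrum(informational_spectrum(enc, n_fft),
                         ligand_is(n_fft))
    out$n_fft[i] <- n_fft
    if (isTRUE(cs$degenerate)) {
      out$dominant_frequency[i] <- NA_real_
      out$snr[i] <- NA_real_
      out$pass[i] <- FALSE
      next
    }
    k_target <- min(max(round(cfg$target_frequency * n_fft), 1L), n_fft %/% 2L)
    k_dom <- round(cs$dominant_frequency * n_fft)
    out$dominant_frequency[i] <- cs$dominant_frequency
    out$snr[i] <- cs$snr
    out$pass[i] <- abs(k_dom - k_target) <= cfg$tolerance_bins
  }

  hits <- out[out$pass, setdiff(names(out), "pass"), drop = FALSE]
  hits <- hits[order(-hits$snr, hits$protein_id), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "summary") <- c(screened = n, skipped = sum(skip),
                             passed = nrow(hits))
  class(hits) <- c("screen_hits", class(hits))
  hits
}

#' @export
print.screen_hits <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<screen_hits> screened %d, skipped %d, passed %d\n",
              s[["screened"]], s[["skipped"]], s[["passed"]]))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a hit table as TSV
#'
#' @param hits A `screen_hits` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
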