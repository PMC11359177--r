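#' Load a protein-protein interaction edge list
#'
#' Reads a tab-separated file `proteinA<TAB>proteinB[<TAB>score]` in the
#' style of a STRING per-seed export.  Self-loops and duplicate pairs
#' (order-independent; highest score kept) are dropped, and when a score
#' column is present at most `max_neighbors` highest-scoring partners are
#' retained per first-column identifier.
#'
#' @param path Edge-list path.
#' @param max_neighbors Per-seed neighbour cap (default `Inf`; applied
#'   only when the file carries scores).
#' @return A data frame of class `edge_list` with columns `a`, `b`,
#'   `score` (`NA` when absent) and an attribute `dropped` counting
#'   removed self-loops and duplicates.
#' @export
load_edges <- function(path, max_neighbors = Inf) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("empty edge list: ", path)
  rows <- which(keep)
  fields <- strsplit(lines[rows], "\t")
  nf <- lengths(fields)
  bad <- which(nf < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge row at line %d of '%s'", rows[bad[1L]], path))
  }
  a <- vapply(fields, `[`, character(1), 1L)
  b <- vapply(fields, `[`, character(1), 2L)
  score <- rep(NA_real_, length(a))
  has3 <- nf >= 3L
  if (any(has3)) {
    raw <- vapply(fields[has3], `[`, character(1), 3L)
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      stop(sprintf("non-numeric score at line %d of '%s'",
                   rows[has3][which(is.na(val))[1L]], path))
    }
    score[has3] <- val
  }
  self <- a == b
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  ord <- order(key, -ifelse(is.na(score), -Inf, score))
  dup <- logical(length(key))
  dup[ord] <- duplicated(key[ord])
  drop <- self | dup
  edges <- data.frame(a = a[!drop], b = b[!drop], score = score[!drop],
                      stringsAsFactors = FALSE)
  if (is.finite(max_neighbors) && any(!is.na(edges$score))) {
    pieces <- split(edges, edges$a)
    pieces <- lapply(pieces, function(d) {
      if (nrow(d) <= max_neighbors) return(d)
      d <- d[order(-d$score, d$b), , drop = FALSE]
      d[seq_len(max_neighbors), , drop = FALSE]
    })
    edges <- do.call(rbind, pieces)
  }
  rownames(edges) <- NULL
  attr(edges, "dropped") <- c(self_loops = sum(self), duplicates = sum(dup))
  class(edges) <- c("edge_list", class(edges))
  edges
}

neighbors_of <- function(edges, id) {
  setdiff(unique(c(edges$b[edges$a == id], edges$a[edges$b == id])), id)
}

#' Count screen hits inside each seed's interaction neighbourhood
#'
#' For every seed protein, intersects its network neighbours with the set
#' of screen hits, carrying each hit's cross-spectrum S/N through.
#' Identifier matching is exact and case-sensitive.
#'
#' @param seeds Character vector of seed identifiers.
#' @param edges An [load_edges()] edge list (or data frame with `a`, `b`).
#' @param hits A `screen_hits` table, any data frame with `protein_id`
#'   and `snr` columns, or a bare character vector of hit ids.
#' @return A data frame of class `seed_reports` with columns `seed_id`,
#'   `hit_count` and a list column `hit_interactors` (each element a
#'   data frame of `hit_id`, `snr` ordered by S/N descending), sorted by
#'   `hit_count` descending then `seed_id`.  Seeds absent from the edge
#'   list get `hit_count` 0 with a warning.
#' @export
count_hits_per_seed <- function(seeds, edges, hits) {
  stopifnot(length(seeds) >= 1L)
  if (is.character(hits)) {
    hits <- data.frame(protein_id = hits,
                       snr = rep(NA_real_, length(hits)),
                       stringsAsFactors = FALSE)
  }
  in_graph <- unique(c(edges$a, edges$b))
  absent <- setdiff(seeds, in_graph)
  if (length(absent) > 0L) {
    warning("seed(s) absent from edge list: ", paste(absent, collapse = ", "))
  }
  per_seed <- lapply(seeds, function(s) {
    nb <- neighbors_of(edges, s)
    sel <- hits[hits$protein_id %in% nb, c("protein_id", "snr"), drop = FALSE]
    sel <- sel[!duplicated(sel$protein_id), , drop = FALSE]
    sel <- sel[order(-xtfrm(sel$snr), sel$protein_id), , drop = FALSE]
    data.frame(hit_id = sel$protein_id, snr = sel$snr,
               stringsAsFactors = FALSE)
  })
  reports <- data.frame(seed_id = seeds,
                        hit_count = vapply(per_seed, nrow, integer(1)),
                        stringsAsFactors = FALSE)
  reports$hit_interactors <- per_seed
  reports <- reports[order(-reports$hit_count, reports$seed_id), ,
                     drop = FALSE]
  rownames(reports) <- NULL
  class(reports) <- c("seed_reports", class(reports))
  reports
}

#' @export
print.seed_reports <- function(x, ...) {
  cat(sprintf("<seed_reports> %d seeds, %d seed-hit pairs\n",
              nrow(x), sum(x$hit_count)))
  print.data.frame(x[, c("seed_id", "hit_count")], ...)
  invisible(x)
}

#' Multiplicity of each hit across seed networks
#'
#' @param reports A [count_hits_per_seed()] result.
#' @return A data frame with one row per hit: `hit_id`, `multiplicity`
#'   (number of distinct seed networks containing it) and `seeds` (the
#'   alphabetically sorted seed list, comma-separated), ordered by
#'   multiplicity descending then `hit_id`.
#' @export
hit_multiplicity <- function(reports) {
  stopifnot(inherits(reports, "seed_reports"))
  pairs <- do.call(rbind, lapply(seq_len(nrow(reports)), function(i) {
    hi <- reports$hit_interactors[[i]]
    if (nrow(hi) == 0L) return(NULL)
    data.frame(seed_id = reports$seed_id[i], hit_id = hi$hit_id,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) {
    return(data.frame(hit_id = character(0), multiplicity = integer(0),
                      seeds = character(0), stringsAsFactors = FALSE))
  }
  by_hit <- split(pairs$seed_id, pairs$hit_id)
  out <- data.frame(hit_id = names(by_hit),
                    multiplicity = vapply(by_hit,
                                          function(s) length(unique(s)),
                                          integer(1)),
                    seeds = vapply(by_hit,
                                   function(s) paste(sort(unique(s)),
                                                     collapse = ","),
                                   character(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$multiplicity, out$hit_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep seeds with at least k hits in their network
#'
#' @param reports A [count_hits_per_seed()] result.
#' @param k Minimum hit count (>= 0).
#' @return The filtered `seed_reports`, order preserved.
#' @export
filter_seeds_by_min_hits <- function(reports, k) {
  stopifnot(inherits(reports, "seed_reports"), k >= 0)
  out <- reports[reports$hit_count >= k, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bundled ovarian-neoplasm seed-network example
#'
#' A worked example shipped with the package: ISM-predicted targets of a
#' ruthenium-complex drug candidate (RuCN) located inside the STRING
#' experimental-interaction neighbourhoods of ovarian-neoplasm-associated
#' seed genes, with their reported cross-spectrum S/N values.
#'
#' @return A list with `seeds` (character), `edges` (an `edge_list`) and
#'   `hits` (data frame `protein_id`, `snr`).
#' @export
#' @examples
#' ex <- ovarian_target_example()
#' reports <- count_hits_per_seed(ex$seeds, ex$edges, ex$hits)
#' head(reports[, c("seed_id", "hit_count")])
ovarian_target_example <- function() {
  ext <- function(f) system.file("extdata", f, package = "ismftir",
                                 mustWork = TRUE)
  list(seeds = readLines(ext("ovarian_seeds.txt")),
       edges = load_edges(ext("ovarian_ppi_edges.tsv")),
       hits = utils::read.table(ext("ovarian_ism_hits.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE))
}

#' Write seed reports as a long TSV
#'
#' One row per seed-hit pair with the hit's S/N and cross-network
#' multiplicity; seeds with no hits appear once with empty hit fields.
#'
#' @param reports A [count_hits_per_seed()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seed_reports <- function(reports, path) {
  mult <- hit_multiplicity(reports)
  rows <- lapply(seq_len(nrow(reports)), function(i) {
    hi <- reports$hit_interactors[[i]]
    if (nrow(hi) == 0L) {
      return(data.frame(seed_id = reports$seed_id[i], hit_id = "",
                        snr = NA_real_, multiplicity = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    data.frame(seed_id = reports$seed_id[i], hit_id = hi$hit_id,
               snr = hi$snr,
               multiplicity = mult$multiplicity[match(hi$hit_id, mult$hit_id)],
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
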