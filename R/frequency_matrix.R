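#' Frequency matrix of CSB 2 variant hits
#'
#' Hit counts indexed by (first-run length m, second-run length n) for each
#' interrupt base, plus a count vector for continuous tracts indexed by
#' total length k. `total_hits` always equals the sum of all cells plus
#' the continuous counts.
#'
#' @param variant_counts Named integer vector of hit counts keyed by
#'   canonical variant name (names parseable by [parse_nomenclature()]).
#' @param m_range,n_range Integer vectors defining the matrix grid.
#' @param continuous_range Integer vector of continuous lengths covered.
#' @return A `frequency_matrix` object: list with `counts` (named list of
#'   m-by-n integer matrices per interrupt base), `continuous` (named
#'   integer vector by k), and `total_hits`.
#' @export
frequency_matrix <- function(variant_counts, m_range = 1:12,
                             n_range = 1:12, continuous_range = integer(0)) {
  stopifnot(is.numeric(variant_counts), !is.null(names(variant_counts)),
            all(variant_counts >= 0))
  m_range <- as.integer(m_range); n_range <- as.integer(n_range)
  continuous_range <- as.integer(continuous_range)
  counts <- list()
  cont <- setNames(integer(length(continuous_range)),
                   as.character(continuous_range))
  mk <- function() matrix(0L, length(m_range), length(n_range),
                          dimnames = list(m = as.character(m_range),
                                          n = as.character(n_range)))
  for (nm in names(variant_counts)) {
    v <- parse_nomenclature(nm)
    cnt <- as.integer(variant_counts[[nm]])
    if (cnt == 0L) next
    if (is_continuous(v)) {
      key <- as.character(v$first_run)
      if (!key %in% names(cont))
        stop("continuous length ", key, " outside continuous_range",
             call. = FALSE)
      cont[key] <- cont[key] + cnt
    } else {
      if (!v$first_run %in% m_range || !v$second_run %in% n_range)
        stop("variant ", nm, " outside the matrix grid", call. = FALSE)
      if (is.null(counts[[v$interrupt]])) counts[[v$interrupt]] <- mk()
      counts[[v$interrupt]][as.character(v$first_run),
                            as.character(v$second_run)] <-
        counts[[v$interrupt]][as.character(v$first_run),
                              as.character(v$second_run)] + cnt
    }
  }
  structure(list(counts = counts, continuous = cont,
                 m_range = m_range, n_range = n_range,
                 total_hits = sum(vapply(counts, sum, 0)) + sum(cont)),
            class = "frequency_matrix")
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat("<frequency_matrix> ", x$total_hits, " hits (",
      sum(vapply(x$counts, sum, 0)), " interrupted over {",
      paste(names(x$counts), collapse = ","), "}, ",
      sum(x$continuous), " continuous)\n", sep = "")
  invisible(x)
}

#' Long-format view of a frequency matrix
#'
#' @param fm A [frequency_matrix()].
#' @param drop_zero Drop zero-count rows (default TRUE).
#' @return A data.frame with columns `variant`, `interrupt`, `m`, `n`,
#'   `k`, `count`.
#' @export
as_variant_counts <- function(fm, drop_zero = TRUE) {
  stopifnot(inherits(fm, "frequency_matrix"))
  rows <- list()
  for (x in names(fm$counts)) {
    mat <- fm$counts[[x]]
    idx <- which(mat >= 0, arr.ind = TRUE)
    rows[[x]] <- data.frame(
      variant = paste0("G", rownames(mat)[idx[, 1]], x, "G",
                       colnames(mat)[idx[, 2]]),
      interrupt = x,
      m = as.integer(rownames(mat)[idx[, 1]]),
      n = as.integer(colnames(mat)[idx[, 2]]),
      k = NA_integer_, count = as.integer(mat[idx]),
      stringsAsFactors = FALSE)
  }
  if (length(fm$continuous))
    rows$cont <- data.frame(
      variant = paste0("G", names(fm$continuous)),
      interrupt = NA_character_, m = NA_integer_, n = NA_integer_,
      k = as.integer(names(fm$continuous)),
      count = as.integer(fm$continuous), stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (drop_zero) out <- out[out$count > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read/write a frequency matrix as TSV
#'
#' The on-disk form is the long format of [as_variant_counts()] including
#' zero cells, so grid bounds survive the round trip.
#'
#' @param fm A [frequency_matrix()].
#' @param path File path.
#' @return `write_frequency_matrix()`: `path` invisibly;
#'   `read_frequency_matrix()`: a [frequency_matrix()].
#' @export
write_frequency_matrix <- function(fm, path) {
  write.table(as_variant_counts(fm, drop_zero = FALSE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequency_matrix
#' @export
read_frequency_matrix <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  ms <- tab$m[!is.na(tab$m)]; ns <- tab$n[!is.na(tab$n)]
  ks <- tab$k[!is.na(tab$k)]
  frequency_matrix(setNames(tab$count, tab$variant),
                   m_range = if (length(ms)) seq(min(ms), max(ms)) else 1:12,
                   n_range = if (length(ns)) seq(min(ns), max(ns)) else 1:12,
                   continuous_range = if (length(ks)) seq(min(ks), max(ks))
                                      else integer(0))
}
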