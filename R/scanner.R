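#' Build the combinatorial CSB 2 search-string library
#'
#' Enumerates one full-length search string per tract variant: the G-rich
#' 5' flank, the literal tract (\eqn{G_mXG_n} over the requested run-length
#' grid and interrupt bases, plus continuous \eqn{G_k} lengths), and the
#' G-rich 3' flank. Because the flanks abut the tract with non-G residues,
#' no library string can be a substring of another; this mutual exclusivity
#' is nevertheless re-checked pairwise at build time. Strings shorter than
#' `min_length` (an exact-match engine's minimum query size) are extended
#' symmetrically into the anchor context, one residue at a time starting on
#' the 5' side, and the extension is reported via a message.
#'
#' @param anchors An [anchor_pair()].
#' @param m_range,n_range Integer vectors of first/second-run lengths for
#'   interrupted variants (default 1-12).
#' @param interrupt_set Subset of `c("A", "C", "T")`; may be empty.
#' @param continuous_range Integer vector of continuous tract lengths k
#'   (default empty).
#' @param min_length Minimum search-string length in nt (default 25).
#' @return A `search_library`: a data.frame with columns `variant`,
#'   `string`, `interrupt`, `m`, `n`, `k`, `extended`, ordered by
#'   (interrupt, m, n) then continuous k, carrying the build parameters as
#'   attributes.
#' @examples
#' lib <- build_search_strings(rcrs_anchors(), m_range = 4:7, n_range = 6:9)
#' lib$string[lib$variant == "G5AG7"]
#' @export
build_search_strings <- function(anchors, m_range = 1:12, n_range = 1:12,
                                 interrupt_set = "A",
                                 continuous_range = integer(0),
                                 min_length = 25L) {
  stopifnot(inherits(anchors, "anchor_pair"))
  interrupt_set <- as.character(interrupt_set)
  if (!all(interrupt_set %in% c("A", "C", "T")))
    stop("interrupt_set must be a subset of {A, C, T}", call. = FALSE)
  rows <- list()
  for (x in sort(interrupt_set)) for (m in sort(m_range)) for (n in sort(n_range))
    rows[[length(rows) + 1L]] <- list(
      variant = paste0("G", m, x, "G", n),
      tract = paste0(strrep("G", m), x, strrep("G", n)),
      interrupt = x, m = as.integer(m), n = as.integer(n), k = NA_integer_)
  for (k in sort(continuous_range))
    rows[[length(rows) + 1L]] <- list(
      variant = paste0("G", k), tract = strrep("G", k),
      interrupt = NA_character_, m = NA_integer_, n = NA_integer_,
      k = as.integer(k))
  if (length(rows) == 0L) {
    lib <- data.frame(variant = character(), string = character(),
                      interrupt = character(), m = integer(), n = integer(),
                      k = integer(), extended = integer())
    attr(lib, "min_length") <- as.integer(min_length)
    attr(lib, "anchors") <- anchors
    class(lib) <- c("search_library", "data.frame")
    return(lib)
  }
  build_one <- function(r) {
    s <- paste0(anchors$flank5, r$tract, anchors$flank3)
    ext <- 0L
    deficit <- min_length - nchar(s)
    if (deficit > 0L) {
      add5 <- ceiling(deficit / 2); add3 <- deficit - add5
      if (add5 > nchar(anchors$context5) || add3 > nchar(anchors$context3))
        stop("cannot extend flanks to min_length = ", min_length,
             ": anchor context exhausted for variant ", r$variant,
             call. = FALSE)
      s <- paste0(substring(anchors$context5,
                            nchar(anchors$context5) - add5 + 1L),
                  s,
                  substring(anchors$context3, 1L, add3))
      ext <- as.integer(deficit)
    }
    c(r, list(string = s, extended = ext))
  }
  rows <- lapply(rows, build_one)
  lib <- data.frame(
    variant = vapply(rows, `[[`, "", "variant"),
    string = vapply(rows, `[[`, "", "string"),
    interrupt = vapply(rows, `[[`, "", "interrupt"),
    m = vapply(rows, `[[`, 1L, "m"),
    n = vapply(rows, `[[`, 1L, "n"),
    k = vapply(rows, `[[`, 1L, "k"),
    extended = vapply(rows, `[[`, 1L, "extended"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(lib$variant))
    stop("duplicate variants in library build", call. = FALSE)
  # pairwise mutual-exclusivity check: no string contains another
  bylen <- lib$string[order(nchar(lib$string))]
  for (i in seq_along(bylen)) {
    longer <- bylen[-seq_len(i)]
    longer <- longer[nchar(longer) > nchar(bylen[i])]
    if (length(longer) && any(grepl(bylen[i], longer, fixed = TRUE)))
      stop("library exclusivity violated: '", bylen[i],
           "' is a substring of another search string", call. = FALSE)
  }
  if (any(lib$extended > 0L))
    message(sum(lib$extended > 0L), " search string(s) below min_length = ",
            min_length, " nt; flanks extended symmetrically into the ",
            "anchor context (max extension ", max(lib$extended), " nt)")
  attr(lib, "min_length") <- as.integer(min_length)
  attr(lib, "anchors") <- anchors
  class(lib) <- c("search_library", "data.frame")
  lib
}

#' Scan sequence records for exact search-string hits
#'
#' Reports every exact, full-length occurrence of a library string in each
#' record. Matching is literal substring search, the in-silico equivalent
#' of a 100%-identity exact-match query. By default both strands are
#' scanned and all hits are reported in G-rich nomenclature with the strand
#' on which the G-rich string was read (`"+"` = as stored, `"-"` = the
#' record stores the C-rich/reference orientation); deposited sequences may
#' be on either strand. For circular records the origin junction is also
#' scanned.
#'
#' @param records A list of [seq_record()] objects (or a single record).
#' @param library A `search_library` from [build_search_strings()].
#' @param both_strands Scan the reverse complement as well (default TRUE).
#' @return A data.frame of hits with columns `record_id`, `variant`,
#'   `start`, `end` (1-based inclusive on the record as stored; for
#'   circular records a hit spanning the origin junction keeps
#'   `end > length`) and `strand` (`"+"` = the G-rich string reads on the
#'   stored strand, `"-"` = on its reverse complement).
#' @export
scan_sequences <- function(records, library, both_strands = TRUE) {
  stopifnot(inherits(library, "search_library"))
  if (inherits(records, "seq_record")) records <- list(records)
  empty <- data.frame(record_id = character(), variant = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (length(records) == 0L || nrow(library) == 0L) return(empty)
  ids <- vapply(records, function(r) r$id, "")
  lens <- vapply(records, function(r) nchar(r$residues), 1L)
  maxw <- max(nchar(library$string))
  # circular records: append a junction window so origin-spanning loci match
  texts <- vapply(records, function(r) {
    if (r$circular && nchar(r$residues) > 1L)
      paste0(r$residues, substring(r$residues, 1L,
                                   min(maxw - 1L, nchar(r$residues))))
    else r$residues
  }, "")
  out <- list()
  strands <- c("+", if (both_strands) "-")
  for (st in strands) {
    for (j in seq_len(nrow(library))) {
      pat <- if (st == "+") library$string[j]
             else reverse_complement(library$string[j])
      w <- nchar(pat)
      pos <- gregexpr(pat, texts, fixed = TRUE)
      for (i in seq_along(texts)) {
        p <- pos[[i]]
        if (p[1] == -1L) next
        # a junction hit is attributed to its (unique) start within [1, len]
        p <- as.integer(p)[as.integer(p) <= lens[i]]
        if (!length(p)) next
        out[[length(out) + 1L]] <- data.frame(
          record_id = ids[i], variant = library$variant[j],
          start = p, end = p + w - 1L, strand = st,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty)
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$record_id, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  # one count per matched locus: drop duplicate (record, start, strand)
  hits[!duplicated(hits[c("record_id", "start", "strand")]), , drop = FALSE]
}

#' @rdname scan_sequences
#' @param record A single [seq_record()].
#' @export
scan_record <- function(record, library, both_strands = TRUE) {
  scan_sequences(list(record), library, both_strands = both_strands)
}

#' Classify the CSB 2 locus of a record by anchored run-length parsing
#'
#' Open-ended classifier (and brute-force cross-check for the library
#' scanner): locates the exact flank pair on either strand, run-length
#' parses the intervening segment, and names it \eqn{G_mXG_n} or \eqn{G_k}
#' when it has that shape. Segments with more than one interruption, an
#' interruption longer than one residue, a degenerate base (N), or no
#' guanine run at all are reported as `"complex"` (never guessed);
#' records without the flank pair are `"absent"`.
#'
#' @param record A [seq_record()].
#' @param anchors An [anchor_pair()].
#' @param both_strands Also search the reverse complement (default TRUE).
#' @return A character scalar: a canonical variant name, `"complex"`, or
#'   `"absent"`. The full per-locus table (columns `start`, `end`,
#'   `strand`, `class`) is attached as attribute `"loci"`; multiple
#'   non-overlapping flank pairs raise a warning and all loci are
#'   classified.
#' @export
classify_locus <- function(record, anchors, both_strands = TRUE) {
  stopifnot(inherits(record, "seq_record"), inherits(anchors, "anchor_pair"))
  loci <- list()
  strands <- c("+", if (both_strands) "-")
  for (st in strands) {
    s <- if (st == "+") record$residues else reverse_complement(record$residues)
    len <- nchar(s)
    f5 <- gregexpr(anchors$flank5, s, fixed = TRUE)[[1]]
    if (f5[1] == -1L) next
    f3 <- gregexpr(anchors$flank3, s, fixed = TRUE)[[1]]
    if (f3[1] == -1L) next
    for (p5 in as.integer(f5)) {
      seg_start <- p5 + nchar(anchors$flank5)
      nxt <- as.integer(f3)[as.integer(f3) >= seg_start]
      if (!length(nxt)) next
      p3 <- min(nxt)
      seg <- substring(s, seg_start, p3 - 1L)
      cls <- classify_segment(seg)
      start <- if (st == "+") p5 else len - (p3 + nchar(anchors$flank3) - 1L) + 1L
      end <- if (st == "+") p3 + nchar(anchors$flank3) - 1L else len - p5 + 1L
      loci[[length(loci) + 1L]] <- data.frame(
        start = start, end = end, strand = st, class = cls,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(loci)) {
    out <- "absent"
    attr(out, "loci") <- data.frame(start = integer(), end = integer(),
                                    strand = character(), class = character(),
                                    stringsAsFactors = FALSE)
    return(out)
  }
  loci <- do.call(rbind, loci)
  if (nrow(loci) > 1L)
    warning("record '", record$id, "': ", nrow(loci),
            " CSB 2 loci found; all classified", call. = FALSE)
  out <- loci$class[1L]
  attr(out, "loci") <- loci
  out
}

# run-length shape of an inter-flank segment -> variant name or "complex"
classify_segment <- function(seg) {
  if (!nzchar(seg)) return("complex")
  runs <- run_length_encode(seg)
  if (nrow(runs) == 1L && runs$base == "G")
    return(paste0("G", runs$count))
  if (nrow(runs) == 3L && runs$base[1] == "G" && runs$base[3] == "G" &&
      runs$count[2] == 1L && runs$base[2] %in% c("A", "C", "T"))
    return(paste0("G", runs$count[1], runs$base[2], "G", runs$count[3]))
  "complex"
}

#' Tally scanner hits into a frequency matrix
#'
#' Folds [scan_sequences()] over a record set and aggregates hit counts
#' into a [frequency_matrix()]: one cell per (first-run, second-run)
#' combination for each interrupt base, plus a count vector for continuous
#' tracts. Each record contributes one count per matched locus; records
#' whose sequence does not cover the CSB 2 locus contribute nothing. With
#' `strict_per_record = TRUE` a record contributes at most one count (its
#' first locus) even if it carries several.
#'
#' @inheritParams scan_sequences
#' @param strict_per_record Count multi-locus records once (default FALSE,
#'   with a warning when multi-locus records are present).
#' @return A [frequency_matrix()].
#' @export
count_hits <- function(records, library, both_strands = TRUE,
                       strict_per_record = FALSE) {
  hits <- scan_sequences(records, library, both_strands = both_strands)
  multi <- unique(hits$record_id[duplicated(hits$record_id)])
  if (length(multi)) {
    if (strict_per_record)
      hits <- hits[!duplicated(hits$record_id), , drop = FALSE]
    else
      warning(length(multi), " record(s) carry multiple CSB 2 loci; ",
              "counted per locus", call. = FALSE)
  }
  counts <- table(factor(hits$variant, levels = library$variant))
  frequency_matrix(setNames(as.integer(counts), names(counts)),
                   m_range = range_or_default(library$m, 1:12),
                   n_range = range_or_default(library$n, 1:12),
                   continuous_range = if (all(is.na(library$k))) integer(0)
                                      else seq_len(max(library$k, na.rm = TRUE)))
}

range_or_default <- function(x, default) {
  x <- x[!is.na(x)]
  if (!length(x)) default else seq(min(x), max(x))
}
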