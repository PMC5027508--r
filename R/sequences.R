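#' Create a sequence record
#'
#' A light container for one DNA sequence. Residues are upper-cased and
#' restricted to the alphabet \{A, C, G, T, N\}; any other IUPAC code is
#' mapped to `N` with a warning (degenerate positions inside a candidate
#' tract make the locus unclassifiable rather than guessed at).
#'
#' @param id Record identifier.
#' @param residues DNA sequence string.
#' @param description Free-text description (defaults to empty).
#' @param circular Logical; `TRUE` for a complete circular genome, in which
#'   case scanning also covers the origin junction.
#' @return A `seq_record` object (list with `id`, `description`, `residues`,
#'   `circular`).
#' @export
seq_record <- function(id, residues, description = "", circular = FALSE) {
  if (!nzchar(residues)) stop("residues must be non-empty", call. = FALSE)
  residues <- toupper(residues)
  other <- gsub("[ACGTN]", "", residues)
  if (nzchar(other)) {
    warning("record '", id, "': ", nchar(other),
            " non-ACGTN residue(s) mapped to N", call. = FALSE)
    residues <- gsub("[^ACGTN]", "N", residues)
  }
  structure(list(id = as.character(id),
                 description = as.character(description),
                 residues = residues, circular = isTRUE(circular)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat("<seq_record> ", x$id, "  (", nchar(x$residues), " nt",
      if (x$circular) ", circular", ")\n", sep = "")
  invisible(x)
}

#' Read sequence records from a multi-FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()]; wrapped or unwrapped line styles
#' are both accepted. Non-ACGTN codes are mapped to N (see [seq_record()]).
#'
#' @param path Path to a FASTA file.
#' @param circular Logical, applied to every record.
#' @return A list of [seq_record()] objects.
#' @export
read_sequences <- function(path, circular = FALSE) {
  ss <- Biostrings::readDNAStringSet(path)
  full <- names(ss)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  lapply(seq_along(ss), function(i)
    seq_record(ids[i], as.character(ss[[i]]), desc[i], circular))
}

#' Write sequence records to a FASTA file
#'
#' @param records List of [seq_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path) {
  ss <- Biostrings::DNAStringSet(vapply(records, function(r) r$residues, ""))
  names(ss) <- vapply(records, function(r)
    if (nzchar(r$description)) paste(r$id, r$description) else r$id, "")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' @param x A DNA string over \{A, C, G, T, N\}.
#' @return The reverse complement string.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Run-length encode a DNA sequence
#'
#' Parses a sequence into maximal single-base runs; the underlying
#' primitive of tract classification.
#'
#' @param seq A string over \{A, C, G, T, N\} (empty allowed).
#' @return A data.frame with columns `base` and `count`; concatenating the
#'   runs reproduces the input ([run_length_decode()]).
#' @export
run_length_encode <- function(seq) {
  if (!nzchar(seq))
    return(data.frame(base = character(), count = integer()))
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  data.frame(base = r$values, count = as.integer(r$lengths))
}

#' @rdname run_length_encode
#' @param runs A data.frame as returned by [run_length_encode()].
#' @export
run_length_decode <- function(runs) {
  paste(strrep(runs$base, runs$count), collapse = "")
}

#' CSB 2 coordinate system
#'
#' Coordinates are handled in two conventions: user-facing positions are
#' 1-based inclusive on the reference (rCRS) numbering, while internal
#' intervals on a scanned strand are 0-based half-open. The variable tract
#' sits at rCRS 303-315 by default and the anchor (search-string) region at
#' rCRS 294-325, which strictly contains it.
#'
#' @param tract_interval_rcrs Integer length-2 vector, 1-based inclusive.
#' @param anchor_region_rcrs Integer length-2 vector, 1-based inclusive;
#'   must strictly contain `tract_interval_rcrs`.
#' @return A `coordinate_system` object.
#' @export
coordinate_system <- function(tract_interval_rcrs = c(303L, 315L),
                              anchor_region_rcrs = c(294L, 325L)) {
  t <- as.integer(tract_interval_rcrs); a <- as.integer(anchor_region_rcrs)
  stopifnot(length(t) == 2L, length(a) == 2L, t[1] <= t[2], a[1] <= a[2])
  if (!(a[1] < t[1] && t[2] < a[2]))
    stop("anchor region must strictly contain the tract interval",
         call. = FALSE)
  structure(list(tract_interval_rcrs = t, anchor_region_rcrs = a),
            class = "coordinate_system")
}

#' Convert between rCRS numbering and internal 0-based intervals
#'
#' `rcrs_to_internal()` maps a 1-based inclusive rCRS interval to the
#' 0-based half-open interval on a sequence whose first residue is rCRS
#' position `offset_rcrs`; `internal_to_rcrs()` is its inverse.
#'
#' @param interval Length-2 integer vector.
#' @param offset_rcrs rCRS position of the sequence's first residue.
#' @return Length-2 integer vector in the other convention.
#' @export
rcrs_to_internal <- function(interval, offset_rcrs) {
  c(interval[1] - offset_rcrs, interval[2] - offset_rcrs + 1L)
}

#' @rdname rcrs_to_internal
#' @export
internal_to_rcrs <- function(interval, offset_rcrs) {
  c(interval[1] + offset_rcrs, interval[2] + offset_rcrs - 1L)
}

#' Map transcript length to a 3'-end reference position
#'
#' LSP transcription proceeds towards decreasing rCRS numbering, so a
#' transcript of `transcript_len` nucleotides initiated at `tss_rcrs` has
#' its 3' end at `tss_rcrs - (transcript_len - 1)`. Conversely,
#' `transcript_length_to()` gives the length needed to reach a fixed
#' downstream residue; inserting a spacer of `insertion_len` nucleotides
#' between the tract and its downstream terminator lengthens that
#' transcript by exactly `insertion_len`.
#'
#' @param tss_rcrs 1-based rCRS position of the transcription start site
#'   (a configuration value, not a built-in constant).
#' @param transcript_len Transcript length in nt (>= 1).
#' @param insertion_len Length in nt of a spacer inserted downstream of the
#'   tract (>= 0).
#' @return `transcript_end_position()`: the rCRS position of the 3' end.
#' @export
transcript_end_position <- function(tss_rcrs, transcript_len,
                                    insertion_len = 0L) {
  tss_rcrs <- as.integer(tss_rcrs)
  transcript_len <- as.integer(transcript_len)
  insertion_len <- as.integer(insertion_len)
  stopifnot(transcript_len >= 1L, insertion_len >= 0L)
  pos <- tss_rcrs - (transcript_len - 1L)
  if (pos < 1L)
    stop("transcript runs past rCRS position 1 (circular wrap is outside ",
         "the non-coding-region window)", call. = FALSE)
  pos
}

#' @rdname transcript_end_position
#' @param end_rcrs rCRS position of the fixed downstream 3'-end residue.
#' @return `transcript_length_to()`: the transcript length in nt reaching
#'   `end_rcrs`, including any inserted spacer.
#' @export
transcript_length_to <- function(tss_rcrs, end_rcrs, insertion_len = 0L) {
  stopifnot(end_rcrs <= tss_rcrs, insertion_len >= 0L)
  as.integer(tss_rcrs - end_rcrs + 1L + insertion_len)
}

#' Read a termination-product (TP) percentage table
#'
#' TP tables key mean termination-product percentages (band density in the
#' TP window as a percentage of total lane density) by canonical variant
#' name; named non-tract constructs (e.g. `"G>A"`, `"dTP"`, `"A6"`,
#' `"(UC)3"`) are allowed as keys. The packaged fixture
#' `system.file("extdata", "tp_table_printed.tsv", package = "csb2scan")`
#' carries only values printed in the survey's text, each with a provenance
#' tag.
#'
#' @param path Path to a TSV with columns `variant`, `mean_tp`, and
#'   optionally `sd`, `n_reps`, `provenance`.
#' @return A data.frame of class `tp_table`.
#' @export
read_tp_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("variant", "mean_tp") %in% names(tab)))
    stop("TP table needs 'variant' and 'mean_tp' columns", call. = FALSE)
  if (anyNA(tab$mean_tp) || any(tab$mean_tp < 0 | tab$mean_tp > 100))
    stop("mean_tp values must lie in [0, 100]", call. = FALSE)
  if (anyDuplicated(tab$variant))
    stop("duplicate variant keys in TP table", call. = FALSE)
  if ("provenance" %in% names(tab) && any(!nzchar(tab$provenance)))
    stop("every TP table entry needs a non-empty provenance", call. = FALSE)
  class(tab) <- c("tp_table", "data.frame")
  tab
}

#' @rdname read_tp_table
#' @param variants Character vector of variant names.
#' @param mean_tp Numeric percentages in `[0, 100]`.
#' @param sd,n_reps,provenance Optional per-entry metadata.
#' @export
tp_table <- function(variants, mean_tp, sd = NA_real_, n_reps = NA_integer_,
                     provenance = "synthetic") {
  stopifnot(length(variants) == length(mean_tp),
            all(mean_tp >= 0 & mean_tp <= 100))
  tab <- data.frame(variant = variants, mean_tp = mean_tp, sd = sd,
                    n_reps = n_reps, provenance = provenance,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab$variant))
    stop("duplicate variant keys in TP table", call. = FALSE)
  class(tab) <- c("tp_table", "data.frame")
  tab
}
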