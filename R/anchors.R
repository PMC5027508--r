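#' Flank anchors for the CSB 2 locus
#'
#' An `anchor_pair` fixes the invariant sequence on either side of the
#' variable G-tract. Anchors may be defined on the reference strand (fields
#' in ascending rCRS orientation: `upstream_flank` runs from rCRS 294 to
#' the tract start, `downstream_flank` from the tract end to rCRS 325) or
#' directly on the G-rich strand; internally they are stored on the G-rich
#' strand as `flank5` (5' of the tract) and `flank3` (3' of the tract).
#' Optional context sequences extending outward from the flanks support
#' symmetric flank extension when short search strings fall below the
#' scanner's minimum length.
#'
#' The G-rich-strand invariant that makes a search-string library mutually
#' exclusive is enforced at construction: `flank5` must end with a non-G
#' residue and `flank3` must begin with one, so the guanine runs of the
#' tract cannot bleed into the flanks.
#'
#' @param upstream_flank,downstream_flank Flank sequences in the chosen
#'   strand convention (see above).
#' @param strand_of_definition `"reference"` (rCRS-ascending, C-rich at
#'   this locus) or `"G-rich"`.
#' @param upstream_context,downstream_context Optional sequence continuing
#'   outward beyond each flank, same strand convention; used only for
#'   minimum-length extension.
#' @return An `anchor_pair` object with G-rich-strand fields `flank5`,
#'   `flank3`, `context5`, `context3`.
#' @seealso [rcrs_anchors()] for the packaged rCRS 294-325 defaults.
#' @export
anchor_pair <- function(upstream_flank, downstream_flank,
                        strand_of_definition = c("reference", "G-rich"),
                        upstream_context = "", downstream_context = "") {
  strand_of_definition <- match.arg(strand_of_definition)
  up <- toupper(upstream_flank); dn <- toupper(downstream_flank)
  upc <- toupper(upstream_context); dnc <- toupper(downstream_context)
  if (!nzchar(up) || !nzchar(dn))
    stop("both flanks must be non-empty", call. = FALSE)
  if (strand_of_definition == "reference") {
    flank5 <- reverse_complement(dn)
    flank3 <- reverse_complement(up)
    context5 <- if (nzchar(dnc)) reverse_complement(dnc) else ""
    context3 <- if (nzchar(upc)) reverse_complement(upc) else ""
  } else {
    flank5 <- up; flank3 <- dn
    context5 <- upc; context3 <- dnc
  }
  if (substring(flank5, nchar(flank5)) == "G")
    stop("G-rich 5' flank must end with a non-G residue", call. = FALSE)
  if (substring(flank3, 1L, 1L) == "G")
    stop("G-rich 3' flank must begin with a non-G residue", call. = FALSE)
  structure(list(flank5 = flank5, flank3 = flank3,
                 context5 = context5, context3 = context3,
                 strand_of_definition = strand_of_definition),
            class = "anchor_pair")
}

#' @export
print.anchor_pair <- function(x, ...) {
  cat("<anchor_pair> (G-rich strand)\n",
      "  5' flank: ", x$flank5, "\n  3' flank: ", x$flank3, "\n",
      "  context:  ", nchar(x$context5), " nt / ", nchar(x$context3),
      " nt\n", sep = "")
  invisible(x)
}

#' Read anchors from a FASTA-style configuration file
#'
#' The configuration is a small FASTA file with records named
#' `upstream_flank` and `downstream_flank` (required) and
#' `upstream_context` / `downstream_context` (optional), plus a
#' `strand=reference|G-rich` token in any record description.
#'
#' @param path Path to the anchor FASTA configuration.
#' @return An [anchor_pair()].
#' @export
read_anchors <- function(path) {
  recs <- read_sequences(path)
  names(recs) <- vapply(recs, function(r) r$id, "")
  need <- c("upstream_flank", "downstream_flank")
  if (!all(need %in% names(recs)))
    stop("anchor config must contain records 'upstream_flank' and ",
         "'downstream_flank'", call. = FALSE)
  descs <- paste(vapply(recs, function(r) r$description, ""), collapse = " ")
  strand <- if (grepl("strand=G-rich", descs, fixed = TRUE)) "G-rich"
            else "reference"
  getres <- function(nm) if (nm %in% names(recs)) recs[[nm]]$residues else ""
  anchor_pair(recs[["upstream_flank"]]$residues,
              recs[["downstream_flank"]]$residues,
              strand_of_definition = strand,
              upstream_context = getres("upstream_context"),
              downstream_context = getres("downstream_context"))
}

#' Packaged CSB 2 anchors and reference context
#'
#' `rcrs_anchors()` returns the default anchor pair for the CSB 2 locus:
#' reference-strand flanks covering rCRS 294-302 (upstream) and 316-325
#' (downstream) around the variable tract at 303-315, with context out to
#' rCRS 241 and 400 for minimum-length flank extension.
#' `rcrs_context()` returns the packaged reference-strand context sequence
#' (rCRS 241-400) used as the template of the synthetic survey generator.
#'
#' @return `rcrs_anchors()`: an [anchor_pair()]; `rcrs_context()`: a
#'   [seq_record()] whose first residue is rCRS position 241.
#' @export
rcrs_anchors <- function() {
  read_anchors(system.file("extdata", "csb2_anchors.fasta",
                           package = "csb2scan", mustWork = TRUE))
}

#' @rdname rcrs_anchors
#' @export
rcrs_context <- function() {
  read_sequences(system.file("extdata", "rcrs_context_241_400.fasta",
                             package = "csb2scan", mustWork = TRUE))[[1]]
}
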