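#' CSB 2 G-tract variant
#'
#' A `gtract_variant` describes one allele of the CSB 2 G-tract on the
#' G-rich strand: a first guanine run of length `first_run`, an optional
#' single interrupting base (`"A"`, `"C"` or `"T"`), and a second guanine
#' run of length `second_run`. Continuous tracts (no interrupting base) are
#' written \eqn{G_k} and have `second_run = 0`.
#'
#' @param first_run Integer number of guanines in the first run (>= 1). For
#'   a continuous tract this is the full tract length k.
#' @param interrupt One of `"A"`, `"C"`, `"T"`, or `NA` for a continuous
#'   tract.
#' @param second_run Integer number of guanines in the second run; must be
#'   >= 1 when `interrupt` is a base and exactly 0 when `interrupt` is `NA`.
#'
#' @return An object of class `gtract_variant` with fields `first_run`,
#'   `interrupt` (`NA_character_` when continuous) and `second_run`.
#' @seealso [parse_nomenclature()], [render_nomenclature()],
#'   [adenine_position()], [light_strand_name()]
#' @examples
#' gtract_variant(5, "A", 7)   # the reference (rCRS) allele G5AG7
#' gtract_variant(13)          # the continuous allele G13
#' @export
gtract_variant <- function(first_run, interrupt = NA_character_,
                           second_run = 0L) {
  first_run <- as.integer(first_run)
  second_run <- as.integer(second_run)
  if (is.na(first_run) || first_run < 1L)
    stop("first_run must be an integer >= 1", call. = FALSE)
  if (is.na(interrupt)) {
    if (second_run != 0L)
      stop("continuous tracts must have second_run = 0", call. = FALSE)
    interrupt <- NA_character_
  } else {
    interrupt <- toupper(as.character(interrupt))
    if (!interrupt %in% c("A", "C", "T"))
      stop("interrupt base must be one of A, C, T (got '", interrupt, "')",
           call. = FALSE)
    if (is.na(second_run) || second_run < 1L)
      stop("interrupted tracts must have second_run >= 1", call. = FALSE)
  }
  structure(list(first_run = first_run, interrupt = interrupt,
                 second_run = second_run),
            class = "gtract_variant")
}

#' @export
print.gtract_variant <- function(x, ...) {
  kind <- if (is_continuous(x)) "continuous" else "discontinuous"
  cat("<gtract_variant> ", render_nomenclature(x), "  (", kind, ", ",
      total_guanines(x), " G, tract length ", tract_length(x), " nt)\n",
      sep = "")
  invisible(x)
}

#' Is a variant a continuous (uninterrupted) tract?
#' @param v A [gtract_variant()].
#' @return Logical scalar.
#' @export
is_continuous <- function(v) {
  stopifnot(inherits(v, "gtract_variant"))
  is.na(v$interrupt)
}

#' Total guanines and tract length of a variant
#'
#' `total_guanines()` is `first_run + second_run`; `tract_length()` adds one
#' for the interrupting base when present.
#' @param v A [gtract_variant()].
#' @return Integer scalar.
#' @export
total_guanines <- function(v) {
  stopifnot(inherits(v, "gtract_variant"))
  v$first_run + v$second_run
}

#' @rdname total_guanines
#' @export
tract_length <- function(v) {
  total_guanines(v) + if (is_continuous(v)) 0L else 1L
}

#' Parse G-tract nomenclature
#'
#' Parses the field-standard G-rich-strand nomenclature for CSB 2 alleles:
#' `"GmXGn"` for a discontinuous tract with interrupting base X in
#' \{A, C, T\} (e.g. `"G5AG7"`, the rCRS allele), or `"Gk"` for a continuous
#' tract (e.g. `"G13"`). Parsing and [render_nomenclature()] are mutually
#' inverse on canonical names.
#'
#' @param name A single nomenclature string.
#' @return A [gtract_variant()].
#' @examples
#' parse_nomenclature("G5AG7")
#' parse_nomenclature("G13")
#' @export
parse_nomenclature <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name))
    stop("variant name must be a single string", call. = FALSE)
  name <- trimws(name)
  m <- regmatches(name, regexec("^G([0-9]+)([A-Za-z])G([0-9]+)$", name))[[1]]
  if (length(m) == 4L) {
    base <- toupper(m[3])
    if (!base %in% c("A", "C", "T"))
      stop("invalid interrupt base '", m[3], "' in '", name,
           "': must be A, C or T", call. = FALSE)
    r1 <- as.integer(m[2]); r2 <- as.integer(m[4])
    if (r1 < 1L || r2 < 1L)
      stop("zero-length G-run in '", name, "'", call. = FALSE)
    return(gtract_variant(r1, base, r2))
  }
  m <- regmatches(name, regexec("^G([0-9]+)$", name))[[1]]
  if (length(m) == 2L) {
    k <- as.integer(m[2])
    if (k < 1L) stop("zero-length G-run in '", name, "'", call. = FALSE)
    return(gtract_variant(k))
  }
  stop("malformed variant name '", name,
       "': expected G<m><A|C|T>G<n> or G<k>", call. = FALSE)
}

#' Render canonical G-tract nomenclature
#'
#' @param v A [gtract_variant()].
#' @return The canonical name, e.g. `"G6AG8"` or `"G13"`.
#' @export
render_nomenclature <- function(v) {
  stopifnot(inherits(v, "gtract_variant"))
  if (is_continuous(v)) paste0("G", v$first_run)
  else paste0("G", v$first_run, v$interrupt, "G", v$second_run)
}

#' Tract sequence of a variant on the G-rich strand
#'
#' @param v A [gtract_variant()].
#' @return The literal tract string, e.g. `"GGGGGAGGGGGGG"` for G5AG7.
#' @export
tract_sequence <- function(v) {
  stopifnot(inherits(v, "gtract_variant"))
  if (is_continuous(v)) strrep("G", v$first_run)
  else paste0(strrep("G", v$first_run), v$interrupt,
              strrep("G", v$second_run))
}

#' Light-strand (C-rich) name of a variant
#'
#' Haplogroup studies usually quote the CSB 2 locus as a polyC-T-polyC
#' sequence on the reference strand; the G-rich nomenclature used here is
#' its reverse complement. This helper converts a name from one strand's
#' convention to the other's by reverse-complementing the literal tract
#' sequence and re-deriving the run-length name, so applying it twice is
#' the identity.
#'
#' @param name A nomenclature string on either strand (e.g. `"G5AG7"` or
#'   `"C7TC5"`).
#' @return The name of the same allele on the opposite strand.
#' @examples
#' light_strand_name("G5AG7")  # "C7TC5", the haplogroup-style name
#' light_strand_name("C7TC5")  # back to "G5AG7"
#' @export
light_strand_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name))
    stop("variant name must be a single string", call. = FALSE)
  m <- regmatches(name,
                  regexec("^([GC])([0-9]+)(?:([A-Za-z])\\1([0-9]+))?$", name,
                          perl = TRUE))[[1]]
  if (length(m) == 0L || m[2] == "")
    stop("malformed variant name '", name, "'", call. = FALSE)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  run_base <- m[2]
  r1 <- as.integer(m[3])
  if (r1 < 1L) stop("zero-length run in '", name, "'", call. = FALSE)
  if (m[4] == "")  # homopolymer: complement the base, keep the length
    return(paste0(comp[[run_base]], r1))
  interrupt <- toupper(m[4])
  if (!interrupt %in% names(comp) || interrupt == run_base)
    stop("invalid interrupt base '", m[4], "' in '", name, "'",
         call. = FALSE)
  r2 <- as.integer(m[5])
  if (r2 < 1L) stop("zero-length run in '", name, "'", call. = FALSE)
  # reverse complement swaps the runs and complements both bases
  paste0(comp[[run_base]], r2, comp[[interrupt]], comp[[run_base]], r1)
}

#' Signed adenine-position index of a discontinuous tract
#'
#' The interrupting base of a discontinuous tract \eqn{G_mXG_n} is assigned
#' a signed offset from the tract midpoint: positive when the first run is
#' longer than the second (interrupt towards the 3' end of the G-rich
#' tract), negative when the first run is shorter (towards the 5' end), and
#' 0 only when the runs are equal — which requires an even total number of
#' guanines. For odd totals the half-integer offset is labelled by the next
#' integer away from zero, so odd-total tracts have no 0 position:
#' \deqn{pos = (m - n)/2} for even \eqn{m + n}, and
#' \deqn{pos = sign(m - n)\,\lceil |m - n| / 2 \rceil} for odd totals.
#'
#' Worked values under this convention: G9AG6 is +2, G6AG7 is -1, G6AG9 is
#' -2, and any equal-run variant (e.g. G7AG7) is 0.
#'
#' @param v A discontinuous [gtract_variant()] (or a name parseable by
#'   [parse_nomenclature()]).
#' @return A signed integer position index.
#' @export
adenine_position <- function(v) {
  if (is.character(v)) v <- parse_nomenclature(v)
  stopifnot(inherits(v, "gtract_variant"))
  if (is_continuous(v))
    stop("adenine position is defined only for interrupted tracts",
         call. = FALSE)
  d <- v$first_run - v$second_run
  if ((v$first_run + v$second_run) %% 2L == 0L) d %/% 2L
  else as.integer(sign(d) * ceiling(abs(d) / 2))
}
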