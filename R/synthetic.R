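# run expr with a private, seeded RNG stream; caller's RNG state untouched
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification of a synthetic sequence survey
#'
#' Parameters of the generator that stands in for a mixed public-database
#' download: a set of control-region records with a known CSB 2 variant
#' spectrum, a fraction of partial records that do not cover the locus at
#' all, records deposited on either strand, and optional noise
#' (substitutions outside the anchor region; replication/sequencing
#' slippage perturbing run lengths by one).
#'
#' The default spectrum is the four most common discontinuous alleles at
#' their observed survey fractions (G5AG7 13%, G6AG7 37%, G6AG8 35%,
#' G6AG9 10%, renormalized), with half the records emulating partial
#' deposits lacking the locus and an even strand mix — the make-up of a
#' real mixed download in which many partial control-region submissions
#' cover only hypervariable segment 1.
#'
#' @param spectrum Named probability vector over canonical variant names;
#'   must sum to 1 (tolerance 1e-9).
#' @param n_records Number of records to generate.
#' @param anchors An [anchor_pair()] whose flanks and contexts form the
#'   record template (default [rcrs_anchors()]).
#' @param strand_mix Fraction of records emitted on the reference (C-rich)
#'   strand (default 0.5).
#' @param fraction_absent Probability that a record is a partial fragment
#'   omitting the CSB 2 locus (default 0.5).
#' @param snp_rate Per-base substitution probability outside the anchor
#'   region (default 0).
#' @param slippage_rate Per-run probability of a +/-1 length perturbation
#'   (default 0).
#' @param seed Integer seed; the generator is fully deterministic given
#'   the spec.
#' @return A `survey_spec` object.
#' @export
survey_spec <- function(spectrum = c(G5AG7 = 0.13, G6AG7 = 0.37,
                                     G6AG8 = 0.35, G6AG9 = 0.10) / 0.95,
                        n_records = 1000L,
                        anchors = rcrs_anchors(),
                        strand_mix = 0.5,
                        fraction_absent = 0.5,
                        snp_rate = 0,
                        slippage_rate = 0,
                        seed = 1L) {
  stopifnot(is.numeric(spectrum), !is.null(names(spectrum)),
            inherits(anchors, "anchor_pair"))
  if (abs(sum(spectrum) - 1) > 1e-9)
    stop("spectrum probabilities must sum to 1", call. = FALSE)
  rates <- c(strand_mix, fraction_absent, snp_rate, slippage_rate)
  if (any(rates < 0 | rates > 1))
    stop("all rates must lie in [0, 1]", call. = FALSE)
  for (nm in names(spectrum)) parse_nomenclature(nm)  # fail before generation
  structure(list(spectrum = spectrum, n_records = as.integer(n_records),
                 anchors = anchors, strand_mix = strand_mix,
                 fraction_absent = fraction_absent, snp_rate = snp_rate,
                 slippage_rate = slippage_rate, seed = as.integer(seed)),
            class = "survey_spec")
}

# perturb each G-run of a variant by +/-1 with the given probability
slip_variant <- function(v, rate) {
  slip <- function(run) {
    if (runif(1) < rate) max(1L, run + sample(c(-1L, 1L), 1L)) else run
  }
  if (is_continuous(v)) gtract_variant(slip(v$first_run))
  else gtract_variant(slip(v$first_run), v$interrupt, slip(v$second_run))
}

mutate_outside <- function(seqstr, protect_start, protect_end, rate) {
  if (rate <= 0) return(seqstr)
  chars <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  idx <- which(runif(length(chars)) < rate)
  idx <- idx[idx < protect_start | idx > protect_end]
  for (i in idx)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

#' Generate a synthetic sequence survey with ground truth
#'
#' Emits `n_records` sequence records built on the anchor template: each
#' present record embeds a variant drawn from the spectrum between the
#' G-rich flanks (with surrounding context), optionally run-length
#' slipped, substituted outside the anchor region, and emitted on either
#' strand; absent records are partial fragments (the context upstream of
#' the locus only). Deterministic given the spec seed.
#'
#' @param spec A [survey_spec()].
#' @return A list with `records` (list of [seq_record()]) and `truth`, a
#'   data.frame with columns `record_id`, `planted` (variant name or
#'   `"absent"`), `realized` (after slippage), and `strand` (`"G-rich"` or
#'   `"reference"`).
#' @export
simulate_survey <- function(spec) {
  stopifnot(inherits(spec, "survey_spec"))
  a <- spec$anchors
  if (spec$fraction_absent > 0 && !nzchar(a$context5))
    stop("absent (partial) records need non-empty anchor context",
         call. = FALSE)
  with_seed(spec$seed, {
    records <- vector("list", spec$n_records)
    truth <- data.frame(record_id = character(spec$n_records),
                        planted = character(spec$n_records),
                        realized = character(spec$n_records),
                        strand = character(spec$n_records),
                        stringsAsFactors = FALSE)
    if (spec$n_records == 0L) return(list(records = list(), truth = truth))
    for (i in seq_len(spec$n_records)) {
      id <- sprintf("synth%05d", i)
      on_ref <- runif(1) < spec$strand_mix
      if (runif(1) < spec$fraction_absent) {
        grich <- a$context5  # partial fragment not covering the locus
        planted <- realized <- "absent"
      } else {
        planted <- sample(names(spec$spectrum), 1L, prob = spec$spectrum)
        v <- slip_variant(parse_nomenclature(planted), spec$slippage_rate)
        realized <- render_nomenclature(v)
        prot_start <- nchar(a$context5) + 1L
        grich <- paste0(a$context5, a$flank5, tract_sequence(v), a$flank3,
                        a$context3)
        prot_end <- nchar(grich) - nchar(a$context3)
        grich <- mutate_outside(grich, prot_start, prot_end, spec$snp_rate)
      }
      residues <- if (on_ref) reverse_complement(grich) else grich
      records[[i]] <- seq_record(id, residues,
                                 description = "synthetic control-region record")
      truth[i, ] <- list(id, planted, realized,
                         if (on_ref) "reference" else "G-rich")
    }
    list(records = records, truth = truth)
  })
}

#' Specification of a synthetic gel lane
#'
#' Bands are rendered as Gaussians in pixel space through a logarithmic
#' migration model `pixel = a + b * log(length)` with `b < 0` (longer
#' fragments migrate less). Band widths are given in nt and converted to
#' pixel standard deviations through the local slope of the migration
#' model. The ladder is rendered noise-free at the model's exact
#' positions; defaults follow a 25 bp ladder.
#'
#' @param bands Data.frame with columns `length` (nt), `area` (> 0) and
#'   `width` (nt); may have zero rows.
#' @param migration Named numeric vector `c(a = ..., b = ...)`, `b < 0`.
#' @param noise_sd Standard deviation of additive pixel noise (default 0).
#' @param n_pixels Number of pixels in the lane (default 1000).
#' @param ladder_lengths Marker lengths in nt (default `seq(25, 300, 25)`).
#' @param seed Integer seed.
#' @return A `gel_spec` object.
#' @export
gel_spec <- function(bands, migration = c(a = 1475, b = -250),
                     noise_sd = 0, n_pixels = 1000L,
                     ladder_lengths = seq(25, 300, by = 25), seed = 1L) {
  stopifnot(is.data.frame(bands),
            all(c("length", "area", "width") %in% names(bands)) ||
              nrow(bands) == 0L,
            all(c("a", "b") %in% names(migration)))
  if (migration[["b"]] >= 0)
    stop("migration slope b must be negative (longer fragments migrate ",
         "less)", call. = FALSE)
  if (nrow(bands) && any(bands$area <= 0))
    stop("band areas must be positive", call. = FALSE)
  structure(list(bands = bands, migration = migration,
                 noise_sd = noise_sd, n_pixels = as.integer(n_pixels),
                 ladder_lengths = sort(as.numeric(ladder_lengths),
                                       decreasing = TRUE),
                 seed = as.integer(seed)),
            class = "gel_spec")
}

#' Render a synthetic gel lane with ground truth
#'
#' @param spec A [gel_spec()].
#' @return A list with `lane` (a [lane_profile()]), `ladder` (data.frame
#'   `pixel`, `length`, noise-free) and `truth` (the band table with the
#'   rendered `pixel` centre of each band).
#' @export
simulate_gel <- function(spec) {
  stopifnot(inherits(spec, "gel_spec"))
  a <- spec$migration[["a"]]; b <- spec$migration[["b"]]
  px <- seq_len(spec$n_pixels)
  mu <- if (nrow(spec$bands)) a + b * log(spec$bands$length) else numeric(0)
  if (length(mu) && (any(mu < 1) || any(mu > spec$n_pixels)))
    stop("band(s) migrate outside the rendered pixel range", call. = FALSE)
  with_seed(spec$seed, {
    dens <- numeric(spec$n_pixels)
    for (i in seq_len(nrow(spec$bands))) {
      sd_px <- abs(b) * spec$bands$width[i] / spec$bands$length[i]
      dens <- dens + spec$bands$area[i] * dnorm(px, mu[i], sd_px)
    }
    if (spec$noise_sd > 0)
      dens <- pmax(0, dens + rnorm(spec$n_pixels, 0, spec$noise_sd))
    ladder <- data.frame(pixel = a + b * log(spec$ladder_lengths),
                         length = spec$ladder_lengths)
    truth <- spec$bands
    if (nrow(truth)) truth$pixel <- mu
    list(lane = lane_profile(dens, lane_id = paste0("synthetic_seed",
                                                    spec$seed)),
         ladder = ladder[order(ladder$pixel), , drop = FALSE],
         truth = truth)
  })
}
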