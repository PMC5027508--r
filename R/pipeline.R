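#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values that look
#' numeric are converted; comma-separated values become vectors.
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  out <- list()
  for (ln in lines) {
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) nums else parts
  }
  out
}

merge_config <- function(defaults, file_cfg, flags) {
  out <- defaults
  for (src in list(file_cfg, flags))
    for (k in names(src)) out[[k]] <- src[[k]]
  out
}

resolved_config_json <- function(command, cfg, path) {
  keep <- cfg[!vapply(cfg, is.object, TRUE)]
  jsonlite::write_json(
    list(command = command, package = "csb2scan",
         version = as.character(utils::packageVersion("csb2scan")),
         config = keep),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run one pipeline command
#'
#' Orchestrates the package modules behind a single entry point, the same
#' surface the `inst/cli/csb2.R` script exposes from a shell. Every
#' command writes its outputs plus a `*_config.json` echoing the fully
#' resolved configuration (package version, seed and parameters), so runs
#' are reproducible byte-for-byte given config and seed.
#'
#' Commands and their main config keys:
#' \describe{
#'   \item{`simulate-survey`}{`n_records`, `seed`, `fraction_absent`,
#'     `strand_mix`, `snp_rate`, `slippage_rate`, `spectrum_names`,
#'     `spectrum_probs` -> `survey.fasta`, `survey_truth.tsv`.}
#'   \item{`scan`}{`fasta`, optional `anchors` (FASTA-style config),
#'     `m_min`/`m_max`, `n_min`/`n_max`, `interrupts`, `continuous_max`
#'     -> `hits.tsv`, `frequency_matrix.tsv`.}
#'   \item{`survey-stats`}{`matrix` (TSV), optional `tp_table` (TSV),
#'     `pivot_m`/`pivot_n` -> `survey_report.json`.}
#'   \item{`simulate-gel`}{`band_lengths`, `band_areas`, `band_widths`,
#'     `noise_sd`, `seed` -> `lane.tsv`, `ladder.tsv`, `gel_truth.tsv`.}
#'   \item{`gel-quant`}{`lane`, `ladder` (TSVs), `tp_lo`, `tp_hi`,
#'     `cutoff`, optional `tss` -> `gel_quant.json`, `peaks.tsv`.}
#'   \item{`report`}{`fasta` plus the `scan`/`survey-stats` keys -> the
#'     full chain: `hits.tsv`, `frequency_matrix.tsv`,
#'     `survey_report.json`.}
#' }
#'
#' @param command One of `"simulate-survey"`, `"scan"`, `"survey-stats"`,
#'   `"simulate-gel"`, `"gel-quant"`, `"report"`.
#' @param config Named list of parameters (highest precedence).
#' @param config_file Optional flat key-value file ([read_config()]),
#'   overridden by `config`.
#' @param out_dir Output directory (created if needed).
#' @return A named list of output file paths, invisibly.
#' @export
csb2_run <- function(command = c("simulate-survey", "scan", "survey-stats",
                                 "simulate-gel", "gel-quant", "report"),
                     config = list(), config_file = NULL,
                     out_dir = ".") {
  command <- match.arg(command)
  file_cfg <- if (!is.null(config_file)) read_config(config_file) else list()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  switch(command,
    "simulate-survey" = {
      cfg <- merge_config(list(n_records = 1000, seed = 1,
                               fraction_absent = 0.5, strand_mix = 0.5,
                               snp_rate = 0, slippage_rate = 0),
                          file_cfg, config)
      spectrum <- if (!is.null(cfg$spectrum_names))
        setNames(as.numeric(cfg$spectrum_probs), cfg$spectrum_names)
      else c(G5AG7 = 0.13, G6AG7 = 0.37, G6AG8 = 0.35, G6AG9 = 0.10) / 0.95
      spec <- survey_spec(spectrum = spectrum,
                          n_records = cfg$n_records,
                          strand_mix = cfg$strand_mix,
                          fraction_absent = cfg$fraction_absent,
                          snp_rate = cfg$snp_rate,
                          slippage_rate = cfg$slippage_rate,
                          seed = cfg$seed)
      sim <- simulate_survey(spec)
      write_sequences(sim$records, p("survey.fasta"))
      write.table(sim$truth, p("survey_truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      resolved_config_json(command, cfg, p("simulate-survey_config.json"))
      invisible(list(fasta = p("survey.fasta"),
                     truth = p("survey_truth.tsv")))
    },
    "scan" = {
      cfg <- merge_config(list(m_min = 1, m_max = 12, n_min = 1, n_max = 12,
                               interrupts = "A", continuous_max = 0),
                          file_cfg, config)
      if (is.null(cfg$fasta)) stop("scan needs config key 'fasta'",
                                   call. = FALSE)
      anchors <- if (!is.null(cfg$anchors)) read_anchors(cfg$anchors)
                 else rcrs_anchors()
      lib <- build_search_strings(
        anchors, m_range = cfg$m_min:cfg$m_max,
        n_range = cfg$n_min:cfg$n_max,
        interrupt_set = cfg$interrupts,
        continuous_range = if (cfg$continuous_max > 0)
          seq_len(cfg$continuous_max) else integer(0))
      records <- read_sequences(cfg$fasta)
      hits <- scan_sequences(records, lib)
      fm <- count_hits(records, lib)
      write.table(hits, p("hits.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write_frequency_matrix(fm, p("frequency_matrix.tsv"))
      resolved_config_json(command, cfg, p("scan_config.json"))
      invisible(list(hits = p("hits.tsv"),
                     matrix = p("frequency_matrix.tsv")))
    },
    "survey-stats" = {
      cfg <- merge_config(list(pivot_m = 6, pivot_n = 7), file_cfg, config)
      if (is.null(cfg$matrix))
        stop("survey-stats needs config key 'matrix'", call. = FALSE)
      fm <- read_frequency_matrix(cfg$matrix)
      tp <- if (!is.null(cfg$tp_table)) read_tp_table(cfg$tp_table)
      survey_report(fm, tp = tp, pivot = c(cfg$pivot_m, cfg$pivot_n),
                    path = p("survey_report.json"))
      resolved_config_json(command, cfg, p("survey-stats_config.json"))
      invisible(list(report = p("survey_report.json")))
    },
    "simulate-gel" = {
      cfg <- merge_config(list(band_lengths = c(125, 250),
                               band_areas = c(30, 70),
                               band_widths = c(1, 2),
                               noise_sd = 0, seed = 1),
                          file_cfg, config)
      spec <- gel_spec(data.frame(length = cfg$band_lengths,
                                  area = cfg$band_areas,
                                  width = cfg$band_widths),
                       noise_sd = cfg$noise_sd, seed = cfg$seed)
      sim <- simulate_gel(spec)
      write.table(data.frame(pixel = seq_along(sim$lane$density),
                             density = sim$lane$density),
                  p("lane.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write.table(sim$ladder, p("ladder.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write.table(sim$truth, p("gel_truth.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      resolved_config_json(command, cfg, p("simulate-gel_config.json"))
      invisible(list(lane = p("lane.tsv"), ladder = p("ladder.tsv"),
                     truth = p("gel_truth.tsv")))
    },
    "gel-quant" = {
      cfg <- merge_config(list(tp_lo = 92, tp_hi = 140, cutoff = 100,
                               min_prominence = 0.05),
                          file_cfg, config)
      if (is.null(cfg$lane) || is.null(cfg$ladder))
        stop("gel-quant needs config keys 'lane' and 'ladder'",
             call. = FALSE)
      lane <- read_lane_profile(cfg$lane)
      cal <- fit_ladder(read_ladder_bands(cfg$ladder))
      regions <- quant_regions(tp_window = c(cfg$tp_lo, cfg$tp_hi),
                               lower_cutoff = cfg$cutoff)
      tp_pct <- quantify_tp_fraction(lane, cal, regions)
      norm <- normalize_profile(lane, cal, window = c(cfg$tp_lo, cfg$tp_hi))
      peaks <- call_peaks(norm, cal, min_prominence = cfg$min_prominence,
                          tss_rcrs = cfg$tss)
      write.table(peaks, p("peaks.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      jsonlite::write_json(
        list(lane = lane$lane_id, tp_percent = tp_pct,
             calibration_knots = cal$knots,
             tp_window_nt = c(cfg$tp_lo, cfg$tp_hi),
             lower_cutoff_nt = cfg$cutoff),
        p("gel_quant.json"), auto_unbox = TRUE, digits = NA,
        dataframe = "rows", pretty = TRUE)
      resolved_config_json(command, cfg, p("gel-quant_config.json"))
      invisible(list(quant = p("gel_quant.json"),
                     peaks = p("peaks.tsv")))
    },
    "report" = {
      scan_out <- csb2_run("scan", config = config,
                           config_file = config_file, out_dir = out_dir)
      stats_cfg <- config
      stats_cfg$matrix <- scan_out$matrix
      stats_out <- csb2_run("survey-stats", config = stats_cfg,
                            config_file = config_file, out_dir = out_dir)
      invisible(c(scan_out, stats_out))
    })
}
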