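#' Construct a spike train
#'
#' A spike train holds the sorted spike times of one isolated unit, in seconds
#' from session start. Times must be strictly increasing (duplicates are
#' rejected) and nonnegative.
#'
#' @param cell_id Character scalar identifying the unit.
#' @param times Numeric vector of spike times in seconds from session start.
#' @return An object of class \code{spike_train}: a list with elements
#'   \code{cell_id} and \code{times}.
#' @examples
#' st <- spike_train("cell01", c(0.5, 1.2, 3.7))
#' @export
spike_train <- function(cell_id, times = numeric(0)) {
  stopifnot(is.character(cell_id), length(cell_id) == 1L, nzchar(cell_id))
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times))) {
    stop("spike_train: times must be finite", call. = FALSE)
  }
  if (any(times < 0)) {
    stop("spike_train: times must be >= 0", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("spike_train: times must be strictly increasing (no duplicates)",
         call. = FALSE)
  }
  structure(list(cell_id = cell_id, times = times), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> cell %s: %d spikes", x$cell_id, length(x$times)))
  if (length(x$times)) {
    cat(sprintf(" over [%.3f, %.3f] s", min(x$times), max(x$times)))
  }
  cat("\n")
  invisible(x)
}

#' Construct an odor event table
#'
#' One row per odor presentation. Intervals are half-open \code{[onset,
#' offset)}, sorted by onset and non-overlapping. Exactly one odor identity
#' must be flagged as the vehicle (mineral-oil) control when any vehicle rows
#' are present; sessions analysed for responsiveness are expected to carry a
#' vehicle channel.
#'
#' @param odor_id Character vector of odorant identifiers.
#' @param is_vehicle Logical vector flagging the vehicle-control channel.
#' @param onset_s,offset_s Numeric vectors of presentation onsets/offsets in
#'   seconds from session start.
#' @return A \code{data.frame} of class \code{event_table}.
#' @export
event_table <- function(odor_id, is_vehicle, onset_s, offset_s) {
  ev <- data.frame(odor_id = as.character(odor_id),
                   is_vehicle = as.logical(is_vehicle),
                   onset_s = as.numeric(onset_s),
                   offset_s = as.numeric(offset_s),
                   stringsAsFactors = FALSE)
  validate_event_table(ev)
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_table", "data.frame")
  ev
}

validate_event_table <- function(ev) {
  if (nrow(ev) == 0L) return(invisible(ev))
  if (anyNA(ev)) stop("event_table: missing values", call. = FALSE)
  bad <- which(ev$offset_s <= ev$onset_s)
  if (length(bad)) {
    stop(sprintf("event_table: offset <= onset at row %d", bad[1L]),
         call. = FALSE)
  }
  o <- order(ev$onset_s)
  on <- ev$onset_s[o]; off <- ev$offset_s[o]
  if (nrow(ev) > 1L) {
    ovl <- which(on[-1L] < off[-length(off)])
    if (length(ovl)) {
      stop(sprintf("event_table: overlapping intervals at sorted rows %d/%d",
                   ovl[1L], ovl[1L] + 1L), call. = FALSE)
    }
  }
  veh <- unique(ev$odor_id[ev$is_vehicle])
  if (length(veh) > 1L) {
    stop("event_table: more than one odor_id flagged as vehicle", call. = FALSE)
  }
  flagged <- unique(tapply(ev$is_vehicle, ev$odor_id, function(z) length(unique(z))))
  if (any(flagged > 1L)) {
    stop("event_table: inconsistent vehicle flag within an odor_id", call. = FALSE)
  }
  invisible(ev)
}

#' Construct a respiration trace
#'
#' Uniformly sampled respiration signal (e.g. a chest piezoelectric sensor) in
#' arbitrary units.
#'
#' @param values Numeric vector of samples.
#' @param sample_rate_hz Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample, seconds from session start.
#' @return An object of class \code{respiration_trace}.
#' @export
respiration_trace <- function(values, sample_rate_hz, t0 = 0) {
  sample_rate_hz <- as.numeric(sample_rate_hz)
  stopifnot(length(sample_rate_hz) == 1L, is.finite(sample_rate_hz),
            sample_rate_hz > 0)
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("respiration_trace: values must be finite", call. = FALSE)
  }
  structure(list(values = values, sample_rate_hz = sample_rate_hz,
                 t0 = as.numeric(t0)),
            class = "respiration_trace")
}

#' Construct a cell metadata table
#'
#' @param cell_id Character vector of unique unit identifiers.
#' @param region Recording region, one of \code{"DTT"}, \code{"VTT"},
#'   \code{"AON"}, \code{"OTHER"}.
#' @param subject_id Character vector of subject identifiers.
#' @param sex One of \code{"F"}, \code{"M"}, \code{"unknown"}.
#' @return A \code{data.frame} of class \code{cell_table}.
#' @export
cell_table <- function(cell_id, region, subject_id, sex = "unknown") {
  regions <- c("DTT", "VTT", "AON", "OTHER")
  sexes <- c("F", "M", "unknown")
  cells <- data.frame(cell_id = as.character(cell_id),
                      region = as.character(region),
                      subject_id = as.character(subject_id),
                      sex = as.character(rep_len(sex, length(cell_id))),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(cells$cell_id)) {
    stop("cell_table: duplicate cell_id", call. = FALSE)
  }
  if (!all(cells$region %in% regions)) {
    stop("cell_table: region must be one of ", paste(regions, collapse = ", "),
         call. = FALSE)
  }
  if (!all(cells$sex %in% sexes)) {
    stop("cell_table: sex must be one of ", paste(sexes, collapse = ", "),
         call. = FALSE)
  }
  class(cells) <- c("cell_table", "data.frame")
  cells
}

#' Assemble a recording session
#'
#' Bundles the per-unit spike trains, odor event table, optional respiration
#' trace and cell metadata for one recording session, enforcing the container
#' invariants (all spike times and event offsets within the session duration,
#' one spike train per metadata row).
#'
#' @param cells A \code{\link{cell_table}}.
#' @param spikes Named list of numeric spike-time vectors (or
#'   \code{spike_train} objects), one per \code{cell_id} in \code{cells}.
#' @param events An \code{\link{event_table}}.
#' @param duration_s Session duration in seconds.
#' @param respiration Optional \code{\link{respiration_trace}}.
#' @return An object of class \code{os_session}.
#' @export
session <- function(cells, spikes, events, duration_s, respiration = NULL) {
  if (!inherits(cells, "cell_table")) {
    cells <- cell_table(cells$cell_id, cells$region, cells$subject_id, cells$sex)
  }
  validate_event_table(events)
  duration_s <- as.numeric(duration_s)
  stopifnot(length(duration_s) == 1L, is.finite(duration_s), duration_s > 0)
  spikes <- lapply(spikes, function(s) {
    if (inherits(s, "spike_train")) s$times else as.numeric(s)
  })
  if (is.null(names(spikes)) || !setequal(names(spikes), cells$cell_id)) {
    stop("session: spikes must be a named list matching cells$cell_id",
         call. = FALSE)
  }
  spikes <- spikes[cells$cell_id]
  for (id in names(spikes)) {
    st <- spike_train(id, spikes[[id]])  # re-validates ordering
    if (length(st$times) && max(st$times) >= duration_s) {
      stop(sprintf("session: spike time beyond duration for cell %s", id),
           call. = FALSE)
    }
    spikes[[id]] <- st$times
  }
  if (nrow(events) && max(events$offset_s) >= duration_s) {
    stop("session: event offset beyond session duration", call. = FALSE)
  }
  if (!is.null(respiration) && !inherits(respiration, "respiration_trace")) {
    stop("session: respiration must be a respiration_trace or NULL",
         call. = FALSE)
  }
  structure(list(cells = cells, spikes = spikes, events = events,
                 respiration = respiration, duration_s = duration_s),
            class = "os_session")
}

#' @export
print.os_session <- function(x, ...) {
  cat(sprintf("<session> %d cells, %d odor events, %.1f s%s\n",
              nrow(x$cells), nrow(x$events), x$duration_s,
              if (is.null(x$respiration)) "" else ", respiration recorded"))
  invisible(x)
}

#' Analysis window and threshold settings
#'
#' Collects the epoching windows and decision thresholds used throughout the
#' pipeline: 4 s pre-odor baseline and 4 s odor windows for response
#' statistics, an 8 s post-onset window for respiratory phase statistics, the
#' final 10 s of each interstimulus interval for spontaneous metrics, the
#' per-pair significance level, and the z-score threshold defining strong
#' excitatory responses.
#'
#' @param baseline_dur Baseline window before odor onset, seconds.
#' @param odor_dur Odor-response window after onset, seconds.
#' @param phase_dur Window after onset for respiratory phase statistics,
#'   seconds.
#' @param spont_tail Final portion of each interstimulus interval used for
#'   spontaneous metrics, seconds.
#' @param alpha_pair Per odor-cell pair significance level (Wilcoxon
#'   signed-rank).
#' @param alpha_phase Significance level for the Rayleigh test of respiratory
#'   modulation.
#' @param sd_threshold z-score (baseline SD units) above which an odor response
#'   is classed as a strong excitatory response.
#' @param psth_bin_s PSTH bin width, seconds.
#' @param psth_span Two-element numeric, PSTH span relative to odor onset.
#' @return A list of class \code{analysis_windows}.
#' @export
analysis_windows <- function(baseline_dur = 4, odor_dur = 4, phase_dur = 8,
                             spont_tail = 10, alpha_pair = 0.01,
                             alpha_phase = 0.01, sd_threshold = 3,
                             psth_bin_s = 0.1, psth_span = c(-4, 8)) {
  w <- list(baseline_dur = baseline_dur, odor_dur = odor_dur,
            phase_dur = phase_dur, spont_tail = spont_tail,
            alpha_pair = alpha_pair, alpha_phase = alpha_phase,
            sd_threshold = sd_threshold, psth_bin_s = psth_bin_s,
            psth_span = psth_span)
  durs <- c(w$baseline_dur, w$odor_dur, w$phase_dur, w$spont_tail, w$psth_bin_s)
  stopifnot(all(durs > 0), w$alpha_pair > 0, w$alpha_pair < 1,
            w$alpha_phase > 0, w$alpha_phase < 1,
            length(w$psth_span) == 2L, diff(w$psth_span) > 0)
  class(w) <- "analysis_windows"
  w
}

#' Final-tail spontaneous windows of the interstimulus intervals
#'
#' For each gap between consecutive odor presentations, returns the final
#' \code{spont_tail} seconds of the gap (the period after evacuation of
#' detectable odor), as half-open intervals \code{[start, end)}. Gaps shorter
#' than \code{spont_tail} contribute their full length. Segments before the
#' first event and after the last are not interstimulus intervals and are
#' excluded.
#'
#' @param events An \code{\link{event_table}}.
#' @param windows An \code{\link{analysis_windows}} (uses \code{spont_tail}).
#' @return A data.frame with columns \code{start_s}, \code{end_s}; zero rows
#'   when fewer than two events.
#' @export
interstimulus_tail_windows <- function(events, windows = analysis_windows()) {
  if (nrow(events) < 2L) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  gap_start <- events$offset_s[-nrow(events)]
  gap_end <- events$onset_s[-1L]
  start <- pmax(gap_start, gap_end - windows$spont_tail)
  keep <- gap_end > start
  data.frame(start_s = start[keep], end_s = gap_end[keep])
}

manifest_path <- function(dir) file.path(dir, "manifest.txt")

write_kv <- function(kv, path) {
  writeLines(sprintf("%s=%s", names(kv), vapply(kv, as.character, "")), path)
}

read_kv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  kv <- vapply(parts, `[`, "", 2L)
  names(kv) <- trimws(vapply(parts, `[`, "", 1L))
  kv
}

# full-precision numeric formatting so times survive a text round trip exactly
fmt_num <- function(x) sprintf("%.17g", x)

#' Write a session to a delimited-text directory
#'
#' Serialises a session as comma-delimited UTF-8 files with single header
#' rows: \code{spikes.csv} (cell_id, time_s), \code{events.csv} (odor_id,
#' is_vehicle, onset_s, offset_s), \code{cells.csv} (cell_id, region,
#' subject_id, sex), optional \code{respiration.csv} (value), plus a
#' \code{manifest.txt} key-value file carrying \code{duration_s} and the
#' respiration sampling metadata. Numeric fields are printed at full binary
#' precision so \code{\link{read_session}} reproduces the session exactly.
#'
#' @param x An \code{os_session}.
#' @param dir Directory to create/populate.
#' @return Invisibly, \code{dir}.
#' @export
write_session <- function(x, dir) {
  stopifnot(inherits(x, "os_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("write_session: cannot create ", dir, call. = FALSE)

  n_per <- lengths(x$spikes)
  sp <- data.frame(cell_id = rep(names(x$spikes), n_per),
                   time_s = fmt_num(unlist(x$spikes, use.names = FALSE)))
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")

  ev <- data.frame(odor_id = x$events$odor_id,
                   is_vehicle = x$events$is_vehicle,
                   onset_s = fmt_num(x$events$onset_s),
                   offset_s = fmt_num(x$events$offset_s))
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")

  utils::write.csv(as.data.frame(x$cells), file.path(dir, "cells.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")

  kv <- c(duration_s = fmt_num(x$duration_s))
  if (!is.null(x$respiration)) {
    kv <- c(kv,
            resp_sample_rate_hz = fmt_num(x$respiration$sample_rate_hz),
            resp_t0_s = fmt_num(x$respiration$t0))
    utils::write.csv(data.frame(value = fmt_num(x$respiration$values)),
                     file.path(dir, "respiration.csv"), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  }
  write_kv(kv, manifest_path(dir))
  invisible(dir)
}

#' Read a session from a delimited-text directory
#'
#' Counterpart of \code{\link{write_session}}; validates all container
#' invariants on load and reports the offending file or rule on failure.
#'
#' @param dir Directory containing \code{manifest.txt}, \code{spikes.csv},
#'   \code{events.csv}, \code{cells.csv} and optionally
#'   \code{respiration.csv}.
#' @return An \code{os_session}.
#' @export
read_session <- function(dir) {
  required <- c("manifest.txt", "spikes.csv", "events.csv", "cells.csv")
  for (f in required) {
    if (!file.exists(file.path(dir, f))) {
      stop(sprintf("read_session: missing required file '%s' in %s", f, dir),
           call. = FALSE)
    }
  }
  kv <- read_kv(manifest_path(dir))
  if (!"duration_s" %in% names(kv)) {
    stop("read_session: manifest.txt lacks duration_s", call. = FALSE)
  }
  duration_s <- as.numeric(kv[["duration_s"]])

  cells_df <- utils::read.csv(file.path(dir, "cells.csv"),
                              colClasses = "character")
  cells <- cell_table(cells_df$cell_id, cells_df$region, cells_df$subject_id,
                      cells_df$sex)

  sp <- utils::read.csv(file.path(dir, "spikes.csv"),
                        colClasses = c(cell_id = "character",
                                       time_s = "numeric"))
  spikes <- split(sp$time_s, factor(sp$cell_id, levels = cells$cell_id))
  spikes <- lapply(spikes, function(v) if (is.null(v)) numeric(0) else v)

  evd <- utils::read.csv(file.path(dir, "events.csv"),
                         colClasses = c(odor_id = "character",
                                        is_vehicle = "logical",
                                        onset_s = "numeric",
                                        offset_s = "numeric"))
  events <- event_table(evd$odor_id, evd$is_vehicle, evd$onset_s, evd$offset_s)

  respiration <- NULL
  resp_file <- file.path(dir, "respiration.csv")
  if (file.exists(resp_file)) {
    if (!"resp_sample_rate_hz" %in% names(kv)) {
      stop("read_session: respiration.csv present but manifest lacks resp_sample_rate_hz",
           call. = FALSE)
    }
    vals <- utils::read.csv(resp_file, colClasses = "numeric")$value
    t0 <- if ("resp_t0_s" %in% names(kv)) as.numeric(kv[["resp_t0_s"]]) else 0
    respiration <- respiration_trace(vals, as.numeric(kv[["resp_sample_rate_hz"]]),
                                     t0 = t0)
  }
  session(cells, spikes, events, duration_s, respiration)
}
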