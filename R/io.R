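#' Read an epoch set from long-format TSV
#'
#' The interchange format is a tab-separated file with header
#' \code{subject_id  condition  chrono_index  valid  channel  time_ms
#' amplitude_uv} (one row per sample) and a JSON sidecar at
#' \code{<path>.json} carrying \code{sampling_rate_hz}, \code{epoch_start_ms},
#' \code{epoch_end_ms}, \code{channels} and \code{conditions}. Amplitudes are
#' written with 17 significant digits so a write/read round trip reproduces
#' every double bit-for-bit.
#'
#' @param path Path to the TSV file; \code{<path>.json} must exist.
#' @return An \code{\link{epoch_set}}.
#' @export
read_epochs <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("sampling_rate_hz", "epoch_start_ms", "epoch_end_ms", "channels", "conditions"))
    if (is.null(meta[[f]])) stop("sidecar missing field: ", f)

  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = c("subject_id", "condition", "channel")))
  required <- c("subject_id", "condition", "chrono_index", "valid",
                "channel", "time_ms", "amplitude_uv")
  miss <- setdiff(required, names(dt))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))

  channels <- as.character(meta$channels)
  n_samp <- round((meta$epoch_end_ms - meta$epoch_start_ms) * meta$sampling_rate_hz / 1000)

  bad_ch <- setdiff(unique(dt$channel), channels)
  if (length(bad_ch)) {
    row <- which(dt$channel == bad_ch[1])[1]
    stop("unknown channel '", bad_ch[1], "' at row ", row)
  }

  if (nrow(dt) == 0) {
    return(epoch_set(
      subject_id = if (length(meta$subject_id)) meta$subject_id else "unknown",
      sampling_rate = meta$sampling_rate_hz, channels = channels,
      trials = data.frame(chrono_index = integer(0), condition = character(0),
                          valid = logical(0)),
      data = array(numeric(0), dim = c(0, length(channels), n_samp)),
      epoch_start = meta$epoch_start_ms, epoch_end = meta$epoch_end_ms,
      conditions = as.character(meta$conditions)))
  }

  # group rows into trials by (chrono_index, condition)
  key <- paste(dt$chrono_index, dt$condition, sep = "\r")
  trial_keys <- unique(key)
  counts <- table(key)[trial_keys]
  expected <- length(channels) * n_samp
  bad <- which(counts != expected)
  if (length(bad)) {
    k <- trial_keys[bad[1]]
    row <- which(key == k)[1]
    stop("trial at chrono_index ", dt$chrono_index[row], " has ",
         counts[bad[1]] / length(channels), " samples per channel when ",
         n_samp, " declared (first offending row ", row, ")")
  }

  ord <- order(match(key, trial_keys), match(dt$channel, channels), dt$time_ms)
  amp <- dt$amplitude_uv[ord]
  n_tr <- length(trial_keys)
  # filled as samples-fastest within channel within trial
  data <- aperm(array(amp, dim = c(n_samp, length(channels), n_tr)), c(3, 2, 1))

  first <- dt[match(trial_keys, key), ]
  trials <- data.frame(chrono_index = as.integer(first$chrono_index),
                       condition = first$condition,
                       valid = as.logical(first$valid))

  epoch_set(subject_id = first$subject_id[1],
            sampling_rate = meta$sampling_rate_hz, channels = channels,
            trials = trials, data = data,
            epoch_start = meta$epoch_start_ms, epoch_end = meta$epoch_end_ms,
            conditions = as.character(meta$conditions))
}

#' Write an epoch set to long-format TSV
#'
#' Rows are emitted in a stable order (trial by chronological index, then
#' channel in declared order, then time), so two writes of the same object
#' produce byte-identical files.
#'
#' @param es An \code{\link{epoch_set}}.
#' @param path Output TSV path; the JSON sidecar is written to
#'   \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_epochs <- function(es, path) {
  validate_epoch_set(es)
  meta <- list(subject_id = es$subject_id,
               sampling_rate_hz = es$sampling_rate,
               epoch_start_ms = es$epoch_start,
               epoch_end_ms = es$epoch_end,
               channels = es$channels,
               conditions = es$conditions)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  header <- "subject_id\tcondition\tchrono_index\tvalid\tchannel\ttime_ms\tamplitude_uv"
  ord <- order(es$trials$chrono_index)
  n_samp <- dim(es$data)[3]
  n_ch <- length(es$channels)
  con <- file(path, open = "wb")  # binary: LF on every platform
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (length(ord)) {
    per_trial <- n_ch * n_samp
    tms <- sprintf("%.17g", rep(es$times, times = n_ch))
    lines <- character(length(ord) * per_trial)
    pos <- 0L
    for (i in ord) {
      m <- es$data[i, , , drop = FALSE]
      dim(m) <- c(n_ch, n_samp)
      amp <- as.vector(t(m))  # channel-major, samples-fastest
      lines[pos + seq_len(per_trial)] <- sprintf(
        "%s\t%s\t%d\t%d\t%s\t%s\t%.17g",
        es$subject_id, es$trials$condition[i], es$trials$chrono_index[i],
        as.integer(es$trials$valid[i]),
        rep(es$channels, each = n_samp), tms, amp)
      pos <- pos + per_trial
    }
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Write a detection report to JSON
#'
#' Serialises a \code{\link{cit_detect}} result. A combined p of zero is the
#' floor of a B-resample randomisation test, so the report also carries a
#' display string \code{"<1/B"} (e.g. \code{"<0.001"} at B = 1000) alongside
#' the numeric value.
#'
#' @param r A \code{cit_detection} object.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(r, path) {
  stopifnot(inherits(r, "cit_detection"))
  out <- list(
    subject_id = r$subject_id,
    channels = r$channels,
    m = r$m,
    observed_p2p_uv = as.list(r$observed),
    p_per_channel = as.list(r$p_per_channel),
    p_display = as.list(vapply(r$p_per_channel, p_display, character(1), B = r$B)),
    fisher_observed = r$fisher_observed,
    fisher_p = r$fisher_p,
    fisher_p_display = p_display(r$fisher_p, r$B),
    alpha = r$alpha,
    decision = r$decision,
    B = r$B,
    seed = if (is.null(r$seed)) NA else r$seed,
    n_valid = as.list(r$n_valid)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read back a detection report written by \code{write_report}
#' @param path JSON path.
#' @return A list with the report fields (numeric p-values preserved exactly).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# "<1/B" convention for p-values at the randomisation floor
p_display <- function(p, B) {
  if (p == 0) sprintf("<%s", format(1 / B, scientific = FALSE)) else
    format(p, scientific = FALSE)
}
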