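#' Describe a field-stimulation and perfusion protocol
#'
#' A `stim_protocol` captures the timing of everything the analysis needs to
#' know about an imaging experiment: repeated action-potential (AP) rounds,
#' an optional single long AP train, the glucose perfusion timeline, an
#' optional NH4Cl unquenching epoch (which reveals total pHluorin sensor
#' fluorescence and anchors pool-fraction normalization), and an optional
#' dedicated reference round used to fit the re-acidification time constant
#' in 5 mM glucose.
#'
#' @param frame_interval Seconds between acquired frames.
#' @param rounds Number of repeated stimulus rounds (may be 0 when only a
#'   `long_train` is delivered).
#' @param aps_per_round APs per round (default 50).
#' @param ap_frequency Stimulation frequency in Hz (default 10).
#' @param inter_round_interval Seconds from the start of one round to the
#'   start of the next (rounds are "applied every minute": default 60).
#' @param rounds_start Start time (s) of the first main round.
#' @param reference_round_start Start time (s) of the dedicated reference
#'   round delivered in 5 mM glucose, or `NULL` if none.
#' @param glucose_timeline Data frame with columns `start_s` and `glucose_mM`:
#'   a step function of bath glucose over time.
#' @param nh4cl_epoch Length-2 numeric `c(start_s, end_s)` of the NH4Cl
#'   perfusion epoch, or `NULL`.
#' @param long_train Length-2 numeric `c(n_aps, frequency_hz)` describing a
#'   single prolonged train (the ATP-imaging paradigm), or `NULL`.
#' @param span_s Total recording duration in seconds. Defaults to covering
#'   all declared epochs plus a short tail.
#'
#' @return A `stim_protocol` object (a validated list).
#' @seealso [endurance_protocol()], [atp_protocol()] for the two default
#'   paradigms.
#' @export
stim_protocol <- function(frame_interval = 0.5,
                          rounds = 30,
                          aps_per_round = 50,
                          ap_frequency = 10,
                          inter_round_interval = 60,
                          rounds_start = 360,
                          reference_round_start = 20,
                          glucose_timeline = tibble(start_s = c(0, 60), glucose_mM = c(5, 0)),
                          nh4cl_epoch = NULL,
                          long_train = NULL,
                          span_s = NULL) {
  check_number(frame_interval, "frame_interval", min = 0, strict_min = TRUE)
  check_number(rounds, "rounds", min = 0)
  rounds <- as.integer(rounds)
  if (rounds < 1 && is.null(long_train)) {
    abort("A protocol needs at least one stimulus round or a `long_train`.")
  }
  if (rounds > 0) {
    check_number(aps_per_round, "aps_per_round", min = 1)
    check_number(ap_frequency, "ap_frequency", min = 0, strict_min = TRUE)
    check_number(inter_round_interval, "inter_round_interval", min = 0, strict_min = TRUE)
    check_number(rounds_start, "rounds_start", min = 0)
    train_dur <- aps_per_round / ap_frequency
    if (inter_round_interval <= train_dur) {
      abort("Stimulus rounds overlap: `inter_round_interval` must exceed the train duration.")
    }
  }
  if (!is.null(reference_round_start)) {
    check_number(reference_round_start, "reference_round_start", min = 0)
  }
  glucose_timeline <- as_tibble(glucose_timeline)
  if (!all(c("start_s", "glucose_mM") %in% names(glucose_timeline)) ||
      nrow(glucose_timeline) < 1) {
    abort("`glucose_timeline` needs columns start_s, glucose_mM and at least one row.")
  }
  if (any(glucose_timeline$start_s < 0) || any(glucose_timeline$glucose_mM < 0)) {
    abort("`glucose_timeline` times and concentrations must be non-negative.")
  }
  if (is.unsorted(glucose_timeline$start_s, strictly = TRUE)) {
    abort("`glucose_timeline$start_s` must be strictly increasing.")
  }
  if (!is.null(long_train)) {
    if (length(long_train) != 2 || any(!is.finite(long_train)) || any(long_train <= 0)) {
      abort("`long_train` must be c(n_aps, frequency_hz), both positive.")
    }
    long_train <- c(n_aps = unname(long_train[1]), frequency = unname(long_train[2]))
  }

  proto <- structure(
    list(
      frame_interval = frame_interval,
      rounds = rounds,
      aps_per_round = aps_per_round,
      ap_frequency = ap_frequency,
      inter_round_interval = inter_round_interval,
      rounds_start = rounds_start,
      reference_round_start = reference_round_start,
      glucose_timeline = glucose_timeline,
      nh4cl_epoch = nh4cl_epoch,
      long_train = long_train,
      span_s = NA_real_
    ),
    class = "stim_protocol"
  )

  last_stim <- max(protocol_trains(proto)$t_end)
  if (!is.null(nh4cl_epoch)) {
    if (length(nh4cl_epoch) != 2 || any(!is.finite(nh4cl_epoch)) ||
        nh4cl_epoch[1] >= nh4cl_epoch[2] || nh4cl_epoch[1] < 0) {
      abort("`nh4cl_epoch` must be c(start_s, end_s) with start < end.")
    }
    if (nh4cl_epoch[1] <= last_stim) {
      abort("The NH4Cl epoch must begin after the last stimulus round.")
    }
    proto$nh4cl_epoch <- c(start_s = unname(nh4cl_epoch[1]), end_s = unname(nh4cl_epoch[2]))
  }
  if (is.null(span_s)) {
    span_s <- max(last_stim, if (!is.null(nh4cl_epoch)) nh4cl_epoch[2] else 0) + 20
  }
  check_number(span_s, "span_s", min = last_stim)
  proto$span_s <- span_s
  proto
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("<stim_protocol>\n")
  cat(sprintf(
    "  %d round(s) of %g APs @ %g Hz every %g s (first at %g s)\n",
    x$rounds, x$aps_per_round, x$ap_frequency, x$inter_round_interval, x$rounds_start
  ))
  if (!is.null(x$long_train)) {
    cat(sprintf("  long train: %g APs @ %g Hz\n", x$long_train[1], x$long_train[2]))
  }
  if (!is.null(x$reference_round_start)) {
    cat(sprintf("  reference round at %g s\n", x$reference_round_start))
  }
  if (!is.null(x$nh4cl_epoch)) {
    cat(sprintf("  NH4Cl epoch: %g-%g s\n", x$nh4cl_epoch[1], x$nh4cl_epoch[2]))
  }
  cat(sprintf("  frame interval %g s, span %g s\n", x$frame_interval, x$span_s))
  invisible(x)
}

#' Default repeated-round endurance paradigm
#'
#' One reference round in 5 mM glucose, a switch to the test glucose level at
#' 60 s, five minutes of pre-incubation, then `rounds` stimulus rounds of
#' 50 APs at 10 Hz applied every minute, finishing with an NH4Cl epoch that
#' reveals total sensor fluorescence.
#'
#' @param rounds Number of main stimulus rounds (default 30, the censoring
#'   horizon of the endurance assay).
#' @param glucose_mM Bath glucose after the switch at 60 s (default 0).
#' @param frame_interval Seconds per frame.
#' @return A [stim_protocol()].
#' @export
endurance_protocol <- function(rounds = 30, glucose_mM = 0, frame_interval = 0.5) {
  rounds <- as.integer(rounds)
  last_end <- 360 + (rounds - 1) * 60 + 5
  stim_protocol(
    frame_interval = frame_interval,
    rounds = rounds,
    rounds_start = 360,
    reference_round_start = 20,
    glucose_timeline = tibble(start_s = c(0, 60), glucose_mM = c(5, glucose_mM)),
    nh4cl_epoch = c(last_end + 40, last_end + 70),
    span_s = last_end + 80
  )
}

#' Default single long-train ATP-imaging paradigm
#'
#' 600 APs at 10 Hz after a 5 mM glucose baseline and five minutes at the
#' test glucose level; the recording continues for five minutes after the
#' train so the recovery phase can be measured.
#'
#' @param glucose_mM Bath glucose after the switch at 60 s (default 0).
#' @param frame_interval Seconds per frame (default 1).
#' @param n_aps,frequency Long-train size and rate.
#' @return A [stim_protocol()].
#' @export
atp_protocol <- function(glucose_mM = 0, frame_interval = 1, n_aps = 600, frequency = 10) {
  train_end <- 360 + n_aps / frequency
  stim_protocol(
    frame_interval = frame_interval,
    rounds = 0,
    rounds_start = 360,
    reference_round_start = NULL,
    glucose_timeline = tibble(start_s = c(0, 60), glucose_mM = c(5, glucose_mM)),
    long_train = c(n_aps, frequency),
    span_s = train_end + 300
  )
}

#' Tabulate the stimulus trains of a protocol
#'
#' @param protocol A [stim_protocol()].
#' @return A tibble with one row per stimulus train: `label` (`"reference"`,
#'   `"round"` or `"long_train"`), `round_index` (1-based for main rounds,
#'   `NA` otherwise), `t_start`, `t_end`, `frequency`, `n_aps`.
#' @export
protocol_trains <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  out <- list()
  if (!is.null(protocol$reference_round_start)) {
    dur <- protocol$aps_per_round / protocol$ap_frequency
    out$ref <- tibble(
      label = "reference", round_index = NA_integer_,
      t_start = protocol$reference_round_start,
      t_end = protocol$reference_round_start + dur,
      frequency = protocol$ap_frequency, n_aps = protocol$aps_per_round
    )
  }
  if (protocol$rounds > 0) {
    dur <- protocol$aps_per_round / protocol$ap_frequency
    starts <- protocol$rounds_start + (seq_len(protocol$rounds) - 1) * protocol$inter_round_interval
    out$rounds <- tibble(
      label = "round", round_index = seq_len(protocol$rounds),
      t_start = starts, t_end = starts + dur,
      frequency = protocol$ap_frequency, n_aps = protocol$aps_per_round
    )
  }
  if (!is.null(protocol$long_train)) {
    dur <- protocol$long_train[["n_aps"]] / protocol$long_train[["frequency"]]
    out$lt <- tibble(
      label = "long_train", round_index = NA_integer_,
      t_start = protocol$rounds_start, t_end = protocol$rounds_start + dur,
      frequency = protocol$long_train[["frequency"]],
      n_aps = protocol$long_train[["n_aps"]]
    )
  }
  trains <- dplyr::arrange(dplyr::bind_rows(out), .data$t_start)
  if (nrow(trains) > 1 && any(trains$t_start[-1] < trains$t_end[-nrow(trains)])) {
    abort("Protocol stimulus trains overlap in time.")
  }
  trains
}

#' Bath glucose concentration at given times
#'
#' @param protocol A [stim_protocol()].
#' @param time_s Numeric vector of times (s).
#' @return Numeric vector of glucose concentrations (mM).
#' @export
glucose_at <- function(protocol, time_s) {
  tl <- protocol$glucose_timeline
  idx <- findInterval(time_s, tl$start_s)
  ifelse(idx < 1, tl$glucose_mM[1], tl$glucose_mM[pmax(idx, 1)])
}

# Onset of the first stimulation (main rounds or long train), used as the end
# of the pre-stimulus baseline window.
stim_onset <- function(protocol, include_reference = FALSE) {
  trains <- protocol_trains(protocol)
  if (!include_reference) {
    trains <- trains[trains$label != "reference", , drop = FALSE]
  }
  if (!nrow(trains)) abort("Protocol declares no stimulation.")
  min(trains$t_start)
}

#' Read or write a protocol as YAML
#'
#' Protocols serialize to a plain YAML document so an analysis can be
#' re-run from config files alone.
#'
#' @param protocol A [stim_protocol()].
#' @param path File path.
#' @return `write_protocol_yaml()` returns `path` invisibly;
#'   `read_protocol_yaml()` returns a [stim_protocol()].
#' @export
write_protocol_yaml <- function(protocol, path) {
  stopifnot(inherits(protocol, "stim_protocol"))
  x <- unclass(protocol)
  x$glucose_timeline <- lapply(seq_len(nrow(x$glucose_timeline)), function(i) {
    as.list(x$glucose_timeline[i, ])
  })
  if (!is.null(x$nh4cl_epoch)) x$nh4cl_epoch <- as.list(x$nh4cl_epoch)
  if (!is.null(x$long_train)) x$long_train <- as.list(x$long_train)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  gl <- dplyr::bind_rows(lapply(x$glucose_timeline, as_tibble))
  stim_protocol(
    frame_interval = x$frame_interval,
    rounds = x$rounds,
    aps_per_round = x$aps_per_round,
    ap_frequency = x$ap_frequency,
    inter_round_interval = x$inter_round_interval,
    rounds_start = x$rounds_start,
    reference_round_start = x$reference_round_start,
    glucose_timeline = gl,
    nh4cl_epoch = if (!is.null(x$nh4cl_epoch)) unlist(x$nh4cl_epoch),
    long_train = if (!is.null(x$long_train)) unlist(x$long_train),
    span_s = x$span_s
  )
}
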