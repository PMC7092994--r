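#' Generate a respiratory challenge protocol schedule
#'
#' Builds the epoch schedule of a breath-hold or exogenous CO2 challenge:
#' a lead-in free-breathing baseline, then `n_epochs` challenge epochs of
#' `bh_duration_s` seconds each, interleaved with free-breathing (or
#' normocapnia) gaps drawn uniformly from `free_range_s`. A trailing
#' recovery gap from the same range closes the record, so challenge
#' responses that outlast the epoch remain observable. With the defaults
#' (6 x 30 s epochs, 60--90 s gaps) the schedule spans roughly ten minutes.
#'
#' For `kind = "co2"` the challenge epochs alternate between a +4 mmHg and
#' a +8 mmHg end-tidal CO2 step (labels `hypercapnia_4` / `hypercapnia_8`,
#' half of each for even `n_epochs`) and the gaps are labelled
#' `normocapnia`.
#'
#' @param kind `"breath_hold"` or `"co2"`.
#' @param n_epochs number of challenge epochs (>= 0).
#' @param bh_duration_s challenge epoch duration, seconds.
#' @param free_range_s length-2 numeric `(lo, hi)`: range of the
#'   free-breathing / normocapnia gap durations, seconds.
#' @param seed integer seed for the gap draws.
#' @param baseline_s lead-in baseline duration, seconds (default 60).
#' @return A `protocol_schedule`: a tibble with columns `onset_s`,
#'   `duration_s`, `label`, plus attributes `total_duration_s` and `kind`.
#' @examples
#' generate_protocol("breath_hold", n_epochs = 6, bh_duration_s = 30,
#'                   free_range_s = c(60, 90), seed = 1)
#' @export
generate_protocol <- function(kind = c("breath_hold", "co2"),
                              n_epochs = 6,
                              bh_duration_s = 30,
                              free_range_s = c(60, 90),
                              seed = 1L,
                              baseline_s = 60) {
  kind <- match.arg(kind)
  assert_scalar_number(n_epochs, "n_epochs", lower = 0)
  assert_scalar_number(bh_duration_s, "bh_duration_s", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(baseline_s, "baseline_s", lower = 0)
  if (length(free_range_s) != 2L || any(free_range_s < 0) ||
      free_range_s[1] > free_range_s[2]) {
    stop_cvreact("`free_range_s` must be c(lo, hi) with 0 <= lo <= hi.",
                 "cvreact_invalid_parameter")
  }
  n_epochs <- as.integer(n_epochs)

  free_label <- if (kind == "co2") "normocapnia" else "free_breathing"
  gaps <- with_seed(seed, runif(n_epochs, free_range_s[1], free_range_s[2]))

  challenge_labels <- if (kind == "co2") {
    rep(c("hypercapnia_4", "hypercapnia_8"), length.out = n_epochs)
  } else {
    rep("breath_hold", n_epochs)
  }

  onset <- 0
  rows <- list()
  add <- function(duration, label) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      onset_s = onset, duration_s = duration, label = label)
    onset <<- onset + duration
  }
  if (baseline_s > 0) add(baseline_s, free_label)
  for (k in seq_len(n_epochs)) {
    add(bh_duration_s, challenge_labels[k])
    add(gaps[k], free_label)
  }
  epochs <- dplyr::bind_rows(rows)
  if (nrow(epochs) == 0L) {
    epochs <- tibble::tibble(onset_s = numeric(0), duration_s = numeric(0),
                             label = character(0))
  }
  new_protocol_schedule(epochs, total_duration_s = onset, kind = kind)
}

new_protocol_schedule <- function(epochs, total_duration_s, kind) {
  out <- tibble::new_tibble(epochs, class = "protocol_schedule",
                            total_duration_s = total_duration_s,
                            kind = kind)
  validate_protocol_schedule(out)
}

validate_protocol_schedule <- function(p) {
  if (nrow(p) > 0) {
    if (is.unsorted(p$onset_s)) {
      stop_cvreact("Protocol epochs must be sorted by onset.")
    }
    ends <- p$onset_s + p$duration_s
    if (any(p$onset_s[-1] < ends[-length(ends)] - 1e-9)) {
      stop_cvreact("Protocol epochs must not overlap.")
    }
    if (max(ends) > attr(p, "total_duration_s") + 1e-9) {
      stop_cvreact("Protocol epochs exceed total_duration_s.")
    }
  }
  p
}

#' @export
print.protocol_schedule <- function(x, ...) {
  cat(sprintf("<protocol_schedule: %s, %.0f s, %d epochs>\n",
              attr(x, "kind"), attr(x, "total_duration_s"), nrow(x)))
  NextMethod()
}

challenge_labels <- c("breath_hold", "hypercapnia_4", "hypercapnia_8")

# Epoch rows corresponding to the challenge phases.
protocol_challenges <- function(protocol) {
  protocol[protocol$label %in% challenge_labels, , drop = FALSE]
}

#' Serialize / read a protocol schedule as JSON
#'
#' @param protocol a `protocol_schedule`.
#' @param path file path.
#' @return `read_protocol_json()` returns a `protocol_schedule`;
#'   `write_protocol_json()` returns `path` invisibly.
#' @export
write_protocol_json <- function(protocol, path) {
  payload <- list(
    kind = attr(protocol, "kind"),
    total_duration_s = attr(protocol, "total_duration_s"),
    epochs = as.data.frame(protocol)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_protocol_schedule(tibble::as_tibble(payload$epochs),
                        total_duration_s = payload$total_duration_s,
                        kind = payload$kind)
}
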