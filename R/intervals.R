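#' Contiguous intervals of one vigilance state
#'
#' Merges consecutive epochs sharing `state` into half-open intervals
#' `[start_s, end_s)` in seconds from recording start.
#'
#' @param track a [vigilance_track()].
#' @param state state label.
#' @return data.frame with columns `start_s`, `end_s`, sorted,
#'   non-overlapping.
#' @export
state_intervals <- function(track, state) {
  epoch_s <- attr(track, "epoch_s")
  hit <- track$state == state
  if (!any(hit)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_s = (starts[keep] - 1L) * epoch_s,
             end_s = ends[keep] * epoch_s)
}

#' Gather the per-interval segments of one vigilance state
#'
#' Returns the raw per-channel sample slices for every contiguous interval of
#' `state`, provided their total duration reaches `min_total_s` (the study
#' rule: at least 2 min of data, otherwise the recording is excluded from
#' that analysis). Filtering and enveloping are performed per interval
#' *before* any pooling, so windows never straddle an interval seam; the
#' returned provenance records the original interval boundaries.
#'
#' @param rec an [lfp_recording()].
#' @param track a [vigilance_track()] aligned to the recording in 5-s epochs.
#' @param state vigilance state to collect.
#' @param min_total_s minimum summed interval duration in seconds
#'   (default 120).
#' @return list with `included` (logical), `reason` (`"ok"` or
#'   `"insufficient_state_duration"`), `total_s`, `intervals` (provenance
#'   data.frame) and `segments` (list of samples-x-channels matrices, one per
#'   interval; empty when excluded).
#' @export
concatenate_state <- function(rec, track, state, min_total_s = 120) {
  stopifnot(inherits(rec, "lfp_recording"))
  epoch_s <- attr(track, "epoch_s")
  n_ep_rec <- floor(rec$duration_s / epoch_s)
  if (nrow(track) > n_ep_rec) {
    stop("annotation has ", nrow(track), " epochs but recording holds only ",
         n_ep_rec, " full epochs")
  }
  iv <- state_intervals(track, state)
  total_s <- sum(iv$end_s - iv$start_s)
  if (total_s < min_total_s) {
    return(list(included = FALSE, reason = "insufficient_state_duration",
                total_s = total_s, intervals = iv, segments = list()))
  }
  segs <- lapply(seq_len(nrow(iv)), function(i) {
    idx <- (round(iv$start_s[i] * rec$fs) + 1L):round(iv$end_s[i] * rec$fs)
    rec$data[idx, , drop = FALSE]
  })
  list(included = TRUE, reason = "ok", total_s = total_s,
       intervals = iv, segments = segs)
}
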