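# Novel-texture-discrimination accounting: valid interaction time per
# texture and the NTD preference index.

#' Per-texture interaction time
#'
#' Sums bout durations that count as interactions: the animal is inside
#' the 4 cm x 4 cm panel zone, makes whisker-directed contact, and the
#' bout is not excluded (pass-throughs, climbing). Overlapping valid
#' bouts on the same texture are merged with a warning before summing.
#'
#' @param bouts Bout tibble with columns `texture`, `start`, `end`,
#'   `in_zone`, `whisker_contact`, `excluded`, and optionally `segment`.
#' @param segment Restrict to this session segment (`"test"` by default;
#'   `NULL` keeps all rows).
#' @return A tibble (`texture`, `time_s`) with a row for each of
#'   `familiar` and `novel`.
#' @export
interaction_times <- function(bouts, segment = "test") {
  req <- c("texture", "start", "end", "in_zone", "whisker_contact", "excluded")
  if (!all(req %in% names(bouts))) {
    abort(sprintf("`bouts` needs columns: %s.", paste(req, collapse = ", ")))
  }
  if (any(bouts$end <= bouts$start)) abort("Bout `end` must exceed `start`.")
  if (!is.null(segment) && "segment" %in% names(bouts)) {
    bouts <- dplyr::filter(bouts, .data$segment %in% !!segment)
  }
  valid <- dplyr::filter(bouts, .data$in_zone, .data$whisker_contact,
                         !.data$excluded)
  merge_total <- function(df) {
    if (nrow(df) == 0) return(0)
    df <- df[order(df$start), ]
    merged_end <- df$end[1]
    total <- 0
    cur_start <- df$start[1]
    cur_end <- df$end[1]
    overlapped <- FALSE
    if (nrow(df) > 1) {
      for (i in 2:nrow(df)) {
        if (df$start[i] < cur_end) {
          overlapped <- TRUE
          cur_end <- max(cur_end, df$end[i])
        } else {
          total <- total + (cur_end - cur_start)
          cur_start <- df$start[i]
          cur_end <- df$end[i]
        }
      }
    }
    total <- total + (cur_end - cur_start)
    if (overlapped) warn("Overlapping bouts merged before summing.")
    total
  }
  tibble(
    texture = c("familiar", "novel"),
    time_s = c(merge_total(valid[valid$texture == "familiar", ]),
               merge_total(valid[valid$texture == "novel", ]))
  )
}

#' Novel-texture-discrimination index
#'
#' `(novel - familiar) / (novel + familiar)` interaction time; +1 is
#' exclusive novel-texture interaction, 0 no preference. Undefined (NA,
#' with a warning) when the total interaction time is zero.
#'
#' @param novel,familiar Interaction times in seconds.
#' @return The index in `[-1, 1]`.
#' @export
ntd_index <- function(novel, familiar) {
  if (novel < 0 || familiar < 0) abort("Interaction times must be >= 0.")
  total <- novel + familiar
  if (total == 0) {
    warn("Total interaction time is zero; NTD index undefined.")
    return(NA_real_)
  }
  (novel - familiar) / total
}

#' Summarize a session's discrimination performance
#'
#' @param bouts Bout tibble (see [interaction_times()]).
#' @param segment Session segment to score (the paper's reported index
#'   uses the test segment; the pre-test is exposed but not pooled).
#' @return A one-row tibble (`familiar_s`, `novel_s`, `total_s`,
#'   `ntd_index`).
#' @export
ntd_session <- function(bouts, segment = "test") {
  it <- interaction_times(bouts, segment)
  fam <- it$time_s[it$texture == "familiar"]
  nov <- it$time_s[it$texture == "novel"]
  tibble(familiar_s = fam, novel_s = nov, total_s = fam + nov,
         ntd_index = suppressWarnings(ntd_index(nov, fam)))
}
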