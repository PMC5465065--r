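#' Onset channel of an event
#'
#' The onset channel is the channel with the earliest per-channel onset;
#' exact ties are broken toward the lowest channel index and flagged.
#'
#' @param event one-row event data.frame with `onset_ch1_s..onset_ch4_s`.
#' @param montage a [default_montage()]-style data.frame.
#' @return list with `channel`, `region`, `lobe`, `tie` (logical).
#' @export
onset_channel <- function(event, montage = default_montage()) {
  ons <- as.numeric(event[paste0("onset_ch", 1:4, "_s")])
  if (all(is.na(ons))) stop("event has no per-channel onsets", call. = FALSE)
  m <- min(ons, na.rm = TRUE)
  at_min <- which(!is.na(ons) & ons == m)
  ch <- at_min[1]
  list(channel = ch, region = montage$region[ch], lobe = montage$lobe[ch],
       tie = length(at_min) > 1L)
}

#' Classify event spread
#'
#' An event is `"generalized"` only when all four channels are involved;
#' any smaller involvement is `"focal"`.
#'
#' @param event one-row event data.frame with per-channel onsets.
#' @param n_channels number of channels required for generalization.
#' @return `"focal"` or `"generalized"`.
#' @export
classify_spread <- function(event, n_channels = 4) {
  ons <- as.numeric(event[paste0("onset_ch", seq_len(n_channels), "_s")])
  if (sum(!is.na(ons)) == n_channels) "generalized" else "focal"
}

#' Onset-channel and onset-region distributions
#'
#' Summarizes where seizures start: proportions per channel and aggregated
#' into telencephalic vs posterior onsets, optionally per group (e.g. sex).
#'
#' @param events event data.frame with an `onset_channel` column; may also
#'   carry a grouping column.
#' @param montage a [default_montage()]-style data.frame.
#' @param group_by optional name of a grouping column in `events`.
#' @return list with `by_channel` and `by_lobe` data.frames (columns group,
#'   channel/lobe, n_events, proportion); zero-row data.frames when
#'   `events` is empty.
#' @export
#' @examples
#' ev <- data.frame(onset_channel = c(2, 2, 1, 4), sex = c("m", "m", "f", "f"))
#' onset_distribution(ev, group_by = "sex")$by_lobe
onset_distribution <- function(events, montage = default_montage(),
                               group_by = NULL) {
  empty <- list(
    by_channel = data.frame(group = character(0), channel = integer(0),
                            n_events = integer(0), proportion = numeric(0)),
    by_lobe = data.frame(group = character(0), lobe = character(0),
                         n_events = integer(0), proportion = numeric(0)))
  if (!nrow(events)) return(empty)
  grp <- if (is.null(group_by)) rep("all", nrow(events)) else
    as.character(events[[group_by]])
  ch <- factor(events$onset_channel, levels = montage$channel)
  by_channel <- do.call(rbind, lapply(split(ch, grp), function(v) {
    tab <- table(v)
    data.frame(channel = as.integer(names(tab)), n_events = as.integer(tab),
               proportion = as.numeric(tab) / length(v))
  }))
  by_channel <- cbind(group = rep(names(split(ch, grp)),
                                  each = nrow(montage)), by_channel)
  lobe <- montage$lobe[match(events$onset_channel, montage$channel)]
  by_lobe <- do.call(rbind, lapply(split(lobe, grp), function(v) {
    tab <- table(factor(v, levels = unique(montage$lobe)))
    data.frame(lobe = names(tab), n_events = as.integer(tab),
               proportion = as.numeric(tab) / length(v))
  }))
  by_lobe <- cbind(group = rep(names(split(lobe, grp)),
                               each = length(unique(montage$lobe))), by_lobe)
  rownames(by_channel) <- rownames(by_lobe) <- NULL
  list(by_channel = by_channel, by_lobe = by_lobe)
}
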