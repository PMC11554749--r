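# The 47-channel acquisition table.
#
# The instrument combines 18 LED excitation lines with 5 emission filters.
# Only physically valid pairs (filter band above the excitation line plus a
# guard band) are admissible, which leaves 62 of the 90 combinations; the
# published table has 47 channels but does not identify which pairs were
# used, so the default table reduces the 62 valid pairs to 47 by a balanced
# deterministic rule that retains every excitation line. Any true instrument
# table can be supplied instead wherever a channel table is accepted.

.afmi_excitations <- c(358, 371, 377, 381, 385, 391, 397, 400, 403, 406,
                       412, 418, 430, 437, 451, 457, 469, 476)
.afmi_excitation_halfwidth <- 5

.afmi_filters <- data.frame(
  emission_kind = c("bandpass", "bandpass", "bandpass", "longpass", "bandpass"),
  emission_center_or_cutoff_nm = c(414, 451, 575, 594, 675),
  emission_halfwidth_nm = c(23, 53, 29.5, 0, 33.5),
  stringsAsFactors = FALSE
)

#' Default 47-channel excitation/emission table
#'
#' Builds the canonical acquisition table: 18 LED excitation centres
#' (358--476 nm, each +/- 5 nm) crossed with 5 emission filters
#' (414 +/- 23, 451 +/- 53, 575 +/- 29.5, 594 long-pass, 675 +/- 33.5 nm),
#' restricted to pairs whose emission band starts above the excitation
#' centre plus a 10 nm guard band, then reduced to exactly 47 channels by
#' repeatedly dropping the highest-emission filter from the excitation
#' holding the most channels (ties broken towards the longer excitation).
#' The result is deterministic, Stokes-valid, and keeps all 18 excitations.
#'
#' @param n_channels number of channels to keep (default 47).
#' @param guard_nm guard band between excitation centre and the lower edge
#'   of an admissible emission band, in nm.
#' @return a `data.frame` with one row per channel: `channel_id` (0-based),
#'   `excitation_center_nm`, `excitation_halfwidth_nm`, `emission_kind`,
#'   `emission_center_or_cutoff_nm`, `emission_halfwidth_nm`, `exposure_s`.
#' @examples
#' ch <- default_channel_table()
#' nrow(ch)                      # 47
#' length(unique(ch$excitation_center_nm))  # 18
#' @export
default_channel_table <- function(n_channels = 47L, guard_nm = 10) {
  cand <- merge(
    data.frame(excitation_center_nm = .afmi_excitations,
               excitation_halfwidth_nm = .afmi_excitation_halfwidth),
    .afmi_filters
  )
  lower_edge <- ifelse(cand$emission_kind == "longpass",
                       cand$emission_center_or_cutoff_nm,
                       cand$emission_center_or_cutoff_nm - cand$emission_halfwidth_nm)
  cand <- cand[lower_edge > cand$excitation_center_nm + guard_nm, ]
  cand <- cand[order(cand$excitation_center_nm,
                     cand$emission_center_or_cutoff_nm), ]
  if (nrow(cand) < n_channels)
    stopf("only %d physically valid channel pairs; cannot build %d channels",
          nrow(cand), n_channels)
  while (nrow(cand) > n_channels) {
    cnt <- table(cand$excitation_center_nm)
    busiest <- as.numeric(names(cnt)[cnt == max(cnt)])
    ex <- max(busiest)
    rows <- which(cand$excitation_center_nm == ex)
    drop <- rows[which.max(cand$emission_center_or_cutoff_nm[rows])]
    cand <- cand[-drop, ]
  }
  cand$channel_id <- seq_len(nrow(cand)) - 1L
  cand$exposure_s <- NA_real_
  rownames(cand) <- NULL
  cand[, c("channel_id", "excitation_center_nm", "excitation_halfwidth_nm",
           "emission_kind", "emission_center_or_cutoff_nm",
           "emission_halfwidth_nm", "exposure_s")]
}

#' Validate a channel table
#'
#' Checks the structural invariants of an excitation/emission channel table:
#' unique 0-based ids, excitation centres in 300--700 nm, non-negative
#' halfwidths, known emission kinds, and Stokes validity (emission centre or
#' cutoff above the excitation centre).
#'
#' @param channels a channel `data.frame` as from [default_channel_table()].
#' @return the validated table, invisibly.
#' @export
validate_channel_table <- function(channels) {
  req <- c("channel_id", "excitation_center_nm", "excitation_halfwidth_nm",
           "emission_kind", "emission_center_or_cutoff_nm",
           "emission_halfwidth_nm")
  miss <- setdiff(req, names(channels))
  if (length(miss)) stopf("channel table missing columns: %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(channels$channel_id))
    stopf("channel_id values must be unique")
  if (any(channels$excitation_center_nm < 300 |
          channels$excitation_center_nm > 700))
    stopf("excitation centers must lie in [300, 700] nm")
  if (any(channels$excitation_halfwidth_nm < 0) ||
      any(channels$emission_halfwidth_nm < 0))
    stopf("halfwidths must be non-negative")
  if (!all(channels$emission_kind %in% c("bandpass", "longpass")))
    stopf("emission_kind must be 'bandpass' or 'longpass'")
  if (any(channels$emission_center_or_cutoff_nm <=
          channels$excitation_center_nm))
    stopf("emission center/cutoff must exceed the excitation center")
  invisible(channels)
}
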