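## Published distance -> mean-CP summaries of the field trial, and the
## two-site field geometry.

# Per-experiment mean observed CP rate (%) by sampling distance, as
# published for the eight experiments (TARI plots reported per wind side,
# AES plots jointly).  Rows: 19 sampling distances 0.35-12.95 m.
table1_means <- local({
  cols <- c("2013-1_up", "2013-1_down", "2014-1_up", "2014-1_down",
            "2015-1_up", "2015-1_down", "2016-1_up", "2016-1_down",
            "2013-2", "2014-2", "2015-2", "2016-2")
  m <- matrix(c(
    1.87, 3.26, 5.07, 3.42, 4.50, 3.43, 2.21, 1.58, 2.36, 0.48, 3.16, 1.98,
    0.47, 1.17, 1.11, 1.03, 1.35, 1.88, 0.70, 0.51, 0.96, 0.17, 0.92, 1.08,
    0.26, 0.30, 0.34, 0.71, 0.31, 0.85, 0.11, 0.81, 0.39, 0.15, 0.56, 0.38,
    0.31, 0.20, 0.88, 0.22, 0.44, 0.22, 0.18, 0.41, 0.23, 0.00, 0.16, 0.28,
    0.34, 0.34, 0.15, 0.47, 0.09, 0.11, 0.19, 0.15, 0.09, 0.08, 0.29, 0.12,
    0.48, 0.25, 0.06, 0.31, 0.03, 0.11, 0.07, 0.15, 0.10, 0.04, 0.12, 0.05,
    0.10, 0.02, 0.80, 0.05, 0.76, 0.51, 0.06, 0.19, 0.13, 0.00, 0.07, 0.06,
    0.03, 0.07, 0.17, 0.14, 0.00, 0.24, 0.00, 0.00, 0.05, 0.00, 0.00, 0.03,
    0.10, 0.03, 0.17, 0.06, 0.13, 0.13, 0.07, 0.03, 0.08, 0.02, 0.04, 0.06,
    0.05, 0.03, 0.06, 0.11, 0.05, 0.14, 0.03, 0.12, 0.13, 0.00, 0.05, 0.04,
    0.04, 0.03, 0.05, 0.06, 0.05, 0.06, 0.11, 0.06, 0.00, 0.00, 0.05, 0.03,
    0.04, 0.00, 0.10, 0.13, 0.22, 0.00, 0.04, 0.03, 0.07, 0.00, 0.06, 0.03,
    0.00, 0.00, 0.03, 0.03, 0.00, 0.00, 0.09, 0.00, 0.00, 0.00, 0.03, 0.04,
    0.07, 0.00, 0.03, 0.06, 0.62, 0.06, 0.03, 0.00, 0.03, 0.01, 0.01, 0.01,
    0.00, 0.00, 0.08, 0.03, 0.10, 0.07, 0.03, 0.00, 0.02, 0.00, 0.04, 0.00,
    0.00, 0.00, 0.00, 0.19, 0.08, 0.00, 0.00, 0.03, 0.00, 0.00, 0.00, 0.00,
    0.07, 0.10, 0.00, 0.00, 0.04, 0.00, 0.00, 0.00, 0.01, 0.03, 0.01, 0.00,
    0.04, 0.00, 0.00, 0.00, 0.06, 0.07, 0.00, 0.00, 0.03, 0.00, 0.00, 0.06,
    0.00, 0.04, 0.00, 0.00, 0.07, 0.11, 0.00, 0.04, 0.04, 0.00, 0.02, 0.02
  ), nrow = 19, byrow = TRUE, dimnames = list(NULL, cols))
  m
})

#' Design sampling distances of the field trial
#'
#' Recipient plants were sampled at 19 distances from the donor-plot edge,
#' 0.35 to 12.95 m in 0.7-m steps.
#'
#' @return Numeric vector of 19 distances in metres.
#' @export
design_distances <- function() 0.35 + 0.7 * (0:18)

#' Published per-experiment mean CP rates by distance
#'
#' The mean observed cross-pollination rate (%) of each of the 12
#' experiment/plot summary columns (four TARI experiments split by wind
#' side, four AES experiments pooled) at each of the 19 sampling distances.
#'
#' @return A data.frame: `distance_m` plus 12 mean-CP columns.
#' @export
cp_field_means <- function() {
  data.frame(distance_m = design_distances(), table1_means,
             check.names = FALSE)
}

#' Pooled distance to mean-CP profile
#'
#' The unweighted average of the 12 per-experiment mean CP columns at each
#' sampling distance: the default calibration target of the empirical-mode
#' simulator.  The profile runs from 2.78% at 0.35 m down to 0.028% at
#' 12.95 m.
#'
#' @return A data.frame with columns `distance_m` and `mean_cp` (percent).
#' @export
default_mean_profile <- function() {
  data.frame(distance_m = design_distances(),
             mean_cp = unname(rowMeans(table1_means)))
}

#' Construct the donor/recipient field layout of a study site
#'
#' Each 36 x 15 m field holds a central donor plot flanked by two recipient
#' plots (north/south of the donor at TARI, east/west at AES), planted in
#' 12 furrows of two rows each: 696 donor and 1776 recipient plants.
#' Recipient plants sit at 0.35-m intervals from the donor-plot edge, so
#' their offsets reproduce the 0.35-12.95 m sampling grid.
#'
#' @param site `"TARI"` or `"AES"`.
#' @return An object of class `field_layout`: site, `donor_positions` and
#'   `recipient_positions` data.frames (`x`, `y` in metres; recipients also
#'   carry `plot_side` and `offset_m`, the distance from the donor edge),
#'   `field_extent` (length, width), `furrow_count`, and plant totals.
#' @export
build_field_layout <- function(site = c("TARI", "AES")) {
  site <- match.arg(site)
  length_m <- 36; width_m <- 15
  n_rows <- 24                        # 12 furrows x 2 rows
  row_pos <- (seq_len(n_rows) - 0.5) * width_m / n_rows
  donor_len <- 10                     # central band along the long axis
  donor_lo <- (length_m - donor_len) / 2
  donor_axis <- donor_lo + (seq_len(29) - 0.5) * donor_len / 29
  offsets <- 0.35 * seq_len(37)       # 0.35 .. 12.95 m from the donor edge
  sides <- if (site == "TARI") c("up", "down") else c("east", "west")

  donors <- expand.grid(axis = donor_axis, row = row_pos)
  rec1 <- expand.grid(offset = offsets, row = row_pos)  # low-coordinate side
  rec2 <- rec1

  # the long (36 m) axis is north-south at TARI, east-west at AES; both map
  # to the x coordinate with y across furrows
  donor_positions <- data.frame(x = donors$axis, y = donors$row)
  recipient_positions <- rbind(
    data.frame(x = donor_lo - rec1$offset, y = rec1$row,
               plot_side = sides[1], offset_m = rec1$offset),
    data.frame(x = donor_lo + donor_len + rec2$offset, y = rec2$row,
               plot_side = sides[2], offset_m = rec2$offset)
  )
  structure(list(
    site = site,
    donor_positions = donor_positions,
    recipient_positions = recipient_positions,
    field_extent = c(length_m = length_m, width_m = width_m),
    furrow_count = 12L,
    n_donor = nrow(donor_positions),
    n_recipient = nrow(recipient_positions)
  ), class = "field_layout")
}

#' @export
print.field_layout <- function(x, ...) {
  cat(sprintf("Field layout (%s): %g x %g m, %d furrows\n", x$site,
              x$field_extent[1], x$field_extent[2], x$furrow_count))
  cat(sprintf("  %d donor plants, %d recipient plants (sides: %s)\n",
              x$n_donor, x$n_recipient,
              paste(unique(x$recipient_positions$plot_side), collapse = "/")))
  invisible(x)
}
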