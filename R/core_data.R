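## Domain primitives: CP-rate arithmetic, plant distance, sample table I/O.

#' Cross-pollination rate of a progeny assay
#'
#' The CP rate is the percentage of hybrid progenies among the seedlings
#' assayed from a recipient-plant sample: `100 * n_hybrid / n_seeds`.
#'
#' @param n_hybrid Non-negative integer vector, number of hybrid progenies.
#' @param n_seeds Positive integer vector, total seedlings assayed per
#'   sample (the study design uses 384).
#' @return Numeric vector of CP rates in percent, in `[0, 100]`.
#' @examples
#' compute_cp_rate(11, 384)
#' @export
compute_cp_rate <- function(n_hybrid, n_seeds) {
  if (any(!is.finite(n_hybrid)) || any(!is.finite(n_seeds)))
    stop("invalid sample: non-finite counts", call. = FALSE)
  if (any(n_seeds <= 0))
    stop("invalid sample: n_seeds must be positive", call. = FALSE)
  if (any(n_hybrid < 0) || any(n_hybrid > n_seeds))
    stop("invalid sample: n_hybrid must lie in [0, n_seeds]", call. = FALSE)
  100 * n_hybrid / n_seeds
}

#' Convert a CP rate back to a model-scale count
#'
#' Rates are converted to counts on the 384-seed assay scale by multiplying
#' by `n_seeds` and rounding half-up (so a rate derived from an integer
#' count is recovered exactly).
#'
#' @param cp_percent Numeric vector of CP rates in percent.
#' @param n_seeds Assay size the count is expressed on (default 384).
#' @return Integer vector of counts.
#' @examples
#' cp_rate_to_count(2.8646)  # 11
#' @export
cp_rate_to_count <- function(cp_percent, n_seeds = 384L) {
  if (any(!is.finite(cp_percent)) || any(cp_percent < 0) || any(cp_percent > 100))
    stop("invalid sample: cp_percent must lie in [0, 100]", call. = FALSE)
  as.integer(floor(cp_percent / 100 * n_seeds + 0.5))
}

#' Euclidean distance between a recipient and a donor plant
#'
#' Plant positions are points on the field's 2-D coordinate plane; the
#' separation entering the dispersal kernel is the Euclidean distance.
#'
#' @param recipient,donor Numeric length-2 vectors `(x, y)` in metres, or
#'   two-column matrices of positions (rows are paired).
#' @return Numeric vector of distances in metres.
#' @examples
#' plant_distance(c(3, 4), c(0, 0))  # 5
#' @export
plant_distance <- function(recipient, donor) {
  r <- if (is.matrix(recipient)) recipient else matrix(recipient, ncol = 2)
  d <- if (is.matrix(donor)) donor else matrix(donor, ncol = 2)
  if (any(!is.finite(r)) || any(!is.finite(d)))
    stop("invalid coordinate: non-finite input", call. = FALSE)
  sqrt((r[, 1] - d[, 1])^2 + (r[, 2] - d[, 2])^2)
}

## canonical CSV column order for sample tables
sample_columns <- c("experiment_id", "site", "plot_side", "distance_m",
                    "n_seeds", "n_hybrid", "cp_percent")

#' Assemble and validate a table of pollination samples
#'
#' A sample is one 384-seed progeny assay taken at a nominal sampling
#' distance from the donor plot.  `cp_percent` is recomputed from the
#' counts when missing, and all row-level invariants are checked.
#'
#' @param experiment_id,site,plot_side Character label vectors.
#' @param distance_m Positive sampling distances in metres.
#' @param n_seeds,n_hybrid Assay size and hybrid count per sample.
#' @param cp_percent Optional CP rates in percent; derived from counts if
#'   `NULL`.
#' @return A `data.frame` with the canonical sample columns.
#' @export
pollination_samples <- function(experiment_id, site, plot_side, distance_m,
                                n_seeds, n_hybrid, cp_percent = NULL) {
  df <- data.frame(
    experiment_id = as.character(experiment_id),
    site = as.character(site),
    plot_side = as.character(plot_side),
    distance_m = as.numeric(distance_m),
    n_seeds = as.integer(n_seeds),
    n_hybrid = as.integer(n_hybrid),
    stringsAsFactors = FALSE
  )
  df$cp_percent <- if (is.null(cp_percent))
    compute_cp_rate(df$n_hybrid, df$n_seeds) else as.numeric(cp_percent)
  validate_samples(df)
}

#' Validate a sample table against its invariants
#'
#' @param samples A data.frame with the canonical sample columns.
#' @return The validated data.frame (invisibly unchanged), or an error
#'   naming the first offending row.
#' @export
validate_samples <- function(samples) {
  missing <- setdiff(sample_columns, names(samples))
  if (length(missing))
    stop("sample table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("distance_m", "n_seeds", "n_hybrid", "cp_percent")) {
    bad <- which(!is.finite(samples[[col]]))
    if (length(bad))
      stop(sprintf("row %d: non-numeric or missing %s", bad[1], col),
           call. = FALSE)
  }
  checks <- list(
    "distance_m must be positive" = samples$distance_m <= 0,
    "n_seeds must be positive" = samples$n_seeds <= 0,
    "n_hybrid must lie in [0, n_seeds]" =
      samples$n_hybrid < 0 | samples$n_hybrid > samples$n_seeds,
    "cp_percent must lie in [0, 100]" =
      samples$cp_percent < 0 | samples$cp_percent > 100
  )
  for (msg in names(checks)) {
    bad <- which(checks[[msg]])
    if (length(bad)) stop(sprintf("row %d: %s", bad[1], msg), call. = FALSE)
  }
  samples[sample_columns]
}

#' Model-scale counts of a sample table
#'
#' Returns the count variable entering the zero-inflated likelihood: the
#' recorded hybrid count where present, otherwise the CP rate converted to
#' a 384-seed count.
#'
#' @param samples A validated sample table.
#' @return Integer vector of counts, one per row.
#' @export
model_counts <- function(samples) {
  y <- samples$n_hybrid
  from_rate <- is.na(y)
  if (any(from_rate))
    y[from_rate] <- cp_rate_to_count(samples$cp_percent[from_rate])
  as.integer(y)
}

#' Read / write sample tables as CSV
#'
#' The on-disk dialect is comma-separated UTF-8 with a header row and "."
#' decimal; lines starting with `#` are metadata comments (the simulator
#' records its seed there).  Reading validates every row and reports the
#' first violation with its row number.
#'
#' @param path File path.
#' @param samples A validated sample table.
#' @param meta Optional character vector of metadata lines to write as
#'   leading `#` comments.
#' @return `read_samples()` returns the validated data.frame;
#'   `write_samples()` returns `path` invisibly.
#' @export
read_samples <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    df <- df[sample_columns[sample_columns %in% names(df)]]
    missing <- setdiff(sample_columns, names(df))
    if (length(missing))
      stop("sample table is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    return(df)
  }
  validate_samples(df)
}

#' @rdname read_samples
#' @export
write_samples <- function(samples, path, meta = NULL) {
  samples <- validate_samples(samples)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  write.csv(samples, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
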