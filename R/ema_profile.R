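#' Exponential moving average of per-base depth
#'
#' Smooths per-base depth over a region with an exponential moving average:
#' smoothing ratio `2 / (window_bp + 1)`, seeded by the simple mean of the
#' first `window_bp` values, stepped 1 bp at a time. The first
#' `window_bp - 1` positions (the seed burn-in) are excluded from the
#' output, so the profile starts at position `start + window_bp - 1`.
#'
#' @param profile A `depth_profile` covering `region`.
#' @param region One-row data.frame (`chrom`, `start`, `end`); must be at
#'   least `window_bp` long.
#' @param window_bp Window length in bp (default 50000).
#' @return A `smoothed_profile`: list with `sample_id`, `chrom`, `positions`
#'   (0-based), `values` and `window_bp`.
#' @export
ema <- function(profile, region, window_bp = 50000L) {
  n <- as.integer(window_bp)
  if (n < 1) stop("window_bp must be positive")
  len <- region$end - region$start
  if (len < n) stop("region (", len, " bp) shorter than the smoothing window (",
                    n, " bp)")
  x <- extract_depth(profile, region$chrom, region$start, region$end)
  ratio <- 2 / (n + 1)
  seed <- mean(x[1:n])
  vals <- if (len > n) {
    rest <- stats::filter(ratio * x[(n + 1):len], 1 - ratio,
                          method = "recursive", init = seed)
    c(seed, as.numeric(rest))
  } else seed
  structure(list(sample_id = profile$sample_id,
                 chrom = region$chrom,
                 positions = region$start + seq.int(n - 1, len - 1),
                 values = vals,
                 window_bp = n),
            class = "smoothed_profile")
}

#' @export
print.smoothed_profile <- function(x, ...) {
  cat("smoothed profile '", x$sample_id, "': ", length(x$positions),
      " positions, ", x$window_bp, "-bp window\n", sep = "")
  invisible(x)
}

#' Normalize a smoothed profile by control samples
#'
#' Divides the test sample's smoothed depth, position by position, by the
#' arithmetic mean of the control samples' smoothed depth. A value near 1
#' within an amplicon indicates the reference copy number; other values
#' denote copy-number variation. Positions where the control mean is zero
#' become `NaN` with a warning.
#'
#' @param sample A `smoothed_profile`.
#' @param controls List of `smoothed_profile`s on identical positions.
#' @param per_control If `TRUE`, return a list of profiles, one per control,
#'   instead of dividing by the control mean.
#' @return A `smoothed_profile` of ratios (or a list of them).
#' @export
normalize_by_controls <- function(sample, controls, per_control = FALSE) {
  if (inherits(controls, "smoothed_profile")) controls <- list(controls)
  if (!length(controls)) stop("at least one control profile is required")
  for (ctl in controls) {
    if (!identical(ctl$positions, sample$positions) ||
        !identical(ctl$chrom, sample$chrom))
      stop("control '", ctl$sample_id, "' is not on the same positions as ",
           "the test sample")
  }
  ratio_profile <- function(denom, id) {
    if (any(denom == 0)) warning("zero control smoothed depth at ",
                                 sum(denom == 0), " positions; ratios set to NaN")
    structure(list(sample_id = id, chrom = sample$chrom,
                   positions = sample$positions,
                   values = sample$values / denom,
                   window_bp = sample$window_bp),
              class = "smoothed_profile")
  }
  if (per_control) {
    lapply(controls, function(ctl)
      ratio_profile(ctl$values, paste0(sample$sample_id, "/", ctl$sample_id)))
  } else {
    denom <- Reduce(`+`, lapply(controls, `[[`, "values")) / length(controls)
    ratio_profile(denom, paste0(sample$sample_id, "/controls"))
  }
}

#' Export a smoothed profile as bedGraph
#'
#' Writes 0-based half-open bedGraph rows, merging runs of consecutive
#' positions with identical values. `stride` keeps every `stride`-th
#' position (each emitted as a 1-bp row) for down-sampled output.
#'
#' @param profile A `smoothed_profile`.
#' @param path Output file.
#' @param stride Down-sampling stride (default 1 = every position).
#' @return `path`, invisibly.
#' @export
export_profile <- function(profile, path, stride = 1L) {
  pos <- profile$positions
  val <- profile$values
  if (stride > 1L) {
    keep <- seq(1L, length(pos), by = as.integer(stride))
    pos <- pos[keep]; val <- val[keep]
    df <- data.frame(chrom = profile$chrom, start = pos, end = pos + 1,
                     value = val)
  } else {
    brk <- c(TRUE, diff(pos) != 1 | diff(val) != 0)
    grp <- cumsum(brk)
    df <- data.frame(chrom = profile$chrom,
                     start = tapply(pos, grp, min),
                     end = tapply(pos, grp, max) + 1,
                     value = tapply(val, grp, `[`, 1))
  }
  write.table(format(df, scientific = FALSE, trim = TRUE, digits = 15),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph written by [export_profile()] back into a profile
#'
#' @param path bedGraph file.
#' @param sample_id Label for the profile.
#' @param window_bp Window annotation to attach.
#' @return A `smoothed_profile`.
#' @export
read_profile <- function(path, sample_id = basename(path), window_bp = NA_integer_) {
  df <- read.table(path, sep = "\t",
                   col.names = c("chrom", "start", "end", "value"),
                   stringsAsFactors = FALSE)
  pos <- unlist(mapply(function(s, e) seq.int(s, e - 1), df$start, df$end,
                       SIMPLIFY = FALSE))
  val <- rep(df$value, df$end - df$start)
  structure(list(sample_id = sample_id, chrom = df$chrom[1],
                 positions = pos, values = val, window_bp = window_bp),
            class = "smoothed_profile")
}

#' Mean of a smoothed profile over an interval
#'
#' Convenience accessor used to compare the normalized smoothed profile with
#' the interval-mean normalized depths of the calling layer.
#'
#' @param profile A `smoothed_profile`.
#' @param interval One-row data.frame (`chrom`, `start`, `end`).
#' @return Mean smoothed value over positions inside the interval.
#' @export
profile_segment_mean <- function(profile, interval) {
  sel <- profile$positions >= interval$start & profile$positions < interval$end
  if (!any(sel)) stop("no smoothed positions inside ", interval$chrom, ":",
                      interval$start, "-", interval$end)
  mean(profile$values[sel])
}

#' Plot a smoothed (or control-normalized) profile
#'
#' Simple line plot of the profile, with optional amplicon segment shading
#' from a reference map. Requires ggplot2.
#'
#' @param profile A `smoothed_profile`.
#' @param map Optional `azfc_map` used to shade segments.
#' @param path Optional file to save the plot to (png).
#' @return The ggplot object, invisibly.
#' @export
plot_profile <- function(profile, map = NULL, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_profile requires the ggplot2 package")
  df <- data.frame(pos = profile$positions, value = profile$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = pos, y = value))
  if (!is.null(map)) {
    seg <- map$segments
    seg <- seg[seg$family %in% names(amplicon_families()), , drop = FALSE]
    p <- p + ggplot2::geom_rect(
      data = seg,
      ggplot2::aes(xmin = start, xmax = end, fill = family),
      ymin = -Inf, ymax = Inf, alpha = 0.15, inherit.aes = FALSE)
  }
  p <- p + ggplot2::geom_line() +
    ggplot2::labs(x = paste0(profile$chrom, " position (bp)"),
                  y = "smoothed depth",
                  title = profile$sample_id)
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 9, height = 3.5, dpi = 150)
  invisible(p)
}

utils::globalVariables(c("pos", "value", "start", "end", "family"))
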