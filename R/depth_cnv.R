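#' Read a per-base depth table into a depth profile
#'
#' Accepts the two common depth dumps: three-column per-base text
#' (chromosome, 1-based position, depth — `samtools depth` style) or
#' four-column bedGraph (chromosome, 0-based start, half-open end, depth).
#' Only positions inside the requested intervals are loaded. Positions of a
#' requested interval absent from the file are treated as depth 0 (depth
#' dumps conventionally omit zero rows); set `missing_as = NA` to keep them
#' missing instead.
#'
#' @param path Input file.
#' @param intervals Data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) declaring the regions to load.
#' @param sample_id Sample label attached to the profile.
#' @param missing_as Value for positions without a row (default 0).
#' @return A `depth_profile`: list with `sample_id`, `intervals` and `depth`
#'   (one numeric vector per declared interval).
#' @export
read_depth_table <- function(path, intervals, sample_id = basename(path),
                             missing_as = 0) {
  raw <- read.table(path, sep = "\t", comment.char = "#",
                    colClasses = "character", stringsAsFactors = FALSE)
  if (!ncol(raw) %in% c(3L, 4L))
    stop("depth table must have 3 (per-base) or 4 (bedGraph) columns, found ",
         ncol(raw))
  num <- lapply(raw[-1], function(col) suppressWarnings(as.numeric(col)))
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad))
    stop("malformed depth row at line ", bad[1], ": ",
         paste(unlist(raw[bad[1], ]), collapse = "\t"))
  if (ncol(raw) == 3L) {
    df <- data.frame(chrom = raw[[1]], start = num[[1]] - 1,
                     end = num[[1]], depth = num[[2]])
  } else {
    df <- data.frame(chrom = raw[[1]], start = num[[1]],
                     end = num[[2]], depth = num[[3]])
  }
  known <- unique(intervals$chrom)
  if (any(unk <- !df$chrom %in% known)) {
    warning("skipping ", sum(unk), " rows on chromosomes outside the ",
            "requested intervals (", paste(unique(df$chrom[unk]), collapse = ", "), ")")
    df <- df[!unk, , drop = FALSE]
  }
  depth <- vector("list", nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    v <- rep(as.numeric(missing_as), e - s)
    rows <- df[df$chrom == intervals$chrom[i] & df$end > s & df$start < e, , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      from <- max(rows$start[j], s); to <- min(rows$end[j], e)
      v[(from - s + 1):(to - s)] <- rows$depth[j]
    }
    depth[[i]] <- v
  }
  new_depth_profile(sample_id, intervals, depth)
}

new_depth_profile <- function(sample_id, intervals, depth) {
  stopifnot(nrow(intervals) == length(depth),
            all(intervals$end - intervals$start == lengths(depth)))
  if (any(unlist(depth) < 0, na.rm = TRUE)) stop("depths must be non-negative")
  structure(list(sample_id = sample_id,
                 intervals = intervals[, c("chrom", "start", "end")],
                 depth = depth),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("depth profile '", x$sample_id, "': ", nrow(x$intervals),
      " intervals, ", sum(lengths(x$depth)), " bases\n", sep = "")
  invisible(x)
}

# per-base depth over one query interval; errors if any position is undeclared
extract_depth <- function(profile, chrom, start, end) {
  decl <- profile$intervals
  hit <- which(decl$chrom == chrom & decl$end > start & decl$start < end)
  if (!length(hit)) stop("query ", chrom, ":", start, "-", end,
                         " lies outside the declared intervals")
  hit <- hit[order(decl$start[hit])]
  out <- numeric(0); cursor <- start
  for (i in hit) {
    if (decl$start[i] > cursor)
      stop("query ", chrom, ":", start, "-", end, " not fully covered ",
           "by the declared intervals (gap at ", cursor, ")")
    from <- max(decl$start[i], cursor); to <- min(decl$end[i], end)
    out <- c(out, profile$depth[[i]][(from - decl$start[i] + 1):(to - decl$start[i])])
    cursor <- to
    if (cursor >= end) break
  }
  if (cursor < end)
    stop("query ", chrom, ":", start, "-", end, " not fully covered ",
         "by the declared intervals (gap at ", cursor, ")")
  out
}

#' Mean depth over a set of intervals
#'
#' Arithmetic mean of per-base depth over the union of the intervals; bases
#' covered by more than one query interval are counted once.
#'
#' @param profile A `depth_profile`.
#' @param intervals Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); must be covered by the profile's declared intervals.
#' @return Mean depth (numeric scalar).
#' @export
mean_depth <- function(profile, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0)
    stop("mean_depth needs at least one interval")
  total <- 0; n <- 0
  for (chrom in unique(intervals$chrom)) {
    sub <- intervals[intervals$chrom == chrom, , drop = FALSE]
    red <- IRanges::reduce(IRanges::IRanges(start = sub$start + 1, end = sub$end))
    for (k in seq_along(red)) {
      v <- extract_depth(profile, chrom,
                         IRanges::start(red)[k] - 1, IRanges::end(red)[k])
      total <- total + sum(v)
      n <- n + length(v)
    }
  }
  total / n
}

#' Normalized depth of an amplicon family
#'
#' Mean depth over all copies of the family divided by the mean depth of the
#' single-copy normalization interval of the same chromosome. A family at the
#' reference copy number has normalized depth 1; the value scales with the
#' sample's copy count relative to the reference.
#'
#' @param profile A `depth_profile`.
#' @param intervals Data.frame of the family's segment intervals.
#' @param normalization_interval One-row data.frame, the 1-Mb single-copy
#'   interval.
#' @return Normalized depth (numeric scalar).
#' @export
normalized_depth <- function(profile, intervals, normalization_interval) {
  denom <- mean_depth(profile, normalization_interval)
  if (denom <= 0) stop("zero depth over the normalization interval; ",
                       "degenerate control")
  mean_depth(profile, intervals) / denom
}

#' Expected normalized depth for a given copy number
#'
#' For a sample carrying `k` copies of a family whose reference copy number
#' is `ref`, the expected normalized depth is `k / ref`: with two copies of
#' the teal amplicon (like the reference) it is 1 (2/2), with one copy 0.5
#' (1/2), with zero copies 0 (0/2).
#'
#' @param k Sample copy count (non-negative integer, vectorized).
#' @param ref Reference copy count (positive integer).
#' @return `k / ref`.
#' @export
expected_normalized_depth <- function(k, ref) {
  if (any(ref < 1)) stop("reference copy number must be >= 1")
  if (any(k < 0)) stop("copy number must be >= 0")
  k / ref
}

#' Calling interval for a copy number
#'
#' The copy-number caller accepts normalized depth `nd` as `k` copies when
#' `nd` falls between the midpoints of the expected values of adjacent copy
#' numbers: `[(k - 0.5)/ref, (k + 0.5)/ref)`. For a two-copy reference this
#' gives the one-copy window `[0.25, 0.75)` and the zero-copy call below
#' 0.25. The lower bound of the zero-copy interval is clamped to 0.
#'
#' @param k Copy number.
#' @param ref Reference copy number.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
calling_thresholds <- function(k, ref) {
  if (ref < 1) stop("reference copy number must be >= 1")
  c(lower = max(0, (k - 0.5) / ref), upper = (k + 0.5) / ref)
}

#' Call a copy number from a normalized depth
#'
#' Midpoint thresholding: returns the `k` whose expected normalized depth
#' `k/ref` is nearest to `nd`, i.e. `nd` in `[(k-0.5)/ref, (k+0.5)/ref)`
#' (intervals half-open, lower-inclusive). Values at or above the upper
#' bound of `k_max` clamp to `k_max` with a warning.
#'
#' @param nd Normalized depth (non-negative, vectorized).
#' @param ref Reference copy number (positive integer).
#' @param k_max Largest callable copy number (default `3 * ref`).
#' @return Integer copy number(s).
#' @export
call_copy_number <- function(nd, ref, k_max = 3L * ref) {
  if (any(nd < 0)) stop("normalized depth must be non-negative")
  if (ref < 1) stop("reference copy number must be >= 1")
  if (k_max < ref) stop("k_max must be at least the reference copy number")
  k <- as.integer(floor(nd * ref + 0.5))
  if (any(k > k_max)) {
    warning("normalized depth beyond the calling range; clamping to k_max = ", k_max)
    k[k > k_max] <- as.integer(k_max)
  }
  k
}

#' Call copy numbers for every amplicon family and the P3 spacer
#'
#' Computes the normalized depth of each family (mean over all its copies,
#' divided by the single-copy mean) and applies midpoint thresholding.
#'
#' @param profile A `depth_profile` covering all map segments and the
#'   normalization interval.
#' @param map An `azfc_map`.
#' @param k_max_mult `k_max` for each family is `k_max_mult * ref` (the
#'   spacer has ref 1 but may legitimately duplicate, so it shares the rule).
#' @return List with `calls` (data.frame: family, normalized_depth,
#'   reference_count, called_copies, lower_bound, upper_bound) and `vector`
#'   (the assembled `copy_vector`).
#' @export
call_all <- function(profile, map, k_max_mult = 3L) {
  fam <- amplicon_families()
  nrm <- norm_interval(map)
  entries <- c(names(fam), "spacer")
  refs <- c(fam, spacer = 1L)
  nds <- vapply(entries, function(f) {
    iv <- if (f == "spacer") {
      seg <- map$segments
      seg[seg$family == "spacer", c("chrom", "start", "end"), drop = FALSE]
    } else family_intervals(map, f)
    normalized_depth(profile, iv, nrm)
  }, numeric(1))
  calls <- calls_from_nd(nds, refs, k_max_mult)
  list(calls = calls, vector = as_copy_vector(setNames(calls$called_copies, calls$family)))
}

calls_from_nd <- function(nds, refs, k_max_mult = 3L) {
  ks <- mapply(function(nd, ref) call_copy_number(nd, ref, k_max_mult * ref),
               nds, refs)
  bounds <- mapply(function(k, ref) calling_thresholds(k, ref), ks, refs)
  data.frame(family = names(nds),
             normalized_depth = unname(nds),
             reference_count = unname(as.integer(refs)),
             called_copies = unname(as.integer(ks)),
             lower_bound = unname(bounds["lower", ]),
             upper_bound = unname(bounds["upper", ]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call a copy-number vector from printed normalized depths
#'
#' Bypasses depth computation: applies the midpoint calling rule to one
#' normalized-depth value per family (and the P3 spacer), e.g. the published
#' per-sample values of a depth table.
#'
#' @param values Named numeric vector with entries `b, t, g, r, y, Gr,
#'   spacer`.
#' @param map An `azfc_map` (supplies the reference counts).
#' @param k_max_mult As in [call_all()].
#' @return List with `calls` and `vector` as in [call_all()].
#' @export
call_from_normalized <- function(values, map = azfc_reference_map(),
                                 k_max_mult = 3L) {
  entries <- copy_vector_names()
  if (!all(entries %in% names(values)))
    stop("missing normalized depth for: ",
         paste(setdiff(entries, names(values)), collapse = ", "))
  refs <- c(amplicon_families(), spacer = 1L)
  nds <- setNames(as.numeric(values[entries]), entries)
  calls <- calls_from_nd(nds, refs, k_max_mult)
  list(calls = calls, vector = as_copy_vector(setNames(calls$called_copies, calls$family)))
}

#' Write copy-number calls to TSV and the vector to JSON
#'
#' @param result List from [call_all()] or [call_from_normalized()].
#' @param calls_path Output TSV for the per-family calls.
#' @param vector_path Optional output JSON for the copy-number vector.
#' @return `calls_path`, invisibly.
#' @export
write_calls <- function(result, calls_path, vector_path = NULL) {
  write.table(result$calls, calls_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(vector_path))
    jsonlite::write_json(as.list(setNames(as.integer(result$vector),
                                          names(result$vector))),
                         vector_path, auto_unbox = TRUE)
  invisible(calls_path)
}
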