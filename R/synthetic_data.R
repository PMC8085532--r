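#' Simulate a per-base depth profile for a copy-number vector
#'
#' Emulates multi-mapping collapse over near-identical amplicon copies:
#' reads from every copy of a family pile onto the family's reference
#' segments, so the expected per-base depth over a family segment is
#' `base_coverage * family copies / reference copies`. The P3 spacer scales
#' with its own count, unique segments and the normalization interval sit at
#' `base_coverage`. Per-base counting noise is Poisson (or none, for exact
#' expectations).
#'
#' @param map An `azfc_map` (full-size or toy-scaled).
#' @param vector `copy_vector` of the simulated chromosome.
#' @param base_coverage Haploid single-copy mean depth (e.g. 38.7).
#' @param noise `"poisson"` or `"none"`.
#' @param seed Integer seed for reproducible draws (`NULL` leaves the RNG
#'   state alone).
#' @param sample_id Label of the simulated sample.
#' @return A `depth_profile` covering every map segment and the
#'   normalization interval.
#' @export
simulate_depth <- function(map, vector = reference_copy_vector(map),
                           base_coverage = 30, noise = c("poisson", "none"),
                           seed = NULL, sample_id = "simulated") {
  noise <- match.arg(noise)
  if (base_coverage <= 0) stop("base_coverage must be positive")
  vector <- as_copy_vector(vector)
  fam <- amplicon_families()
  seg <- map$segments
  intervals <- rbind(seg[, c("chrom", "start", "end")], norm_interval(map))
  expected <- c(vapply(seq_len(nrow(seg)), function(i) {
    f <- seg$family[i]
    if (f %in% names(fam)) base_coverage * vector[[f]] / fam[[f]]
    else if (f == "spacer") base_coverage * vector[["spacer"]]
    else base_coverage
  }, numeric(1)), base_coverage)
  draw <- function() {
    lapply(seq_len(nrow(intervals)), function(i) {
      n <- intervals$end[i] - intervals$start[i]
      if (noise == "poisson") as.numeric(rpois(n, expected[i]))
      else rep(expected[i], n)
    })
  }
  depth <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_depth_profile(sample_id, intervals, depth)
}

#' Write a depth profile as a per-base depth table
#'
#' Emits the 3-column per-base format (chromosome, 1-based position, depth)
#' or 4-column bedGraph. Zero-depth rows are omitted in the per-base format,
#' the usual depth-dump convention.
#'
#' @param profile A `depth_profile`.
#' @param path Output file.
#' @param format `"tsv"` (per-base) or `"bedGraph"`.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(profile, path, format = c("tsv", "bedGraph")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(profile$intervals))) {
    iv <- profile$intervals[i, ]
    v <- profile$depth[[i]]
    if (format == "tsv") {
      keep <- v != 0
      if (!any(keep)) next
      df <- data.frame(chrom = iv$chrom,
                       pos = iv$start + which(keep),  # 1-based
                       depth = v[keep])
    } else {
      brk <- c(TRUE, diff(v) != 0)
      grp <- cumsum(brk)
      off <- iv$start + seq_along(v) - 1
      df <- data.frame(chrom = iv$chrom,
                       start = tapply(off, grp, min),
                       end = tapply(off, grp, max) + 1,
                       depth = tapply(v, grp, `[`, 1))
    }
    write.table(format(df, scientific = FALSE, trim = TRUE, digits = 15),
                con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Scale the reference map down for fast tests
#'
#' Multiplies every coordinate by `scale` (floor), preserving segment order,
#' adjacency, family counts and orientations. The b2-to-b4 and b1-to-b3
#' spans scale proportionally (e.g. 35 kb and 16 kb at scale 0.01), as does
#' the normalization interval, so simulations over the toy map run in
#' milliseconds.
#'
#' @param scale Factor in (0, 1].
#' @param map The map to scale (default: the bundled fixture).
#' @return A validated `azfc_map` with the `scale` field set.
#' @export
make_toy_map <- function(scale = 0.01, map = azfc_reference_map()) {
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  shrink <- function(df) {
    df$start <- floor(df$start * scale)
    df$end <- floor(df$end * scale)
    df
  }
  out <- map
  out$segments <- shrink(map$segments)
  out$norm <- shrink(map$norm)
  out$scale <- map$scale * scale
  if (any(out$segments$end - out$segments$start < 100))
    stop("scale ", scale, " degenerates segments below 100 bp")
  validate_reference_map(out)
  out
}

#' Evolve haplotypes under the single-step stepwise mutation model
#'
#' Each lineage evolves independently for `generations` generations: per
#' generation and locus a mutation occurs with the locus rate, shifting the
#' allele by +1 or -1 repeat with equal probability. A mutation that would
#' take an allele to zero is reflected to a +1 step (with a warning).
#'
#' @param founder Named integer allele vector.
#' @param n_tips Number of descendant lineages.
#' @param generations Generations from founder to tips.
#' @param rates Named per-locus mutation rates (default bundled table).
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @param tip_ids Sample ids for the tips.
#' @return Data.frame of haplotypes (`sample_id` + locus columns).
#' @export
simulate_haplotypes <- function(founder, n_tips, generations,
                                rates = default_mutation_rates(),
                                seed = NULL,
                                tip_ids = sprintf("tip_%03d", seq_len(n_tips))) {
  if (generations < 0) stop("generations must be >= 0")
  panel <- names(founder)
  missing <- setdiff(panel, names(rates))
  if (length(missing))
    stop("no mutation rate for: ", paste(missing, collapse = ", "))
  mu <- rates[panel]
  run <- function() {
    A <- matrix(as.integer(founder), nrow = length(panel), ncol = n_tips)
    reflected <- FALSE
    for (g in seq_len(generations)) {
      mut <- matrix(runif(length(A)) < mu, nrow = length(panel))
      if (!any(mut)) next
      step <- matrix(sample(c(-1L, 1L), length(A), replace = TRUE),
                     nrow = length(panel))
      B <- A + step * mut
      if (any(bad <- B < 1)) {
        B[bad] <- A[bad] + 1L  # reflect the -1 step that would reach zero
        reflected <- TRUE
      }
      A <- B
    }
    if (reflected) warning("allele would have reached zero; step reflected to +1")
    A
  }
  A <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- data.frame(sample_id = tip_ids, t(A), stringsAsFactors = FALSE)
  names(out) <- c("sample_id", panel)
  out
}

#' A plausible founder haplotype for simulations
#'
#' Typical repeat counts for the default 16-locus panel, far from the
#' zero-allele boundary so reflection never matters at realistic time
#' depths.
#'
#' @return Named integer allele vector.
#' @export
default_founder <- function() {
  c(DYS19 = 15L, DYS389I = 13L, DYS390 = 24L, DYS391 = 11L, DYS392 = 13L,
    DYS393 = 13L, DYS437 = 15L, DYS438 = 11L, DYS439 = 12L, DYS456 = 16L,
    DYS458 = 17L, DYS460 = 11L, DYS481 = 22L, DYS533 = 12L, DYS635 = 23L,
    YGATAH4 = 12L)
}

#' Write a haplotype table
#'
#' @param haplotypes Data.frame from [simulate_haplotypes()] or
#'   [read_haplotypes()].
#' @param path Output file (TSV, or CSV if the extension is .csv).
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(haplotypes, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(haplotypes, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
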