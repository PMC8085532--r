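#' @importFrom utils read.table write.table head tail
#' @importFrom stats rpois runif sd setNames
NULL

#' Amplicon families of the AZFc and their reference copy numbers
#'
#' The AZFc region is built from six nearly identical amplicon families
#' (blue, teal, green, red, yellow, gray). On the reference Y chromosome they
#' are present in 4, 2, 3, 4, 2 and 2 copies respectively; these counts are
#' the denominators of every copy-number ratio the calling layer reports.
#'
#' @return Named integer vector of reference copy counts.
#' @export
amplicon_families <- function() {
  c(b = 4L, t = 2L, g = 3L, r = 4L, y = 2L, Gr = 2L)
}

# canonical ordering of copy-number vector entries: six families + P3 spacer
copy_vector_names <- function() c(names(amplicon_families()), "spacer")

#' Construct a copy-number vector
#'
#' @param b,t,g,r,y,Gr,spacer Non-negative integer copy counts per amplicon
#'   family, plus the P3-spacer count (1 on the reference chromosome).
#' @return Named integer vector with class `copy_vector`.
#' @export
copy_vector <- function(b = 4, t = 2, g = 3, r = 4, y = 2, Gr = 2, spacer = 1) {
  v <- c(b = b, t = t, g = g, r = r, y = y, Gr = Gr, spacer = spacer)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
    stop("copy-number entries must be non-negative integers")
  structure(as.integer(v), names = copy_vector_names(), class = "copy_vector")
}

as_copy_vector <- function(x) {
  nm <- copy_vector_names()
  if (is.null(names(x)) || !all(nm %in% names(x)))
    stop("copy-number vector must carry entries named ",
         paste(nm, collapse = ", "))
  do.call(copy_vector, as.list(as.numeric(x[nm])))
}

#' Load an AZFc reference map from a BED-like file
#'
#' The map file is 6-column tab-separated text (chrom, start, end, id, family,
#' strand) with 0-based half-open coordinates. Families are the six amplicon
#' families plus `spacer` (P3 spacer), `unique` (single-copy sequence such as
#' IR1) and `norm` (the 1-Mb single-copy normalization interval). A comment
#' line `# scale=<s>` records the coordinate scale (1 for the full-size map;
#' toy maps produced by [make_toy_map()] carry their scale factor so the
#' normalization-interval length check stays meaningful).
#'
#' @param path Path to the map file. Defaults to the bundled schematic GRCh37
#'   fixture.
#' @param gene_path,anchor_path Paths to the gene-family and STR-anchor
#'   sidecar TSVs; default to the bundled fixtures.
#' @return A validated object of class `azfc_map`: list with `segments`
#'   (data.frame of amplicon/spacer/unique segments, sorted), `norm`
#'   (one-row data.frame, the normalization interval), `genes`, `str_anchors`
#'   and `scale`.
#' @seealso [reference_copy_vector()], [validate_reference_map()]
#' @export
load_reference_map <- function(path = azfc_map_path(),
                               gene_path = system.file("extdata", "gene_families.tsv", package = "azfcnahr"),
                               anchor_path = system.file("extdata", "str_anchors.tsv", package = "azfcnahr")) {
  lines <- readLines(path)
  scale <- 1
  sc <- grep("^#\\s*scale=", lines, value = TRUE)
  if (length(sc)) scale <- as.numeric(sub("^#\\s*scale=", "", sc[1]))
  tab <- read.table(path, sep = "\t", comment.char = "#",
                    col.names = c("chrom", "start", "end", "id", "family", "strand"),
                    colClasses = c("character", "numeric", "numeric",
                                   "character", "character", "character"),
                    stringsAsFactors = FALSE)
  is_norm <- tab$family == "norm"
  if (sum(is_norm) != 1L)
    stop("map must contain exactly one normalization interval (family 'norm')")
  genes <- read.table(gene_path, sep = "\t", header = TRUE,
                      comment.char = "#", stringsAsFactors = FALSE)
  anchors <- read.table(anchor_path, sep = "\t", header = TRUE,
                        comment.char = "#", stringsAsFactors = FALSE)
  map <- structure(
    list(segments = tab[!is_norm, , drop = FALSE],
         norm = tab[is_norm, , drop = FALSE],
         genes = genes,
         str_anchors = anchors,
         scale = scale),
    class = "azfc_map")
  rownames(map$segments) <- NULL
  validate_reference_map(map)
  map
}

#' Path of the bundled schematic AZFc map
#' @return File path of the packaged BED-like fixture.
#' @export
azfc_map_path <- function() {
  system.file("extdata", "azfc_map_synthetic_grch37.bed", package = "azfcnahr")
}

#' Bundled AZFc reference map
#'
#' Convenience wrapper loading the packaged schematic GRCh37 map with its
#' gene-family and STR-anchor sidecars.
#' @return An `azfc_map` object.
#' @export
azfc_reference_map <- function() load_reference_map()

#' Validate an AZFc reference map
#'
#' Checks the structural invariants of the map: positive-length,
#' non-overlapping, sorted segments; family copy counts equal to the reference
#' (b=4, t=2, g=3, r=4, y=2, Gr=2) with exactly one P3 spacer; a
#' normalization interval of 1 Mb (times the map scale, within 1 bp) that does
#' not overlap any segment; DYS448 anchored in the P3 spacer and DYF387S1 in
#' the yellow amplicons. Errors name the offending segment.
#'
#' @param map An `azfc_map` object.
#' @return The map, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_reference_map <- function(map) {
  seg <- map$segments
  if (any(bad <- seg$end <= seg$start))
    stop("segment ", seg$id[which(bad)[1]], ": end must exceed start")
  if (is.unsorted(seg$start, strictly = TRUE))
    stop("segments are not sorted by start (offender: ",
         seg$id[which(diff(seg$start) <= 0)[1] + 1L], ")")
  if (any(bad <- head(seg$end, -1) > tail(seg$start, -1)))
    stop("segment ", seg$id[which(bad)[1] + 1L], " overlaps its predecessor")
  fam <- amplicon_families()
  counts <- table(factor(seg$family, levels = names(fam)))
  for (f in names(fam))
    if (counts[[f]] != fam[[f]])
      stop("family ", f, ": found ", counts[[f]], " segments, expected ", fam[[f]])
  if (sum(seg$family == "spacer") != 1L)
    stop("map must contain exactly one P3 spacer segment")
  if (!all(seg$strand %in% c("+", "-")))
    stop("segment strands must be '+' or '-'")
  nrm <- map$norm
  len <- nrm$end - nrm$start
  if (abs(len - 1e6 * map$scale) > 1)
    stop("normalization interval ", nrm$id, " has length ", len,
         ", expected ", 1e6 * map$scale, " +/- 1 bp")
  same_chrom <- seg$chrom == nrm$chrom
  if (any(same_chrom & seg$start < nrm$end & seg$end > nrm$start))
    stop("normalization interval overlaps an amplicon segment")
  an <- map$str_anchors
  host448 <- an$segment[an$str == "DYS448"]
  if (!all(seg$family[match(host448, seg$id)] == "spacer"))
    stop("DYS448 anchor must lie in the P3 spacer")
  host387 <- an$segment[an$str == "DYF387S1"]
  if (length(host387) < 1 || !all(seg$family[match(host387, seg$id)] == "y"))
    stop("DYF387S1 anchors must lie in yellow (y) segments")
  invisible(map)
}

#' Reference copy-number vector of a map
#'
#' Counts the segments of each amplicon family (plus the P3 spacer) in the
#' map. On a valid reference map this reproduces the reference denominators
#' (b=4, t=2, g=3, r=4, y=2, Gr=2, spacer=1).
#'
#' @param map An `azfc_map` object.
#' @return A `copy_vector`.
#' @export
reference_copy_vector <- function(map) {
  seg <- map$segments
  fam <- amplicon_families()
  v <- vapply(names(fam), function(f) sum(seg$family == f), integer(1))
  do.call(copy_vector, c(as.list(v), list(spacer = sum(seg$family == "spacer"))))
}

#' Write an AZFc map back to its BED-like representation
#'
#' Inverse of [load_reference_map()] for the segment table: emits the 6-column
#' text (including the normalization interval and the `# scale=` header) so
#' load -> write -> load is the identity.
#'
#' @param map An `azfc_map` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scale=%.10g", map$scale), con)
  all_rows <- rbind(map$norm, map$segments)
  all_rows <- all_rows[order(all_rows$start), , drop = FALSE]
  write.table(format(all_rows, scientific = FALSE, trim = TRUE),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# interval helpers -----------------------------------------------------------

# segments of one family as a data.frame of intervals (chrom, start, end)
family_intervals <- function(map, family) {
  seg <- map$segments
  seg[seg$family == family, c("chrom", "start", "end"), drop = FALSE]
}

norm_interval <- function(map) map$norm[, c("chrom", "start", "end"), drop = FALSE]

#' @export
print.azfc_map <- function(x, ...) {
  cat("AZFc reference map (", nrow(x$segments), " segments, scale ",
      x$scale, ")\n", sep = "")
  v <- reference_copy_vector(x)
  cat("  copy vector:", paste(names(v), unname(v), sep = "=", collapse = " "), "\n")
  cat("  normalization interval: ", x$norm$chrom, ":", x$norm$start, "-",
      x$norm$end, "\n", sep = "")
  invisible(x)
}

#' @export
print.copy_vector <- function(x, ...) {
  cat("AZFc copy-number vector:",
      paste(names(x), unname(x), sep = "=", collapse = " "), "\n")
  invisible(x)
}
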