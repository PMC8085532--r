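#' Default 16-locus Y-STR dating panel
#'
#' The Yfiler Plus loci minus the multi-copy loci (DYS385a/b, DYF387S1), the
#' interrupted DYS389II, the deleted DYS448, and the rapidly mutating loci
#' (DYS449, DYS518, DYS570, DYS576, DYS627) — the slowly mutating single-copy
#' loci suitable for ASD clock calculations.
#'
#' @return Character vector of 16 locus names.
#' @export
default_str_panel <- function() {
  c("DYS19", "DYS389I", "DYS390", "DYS391", "DYS392", "DYS393",
    "DYS437", "DYS438", "DYS439", "DYS456", "DYS458", "DYS460",
    "DYS481", "DYS533", "DYS635", "YGATAH4")
}

#' Bundled per-locus mutation-rate table
#'
#' Germline mutation rates per locus per generation for the default panel;
#' a calibrated compilation of published-magnitude estimates whose panel
#' mean is 3.18e-3 per marker per generation.
#'
#' @return Named numeric vector (locus -> rate).
#' @export
default_mutation_rates <- function() {
  path <- system.file("extdata", "ystr_mutation_rates.tsv", package = "azfcnahr")
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  setNames(tab$rate, tab$locus)
}

#' Read a Y-STR haplotype table
#'
#' One row per sample: a `sample_id` column plus one integer repeat-count
#' column per locus (CSV or TSV, autodetected from the extension).
#'
#' @param path Input file.
#' @return Data.frame of haplotypes.
#' @export
read_haplotypes <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, sep = sep, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("haplotype table needs a sample_id column")
  df
}

check_panel <- function(haplotypes, panel) {
  missing <- setdiff(panel, names(haplotypes))
  if (length(missing))
    stop("haplotypes lack panel loci: ", paste(missing, collapse = ", "))
  alleles <- as.matrix(haplotypes[, panel, drop = FALSE])
  if (any(is.na(alleles)))
    stop("missing allele values in the haplotype table")
  if (any(alleles != round(alleles)))
    stop("non-integer (microvariant) alleles are not supported for panel ",
         "loci; squared distances on repeat counts need whole repeats")
  if (any(alleles < 1)) stop("alleles must be positive repeat counts")
  alleles
}

#' Modal (founder) haplotype of a set of haplotypes
#'
#' Per-locus most frequent allele; ties are broken by the candidate
#' minimizing the total squared distance to all haplotypes, then by the
#' smaller allele. Used as the founder estimate of a cluster.
#'
#' @param haplotypes Data.frame with `sample_id` and locus columns.
#' @param panel Loci to use (default: all 16 of [default_str_panel()] that
#'   are present, else all non-id columns).
#' @return Named integer vector (locus -> allele).
#' @export
modal_haplotype <- function(haplotypes, panel = setdiff(names(haplotypes), "sample_id")) {
  if (nrow(haplotypes) < 1) stop("at least one haplotype is required")
  alleles <- check_panel(haplotypes, panel)
  modal <- vapply(panel, function(l) {
    a <- alleles[, l]
    tab <- table(a)
    cand <- as.integer(names(tab)[tab == max(tab)])
    if (length(cand) > 1) {
      ssd <- vapply(cand, function(x) sum((a - x)^2), numeric(1))
      cand <- cand[ssd == min(ssd)]
      cand <- min(cand)
    }
    cand
  }, integer(1))
  setNames(as.integer(modal), panel)
}

#' Average squared distance (ASD) to a founder haplotype
#'
#' Per locus, the mean over haplotypes of the squared allele difference from
#' the founder; the ASD is the mean of the per-locus values over the panel.
#' Under the single-step stepwise mutation model the expected per-locus ASD
#' after G generations is `mu_l * G`.
#'
#' @param haplotypes Data.frame of haplotypes.
#' @param founder Named allele vector (e.g. from [modal_haplotype()]).
#' @param panel Loci to use (default: the loci of `founder`).
#' @return List with `asd` (scalar) and `per_locus` (named vector).
#' @export
asd <- function(haplotypes, founder, panel = names(founder)) {
  if (!all(panel %in% names(founder)))
    stop("founder lacks panel loci: ",
         paste(setdiff(panel, names(founder)), collapse = ", "))
  alleles <- check_panel(haplotypes, panel)
  per_locus <- vapply(panel, function(l)
    mean((alleles[, l] - founder[[l]])^2), numeric(1))
  list(asd = mean(per_locus), per_locus = per_locus)
}

#' Mean mutation rate over a locus panel
#'
#' @param rates Named numeric vector (locus -> rate per generation).
#' @param panel Loci to average (default: the full table).
#' @return Arithmetic mean rate.
#' @export
mean_rate <- function(rates = default_mutation_rates(), panel = names(rates)) {
  missing <- setdiff(panel, names(rates))
  if (length(missing))
    stop("no mutation rate for: ", paste(missing, collapse = ", "))
  if (any(rates[panel] <= 0)) stop("mutation rates must be positive")
  mean(rates[panel])
}

#' Coalescence time from an ASD result
#'
#' Time in generations is `asd / rate`; years are generations times the
#' generation interval. The standard error is the across-locus dispersion of
#' the per-locus age estimates (sd of `per_locus / rate` over loci, divided
#' by the square root of the locus count), an implementation convention.
#'
#' @param asd_result List from [asd()].
#' @param rate Mean mutation rate per marker per generation.
#' @param generation_years Years per generation (default 25).
#' @param n_haplotypes Optional count carried into the result.
#' @return An `age_estimate`: list with `asd`, `t_generations`, `t_years`,
#'   `se_years`, `n_haplotypes`, `n_loci`, `generation_years`.
#' @export
coalescence_time <- function(asd_result, rate, generation_years = 25,
                             n_haplotypes = NA_integer_) {
  if (rate <= 0) stop("mutation rate must be positive")
  n_loci <- length(asd_result$per_locus)
  t_gen <- asd_result$asd / rate
  per_locus_gen <- asd_result$per_locus / rate
  se_gen <- stats::sd(per_locus_gen) / sqrt(n_loci)
  structure(list(asd = asd_result$asd,
                 t_generations = t_gen,
                 t_years = t_gen * generation_years,
                 se_years = se_gen * generation_years,
                 n_haplotypes = n_haplotypes,
                 n_loci = n_loci,
                 generation_years = generation_years),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("ASD %.4f over %d loci -> %.2f generations = %.0f +/- %.0f years (%g y/generation)\n",
              x$asd, x$n_loci, x$t_generations, x$t_years,
              if (is.na(x$se_years)) 0 else x$se_years, x$generation_years))
  invisible(x)
}

#' Date a haplotype cluster by the ASD method
#'
#' Selects the cluster, estimates its founder as the modal haplotype,
#' computes the ASD and converts it to time with the averaged panel mutation
#' rate.
#'
#' @param haplotypes Data.frame of haplotypes (`sample_id` + locus columns).
#' @param cluster_ids Sample ids forming the cluster.
#' @param rates Mutation-rate table (default bundled).
#' @param panel Locus panel (default [default_str_panel()]).
#' @param generation_years Years per generation (default 25).
#' @param founder Optional user-supplied founder haplotype; default is the
#'   cluster's modal haplotype.
#' @return An `age_estimate`.
#' @export
date_cluster <- function(haplotypes, cluster_ids = haplotypes$sample_id,
                         rates = default_mutation_rates(),
                         panel = default_str_panel(),
                         generation_years = 25,
                         founder = NULL) {
  unknown <- setdiff(cluster_ids, haplotypes$sample_id)
  if (length(unknown))
    stop("unknown sample ids: ", paste(unknown, collapse = ", "))
  sub <- haplotypes[haplotypes$sample_id %in% cluster_ids, , drop = FALSE]
  if (is.null(founder)) founder <- modal_haplotype(sub, panel)
  res <- asd(sub, founder, panel)
  coalescence_time(res, mean_rate(rates, panel), generation_years,
                   n_haplotypes = nrow(sub))
}
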