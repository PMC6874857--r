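# Ecological Integrity Index: biotic (AMBI/ASPT), habitat (QBR-Am/IHF-Am)
# and physical-chemical components, each parameter scaled to [0,1] with 1 =
# best, averaged within component, then combined across components.

#' Family-level biotic index (AMBI)
#'
#' BMWP-style score: the sum of tolerance scores over the distinct
#' invertebrate families present at a site. Higher scores indicate a
#' community richer in pollution-sensitive families.
#'
#' @param taxa Character vector of family names recorded at the site
#'   (duplicates are counted once).
#' @param tolerance_table Named numeric vector or two-column data frame
#'   (`family`, `score`) mapping family to tolerance score (> 0).
#' @param unknown How to treat names absent from the table: `"warn"`
#'   (default; skip with a warning) or `"error"`.
#' @return A single numeric score.
#' @export
compute_ambi <- function(taxa, tolerance_table,
                         unknown = c("warn", "error")) {
  unknown <- match.arg(unknown)
  tab <- as_tolerance_vector(tolerance_table)
  fams <- unique(as.character(taxa))
  miss <- setdiff(fams, names(tab))
  if (length(miss)) {
    msg <- paste0("unrecognized families: ", paste(miss, collapse = ", "))
    if (unknown == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    fams <- setdiff(fams, miss)
  }
  if (!length(fams))
    stop("no resolvable taxa at site; biotic index undefined", call. = FALSE)
  sum(tab[fams])
}

#' Average score per taxon (ASPT)
#'
#' Standardizes the biotic index by richness: `ambi / n_families`.
#'
#' @param ambi Biotic index score.
#' @param n_families Number of distinct families counted, >= 1.
#' @return A single numeric score.
#' @export
compute_aspt <- function(ambi, n_families) {
  if (n_families < 1) stop("ASPT undefined for zero families", call. = FALSE)
  ambi / n_families
}

as_tolerance_vector <- function(tolerance_table) {
  if (is.data.frame(tolerance_table)) {
    tab <- stats::setNames(tolerance_table$score,
                           as.character(tolerance_table$family))
  } else {
    tab <- tolerance_table
  }
  if (is.null(names(tab)) || any(!nzchar(names(tab))))
    stop("tolerance table needs family names", call. = FALSE)
  if (anyDuplicated(names(tab))) stop("duplicate family names", call. = FALSE)
  if (any(tab <= 0)) stop("tolerance scores must be > 0", call. = FALSE)
  tab
}

#' Deviation of an observed physical-chemical value from reference
#'
#' @param observed,reference Finite numeric values (vectors recycle).
#' @return `abs(observed - reference)` in the parameter's units.
#' @export
physchem_deviation <- function(observed, reference) {
  if (any(!is.finite(observed)) || any(!is.finite(reference)))
    stop("observed and reference values must be finite", call. = FALSE)
  abs(observed - reference)
}

#' Scale a parameter across sites to \[0, 1\], 1 = best
#'
#' Min-max scaling against bounds: empirical (the observed min/max across
#' sites) by default, or fixed bounds from configuration. With
#' `invert = TRUE` (for deviations, where larger is worse) the scale is
#' flipped so 1 is still the best condition. A constant column carries no
#' evidence of impairment and maps to 1.0 everywhere (with a warning).
#'
#' @param values Numeric vector across sites (NA allowed, propagated).
#' @param invert Flip the scale (`TRUE` for "higher raw value = worse").
#' @param bounds Optional `c(lo, hi)` fixed bounds; values are clamped into
#'   them before scaling.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
normalize_parameter <- function(values, invert = FALSE, bounds = NULL) {
  ok <- is.finite(values)
  if (!any(ok)) stop("no finite values to normalize", call. = FALSE)
  if (is.null(bounds)) bounds <- range(values[ok])
  stopifnot(length(bounds) == 2L, bounds[1] <= bounds[2])
  if (bounds[2] == bounds[1]) {
    warning("constant parameter: scored 1.0 everywhere (no evidence of impairment)",
            call. = FALSE)
    out <- rep(1, length(values))
    out[!ok] <- NA_real_
    return(out)
  }
  v <- pmin(bounds[2], pmax(bounds[1], values))
  s <- (v - bounds[1]) / (bounds[2] - bounds[1])
  if (invert) s <- 1 - s
  s
}

#' Average parameter scores into a component score
#'
#' @param scores Numeric vector of parameter scores in \[0, 1\] (NAs dropped).
#' @return The arithmetic mean.
#' @export
component_score <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("no scores to average", call. = FALSE)
  if (any(scores < 0 | scores > 1))
    stop("component inputs must lie in [0, 1]", call. = FALSE)
  mean(scores)
}

#' Combine component scores into the Ecological Integrity Index
#'
#' Weighted mean of the biotic, habitat and physical-chemical components.
#' Equal weights give the plain arithmetic EII; `c(2, 1, 1)` gives the
#' biology-weighted variant (biotic counted twice).
#'
#' @param biotic,habitat,physchem Component scores in \[0, 1\] (vectors
#'   recycle).
#' @param weights Positive length-3 weights, ordered (biotic, habitat,
#'   physchem). Default `c(1, 1, 1)`.
#' @return EII value(s) in \[0, 1\].
#' @examples
#' compute_eii(0.6, 0.9, 0.9)              # 0.8
#' compute_eii(0.6, 0.9, 0.9, c(2, 1, 1))  # 0.75
#' @export
compute_eii <- function(biotic, habitat, physchem, weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3L, all(weights > 0))
  comp <- cbind(biotic, habitat, physchem)
  if (any(comp < 0 | comp > 1, na.rm = TRUE))
    stop("components must lie in [0, 1]", call. = FALSE)
  as.numeric(comp %*% weights) / sum(weights)
}

#' Default physical-chemical reference values and deviation bounds
#'
#' Reference conditions for minimally impacted Andean-Amazon streams and the
#' maximum plausible deviation used when fixed-bound scaling is requested.
#' These are package defaults, global across the elevation gradient, and
#' should be overridden with study-specific references where available.
#'
#' @return Data frame with columns `parameter`, `reference`, `bound`.
#' @export
default_reference_values <- function() {
  data.frame(
    parameter = c("ph", "conductivity", "dissolved_oxygen", "temperature"),
    reference = c(7.0, 150, 8, 18),
    bound     = c(3, 400, 6, 15),
    stringsAsFactors = FALSE)
}

#' Score a site table into components and EII
#'
#' Runs the full index pipeline: biotic indices from the taxa lists, habitat
#' scores from raw QBR-Am/IHF-Am values against their maxima,
#' physical-chemical deviation scores against reference values; every
#' parameter scaled to \[0, 1\] with 1 = best, averaged within component, and
#' combined into the arithmetic and the 2:1:1 biology-weighted EII.
#'
#' @param sites Data frame, one row per site, with columns `site_id`, `x`,
#'   `y`, optional `elevation`, habitat raw scores `qbr` and `ihf`, and
#'   physical-chemical columns `ph`, `conductivity`, `dissolved_oxygen`,
#'   `temperature`.
#' @param taxa Long-format data frame with columns `site_id`, `family`.
#' @param tolerance_table Family tolerance scores (see [compute_ambi()]).
#' @param references Reference values/bounds data frame (default
#'   [default_reference_values()]).
#' @param habitat_max Maximum attainable raw score for `qbr` and `ihf`
#'   (length-2 or scalar; default 100 each).
#' @param physchem_bounds `"fixed"` scales each deviation against the
#'   reference table's `bound`; `"empirical"` (default) against the maximum
#'   deviation observed across sites.
#' @param biotic_bounds `NULL` (empirical min-max across sites, the default)
#'   or a list with elements `ambi = c(lo, hi)` and `aspt = c(lo, hi)` for
#'   fixed bounds.
#' @param unknown Passed to [compute_ambi()].
#' @return Data frame of class `eii_table`: `site_id`, component scores
#'   (`biotic`, `habitat`, `physchem`), `eii` (arithmetic) and
#'   `eii_weighted` (2:1:1), plus raw `ambi`, `aspt`, `n_families`.
#' @export
score_sites <- function(sites, taxa, tolerance_table,
                        references = default_reference_values(),
                        habitat_max = c(100, 100),
                        physchem_bounds = c("empirical", "fixed"),
                        biotic_bounds = NULL,
                        unknown = c("warn", "error")) {
  physchem_bounds <- match.arg(physchem_bounds)
  unknown <- match.arg(unknown)
  habitat_max <- rep_len(habitat_max, 2L)
  n <- nrow(sites)
  if (n < 1L) stop("empty site table", call. = FALSE)

  # biotic: AMBI and ASPT per site, scaled across sites (higher = better)
  ambi <- aspt <- nfam <- numeric(n)
  tab <- as_tolerance_vector(tolerance_table)
  for (i in seq_len(n)) {
    fams <- unique(taxa$family[taxa$site_id == sites$site_id[i]])
    fams <- as.character(fams)
    ambi[i] <- compute_ambi(fams, tab, unknown = unknown)
    nfam[i] <- length(intersect(fams, names(tab)))
    aspt[i] <- compute_aspt(ambi[i], nfam[i])
  }
  ambi_s <- normalize_parameter(ambi, bounds = biotic_bounds$ambi)
  aspt_s <- normalize_parameter(aspt, bounds = biotic_bounds$aspt)
  biotic <- (ambi_s + aspt_s) / 2

  # habitat: raw index scores against their declared maxima
  qbr_s <- normalize_parameter(sites$qbr, bounds = c(0, habitat_max[1]))
  ihf_s <- normalize_parameter(sites$ihf, bounds = c(0, habitat_max[2]))
  habitat <- (qbr_s + ihf_s) / 2

  # physical-chemical: deviation from reference, inverted so 1 = at reference
  pc_params <- intersect(references$parameter, names(sites))
  if (!length(pc_params))
    stop("no physical-chemical columns found in site table", call. = FALSE)
  pc_scores <- sapply(pc_params, function(p) {
    ref <- references[references$parameter == p, ]
    dev <- physchem_deviation(sites[[p]], ref$reference)
    b <- if (physchem_bounds == "fixed") c(0, ref$bound) else NULL
    normalize_parameter(dev, invert = TRUE, bounds = b)
  })
  physchem <- rowMeans(as.matrix(pc_scores))

  out <- data.frame(site_id = sites$site_id,
                    biotic = biotic, habitat = habitat, physchem = physchem,
                    eii = compute_eii(biotic, habitat, physchem),
                    eii_weighted = compute_eii(biotic, habitat, physchem,
                                               weights = c(2, 1, 1)),
                    ambi = ambi, aspt = aspt, n_families = nfam,
                    stringsAsFactors = FALSE)
  class(out) <- c("eii_table", "data.frame")
  out
}
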