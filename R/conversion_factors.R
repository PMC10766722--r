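#' Centered estimate with rectangular-distribution uncertainty
#'
#' Centers a set of candidate values on the midpoint of their min-max
#' range; the standard uncertainty is the half-range divided by sqrt(3)
#' (rectangular-distribution assumption for a bounded quantity). With a
#' single basis value the uncertainty is 0 and a warning flags the
#' single-basis case. The plain arithmetic mean is kept alongside for
#' transparency.
#'
#' @param values numeric vector (>= 1 finite value).
#' @return an object of class `aq_centered` with `center`, `u`,
#'   `basis_min`, `basis_max`, `n_basis`, `mean`.
#' @export
#' @examples
#' centered_estimate(c(0.3, 0.4)) # center 0.35, u = 0.05/sqrt(3)
centered_estimate <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values supplied", call. = FALSE)
  lo <- min(values)
  hi <- max(values)
  u <- if (length(values) >= 2L) (hi - lo) / 2 / sqrt(3) else {
    warning("single basis value; standard uncertainty set to 0",
            call. = FALSE)
    0
  }
  structure(list(center = (hi + lo) / 2, u = u, basis_min = lo,
                 basis_max = hi, n_basis = length(values),
                 mean = mean(values)), class = "aq_centered")
}

#' @export
print.aq_centered <- function(x, ...) {
  cat(sprintf("<centered estimate> %.6g, u = %.3g (n = %d, range %.6g-%.6g)\n",
              x$center, x$u, x$n_basis, x$basis_min, x$basis_max))
  invisible(x)
}

#' Centered conversion factor from per-replicate values
#'
#' @param cfs per-replicate conversion factors, each in (0, 1].
#' @return an `aq_centered`.
#' @export
centered_cf <- function(cfs) {
  if (any(!is.finite(cfs) | cfs <= 0 | cfs > 1)) {
    stop("conversion factors must lie in (0, 1]", call. = FALSE)
  }
  centered_estimate(cfs)
}

#' Centered molar mass over sequenced isoforms/variants
#'
#' @param isoform_mms molar masses, g/mol, all > 0.
#' @return an `aq_centered`.
#' @export
#' @examples
#' centered_molar_mass(c(22500, 23500)) # center 23000, u = 500/sqrt(3)
centered_molar_mass <- function(isoform_mms) {
  if (any(!is.finite(isoform_mms) | isoform_mms <= 0)) {
    stop("molar masses must be positive", call. = FALSE)
  }
  centered_estimate(isoform_mms)
}

#' Conversion factor from one discovery replicate
#'
#' The conversion factor is the relative abundance of the marker's parent
#' protein(s) in the ingredient's total protein: the summed intensity of
#' all marker-carrying accessions that pass the unique-peptide filter,
#' divided by the summed intensity of all identified proteins in the
#' replicate. Isoform/variant accessions sharing the marker are summed
#' before the ratio is formed; the "at least one unique peptide" filter
#' is a per-accession gate.
#'
#' @param replicate_rows rows of a protein-intensity table for one
#'   replicate: columns `accession`, `intensity`, `unique_peptide_count`.
#' @param marker_accessions accessions whose intensity counts toward the
#'   marker protein.
#' @param min_unique_peptides per-accession unique-peptide gate
#'   (default 1).
#' @return the conversion factor, a fraction in (0, 1].
#' @export
replicate_cf <- function(replicate_rows, marker_accessions,
                         min_unique_peptides = 1L) {
  assert_columns(replicate_rows,
                 c("accession", "intensity", "unique_peptide_count"),
                 "replicate_rows")
  if (anyDuplicated(replicate_rows$accession)) {
    stop("duplicate accessions within a replicate", call. = FALSE)
  }
  if (any(replicate_rows$intensity < 0)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  total <- sum(replicate_rows$intensity)
  if (total <= 0) stop("total intensity is zero", call. = FALSE)
  pass <- replicate_rows$accession %in% marker_accessions &
    replicate_rows$unique_peptide_count >= min_unique_peptides
  if (!any(pass)) {
    stop("no marker accession passes the filter (looked for: ",
         paste(marker_accessions, collapse = ", "), ")", call. = FALSE)
  }
  sum(replicate_rows$intensity[pass]) / total
}

#' Estimate a conversion factor over discovery replicates
#'
#' Applies [replicate_cf()] to each replicate of a protein-intensity
#' table and centers the per-replicate values ([centered_cf()]).
#' Replicates in which no marker accession passes the filter are excluded
#' with a warning rather than treated as CF = 0.
#'
#' @param intensities protein-intensity table with columns
#'   `replicate_id`, `accession`, `intensity`, `unique_peptide_count`
#'   (e.g. from [simulate_discovery()] or a MaxQuant proteinGroups export
#'   subset).
#' @param marker_accessions,min_unique_peptides see [replicate_cf()].
#' @return a list with `centered` (an `aq_centered`), `per_replicate`
#'   (named numeric) and `n_used`.
#' @export
estimate_cf <- function(intensities, marker_accessions,
                        min_unique_peptides = 1L) {
  assert_columns(intensities,
                 c("replicate_id", "accession", "intensity",
                   "unique_peptide_count"), "intensities")
  reps <- split(intensities, intensities$replicate_id)
  vals <- vapply(reps, function(r) {
    tryCatch(replicate_cf(r, marker_accessions, min_unique_peptides),
             error = function(e) NA_real_)
  }, 0)
  dropped <- names(vals)[is.na(vals)]
  if (length(dropped)) {
    warning("replicate(s) without a passing marker accession excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    vals <- vals[!is.na(vals)]
  }
  if (!length(vals)) {
    stop("no replicate yielded a conversion factor", call. = FALSE)
  }
  list(centered = centered_cf(vals), per_replicate = vals,
       n_used = length(vals))
}
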