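#' Collapse duplicate assay measurements with a CV filter
#'
#' For every entry the coefficient of variation of its replicate pair is
#' `100 * sd / mean` (two-replicate sample sd, divisor 1).  Entries with
#' CV at or below the threshold keep the replicate mean; noisier entries
#' become missing.  Entries whose replicate mean is nonpositive are set
#' missing as undetectable.  Values stay on the raw concentration scale.
#'
#' @param dups A `duplicate_panel` from [inject_duplicate_noise()] (or any
#'   list with matrices `rep1`, `rep2`).
#' @param cv_threshold Retention threshold in percent (default 20; a CV
#'   exactly at the threshold is retained).
#' @return Visits x markers matrix of collapsed concentrations with `NA`
#'   where the filter removed an entry.
#' @export
collapse_duplicates_cv_filter <- function(dups, cv_threshold = 20) {
  if (cv_threshold <= 0) stop("cv_threshold must be positive")
  r1 <- dups$rep1; r2 <- dups$rep2
  stopifnot(identical(dim(r1), dim(r2)))
  m <- (r1 + r2) / 2
  s <- abs(r1 - r2) / sqrt(2)            # sample sd of a pair
  cv <- 100 * s / m
  bad <- !is.finite(cv) | cv > cv_threshold | m <= 0
  m[bad] <- NA_real_
  m
}

#' Replicate-pair coefficient of variation
#'
#' @param r1,r2 Replicate values (vectors or matrices).
#' @return `100 * sd / mean` per pair.
#' @export
replicate_cv <- function(r1, r2) 100 * (abs(r1 - r2) / sqrt(2)) / ((r1 + r2) / 2)

#' Natural-log transform a concentration panel
#'
#' @param panel Matrix of raw concentrations; all observed values must be
#'   strictly positive.
#' @return Matrix of natural-log concentrations; missingness unchanged.
#' @export
log_transform <- function(panel) {
  bad <- which(!is.na(panel) & panel <= 0, arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)) > 0)
    stop(sprintf("nonpositive observed value at row %s, marker %s",
                 bad[1, 1], colnames(panel)[bad[1, 2]]))
  log(panel)
}

#' Drop markers whose missingness exceeds a threshold
#'
#' @param panel Visits x markers matrix with `NA` for missing.
#' @param threshold Missing-fraction cutoff in `(0, 1)`; markers strictly
#'   above it are removed (default 0.55).
#' @return List with the reduced `panel` (column order preserved) and the
#'   `dropped` marker labels.
#' @export
drop_high_missingness_markers <- function(panel, threshold = 0.55) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  miss <- marker_missingness(panel)
  drop <- miss > threshold
  if (all(drop)) stop("all markers exceed the missingness threshold")
  list(panel = panel[, !drop, drop = FALSE],
       dropped = colnames(panel)[drop])
}

#' Remove additive batch effects from a cytokine panel
#'
#' Per marker, the observed log-levels are regressed on an intercept, the
#' biological covariates (age and sex), and sum-to-zero batch indicator
#' contrasts; the fitted batch component is subtracted.  Covariate-driven
#' structure is left untouched and missing entries stay missing.  A batch
#' with no observed entries for a marker contributes no correction for
#' that marker (its coefficient is taken as zero, with a warning).
#'
#' @param panel Visits x markers log-scale matrix (`NA` = missing).
#' @param batches Batch label per visit.
#' @param age,sex Covariates per visit, kept in the design so their
#'   contribution is not absorbed by the batch terms.
#' @return Corrected matrix of the same shape.
#' @export
remove_batch_effects <- function(panel, batches, age, sex) {
  n <- nrow(panel)
  stopifnot(length(batches) == n, length(age) == n, length(sex) == n)
  bf <- factor(batches)
  L <- nlevels(bf)
  if (L < 2L) return(panel)
  # sum-to-zero indicator codes: column l is +1 in batch l, -1 in batch L
  B <- matrix(0, n, L - 1L)
  for (l in seq_len(L - 1L)) B[bf == levels(bf)[l], l] <- 1
  B[bf == levels(bf)[L], ] <- -1
  X <- cbind(1, age, sex, B)
  nb <- ncol(B)
  out <- panel
  for (j in seq_len(ncol(panel))) {
    obs <- which(!is.na(panel[, j]))
    if (length(obs) <= ncol(X)) next
    if (any(tabulate(bf[obs], nlevels(bf)) == 0))
      warning(sprintf(
        "marker %s: a batch has no observed entries; its offset is taken as zero",
        colnames(panel)[j]))
    fit <- stats::lm.fit(X[obs, , drop = FALSE], panel[obs, j])
    gam <- coef(fit)[seq.int(to = length(coef(fit)), length.out = nb)]
    gam[is.na(gam)] <- 0
    out[obs, j] <- panel[obs, j] - drop(B[obs, , drop = FALSE] %*% gam)
  }
  out
}

#' Age-bin balancing weights
#'
#' Bins the visit ages into fixed-width bins spanning the observed age
#' range and assigns each visit the weight `1 / (count in its bin)`, so
#' every age group contributes equally to downstream weighted fits.
#'
#' @param ages Visit ages in years (nonempty).
#' @param bin_width Bin width in years (> 0; default 5).
#' @return A list of class `balancing_weights` with per-visit weights `w`,
#'   `bin_edges`, and `bin_counts`.
#' @export
compute_balancing_weights <- function(ages, bin_width = 5) {
  if (!length(ages)) stop("ages must be nonempty")
  if (bin_width <= 0) stop("bin_width must be positive")
  lo <- min(ages)
  edges <- seq(lo, max(ages) + bin_width, by = bin_width)
  idx <- findInterval(ages, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(w = 1 / counts[idx], bin_edges = edges,
                 bin_counts = counts),
            class = "balancing_weights")
}
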