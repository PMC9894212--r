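#' Normalize brain volumes to total intracranial volume
#'
#' Divides GMV and the seven network volumes (mL) by each visit's TIV,
#' appending dimensionless `_frac` columns; raw columns are preserved.
#' Head-size variability is thereby removed before any statistics.  A
#' range check rejects input that already looks normalized (volumes not
#' exceeding 1), so the transform cannot be applied twice.
#'
#' @param volumes Data frame with `tiv`, `gmv` and the seven network
#'   columns, in mL.
#' @return The data frame with added `gmv_frac` and `<network>_frac`
#'   columns, each in (0, 1).
#' @export
normalize_to_tiv <- function(volumes) {
  vol_cols <- c("gmv", network_names)
  stopifnot(all(c("tiv", vol_cols) %in% names(volumes)))
  if (any(bad <- volumes$tiv <= 0))
    stop("nonpositive TIV at visit ", which(bad)[1])
  if (all(as.matrix(volumes[vol_cols]) <= 1))
    stop("volumes appear already TIV-normalized (all values <= 1)")
  for (v in vol_cols) {
    frac <- volumes[[v]] / volumes$tiv
    if (any(frac <= 0 | frac >= 1))
      stop("normalized ", v, " outside (0, 1); check units")
    volumes[[paste0(v, "_frac")]] <- frac
  }
  volumes
}

#' Pairwise correlation matrix with significance flags
#'
#' Pearson correlations on pairwise-complete observations together with
#' two-sided t-test p-values, for the descriptive structure among age,
#' clock, sex and the seven normalized network volumes.
#'
#' @param x Data frame or matrix of numeric variables (>= 3 complete
#'   rows per pair).
#' @return List of class `cor_matrix` with symmetric matrices `r` (unit
#'   diagonal), `p`, and `n` (pair counts).  Constant columns yield `NA`
#'   entries with a warning.
#' @export
correlation_matrix <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  cst <- apply(x, 2, function(v) sd(v, na.rm = TRUE)) == 0
  if (any(cst))
    warning("constant column(s): ", paste(colnames(x)[cst], collapse = ", "),
            "; correlations reported as NA")
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  nmat <- crossprod(!is.na(x))
  tstat <- r * sqrt((nmat - 2) / pmax(1 - r^2, .Machine$double.eps))
  pmat <- 2 * pt(abs(tstat), pmax(nmat - 2, 1), lower.tail = FALSE)
  diag(r) <- 1; diag(pmat) <- 0
  structure(list(r = r, p = pmat, n = nmat), class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, digits = 2, ...) {
  print(round(x$r, digits))
  invisible(x)
}
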