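#' District-level descriptive statistics
#'
#' Min, max, mean and coefficient of variation (CV, percent) of each metal
#' within each district. CV is `100 * sd / mean` with the n-1 standard
#' deviation, so every district needs at least two samples; a zero mean
#' yields an `NA` CV (undefined), which can only arise when a metal is
#' entirely below detection.
#'
#' @param samples Samples table (see [validate_samples()]).
#' @return A tibble `district`, `metal`, `n`, `min`, `max`, `mean`, `cv`.
#' @export
district_summary <- function(samples) {
  samples <- validate_samples(samples)
  counts <- table(samples$district)
  if (any(counts < 2)) {
    stop(sprintf("district(s) with fewer than 2 samples: %s (CV undefined)",
                 paste(names(counts)[counts < 2], collapse = ", ")), call. = FALSE)
  }
  samples |>
    tidyr::pivot_longer(dplyr::all_of(METAL_ORDER),
                        names_to = "metal", values_to = "conc") |>
    dplyr::group_by(.data$district, .data$metal) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$conc), max = max(.data$conc), mean = mean(.data$conc),
      cv = ifelse(mean(.data$conc) == 0, NA_real_,
                  100 * stats::sd(.data$conc) / mean(.data$conc)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$district, match(.data$metal, METAL_ORDER))
}

#' Standardize concentrations to z-scores
#'
#' Column-wise centering and scaling (n-1 standard deviation) of the seven
#' metal concentrations, the preprocessing step for correlation-matrix PCA.
#'
#' @param x Samples table or a numeric matrix with the metal columns.
#' @return A numeric matrix with column means 0 and standard deviations 1.
#' @export
standardize_metals <- function(x) {
  m <- if (is.data.frame(x)) conc_matrix(validate_samples(x)) else as.matrix(x)
  sds <- apply(m, 2, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    stop(sprintf("zero-variance column(s): %s",
                 paste(colnames(m)[zero], collapse = ", ")), call. = FALSE)
  }
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

#' Pearson correlation matrix with significance stars
#'
#' Pairwise product-moment correlations of the seven metals pooled over all
#' samples, with two-sided p-values from the t distribution on n - 2 degrees
#' of freedom and the conventional annotation (`*` p < 0.05, `**` p < 0.01).
#' Stars are kept as a separate annotation matrix, never concatenated into
#' the numeric values.
#'
#' @param x Samples table or a numeric matrix with the metal columns
#'   (at least 3 rows).
#' @return An object of class `metal_correlation` with elements `r`, `p`,
#'   `stars` (7 x 7 matrices) and `n`.
#' @export
metal_correlation <- function(x) {
  m <- if (is.data.frame(x)) conc_matrix(validate_samples(x)) else as.matrix(x)
  n <- nrow(m)
  if (n < 3) stop("need at least 3 samples for correlation", call. = FALSE)
  r <- stats::cor(m)
  rr <- pmin(pmax(r, -1), 1)
  tstat <- rr * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  structure(list(r = r, p = p, stars = stars, n = n),
            class = "metal_correlation")
}

#' @export
print.metal_correlation <- function(x, digits = 3, ...) {
  cat(sprintf("<metal_correlation> n = %d (* p < 0.05, ** p < 0.01)\n", x$n))
  shown <- matrix(paste0(format(round(x$r, digits)),
                         ifelse(x$stars == "", "", paste0(" ", x$stars))),
                  nrow(x$r), dimnames = dimnames(x$r))
  print(shown, quote = FALSE)
  invisible(x)
}

#' Tidy a correlation object
#'
#' @param corr A [metal_correlation()] result.
#' @return A long tibble `metal_a`, `metal_b`, `r`, `p`, `stars` over the
#'   upper triangle.
#' @export
correlation_table <- function(corr) {
  stopifnot(inherits(corr, "metal_correlation"))
  idx <- which(upper.tri(corr$r), arr.ind = TRUE)
  tibble::tibble(
    metal_a = rownames(corr$r)[idx[, 1]],
    metal_b = colnames(corr$r)[idx[, 2]],
    r = corr$r[idx], p = corr$p[idx], stars = corr$stars[idx]
  )
}

#' Principal component analysis of standardized concentrations
#'
#' Eigendecomposition of the correlation matrix of the (internally
#' standardized) metal concentrations. Components are sorted by descending
#' eigenvalue; the contribution rate of a component is its eigenvalue over
#' the number of metals, in percent, so rates sum to 100. Components are
#' retained by the Kaiser criterion (eigenvalue >= 1). Loadings are
#' `eigenvector * sqrt(eigenvalue)` (no rotation), with each component's
#' sign fixed so its largest-magnitude loading is positive, making runs
#' reproducible.
#'
#' @param x Samples table or numeric matrix; needs more rows than metals.
#' @return An object of class `metal_pca`: `eigenvalues`, `contribution`,
#'   `cumulative` (percent), `retained` (logical), `n_retained`, `loadings`
#'   (metal x retained component), `loadings_full`, `n`.
#' @export
metal_pca <- function(x) {
  z <- standardize_metals(x)  # idempotent on an already-standardized matrix
  if (nrow(z) <= ncol(z)) {
    stop(sprintf("need more samples (%d) than variables (%d) for PCA",
                 nrow(z), ncol(z)), call. = FALSE)
  }
  R <- stats::cor(z)
  e <- eigen(R, symmetric = TRUE)
  ev <- e$values
  vec <- e$vectors
  load_full <- vec %*% diag(sqrt(pmax(ev, 0)), length(ev))
  dimnames(load_full) <- list(colnames(z), paste0("PC", seq_along(ev)))
  for (j in seq_len(ncol(load_full))) {
    k <- which.max(abs(load_full[, j]))
    if (load_full[k, j] < 0) load_full[, j] <- -load_full[, j]
  }
  retained <- ev >= 1
  structure(
    list(
      eigenvalues = ev,
      contribution = 100 * ev / length(ev),
      cumulative = cumsum(100 * ev / length(ev)),
      retained = retained,
      n_retained = sum(retained),
      loadings = load_full[, retained, drop = FALSE],
      loadings_full = load_full,
      n = nrow(z)
    ),
    class = "metal_pca"
  )
}

#' @export
print.metal_pca <- function(x, ...) {
  cat(sprintf("<metal_pca> n = %d, %d component(s) retained (eigenvalue >= 1)\n",
              x$n, x$n_retained))
  tab <- rbind(eigenvalue = x$eigenvalues, `contribution %` = x$contribution,
               `cumulative %` = x$cumulative)
  colnames(tab) <- paste0("PC", seq_along(x$eigenvalues))
  print(round(tab, 3))
  cat("loadings (retained):\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' PCA per district
#'
#' Runs [metal_pca()] on each district's own standardized concentrations,
#' matching the convention of reporting district-wise components.
#'
#' @param samples Samples table.
#' @return A named list of `metal_pca` objects, one per district.
#' @export
pca_by_district <- function(samples) {
  samples <- validate_samples(samples)
  lapply(split(samples, samples$district), metal_pca)
}
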