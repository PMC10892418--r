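#' Round half away from zero
#'
#' Presentation rounding used by all report tables (base `round()` rounds
#' half to even, which does not match how the published tables are printed).
#' Internal pipeline values are never rounded; rounding is applied only when
#' a table is written.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2, the convention of the report
#'   tables).
#' @return `x` rounded half-up at `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(0.125, -0.125), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Extract the n x 7 concentration matrix (panel order) from a samples table.
conc_matrix <- function(samples) {
  m <- as.matrix(samples[, METAL_ORDER, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- samples$sample_id
  m
}

#' Validate a soil-sample table
#'
#' Checks the in-memory contract every pipeline stage assumes: columns
#' `sample_id`, `district`, `x`, `y` plus the seven metal columns; unique
#' sample ids; finite coordinates; numeric, non-negative, non-missing
#' concentrations (missing values must be made explicit upstream and
#' resolved before indices are computed).
#'
#' @param samples A data frame of samples.
#' @return `samples` as a tibble, invisibly checked.
#' @export
validate_samples <- function(samples) {
  samples <- tibble::as_tibble(samples)
  need <- c("sample_id", "district", "x", "y", METAL_ORDER)
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    stop(sprintf("samples are missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    stop(sprintf("duplicate sample_id: %s", paste(dup, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(samples$x)) || any(!is.finite(samples$y))) {
    stop("non-finite coordinates in samples", call. = FALSE)
  }
  for (m in METAL_ORDER) {
    v <- samples[[m]]
    if (!is.numeric(v)) stop(sprintf("column '%s' is not numeric", m), call. = FALSE)
    bad <- !is.finite(v) | v < 0
    if (any(bad)) {
      stop(sprintf("invalid %s concentration for sample(s) %s (must be finite and >= 0)",
                   m, paste(samples$sample_id[bad], collapse = ", ")), call. = FALSE)
    }
  }
  samples
}
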