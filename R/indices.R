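#' Geo-accumulation index
#'
#' Muller's index `Igeo = log2(C / (margin * B))` comparing a measured
#' concentration `C` to `margin` times the geochemical background `B`; the
#' default margin 1.5 absorbs natural fluctuation of background levels.
#' Being a log ratio it requires strictly positive concentrations:
#' below-detection values must be substituted (conventionally by half the
#' detection limit) before calling; [index_table()] does this automatically.
#'
#' @param conc Measured concentration(s), mg/kg, strictly positive.
#' @param background Background value B, mg/kg, positive.
#' @param margin Background fluctuation multiplier, positive; default 1.5.
#' @return Dimensionless index value(s); grade with the `"igeo"` scheme.
#' @export
#' @examples
#' igeo(0.69, 0.08)                      # Cd well above background
#' classify_values(igeo(0.69, 0.08), "igeo")
igeo <- function(conc, background, margin = 1.5) {
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("igeo needs strictly positive concentrations; substitute below-detection values first",
         call. = FALSE)
  }
  if (any(background <= 0) || any(margin <= 0)) {
    stop("'background' and 'margin' must be positive", call. = FALSE)
  }
  log2(conc / (margin * background))
}

#' Single pollution index
#'
#' The ratio `P = C / S` of a measured concentration to its risk screening
#' standard; the building block of the Nemerow composite index.
#'
#' @param conc Concentration(s), mg/kg, non-negative.
#' @param standard Screening standard S, mg/kg, positive.
#' @return Dimensionless ratio(s).
#' @export
single_pollution_index <- function(conc, standard) {
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("'conc' must be finite and >= 0", call. = FALSE)
  }
  if (any(standard <= 0)) stop("'standard' must be positive", call. = FALSE)
  conc / standard
}

#' Nemerow composite pollution index
#'
#' Combines the per-metal single pollution indices of one sample into a
#' composite that emphasises the worst metal. The default `"rms"` dialect is
#' the standard Nemerow form `sqrt((mean^2 + max^2) / 2)`; the
#' `"arithmetic"` dialect `(mean + max) / 2` is also provided. Both reduce to
#' the common value when all ratios are equal.
#'
#' @param ratios Non-empty vector of single pollution indices (>= 0).
#' @param dialect `"rms"` (default) or `"arithmetic"`.
#' @return Dimensionless composite; grade with the `"pn"` scheme.
#' @export
#' @examples
#' nemerow(c(1, 0, 0, 0, 0, 0, 0))                # 0.71429
#' nemerow(c(1, 0, 0, 0, 0, 0, 0), "arithmetic")  # 0.57143
nemerow <- function(ratios, dialect = c("rms", "arithmetic")) {
  dialect <- match.arg(dialect)
  if (length(ratios) == 0) stop("'ratios' must be non-empty", call. = FALSE)
  if (any(!is.finite(ratios)) || any(ratios < 0)) {
    stop("'ratios' must be finite and >= 0", call. = FALSE)
  }
  m <- mean(ratios)
  mx <- max(ratios)
  if (dialect == "rms") sqrt((m^2 + mx^2) / 2) else (m + mx) / 2
}

#' Single-factor potential ecological risk
#'
#' Hakanson's `Er = T * C / S`: the single pollution index weighted by the
#' metal's toxic response factor `T`.
#'
#' @param conc Concentration(s), mg/kg, non-negative.
#' @param standard Screening standard S, mg/kg, positive.
#' @param toxicity Toxic response factor T, dimensionless, positive.
#' @return Dimensionless risk value(s); grade with the `"er"` scheme.
#' @export
#' @examples
#' er(0.11, 0.6, 30)   # Cd at 0.11 mg/kg -> 5.5
er <- function(conc, standard, toxicity) {
  if (any(toxicity <= 0)) stop("'toxicity' must be positive", call. = FALSE)
  toxicity * single_pollution_index(conc, standard)
}

#' Composite potential ecological risk index
#'
#' `PERI = sum over metals of Er`; linear in the concentration vector. The
#' seven per-metal Er components are attached as the `"components"`
#' attribute.
#'
#' @param conc Named concentration vector over the full panel (`metals()`),
#'   mg/kg, or a one-row samples table.
#' @param refs A [reference_set()].
#' @return The composite risk value with attribute `components`; grade with
#'   the `"peri"` scheme.
#' @export
#' @examples
#' xd_mean <- c(As = 12.33, Hg = 0.07, Cd = 0.27, Cr = 59.15,
#'              Pb = 21.52, Cu = 30.03, Zn = 97.18)
#' peri(xd_mean)
peri <- function(conc, refs = reference_set()) {
  stopifnot(inherits(refs, "reference_set"))
  if (is.data.frame(conc)) {
    if (nrow(conc) != 1) stop("pass a single sample or a named vector", call. = FALSE)
    conc <- unlist(conc[, METAL_ORDER])
  }
  conc <- check_metal_table(conc, "conc", positive = FALSE)
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  comps <- er(conc, refs$standard, refs$toxicity)
  structure(sum(comps), components = comps)
}

#' Compute all indices for a sample table
#'
#' Evaluates, for every sample: the seven geo-accumulation indices, the
#' seven single pollution indices, the seven single-factor ecological risks,
#' the Nemerow composite, and the composite PERI — 23 rows per sample, each
#' graded by its scheme (the single pollution index uses the Nemerow class
#' cut-offs). Values are full precision; rounding happens only in report
#' writers.
#'
#' Concentrations of zero are legal for the linear indices but not for the
#' log-ratio geo-accumulation index: for that index only, non-positive
#' values are substituted by half the reference set's detection limit. A
#' sample that still cannot be evaluated aborts the computation, or is
#' dropped with a warning when `lenient = TRUE`.
#'
#' @param samples Samples table (see [validate_samples()]).
#' @param refs A [reference_set()].
#' @param nemerow_dialect Passed to [nemerow()].
#' @param lenient Drop failing samples with a warning instead of erroring.
#' @return A tibble with columns `sample_id`, `district`, `metal` (`NA` for
#'   the composites), `index_name` (`Igeo`, `P_single`, `Er`, `P_N`,
#'   `PERI`), `value`, `grade`.
#' @export
index_table <- function(samples, refs = reference_set(),
                        nemerow_dialect = c("rms", "arithmetic"),
                        lenient = FALSE) {
  nemerow_dialect <- match.arg(nemerow_dialect)
  stopifnot(inherits(refs, "reference_set"))
  samples <- validate_samples(samples)
  if (nrow(samples) == 0) {
    return(tibble::tibble(sample_id = character(), district = character(),
                          metal = character(), index_name = character(),
                          value = double(), grade = character()))
  }

  m <- conc_matrix(samples)

  # Half-detection-limit substitution, Igeo only (log domain).
  m_igeo <- m
  for (j in METAL_ORDER) {
    nz <- m_igeo[, j] <= 0
    if (any(nz)) m_igeo[nz, j] <- refs$detection[[j]] / 2
  }
  bad <- rowSums(m_igeo <= 0) > 0
  if (any(bad)) {
    msg <- sprintf("non-positive concentration after substitution for sample(s) %s",
                   paste(rownames(m)[bad], collapse = ", "))
    if (!lenient) stop(msg, call. = FALSE)
    warning(paste0(msg, "; dropped"), call. = FALSE)
    samples <- samples[!bad, , drop = FALSE]
    m <- m[!bad, , drop = FALSE]
    m_igeo <- m_igeo[!bad, , drop = FALSE]
    if (nrow(samples) == 0) return(index_table(samples, refs))
  }

  sch <- grade_schemes()
  n <- nrow(samples)
  ig <- sweep(m_igeo, 2, refs$igeo_margin * refs$background, `/`)
  ig <- log2(ig)
  ps <- sweep(m, 2, refs$standard, `/`)
  erm <- sweep(ps, 2, refs$toxicity, `*`)
  pn <- apply(ps, 1, nemerow, dialect = nemerow_dialect)
  peri_v <- rowSums(erm)

  per_metal <- function(vals, index_name, scheme) {
    tibble::tibble(
      sample_id = rep(samples$sample_id, each = length(METAL_ORDER)),
      district = rep(samples$district, each = length(METAL_ORDER)),
      metal = rep(METAL_ORDER, times = n),
      index_name = index_name,
      value = as.vector(t(vals)),
      grade = as.character(classify_values(as.vector(t(vals)), scheme))
    )
  }
  composite <- function(vals, index_name, scheme) {
    tibble::tibble(
      sample_id = samples$sample_id, district = samples$district,
      metal = NA_character_, index_name = index_name, value = unname(vals),
      grade = as.character(classify_values(vals, scheme))
    )
  }

  out <- dplyr::bind_rows(
    per_metal(ig, "Igeo", sch$igeo),
    per_metal(ps, "P_single", sch$pn),
    per_metal(erm, "Er", sch$er),
    composite(pn, "P_N", sch$pn),
    composite(peri_v, "PERI", sch$peri)
  )
  dplyr::arrange(out,
                 match(.data$sample_id, samples$sample_id),
                 match(.data$index_name, c("Igeo", "P_single", "Er", "P_N", "PERI")),
                 match(.data$metal, METAL_ORDER))
}

scheme_for_index <- function(index_name) {
  switch(index_name,
         Igeo = "igeo", P_single = "pn", P_N = "pn", Er = "er", PERI = "peri",
         stop(sprintf("unknown index '%s'", index_name), call. = FALSE))
}

#' Grade-frequency tables by district
#'
#' For each district x metal x index present in an [index_table()] result,
#' counts the samples in every grade of the matching scheme and expresses
#' them as percentages of the district sample count (rounded half-up to two
#' decimals, so percentages sum to 100 within rounding).
#'
#' @param results An [index_table()] tibble.
#' @return A tibble with columns `district`, `metal`, `index_name`, `grade`
#'   (ordered as in the scheme), `count`, `percentage`.
#' @export
grade_frequency <- function(results) {
  if (nrow(results) == 0) stop("'results' is empty", call. = FALSE)
  pieces <- lapply(split(results, results$index_name), function(part) {
    scheme <- grade_schemes()[[scheme_for_index(part$index_name[1])]]
    part |>
      dplyr::count(.data$district, .data$metal, .data$index_name,
                   grade = factor(.data$grade, levels = scheme$labels),
                   .drop = FALSE, name = "count") |>
      dplyr::group_by(.data$district, .data$metal, .data$index_name) |>
      dplyr::mutate(percentage = round_half_up(100 * .data$count / sum(.data$count), 2)) |>
      dplyr::ungroup()
  })
  out <- dplyr::bind_rows(pieces)
  out$grade <- as.character(out$grade)
  dplyr::arrange(out, .data$district,
                 match(.data$index_name, c("Igeo", "P_single", "Er", "P_N", "PERI")),
                 match(.data$metal, METAL_ORDER))
}

#' Per-district ranges of single-factor ecological risk
#'
#' Min and max of Er for every district x metal. Because Er is strictly
#' increasing in concentration, these endpoints equal Er evaluated at the
#' district's extreme concentrations of that metal.
#'
#' @param results An [index_table()] tibble containing `Er` rows.
#' @return A tibble `district`, `metal`, `er_min`, `er_max` (full precision).
#' @export
er_range_table <- function(results) {
  ers <- dplyr::filter(results, .data$index_name == "Er")
  if (nrow(ers) == 0) stop("'results' contains no Er rows", call. = FALSE)
  ers |>
    dplyr::group_by(.data$district, .data$metal) |>
    dplyr::summarise(er_min = min(.data$value), er_max = max(.data$value),
                     .groups = "drop") |>
    dplyr::arrange(.data$district, match(.data$metal, METAL_ORDER))
}
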