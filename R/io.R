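#' Read a soil-sample CSV
#'
#' Expects a header with `sample_id`, `district`, `x`, `y` and the seven
#' metal columns (any column order, decimal-point notation). Explicit
#' below-detection tokens (`<DL`, case-insensitive) are read as 0 and
#' flagged; concentrations of 0 or less are likewise flagged
#' (`below_detection:<metal>`), with negative values clamped to 0. Flags
#' land in a `flags` list-column so downstream stages can apply their
#' substitution policies.
#'
#' @param path CSV path.
#' @return A validated samples tibble with a `flags` list-column.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop(sprintf("sample file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  need <- c("sample_id", "district", "x", "y", METAL_ORDER)
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop(sprintf("sample file is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(raw$sample_id)) {
    dup <- unique(raw$sample_id[duplicated(raw$sample_id)])
    stop(sprintf("duplicate sample_id: %s", paste(dup, collapse = ", ")), call. = FALSE)
  }

  parse_col <- function(vals, col) {
    dl <- grepl("^<\\s*dl$", vals, ignore.case = TRUE)
    num <- suppressWarnings(as.numeric(ifelse(dl, "0", vals)))
    bad <- which(is.na(num) & !dl)
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in column %s, data row %d",
                   vals[bad[1]], col, bad[1]), call. = FALSE)
    }
    list(value = num, dl = dl)
  }

  out <- tibble::tibble(
    sample_id = raw$sample_id,
    district = raw$district,
    x = parse_col(raw$x, "x")$value,
    y = parse_col(raw$y, "y")$value
  )
  flags <- vector("list", nrow(raw))
  for (i in seq_along(flags)) flags[[i]] <- character()
  for (m in METAL_ORDER) {
    parsed <- parse_col(raw[[m]], m)
    v <- parsed$value
    below <- parsed$dl | v <= 0
    v[v < 0] <- 0
    out[[m]] <- v
    for (i in which(below)) {
      flags[[i]] <- c(flags[[i]], paste0("below_detection:", m))
    }
  }
  out$flags <- flags
  validate_samples(out)
}

#' Write a soil-sample CSV
#'
#' Full-precision writer (values round-trip through [read_samples()]
#' exactly). A `flags` list-column, if present, is serialized as a
#' semicolon-separated string.
#'
#' @param samples Samples tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  samples <- validate_samples(samples)
  if ("flags" %in% names(samples)) {
    samples$flags <- vapply(samples$flags, paste, character(1), collapse = ";")
  }
  readr::write_csv(samples[, c("sample_id", "district", "x", "y", METAL_ORDER,
                               intersect("flags", names(samples)))], path)
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' Exactly one of `input` (a sample CSV) or `simulate = TRUE` (the shipped
#' synthetic study design) must be chosen.
#'
#' @param input Path to a sample CSV, or `NULL`.
#' @param simulate Generate the shipped synthetic campaign instead of
#'   reading a file.
#' @param out_dir Output directory for the report bundle (created if
#'   needed).
#' @param seed Integer seed driving all randomness of the run.
#' @param reference Path to a reference config (YAML/TOML), or `NULL` for
#'   the shipped defaults.
#' @param nemerow_dialect `"rms"` or `"arithmetic"` (see [nemerow()]).
#' @param pca_scope `"district"` (default) or `"pooled"`.
#' @param idw_power,idw_neighbors,idw_cells IDW decay exponent, neighbour
#'   count (`Inf` = all), and grid cells along the longer axis.
#' @param write_grids Also write per-metal IDW concentration grids
#'   (ESRI ASCII).
#' @param idw_scope Interpolate `"pooled"` over all samples (default) or
#'   `"district"`-wise.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, simulate = is.null(input), out_dir,
                       seed = 1, reference = NULL,
                       nemerow_dialect = c("rms", "arithmetic"),
                       pca_scope = c("district", "pooled"),
                       idw_power = 2, idw_neighbors = Inf, idw_cells = 50,
                       write_grids = FALSE, idw_scope = c("pooled", "district")) {
  if (is.null(input) == !isTRUE(simulate)) {
    stop("choose exactly one of 'input' or 'simulate'", call. = FALSE)
  }
  structure(
    list(input = input, simulate = isTRUE(simulate), out_dir = out_dir,
         seed = as.integer(seed), reference = reference,
         nemerow_dialect = match.arg(nemerow_dialect),
         pca_scope = match.arg(pca_scope),
         idw_power = idw_power, idw_neighbors = idw_neighbors,
         idw_cells = idw_cells, write_grids = isTRUE(write_grids),
         idw_scope = match.arg(idw_scope)),
    class = "run_config"
  )
}

round_df <- function(df, digits = 2) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round_half_up, digits = digits)
  df
}

#' Run the full assessment pipeline
#'
#' Orchestrates every stage end to end and writes the report bundle to
#' `config$out_dir`: the district summary, the pooled correlation matrix
#' with its separate star annotation, PCA eigenvalue bookkeeping and
#' loadings, geo-accumulation grade frequencies, the Nemerow district
#' summary, per-district Er ranges, the per-sample long-format index table,
#' optional IDW grids, and a structured log of the parameters and reference
#' values actually used. Presentation tables are rounded half-up to two
#' decimals; raw-precision companions (`*_raw.csv`) are always written.
#' Identical configurations produce byte-identical bundles. Any stage error
#' aborts the run and removes the partial outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the samples, index table and written file
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit_csv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    readr::write_csv(df, p)
    written <<- c(written, p)
    p
  }
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  result <- tryCatch({
    stage <- "configuration"
    refs <- load_reference_set(config$reference)
    note("nemerow_dialect: %s", config$nemerow_dialect)
    note("pca_scope: %s", config$pca_scope)
    note("seed: %d", config$seed)
    note("idw: power=%g neighbors=%s cells=%d scope=%s",
         config$idw_power, format(config$idw_neighbors), config$idw_cells,
         config$idw_scope)
    note("reference_source: %s",
         if (is.null(config$reference)) "shipped defaults" else config$reference)
    for (tb in c("background", "standard", "toxicity", "detection")) {
      note("reference %s: %s", tb,
           paste(sprintf("%s=%g", METAL_ORDER, refs[[tb]]), collapse = " "))
    }
    note("igeo_margin: %g", refs$igeo_margin)

    stage <- "input"
    samples <- if (config$simulate) {
      s <- study_fixture(seed = config$seed)
      emit_csv(s, "samples.csv")
      s
    } else {
      read_samples(config$input)
    }
    note("samples: %d across %d district(s)", nrow(samples),
         length(unique(samples$district)))

    stage <- "district summary"
    summ <- district_summary(samples)
    emit_csv(round_df(summ), "district_summary.csv")
    emit_csv(summ, "district_summary_raw.csv")

    stage <- "correlation"
    corr <- metal_correlation(samples)
    wide <- tibble::as_tibble(round_half_up(corr$r, 3), rownames = "metal")
    emit_csv(wide, "correlation.csv")
    emit_csv(correlation_table(corr), "correlation_long.csv")

    stage <- "pca"
    groups <- if (config$pca_scope == "district") split(samples, samples$district)
              else list(pooled = samples)
    # PCA needs more samples than variables; undersized groups are logged
    # and omitted rather than aborting the whole run.
    small <- names(groups)[vapply(groups, nrow, integer(1)) <= length(METAL_ORDER)]
    for (nm in small) note("pca skipped for %s (needs more samples than metals)", nm)
    pcas <- lapply(groups[setdiff(names(groups), small)], metal_pca)
    pca_template <- tibble::tibble(scope = character(), component = character(),
                                   eigenvalue = double(), contribution_pct = double(),
                                   cumulative_pct = double(), retained = logical())
    pca_summary <- dplyr::bind_rows(pca_template, lapply(names(pcas), function(nm) {
      p <- pcas[[nm]]
      tibble::tibble(scope = nm, component = paste0("PC", seq_along(p$eigenvalues)),
                     eigenvalue = p$eigenvalues, contribution_pct = p$contribution,
                     cumulative_pct = p$cumulative, retained = p$retained)
    }))
    emit_csv(round_df(pca_summary), "pca_summary.csv")
    emit_csv(pca_summary, "pca_summary_raw.csv")
    pca_load <- dplyr::bind_rows(
      tibble::tibble(scope = character(), metal = character(),
                     component = character(), loading = double()),
      lapply(names(pcas), function(nm) {
      L <- pcas[[nm]]$loadings
      tibble::tibble(scope = nm, metal = rep(rownames(L), ncol(L)),
                     component = rep(colnames(L), each = nrow(L)),
                     loading = as.vector(L))
    }))
    emit_csv(round_df(pca_load, 3), "pca_loadings.csv")

    stage <- "indices"
    idx <- index_table(samples, refs, nemerow_dialect = config$nemerow_dialect)
    emit_csv(idx, "indices_long_raw.csv")
    emit_csv(round_df(idx), "indices_long.csv")

    stage <- "geo-accumulation grade frequencies"
    igeo_freq <- grade_frequency(dplyr::filter(idx, .data$index_name == "Igeo"))
    avg_igeo <- idx |>
      dplyr::filter(.data$index_name == "Igeo") |>
      dplyr::group_by(.data$district, .data$metal) |>
      dplyr::summarise(average_igeo = mean(.data$value), .groups = "drop")
    igeo_wide <- igeo_freq |>
      dplyr::select("district", "metal", "grade", "percentage") |>
      tidyr::pivot_wider(names_from = "grade", values_from = "percentage") |>
      dplyr::left_join(avg_igeo, by = c("district", "metal")) |>
      dplyr::relocate("average_igeo", .after = "metal") |>
      dplyr::arrange(.data$district, match(.data$metal, METAL_ORDER))
    emit_csv(round_df(igeo_wide), "igeo_grade_frequency.csv")
    emit_csv(igeo_freq, "igeo_grade_frequency_counts.csv")

    stage <- "nemerow summary"
    pn <- dplyr::filter(idx, .data$index_name == "P_N")
    pn_summ <- pn |>
      dplyr::group_by(.data$district) |>
      dplyr::summarise(pn_min = min(.data$value), pn_max = max(.data$value),
                       pn_mean = mean(.data$value), .groups = "drop") |>
      dplyr::mutate(pollution_level =
                      as.character(classify_values(.data$pn_mean, "pn")))
    emit_csv(round_df(pn_summ), "nemerow_summary.csv")
    emit_csv(pn_summ, "nemerow_summary_raw.csv")

    stage <- "ecological risk ranges"
    er_rng <- er_range_table(idx)
    peri_summ <- idx |>
      dplyr::filter(.data$index_name == "PERI") |>
      dplyr::group_by(.data$district) |>
      dplyr::summarise(peri_min = min(.data$value), peri_max = max(.data$value),
                       peri_mean = mean(.data$value), .groups = "drop") |>
      dplyr::mutate(risk_level =
                      as.character(classify_values(.data$peri_mean, "peri")))
    emit_csv(round_df(er_rng), "er_ranges.csv")
    emit_csv(er_rng, "er_ranges_raw.csv")
    emit_csv(round_df(peri_summ), "peri_summary.csv")
    emit_csv(peri_summ, "peri_summary_raw.csv")

    stage <- "idw grids"
    if (config$write_grids) {
      groups <- if (config$idw_scope == "district") {
        split(samples, samples$district)
      } else list(pooled = samples)
      for (nm in names(groups)) {
        g <- groups[[nm]]
        span_x <- diff(range(g$x)); span_y <- diff(range(g$y))
        cell <- max(span_x, span_y) / config$idw_cells
        if (cell <= 0) cell <- 1
        grid <- make_grid(min(g$x), min(g$y), cell,
                          max(1, ceiling(span_x / cell)),
                          max(1, ceiling(span_y / cell)))
        for (m in METAL_ORDER) {
          pts <- data.frame(x = g$x, y = g$y, value = g[[m]])
          surf <- idw(pts, grid, power = config$idw_power,
                      max_neighbors = config$idw_neighbors,
                      average_duplicates = TRUE)
          p <- file.path(config$out_dir, sprintf("idw_%s_%s.asc", nm, m))
          write_esri_ascii(surf, p)
          written <<- c(written, p)
        }
      }
      note("idw grids written for scope(s): %s", paste(names(groups), collapse = ", "))
    }

    stage <- "log"
    log_path <- file.path(config$out_dir, "run_log.txt")
    writeLines(log_lines, log_path)
    written <- c(written, log_path)

    list(samples = samples, indices = idx, files = written)
  }, error = function(e) {
    suppressWarnings(file.remove(written[file.exists(written)]))
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(result)
}
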