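# Fixed panel order: used for every concentration vector and report column.
METAL_ORDER <- c("As", "Hg", "Cd", "Cr", "Pb", "Cu", "Zn")

#' The heavy-metal panel
#'
#' The seven metals assessed by the package, in the fixed order used for all
#' vectors, matrices and report columns: As, Hg, Cd, Cr, Pb, Cu, Zn.
#'
#' @return A character vector of length seven.
#' @export
#' @examples
#' metals()
metals <- function() METAL_ORDER

# Validate a per-metal numeric table: named over the full panel, finite,
# and (optionally) strictly positive. Returns the vector in panel order.
check_metal_table <- function(x, what, positive = TRUE) {
  if (is.null(names(x)) || !all(names(x) %in% METAL_ORDER)) {
    bad <- setdiff(names(x), METAL_ORDER)
    if (length(bad) > 0) {
      stop(sprintf("unknown metal %s in '%s' (panel is %s)",
                   paste(bad, collapse = ", "), what,
                   paste(METAL_ORDER, collapse = ", ")), call. = FALSE)
    }
    stop(sprintf("'%s' must be a named per-metal table", what), call. = FALSE)
  }
  miss <- setdiff(METAL_ORDER, names(x))
  if (length(miss) > 0) {
    stop(sprintf("missing metal %s in '%s'", paste(miss, collapse = ", "), what),
         call. = FALSE)
  }
  x <- as.numeric(x[METAL_ORDER])
  names(x) <- METAL_ORDER
  if (any(!is.finite(x))) {
    stop(sprintf("non-finite value in '%s' (%s)", what,
                 paste(METAL_ORDER[!is.finite(x)], collapse = ", ")), call. = FALSE)
  }
  if (positive && any(x <= 0)) {
    stop(sprintf("non-positive value in '%s' (%s)", what,
                 paste(METAL_ORDER[x <= 0], collapse = ", ")), call. = FALSE)
  }
  x
}

# Shipped reference values (mg/kg except toxicity, dimensionless):
#   background — Taiyuan geochemical background concentrations;
#   standard   — GB15618-2018 agricultural-soil risk screening values;
#   toxicity   — Hakanson toxic response factors;
#   detection  — instrument detection limits, advisory only.
default_background <- function() {
  c(As = 7.60, Hg = 0.03, Cd = 0.08, Cr = 57.30, Pb = 13.80, Cu = 18.40, Zn = 56.30)
}
default_standard <- function() {
  c(As = 25, Hg = 3.4, Cd = 0.6, Cr = 250, Pb = 170, Cu = 100, Zn = 300)
}
default_toxicity <- function() {
  c(As = 10, Hg = 40, Cd = 30, Cr = 2, Pb = 5, Cu = 5, Zn = 1)
}
default_detection <- function() {
  c(As = 0.01, Hg = 0.002, Cd = 0.6, Cr = 1.0, Pb = 2.1, Cu = 1.2, Zn = 3.2)
}

#' Reference values for index computation
#'
#' Bundles the per-metal reference tables every index needs: geochemical
#' background values `background` (B, mg/kg, denominator of the
#' geo-accumulation index), risk screening standards `standard` (S, mg/kg,
#' denominator of the pollution and ecological-risk indices), Hakanson toxic
#' response factors `toxicity` (T, dimensionless), and advisory instrument
#' detection limits `detection` (mg/kg, used to flag and substitute
#' below-detection values). The shipped defaults are the Taiyuan city
#' backgrounds, the GB15618-2018 agricultural screening values, and the
#' classical Hakanson factors (Cd 30, Hg 40, As 10, Pb 5, Cr 2, Cu 5, Zn 1).
#'
#' Entries passed as partial named vectors merge over the defaults, so a
#' single metal can be overridden without restating the full table.
#'
#' @param background,standard,toxicity,detection Named numeric vectors
#'   (names among `metals()`); omitted entries fall back to the defaults.
#' @param igeo_margin Multiplier on the background in the geo-accumulation
#'   index accounting for natural fluctuation of background levels;
#'   default 1.5.
#' @return An object of class `reference_set`.
#' @export
#' @examples
#' reference_set()
#' reference_set(standard = c(Cd = 0.3))   # override one screening value
reference_set <- function(background = NULL, standard = NULL, toxicity = NULL,
                          detection = NULL, igeo_margin = 1.5) {
  merge_over <- function(user, def, what, positive = TRUE) {
    if (is.null(user)) return(def)
    if (is.null(names(user)) || any(!nzchar(names(user)))) {
      stop(sprintf("'%s' entries must be named by metal", what), call. = FALSE)
    }
    bad <- setdiff(names(user), METAL_ORDER)
    if (length(bad) > 0) {
      stop(sprintf("unknown metal %s in '%s'", paste(bad, collapse = ", "), what),
           call. = FALSE)
    }
    def[names(user)] <- as.numeric(user)
    check_metal_table(def, what, positive = positive)
  }
  if (!is.numeric(igeo_margin) || length(igeo_margin) != 1 ||
      !is.finite(igeo_margin) || igeo_margin <= 0) {
    stop("'igeo_margin' must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      background = merge_over(background, default_background(), "background"),
      standard = merge_over(standard, default_standard(), "standard"),
      toxicity = merge_over(toxicity, default_toxicity(), "toxicity"),
      detection = merge_over(detection, default_detection(), "detection"),
      igeo_margin = igeo_margin
    ),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set>  (mg/kg; toxicity dimensionless)\n")
  tab <- rbind(background = x$background, standard = x$standard,
               toxicity = x$toxicity, detection = x$detection)
  print(tab)
  cat("igeo_margin:", x$igeo_margin, "\n")
  invisible(x)
}

# Minimal flat-TOML reader: "[table]" headers and "key = value" pairs,
# numbers or quoted strings, '#' comments. Enough for reference configs.
parse_flat_toml <- function(lines) {
  out <- list()
  section <- NULL
  for (raw in lines) {
    line <- sub("#.*$", "", raw)
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.+\\]$", line)) {
      section <- trimws(sub("^\\[(.+)\\]$", "\\1", line))
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    if (!grepl("=", line, fixed = TRUE)) {
      stop(sprintf("cannot parse TOML line: '%s'", raw), call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", line))
    val <- trimws(sub("^[^=]*=", "", line))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    val <- if (is.na(num)) val else num
    if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
  }
  out
}

#' Load a reference set from a configuration file
#'
#' Reads a flat keyed document with optional tables `background`, `standard`,
#' `toxicity`, `detection` and scalar `igeo_margin`. Both YAML and a flat
#' TOML dialect are accepted; the format is chosen by file extension
#' (`.toml` vs anything else). Absent tables and absent per-metal entries
#' fall back to the shipped defaults of [reference_set()].
#'
#' @param path Path to a YAML or TOML document, or `NULL` for the shipped
#'   defaults.
#' @return A `reference_set`.
#' @export
load_reference_set <- function(path = NULL) {
  if (is.null(path)) return(reference_set())
  if (!file.exists(path)) stop(sprintf("reference config not found: %s", path), call. = FALSE)
  doc <- if (grepl("\\.toml$", path, ignore.case = TRUE)) {
    parse_flat_toml(readLines(path, warn = FALSE))
  } else {
    yaml::read_yaml(path)
  }
  as_named <- function(x) if (is.null(x)) NULL else unlist(x)
  reference_set(
    background = as_named(doc$background),
    standard = as_named(doc$standard),
    toxicity = as_named(doc$toxicity),
    detection = as_named(doc$detection),
    igeo_margin = if (is.null(doc$igeo_margin)) 1.5 else as.numeric(doc$igeo_margin)
  )
}

#' Write a reference set to YAML
#'
#' Inverse of [load_reference_set()]; the written document round-trips to an
#' identical `reference_set`.
#'
#' @param refs A `reference_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference_set <- function(refs, path) {
  stopifnot(inherits(refs, "reference_set"))
  doc <- list(
    background = as.list(refs$background),
    standard = as.list(refs$standard),
    toxicity = as.list(refs$toxicity),
    detection = as.list(refs$detection),
    igeo_margin = refs$igeo_margin
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
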