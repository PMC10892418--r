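#' Construct a grading scheme
#'
#' A grading scheme maps any finite real index value to exactly one ordered
#' class label. `boundaries` are the interior thresholds; with k boundaries
#' there are k + 1 labels. `boundary_rule` states which side a threshold
#' belongs to: `"left_closed"` assigns a boundary value to the class above it
#' (intervals `[b, next)`), `"right_closed"` to the class below (intervals
#' `(prev, b]`). The published index scales are inconsistent on this point —
#' the geo-accumulation grades are left-closed (1 <= Igeo < 2) while the
#' Nemerow and PERI classes are right-closed (0.7 < PN <= 1) — so the rule is
#' carried per scheme rather than fixed globally.
#'
#' @param name Scheme name.
#' @param boundaries Strictly increasing finite thresholds.
#' @param labels Ordered class labels, `length(boundaries) + 1` of them.
#' @param boundary_rule `"left_closed"` or `"right_closed"`.
#' @return An object of class `grade_scheme`.
#' @export
grade_scheme <- function(name, boundaries, labels,
                         boundary_rule = c("left_closed", "right_closed")) {
  boundary_rule <- match.arg(boundary_rule)
  boundaries <- as.numeric(boundaries)
  if (any(!is.finite(boundaries)) || is.unsorted(boundaries, strictly = TRUE)) {
    stop("'boundaries' must be finite and strictly increasing", call. = FALSE)
  }
  if (length(labels) != length(boundaries) + 1) {
    stop("need exactly one more label than boundaries", call. = FALSE)
  }
  structure(
    list(name = name, boundaries = boundaries,
         labels = as.character(labels), boundary_rule = boundary_rule),
    class = "grade_scheme"
  )
}

#' @export
print.grade_scheme <- function(x, ...) {
  cat(sprintf("<grade_scheme '%s'> (%s)\n", x$name, x$boundary_rule))
  cat("boundaries:", paste(x$boundaries, collapse = ", "), "\n")
  cat("labels:", paste(x$labels, collapse = " < "), "\n")
  invisible(x)
}

#' Shipped grading schemes
#'
#' The four class scales used throughout the package, with their published
#' cut-offs:
#' \describe{
#'   \item{igeo}{Geo-accumulation index, seven grades: `< 0` unpolluted,
#'     `[0,1)` lightly, `[1,2)` moderately, `[2,3)` moderately to heavily,
#'     `[3,4)` heavily, `[4,5)` heavily to extremely, `>= 5` extremely
#'     polluted.}
#'   \item{pn}{Nemerow composite index, five classes: `<= 0.7` clean,
#'     `(0.7,1]` warning, `(1,2]` slightly, `(2,3]` moderately, `> 3`
#'     heavily polluted. Also used for the single pollution index C/S.}
#'   \item{er}{Single-factor ecological risk: `< 40` low, `[40,80)` moderate,
#'     `[80,160)` considerable, `[160,320)` strong, `>= 320` extreme
#'     pollution.}
#'   \item{peri}{Composite potential ecological risk: `<= 150` low,
#'     `(150,300]` moderate, `(300,600]` considerable, `> 600` strong risk.}
#' }
#'
#' @return A named list of `grade_scheme` objects.
#' @export
grade_schemes <- function() {
  list(
    igeo = grade_scheme(
      "igeo", boundaries = 0:5,
      labels = c("unpolluted", "lightly polluted", "moderately polluted",
                 "moderately to heavily polluted", "heavily polluted",
                 "heavily to extremely polluted", "extremely polluted"),
      boundary_rule = "left_closed"
    ),
    pn = grade_scheme(
      "pn", boundaries = c(0.7, 1, 2, 3),
      labels = c("clean", "warning", "slightly polluted",
                 "moderately polluted", "heavily polluted"),
      boundary_rule = "right_closed"
    ),
    er = grade_scheme(
      "er", boundaries = c(40, 80, 160, 320),
      labels = c("low pollution", "moderate pollution",
                 "considerable pollution", "strong pollution",
                 "extreme pollution"),
      boundary_rule = "left_closed"
    ),
    peri = grade_scheme(
      "peri", boundaries = c(150, 300, 600),
      labels = c("low risk", "moderate risk", "considerable risk",
                 "strong risk"),
      boundary_rule = "right_closed"
    )
  )
}

#' Classify index values under a grading scheme
#'
#' Total on finite inputs: every value maps to exactly one label, with
#' boundary membership governed by the scheme's `boundary_rule`.
#'
#' @param values Numeric vector of finite index values.
#' @param scheme A `grade_scheme`, or the name of a shipped scheme
#'   (`"igeo"`, `"pn"`, `"er"`, `"peri"`).
#' @return An ordered factor over the scheme's labels.
#' @export
#' @examples
#' classify_values(c(-0.5, 0, 1, 2.52), "igeo")
#' classify_values(40, "er")    # boundary belongs to "moderate pollution"
#' classify_values(0.7, "pn")   # boundary belongs to "clean"
classify_values <- function(values, scheme) {
  if (is.character(scheme)) scheme <- grade_schemes()[[match.arg(scheme, names(grade_schemes()))]]
  stopifnot(inherits(scheme, "grade_scheme"))
  values <- as.numeric(values)
  if (any(!is.finite(values))) {
    stop(sprintf("cannot classify non-finite value under scheme '%s'", scheme$name),
         call. = FALSE)
  }
  idx <- findInterval(values, scheme$boundaries,
                      left.open = scheme$boundary_rule == "right_closed") + 1L
  factor(scheme$labels[idx], levels = scheme$labels, ordered = TRUE)
}
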