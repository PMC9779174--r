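#' Fractional vegetation coverage of a mask
#'
#' FVC is the exact pixel-count ratio `100 * n_vegetation / n_total`,
#' expressed as a percentage.
#'
#' @param mask Binary vegetation mask (0/1 matrix or logical).
#' @return A list of class `fvc` with `fvc` (percent), `n_vegetation`
#'   and `n_total`.
#' @examples
#' m <- matrix(0L, 10, 10); m[1:25] <- 1L
#' compute_fvc(m)$fvc  # 25
#' @export
compute_fvc <- function(mask) {
  mask <- as_mask(mask)
  n <- length(mask)
  if (n == 0L) stop("cannot compute FVC of a zero-pixel mask")
  nv <- sum(mask)
  structure(list(fvc = 100 * nv / n, n_vegetation = nv, n_total = n),
            class = "fvc")
}

#' @export
print.fvc <- function(x, ...) {
  cat(sprintf("FVC %.4f%% (%d / %d vegetation pixels)\n",
              x$fvc, x$n_vegetation, x$n_total))
  invisible(x)
}

# severity-ordered grade labels (most severe first)
GRADE_LEVELS <- c("Severe", "High", "Moderate", "Slight", "Non-desertification")
GRADE_BREAKS <- c(5, 21, 51, 71)

#' Desertification grade bands
#'
#' The five grades partition FVC in `[0, 100]` into half-open bands:
#' Severe `[0, 5)`, High `[5, 21)`, Moderate `[21, 51)`, Slight `[51, 71)`,
#' Non-desertification `[71, 100]`. Published band edges are integers
#' ("5-20%", "21-50%", "51-70%"); the half-open convention closes the
#' real-valued gaps so every FVC receives exactly one grade.
#'
#' @return A data frame with grade label, lower and upper FVC bound.
#' @export
grade_thresholds <- function() {
  data.frame(
    grade = GRADE_LEVELS,
    fvc_min = c(0, GRADE_BREAKS),
    fvc_max = c(GRADE_BREAKS, 100),
    upper_open = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

#' Assign a desertification grade from FVC
#'
#' @param fvc Numeric vector of FVC percentages in `[0, 100]` (or `fvc`
#'   objects from [compute_fvc()]).
#' @return A factor with severity-ordered levels
#'   `Severe < High < Moderate < Slight < Non-desertification`.
#' @examples
#' assign_grade(c(4.3243, 13.2679, 71.6581))
#' @export
assign_grade <- function(fvc) {
  if (inherits(fvc, "fvc")) fvc <- fvc$fvc
  fvc <- as.numeric(fvc)
  if (anyNA(fvc) || any(fvc < 0 | fvc > 100))
    stop("FVC must lie in [0, 100]")
  factor(GRADE_LEVELS[findInterval(fvc, GRADE_BREAKS) + 1L],
         levels = GRADE_LEVELS, ordered = TRUE)
}
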