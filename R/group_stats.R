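#' One-way analysis of variance
#'
#' Textbook decomposition of the total sum of squares into between-group and
#' within-group components, with the F statistic and its upper-tail p-value.
#' The layout mirrors the conventional report: Between Groups / Within
#' Groups / Grand Total rows with TSS, df, MS, F and p.
#'
#' @param groups Either a list of numeric vectors (one per group) or a data
#'   frame with columns `value` and `group`.
#' @return An object of class `anova_table`: a data frame with rows
#'   `Between Groups`, `Within Groups`, `Grand Total` and columns
#'   `tss`, `df`, `ms`, `f`, `p`. When the within-group mean square is 0 the
#'   F statistic is `NA` with an explanatory attribute `note`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
#' @export
one_way_anova <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  k <- length(groups)
  n_i <- lengths(groups)
  if (k < 2L) stop("one-way ANOVA needs at least 2 groups")
  if (any(n_i < 2L)) stop("every group needs at least 2 observations")
  values <- unlist(groups, use.names = FALSE)
  if (anyNA(values) || !all(is.finite(values)))
    stop("ANOVA observations must be finite")
  n <- length(values)
  grand <- mean(values)
  means <- vapply(groups, mean, 0)
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((groups[[i]] - means[i])^2), 0))
  dfb <- k - 1L
  dfw <- n - k
  msb <- ssb / dfb
  msw <- ssw / dfw
  note <- NULL
  if (msw == 0) {
    f <- NA_real_; p <- NA_real_
    note <- "within-group mean square is 0: F undefined"
  } else {
    f <- msb / msw
    p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  }
  out <- data.frame(
    source = c("Between Groups", "Within Groups", "Grand Total"),
    tss = c(ssb, ssw, ssb + ssw),
    df = c(dfb, dfw, dfb + dfw),
    ms = c(msb, msw, NA),
    f = c(f, NA, NA),
    p = c(p, NA, NA)
  )
  class(out) <- c("anova_table", "data.frame")
  attr(out, "group_means") <- means
  attr(out, "n_per_group") <- n_i
  if (!is.null(note)) attr(out, "note") <- note
  out
}

#' Audit a printed ANOVA summary row
#'
#' Recomputes the mean squares and F ratio implied by a report's TSS and df
#' columns, for checking the internal arithmetic of published ANOVA tables.
#'
#' @param tss_between,df_between,tss_within,df_within Sums of squares and
#'   degrees of freedom of the two rows.
#' @return A list with `ms_between`, `ms_within` and `f`.
#' @examples
#' anova_consistency(14840.249, 18, 14083.024, 95)
#' @export
anova_consistency <- function(tss_between, df_between, tss_within, df_within) {
  stopifnot(df_between > 0, df_within > 0)
  msb <- tss_between / df_between
  msw <- tss_within / df_within
  list(ms_between = msb, ms_within = msw, f = msb / msw)
}

# Duncan critical range for span p: the studentized-range quantile at the
# span-dependent significance level alpha_p = 1 - (1-alpha)^(p-1) (so the
# quantile is taken at probability (1-alpha)^(p-1)), scaled by the standard
# error of a group mean.
duncan_critical_ranges <- function(k, df_within, ms_within, n, alpha) {
  p <- 2:k
  q <- stats::qtukey((1 - alpha)^(p - 1), p, df_within)
  stats::setNames(q * sqrt(ms_within / n), p)
}

#' Duncan's multiple range test
#'
#' Post-hoc multiple comparison of balanced group means. Means are sorted in
#' decreasing order; a pair spanning `p` positions differs significantly
#' when its difference exceeds the critical range
#' `R_p = q*(p, df_within) * sqrt(ms_within / n)`, where `q*` is the
#' studentized-range quantile at the protection level
#' `1 - (1 - alpha)^(p - 1)`. A range contained in a wider non-significant
#' range is never declared significant. Groups are labeled with letters by
#' the standard underlining rule: groups sharing a letter do not differ at
#' level `alpha`.
#'
#' @param groups List of equal-length numeric vectors or a `value`/`group`
#'   data frame (balanced design required).
#' @param alpha Significance level (default 0.05).
#' @param ms_within,df_within Error mean square and df; computed from the
#'   companion one-way ANOVA of `groups` when omitted.
#' @return An object of class `duncan_result`: a data frame with `group`,
#'   `mean` and `letters`, sorted by decreasing mean, with the per-span
#'   critical ranges as attribute `critical_ranges`.
#' @examples
#' duncan_mrt(list(a = c(10, 11, 12), b = c(10.5, 11.5, 12.5), c = c(30, 31, 32)))
#' @export
duncan_mrt <- function(groups, alpha = 0.05, ms_within = NULL, df_within = NULL) {
  if (is.data.frame(groups)) groups <- split(groups$value, groups$group)
  n_i <- lengths(groups)
  if (length(unique(n_i)) != 1L)
    stop("Duncan's test requires balanced groups (equal n)")
  n <- n_i[[1]]
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  if (is.null(ms_within) || is.null(df_within)) {
    at <- one_way_anova(groups)
    ms_within <- at$ms[2]
    df_within <- at$df[2]
  }
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_len(k))
  means <- vapply(groups, mean, 0)
  # sort decreasing; ties broken by original (registry) order
  ord <- order(-means, seq_len(k))
  m <- means[ord]
  if (ms_within == 0) {
    # no residual variation: any difference is significant
    rp <- stats::setNames(rep(0, k - 1), 2:k)
  } else {
    rp <- duncan_critical_ranges(k, df_within, ms_within, n, alpha)
  }
  # nonsig[i, j]: the sorted groups i..j are mutually non-significant.
  # Spans are tested longest-first; once a span tests non-significant all of
  # its sub-spans are protected (never tested, declared non-significant).
  nonsig <- matrix(FALSE, k, k)
  diag(nonsig) <- TRUE
  for (L in seq(k, 2)) {
    for (i in seq_len(k - L + 1L)) {
      j <- i + L - 1L
      if (nonsig[i, j]) next
      if (m[i] - m[j] <= rp[[as.character(L)]] + 1e-12) {
        for (a in i:j) for (b in a:j) nonsig[a, b] <- TRUE
      }
    }
  }
  # letters: maximal homogeneous intervals over the sorted means
  letters_per_group <- rep("", k)
  letter_id <- 0L
  prev_end <- 0L
  for (i in seq_len(k)) {
    j <- max(which(nonsig[i, i:k])) + i - 1L
    if (j > prev_end) {
      letter_id <- letter_id + 1L
      lab <- make_letter(letter_id)
      letters_per_group[i:j] <- paste0(letters_per_group[i:j], lab)
      prev_end <- j
    }
  }
  out <- data.frame(group = names(groups)[ord], mean = m,
                    letters = letters_per_group, row.names = NULL)
  class(out) <- c("duncan_result", "data.frame")
  attr(out, "critical_ranges") <- rp
  attr(out, "alpha") <- alpha
  attr(out, "ms_within") <- ms_within
  attr(out, "df_within") <- df_within
  out
}

# a, b, ..., z, aa, ab, ... for many letter blocks
make_letter <- function(i) {
  out <- ""
  while (i > 0L) {
    out <- paste0(letters[(i - 1L) %% 26L + 1L], out)
    i <- (i - 1L) %/% 26L
  }
  out
}

#' Grade-wise ANOVA and Duncan comparison of index accuracy
#'
#' Runs, for every desertification grade and every accuracy metric, a
#' one-way ANOVA across the vegetation indices followed by Duncan's multiple
#' range test, reproducing the layout of a grade-by-metric comparison study
#' (per grade: indices are groups, scenes are replicates).
#'
#' @param metric_table Data frame with columns `index`, `image`, `grade`,
#'   `metric`, `value`; each grade x metric cell must be balanced (every
#'   index observed on the same number of images).
#' @param alpha Significance level for Duncan letters (default 0.05).
#' @return A list of class `grade_report` with components `anova` (data
#'   frame of all ANOVA rows, one block per grade x metric), `duncan` (data
#'   frame of letters with group means) and `means` (per grade x metric x
#'   index mean values).
#' @export
replicate_study <- function(metric_table, alpha = 0.05) {
  req <- c("index", "image", "grade", "metric", "value")
  stopifnot(all(req %in% names(metric_table)))
  anova_rows <- list()
  duncan_rows <- list()
  mean_rows <- list()
  for (gr in unique(as.character(metric_table$grade))) {
    for (met in unique(metric_table$metric)) {
      sub <- metric_table[metric_table$grade == gr & metric_table$metric == met, ]
      if (nrow(sub) == 0L) next
      counts <- table(sub$index)
      if (length(unique(counts)) != 1L)
        stop("unbalanced design at grade '", gr, "', metric '", met,
             "': every index needs the same number of images")
      grps <- split(sub$value, factor(sub$index, unique(sub$index)))
      at <- one_way_anova(grps)
      dm <- duncan_mrt(grps, alpha = alpha,
                       ms_within = at$ms[2], df_within = at$df[2])
      anova_rows[[length(anova_rows) + 1L]] <-
        cbind(grade = gr, metric = met, as.data.frame(at))
      duncan_rows[[length(duncan_rows) + 1L]] <-
        cbind(grade = gr, metric = met, as.data.frame(dm))
      mean_rows[[length(mean_rows) + 1L]] <- data.frame(
        grade = gr, metric = met, index = names(grps),
        mean = vapply(grps, mean, 0), row.names = NULL)
    }
  }
  structure(list(anova = do.call(rbind, anova_rows),
                 duncan = do.call(rbind, duncan_rows),
                 means = do.call(rbind, mean_rows)),
            class = "grade_report")
}

#' @export
print.grade_report <- function(x, ...) {
  cells <- unique(x$means[c("grade", "metric")])
  cat(sprintf("<grade_report> %d grade x metric cells, %d indices\n",
              nrow(cells), length(unique(x$means$index))))
  invisible(x)
}
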