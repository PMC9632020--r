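descriptorNames <- function() {
  setdiff(morphTableColumns(),
          c("subject_id", "group", "position", "watertight",
            paste0("degenerate_", c("cor", "sag", "hor"))))
}

#' Paired position change for one subject
#'
#' Differences and percentage rates of change of every descriptor between the
#' supine and maximum-extension records of one subject.  The difference is
#' `extension - supine` in native units; the rate of change is
#' `100 * difference / denominator value`, with the extension value as the
#' default denominator (matching the arithmetic of the published group-level
#' volume rates; the supine convention is selectable).  A zero denominator
#' yields an `NA` rate rather than an error.
#'
#' @param supine,extension [MorphRecord-class] objects for the same subject
#' @param denominator `"extension"` (default) or `"supine"`
#' @return data.frame with columns `subject_id`, `descriptor`, `supine`,
#'   `extension`, `difference`, `rate_pct`
#' @examples
#' ## volumes 6000 -> 9000 give difference 3000 and rate 33.33%
#' @export
positionChange <- function(supine, extension,
                           denominator = c("extension", "supine")) {
  denominator <- match.arg(denominator)
  stopifnot(is(supine, "MorphRecord"), is(extension, "MorphRecord"))
  if (supine@subjectId != extension@subjectId)
    stop("pairing error: records belong to different subjects ('",
         supine@subjectId, "' vs '", extension@subjectId, "')")
  if (supine@position != "supine" || extension@position != "extension")
    stop("pairing error: expected one supine and one extension record")
  sv <- unlist(morphRecordsToFrame(supine)[descriptorNames()])
  ev <- unlist(morphRecordsToFrame(extension)[descriptorNames()])
  diff <- ev - sv
  den <- if (denominator == "extension") ev else sv
  rate <- ifelse(is.na(den) | den == 0, NA_real_, 100 * diff / den)
  rate[!is.na(diff) & diff == 0] <- 0
  data.frame(subject_id = supine@subjectId, descriptor = descriptorNames(),
             supine = as.numeric(sv), extension = as.numeric(ev),
             difference = as.numeric(diff), rate_pct = as.numeric(rate),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-group comparison of a descriptor
#'
#' Two-tailed two-sample t-test: classical pooled-variance Student test by
#' default, Welch's unequal-variance variant on request.  Degenerate inputs
#' are resolved explicitly: both groups constant and equal means give
#' `t = 0, p = 1`; constant groups with unequal means give an infinite t and
#' `p = 0`.
#'
#' @param valuesA,valuesB numeric vectors, length >= 2, finite
#' @param variant `"pooled"` (Student) or `"welch"`
#' @return list of class `"groupComparison"` with elements `meanA`, `sdA`,
#'   `nA`, `meanB`, `sdB`, `nB`, `t`, `df`, `p`, `variant`.  The sign of `t`
#'   matches the sign of `meanA - meanB`.
#' @examples
#' groupCompare(c(10, 12, 14), c(20, 22, 24))  # t = -6.124, p = 0.0036
#' @export
groupCompare <- function(valuesA, valuesB, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(valuesA) < 2L || length(valuesB) < 2L)
    stop("each group needs at least 2 values")
  if (any(!is.finite(valuesA)) || any(!is.finite(valuesB)))
    stop("non-finite values in input")
  nA <- length(valuesA); nB <- length(valuesB)
  mA <- mean(valuesA); mB <- mean(valuesB)
  sA <- stats::sd(valuesA); sB <- stats::sd(valuesB)
  if (sA == 0 && sB == 0) {
    if (mA == mB) {
      t <- 0; df <- nA + nB - 2; p <- 1
    } else {
      t <- sign(mA - mB) * Inf; df <- nA + nB - 2; p <- 0
    }
  } else {
    ht <- stats::t.test(valuesA, valuesB, var.equal = (variant == "pooled"))
    t <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
  }
  structure(list(meanA = mA, sdA = sA, nA = nA, meanB = mB, sdB = sB,
                 nB = nB, t = t, df = df, p = p, variant = variant),
            class = "groupComparison")
}

#' @export
print.groupComparison <- function(x, ...) {
  cat(sprintf("Two-sample t-test (%s): t = %.4g, df = %.4g, p = %.4g\n",
              x$variant, x$t, x$df, x$p))
  cat(sprintf("  A: %.4g +/- %.4g (n = %d)   B: %.4g +/- %.4g (n = %d)\n",
              x$meanA, x$sdA, x$nA, x$meanB, x$sdB, x$nB))
  invisible(x)
}

#' Power of the two-sample two-tailed t-test
#'
#' Exact power from the noncentral t distribution: with `n` subjects per
#' group and standardized mean difference `d` (Cohen's d), the test statistic
#' under the alternative is noncentral t with `df = 2n - 2` and
#' noncentrality `d * sqrt(n / 2)`; power is the probability that it exceeds
#' the two-tailed critical value.  At `d = 0` the power equals `alpha`.
#'
#' @param d Cohen's d, >= 0 (vectorized)
#' @param n sample size per group, >= 2
#' @param alpha significance level (default 0.05)
#' @param twoTailed two-tailed test (default TRUE)
#' @return power in `[0, 1]`
#' @examples
#' powerTwoSampleT(c(0.2, 0.5, 0.8), n = 20)  # 0.095, 0.338, 0.693
#' @export
powerTwoSampleT <- function(d, n, alpha = 0.05, twoTailed = TRUE) {
  stopifnot(all(d >= 0), n >= 2, alpha > 0, alpha < 1)
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (twoTailed) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    1 - stats::pt(tc, df, ncp)
  }
}

#' Mean +/- SD summary of a cohort of records
#'
#' Summarises every descriptor by group and position (the shape of the
#' published cohort tables): mean, standard deviation and n per cell.
#' Cells with fewer than 2 records are omitted with a warning.
#'
#' @param records list of [MorphRecord-class] objects
#' @return data.frame with columns `group`, `position`, `descriptor`,
#'   `mean`, `sd`, `n`
#' @export
summarizeCohort <- function(records) {
  df <- morphRecordsToFrame(records)
  out <- list()
  for (g in unique(df$group)) for (pos in unique(df$position)) {
    cell <- df[df$group == g & df$position == pos, ]
    if (nrow(cell) == 0L) next
    if (nrow(cell) < 2L) {
      warning("omitting cell ", g, " / ", pos, ": fewer than 2 records")
      next
    }
    for (dsc in descriptorNames()) {
      vals <- cell[[dsc]]
      out[[length(out) + 1L]] <- data.frame(
        group = g, position = pos, descriptor = dsc,
        mean = mean(vals, na.rm = TRUE), sd = stats::sd(vals, na.rm = TRUE),
        n = sum(!is.na(vals)), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) stop("no summarisable cells in the record list")
  do.call(rbind, out)
}

#' Full two-group comparison report
#'
#' Builds the cohort comparison in the shape of the published tables: for
#' every descriptor, group A vs group B at each position, plus the paired
#' position change (extension - supine difference and percentage rate)
#' compared between groups.
#'
#' @param records list of [MorphRecord-class] objects covering two groups,
#'   each subject measured supine and in extension
#' @param variant t-test variant, `"pooled"` or `"welch"`
#' @param denominator rate-of-change denominator convention
#' @return data.frame with one row per descriptor x quantity: columns
#'   `descriptor`, `quantity` (position, `"difference"` or `"rate_pct"`),
#'   `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`, `t`, `df`, `p`
#' @export
compareCohorts <- function(records, variant = c("pooled", "welch"),
                           denominator = c("extension", "supine")) {
  variant <- match.arg(variant)
  denominator <- match.arg(denominator)
  df <- morphRecordsToFrame(records)
  groups <- sort(unique(df$group))
  if (length(groups) != 2L)
    stop("expected exactly 2 groups, found ", length(groups))
  byId <- split(seq_along(records), vapply(records, slot, "", "subjectId"))
  changes <- lapply(byId, function(ii) {
    pos <- vapply(records[ii], slot, "", "position")
    if (!all(c("supine", "extension") %in% pos)) return(NULL)
    pc <- positionChange(records[[ii[match("supine", pos)]]],
                         records[[ii[match("extension", pos)]]],
                         denominator = denominator)
    pc$group <- records[[ii[1]]]@group
    pc
  })
  changes <- do.call(rbind, changes)
  out <- list()
  addRow <- function(descriptor, quantity, a, b) {
    if (length(a) < 2L || length(b) < 2L) return()
    ok <- is.finite(a) & !is.na(a); a <- a[ok]
    ok <- is.finite(b) & !is.na(b); b <- b[ok]
    if (length(a) < 2L || length(b) < 2L) return()
    gc <- groupCompare(a, b, variant = variant)
    out[[length(out) + 1L]] <<- data.frame(
      descriptor = descriptor, quantity = quantity,
      mean_a = gc$meanA, sd_a = gc$sdA, n_a = gc$nA,
      mean_b = gc$meanB, sd_b = gc$sdB, n_b = gc$nB,
      t = gc$t, df = gc$df, p = gc$p, stringsAsFactors = FALSE)
  }
  for (dsc in descriptorNames()) {
    for (pos in c("supine", "extension")) {
      sel <- df$position == pos
      addRow(dsc, pos, df[sel & df$group == groups[1], dsc],
             df[sel & df$group == groups[2], dsc])
    }
    if (!is.null(changes)) {
      sel <- changes$descriptor == dsc
      addRow(dsc, "difference",
             changes$difference[sel & changes$group == groups[1]],
             changes$difference[sel & changes$group == groups[2]])
      addRow(dsc, "rate_pct",
             changes$rate_pct[sel & changes$group == groups[1]],
             changes$rate_pct[sel & changes$group == groups[2]])
    }
  }
  do.call(rbind, out)
}
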