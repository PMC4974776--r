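#' Sample manifest
#'
#' Maps each sample id to its kidney, perfusion time point and effective
#' sample volume.
#'
#' @param kidney kidney identifiers.
#' @param time_h perfusion time points in hours (positive).
#' @param sample_id unique sample identifiers.
#' @param volume_l effective sample volumes in litres.
#' @return Data frame of class `sample_manifest`.
#' @export
sample_manifest <- function(kidney, time_h, sample_id, volume_l) {
  df <- data.frame(kidney = as.character(kidney), time_h = as.numeric(time_h),
                   sample = as.character(sample_id),
                   volume_l = as.numeric(volume_l), stringsAsFactors = FALSE)
  if (any(df$time_h <= 0)) stop("time points must be positive")
  if (anyDuplicated(df[, c("kidney", "time_h")])) {
    stop("duplicate (kidney, time) pairs in manifest")
  }
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in manifest")
  class(df) <- c("sample_manifest", "data.frame")
  df
}

#' Summarise enrichment records per metabolite, quantity and time point
#'
#' Mean and sample SD (n-1 denominator) across kidneys of each quantity
#' (enrichment %, total mM, labelled nmol) at each time point.
#'
#' @param records data frame of [enrichment_record()] rows.
#' @param manifest a [sample_manifest()] covering every record.
#' @return Data frame with columns `metabolite`, `quantity`, `time_h`, `n`,
#'   `mean`, `sd`. Enrichment is reported in percent.
#' @export
summarize_timecourse <- function(records, manifest) {
  stopifnot(is.data.frame(records), inherits(manifest, "sample_manifest"))
  orphan <- setdiff(records$sample, manifest$sample)
  if (length(orphan)) {
    stop("records reference samples absent from the manifest: ",
         paste(orphan, collapse = ", "))
  }
  merged <- merge(records, manifest[, c("sample", "kidney", "time_h")],
                  by = "sample")
  long <- rbind(
    data.frame(metabolite = merged$metabolite, quantity = "enrichment_pct",
               time_h = merged$time_h, value = 100 * merged$enrichment),
    data.frame(metabolite = merged$metabolite, quantity = "total_mm",
               time_h = merged$time_h, value = merged$total_mm),
    data.frame(metabolite = merged$metabolite, quantity = "labelled_nmol",
               time_h = merged$time_h, value = merged$amount_nmol)
  )
  out <- do.call(rbind, lapply(
    split(long, list(long$metabolite, long$quantity, long$time_h), drop = TRUE),
    function(g) {
      data.frame(metabolite = g$metabolite[1], quantity = g$quantity[1],
                 time_h = g$time_h[1], n = nrow(g), mean = mean(g$value),
                 sd = stats::sd(g$value))
    }))
  out <- out[order(out$metabolite, out$quantity, out$time_h), ]
  rownames(out) <- NULL
  out
}

#' Student's t test from group summary statistics
#'
#' Pooled-variance two-tailed Student's t test computed from means, SDs and
#' group sizes; identical to the raw-data test whenever raw data have exactly
#' these summaries. `welch = TRUE` gives the unequal-variance variant with
#' Satterthwaite degrees of freedom.
#'
#' @param m1,sd1,n1 mean, sample SD and size of group 1.
#' @param m2,sd2,n2 mean, sample SD and size of group 2.
#' @param welch use the Welch variant instead of pooled variance.
#' @return List of class `summary_ttest`: `t`, `df`, `p` (two-tailed).
#' @examples
#' ttest_from_summary(31.1, 12.2, 6, 93.4, 25.6, 6)  # p < 0.01
#' @export
ttest_from_summary <- function(m1, sd1, n1, m2, sd2, n2, welch = FALSE) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 2L || n2 < 2L) stop("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative")
  if (sd1 == 0 && sd2 == 0 && m1 == m2) {
    return(structure(list(t = 0, df = n1 + n2 - 2, p = 1),
                     class = "summary_ttest"))
  }
  if (sd1 == 0 && sd2 == 0) stop("both SDs zero with unequal means: t undefined")
  v1 <- sd1^2; v2 <- sd2^2
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    t <- (m1 - m2) / sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, p = p), class = "summary_ttest")
}

#' @export
print.summary_ttest <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %.4g, two-tailed p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Run the configured time-course comparisons
#'
#' For each (metabolite, quantity, t1, t2) comparison, performs the pooled
#' two-tailed Student's t test between the two time points and flags p < alpha
#' as significant. Comparisons with a missing group are skipped with a
#' warning rather than silently omitted.
#'
#' @param records data frame of [enrichment_record()] rows.
#' @param manifest a [sample_manifest()].
#' @param comparisons data frame with columns `metabolite`, `quantity`
#'   (`"enrichment_pct"`, `"total_mm"` or `"labelled_nmol"`), `t1`, `t2`
#'   (hours). Default: 6 h vs 24 h for every metabolite/quantity present.
#' @param alpha significance level (default 0.05).
#' @param bonferroni divide alpha by the number of comparisons.
#' @param welch use Welch's variant.
#' @return List with `summary` (the [summarize_timecourse()] table) and
#'   `tests` (one row per executed comparison: t, df, p, significant).
#' @export
run_timecourse <- function(records, manifest, comparisons = NULL,
                           alpha = 0.05, bonferroni = FALSE, welch = FALSE) {
  summ <- summarize_timecourse(records, manifest)
  if (is.null(comparisons)) {
    keys <- unique(summ[, c("metabolite", "quantity")])
    comparisons <- data.frame(metabolite = keys$metabolite,
                              quantity = keys$quantity, t1 = 6, t2 = 24)
  }
  thr <- if (bonferroni) alpha / nrow(comparisons) else alpha
  rows <- vector("list", nrow(comparisons))
  for (r in seq_len(nrow(comparisons))) {
    cm <- comparisons[r, ]
    g1 <- summ[summ$metabolite == cm$metabolite & summ$quantity == cm$quantity &
                 summ$time_h == cm$t1, ]
    g2 <- summ[summ$metabolite == cm$metabolite & summ$quantity == cm$quantity &
                 summ$time_h == cm$t2, ]
    if (nrow(g1) != 1L || nrow(g2) != 1L || g1$n < 2L || g2$n < 2L) {
      warning("skipping comparison ", cm$metabolite, "/", cm$quantity, " ",
              cm$t1, "h vs ", cm$t2, "h: group missing or n < 2")
      next
    }
    tt <- ttest_from_summary(g1$mean, g1$sd, g1$n, g2$mean, g2$sd, g2$n,
                             welch = welch)
    rows[[r]] <- data.frame(
      metabolite = cm$metabolite, quantity = cm$quantity,
      t1 = cm$t1, t2 = cm$t2,
      mean1 = g1$mean, sd1 = g1$sd, n1 = g1$n,
      mean2 = g2$mean, sd2 = g2$sd, n2 = g2$n,
      t = tt$t, df = tt$df, p = tt$p, significant = tt$p < thr)
  }
  tests <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  list(summary = summ, tests = tests, alpha = thr)
}
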