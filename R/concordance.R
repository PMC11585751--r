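#' Reader-by-ROI score table
#'
#' Container for the proliferation-index scores of several readers
#' (pathologists, the AI, AI-assisted pathologists) over a common set of
#' ROIs. All concordance statistics operate on this object. Missing
#' cells are rejected: every reader must score every ROI.
#'
#' @param scores numeric readers x ROIs matrix of PI percentages in
#'   \[0, 100\].
#' @param reader_ids,roi_ids identifiers; default to the dimnames or to
#'   generated labels.
#' @return An object of class `score_table`.
#' @export
score_table <- function(scores, reader_ids = rownames(scores),
                        roi_ids = colnames(scores)) {
  scores <- as.matrix(scores)
  if (any(is.na(scores)))
    stop("score table has missing cells; every reader must score every ROI")
  if (any(scores < 0 | scores > 100))
    stop("PI scores must lie in [0, 100]")
  if (is.null(reader_ids)) reader_ids <- paste0("R", seq_len(nrow(scores)))
  if (is.null(roi_ids)) roi_ids <- paste0("roi", seq_len(ncol(scores)))
  if (anyDuplicated(reader_ids)) stop("duplicated reader ids")
  dimnames(scores) <- list(reader_ids, roi_ids)
  structure(list(scores = scores,
                 reader_ids = as.character(reader_ids),
                 roi_ids = as.character(roi_ids)),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d readers x %d ROIs (%s)\n",
              nrow(x$scores), ncol(x$scores),
              paste(x$reader_ids, collapse = ", ")))
  invisible(x)
}

#' Read / write a score table as CSV
#'
#' The CSV layout is rows = ROIs, columns = readers, with a leading
#' `roi_id` column and a header row of reader ids.
#'
#' @param path file path.
#' @return `read_score_table` returns a [score_table()];
#'   `write_score_table` invisibly returns `path`.
#' @export
read_score_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"roi_id" %in% names(df)) stop("score CSV must have a 'roi_id' column")
  roi <- as.character(df$roi_id)
  m <- t(as.matrix(df[setdiff(names(df), "roi_id")]))
  score_table(m, reader_ids = rownames(m), roi_ids = roi)
}

#' @rdname read_score_table
#' @param table a [score_table()].
#' @export
write_score_table <- function(table, path) {
  df <- data.frame(roi_id = table$roi_ids, t(table$scores),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Root mean squared error between two readers' scores
#'
#' `sqrt(mean((a - b)^2))` -- the pairwise discordance measure used to
#' compare readers. Symmetric in its arguments and zero iff the scores
#' agree exactly.
#'
#' @param a,b numeric vectors of equal length >= 1.
#' @return Nonnegative scalar.
#' @examples
#' rmse(c(0, 0), c(3, 4)) # sqrt(25 / 2) = 3.5355
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  if (length(a) < 1) stop("need at least one paired score")
  sqrt(mean((a - b)^2))
}

#' Pairwise RMSE matrix over all readers
#'
#' @param table a [score_table()] with at least two readers.
#' @return Symmetric readers x readers matrix with zero diagonal, class
#'   `rmse_matrix`. Values are kept at full precision; round to 2
#'   decimals for display.
#' @export
rmse_matrix <- function(table) {
  if (!inherits(table, "score_table")) stop("`table` must be a score_table")
  s <- table$scores
  n <- nrow(s)
  if (n < 2) stop("need at least two readers")
  m <- matrix(0, n, n, dimnames = list(table$reader_ids, table$reader_ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- rmse(s[i, ], s[j, ])
    }
  }
  class(m) <- c("rmse_matrix", class(m))
  m
}

#' @export
print.rmse_matrix <- function(x, ...) {
  print(round(unclass(x), 2), ...)
  invisible(x)
}

#' Mean pairwise discordance among a reader subset
#'
#' Arithmetic mean of the upper-triangle RMSE entries over the chosen
#' readers -- the single-number discordance summary for a reading round.
#'
#' @param m an [rmse_matrix()] (or plain symmetric matrix with reader
#'   dimnames).
#' @param readers character or integer subset of size >= 2; defaults to
#'   all readers.
#' @return Scalar mean discordance.
#' @examples
#' # unassisted-round pairwise RMSEs of 18.10, 12.12 and 12.01
#' # average to 14.08; assisted-round 2.53, 2.93, 2.10 average to 2.52
#' @export
mean_pairwise_discordance <- function(m, readers = NULL) {
  m <- unclass(m)
  if (!is.null(readers)) m <- m[readers, readers, drop = FALSE]
  if (nrow(m) < 2) stop("need at least two readers")
  mean(m[upper.tri(m)])
}

#' Relative reduction in discordance
#'
#' `100 * (pre - post) / pre`: the percentage by which the mean pairwise
#' discordance fell between the unassisted and assisted reading rounds.
#'
#' @param pre,post mean discordances; `pre` must be positive.
#' @return Reduction in percent (negative if discordance increased).
#' @examples
#' discordance_reduction(14.08, 2.52) # 82.1 (to 1 decimal)
#' @export
discordance_reduction <- function(pre, post) {
  if (!is.finite(pre) || pre <= 0) stop("`pre` discordance must be > 0")
  100 * (pre - post) / pre
}

#' Bland-Altman agreement between two score vectors
#'
#' Computes the paired differences `a - b`, their mean and standard
#' deviation, and the limits of agreement `mean +/- 1.96 * SD` expected
#' to contain about 95% of differences. The SD uses the n-1 (sample)
#' denominator by default. The paired means and differences are returned
#' for plotting.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n).
#' @return An object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, plus `means` and `diffs` vectors.
#' @examples
#' ba <- bland_altman(c(3, 5), c(2, 2)) # diffs 1, 3
#' c(ba$mean_diff, ba$loa_low, ba$loa_high)
#' @export
bland_altman <- function(a, b, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  n <- length(a)
  if (n < 2) stop("Bland-Altman needs at least two pairs")
  d <- a - b
  md <- mean(d)
  s <- if (sd_type == "sample") sd(d) else sqrt(mean((d - md)^2))
  structure(list(mean_diff = md, sd_diff = s,
                 loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
                 n = n, means = (a + b) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, mean difference %.2f, limits of agreement [%.2f, %.2f]\n",
              x$n, x$mean_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Plot a Bland-Altman analysis
#'
#' Differences against paired means, with a dashed line at the mean
#' difference and dashed lines at the limits of agreement.
#'
#' @param x a [bland_altman()] result.
#' @param main plot title.
#' @param ... passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.bland_altman <- function(x, main = "Bland-Altman agreement", ...) {
  plot(x$means, x$diffs, xlab = "Mean of paired scores (%)",
       ylab = "Difference (pp)", main = main, pch = 16,
       col = "grey30", ...)
  abline(h = x$mean_diff, lty = 2, col = "blue")
  abline(h = c(x$loa_low, x$loa_high), lty = 2, col = "darkorange")
  invisible(x)
}

#' Agreement rate between a reader and the AI
#'
#' Percentage of ROIs on which the reader accepted the AI output.
#'
#' @param n_accepted number of accepted ROIs.
#' @param n_total total number of ROIs (> 0).
#' @return Rate in percent.
#' @examples
#' agreement_rate(404, 440) # 91.8 (to 1 decimal)
#' @export
agreement_rate <- function(n_accepted, n_total) {
  if (n_total <= 0) stop("`n_total` must be positive")
  if (n_accepted < 0 || n_accepted > n_total)
    stop("`n_accepted` must lie in [0, n_total]")
  100 * n_accepted / n_total
}

#' Histogram of absolute scoring errors by 10-pp bracket
#'
#' Bins the absolute differences between two score vectors into the
#' brackets `[0,10), [10,20), ..., [90,100]` (last bracket closed). Used
#' to show in which PI range manual and assisted scores disagree.
#'
#' @param manual,assisted numeric score vectors of equal length.
#' @return An object of class `error_histogram`: `edges` (0, 10, ...,
#'   100), `counts` (length 10, summing to the number of ROIs), and
#'   `errors` (the absolute differences).
#' @examples
#' eh <- error_histogram(c(65, 5), c(7.5, 5))
#' eh$counts # one ROI in [50,60), one in [0,10)
#' @export
error_histogram <- function(manual, assisted) {
  if (length(manual) != length(assisted))
    stop("`manual` and `assisted` must have equal length")
  err <- abs(manual - assisted)
  if (any(err > 100)) stop("absolute PI errors cannot exceed 100")
  bin <- pmin(floor(err / 10), 9) + 1L # last bracket [90, 100] closed
  structure(list(edges = seq(0, 100, by = 10),
                 counts = tabulate(bin, nbins = 10L),
                 errors = err),
            class = "error_histogram")
}

#' @export
print.error_histogram <- function(x, ...) {
  lab <- paste0("[", x$edges[-11], ",", x$edges[-1],
                c(rep(")", 9), "]"))
  print(setNames(x$counts, lab))
  invisible(x)
}

#' Full concordance report for a two-round reader study
#'
#' Convenience wrapper: pairwise RMSE matrix over all readers, mean
#' pairwise discordance of the unassisted and assisted rounds, and the
#' relative reduction.
#'
#' @param table a [score_table()] containing both rounds.
#' @param pre_readers,post_readers reader-id subsets for the unassisted
#'   and assisted rounds.
#' @return List with `rmse_matrix`, `discordance_pre`,
#'   `discordance_post`, `reduction_percent`.
#' @export
concordance_report <- function(table, pre_readers, post_readers) {
  m <- rmse_matrix(table)
  pre <- mean_pairwise_discordance(m, pre_readers)
  post <- mean_pairwise_discordance(m, post_readers)
  list(rmse_matrix = m,
       discordance_pre = pre,
       discordance_post = post,
       reduction_percent = discordance_reduction(pre, post))
}
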