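#' Per-nucleus ratiometric reporter ratio
#'
#' BES1 signal divided by the constitutive nuclear H2B signal; the ratio
#' proxies brassinosteroid signaling level independent of nuclear size and
#' imaging depth.
#'
#' @param bes1 BES1 fluorescence total (>= 0).
#' @param h2b H2B fluorescence total (> 0).
#' @param nucleus_id optional id(s) used in error messages.
#' @return numeric ratio(s).
#' @export
nucleus_ratio <- function(bes1, h2b, nucleus_id = NULL) {
  bad <- h2b <= 0
  if (any(bad)) {
    ids <- if (is.null(nucleus_id)) which(bad) else nucleus_id[bad]
    stop("non-positive H2B signal for nucleus: ", paste(ids, collapse = ", "))
  }
  if (any(bes1 < 0)) stop("negative BES1 signal")
  bes1 / h2b
}

#' Per-sepal reporter summary (mean and CV)
#'
#' Rolls nucleus records up to one row per sepal: the mean BES1/H2B ratio
#' and its coefficient of variation (sample standard deviation / mean).
#' Sepals with fewer than `min_nuclei` nuclei are dropped with a warning;
#' a zero mean leaves the CV missing with a warning.
#'
#' @param records data.frame with columns `sepal_id`, `bes1_signal`,
#'   `h2b_signal` and label columns (`group`, `position`, ... carried
#'   through).
#' @param min_nuclei minimum nuclei per sepal, default 5.
#' @return data.frame with `sepal_id`, carried labels, `n_nuclei`,
#'   `mean_ratio`, `cv_ratio`.
#' @export
sepal_summary <- function(records, min_nuclei = 5) {
  stopifnot(all(c("sepal_id", "bes1_signal", "h2b_signal") %in% names(records)))
  records$.ratio <- nucleus_ratio(records$bes1_signal, records$h2b_signal,
                                  records$nucleus_id)
  carry <- intersect(c("bud_id", "stage", "position", "group"), names(records))
  pieces <- split(records, records$sepal_id)
  small <- vapply(pieces, nrow, integer(1)) < min_nuclei
  if (any(small))
    warning(sprintf("dropped %d sepal(s) with < %d nuclei", sum(small), min_nuclei))
  pieces <- pieces[!small]
  out <- do.call(rbind, lapply(pieces, function(d) {
    m <- mean(d$.ratio)
    cv <- if (m == 0) NA_real_ else stats::sd(d$.ratio) / m
    base <- data.frame(sepal_id = d$sepal_id[1], n_nuclei = nrow(d),
                       mean_ratio = m, cv_ratio = cv, stringsAsFactors = FALSE)
    for (cc in carry) base[[cc]] <- d[[cc]][1]
    base
  }))
  if (!is.null(out) && any(is.na(out$cv_ratio)))
    warning("sepal(s) with zero mean ratio: CV undefined")
  rownames(out) <- NULL
  out
}

#' Compare per-sepal reporter summaries between two groups
#'
#' Two-sided Wilcoxon rank-sum tests on the per-sepal values of each metric
#' (mean ratio and CV), overall and, when `by = "position"`, stratified by
#' sepal position. Strata where either group has fewer than 2 sepals are
#' reported with a missing p-value and a warning.
#'
#' @param summaries output of [sepal_summary()] with a `group` column
#'   (exactly two levels) and, for stratification, `position`.
#' @param by `"overall"` or `"position"`.
#' @return data.frame `stratum`, `metric`, `group1`, `group2`, `n1`, `n2`,
#'   `p`.
#' @export
group_compare <- function(summaries, by = c("overall", "position")) {
  by <- match.arg(by)
  groups <- sort(unique(summaries$group))
  if (length(groups) != 2) stop("exactly two groups required")
  strata <- if (by == "position")
    c("overall", sort(unique(summaries$position))) else "overall"
  rows <- list()
  for (st in strata) {
    d <- if (st == "overall") summaries else summaries[summaries$position == st, ]
    for (metric in c("mean_ratio", "cv_ratio")) {
      v1 <- d[[metric]][d$group == groups[1]]
      v2 <- d[[metric]][d$group == groups[2]]
      v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
      if (length(v1) < 2 || length(v2) < 2) {
        warning(sprintf("stratum '%s' has < 2 sepals in a group", st))
        p <- NA_real_
      } else p <- wilcoxon_rank_sum(v1, v2)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, metric = metric, group1 = groups[1], group2 = groups[2],
        n1 = length(v1), n2 = length(v2), p = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
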