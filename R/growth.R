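#' Sepal length ratios from single-timepoint measurements
#'
#' Outer/inner, outer/bud and inner/bud length ratios per bud. A missing
#' operand yields a missing ratio, not an error (inner sepals may not yet
#' have initiated).
#'
#' @param buds data.frame with columns `bud_id`, `outer_length`,
#'   `inner_length`, `bud_length` (micrometres); label columns carried
#'   through.
#' @return data.frame with `outer_inner`, `outer_bud`, `inner_bud` appended.
#' @export
length_ratios <- function(buds) {
  stopifnot("bud_id" %in% names(buds))
  lens <- c("outer_length", "inner_length", "bud_length")
  for (l in intersect(lens, names(buds)))
    if (any(buds[[l]] <= 0, na.rm = TRUE)) stop("lengths must be positive")
  buds$outer_inner <- buds$outer_length / buds$inner_length
  buds$outer_bud <- buds$outer_length / buds$bud_length
  buds$inner_bud <- buds$inner_length / buds$bud_length
  buds
}

#' Absolute area growth per consecutive interval
#'
#' `delta = A(t1) - A(t0)` per consecutive observed pair of timepoints, per
#' sepal. Sepal areas at these stages grow monotonically, so negative deltas
#' indicate segmentation error; they are clamped to 0 and flagged.
#'
#' @param series data.frame with columns `bud_id`, `sepal_id`, `position`,
#'   `time_h`, `area_um2` (label columns carried through).
#' @return data.frame with one row per (sepal, interval): `t0`, `t1`,
#'   `delta_area`, `clamped`.
#' @export
absolute_growth <- function(series) {
  stopifnot(all(c("bud_id", "sepal_id", "time_h", "area_um2") %in% names(series)))
  if (any(series$area_um2 <= 0)) stop("areas must be positive")
  carry <- intersect(c("group", "position"), names(series))
  out <- do.call(rbind, lapply(split(series, series$sepal_id), function(d) {
    d <- d[order(d$time_h), ]
    if (any(diff(d$time_h) <= 0)) stop("times must be strictly increasing per sepal")
    if (nrow(d) < 2) return(NULL)
    delta <- diff(d$area_um2)
    clamped <- delta < 0
    res <- data.frame(bud_id = d$bud_id[1], sepal_id = d$sepal_id[1],
                      t0 = d$time_h[-nrow(d)], t1 = d$time_h[-1],
                      delta_area = pmax(delta, 0), clamped = clamped,
                      stringsAsFactors = FALSE)
    for (cc in carry) res[[cc]] <- d[[cc]][1]
    res
  }))
  rownames(out) <- NULL
  if (!is.null(out) && any(out$clamped))
    warning(sprintf("%d negative delta(s) clamped to 0", sum(out$clamped)))
  out
}

#' Per-sepal contributions to total bud growth in one interval
#'
#' Each sepal's absolute growth divided by the summed growth of all sepals
#' in the bud over the interval; normalizes for overall growth-rate
#' differences between buds and treatments.
#'
#' @param deltas named numeric vector of per-sepal `delta_area` for one
#'   bud-interval (>= 2 sepals).
#' @return named fractions summing to 1; all-NA with a warning when total
#'   growth is 0.
#' @export
growth_contributions <- function(deltas) {
  if (length(deltas) < 2) stop("need at least 2 sepals")
  total <- sum(deltas)
  if (total == 0) {
    warning("total growth is 0; contributions undefined")
    return(stats::setNames(rep(NA_real_, length(deltas)), names(deltas)))
  }
  deltas / total
}

#' Growth records (contributions and area ratios) for a full time series
#'
#' Convenience wrapper: per bud and consecutive interval, the per-sepal
#' growth contributions; per bud and timepoint, the outer/inner and
#' outer/lateral area ratios.
#'
#' @param series data.frame as in [absolute_growth()], with `position` in
#'   `outer`, `inner`, `lateral` (two inner sepals allowed).
#' @return list with `contributions` (long data.frame: bud_id, t0, t1,
#'   sepal_id, position, delta_area, contribution) and `ratios` (bud_id,
#'   time_h, ratio name, value).
#' @export
growth_records <- function(series) {
  ag <- absolute_growth(series)
  contrib <- do.call(rbind, lapply(split(ag, list(ag$bud_id, ag$t0), drop = TRUE),
    function(d) {
      if (nrow(d) < 2) return(NULL)
      fr <- growth_contributions(stats::setNames(d$delta_area, d$sepal_id))
      d$contribution <- as.numeric(fr)
      d
    }))
  rownames(contrib) <- NULL
  ratios <- do.call(rbind, lapply(
    split(series, list(series$bud_id, series$time_h), drop = TRUE),
    function(d) {
      r <- area_ratios(stats::setNames(d$area_um2, d$sepal_id), d$position)
      if (is.null(r)) return(NULL)
      data.frame(bud_id = d$bud_id[1], time_h = d$time_h[1],
                 ratio = names(r), value = as.numeric(r),
                 stringsAsFactors = FALSE)
    }))
  rownames(ratios) <- NULL
  list(contributions = contrib, ratios = ratios)
}

#' Outer/inner and outer/lateral area ratios at one timepoint
#'
#' Outer sepal area divided by inner sepal area; when a bud carries two
#' inner sepals their areas are first summed and treated as one sepal, so
#' the split does not inflate the outer/inner ratio. Lateral ratios are
#' reported per lateral sepal.
#'
#' @param areas named per-sepal areas at one timepoint.
#' @param positions per-sepal positions (`outer`, `inner`, `lateral`),
#'   aligned with `areas`; exactly one outer sepal required.
#' @return named vector: `outer_inner` (missing if no inner sepal) and
#'   `outer_lateral_<sepal>` per lateral.
#' @export
area_ratios <- function(areas, positions) {
  stopifnot(length(areas) == length(positions))
  outer <- areas[positions == "outer"]
  if (length(outer) != 1) stop("exactly one outer sepal required")
  inner_total <- sum(areas[positions == "inner"])
  out <- c(outer_inner = if (inner_total > 0) unname(outer) / inner_total
           else NA_real_)
  lats <- which(positions == "lateral")
  if (length(lats)) {
    lr <- unname(outer) / areas[lats]
    names(lr) <- paste0("outer_lateral_", names(areas)[lats])
    out <- c(out, lr)
  }
  out
}

#' Per-cell growth ratios between two timepoints
#'
#' Area ratio `A(t1)/A(t0)` per tracked cell via a lineage (parent-label)
#' map, mirroring per-cell heat maps of relative growth. Raw ratios are kept
#' and a display column clamped to the conventional heat-map range
#' \[0, 2.5\] is added. Cells without a lineage match are excluded with a
#' warning.
#'
#' @param areas_t0,areas_t1 named per-cell areas at the two timepoints.
#' @param lineage named character vector mapping t1 cell labels to t0 parent
#'   labels (a bijection on tracked cells); defaults to identity on shared
#'   names.
#' @param display_range display clamp bounds, default `c(0, 2.5)`.
#' @return data.frame `cell`, `parent`, `area_t0`, `area_t1`, `ratio`,
#'   `ratio_display`.
#' @export
cell_growth_ratios <- function(areas_t0, areas_t1, lineage = NULL,
                               display_range = c(0, 2.5)) {
  if (is.null(lineage)) {
    shared <- intersect(names(areas_t1), names(areas_t0))
    lineage <- stats::setNames(shared, shared)
  }
  if (anyDuplicated(lineage) || anyDuplicated(names(lineage)))
    stop("lineage map must be a bijection on tracked cells")
  tracked <- names(lineage)[names(lineage) %in% names(areas_t1) &
                              lineage %in% names(areas_t0)]
  dropped <- setdiff(names(areas_t1), tracked)
  if (length(dropped))
    warning(sprintf("%d untracked cell(s) excluded", length(dropped)))
  parent <- lineage[tracked]
  ratio <- as.numeric(areas_t1[tracked] / areas_t0[parent])
  data.frame(cell = tracked, parent = unname(parent),
             area_t0 = as.numeric(areas_t0[parent]),
             area_t1 = as.numeric(areas_t1[tracked]),
             ratio = ratio,
             ratio_display = pmin(pmax(ratio, display_range[1]), display_range[2]),
             row.names = NULL, stringsAsFactors = FALSE)
}
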