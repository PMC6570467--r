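#' Two-sided Mann-Whitney U p-value for two groups
#'
#' Wraps the Wilcoxon rank-sum test with the conventions used throughout the
#' workflow: the exact null distribution is used for small samples
#' (`length(x) + length(y) <= 12`) without ties; otherwise the normal
#' approximation with mid-rank tie correction and continuity correction is
#' used. Missing values are removed first.
#'
#' @param x,y numeric abundance vectors for the two groups; at least two
#'   non-missing values per group are required.
#' @return two-sided p-value in `[0, 1]`.
#' @export
mann_whitney_p <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least two non-missing values per group", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && (length(x) + length(y)) <= 12
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = TRUE)$p.value
  )
  min(1, max(0, p))
}

#' Two-sided Welch t-test p-value
#'
#' Welch's unequal-variance t-test with Satterthwaite degrees of freedom,
#' the stand-in test for transcriptomics (applied to log2 abundances by
#' [run_differential()]). Degenerate constant inputs are handled explicitly:
#' both groups constant and equal gives p = 1; both constant but different
#' gives p = 0.
#'
#' @inheritParams mann_whitney_p
#' @return two-sided p-value in `[0, 1]`.
#' @export
welch_t_p <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least two non-missing values per group", call. = FALSE)
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  p <- stats::t.test(x, y, var.equal = FALSE)$p.value
  min(1, max(0, p))
}

#' Group-mean fold change and direction
#'
#' Fold change is the ratio of the ERneg group mean to the ERpos group mean
#' on the linear abundance scale (arithmetic means by default; geometric
#' available). Direction is `"up"` when the ratio exceeds 1 (higher in
#' ERneg), `"down"` below 1, `"unchanged"` at exactly 1.
#'
#' @param x values of the ERneg group; `y` values of the ERpos group.
#' @param y see `x`.
#' @param method `"arithmetic"` (default) or `"geometric"` group means.
#' @return list with `ratio` (positive real) and `direction`.
#' @export
fold_change <- function(x, y, method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  gm <- function(v) exp(mean(log(v)))
  mx <- if (method == "arithmetic") mean(x) else gm(x)
  my <- if (method == "arithmetic") mean(y) else gm(y)
  if (!is.finite(mx) || !is.finite(my) || mx <= 0 || my <= 0)
    stop("group means must be strictly positive", call. = FALSE)
  ratio <- mx / my
  direction <- if (ratio > 1) "up" else if (ratio < 1) "down" else "unchanged"
  list(ratio = ratio, direction = direction)
}

#' Prevalence filter: keep features observed in enough samples of one group
#'
#' Retains features with at least `min_per_group` non-missing observations
#' in at least one of the two groups (the either-group rule): a protein seen
#' in six ERpos samples and zero ERneg samples is kept at `min_per_group =
#' 6`.
#'
#' @param om an [omics_matrix()].
#' @param min_per_group minimum non-missing observations required in either
#'   group (>= 1).
#' @return the filtered [omics_matrix()].
#' @export
prevalence_filter <- function(om, min_per_group = 6L) {
  stopifnot(inherits(om, "omics_matrix"))
  if (min_per_group < 1) stop("'min_per_group' must be >= 1", call. = FALSE)
  neg <- om$labels == "ERneg"
  n_neg <- rowSums(!is.na(om$values[, neg, drop = FALSE]))
  n_pos <- rowSums(!is.na(om$values[, !neg, drop = FALSE]))
  keep <- n_neg >= min_per_group | n_pos >= min_per_group
  omics_matrix(om$values[keep, , drop = FALSE], om$labels, om$platform,
               om$study_id)
}

#' Per-study differential statistics table
#'
#' Computes, for every feature of a labeled abundance matrix, a raw two-group
#' p-value (Mann-Whitney U or Welch t), the ERneg/ERpos fold change and its
#' direction. Welch tests are applied to log2-transformed abundances (the
#' transcriptomics convention); fold changes are always computed on the
#' linear scale. No multiple-testing correction is applied: the raw p-values
#' feed the downstream meta-analysis and set enrichment directly. Features
#' with too few observations or non-positive group means are skipped with a
#' collected warning, not an error.
#'
#' @param om an [omics_matrix()].
#' @param test `"mwu"` (Mann-Whitney U, the metabolomics/proteomics default)
#'   or `"welch"` (Welch t on log2 values, the transcriptomics stand-in).
#' @param fold_method passed to [fold_change()].
#' @return a `diff_table`: data frame with columns `feature_id`, `raw_p`,
#'   `fold_change`, `direction`, `test`, `n_neg`, `n_pos`, carrying the
#'   study id and platform as attributes and skipped features (with reasons)
#'   in `attr(, "skipped")`.
#' @export
run_differential <- function(om, test = c("mwu", "welch"),
                             fold_method = "arithmetic") {
  stopifnot(inherits(om, "omics_matrix"))
  test <- match.arg(test)
  neg <- om$labels == "ERneg"
  ids <- rownames(om$values)
  if (is.null(ids)) ids <- character(0)
  n <- length(ids)
  raw_p <- fc <- rep(NA_real_, n)
  dir <- rep(NA_character_, n)
  nn <- np <- rep(NA_integer_, n)
  skipped <- character(0)

  for (i in seq_len(n)) {
    x <- om$values[i, neg]
    y <- om$values[i, !neg]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      skipped[ids[i]] <- "fewer than two observations in a group"
      next
    }
    if (mean(x) <= 0 || mean(y) <= 0) {
      skipped[ids[i]] <- "non-positive group mean"
      next
    }
    p <- if (test == "mwu") mann_whitney_p(x, y)
         else welch_t_p(log2(x), log2(y))
    f <- fold_change(x, y, method = fold_method)
    raw_p[i] <- p
    fc[i] <- f$ratio
    dir[i] <- f$direction
    nn[i] <- length(x)
    np[i] <- length(y)
  }

  keep <- !is.na(raw_p)
  out <- data.frame(feature_id = ids[keep], raw_p = raw_p[keep],
                    fold_change = fc[keep], direction = dir[keep],
                    test = rep(test, sum(keep)), n_neg = nn[keep],
                    n_pos = np[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (length(skipped) > 0)
    warning(length(skipped), " feature(s) skipped (see attr 'skipped')",
            call. = FALSE)
  structure(out, study_id = om$study_id, platform = om$platform,
            skipped = skipped, class = c("diff_table", "data.frame"))
}

#' Significance summary counts for a differential table
#'
#' Tallies total features, altered features (`raw_p < alpha`), and the
#' up/down split of the altered features by fold-change direction.
#'
#' @param tbl a `diff_table` from [run_differential()].
#' @param alpha significance level in `(0, 1]`.
#' @return list with integer fields `total`, `altered`, `down`, `up`.
#' @export
summarize_counts <- function(tbl, alpha = 0.05) {
  if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]", call. = FALSE)
  sig <- tbl$raw_p < alpha
  list(total = nrow(tbl),
       altered = sum(sig),
       down = sum(sig & tbl$fold_change < 1),
       up = sum(sig & tbl$fold_change > 1))
}
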