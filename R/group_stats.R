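# group_stats: per-material DEI summaries, pairwise Wilcoxon rank-sum
# matrix, and material-category classification.

# Coerce the accepted group inputs to a named list of numeric vectors.
as_group_list <- function(groups, value_col = "mean_dei",
                          group_col = "material") {
  if (is.data.frame(groups)) {
    if (!all(c(group_col, value_col) %in% names(groups))) {
      stop(sprintf("data frame input needs columns '%s' and '%s'",
                   group_col, value_col), call. = FALSE)
    }
    # preserve first-appearance order rather than alphabetical
    f <- factor(groups[[group_col]], levels = unique(groups[[group_col]]))
    groups <- split(groups[[value_col]], f, drop = TRUE)
  }
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be a named list of numeric vectors or a data frame",
         call. = FALSE)
  }
  lapply(groups, function(g) {
    g <- as.numeric(g)
    if (length(g) < 1L) stop("each group must be nonempty", call. = FALSE)
    if (!all(is.finite(g))) stop("group values must be finite", call. = FALSE)
    g
  })
}

#' Summarize per-material DEI groups
#'
#' Sample mean, standard deviation (n - 1 denominator; `NA` for singleton
#' groups) and box-plot quartiles (type-7) of the per-pellet mean DEI values
#' of each material group.
#'
#' @param groups Named list of numeric vectors (one per material), or a data
#'   frame with `material` and `mean_dei` columns (e.g. pellet records with
#'   a material label attached).
#' @return Data frame with columns `material`, `n`, `mean`, `sd`, `min`,
#'   `q1`, `median`, `q3`, `max`.
#' @examples
#' summarize_groups(list(Fe = c(0.21, 0.22), Pb = c(0.008, 0.009)))
#' @export
summarize_groups <- function(groups) {
  gl <- as_group_list(groups)
  if (length(gl) < 1L) stop("at least one group required", call. = FALSE)
  rows <- mapply(function(name, g) {
    q <- stats::quantile(g, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(material = name, n = length(g), mean = mean(g),
               sd = if (length(g) > 1L) stats::sd(g) else NA_real_,
               min = min(g), q1 = q[1], median = q[2], q3 = q[3],
               max = max(g))
  }, names(gl), gl, SIMPLIFY = FALSE)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pairwise two-sided Wilcoxon rank-sum matrix
#'
#' For every unordered pair of material groups, a two-sided Wilcoxon
#' rank-sum test: exact enumeration when the combined sample size is at most
#' `exact_max_n` and the pooled values contain no ties, tie-corrected normal
#' approximation with continuity correction otherwise. The diagonal is fixed
#' at p = 1. Raw p-values are reported (as in the reference analysis); set
#' `p_adjust = "holm"` for a family-wise correction of the off-diagonal
#' p-values.
#'
#' @inheritParams summarize_groups
#' @param exact_max_n Combined-size ceiling for the exact branch (default 20).
#' @param alpha Significance level for the `significant` flags (default 0.05).
#' @param p_adjust Multiple-testing correction, `"none"` (default) or any
#'   method accepted by [stats::p.adjust()].
#' @return Object of class `wilcoxon_matrix`: list with symmetric matrices
#'   `p` (p-values), `statistic` (rank sum of the row group) and `method`
#'   ("exact" or "normal-approximation"), logical matrix `significant`, and
#'   `alpha`.
#' @export
wilcoxon_matrix <- function(groups, exact_max_n = 20, alpha = 0.05,
                            p_adjust = "none") {
  gl <- as_group_list(groups)
  k <- length(gl)
  if (k < 2L) stop("at least two groups required", call. = FALSE)
  nm <- names(gl)
  p <- matrix(1, k, k, dimnames = list(nm, nm))
  stat <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  method <- matrix("", k, k, dimnames = list(nm, nm))
  diag(method) <- "diagonal"
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      x <- gl[[a]]; y <- gl[[b]]
      ties <- anyDuplicated(c(x, y)) > 0L
      exact <- (length(x) + length(y)) <= exact_max_n && !ties
      wt <- suppressWarnings(stats::wilcox.test(
        x, y, alternative = "two.sided", exact = exact, correct = TRUE))
      p[a, b] <- p[b, a] <- wt$p.value
      # R reports the Mann-Whitney U; convert to the rank sum of group a
      rs <- unname(wt$statistic) + length(x) * (length(x) + 1) / 2
      stat[a, b] <- rs
      stat[b, a] <- sum(seq_len(length(x) + length(y))) - rs
      method[a, b] <- method[b, a] <-
        if (exact) "exact" else "normal-approximation"
    }
  }
  if (p_adjust != "none") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = p_adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  structure(list(p = p, statistic = stat, method = method,
                 significant = p < alpha & row(p) != col(p), alpha = alpha),
            class = "wilcoxon_matrix")
}

#' @export
print.wilcoxon_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Pairwise two-sided Wilcoxon rank-sum p-values (alpha = %g)\n",
              x$alpha))
  print(round(x$p, digits))
  invisible(x)
}

#' Classification boundaries for material categories
#'
#' Interval boundaries on per-pellet mean DEI separating the three
#' radiologically distinguishable categories. DEI thresholds are scanner-
#' and protocol-specific (steel moves from about 0.21 at 100/140 kVp to
#' about 0.30 at 80/140 kVp), so boundaries are configuration tied to a
#' named acquisition profile rather than constants in code. For the default
#' 100/140 kVp profile the steel boundary is the midpoint of the reference
#' copper (0.187) and steel (0.212) means.
#'
#' @param profile Acquisition profile name; `"paper-100-140"` is the default
#'   100/140 kVp protocol.
#' @param steel_min Lower DEI bound of the steel category.
#' @param copper_min Lower DEI bound of the copper category.
#' @param buffer Half-width of an "ambiguous" band around each boundary;
#'   values inside it classify as indeterminate. Default 0 (off).
#' @return List of class `classification_boundaries`.
#' @export
classification_boundaries <- function(profile = "paper-100-140",
                                      steel_min = 0.1995, copper_min = 0.1,
                                      buffer = 0) {
  if (copper_min >= steel_min) stop("copper_min must be < steel_min",
                                    call. = FALSE)
  if (buffer < 0) stop("buffer must be >= 0", call. = FALSE)
  structure(list(profile = profile, steel_min = steel_min,
                 copper_min = copper_min, buffer = buffer),
            class = "classification_boundaries")
}

#' Classify a pellet's material category from its mean DEI
#'
#' Maps mean DEI to one of three categories: `"steel"` (ferromagnetic --
#' the clinically actionable MRI-hazard flag), `"copper"`, or
#' `"high-Z indeterminate (Pb/W/Bi)"`. Lead, tungsten and bismuth have
#' nearly identical DEI at diagnostic energies and are never separated.
#' Values inside the configured ambiguity buffer around a boundary return
#' `"indeterminate"`.
#'
#' @param mean_dei Numeric vector of per-pellet mean DEI values.
#' @param boundaries A [classification_boundaries()] object.
#' @return Data frame with columns `mean_dei`, `category`, `ferromagnetic`.
#' @examples
#' classify_category(c(0.212, 0.187, 0.008))
#' @export
classify_category <- function(mean_dei,
                              boundaries = classification_boundaries()) {
  if (!all(is.finite(mean_dei))) stop("mean_dei must be finite", call. = FALSE)
  b <- boundaries
  category <- ifelse(mean_dei >= b$steel_min, "steel",
              ifelse(mean_dei >= b$copper_min, "copper",
                     "high-Z indeterminate (Pb/W/Bi)"))
  if (b$buffer > 0) {
    amb <- abs(mean_dei - b$steel_min) < b$buffer |
           abs(mean_dei - b$copper_min) < b$buffer
    category[amb] <- "indeterminate"
  }
  data.frame(mean_dei = mean_dei, category = category,
             ferromagnetic = category == "steel")
}
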