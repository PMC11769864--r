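# Trueness/precision evaluation (ISO 5725-1) and nonparametric group
# comparisons: descriptive summaries with t-based 95% CI, normality checks,
# Kruskal-Wallis across strategies, pairwise Mann-Whitney with Bonferroni
# correction for trueness, pairwise Brown-Forsythe dispersion tests for
# precision, and compact letter displays (uppercase = trueness family,
# lowercase = precision family).

.check_group_values <- function(values, min_n = 2L) {
  values <- as.double(values)
  if (any(!is.finite(values))) stop("non-finite values in group", call. = FALSE)
  if (length(values) < min_n) {
    stop("insufficient data: need at least ", min_n, " values, got ",
         length(values), call. = FALSE)
  }
  values
}

#' Descriptive trueness summary of one strategy group
#'
#' Mean, sample SD, median, range and the t-based 95% confidence interval of
#' the mean, `M +/- t(0.975, n-1) * SD / sqrt(n)`.
#'
#' @param values numeric deviations of one group (micrometres or degrees),
#'   n >= 2.
#' @return One-row data frame: `n`, `M`, `SD`, `MED`, `MIN`, `MAX`,
#'   `CI_lower`, `CI_upper`.
#' @export
summarize_group <- function(values) {
  values <- .check_group_values(values, 2L)
  n <- length(values)
  m <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt(0.975, n - 1) * s / sqrt(n)
  data.frame(n = n, M = m, SD = s, MED = stats::median(values),
             MIN = min(values), MAX = max(values),
             CI_lower = m - half, CI_upper = m + half)
}

#' Normality tests for one group
#'
#' Shapiro-Wilk plus the Kolmogorov-Smirnov check in two flavours: the
#' Lilliefors variant (normal with estimated parameters, the composite
#' hypothesis actually at stake) and the plain one-sample KS against the
#' normal with the sample mean and SD plugged in. A group is flagged
#' non-normal when Shapiro-Wilk p < 0.05.
#'
#' @param values numeric sample, n >= 3, not constant.
#' @return Data frame with one row per test: `test`, `statistic`, `p`,
#'   plus attribute `non_normal` (logical).
#' @export
test_normality <- function(values) {
  values <- .check_group_values(values, 3L)
  if (stats::sd(values) < .Machine$double.eps^0.5 * max(1, abs(mean(values)))) {
    stop("insufficient variation: normality tests are undefined for a ",
         "constant sample", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  lf <- nortest::lillie.test(values)
  ks <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values))
  )
  out <- data.frame(
    test = c("shapiro_wilk", "ks_lilliefors", "ks_plugin"),
    statistic = c(unname(sw$statistic), unname(lf$statistic), unname(ks$statistic)),
    p = c(sw$p.value, lf$p.value, ks$p.value)
  )
  attr(out, "non_normal") <- sw$p.value < 0.05
  out
}

#' Kruskal-Wallis test across strategy groups
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees of
#' freedom. If every observation in every group is identical there is no
#' variation to rank: H = 0 and p = 1 by convention.
#'
#' @param groups list of >= 2 numeric vectors (same parameter, one per
#'   strategy), each with n >= 2.
#' @return One-row data frame: `test`, `statistic` (H), `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  groups <- lapply(groups, .check_group_values, min_n = 2L)
  all_values <- unlist(groups, use.names = FALSE)
  if (length(unique(all_values)) == 1L) {
    return(data.frame(test = "kruskal_wallis", statistic = 0,
                      df = length(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(groups)
  data.frame(test = "kruskal_wallis", statistic = unname(kt$statistic),
             df = unname(kt$parameter), p = kt$p.value)
}

.bonferroni_threshold <- function(family_alpha, m) {
  if (m < 1L) stop("comparison count m must be >= 1", call. = FALSE)
  round(family_alpha / m, 3L)
}

# two-sided Mann-Whitney p; exact when both samples are small and tie-free,
# normal approximation with continuity and tie correction otherwise
.mw_pvalue <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && min(length(x), length(y)) <= 8L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Pairwise Mann-Whitney comparisons with Bonferroni correction
#'
#' Two-sided U tests for every pair of groups; a pair is significant when its
#' p value falls below `family_alpha / m`, reported to 3 decimals
#' (0.05 / 3 -> 0.017).
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @param family_alpha family-wise significance level (default 0.05).
#' @param m number of comparisons in the Bonferroni family (default: the
#'   number of pairs, i.e. 3 when comparing the 3 levels of one factor).
#' @return Data frame with one row per pair: `group1`, `group2`, `U`, `p`,
#'   `exact`, `threshold`, `significant`.
#' @export
pairwise_mannwhitney <- function(groups, family_alpha = 0.05, m = NULL) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("G", seq_along(groups))
  groups <- lapply(groups, .check_group_values, min_n = 1L)
  pairs <- utils::combn(length(groups), 2L)
  if (is.null(m)) m <- ncol(pairs)
  thr <- .bonferroni_threshold(family_alpha, m)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    r <- .mw_pvalue(groups[[i]], groups[[j]])
    data.frame(group1 = nm[i], group2 = nm[j], U = r$U, p = r$p,
               exact = r$exact, threshold = thr,
               significant = r$p < thr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Brown-Forsythe: one-way dispersion test on absolute deviations from the
# group medians (car::leveneTest with center = median)
.bf_pvalue <- function(x, y) {
  values <- c(x, y)
  grp <- factor(rep(c("a", "b"), c(length(x), length(y))))
  dev <- abs(values - stats::ave(values, grp, FUN = stats::median))
  if (stats::sd(dev) < .Machine$double.eps^0.5) {
    return(list(F = 0, p = 1))
  }
  lt <- car::leveneTest(values ~ grp, center = stats::median)
  list(F = lt[1L, "F value"], p = lt[1L, "Pr(>F)"])
}

#' Pairwise precision comparisons (Brown-Forsythe)
#'
#' Precision per ISO 5725-1 is summarized by the group SD; whether two
#' strategies differ in precision is tested with the Brown-Forsythe test
#' (a Levene-type test on absolute deviations from the group medians, robust
#' to non-normal deviations), at the same Bonferroni-adjusted threshold as
#' the trueness comparisons. Identical dispersions (e.g. a group against a
#' shifted copy of itself) give p = 1.
#'
#' @inheritParams pairwise_mannwhitney
#' @return Data frame with one row per pair: `group1`, `group2`, `SD1`,
#'   `SD2`, `F`, `p`, `threshold`, `significant`.
#' @export
compare_precision <- function(groups, family_alpha = 0.05, m = NULL) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("G", seq_along(groups))
  groups <- lapply(groups, .check_group_values, min_n = 3L)
  pairs <- utils::combn(length(groups), 2L)
  if (is.null(m)) m <- ncol(pairs)
  thr <- .bonferroni_threshold(family_alpha, m)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    r <- .bf_pvalue(groups[[i]], groups[[j]])
    data.frame(group1 = nm[i], group2 = nm[j],
               SD1 = stats::sd(groups[[i]]), SD2 = stats::sd(groups[[j]]),
               F = r$F, p = r$p, threshold = thr,
               significant = r$p < thr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compact letter display from pairwise comparisons
#'
#' Insert-and-absorb letter assignment: two groups share at least one letter
#' if and only if their pairwise comparison is non-significant. Uppercase
#' letters are conventionally used for the trueness family and lowercase for
#' the precision family.
#'
#' @param pairwise data frame with columns `group1`, `group2`, `significant`
#'   covering every pair of `group_names`.
#' @param group_names character vector of all group names.
#' @param case `"upper"` or `"lower"`.
#' @return Named character vector of letter strings, one per group.
#' @export
assign_letters <- function(pairwise, group_names, case = c("upper", "lower")) {
  case <- match.arg(case)
  k <- length(group_names)
  have <- paste(pmin(match(pairwise$group1, group_names),
                     match(pairwise$group2, group_names)),
                pmax(match(pairwise$group1, group_names),
                     match(pairwise$group2, group_names)))
  want <- utils::combn(k, 2L)
  if (k > 1L && !all(paste(want[1L, ], want[2L, ]) %in% have)) {
    stop("incomplete pairwise matrix: every pair of groups must be compared",
         call. = FALSE)
  }
  sets <- list(seq_len(k))
  sig <- pairwise[pairwise$significant, , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    i <- match(sig$group1[r], group_names)
    j <- match(sig$group2[r], group_names)
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    new_sets <- Filter(length, new_sets)
    # absorb sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (u in seq_along(new_sets)) {
      for (v in seq_along(new_sets)) {
        if (u != v && keep[v] &&
            all(new_sets[[u]] %in% new_sets[[v]]) &&
            (length(new_sets[[u]]) < length(new_sets[[v]]) || u > v)) {
          keep[u] <- FALSE
          break
        }
      }
    }
    sets <- new_sets[keep]
  }
  # order letters by the first group they contain
  sets <- sets[order(vapply(sets, min, integer(1L)))]
  alphabet <- if (case == "upper") LETTERS else letters
  if (length(sets) > length(alphabet)) {
    alphabet <- c(alphabet, paste0(alphabet, rep(alphabet, each = length(alphabet))))
  }
  out <- vapply(seq_len(k), function(g) {
    paste(alphabet[which(vapply(sets, function(s) g %in% s, logical(1L)))],
          collapse = ", ")
  }, character(1L))
  stats::setNames(out, group_names)
}

.report_parameters <- c("deltaL_um", "VE_um", "VE_x_um", "VE_y_um", "VE_z_um",
                        "alpha_overall_deg", "alpha_coronal_deg",
                        "alpha_axial_deg")

#' Build the full accuracy report
#'
#' For every deviation parameter: per-strategy descriptive summaries,
#' normality tests, the Kruskal-Wallis test across strategies, pairwise
#' Mann-Whitney trueness comparisons (on the signed deviations) and pairwise
#' Brown-Forsythe precision comparisons, with compact letter displays
#' (uppercase trueness, lowercase precision).
#'
#' @param records data frame of per-scan measurements with a `strategy`
#'   column and the eight deviation columns (`deltaL_um`, `VE_um`,
#'   `VE_x_um`, `VE_y_um`, `VE_z_um`, `alpha_overall_deg`,
#'   `alpha_coronal_deg`, `alpha_axial_deg`).
#' @param family_alpha family-wise significance level (default 0.05).
#' @param m Bonferroni comparison count; the default 3 matches comparing the
#'   three levels of one design factor (threshold 0.017).
#' @return An object of class `accuracy_report`: list with `summaries`,
#'   `normality`, `kruskal`, `trueness_tests`, `precision_tests`, `letters`
#'   (data frame with `parameter`, `strategy`, `trueness`, `precision`),
#'   `family_alpha`, `m`, `threshold`.
#' @export
build_report <- function(records, family_alpha = 0.05, m = 3) {
  if (!is.data.frame(records) || !"strategy" %in% names(records)) {
    stop("records must be a data frame with a 'strategy' column", call. = FALSE)
  }
  missing_cols <- setdiff(.report_parameters, names(records))
  if (length(missing_cols) > 0L) {
    stop("records are missing parameter columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  strategies <- unique(records$strategy)
  if (length(strategies) < 2L) {
    stop("need measurements from at least 2 strategies, got ",
         length(strategies), call. = FALSE)
  }
  thr <- .bonferroni_threshold(family_alpha, m)
  summaries <- list(); normality <- list(); kruskal <- list()
  trueness <- list(); precision <- list(); letters <- list()
  for (param in .report_parameters) {
    groups <- lapply(stats::setNames(nm = strategies), function(s) {
      records[[param]][records$strategy == s]
    })
    summ <- do.call(rbind, lapply(strategies, function(s) {
      cbind(data.frame(parameter = param, strategy = s,
                       stringsAsFactors = FALSE),
            summarize_group(groups[[s]]))
    }))
    norm <- do.call(rbind, lapply(strategies, function(s) {
      cbind(data.frame(parameter = param, strategy = s,
                       stringsAsFactors = FALSE),
            test_normality(groups[[s]]))
    }))
    kw <- cbind(data.frame(parameter = param, stringsAsFactors = FALSE),
                kruskal_wallis(groups))
    tt <- cbind(data.frame(parameter = param, stringsAsFactors = FALSE),
                pairwise_mannwhitney(groups, family_alpha, m))
    pt <- cbind(data.frame(parameter = param, stringsAsFactors = FALSE),
                compare_precision(groups, family_alpha, m))
    lt <- data.frame(parameter = param, strategy = strategies,
                     trueness = unname(assign_letters(tt, strategies, "upper")),
                     precision = unname(assign_letters(pt, strategies, "lower")),
                     stringsAsFactors = FALSE)
    summaries[[param]] <- summ; normality[[param]] <- norm
    kruskal[[param]] <- kw; trueness[[param]] <- tt
    precision[[param]] <- pt; letters[[param]] <- lt
  }
  structure(list(summaries = do.call(rbind, c(summaries, make.row.names = FALSE)),
                 normality = do.call(rbind, c(normality, make.row.names = FALSE)),
                 kruskal = do.call(rbind, c(kruskal, make.row.names = FALSE)),
                 trueness_tests = do.call(rbind, c(trueness, make.row.names = FALSE)),
                 precision_tests = do.call(rbind, c(precision, make.row.names = FALSE)),
                 letters = do.call(rbind, c(letters, make.row.names = FALSE)),
                 family_alpha = family_alpha, m = m, threshold = thr),
            class = "accuracy_report")
}

#' Rendered report tables
#'
#' Splits the report into the two publication-shaped tables: linear
#' deviations (micrometres) and angular deviations (degrees), one block per
#' strategy with M, SD, MED, MIN, MAX, CI95 and the significance letters.
#'
#' @param report an [build_report()] result.
#' @return List with data frames `linear` and `angular`.
#' @export
report_tables <- function(report) {
  stopifnot(inherits(report, "accuracy_report"))
  tab <- merge(report$summaries, report$letters,
               by = c("parameter", "strategy"), sort = FALSE)
  tab <- tab[, c("parameter", "strategy", "n", "M", "SD", "MED", "MIN", "MAX",
                 "CI_lower", "CI_upper", "trueness", "precision")]
  linear_params <- c("deltaL_um", "VE_um", "VE_x_um", "VE_y_um", "VE_z_um")
  ord <- function(d, params) {
    d <- d[order(match(d$strategy, unique(d$strategy)),
                 match(d$parameter, params)), ]
    rownames(d) <- NULL
    d
  }
  list(linear = ord(tab[tab$parameter %in% linear_params, ], linear_params),
       angular = ord(tab[!tab$parameter %in% linear_params, ],
                     setdiff(.report_parameters, linear_params)))
}

#' @export
print.accuracy_report <- function(x, ...) {
  ns <- length(unique(x$summaries$strategy))
  cat(sprintf("<accuracy_report> %d strategies, %d parameters, Bonferroni threshold %.3f\n",
              ns, length(unique(x$summaries$parameter)), x$threshold))
  sig <- x$trueness_tests[x$trueness_tests$significant, ]
  cat(sprintf("  significant trueness pairs: %d; significant precision pairs: %d\n",
              nrow(sig), sum(x$precision_tests$significant)))
  invisible(x)
}
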