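# Group assignment and nonparametric comparisons.

#' Grouping configuration
#'
#' Categorization breaks for the four obesity groupings: BMI (kg/m2),
#' abdominal circumference (cm), visceral fat (kg, dichotomized) and total
#' fat percentage. Interval conventions are half-open at integer break
#' labels: BMI `[25,30) / [30,35) / [35,Inf)`; abdominal circumference
#' `[81,94) / [94,105) / [105,Inf)` (reported as "81-93 / 94-104 / >104");
#' visceral fat `<=16` vs `>16`; fat percentage `<36 / [36,46] / >46`.
#'
#' @param bmi_breaks,ac_breaks,fat_percent_breaks strictly increasing breaks.
#' @param visceral_fat_cutoff dichotomization threshold in kg.
#' @return an object of class `grouping_config`.
#' @export
grouping_config <- function(bmi_breaks = c(25, 30, 35),
                            ac_breaks = c(81, 94, 105),
                            visceral_fat_cutoff = 16,
                            fat_percent_breaks = c(36, 46)) {
  for (b in list(bmi_breaks, ac_breaks, fat_percent_breaks)) {
    if (any(diff(b) <= 0)) {
      abort("breaks must be strictly increasing", "urinmr_validation_error")
    }
  }
  structure(list(bmi_breaks = bmi_breaks, ac_breaks = ac_breaks,
                 visceral_fat_cutoff = visceral_fat_cutoff,
                 fat_percent_breaks = fat_percent_breaks),
            class = "grouping_config")
}

#' Assign obesity group labels to subjects
#'
#' Adds four factor columns (`bmi_group`, `ac_group`, `vf_group`,
#' `fat_group`) to the subject table, using the conventions of
#' [grouping_config()]. Values outside the lowest break (or missing) become
#' `NA` and are excluded from that scheme only.
#'
#' @param subjects a subject data.frame with columns `bmi`,
#'   `abdominal_circumference`, `visceral_fat`, `fat_percent`.
#' @param cfg a [grouping_config()].
#' @return the subject table with the four group columns appended.
#' @examples
#' s <- data.frame(bmi = 25, abdominal_circumference = 95,
#'                 visceral_fat = 17.52, fat_percent = 40)
#' assign_groups(s)[, c("bmi_group", "vf_group")]
#' @export
assign_groups <- function(subjects, cfg = grouping_config()) {
  need <- c("bmi", "abdominal_circumference", "visceral_fat", "fat_percent")
  for (f in need) {
    if (!f %in% names(subjects)) subjects[[f]] <- NA_real_
  }
  b <- cfg$bmi_breaks
  subjects$bmi_group <- cut(subjects$bmi, c(b, Inf), right = FALSE,
                            labels = c(sprintf("%g-%g", b[1], b[2]),
                                       sprintf("%g-%g", b[2], b[3]),
                                       sprintf(">=%g", b[3])))
  a <- cfg$ac_breaks
  subjects$ac_group <- cut(subjects$abdominal_circumference, c(a, Inf),
                           right = FALSE,
                           labels = c(sprintf("%g-%g", a[1], a[2] - 1),
                                      sprintf("%g-%g", a[2], a[3] - 1),
                                      sprintf(">%g", a[3] - 1)))
  v <- cfg$visceral_fat_cutoff
  subjects$vf_group <- factor(ifelse(is.na(subjects$visceral_fat), NA,
                                     ifelse(subjects$visceral_fat <= v,
                                            sprintf("<=%g", v), sprintf(">%g", v))),
                              levels = c(sprintf("<=%g", v), sprintf(">%g", v)))
  fp <- cfg$fat_percent_breaks
  subjects$fat_group <- cut(subjects$fat_percent,
                            c(-Inf, fp[1], fp[2], Inf), right = TRUE,
                            labels = c(sprintf("<%g", fp[1]),
                                       sprintf("%g-%g", fp[1], fp[2]),
                                       sprintf(">%g", fp[2])))
  # fat convention: <36 is exclusive, [36,46] inclusive both sides
  subjects$fat_group[!is.na(subjects$fat_percent) &
                       subjects$fat_percent == fp[1]] <-
    sprintf("%g-%g", fp[1], fp[2])
  subjects
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples, with midrank
#' handling of ties. The p-value is exact (via [stats::wilcox.test()]'s
#' exact null distribution) when `n_x * n_y <= 400` and there are no ties,
#' and otherwise uses the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param x,y numeric samples.
#' @return list with `U` (the U statistic of `x`), `p_value`, and `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    abort("both samples must be non-empty", "urinmr_validation_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) * length(y) <= 400) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

# Dunn pairwise z tests on the pooled midranks, Bonferroni-adjusted.
dunn_posthoc <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (n - 1))
  pairs <- utils::combn(levels(groups), 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = NA_real_, p_unadjusted = NA_real_,
                    p_adjusted = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ng[[g1]] + 1 / ng[[g2]]))
    z <- (rbar[[g1]] - rbar[[g2]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    out$z[j] <- z
    out$p_unadjusted[j] <- p
    out$p_adjusted[j] <- min(1, m * p)
  }
  out
}

#' Kruskal-Wallis omnibus test with Dunn post-hoc
#'
#' Tie-corrected Kruskal-Wallis H (chi-square reference) across k groups via
#' [stats::kruskal.test()]; when the omnibus p-value is below `alpha` and
#' there are at least three groups, Dunn pairwise z tests on the pooled
#' midranks locate the differences, with Bonferroni adjustment. Groups of
#' identical constant values (H undefined through total ties) return
#' `H = 0, p = 1` by convention.
#'
#' @param groups list of numeric samples (each of size >= 2; at least 2
#'   groups).
#' @param alpha omnibus significance gate for the post-hoc step.
#' @return list with `H`, `p_value`, `posthoc` (data.frame or `NULL`),
#'   `group_summary` (per-group n, mean, sd).
#' @export
kruskal_wallis_dunn <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) {
    abort("at least 2 groups are required", "urinmr_validation_error")
  }
  if (any(vapply(groups, length, integer(1)) < 2)) {
    abort("each group must contain at least 2 observations",
          "urinmr_validation_error")
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))),
                   labels = if (is.null(names(groups)))
                     paste0("g", seq_along(groups)) else names(groups))
  summary <- data.frame(
    group = levels(labels),
    n = as.integer(table(labels)),
    mean = as.numeric(tapply(values, labels, mean)),
    sd = as.numeric(tapply(values, labels, stats::sd)),
    stringsAsFactors = FALSE
  )
  if (length(unique(values)) == 1L) {
    return(list(H = 0, p_value = 1, posthoc = NULL, group_summary = summary))
  }
  kt <- stats::kruskal.test(values, labels)
  posthoc <- NULL
  if (length(groups) >= 3 && is.finite(kt$p.value) && kt$p.value < alpha) {
    posthoc <- dunn_posthoc(values, labels)
  }
  list(H = unname(kt$statistic), p_value = kt$p.value, posthoc = posthoc,
       group_summary = summary)
}

#' Compare proportions across groups
#'
#' Chi-square test without continuity correction by default; Fisher's exact
#' test (two-sided by the point-probability rule) is selected for 2x2
#' tables with any expected count below 5.
#'
#' @param table a matrix of nonnegative integer counts (rows = outcome,
#'   columns = groups).
#' @return list with `test` (`"chi-square"` or `"fisher"`), `statistic`
#'   (chi-square only), `p_value`.
#' @examples
#' compare_proportions(matrix(c(3, 0, 0, 3), 2))  # Fisher, p = 0.1
#' @export
compare_proportions <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be nonnegative integers", "urinmr_validation_error")
  }
  if (sum(table) == 0) {
    abort("all counts are zero", "urinmr_validation_error")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  use_fisher <- all(dim(table) == c(2L, 2L)) && any(expected < 5)
  if (use_fisher) {
    ft <- stats::fisher.test(table)
    list(test = "fisher", statistic = NULL, p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    list(test = "chi-square", statistic = unname(ct$statistic),
         p_value = ct$p.value)
  }
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks with the t-distribution approximation
#' for the p-value (via [stats::cor.test()] with `exact = FALSE`).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p_value`.
#' @examples
#' spearman_rho(1:5, c(1, 3, 2, 5, 4))$rho  # 0.8
#' @export
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3) {
    abort("x and y must have equal length >= 3", "urinmr_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined for constant input", "urinmr_validation_error")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Group comparison tables for all four obesity groupings
#'
#' For every metabolite signal, compares concentrations across each grouping
#' scheme: Mann-Whitney for the two visceral-fat groups, Kruskal-Wallis
#' (with Dunn post-hoc when significant) for the three BMI, abdominal
#' circumference and fat-percentage groups. Per-group means and standard
#' deviations accompany each raw p-value; no multiplicity correction is
#' applied across metabolites (an FDR column can be requested).
#'
#' @param conc a [quantify_panel()] concentration table.
#' @param subjects a subject table already labeled by [assign_groups()],
#'   with `id` matching the concentration table's sample ids.
#' @param fdr add a Benjamini-Hochberg adjusted column per scheme.
#' @return named list of data.frames (`bmi`, `ac`, `vf`, `fat`), one row
#'   per metabolite signal.
#' @export
run_group_tables <- function(conc, subjects, fdr = FALSE) {
  stopifnot(inherits(conc, "concentration_table"))
  missing_ids <- setdiff(conc$sample_ids, subjects$id)
  extra_ids <- setdiff(subjects$id, conc$sample_ids)
  if (length(missing_ids) || length(extra_ids)) {
    abort(sprintf("sample ids do not align; missing from subjects: [%s]; missing from concentrations: [%s]",
                  paste(missing_ids, collapse = ", "),
                  paste(extra_ids, collapse = ", ")),
          "urinmr_alignment_error")
  }
  subjects <- subjects[match(conc$sample_ids, subjects$id), ]
  schemes <- c(bmi = "bmi_group", ac = "ac_group", vf = "vf_group",
               fat = "fat_group")
  out <- list()
  for (sc in names(schemes)) {
    col <- schemes[[sc]]
    if (!col %in% names(subjects)) {
      abort(sprintf("subjects lack grouping column '%s'; run assign_groups() first", col),
            "urinmr_validation_error")
    }
    g <- droplevels(as.factor(subjects[[col]]))
    keep <- !is.na(g)
    lv <- levels(droplevels(g[keep]))
    rows <- lapply(conc$metabolites, function(met) {
      v <- conc$matrix[keep, met]
      gg <- droplevels(g[keep])
      ok <- !is.na(v)
      v <- v[ok]; gg <- droplevels(gg[ok])
      # groups too small to test are dropped from this scheme only
      counts <- table(gg)
      usable <- names(counts)[counts >= 2]
      ok2 <- gg %in% usable
      v <- v[ok2]; gg <- droplevels(gg[ok2])
      row <- list(metabolite = met)
      for (l in levels(gg)) {
        row[[paste0("mean_", l)]] <- mean(v[gg == l])
        row[[paste0("sd_", l)]] <- stats::sd(v[gg == l])
      }
      if (nlevels(gg) < 2) {
        row$test <- NA_character_
        row$statistic <- NA_real_
        row$p_value <- NA_real_
      } else if (nlevels(gg) == 2) {
        mw <- mann_whitney(v[gg == levels(gg)[1]], v[gg == levels(gg)[2]])
        row$test <- "Mann-Whitney"
        row$statistic <- mw$U
        row$p_value <- mw$p_value
      } else {
        kw <- kruskal_wallis_dunn(split(v, gg))
        row$test <- "Kruskal-Wallis"
        row$statistic <- kw$H
        row$p_value <- kw$p_value
        if (!is.null(kw$posthoc)) {
          for (j in seq_len(nrow(kw$posthoc))) {
            row[[sprintf("dunn_%s_vs_%s", kw$posthoc$group1[j],
                         kw$posthoc$group2[j])]] <- kw$posthoc$p_adjusted[j]
          }
        }
      }
      row
    })
    all_names <- unique(unlist(lapply(rows, names)))
    tab <- do.call(rbind, lapply(rows, function(r) {
      r[setdiff(all_names, names(r))] <- NA
      as.data.frame(r[all_names], stringsAsFactors = FALSE,
                    check.names = FALSE)
    }))
    if (fdr) tab$p_fdr <- stats::p.adjust(tab$p_value, method = "BH")
    out[[sc]] <- tab
  }
  out
}
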