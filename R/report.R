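#' Group/condition comparison report over pipeline metrics
#'
#' Applies the study's comparison structure to a table of per-animal,
#' per-condition metrics: unpaired two-sided t-tests between the two
#' groups within each condition, paired two-sided t-tests between
#' baseline and learning within each group, and Pearson correlation
#' panels over the learning-condition values (pooled and per group).
#' Raw and Bonferroni-adjusted p-values are both reported for the group
#' comparisons (family = number of conditions tested per metric).
#'
#' Animals missing one condition are dropped from the paired tests
#' (listwise deletion) with a logged notice; cells missing entirely are
#' flagged, never imputed.
#'
#' @param metrics data.frame with columns `animal`, `group` (exactly two
#'   levels), `condition` (`"baseline"`/`"learning"`) and one or more
#'   numeric metric columns.
#' @param correlations list of character pairs `c(x, y)` to correlate on
#'   learning-condition rows; defaults cover the sleep-quality panels
#'   (spindle count vs arousal index, arousal index vs NREM duration and
#'   NREM:REM ratio, proliferation covariate vs NREM:REM ratio, NREM
#'   duration and spindle count vs route efficiency) when the columns
#'   are present.
#' @return object of class `somno_report`: data.frames `group_tests`,
#'   `learning_tests`, `correlations` and a character vector `notices`.
#' @export
build_report <- function(metrics, correlations = NULL) {
  need <- c("animal", "group", "condition")
  if (!all(need %in% names(metrics)) ||
      any(is.na(metrics$group)) || any(is.na(metrics$animal)))
    stop("design incomplete")
  groups <- sort(unique(as.character(metrics$group)))
  if (length(groups) != 2) stop("design incomplete: need exactly two groups")
  conds <- intersect(c("baseline", "learning"),
                     unique(as.character(metrics$condition)))
  if (length(conds) == 0) stop("design incomplete: no known conditions")

  metric_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric,
                                               logical(1))],
                         need)
  notices <- character(0)

  ## between-group tests within condition
  gt <- list()
  for (m in metric_cols) for (cc in conds) {
    sub <- metrics[metrics$condition == cc, c("group", m)]
    sub <- sub[stats::complete.cases(sub), ]
    xa <- sub[[m]][sub$group == groups[1]]
    xb <- sub[[m]][sub$group == groups[2]]
    if (length(xa) < 2 || length(xb) < 2) next
    res <- tryCatch(unpaired_t(xa, xb), error = function(e) NULL)
    if (is.null(res)) next
    gt[[length(gt) + 1L]] <- data.frame(
      metric = m, condition = cc,
      group1 = groups[1], group2 = groups[2],
      n1 = length(xa), n2 = length(xb),
      effect = res$effect, statistic = res$statistic, df = res$df,
      p_raw = res$p_value, stringsAsFactors = FALSE)
  }
  group_tests <- if (length(gt)) do.call(rbind, gt) else
    data.frame(metric = character(0))
  if (nrow(group_tests) > 0) {
    group_tests$p_bonferroni <- NA_real_
    for (m in unique(group_tests$metric)) {
      sel <- group_tests$metric == m
      group_tests$p_bonferroni[sel] <-
        bonferroni(group_tests$p_raw[sel], sum(sel))
    }
  }

  ## within-group baseline vs learning (paired by animal)
  lt <- list()
  if (all(c("baseline", "learning") %in% conds)) {
    for (m in metric_cols) for (gg in groups) {
      sub <- metrics[metrics$group == gg, c("animal", "condition", m)]
      wide <- merge(sub[sub$condition == "baseline", c("animal", m)],
                    sub[sub$condition == "learning", c("animal", m)],
                    by = "animal", suffixes = c("_b", "_l"))
      full <- wide[stats::complete.cases(wide), ]
      dropped <- length(unique(sub$animal)) - nrow(full)
      if (dropped > 0)
        notices <- c(notices, sprintf(
          "paired test %s / %s: dropped %d animal(s) with missing cells",
          m, gg, dropped))
      if (nrow(full) < 2) next
      res <- tryCatch(paired_t(full[[paste0(m, "_l")]],
                               full[[paste0(m, "_b")]]),
                      error = function(e) NULL)
      if (is.null(res)) next
      lt[[length(lt) + 1L]] <- data.frame(
        metric = m, group = gg, n = nrow(full),
        effect = res$effect, statistic = res$statistic, df = res$df,
        p = res$p_value, stringsAsFactors = FALSE)
    }
  }
  learning_tests <- if (length(lt)) do.call(rbind, lt) else
    data.frame(metric = character(0))

  ## correlation panels on learning-condition values
  if (is.null(correlations)) {
    default_pairs <- list(
      c("spindle_count", "arousal_index"),
      c("arousal_index", "nrem_minutes"),
      c("arousal_index", "nrem_rem_ratio"),
      c("ki67", "nrem_rem_ratio"),
      c("nrem_minutes", "route_efficiency"),
      c("spindle_count", "route_efficiency"))
    correlations <- Filter(function(p) all(p %in% metric_cols),
                           default_pairs)
  }
  learn <- metrics[metrics$condition == (if ("learning" %in% conds)
    "learning" else conds[1]), , drop = FALSE]
  cr <- list()
  for (pair in correlations) {
    scopes <- c(list(all = learn),
                stats::setNames(lapply(groups, function(gg)
                  learn[learn$group == gg, , drop = FALSE]), groups))
    for (sc in names(scopes)) {
      sub <- scopes[[sc]][, pair]
      sub <- sub[stats::complete.cases(sub), ]
      if (nrow(sub) < 3) next
      res <- tryCatch(pearson_r(sub[[1]], sub[[2]]),
                      error = function(e) NULL)
      if (is.null(res)) next
      cr[[length(cr) + 1L]] <- data.frame(
        x = pair[1], y = pair[2], scope = sc, n = res$n,
        r = res$r, p = res$p, stringsAsFactors = FALSE)
    }
  }
  correlations_tab <- if (length(cr)) do.call(rbind, cr) else
    data.frame(x = character(0))

  structure(list(group_tests = group_tests,
                 learning_tests = learning_tests,
                 correlations = correlations_tab,
                 notices = notices),
            class = "somno_report")
}

#' @export
print.somno_report <- function(x, ...) {
  cat("<somno_report>\n")
  cat("  group tests:", nrow(x$group_tests), " | paired tests:",
      nrow(x$learning_tests), " | correlations:",
      nrow(x$correlations), "\n")
  if (length(x$notices)) cat("  notices:\n",
                             paste("   -", x$notices, collapse = "\n"), "\n")
  invisible(x)
}
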