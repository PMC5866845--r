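# One-way ANOVA with Student-Newman-Keuls (SNK) post-hoc comparisons,
# the procedure used for all group comparisons in this package.

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance, as in the
#' SigmaPlot/Prism defaults): between/within sum-of-squares decomposition
#' with the p-value from the F distribution. The degenerate case of zero
#' within-group variance with unequal means is reported explicitly as
#' `F = Inf, p = 0`.
#'
#' @param data Data frame with the response and grouping columns.
#' @param value,group Column names (strings) of the response and the group
#'   label; defaults `"value"` and `"group"`.
#' @return A list: `f`, `df_between`, `df_within`, `p`, `ms_within`, and
#'   `groups` (per-group n and mean).
#' @examples
#' d <- data.frame(group = rep(c("a", "b", "c"), each = 3),
#'                 value = c(1, 2, 3, 2, 3, 4, 3, 4, 5))
#' one_way_anova(d)
#' @export
one_way_anova <- function(data, value = "value", group = "group") {
  g <- prepare_groups(data, value, group)
  k <- nrow(g$stats)
  n <- length(g$y)
  grand <- mean(g$y)
  ss_between <- sum(g$stats$n * (g$stats$mean - grand)^2)
  ss_within <- sum((g$y - g$stats$mean[match(g$grp, g$stats$group)])^2)
  df_b <- k - 1L
  df_w <- n - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  if (ms_w == 0) {
    f <- if (ss_between == 0) 0 else Inf
    p <- if (ss_between == 0) 1 else 0
  } else {
    f <- ms_b / ms_w
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  list(f = f, df_between = df_b, df_within = df_w, p = p,
       ms_within = ms_w, groups = g$stats)
}

#' Student-Newman-Keuls post-hoc comparisons
#'
#' Stepwise multiple comparison of group means using the studentized range
#' distribution. Means are ranked; each pair is tested with
#' `q = |mean_i - mean_j| / sqrt(MSW / n_h)` (with `n_h` the harmonic mean
#' of the pair's group sizes) against the critical value
#' `qtukey(1 - alpha, r, df_within)` where the stretch `r` is the number of
#' ordered means the pair spans. Testing proceeds from the widest stretch
#' down; every pair lying inside a non-significant span is declared
#' non-significant without testing (the SNK step-down rule).
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return Tibble with one row per pair: `group1`, `group2` (group1 has the
#'   smaller mean), `mean_diff`, `q_statistic`, `stretch`, `critical_q`,
#'   `significant`, `blocked` (TRUE when the decision was forced by an
#'   enclosing non-significant span).
#' @examples
#' d <- data.frame(group = rep(c("a", "b", "c"), each = 4),
#'                 value = c(rnorm(8), rnorm(4, 5)))
#' snk_posthoc(d)
#' @export
snk_posthoc <- function(data, value = "value", group = "group",
                        alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  fit <- one_way_anova(data, value, group)
  st <- fit$groups[order(fit$groups$mean), ]
  k <- nrow(st)
  df_w <- fit$df_within
  ms_w <- fit$ms_within

  rows <- vector("list", k * (k - 1L) / 2L)
  idx <- 0L
  nonsig_spans <- list()  # pairs (i, j) of ordered positions found non-significant
  for (stretch in seq(k, 2L)) {
    crit <- stats::qtukey(1 - alpha, nmeans = stretch, df = df_w)
    for (i in seq_len(k - stretch + 1L)) {
      j <- i + stretch - 1L
      blocked <- any(vapply(nonsig_spans,
                            function(s) s[1] <= i && j <= s[2], logical(1)))
      n_h <- 2 / (1 / st$n[i] + 1 / st$n[j])
      diff <- st$mean[j] - st$mean[i]
      q <- if (ms_w == 0) {
        if (diff == 0) 0 else Inf
      } else diff / sqrt(ms_w / n_h)
      sig <- !blocked && q > crit
      if (!sig) nonsig_spans <- c(nonsig_spans, list(c(i, j)))
      idx <- idx + 1L
      rows[[idx]] <- tibble::tibble(
        group1 = st$group[i], group2 = st$group[j], mean_diff = diff,
        q_statistic = q, stretch = stretch, critical_q = crit,
        significant = sig, blocked = blocked)
    }
  }
  dplyr::bind_rows(rows)
}

prepare_groups <- function(data, value, group) {
  if (!all(c(value, group) %in% names(data))) {
    stop(sprintf("data needs columns '%s' and '%s'", value, group),
         call. = FALSE)
  }
  y <- data[[value]]
  grp <- as.character(data[[group]])
  keep <- !is.na(y) & !is.na(grp)
  y <- y[keep]; grp <- grp[keep]
  if (!is.numeric(y)) stop("response must be numeric", call. = FALSE)
  st <- tibble::tibble(group = grp, y = y) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$y), .groups = "drop")
  if (nrow(st) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(st$n < 2L)) stop("every group needs n >= 2", call. = FALSE)
  list(y = y, grp = grp, stats = st)
}
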