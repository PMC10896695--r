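#' Biological-replicate means
#'
#' Collapses per-track values to one mean per biological replicate within
#' each group — the unit on which all between-group statistics operate.
#'
#' @param data A data frame of per-track values.
#' @param value,group,replicate Columns holding the value, the group label
#'   and the replicate label (tidy-eval).
#' @return Tibble (`group`, `replicate`, `mean`, `n_tracks`).
#' @examples
#' d <- tibble::tibble(
#'   g = "a", rep = c(1, 1, 1, 2, 2), v = c(1, 2, 3, 4, 6)
#' )
#' replicate_means(d, v, g, rep)
#' @export
replicate_means <- function(data, value, group, replicate) {
  value <- enquo(value)
  group <- enquo(group)
  replicate <- enquo(replicate)
  out <- data |>
    dplyr::group_by(group = !!group, replicate = !!replicate) |>
    dplyr::summarise(
      mean = mean(!!value, na.rm = FALSE),
      n_tracks = dplyr::n(),
      .groups = "drop"
    )
  bad <- out[is.na(out$mean) | out$n_tracks == 0, ]
  if (nrow(bad)) {
    abort(sprintf(
      "Replicate '%s' of group '%s' is empty or all-NA.",
      bad$replicate[1], bad$group[1]
    ))
  }
  out
}

# Dunn's post hoc z statistics from pooled ranks with tie correction.
# z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j)),
# T = sum(t^3 - t) / (12 (N - 1)) over tie groups.
dunn_z <- function(values, labels) {
  r <- rank(values)
  n_tot <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  groups <- split(r, labels)
  means <- vapply(groups, mean, numeric(1))
  sizes <- vapply(groups, length, numeric(1))
  pairs <- utils::combn(names(groups), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]
    g2 <- pairs[2, j]
    se <- sqrt(
      (n_tot * (n_tot + 1) / 12 - tie_corr) * (1 / sizes[g1] + 1 / sizes[g2])
    )
    z <- (means[g1] - means[g2]) / se
    tibble(
      group1 = g1, group2 = g2, statistic = unname(z),
      p_value = 2 * pnorm(-abs(unname(z)))
    )
  })
}

#' Dunn's post hoc test
#'
#' Pairwise rank comparisons following a Kruskal-Wallis omnibus test: z
#' statistics from pooled ranks with tie correction, two-sided normal p
#' values, and an optional multiplicity adjustment (Holm by default; the
#' raw values are always reported alongside).
#'
#' @param data Data frame of values (typically replicate means).
#' @param value,group Columns holding the value and group label (tidy-eval).
#' @param adjustment `"holm"` (default) or `"none"`.
#' @return Tibble (`group1`, `group2`, `statistic`, `p_value`,
#'   `p_adjusted`).
#' @export
dunn_posthoc <- function(data, value, group, adjustment = c("holm", "none")) {
  adjustment <- match.arg(adjustment)
  value <- enquo(value)
  group <- enquo(group)
  v <- dplyr::pull(data, !!value)
  g <- as.character(dplyr::pull(data, !!group))
  if (length(unique(g)) < 2) abort("Need at least two groups.")
  out <- dunn_z(v, g)
  out$p_adjusted <- p.adjust(out$p_value, method = adjustment)
  out
}

#' Normality-gated omnibus comparison on replicate means
#'
#' Reproduces the study's statistical pipeline: per-track values are first
#' collapsed to biological-replicate means; each group is then assessed for
#' normality by Shapiro-Wilk. If every group looks normal the parametric
#' branch is taken (Student's t test for two groups, one-way ANOVA with
#' Tukey's post hoc for more); if any group fails the gate — or is too
#' small to test (< 3 values) or has zero variance — the rank-based branch
#' is used (Kruskal-Wallis with Dunn's post hoc). The gate is applied
#' jointly: one non-normal group switches the whole family.
#'
#' @param data Data frame of per-track (or per-unit) values.
#' @param value,group Columns holding the value and group label (tidy-eval).
#' @param replicate Optional replicate column; when supplied, statistics
#'   run on replicate means, otherwise on the values as given.
#' @param alpha Significance level of the Shapiro-Wilk gate (default 0.05).
#' @param adjustment Adjustment for Dunn p values (`"holm"` or `"none"`).
#' @return An object of class `transport_stat`: `test`, `statistic`,
#'   `p_value`, `pairwise` tibble, `normality` tibble, `branch`
#'   (`"parametric"` or `"rank"`), `status` (`"ok"` or
#'   `"degenerate-variance"`).
#' @examples
#' d <- tibble::tibble(
#'   g = rep(c("a", "b", "c"), each = 4),
#'   v = c(1, 2, 3, 4, 2, 3, 4, 5, 10, 11, 12, 13)
#' )
#' res <- omnibus_test(d, v, g)
#' glance(res)
#' tidy(res)
#' @export
omnibus_test <- function(data, value, group, replicate = NULL,
                         alpha = 0.05, adjustment = c("holm", "none")) {
  adjustment <- match.arg(adjustment)
  value <- enquo(value)
  group <- enquo(group)
  replicate <- enquo(replicate)
  if (!rlang::quo_is_null(replicate)) {
    rm <- data |>
      dplyr::group_by(group = !!group, replicate = !!replicate) |>
      dplyr::summarise(mean = mean(!!value), .groups = "drop")
    if (anyNA(rm$mean)) abort("A replicate has missing values.")
    d <- tibble(group = as.character(rm$group), value = rm$mean)
  } else {
    d <- tibble(
      group = as.character(dplyr::pull(data, !!group)),
      value = dplyr::pull(data, !!value)
    )
  }
  groups <- split(d$value, d$group)
  if (length(groups) < 2) abort("Need at least two groups.")
  if (sd(d$value) == 0) {
    return(structure(
      list(
        test = "none", statistic = NA_real_, p_value = NA_real_,
        pairwise = tibble(), normality = tibble(),
        branch = NA_character_, status = "degenerate-variance",
        data = d
      ),
      class = "transport_stat"
    ))
  }
  normality <- purrr::imap_dfr(groups, function(v, g) {
    if (length(v) < 3 || sd(v) == 0) {
      tibble(group = g, n = length(v), shapiro_p = NA_real_, normal = FALSE)
    } else {
      p <- shapiro.test(v)$p.value
      tibble(group = g, n = length(v), shapiro_p = p, normal = p >= alpha)
    }
  })
  parametric <- all(normality$normal)
  if (parametric && length(groups) == 2) {
    ht <- t.test(groups[[1]], groups[[2]], var.equal = TRUE)
    res <- list(
      test = "t", statistic = unname(ht$statistic), p_value = ht$p.value,
      pairwise = tibble(
        group1 = names(groups)[1], group2 = names(groups)[2],
        statistic = unname(ht$statistic), p_value = ht$p.value,
        p_adjusted = ht$p.value
      ),
      branch = "parametric"
    )
  } else if (parametric) {
    fit <- aov(value ~ group, data = d)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$group
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    res <- list(
      test = "anova", statistic = an[1, "F value"],
      p_value = an[1, "Pr(>F)"],
      pairwise = tibble(
        group1 = vapply(pairs, `[`, character(1), 2),
        group2 = vapply(pairs, `[`, character(1), 1),
        statistic = unname(tk[, "diff"]),
        p_value = unname(tk[, "p adj"]),
        p_adjusted = unname(tk[, "p adj"])
      ),
      branch = "parametric"
    )
  } else {
    kw <- kruskal.test(d$value, factor(d$group))
    res <- list(
      test = "kruskal-wallis", statistic = unname(kw$statistic),
      p_value = kw$p.value,
      pairwise = dunn_posthoc(
        tibble(v = d$value, g = d$group), v, g,
        adjustment = adjustment
      ),
      branch = "rank"
    )
  }
  structure(
    c(res, list(normality = normality, status = "ok", data = d)),
    class = "transport_stat"
  )
}

#' @export
print.transport_stat <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<transport_stat> status: %s\n", x$status))
    return(invisible(x))
  }
  cat(sprintf(
    "<transport_stat> %s branch: %s test, statistic %.3f, p = %.4g\n",
    x$branch, x$test, x$statistic, x$p_value
  ))
  print(x$pairwise)
  invisible(x)
}

#' @rdname omnibus_test
#' @param x A `transport_stat` object.
#' @param ... Unused.
#' @export
tidy.transport_stat <- function(x, ...) {
  x$pairwise
}

#' @rdname omnibus_test
#' @export
glance.transport_stat <- function(x, ...) {
  tibble(
    test = x$test, statistic = x$statistic, p_value = x$p_value,
    branch = x$branch %||% NA_character_, status = x$status
  )
}
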