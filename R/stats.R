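#' Osmotic-stability record
#'
#' Counts of non-ruptured protoplasts before (`n0`) and 30 minutes after
#' (`n30`) an osmotic downshift, with the stability ratio n30 / n0.
#'
#' @param n0 Count before the osmotic change (> 0).
#' @param n30 Count after 30 min (>= 0).
#' @param condition,mannitol_M,incubation_h Optional condition labels.
#' @return Object of class `stability_record`.
#' @export
stability_record <- function(n0, n30, condition = NA_character_,
                             mannitol_M = NA_real_, incubation_h = NA_real_) {
  check_number(n0, "n0", 0, strict = TRUE)
  check_number(n30, "n30", 0)
  structure(list(n0 = n0, n30 = n30, condition = condition,
                 mannitol_M = mannitol_M, incubation_h = incubation_h),
            class = "stability_record")
}

#' @export
print.stability_record <- function(x, ...) {
  cat(sprintf("<stability_record> N0 = %d, N30 = %d, stability = %.3f\n",
              as.integer(x$n0), as.integer(x$n30), x$n30 / x$n0))
  invisible(x)
}

#' Osmotic stability ratio
#'
#' The fraction of protoplasts remaining unruptured 30 minutes after an
#' osmotic downshift, N30 / N0. Because the two counts come from different
#' aliquots of the same suspension, values slightly above 1 can occur and
#' are returned with a warning.
#'
#' @param record A [stability_record()].
#' @return The ratio N30 / N0.
#' @export
osmotic_stability <- function(record) {
  stopifnot(inherits(record, "stability_record"))
  if (record$n0 <= 0)
    stop_cwrq("N0 must be positive", "cwrq_config_error")
  r <- record$n30 / record$n0
  if (r > 1)
    warning("osmotic stability > 1: N30 exceeds N0 (counts from different aliquots)")
  r
}

new_group_comparison <- function(method, statistic, p_value, groups, n,
                                 extra = list()) {
  structure(c(list(method = method, statistic = statistic,
                   p_value = p_value, groups = groups, n = n), extra),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s vs %s, statistic = %.4g, p = %.4g %s\n",
              x$method, x$groups[1L], x$groups[2L], x$statistic, x$p_value,
              significance_stars(x$p_value)))
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent samples. U is computed with
#' midranks. When the pooled sample has no ties and `n_a + n_b <= 12`, the
#' two-sided p-value is exact, by enumeration of all label assignments
#' (p = 2 * min(P(U <= u), P(U >= u)), capped at 1); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b Numeric samples (each nonempty).
#' @param labels Group labels, length 2.
#' @return A `group_comparison` with the U statistic, p-value and the
#'   approximation used (`exact` element).
#' @export
mann_whitney <- function(a, b, labels = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L)
    stop_cwrq("both samples must be nonempty", "cwrq_stat_error")
  if (any(!is.finite(c(a, b))))
    stop_cwrq("samples must be finite", "cwrq_stat_error")
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)                      # midranks
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(pooled))
  mu <- na * nb / 2
  if (!ties && N <= 12L) {
    sets <- utils::combn(N, na)
    allU <- apply(sets, 2L, function(ix) sum(rk[ix])) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(allU <= U), mean(allU >= U)))
    exact <- TRUE
  } else {
    tt <- table(pooled)
    sigma2 <- na * nb / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    exact <- FALSE
  }
  new_group_comparison("Mann-Whitney", U, p, labels, c(na, nb),
                       list(exact = exact))
}

#' Student's t test (two-sided, equal variance)
#'
#' Classical pooled-variance two-sample t test.
#'
#' @param a,b Numeric samples, each with n >= 2.
#' @param labels Group labels, length 2.
#' @return A `group_comparison` with t, p and degrees of freedom (`df`).
#' @export
students_t <- function(a, b, labels = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop_cwrq("each sample needs n >= 2", "cwrq_stat_error")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop_cwrq("zero pooled variance: t statistic undefined", "cwrq_stat_error")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  new_group_comparison("Student's t", unname(ht$statistic), ht$p.value,
                       labels, c(length(a), length(b)),
                       list(df = unname(ht$parameter)))
}

#' Tukey-Kramer all-pairs comparison
#'
#' All pairwise comparisons of group means with the pooled within-group
#' variance and the Tukey-Kramer standard error for unequal group sizes:
#' q_ij = |m_i - m_j| / sqrt(s2/2 * (1/n_i + 1/n_j)), with p-values from
#' the studentized-range distribution on (N - k) degrees of freedom. With
#' two groups this reduces (q = t * sqrt(2)) to the pooled-variance t test.
#' A compact letter display at level `alpha` is included: groups sharing no
#' letter differ significantly.
#'
#' @param groups Named list of numeric samples (>= 2 groups, each n >= 2).
#' @param alpha Significance level for the letter display (default 0.05).
#' @return Object of class `tukey_kramer`: data.frame of pairwise
#'   comparisons, the letters, pooled variance and df.
#' @export
tukey_kramer <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_cwrq("need at least two groups", "cwrq_stat_error")
  if (is.null(names(groups)) || anyNA(names(groups)) || any(names(groups) == ""))
    names(groups) <- sprintf("group_%d", seq_along(groups))
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L))
    stop_cwrq("each group needs n >= 2", "cwrq_stat_error")
  m <- vapply(groups, mean, numeric(1))
  ss <- vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))
  df <- sum(n) - k
  s2 <- sum(ss) / df
  pairs <- utils::combn(k, 2L)
  cmp <- data.frame(group1 = names(groups)[pairs[1L, ]],
                    group2 = names(groups)[pairs[2L, ]],
                    diff = m[pairs[1L, ]] - m[pairs[2L, ]],
                    stringsAsFactors = FALSE)
  se <- sqrt(s2 / 2 * (1 / n[pairs[1L, ]] + 1 / n[pairs[2L, ]]))
  cmp$q <- ifelse(se > 0, abs(cmp$diff) / se, ifelse(cmp$diff == 0, 0, Inf))
  cmp$p_value <- ifelse(is.infinite(cmp$q), 0,
                        stats::ptukey(cmp$q, nmeans = k, df = df,
                                      lower.tail = FALSE))
  rownames(cmp) <- NULL
  letters_out <- cld_letters(names(groups), m, cmp, alpha)
  structure(list(comparisons = cmp, letters = letters_out,
                 means = m, n = n, pooled_variance = s2, df = df,
                 alpha = alpha),
            class = "tukey_kramer")
}

#' @export
print.tukey_kramer <- function(x, ...) {
  cat(sprintf("<tukey_kramer> %d groups, pooled s2 = %.4g, df = %d\n",
              length(x$means), x$pooled_variance, x$df))
  df <- x$comparisons
  df$stars <- vapply(df$p_value, significance_stars, character(1))
  print(df, ...)
  cat("letters (alpha =", x$alpha, "):",
      paste(names(x$letters), x$letters, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Compact letter display: maximal cliques of the non-significance graph,
# ordered by group mean, each clique labelled with one letter.
cld_letters <- function(group_names, means, cmp, alpha) {
  k <- length(group_names)
  adj <- matrix(FALSE, k, k, dimnames = list(group_names, group_names))
  diag(adj) <- TRUE
  for (i in seq_len(nrow(cmp))) {
    if (cmp$p_value[i] >= alpha) {
      adj[cmp$group1[i], cmp$group2[i]] <- TRUE
      adj[cmp$group2[i], cmp$group1[i]] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  cl <- igraph::max_cliques(g)
  cl <- lapply(cl, function(v) group_names[as.integer(v)])
  ord <- order(vapply(cl, function(v) min(means[v]), numeric(1)))
  cl <- cl[ord]
  lab <- stats::setNames(rep("", k), group_names)
  for (i in seq_along(cl))
    lab[cl[[i]]] <- paste0(lab[cl[[i]]], letters[i])
  lab
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return r in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L)
    stop_cwrq("x and y must have equal length >= 3", "cwrq_stat_error")
  if (any(!is.finite(c(x, y))))
    stop_cwrq("inputs must be finite", "cwrq_stat_error")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_cwrq("correlation undefined for zero variance", "cwrq_stat_error")
  stats::cor(x, y)
}

#' Significance stars
#'
#' The figure-caption convention for these endpoints: `"**"` for p < 0.01,
#' `"*"` for 0.01 <= p < 0.05, `""` otherwise.
#'
#' @param p A p-value.
#' @return A string.
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}
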