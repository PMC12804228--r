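#' Tukey-Kramer all-pairs comparison
#'
#' All pairwise mean comparisons between labelled groups using the
#' studentized range distribution, with the Kramer correction for unequal
#' sample sizes: for groups i and j,
#' \deqn{q = |\bar y_i - \bar y_j| / \sqrt{ (MSE/2)(1/n_i + 1/n_j) }}
#' with MSE the pooled within-group mean square over all k groups and
#' N - k error degrees of freedom. p-values come from the studentized
#' range distribution with k groups; the family-wise error rate across all
#' pairs is controlled at `alpha`. With equal group sizes this reduces to
#' the classical Tukey HSD.
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation (>= 2 groups, each with >= 2
#'   values).
#' @param alpha family-wise significance level (study convention: 0.05).
#' @return object of class `tukey_table` (a data frame): one row per
#'   unordered pair with `group_i`, `group_j`, `diff` (mean_i - mean_j),
#'   `se`, `q`, `p`, `significant`; attributes `mse`, `df`, `k`, `alpha`,
#'   `q_critical`.
#' @export
tukey_kramer <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  gl <- sort(unique(groups))
  k <- length(gl)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  ns <- vapply(gl, function(g) sum(groups == g), integer(1L))
  if (any(ns < 2L))
    stop("every group needs >= 2 values (degenerate: ",
         paste(gl[ns < 2L], collapse = ", "), ")", call. = FALSE)
  means <- vapply(gl, function(g) mean(values[groups == g]), numeric(1L))
  ss_within <- sum(vapply(gl, function(g) {
    v <- values[groups == g]
    sum((v - mean(v))^2)
  }, numeric(1L)))
  N <- length(values)
  df <- N - k
  mse <- ss_within / df

  pairs <- utils::combn(k, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(c2) {
    i <- pairs[1L, c2]; j <- pairs[2L, c2]
    d <- means[i] - means[j]
    se <- sqrt((mse / 2) * (1 / ns[i] + 1 / ns[j]))
    if (se == 0) {
      q <- if (d == 0) 0 else Inf
      p <- if (d == 0) 1 else .Machine$double.xmin  # numerical floor
    } else {
      q <- abs(d) / se
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    }
    data.frame(group_i = gl[i], group_j = gl[j], diff = d, se = se,
               q = q, p = p, significant = p < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, mse = mse, df = df, k = k, alpha = alpha,
            q_critical = stats::qtukey(1 - alpha, nmeans = k, df = df),
            class = c("tukey_table", "data.frame"))
}

#' @export
print.tukey_table <- function(x, digits = 4, ...) {
  cat(sprintf("Tukey-Kramer pairwise comparisons (k=%d, df=%d, alpha=%g, q_crit=%.3f)\n",
              attr(x, "k"), attr(x, "df"), attr(x, "alpha"),
              attr(x, "q_critical")))
  df <- as.data.frame(x)
  df$p <- format.pval(df$p, digits = digits)
  df$significant <- ifelse(df$significant, "*", "")
  print(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Box plot with a significance panel
#'
#' Per-group box plots (1.5 x IQR whiskers, outliers retained) with the
#' Tukey-Kramer comparison result on the right: pairs sharing a letter are
#' not significantly different.
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation.
#' @param alpha significance level for the letter display.
#' @param ylab y-axis label.
#' @param ... passed to [graphics::boxplot()].
#' @return the [tukey_kramer()] table, invisibly.
#' @export
plot_group_boxes <- function(values, groups, alpha = 0.05, ylab = "value",
                             ...) {
  groups <- factor(groups)
  tk <- tukey_kramer(values, groups, alpha = alpha)
  graphics::boxplot(values ~ groups, range = 1.5, ylab = ylab, ...)
  letters_map <- significance_letters(tk)
  graphics::mtext(letters_map[levels(groups)], side = 3, at =
                    seq_along(levels(groups)), line = 0.2, cex = 0.9)
  invisible(tk)
}

# compact letter display: greedy clique cover over the non-significant graph
significance_letters <- function(tk) {
  gl <- sort(unique(c(tk$group_i, tk$group_j)))
  k <- length(gl)
  ns <- matrix(TRUE, k, k, dimnames = list(gl, gl))
  for (r in seq_len(nrow(tk)))
    if (tk$significant[r])
      ns[tk$group_i[r], tk$group_j[r]] <- ns[tk$group_j[r], tk$group_i[r]] <- FALSE
  letters_out <- stats::setNames(rep("", k), gl)
  lab <- 0L
  covered <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j < i || !ns[i, j] || covered[i, j]) next
    clique <- union(i, j)
    for (cand in setdiff(seq_len(k), clique))
      if (all(ns[cand, clique])) clique <- c(clique, cand)
    lab <- lab + 1L
    letters_out[clique] <- paste0(letters_out[clique], letters[lab])
    covered[clique, clique] <- TRUE
  }
  letters_out[letters_out == ""] <- letters[lab + seq_len(sum(letters_out == ""))]
  letters_out
}
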