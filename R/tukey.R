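#' Tukey-Kramer condition grouping with compact letters
#'
#' Compares the mean response across the distinct (FRR, TFR) conditions of a
#' run table by all pairwise Tukey-Kramer tests on the pooled within-condition
#' variance: the studentised-range statistic for conditions i, j is
#' `q = |m_i - m_j| / sqrt(s2/2 * (1/n_i + 1/n_j))` with `N - g` pooled degrees
#' of freedom (the Kramer form handles unequal replicate counts; with equal n
#' it is the classic Tukey HSD). Conditions are then labelled with a compact
#' letter display by the insert-and-absorb algorithm in order of descending
#' mean: conditions sharing a letter are not significantly different at
#' `alpha`.
#'
#' If the pooled variance is exactly zero the grouping degenerates to exact
#' comparison of means (equal means share a letter) and a condition is raised
#' as a message.
#'
#' @param runs a run table.
#' @param response response column to group on (e.g. `"pdi"`, `"zeta_mv"`).
#' @param alpha family-wise significance level, default 0.05.
#' @param digits decimals for the reported condition means (display only).
#' @return A data frame of class `tukey_groups` with columns `condition`,
#'   `frr`, `tfr`, `n`, `mean`, `letters`, ordered by descending mean;
#'   attributes `n_classes` (number of letter columns), `pooled_sd`, `df` and
#'   `p_matrix` (pairwise Tukey-Kramer p-values).
#' @examples
#' tukey_groups(pdm_runs(), "pdi")
#' @export
tukey_groups <- function(runs, response, alpha = 0.05, digits = 2) {
  stopifnot(is.data.frame(runs))
  if (!response %in% names(runs)) {
    stop_invalid("no response column '", response, "'")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop_invalid("'alpha' must be in (0, 1)")
  }
  keep <- !is.na(runs[[response]])
  y <- runs[[response]][keep]
  cond <- interaction(runs$frr[keep], runs$tfr[keep], drop = TRUE)
  g <- nlevels(cond)
  if (g < 2) stop_invalid("need at least two distinct conditions")
  n_i <- as.integer(table(cond))
  if (any(n_i < 2)) {
    stop_invalid("every condition needs at least two observations")
  }
  m_i <- as.numeric(tapply(y, cond, mean))
  sse <- sum((y - ave(y, cond))^2)
  df <- length(y) - g
  s2 <- sse / df

  frr_i <- as.numeric(tapply(runs$frr[keep], cond, `[`, 1))
  tfr_i <- as.numeric(tapply(runs$tfr[keep], cond, `[`, 1))

  pmat <- matrix(1, g, g)
  if (s2 > 0) {
    for (i in seq_len(g - 1)) {
      for (j in seq(i + 1, g)) {
        se <- sqrt(s2 / 2 * (1 / n_i[i] + 1 / n_i[j]))
        q <- abs(m_i[i] - m_i[j]) / se
        pmat[i, j] <- pmat[j, i] <- ptukey(q, g, df, lower.tail = FALSE)
      }
    }
    sig <- pmat < alpha
  } else {
    message("pooled within-condition variance is zero; ",
            "grouping by exact equality of means")
    sig <- abs(outer(m_i, m_i, "-")) > 0
  }
  diag(sig) <- FALSE

  ord <- order(-m_i)
  letters_by_cond <- cld_insert_absorb(sig[ord, ord, drop = FALSE])

  out <- data.frame(
    condition = sprintf("FRR = %.1f TFR = %.1f", frr_i[ord], tfr_i[ord]),
    frr = frr_i[ord], tfr = tfr_i[ord], n = n_i[ord],
    mean = round(m_i[ord], digits), letters = letters_by_cond$labels,
    stringsAsFactors = FALSE
  )
  attr(out, "mean_full") <- m_i[ord]
  attr(out, "n_classes") <- letters_by_cond$n_classes
  attr(out, "pooled_sd") <- sqrt(s2)
  attr(out, "df") <- df
  attr(out, "alpha") <- alpha
  pm <- pmat[ord, ord, drop = FALSE]
  dimnames(pm) <- list(out$condition, out$condition)
  attr(out, "p_matrix") <- pm
  class(out) <- c("tukey_groups", "data.frame")
  out
}

# Compact letter display by insert-and-absorb (Piepho 2004 style).
# `sig` is a logical matrix of significant pairs, rows/cols ordered by
# descending mean. Returns one letter string per item in that order.
cld_insert_absorb <- function(sig) {
  n <- nrow(sig)
  cols <- list(rep(TRUE, n)) # each column: logical membership vector
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (!sig[i, j]) next
        newcols <- list()
        changed <- FALSE
        for (col in cols) {
          if (col[i] && col[j]) {
            # split the offending column into one without i, one without j
            a <- col; a[i] <- FALSE
            b <- col; b[j] <- FALSE
            newcols <- c(newcols, list(a, b))
            changed <- TRUE
          } else {
            newcols <- c(newcols, list(col))
          }
        }
        if (changed) {
          # absorb: drop any column whose members are a subset of another's
          keep <- rep(TRUE, length(newcols))
          for (u in seq_along(newcols)) {
            for (v in seq_along(newcols)) {
              if (u == v || !keep[u] || !keep[v]) next
              if (all(newcols[[v]][newcols[[u]]])) {     # u subset of v
                if (all(newcols[[u]] == newcols[[v]])) { # exact duplicate
                  if (u > v) keep[u] <- FALSE
                } else {
                  keep[u] <- FALSE
                }
              }
            }
          }
          cols <- newcols[keep]
        }
      }
    }
  }
  # order columns by their first (highest-mean) member, label A, B, C, ...
  first <- vapply(cols, function(col) which(col)[1], 1L)
  cols <- cols[order(first)]
  labs <- make.unique(c(LETTERS, paste0("Z", seq_len(max(0, length(cols) - 26)))))
  labels <- vapply(seq_len(n), function(i) {
    paste0(labs[which(vapply(cols, `[`, TRUE, i))], collapse = "")
  }, "")
  list(labels = labels, n_classes = length(cols))
}

#' @export
print.tukey_groups <- function(x, ...) {
  cat(sprintf(
    "Tukey-Kramer grouping at the %.0f%% confidence level (%d letter class%s)\n",
    100 * (1 - attr(x, "alpha")), attr(x, "n_classes"),
    if (attr(x, "n_classes") == 1) "" else "es"
  ))
  cat("Conditions sharing a letter are not significantly different.\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Paired t-test for stability of a characteristic
#'
#' Two-sided paired t-test on `after - before`, as used to judge whether a
#' liposome property (e.g. size months after production) changed. Identical
#' vectors give `t = 0, p = 1`; a constant non-zero difference has no
#' within-pair variability, so the p-value is reported at its exact limit of
#' zero with a warning.
#'
#' @param before,after numeric vectors of equal length `>= 2`.
#' @return A list with `t`, `p`, `mean_difference` (after minus before), `df`
#'   and a 95% confidence interval for the mean difference.
#' @examples
#' paired_t(c(50, 60, 70), c(52, 59, 71))
#' @export
paired_t <- function(before, after) {
  if (!is.numeric(before) || !is.numeric(after) ||
      length(before) != length(after) || length(before) < 2 ||
      anyNA(before) || anyNA(after)) {
    stop_invalid("'before' and 'after' must be equal-length numeric vectors ",
                 "of length >= 2 without missing values")
  }
  d <- after - before
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p = 1, mean_difference = 0,
                  df = length(d) - 1, conf_int = c(0, 0)))
    }
    warning("all differences identical and non-zero: ",
            "p-value reported at its exact limit of 0", call. = FALSE)
    return(list(t = sign(mean(d)) * Inf, p = 0, mean_difference = mean(d),
                df = length(d) - 1, conf_int = c(mean(d), mean(d))))
  }
  tt <- t.test(after, before, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_difference = unname(tt$estimate), df = unname(tt$parameter),
       conf_int = as.numeric(tt$conf.int))
}
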