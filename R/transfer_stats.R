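# Measurement statistics used throughout the study: conjugative transfer
# frequency, fold change, plating survival rate, pooled-variance t test, and
# one-way ANOVA with Tukey-Kramer post hoc grouping rendered as a compact
# letter display.

#' Conjugative transfer frequency
#'
#' The frequency of transfer is the number of transconjugant CFU per donor
#' CFU. Input is one row per biological replicate.
#'
#' @param assay `data.frame` with columns `donor_cfu_per_ml` and
#'   `transconjugant_cfu_per_ml` (optionally `strain`).
#' @return `list(per_replicate, mean, sd, n)`; `per_replicate` is the vector
#'   of transconjugant/donor ratios.
#' @examples
#' transferFrequency(data.frame(donor_cfu_per_ml = c(1e7, 2e7),
#'                              transconjugant_cfu_per_ml = c(1e4, 3e4)))
#' @export
transferFrequency <- function(assay) {
  need <- c("donor_cfu_per_ml", "transconjugant_cfu_per_ml")
  if (!is.data.frame(assay) || !all(need %in% names(assay)))
    stop("assay must be a data.frame with columns ", paste(need, collapse = ", "))
  if (any(assay$donor_cfu_per_ml <= 0))
    stop("transfer frequency undefined: donor_cfu_per_ml must be > 0")
  if (any(assay$transconjugant_cfu_per_ml < 0))
    stop("transconjugant_cfu_per_ml must be >= 0")
  f <- assay$transconjugant_cfu_per_ml / assay$donor_cfu_per_ml
  list(per_replicate = f, mean = mean(f),
       sd = if (length(f) > 1) sd(f) else NA_real_, n = length(f))
}

#' Fold change between two frequencies
#'
#' @param freq_a,freq_b frequencies to compare (`freq_b` is the reference and
#'   must be > 0).
#' @return `list(ratio, direction, fold)`: `ratio = freq_a / freq_b`,
#'   `direction` is `"higher"`, `"lower"` or `"equal"` for a versus b, and
#'   `fold` is the ratio folded to be >= 1.
#' @examples
#' foldChange(5e-3, 2.5e-6)   # 2000-fold higher
#' @export
foldChange <- function(freq_a, freq_b) {
  if (freq_b <= 0) stop("reference frequency must be > 0")
  if (freq_a < 0) stop("frequencies must be >= 0")
  r <- freq_a / freq_b
  list(ratio = r,
       direction = if (r > 1) "higher" else if (r < 1) "lower" else "equal",
       fold = if (r >= 1) r else 1 / r)
}

#' Plating survival rate
#'
#' Survival in stationary phase is the percentage ratio of CFU/ml counted on
#' selective (3CBA) plates to CFU/ml on non-selective (succinate) plates.
#' Vector inputs are paired replicates.
#'
#' @param cfu_3cba CFU/ml on selective medium.
#' @param cfu_succ CFU/ml on non-selective medium (> 0).
#' @return `list(per_replicate, mean, sd, n)` in percent.
#' @examples
#' survivalRate(c(9e8, 1.1e9), c(1e9, 1e9))
#' @export
survivalRate <- function(cfu_3cba, cfu_succ) {
  if (length(cfu_3cba) != length(cfu_succ))
    stop("replicate vectors differ in length")
  if (any(cfu_succ <= 0)) stop("survival undefined: cfu_succ must be > 0")
  if (any(cfu_3cba < 0)) stop("cfu_3cba must be >= 0")
  p <- 100 * cfu_3cba / cfu_succ
  list(per_replicate = p, mean = mean(p),
       sd = if (length(p) > 1) sd(p) else NA_real_, n = length(p))
}

#' Two-tailed Student's t test with equal variances
#'
#' The pooled-variance two-sample t statistic with
#' `df = n_a + n_b - 2` and a two-sided p value. When the pooled variance is
#' zero the test degenerates: p = 1 if the means are equal, otherwise an
#' error (an infinite statistic has no defined p here).
#'
#' @param a,b numeric vectors, each with at least 2 finite values.
#' @return `list(statistic, df, p_value, mean_a, mean_b, pooled_sd)`.
#' @examples
#' tTestEqualVar(c(1, 2, 3), c(4, 5, 6))
#' @export
tTestEqualVar <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 finite values")
  df <- na + nb - 2
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  dm <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (dm == 0)
      return(list(statistic = 0, df = df, p_value = 1, mean_a = mean(a),
                  mean_b = mean(b), pooled_sd = 0))
    stop("degenerate input: zero pooled variance with unequal means")
  }
  tstat <- dm / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = tstat, df = df, p_value = 2 * pt(-abs(tstat), df),
       mean_a = mean(a), mean_b = mean(b), pooled_sd = sqrt(sp2))
}

#' Result of a one-way ANOVA with Tukey-Kramer letter grouping
#'
#' @slot labels group labels, ordered by decreasing mean of the analysed
#'   (possibly log-transformed) values.
#' @slot means group means of the analysed values.
#' @slot n per-group sample sizes.
#' @slot letters compact letter display: groups sharing a letter are not
#'   significantly different at `alpha`.
#' @slot pairwise `data.frame` of all pairwise comparisons with Tukey-Kramer
#'   adjusted p values and decisions.
#' @slot anova_f,anova_p omnibus one-way ANOVA F statistic and p value.
#' @slot alpha significance level used.
#' @slot log10_transformed whether values were log10-transformed before the
#'   analysis.
#' @export
setClass("GroupComparison",
  representation(labels = "character", means = "numeric", n = "integer",
                 letters = "character", pairwise = "data.frame",
                 anova_f = "numeric", anova_p = "numeric", alpha = "numeric",
                 log10_transformed = "logical")
)

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison: %d groups, ANOVA F = %.3g (p = %.3g), alpha = %g%s\n",
              length(object@labels), object@anova_f, object@anova_p,
              object@alpha,
              if (object@log10_transformed) ", on log10 values" else ""))
  print(data.frame(group = object@labels, mean = object@means, n = object@n,
                   letters = object@letters))
  invisible(NULL)
})

#' @describeIn GroupComparison-class the letters table as a `data.frame`.
#' @param object a `GroupComparison`.
#' @export
lettersTable <- function(object) {
  stopifnot(is(object, "GroupComparison"))
  data.frame(group = object@labels, mean = object@means, n = object@n,
             letters = object@letters)
}

## compact letter display over a symmetric "not significantly different"
## logical matrix. For every non-significant pair not yet sharing a set, a new
## set is opened and absorbed to a maximal clique; singleton letters cover
## isolated groups; subset-sets are dropped. Guarantees: two groups share a
## letter iff their pair is non-significant.
.cldLetters <- function(nsd, order_idx) {
  k <- nrow(nsd)
  sets <- list()
  covers <- function(i, j) any(vapply(sets, function(s) i %in% s && j %in% s,
                                      logical(1)))
  for (a in seq_len(k - 1)) {
    i <- order_idx[a]
    for (b in (a + 1):k) {
      j <- order_idx[b]
      if (nsd[i, j] && !covers(i, j)) {
        s <- c(i, j)
        for (cc in order_idx) {
          if (!cc %in% s && all(nsd[cc, s])) s <- c(s, cc)
        }
        sets[[length(sets) + 1]] <- sort(s)
      }
    }
  }
  for (i in order_idx) {
    if (!any(vapply(sets, function(s) i %in% s, logical(1))))
      sets[[length(sets) + 1]] <- i
  }
  ## drop sets that are subsets of another
  if (length(sets) > 1) {
    keep <- rep(TRUE, length(sets))
    for (u in seq_along(sets)) for (v in seq_along(sets)) {
      if (u != v && keep[u] && keep[v] && all(sets[[u]] %in% sets[[v]]) &&
          length(sets[[u]]) < length(sets[[v]])) keep[u] <- FALSE
    }
    sets <- sets[keep]
  }
  ## order letter sets by the best-ranked member so 'a' labels the top group
  rank_of <- match(seq_len(k), order_idx)
  sets <- sets[order(vapply(sets, function(s) min(rank_of[s]), numeric(1)))]
  out <- character(k)
  for (si in seq_along(sets)) {
    for (i in sets[[si]]) out[i] <- paste0(out[i], letters[si])
  }
  out
}

#' One-way ANOVA with Tukey-Kramer compact letter display
#'
#' Runs an omnibus one-way ANOVA, then all pairwise comparisons using the
#' studentized range distribution in the Tukey-Kramer form (harmonic
#' correction `sqrt(MSE/2 * (1/n_i + 1/n_j))` for unequal group sizes), and
#' assigns letters so that two groups share a letter if and only if their
#' pairwise comparison is not significant at `alpha`.
#'
#' Transfer frequencies span several orders of magnitude, so by convention
#' they are log10-transformed before the analysis
#' (`log10_transform = TRUE`). Zero frequencies are replaced by
#' `pseudo_floor` (which must then be supplied) before the log transform.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @param alpha familywise significance level.
#' @param log10_transform analyse log10 of the values.
#' @param pseudo_floor replacement for zeros under the log transform, e.g.
#'   half a detection limit.
#' @return A [GroupComparison-class].
#' @examples
#' set.seed(1)
#' g <- list(wt = rnorm(3, 0), mut = rnorm(3, 5))
#' anovaTukey(g)
#' @export
anovaTukey <- function(groups, alpha = 0.05, log10_transform = FALSE,
                       pseudo_floor = NULL) {
  if (!is.list(groups) || length(groups) < 2)
    stop("groups must be a list of at least 2 numeric vectors")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least 2 values (empty groups not allowed)")
  vals <- groups
  if (log10_transform) {
    vals <- lapply(vals, function(v) {
      if (any(v < 0)) stop("negative values cannot be log10-transformed")
      if (any(v == 0)) {
        if (is.null(pseudo_floor))
          stop("zero values present: supply pseudo_floor for the log transform")
        message(sprintf("replacing %d zero value(s) by pseudo_floor = %g",
                        sum(v == 0), pseudo_floor))
        v[v == 0] <- pseudo_floor
      }
      log10(v)
    })
  }
  labs <- names(vals)
  k <- length(vals)
  x <- unlist(vals, use.names = FALSE)
  g <- factor(rep(labs, lengths(vals)), levels = labs)
  fit <- aov(x ~ g)
  at <- anova(fit)
  mse <- at["Residuals", "Mean Sq"]
  dfe <- at["Residuals", "Df"]
  fstat <- at["g", "F value"]
  fp <- at["g", "Pr(>F)"]

  m <- vapply(vals, mean, numeric(1))
  n <- vapply(vals, length, integer(1))
  pairs <- utils::combn(k, 2)
  pw <- data.frame(group1 = labs[pairs[1, ]], group2 = labs[pairs[2, ]],
                   diff = m[pairs[1, ]] - m[pairs[2, ]])
  if (mse <= 0) {
    pw$p_adj <- ifelse(pw$diff == 0, 1, 0)
  } else {
    q <- abs(pw$diff) / sqrt(mse / 2 * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]]))
    pw$p_adj <- ptukey(q, nmeans = k, df = dfe, lower.tail = FALSE)
  }
  pw$significant <- pw$p_adj < alpha

  nsd <- matrix(TRUE, k, k, dimnames = list(labs, labs))
  for (r in seq_len(nrow(pw))) {
    nsd[pw$group1[r], pw$group2[r]] <- !pw$significant[r]
    nsd[pw$group2[r], pw$group1[r]] <- !pw$significant[r]
  }
  ord <- order(m, decreasing = TRUE)   # ties keep input order
  ltr <- .cldLetters(nsd, ord)

  new("GroupComparison",
      labels = labs[ord], means = unname(m[ord]), n = unname(n[ord]),
      letters = ltr[ord], pairwise = pw,
      anova_f = unname(fstat), anova_p = unname(fp), alpha = alpha,
      log10_transformed = log10_transform)
}
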