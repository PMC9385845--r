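# ANOVA-based repeatability (intraclass correlation) of site use, in the
# Lessells & Boag formulation for unbalanced one-way designs. Site fidelity
# is quantified on site longitude, with individuals as groups and years as
# replicates; a negative variance component is retained, so r can be
# negative in finite samples.

#' Repeatability (intraclass correlation) from a one-way ANOVA
#'
#' With groups (individuals) `i = 1..a` of sizes `n_i`, the one-way ANOVA
#' mean squares `MS_A` (among) and `MS_W` (within) give
#' `s2_A = (MS_A - MS_W) / n0` with the effective group size
#' `n0 = (N - sum(n_i^2)/N) / (a - 1)`, and
#' `r = s2_A / (MS_W + s2_A)`. `F = MS_A / MS_W` on `(a-1, N-a)` degrees of
#' freedom gives the p-value. A negative `s2_A` is retained rather than
#' truncated.
#'
#' @param values Numeric measurements (e.g. site longitudes).
#' @param groups Grouping factor (e.g. individual id).
#' @return list of class `repeatability`: `r`, `F`, `df_between`,
#'   `df_within`, `p`, `n0`, `a`, `N`, `MS_A`, `MS_W`, `group_sizes`.
#' @examples
#' # identical values within each individual: r = 1
#' repeatability(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
repeatability <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  ni <- as.integer(table(groups))
  a <- length(ni); N <- sum(ni)
  if (a < 2) stop("repeatability needs at least 2 groups")
  if (all(ni < 2)) stop("no within-group replication (all groups of size 1)")
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  SSA <- sum(ni * (means - gm)^2)
  SSW <- sum((values - means[groups])^2)
  dfA <- a - 1L
  dfW <- N - a
  MSA <- SSA / dfA
  MSW <- SSW / dfW
  n0 <- (N - sum(ni^2) / N) / dfA
  s2A <- (MSA - MSW) / n0
  r <- if (MSW + s2A == 0) 1 else s2A / (MSW + s2A)
  Fv <- if (MSW == 0) Inf else MSA / MSW
  p <- stats::pf(Fv, dfA, dfW, lower.tail = FALSE)
  structure(list(r = r, F = Fv, df_between = dfA, df_within = dfW, p = p,
                 n0 = n0, a = a, N = N, MS_A = MSA, MS_W = MSW,
                 group_sizes = ni),
            class = "repeatability")
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("Repeatability: r = %.3f, F(%d,%d) = %.3g, p = %.3g (n0 = %.2f)\n",
              x$r, x$df_between, x$df_within, x$F, x$p, x$n0))
  invisible(x)
}

#' One wintering-site longitude per individual and winter
#'
#' For winters in which an individual used several distinct sites, only the
#' first-occupied site enters the fidelity analysis, avoiding
#' overrepresentation of multi-site individuals.
#'
#' @param inventory A [siteInventory()] data.frame.
#' @return data.frame `individual_id`, `winter`, `longitude`.
#' @export
firstWinterSite <- function(inventory) {
  data.frame(individual_id = inventory$individual_id,
             winter = inventory$winter,
             longitude = inventory$first_site_lon,
             stringsAsFactors = FALSE)
}
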