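# Group-comparison statistics: two-way (mixed) ANOVA, Sidak correction,
# Pearson correlations, Fisher z contrast, pooled t test.

#' Build a StatResult row
#' @noRd
.stat_result <- function(effect, statistic, df1, df2, p, method,
                         family = NA_character_) {
  data.frame(effect = effect, statistic = statistic, df1 = df1, df2 = df2,
             p = p, p_adjusted = NA_real_, family = family, method = method,
             stringsAsFactors = FALSE)
}

#' Two-way ANOVA with a between factor and an optional within factor
#'
#' Fits the two-way design used for the group comparisons: factor A between
#' subjects (e.g. genotype), factor B either between (e.g. sex) or within
#' subjects (e.g. day or time bin). When `subject` is supplied and subjects
#' repeat across levels of B, the subject term partitions the error
#' (univariate repeated-measures ANOVA): A is tested against the
#' between-subject error, B and the A:B interaction against the
#' within-subject residual. Purely between designs use type-III sums of
#' squares with sum-to-zero contrasts, so unbalanced groups are handled the
#' way commercial packages do.
#'
#' Missing values make a repeated-measures partition ill-defined; in that
#' case all available rows are analysed, a warning is raised, and results
#' are labelled `"mixed-effects approximation"`.
#'
#' @param data data frame in long format.
#' @param value name of the response column.
#' @param between name of the between-subjects factor (A).
#' @param within optional name of the within-subjects factor (B); when
#'   `NULL`, `between2` gives a second between factor.
#' @param subject name of the subject id column (required with `within`).
#' @param between2 second between-subjects factor for fully between designs.
#' @return data frame of StatResult rows for A, B and A:B with F, degrees of
#'   freedom and p-values.
#' @examples
#' d <- expand.grid(subj = 1:6, day = factor(1:3))
#' d$geno <- factor(rep(c("a", "b"), each = 3)[d$subj])
#' d$y <- rnorm(nrow(d))
#' two_way_anova(d, "y", "geno", within = "day", subject = "subj")
#' @export
two_way_anova <- function(data, value, between, within = NULL,
                          subject = NULL, between2 = NULL) {
  data <- as.data.frame(data)
  fac_b <- if (is.null(within)) between2 else within
  if (is.null(fac_b)) {
    stop("supply `within` (repeated measures) or `between2` (two between ",
         "factors)", call. = FALSE)
  }
  for (cn in c(between, fac_b)) {
    data[[cn]] <- factor(data[[cn]])
    if (nlevels(data[[cn]]) < 2) {
      stop(sprintf("factor `%s` has fewer than 2 levels", cn), call. = FALSE)
    }
  }
  y <- data[[value]]
  method <- "two-way ANOVA"
  if (anyNA(y)) {
    warning("missing values present: analysing available cases ",
            "(mixed-effects approximation)", call. = FALSE)
    method <- "mixed-effects approximation"
    data <- data[!is.na(y), , drop = FALSE]
  }
  eff_names <- c(between, fac_b, paste0(between, ":", fac_b))

  # an (effectively) constant response carries no effect: F = 0, p = 1 by
  # convention, rather than the 0/0 dust a least-squares fit would produce
  yv <- data[[value]]
  if (max(abs(yv - yv[1])) <= 1e-10 * max(1, abs(yv[1]))) {
    res <- do.call(rbind, lapply(eff_names, function(e)
      .stat_result(e, 0, NA_real_, NA_real_, 1, method)))
    return(res)
  }

  if (!is.null(within)) {
    if (is.null(subject)) {
      stop("a within factor requires `subject` ids", call. = FALSE)
    }
    data[[subject]] <- factor(data[[subject]])
    f <- stats::as.formula(sprintf("%s ~ %s * %s + Error(%s)", value,
                                   between, fac_b, subject))
    fit <- stats::aov(f, data = data)
    s <- summary(fit)
    rows <- do.call(rbind, lapply(s, function(st) {
      tab <- st[[1]]
      data.frame(term = trimws(rownames(tab)), df = tab$Df,
                 ss = tab$`Sum Sq`,
                 F = if ("F value" %in% colnames(tab)) tab$`F value` else NA,
                 p = if ("Pr(>F)" %in% colnames(tab)) tab$`Pr(>F)` else NA,
                 resid_df = tab$Df[trimws(rownames(tab)) == "Residuals"][1],
                 stringsAsFactors = FALSE)
    }))
    res <- do.call(rbind, lapply(eff_names, function(e) {
      r <- rows[rows$term == e, , drop = FALSE][1, ]
      .stat_result(e, r$F, r$df, r$resid_df, r$p, method)
    }))
  } else {
    op <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(op))
    f <- stats::as.formula(sprintf("%s ~ %s * %s", value, between, fac_b))
    fit <- stats::lm(f, data = data)
    a3 <- car::Anova(fit, type = 3)
    resid_df <- a3["Residuals", "Df"]
    res <- do.call(rbind, lapply(eff_names, function(e) {
      .stat_result(e, a3[e, "F value"], a3[e, "Df"], resid_df,
                   a3[e, "Pr(>F)"], method)
    }))
  }
  # degenerate data (zero residual variance): an all-equal response carries
  # no effect, F = 0 and p = 1 by convention
  bad <- !is.finite(res$statistic)
  res$statistic[bad] <- 0
  res$p[bad] <- 1
  rownames(res) <- NULL
  res
}

#' Sidak multiplicity adjustment
#'
#' `p_adj = 1 - (1 - p)^m` over a family of `m` comparisons, clipped to
#' `[0, 1]`. Monotone in both `p` and `m`; identity at `m = 1`.
#'
#' @param p_raw raw p-value(s).
#' @param m family size.
#' @return adjusted p-value(s).
#' @examples
#' sidak_adjust(0.01, 5)  # 0.04901
#' @export
sidak_adjust <- function(p_raw, m) {
  if (any(p_raw < 0 | p_raw > 1)) stop("p-values must lie in [0, 1]",
                                       call. = FALSE)
  if (any(m < 1)) stop("family size m must be >= 1", call. = FALSE)
  # pmax against the raw p keeps the adjusted >= raw invariant exact in
  # floating point (mathematically 1 - (1-p)^m >= p for m >= 1)
  pmin(1, pmax(p_raw, 1 - (1 - p_raw)^m))
}

#' Pearson correlation with its t-based p-value
#'
#' @param x,y numeric vectors of equal length (pairwise complete cases
#'   used).
#' @return list with `r`, `n`, `df`, `p` (two-sided).
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = n, df = n - 2, p = ct$p.value)
}

#' Fisher z test comparing two independent correlations
#'
#' Transforms each correlation with `atanh` and compares the difference to
#' its asymptotic standard error `sqrt(1/(n1-3) + 1/(n2-3))`; p is two-sided
#' normal.
#'
#' @param r1,r2 sample correlations (|r| < 1).
#' @param n1,n2 sample sizes (> 3).
#' @return list with `z` and `p`.
#' @examples
#' fisher_z_compare(0.8, 53, 0.3, 53)  # z = 3.9455
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3", call. = FALSE)
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Two-tailed unpaired t test (pooled variance)
#'
#' Student's t with pooled variance and `n1 + n2 - 2` degrees of freedom
#' (or the paired test when `paired = TRUE`), as used for the pairwise group
#' comparisons.
#'
#' @param group1,group2 numeric vectors.
#' @param paired paired test (default FALSE).
#' @return a StatResult data frame row (effect `"group"`).
#' @export
t_test <- function(group1, group2, paired = FALSE) {
  tt <- stats::t.test(group1, group2, paired = paired, var.equal = !paired)
  res <- .stat_result("group", unname(tt$statistic),
                      unname(tt$parameter), NA_real_, tt$p.value,
                      if (paired) "paired t test" else
                        "unpaired t test (pooled)")
  if (!is.finite(res$statistic)) { res$statistic <- 0; res$p <- 1 }
  res
}

#' Significance stars
#'
#' Renders the significance convention used in the figures: `*` p < 0.05,
#' `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001.
#'
#' @param p p-value(s).
#' @return character vector of stars (`"ns"` when p >= 0.05).
#' @export
significance_stars <- function(p) {
  cut_pts <- c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf)
  lab <- c("****", "***", "**", "*", "ns")
  lab[as.integer(cut(p, cut_pts, labels = FALSE))]
}
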