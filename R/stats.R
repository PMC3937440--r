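## The statistical battery: group comparisons, standardized multiple
## regressions, residual-controlled contrasts, percent differences and
## coefficients of variation. Raw p-values throughout; no multiple-testing
## correction is applied anywhere (stated in the report header).

.CLASS_LEVELS <- c("none", "mendelian", "gwas")

#' Percent difference of class means relative to the baseline class
#'
#' `100 * (mean(class)/mean(none) - 1)` per contrast class; rows with a
#' missing response are dropped.
#'
#' @param values per-gene response vector.
#' @param classes disease-class vector (`none`, `mendelian`, `gwas`).
#' @param baseline baseline class, default `"none"`.
#' @return named numeric vector of percent differences for each non-baseline
#'   class present.
#' @export
percent_difference <- function(values, classes, baseline = "none") {
  ok <- !is.na(values) & !is.na(classes)
  values <- values[ok]; classes <- as.character(classes[ok])
  if (!any(classes == baseline)) stop("no genes in baseline class '", baseline, "'")
  m0 <- mean(values[classes == baseline])
  if (m0 == 0) stop("baseline mean is zero; percent difference undefined")
  other <- setdiff(unique(classes), baseline)
  other <- other[order(match(other, .CLASS_LEVELS))]
  vapply(other, function(cl) 100 * (mean(values[classes == cl]) / m0 - 1),
         numeric(1))
}

#' One-way analysis of variance
#'
#' Classic between/within mean-square F ratio with its F-distribution
#' p-value.
#'
#' @param values response vector.
#' @param classes grouping vector (2 or more groups after dropping `NA`s).
#' @return list with `F`, `p`, `df1`, `df2`, `n`.
#' @export
one_way_anova <- function(values, classes) {
  ok <- !is.na(values) & !is.na(classes)
  values <- values[ok]; classes <- factor(as.character(classes[ok]))
  k <- nlevels(classes); n <- length(values)
  if (k < 2L) stop("need at least two groups")
  if (n - k < 1L) stop("no residual degrees of freedom")
  gm <- tapply(values, classes, mean)
  gn <- tapply(values, classes, length)
  grand <- mean(values)
  ssb <- sum(gn * (gm - grand)^2)
  ssw <- sum((values - gm[classes])^2)
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, p = NA_real_, df1 = k - 1L,
                              df2 = n - k, n = n))
    return(list(F = Inf, p = NA_real_, df1 = k - 1L, df2 = n - k, n = n))
  }
  Fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = Fstat, p = pf(Fstat, k - 1, n - k, lower.tail = FALSE),
       df1 = k - 1L, df2 = n - k, n = n)
}

#' Welch two-sample t-test (two-sided)
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom. The
#' pooled-variance variant is available via `pooled = TRUE`.
#'
#' @param a,b numeric vectors (each of length 2 or more after dropping
#'   `NA`s).
#' @param pooled use the pooled-variance (Student) form.
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(a, b, pooled = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each group needs n >= 2")
  m1 <- mean(a); m2 <- mean(b)
  v1 <- var(a); v2 <- var(b)
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) return(list(t = 0, p = 1, df = n1 + n2 - 2,
                              mean_a = m1, mean_b = m2))
    return(list(t = sign(m1 - m2) * Inf, p = 0, df = n1 + n2 - 2,
                mean_a = m1, mean_b = m2))
  }
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  list(t = t, p = 2 * pt(abs(t), df, lower.tail = FALSE), df = df,
       mean_a = m1, mean_b = m2)
}

#' Standardized multiple regression
#'
#' The response and every factor are z-scored (mean 0, SD 1 with the n-1
#' denominator) on the complete-case rows before ordinary least squares, so
#' coefficients are comparable across predictors with different units. With
#' a single predictor the standardized coefficient equals the Pearson
#' correlation.
#'
#' @param response numeric response vector.
#' @param factors `data.frame` (or matrix) of predictors, one column per
#'   factor.
#' @param standardize_response set `FALSE` to standardize predictors only.
#' @param condition_threshold collinearity guard: error if the condition
#'   number of the standardized design exceeds this.
#' @return list of class `dga_regression` with `coefficients` (data.frame:
#'   factor, beta, t, p), `n`, `r_squared`.
#' @export
standardized_regression <- function(response, factors,
                                    standardize_response = TRUE,
                                    condition_threshold = 1e8) {
  X <- as.data.frame(factors)
  ok <- complete.cases(X) & !is.na(response)
  X <- X[ok, , drop = FALSE]
  y <- response[ok]
  p <- ncol(X)
  if (nrow(X) < p + 2L)
    stop("need at least ", p + 2L, " complete-case rows; have ", nrow(X))
  Z <- scale(as.matrix(X))
  if (any(!is.finite(Z)))
    stop("constant factor(s): ",
         paste(colnames(X)[apply(X, 2, function(v) sd(v) == 0)], collapse = ", "))
  kap <- kappa(crossprod(Z) / (nrow(Z) - 1), exact = FALSE)
  if (kap > condition_threshold)
    stop("collinear factors (condition number ", format(kap, digits = 3),
         "): ", paste(colnames(X), collapse = ", "))
  ys <- if (standardize_response) as.numeric(scale(y)) else y
  fit <- lm(ys ~ Z)
  sm <- summary(fit)
  co <- sm$coefficients[-1, , drop = FALSE]  # drop intercept
  structure(list(
    coefficients = data.frame(
      factor = colnames(X),
      beta = unname(co[, 1]), t = unname(co[, 3]), p = unname(co[, 4]),
      stringsAsFactors = FALSE),
    n = nrow(X), r_squared = sm$r.squared), class = "dga_regression")
}

#' @export
print.dga_regression <- function(x, ...) {
  cat("Standardized multiple regression (n =", x$n,
      ", R^2 =", format(x$r_squared, digits = 3), ")\n")
  print(x$coefficients, digits = 3, row.names = FALSE)
  invisible(x)
}

#' OLS residuals of a response against a factor table
#'
#' Complete-case OLS; residuals come back aligned to the input rows with
#' `NA` where any variable was missing. The log-log variant takes natural
#' logs of both sides first (all values must then be positive).
#'
#' @param response numeric response vector.
#' @param factors `data.frame`/matrix of predictors.
#' @param log_log regress `log(response)` on `log(factors)`.
#' @return numeric vector of residuals, same length as `response`.
#' @export
residualize <- function(response, factors, log_log = FALSE) {
  X <- as.data.frame(factors)
  if (log_log) {
    if (any(response <= 0, na.rm = TRUE) ||
        any(as.matrix(X) <= 0, na.rm = TRUE))
      stop("log-log residualization requires strictly positive values")
    response <- log(response)
    X <- as.data.frame(lapply(X, log))
  }
  ok <- complete.cases(X) & !is.na(response)
  if (sum(ok) < ncol(X) + 2L)
    stop("need at least ", ncol(X) + 2L, " complete-case rows")
  fit <- lm(response ~ ., data = cbind(response = response, X)[ok, ])
  out <- rep(NA_real_, length(response))
  out[ok] <- residuals(fit)
  out
}

#' Mean, SD, CV and 95% confidence interval
#'
#' CV is the sample SD (n-1 denominator) over the mean; the CI is the
#' normal approximation mean +/- 1.96 SE. CV is missing when the mean is 0.
#'
#' @param values numeric vector (`NA`s dropped).
#' @return list with `n`, `mean`, `sd`, `cv`, `ci_lo`, `ci_hi`.
#' @export
summary_stats <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  m <- mean(values)
  s <- if (n >= 2L) sd(values) else NA_real_
  se <- s / sqrt(n)
  list(n = n, mean = m, sd = s,
       cv = if (!is.na(s) && m != 0) s / m else NA_real_,
       ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se)
}

#' Run the full per-response statistical battery
#'
#' For each response: per-class summary statistics, percent differences vs
#' the non-disease class, one-way ANOVA, pairwise Welch t-tests, the
#' residual-controlled versions of the group tests (residualizing on the
#' genomic covariates), and a standardized multiple regression of the
#' response on the covariates. Also emits cohort descriptives (class
#' counts, CVs, the intron-CDS length correlation and its
#' residual-controlled contrasts).
#'
#' @param gene_table joined per-gene table (see [run_pipeline()]); must
#'   contain `disease_class`, the response columns and the covariate
#'   columns.
#' @param responses response columns to analyse (defaults to the four core
#'   responses plus the length columns).
#' @param covariates covariate column names (defaults to the 8 genomic
#'   factors).
#' @param log_log use the log-log variant of the intron-CDS length
#'   residual regression as well.
#' @param pooled_t use pooled-variance t-tests.
#' @return object of class `dga_report`: nested list with elements
#'   `responses`, `descriptives`, `header`.
#' @export
run_report <- function(gene_table,
                       responses = c("total_cds_length", "average_cds_length",
                                     "d_all", "rate_per_site", "rate_genic",
                                     "pi_all", "genealogy_length", "mean_maf"),
                       covariates = dga_covariate_names(),
                       log_log = FALSE, pooled_t = FALSE) {
  need <- c("gene_id", "disease_class", responses, covariates)
  miss <- setdiff(need, names(gene_table))
  if (length(miss)) stop("gene table is missing column(s): ",
                         paste(miss, collapse = ", "))
  cls <- as.character(gene_table$disease_class)
  X <- gene_table[, covariates, drop = FALSE]

  analyse_response <- function(resp) {
    y <- gene_table[[resp]]
    ok <- !is.na(y)
    groups <- lapply(.CLASS_LEVELS, function(cl) y[ok & cls == cl])
    names(groups) <- .CLASS_LEVELS
    res <- list(
      response = resp,
      group_stats = lapply(groups, summary_stats),
      percent_difference = percent_difference(y, cls),
      anova = one_way_anova(y, cls),
      t_tests = lapply(setdiff(.CLASS_LEVELS, "none"), function(cl)
        c(list(contrast = paste0(cl, " vs none")),
          welch_t_test(groups[[cl]], groups[["none"]], pooled = pooled_t))))
    # residual-controlled versions
    r <- tryCatch(residualize(y, X), error = function(e) NULL)
    if (!is.null(r)) {
      res$residual_anova <- one_way_anova(r, cls)
      res$residual_t_tests <- lapply(setdiff(.CLASS_LEVELS, "none"),
        function(cl) c(list(contrast = paste0(cl, " vs none")),
                       welch_t_test(r[cls == cl], r[cls == "none"],
                                    pooled = pooled_t)))
      res$regression <- tryCatch(standardized_regression(y, X),
                                 error = function(e) NULL)
    }
    res
  }
  out <- lapply(responses, analyse_response)
  names(out) <- responses

  desc <- list(
    n_genes = nrow(gene_table),
    n_by_class = table(factor(cls, levels = .CLASS_LEVELS)),
    cv = lapply(gene_table[, intersect(c("total_cds_length", "d_all",
                                         "pi_all", "genealogy_length"),
                                       names(gene_table)), drop = FALSE],
                function(v) summary_stats(v)$cv))
  if (all(c("total_intron_length", "total_cds_length") %in% names(gene_table))) {
    ok <- complete.cases(gene_table[, c("total_intron_length",
                                        "total_cds_length")])
    desc$intron_cds_r <- cor(gene_table$total_intron_length[ok],
                             gene_table$total_cds_length[ok])
    rr <- residualize(gene_table$total_cds_length,
                      gene_table[, "total_intron_length", drop = FALSE])
    desc$cds_given_intron_t <- lapply(setdiff(.CLASS_LEVELS, "none"),
      function(cl) c(list(contrast = paste0(cl, " vs none")),
                     welch_t_test(rr[cls == cl], rr[cls == "none"],
                                  pooled = pooled_t)))
    if (log_log) {
      rl <- residualize(gene_table$total_cds_length,
                        gene_table[, "total_intron_length", drop = FALSE],
                        log_log = TRUE)
      desc$cds_given_intron_t_loglog <- lapply(setdiff(.CLASS_LEVELS, "none"),
        function(cl) c(list(contrast = paste0(cl, " vs none")),
                       welch_t_test(rl[cls == cl], rl[cls == "none"],
                                    pooled = pooled_t)))
    }
  }
  structure(list(
    header = paste("dga report; raw p-values, no multiple-testing",
                   "correction; t-tests are",
                   if (pooled_t) "pooled-variance" else "Welch"),
    responses = out, descriptives = desc), class = "dga_report")
}

#' @export
print.dga_report <- function(x, ...) {
  cat(x$header, "\n")
  d <- x$descriptives
  cat("genes:", d$n_genes, " (",
      paste(names(d$n_by_class), as.integer(d$n_by_class),
            sep = "=", collapse = ", "), ")\n", sep = "")
  if (!is.null(d$intron_cds_r))
    cat("intron~CDS length Pearson r:", format(d$intron_cds_r, digits = 3), "\n")
  for (resp in names(x$responses)) {
    r <- x$responses[[resp]]
    pd <- r$percent_difference
    cat(sprintf("%-20s %% diff vs none: %s | ANOVA F=%.2f p=%.3g\n", resp,
                paste(names(pd), sprintf("%+.1f%%", pd), collapse = ", "),
                r$anova$F, r$anova$p))
  }
  invisible(x)
}

#' Flatten a report to a tidy table
#'
#' @param report a `dga_report`.
#' @return `data.frame` with columns `response`, `statistic`, `class`,
#'   `value`.
#' @export
report_as_table <- function(report) {
  rows <- list()
  add <- function(response, statistic, class, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      response = response, statistic = statistic, class = class,
      value = value, stringsAsFactors = FALSE)
  for (resp in names(report$responses)) {
    r <- report$responses[[resp]]
    for (cl in names(r$group_stats)) {
      gs <- r$group_stats[[cl]]
      add(resp, "mean", cl, gs$mean)
      add(resp, "ci_lo", cl, gs$ci_lo)
      add(resp, "ci_hi", cl, gs$ci_hi)
      add(resp, "n", cl, gs$n)
    }
    for (cl in names(r$percent_difference))
      add(resp, "percent_difference", cl, r$percent_difference[[cl]])
    add(resp, "anova_F", "all", r$anova$F)
    add(resp, "anova_p", "all", r$anova$p)
    for (tt in r$t_tests) {
      add(resp, "t", tt$contrast, tt$t)
      add(resp, "t_p", tt$contrast, tt$p)
    }
    if (!is.null(r$residual_anova)) {
      add(resp, "residual_anova_p", "all", r$residual_anova$p)
      for (tt in r$residual_t_tests)
        add(resp, "residual_t_p", tt$contrast, tt$p)
    }
    if (!is.null(r$regression))
      for (i in seq_len(nrow(r$regression$coefficients))) {
        co <- r$regression$coefficients[i, ]
        add(resp, paste0("beta[", co$factor, "]"), "all", co$beta)
        add(resp, paste0("beta_p[", co$factor, "]"), "all", co$p)
      }
  }
  d <- report$descriptives
  for (nm in names(d$cv)) add("descriptives", paste0("cv_", nm), "all", d$cv[[nm]])
  if (!is.null(d$intron_cds_r))
    add("descriptives", "intron_cds_r", "all", d$intron_cds_r)
  do.call(rbind, rows)
}
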