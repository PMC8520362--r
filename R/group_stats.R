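#' Per-group summary statistics
#'
#' A "mean +- SD (n)" cell of a clinical comparison table.
#'
#' @param label group label.
#' @param mean group mean (mm for thickness tables; years/cm/kg for the
#'   covariate table).
#' @param sd group standard deviation (>= 0).
#' @param n group size (>= 2).
#' @return An object of class `group_summary`.
#' @examples
#' group_summary("vaginal delivery", 1.04, 0.27, 77)
#' @export
group_summary <- function(label, mean, sd, n) {
  if (!is.finite(mean) || !is.finite(sd) || sd < 0)
    stop("`mean` must be finite and `sd` >= 0")
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be >= 2")
  structure(list(label = as.character(label), mean = as.numeric(mean),
                 sd = as.numeric(sd), n = n),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: %.4g +- %.4g (n = %d)\n", x$label, x$mean, x$sd, x$n))
  invisible(x)
}

#' Independent-sample t-test from summary statistics
#'
#' Two-sample t-test computed directly from per-group mean, SD and n.
#' The default is the Welch (unequal-variance) test with
#' Welch-Satterthwaite degrees of freedom; `"pooled"` gives the classical
#' equal-variance test with `n1 + n2 - 2` df. The sign of t follows
#' `mean1 - mean2` (group 1 first). Degenerate inputs with both SDs zero
#' give t = 0, p = 1 for equal means and an infinite t, p = 0 otherwise.
#'
#' @param g1,g2 [group_summary()] objects (or lists with `mean`, `sd`,
#'   `n`); group 1 is conventionally the vaginal-delivery group.
#' @param method `"welch"` (default) or `"pooled"`.
#' @param alpha significance level for the flag (default 0.05).
#' @return An object of class `ttest_result`: list with `t`, `df`, `p`,
#'   `method`, `estimate` (the two means) and `significant`.
#' @examples
#' t_from_summary(group_summary("g1", 1.04, 0.27, 77),
#'                group_summary("g2", 1.87, 0.55, 80))
#' @export
t_from_summary <- function(g1, g2, method = c("welch", "pooled"),
                           alpha = 0.05) {
  method <- match.arg(method)
  m1 <- g1$mean; s1 <- g1$sd; n1 <- g1$n
  m2 <- g2$mean; s2 <- g2$sd; n2 <- g2$n
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) {
      t <- 0; df <- NA_real_; p <- 1
    } else {
      t <- sign(m1 - m2) * Inf; df <- NA_real_; p <- 0
    }
  } else if (method == "welch") {
    v1 <- s1^2 / n1
    v2 <- s2^2 / n2
    t <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    p <- 2 * pt(-abs(t), df)
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(t = t, df = df, p = p, method = method,
                 estimate = c(mean1 = m1, mean2 = m2),
                 significant = is.finite(p) && p < alpha),
            class = "ttest_result")
}

#' Render a p-value the way the clinical tables print it
#'
#' Values below 0.01 render as `"<0.01"`, others to two decimals.
#'
#' @param p numeric p-value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.01, "<0.01", formatC(round(p, 2), format = "g"))
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("%s two-sample t-test: t = %.4g, df = %.4g, p = %s%s\n",
              x$method, x$t, x$df, format_p(x$p),
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Independent-sample t-test from raw values
#'
#' Computes the per-group summaries and delegates to [t_from_summary()],
#' with which it agrees exactly.
#'
#' @param values1,values2 numeric vectors of per-subject measurements
#'   (length >= 2 each).
#' @inheritParams t_from_summary
#' @return A `ttest_result`, see [t_from_summary()].
#' @export
t_from_raw <- function(values1, values2, method = c("welch", "pooled"),
                       alpha = 0.05) {
  if (length(values1) < 2L || length(values2) < 2L)
    stop("each group needs at least 2 values")
  t_from_summary(
    group_summary("group1", mean(values1), sd(values1), length(values1)),
    group_summary("group2", mean(values2), sd(values2), length(values2)),
    method = method, alpha = alpha)
}

#' Site-by-site two-group comparison table
#'
#' One independent-sample t-test per measurement site from summary
#' statistics, reproducing the layout of the published comparison
#' tables. No multiple-testing correction is applied, mirroring the
#' per-site raw p-values of the source tables.
#'
#' @param sites data.frame with columns `site`, `mean1`, `sd1`, `n1`,
#'   `mean2`, `sd2`, `n2` (group 1 = vaginal delivery, group 2 =
#'   Caesarean section). Extra columns are carried through.
#' @inheritParams t_from_summary
#' @return data.frame with columns `site`, `t`, `df`, `p`, `p_label`,
#'   `significant`, in the input row order.
#' @examples
#' compare_table(delivery_tables())[, c("site", "t", "p_label")]
#' @export
compare_table <- function(sites, method = c("welch", "pooled"),
                          alpha = 0.05) {
  method <- match.arg(method)
  need <- c("site", "mean1", "sd1", "n1", "mean2", "sd2", "n2")
  if (!all(need %in% names(sites)))
    stop("`sites` must have columns ", paste(need, collapse = ", "))
  if (nrow(sites) == 0L)
    return(data.frame(site = character(), t = numeric(), df = numeric(),
                      p = numeric(), p_label = character(),
                      significant = logical(), stringsAsFactors = FALSE))
  res <- lapply(seq_len(nrow(sites)), function(i) {
    r <- sites[i, ]
    tt <- t_from_summary(group_summary("group1", r$mean1, r$sd1, r$n1),
                         group_summary("group2", r$mean2, r$sd2, r$n2),
                         method = method, alpha = alpha)
    data.frame(site = r$site, t = tt$t, df = tt$df, p = tt$p,
               p_label = format_p(tt$p), significant = tt$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Published delivery-group comparison tables
#'
#' The printed summary cells (mean, SD, n per group) of the three
#' comparison tables of the source study, shipped as a plain-text
#' fixture: maternal/neonatal covariates, IAS thickness on three planes,
#' and EAS/PRM thickness. Group 1 is the vaginal-delivery group (n = 77),
#' group 2 the Caesarean-section group (n = 80). `printed_t` and
#' `printed_p` are the values as printed; `consistent` is `FALSE` for the
#' two cells whose printed t cannot be reproduced from their own printed
#' mean/SD/n (age; EAS distal 6 o'clock), with the discrepancy in `note`.
#'
#' @return data.frame with one row per table cell.
#' @export
delivery_tables <- function() {
  path <- system.file("extdata", "delivery_tables.csv", package = "sonokr",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Simulate one replicate of a two-group thickness study
#'
#' Draws per-subject Gaussian measurements at each site for two groups
#' with the given true means and SDs; the recovery/power harness for the
#' statistics pipeline.
#'
#' @param effects data.frame with columns `site`, `mean1`, `sd1`,
#'   `mean2`, `sd2` (true per-site group parameters).
#' @param n1,n2 group sizes.
#' @param seed integer seed (explicit; the global RNG is untouched).
#' @return Long data.frame with columns `site`, `group` (`"group1"` /
#'   `"group2"`), `value`.
#' @export
simulate_two_group_study <- function(effects, n1, n2, seed) {
  need <- c("site", "mean1", "sd1", "mean2", "sd2")
  if (!all(need %in% names(effects)))
    stop("`effects` must have columns ", paste(need, collapse = ", "))
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(effects)), function(i) {
      e <- effects[i, ]
      data.frame(
        site = e$site,
        group = rep(c("group1", "group2"), c(n1, n2)),
        value = c(rnorm(n1, e$mean1, e$sd1), rnorm(n2, e$mean2, e$sd2)),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Summarize a raw two-group study into a comparison input
#'
#' @param raw long data.frame from [simulate_two_group_study()].
#' @return data.frame with the [compare_table()] input columns.
#' @export
summarize_study <- function(raw) {
  sites <- unique(raw$site)
  out <- lapply(sites, function(s) {
    x1 <- raw$value[raw$site == s & raw$group == "group1"]
    x2 <- raw$value[raw$site == s & raw$group == "group2"]
    data.frame(site = s, mean1 = mean(x1), sd1 = sd(x1), n1 = length(x1),
               mean2 = mean(x2), sd2 = sd(x2), n2 = length(x2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Monte-Carlo rejection rate of the two-group test
#'
#' Repeatedly simulates a single-site two-group study and records how
#' often the t-test rejects at `alpha`; with equal true means this
#' estimates the type-I error, with unequal means the power.
#'
#' @param mean1,sd1,mean2,sd2 true group parameters at the site.
#' @param n1,n2 group sizes.
#' @param reps number of Monte-Carlo replicates.
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @inheritParams t_from_summary
#' @return Rejection proportion in `[0, 1]`.
#' @export
rejection_rate <- function(mean1, sd1, mean2, sd2, n1, n2, reps,
                           alpha = 0.05, seed = 1L,
                           method = c("welch", "pooled")) {
  method <- match.arg(method)
  with_seed(seed, {
    hits <- vapply(seq_len(reps), function(i) {
      x1 <- rnorm(n1, mean1, sd1)
      x2 <- rnorm(n2, mean2, sd2)
      t_from_raw(x1, x2, method = method, alpha = alpha)$significant
    }, logical(1))
    mean(hits)
  })
}
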