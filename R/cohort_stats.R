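#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test with the Welch-Satterthwaite degrees
#' of freedom, the primary comparison used for per-metric cohort contrasts.
#' If both samples are constant with equal means the test is degenerate and
#' p = 1 is reported with a flag; constant samples with different means give
#' p = 0.
#'
#' @param a,b numeric vectors of per-case metric values, each with at least
#'   two finite entries (NAs dropped).
#' @param conf_level confidence level of the interval on `mean(a) - mean(b)`.
#' @return List with `t`, `df`, `p_two_sided`, `mean_diff`, `ci95`, `se`,
#'   `degenerate`.
#' @export
welch_test <- function(a, b, conf_level = 0.95) {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L)
        config_error("welch_test needs >= 2 finite values per group")
    if (stats::var(a) == 0 && stats::var(b) == 0) {
        diff <- mean(a) - mean(b)
        return(list(t = if (diff == 0) 0 else Inf * sign(diff),
                    df = NA_real_,
                    p_two_sided = if (diff == 0) 1 else 0,
                    mean_diff = diff, ci95 = c(diff, diff), se = 0,
                    degenerate = TRUE))
    }
    ht <- stats::t.test(a, b, var.equal = FALSE, conf.level = conf_level)
    se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p_two_sided = ht$p.value, mean_diff = mean(a) - mean(b),
         ci95 = as.numeric(ht$conf.int), se = se, degenerate = FALSE)
}

#' One-sided non-inferiority test against a margin
#'
#' Tests whether a new protocol's mean metric is not worse than the
#' reference's by more than `margin` (negative: lower contrast is worse):
#' H0: mu_new - mu_ref <= margin vs H1: mu_new - mu_ref > margin, as a
#' one-sided Welch test of the shifted difference at level `alpha` (0.025 by
#' default, the one-sided analogue of a two-sided 0.05 test). The verdict
#' `non_inferior` is returned iff p < alpha, which for the Welch test is
#' exactly equivalent to the lower bound of the two-sided 95% CI on the
#' difference lying above the margin; both forms are reported. Post-hoc
#' power at the observed effect is included.
#'
#' @param new,reference numeric vectors of per-case values (new protocol
#'   first; differences are new minus reference).
#' @param margin non-inferiority margin on the difference, default -0.1
#'   (a 0.1 drop in normalized contrast units).
#' @param alpha one-sided significance level, default 0.025.
#' @param metric optional metric name carried into the result.
#' @param companions also run the companion Mann-Whitney and KS normality
#'   checks (skippable for bulk simulation).
#' @return An object of class `comparison_result` with fields `metric`,
#'   `mean_diff`, `ci95`, `p_two_sided`, `p_noninferiority`,
#'   `power_posthoc`, `mwu_p`, `normality_p` (per group),
#'   `noninferiority_margin`, `alpha_two_sided`, `alpha_noninf`, `verdict`,
#'   `n` (per group).
#' @export
noninferiority_test <- function(new, reference, margin = -0.1, alpha = 0.025,
                                metric = NA_character_, companions = TRUE) {
    if (!is.finite(margin) || margin >= 0)
        config_error("non-inferiority margin must be a negative difference")
    new <- new[is.finite(new)]; reference <- reference[is.finite(reference)]
    w <- welch_test(new, reference)

    if (w$degenerate) {
        p_ni <- if (w$mean_diff > margin) 0 else 1
        verdict <- if (w$mean_diff > margin) "non_inferior" else "inferior_not_shown"
        pow <- NA_real_
    } else {
        ht <- stats::t.test(new, reference, var.equal = FALSE, mu = margin,
                            alternative = "greater")
        p_ni <- ht$p.value
        verdict <- if (p_ni < alpha) "non_inferior" else "inferior_not_shown"
        pow <- posthoc_power(
            list(mean = mean(new), sd = stats::sd(new), n = length(new)),
            list(mean = mean(reference), sd = stats::sd(reference),
                 n = length(reference)),
            alpha = alpha, sided = 1, delta0 = margin)
    }

    if (companions) {
        mwu <- mwu_test(new, reference)
        ks_p <- function(x) if (length(x) >= 5L) ks_normality(x)$p else NA_real_
        ksn <- c(new = ks_p(new), reference = ks_p(reference))
    } else {
        mwu <- list(p = NA_real_)
        ksn <- c(new = NA_real_, reference = NA_real_)
    }

    structure(list(
        metric = metric,
        mean_diff = w$mean_diff,
        ci95 = w$ci95,
        p_two_sided = w$p_two_sided,
        p_noninferiority = p_ni,
        power_posthoc = pow,
        mwu_p = mwu$p,
        normality_p = ksn,
        noninferiority_margin = margin,
        alpha_two_sided = 0.05,
        alpha_noninf = alpha,
        ci_rule_non_inferior = w$ci95[1] > margin,
        verdict = verdict,
        n = c(new = length(new), reference = length(reference)),
        degenerate = w$degenerate
    ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
    cat(sprintf("<comparison_result> %s (n = %d vs %d)\n",
                x$metric, x$n[1], x$n[2]))
    cat(sprintf("  mean diff %.4f, 95%% CI [%.4f, %.4f]\n",
                x$mean_diff, x$ci95[1], x$ci95[2]))
    cat(sprintf("  two-sided p %.3g | non-inferiority p %.3g (margin %.3g) -> %s\n",
                x$p_two_sided, x$p_noninferiority, x$noninferiority_margin,
                x$verdict))
    cat(sprintf("  post-hoc power %.3f | Mann-Whitney p %.3g\n",
                x$power_posthoc, x$mwu_p))
    invisible(x)
}

welch_df <- function(s1, n1, s2, n2) {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
}

#' Post-hoc power of a two-sample t-test at the observed effect
#'
#' Power of the one- or two-sided unequal-variance t-test computed at the
#' observed means/SDs and sample sizes, via the noncentral t distribution
#' with Welch-Satterthwaite degrees of freedom. For a non-inferiority test
#' the noncentrality is taken relative to the margin `delta0`. Post-hoc
#' power is a monotone transform of the observed p-value and is reported as
#' a descriptive quantity only.
#'
#' @param a_summary,b_summary lists with `mean`, `sd`, `n` per group.
#' @param alpha significance level of the test whose power is sought.
#' @param sided 1 or 2.
#' @param delta0 null difference (0 for a superiority test, the margin for
#'   non-inferiority).
#' @return Power in \[0, 1\].
#' @export
posthoc_power <- function(a_summary, b_summary, alpha = 0.05, sided = 2,
                          delta0 = 0) {
    s1 <- a_summary$sd; n1 <- a_summary$n
    s2 <- b_summary$sd; n2 <- b_summary$n
    if (n1 < 2 || n2 < 2 || s1 < 0 || s2 < 0 || (s1 == 0 && s2 == 0))
        config_error("posthoc_power needs n >= 2 and a positive SD")
    se <- sqrt(s1^2 / n1 + s2^2 / n2)
    df <- welch_df(s1, n1, s2, n2)
    ncp <- (a_summary$mean - b_summary$mean - delta0) / se
    if (sided == 2) {
        ncp <- abs(ncp)
        tcrit <- stats::qt(1 - alpha / 2, df)
        stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
            stats::pt(-tcrit, df, ncp = ncp)
    } else {
        tcrit <- stats::qt(1 - alpha, df)
        stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE)
    }
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test; exact enumeration for small tie-free samples
#' (both n <= 8), tie-corrected normal approximation with continuity
#' correction otherwise. The returned `U` counts pairs in which an `a` value
#' exceeds a `b` value (ties 1/2), so `U / (n1*n2)` equals the ROC AUC of
#' `a` against `b` from [rank_auc()].
#'
#' @param a,b numeric vectors, each nonempty.
#' @return List with `U`, `p`, and `auc` (= U/(n1 n2)).
#' @export
mwu_test <- function(a, b) {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    n1 <- length(a); n2 <- length(b)
    if (n1 < 1L || n2 < 1L) config_error("mwu_test needs nonempty groups")
    ties <- any(duplicated(c(a, b)))
    exact <- (max(n1, n2) <= 8L) && !ties
    ht <- suppressWarnings(
        stats::wilcox.test(a, b, exact = exact, correct = !exact))
    U <- unname(ht$statistic)   # wilcox.test W = pairs with a > b
    list(U = U, p = ht$p.value, auc = U / (n1 * n2))
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Tests the sample against a normal with the sample's own mean and SD.
#' With estimated parameters the classical KS p-value is conservative; a
#' Lilliefors-corrected variant (`lilliefors = TRUE`) is provided for a
#' calibrated p. A constant sample has no distribution to test and is
#' returned with `degenerate = TRUE` and `p = NA`.
#'
#' @param x numeric vector, n >= 5.
#' @param lilliefors use the Lilliefors correction.
#' @return List with `p`, `statistic`, `degenerate`.
#' @export
ks_normality <- function(x, lilliefors = FALSE) {
    x <- x[is.finite(x)]
    if (length(x) < 5L) config_error("ks_normality needs n >= 5")
    if (stats::sd(x) == 0)
        return(list(p = NA_real_, statistic = NA_real_, degenerate = TRUE))
    ht <- if (lilliefors) {
        nortest::lillie.test(x)
    } else {
        suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    }
    list(p = ht$p.value, statistic = unname(ht$statistic), degenerate = FALSE)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Sample correlation r with the 95% CI from the Fisher transform,
#' \eqn{\tanh(\mathrm{atanh}(r) \pm z_{0.975}/\sqrt{n-3})}. A perfectly
#' linear sample returns r = +/-1 with a collapsed interval.
#'
#' @param x,y numeric vectors of equal length n >= 4; pairs with any NA are
#'   dropped.
#' @return List with `r`, `ci95`, `n`.
#' @export
pearson_with_ci <- function(x, y) {
    if (length(x) != length(y)) config_error("x and y must have equal length")
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n < 4L) config_error("pearson_with_ci needs n >= 4 complete pairs")
    if (stats::var(x) == 0 || stats::var(y) == 0)
        undefined_correlation_error("correlation undefined for a constant variable")
    r <- stats::cor(x, y)
    z <- atanh(r)
    half <- stats::qnorm(0.975) / sqrt(n - 3)
    list(r = r, ci95 = tanh(c(z - half, z + half)), n = n)
}
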