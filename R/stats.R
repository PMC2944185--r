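## Shared exact statistics: contingency tests, multiple-testing adjustment,
## hypergeometric tails, Kaplan-Meier and log-rank.

## Relative tolerance used when comparing table probabilities in the
## two-sided probability-mass criterion; avoids float-order artifacts when
## the observed probability ties with another table's.
.REL_TOL <- 1e-7

.checkCounts <- function(x, name = "table") {
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != round(x)))
        stop(name, " must contain nonnegative integer counts")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the probability-mass criterion: the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (within a 1e-7
#' relative tolerance). Also returns the sample odds ratio (cross-product;
#' may be 0, `Inf` or `NaN` on zero margins).
#'
#' @param table a 2x2 matrix of nonnegative integer counts.
#' @return A list with elements `p` (two-sided p-value) and `oddsRatio`.
#' @examples
#' fisherExact2x2(matrix(c(9, 0, 2, 17), 2))  # p = 7.96e-6
#' @export
fisherExact2x2 <- function(table) {
    table <- as.matrix(table)
    if (!all(dim(table) == c(2L, 2L)))
        stop("'table' must be 2x2")
    .checkCounts(table)
    N <- sum(table)
    if (N == 0) stop("zero grand total")
    r1 <- sum(table[1L, ]); c1 <- sum(table[, 1L]); x <- table[1L, 1L]
    support <- max(0L, r1 + c1 - N):min(r1, c1)
    d <- dhyper(support, c1, N - c1, r1)
    pObs <- dhyper(x, c1, N - c1, r1)
    p <- min(1, sum(d[d <= pObs * (1 + .REL_TOL)]))
    or <- (table[1L, 1L] * table[2L, 2L]) / (table[1L, 2L] * table[2L, 1L])
    list(p = p, oddsRatio = or)
}

#' Two-sided Freeman-Halton exact test for an r x c table
#'
#' Exhaustively enumerates every table consistent with the observed margins
#' and sums the probabilities of those no more probable than the observed
#' table (probability-mass criterion, 1e-7 relative tolerance). Intended for
#' the small cohort-scale tables of this pipeline; tables with a grand total
#' above 200 are refused.
#'
#' @param table an r x c matrix of nonnegative integer counts (r, c >= 2).
#' @return The two-sided p-value.
#' @examples
#' fisherExactRxC(matrix(c(4, 7, 6, 3, 5, 0), nrow = 2))  # CD3 IHC layout
#' @export
fisherExactRxC <- function(table) {
    table <- as.matrix(table)
    if (nrow(table) < 2L || ncol(table) < 2L)
        stop("'table' must be at least 2x2")
    .checkCounts(table)
    N <- sum(table)
    if (N == 0) stop("zero grand total")
    if (N > 200)
        stop("grand total above 200: exhaustive enumeration refused; ",
             "use a Monte Carlo method instead")
    rs <- rowSums(table); cs <- colSums(table)
    lconst <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N)
    logPObs <- lconst - sum(lfactorial(table))
    thr <- logPObs + log1p(.REL_TOL)
    total <- 0
    nr <- length(rs); nc <- length(cs)
    ## depth-first fill, row-major; prune on impossible remaining margins
    rec <- function(i, j, rowLeft, colLeft, logAcc) {
        if (i == nr) {
            ## last row forced by column margins
            if (any(colLeft < 0)) return()
            lp <- logAcc - sum(lfactorial(colLeft))
            if (lp <= thr) total <<- total + exp(lp)
            return()
        }
        if (j == nc) {
            ## last cell of row i forced
            if (rowLeft < 0 || rowLeft > colLeft[nc]) return()
            rec(i + 1L, 1L, rs[i + 1L], colLeft - c(rep(0, nc - 1L), rowLeft),
                logAcc - lfactorial(rowLeft))
            return()
        }
        hi <- min(rowLeft, colLeft[j])
        for (v in 0:hi) {
            cl <- colLeft; cl[j] <- cl[j] - v
            rec(i, j + 1L, rowLeft - v, cl, logAcc - lfactorial(v))
        }
    }
    rec(1L, 1L, rs[1L], cs, lconst)
    min(1, total)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1
#' and returned in input order.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed and
#'   propagated).
#' @return Vector of q-values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
    if (!is.numeric(p) || any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items from a
#' universe of `N` containing `K` successes.
#'
#' @param N universe size.
#' @param K number of successes in the universe.
#' @param n number of draws.
#' @param k observed overlap.
#' @return The exact upper-tail probability.
#' @examples
#' hypergeometricTail(10, 5, 5, 5)  # 1 / choose(10, 5)
#' @export
hypergeometricTail <- function(N, K, n, k) {
    stopifnot(length(N) == 1L, length(K) == 1L, length(n) == 1L,
              length(k) == 1L)
    if (anyNA(c(N, K, n, k)) || k < 0 || n < 0 || K < 0 ||
        K > N || n > N || k > min(n, K))
        stop("inconsistent hypergeometric arguments: need 0 <= k <= min(n, K)",
             " and K, n <= N")
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()]. Subjects censored at an event time are
#' counted at risk at that time. The median is the smallest observed event
#' time with survival probability `<= 0.5` (NA when the curve never drops
#' that far).
#'
#' @param time positive event/censoring times (months).
#' @param event event indicator (1 = event, 0 = censored).
#' @return A list with `time` (distinct event times), `surv` (survival after
#'   each), `nRisk`, `nEvent`, and `median`.
#' @examples
#' kmEstimator(c(1, 2, 3), c(1, 1, 1))$surv  # 2/3, 1/3, 0
#' @export
kmEstimator <- function(time, event) {
    if (any(time <= 0) || anyNA(time))
        stop("times must be positive and non-missing")
    if (!all(event %in% c(0, 1)))
        stop("event flags must be 0 or 1")
    fit <- survfit(Surv(time, event) ~ 1, conf.type = "none")
    keep <- fit$n.event > 0
    s <- fit$surv[keep]
    t <- fit$time[keep]
    med <- if (any(s <= 0.5)) t[which(s <= 0.5)[1L]] else NA_real_
    list(time = t, surv = s, nRisk = fit$n.risk[keep],
         nEvent = fit$n.event[keep], median = med)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic with the hypergeometric
#' variance at each distinct event time (ties handled by the standard
#' formula, no continuity correction); p-value from chi-square with 1 df.
#' Wraps [survival::survdiff()].
#'
#' @param time positive event/censoring times.
#' @param event event indicator (1 = event, 0 = censored).
#' @param group two-level group labels.
#' @return A list with `chisq` and `p`.
#' @export
logrankTest <- function(time, event, group) {
    group <- as.factor(group)
    if (nlevels(group) != 2L)
        stop("exactly two groups are required")
    if (any(table(group) == 0L))
        stop("both groups must be non-empty")
    if (sum(event) < 1)
        stop("at least one event is required")
    if (any(time <= 0)) stop("times must be positive")
    fit <- survdiff(Surv(time, event) ~ group)
    chisq <- unname(fit$chisq)
    list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

## Inverse of the trigamma function by Newton iteration; used by the
## moderated-t moment matching.
trigammaInverse <- function(x) {
    vapply(x, function(y) {
        if (!is.finite(y)) return(if (y > 0) 0 else NaN)
        if (y <= 0) return(Inf)
        if (y > 1e7) return(1 / sqrt(y))
        if (y < 1e-6) return(1 / y)
        z <- 0.5 + 1 / y
        for (i in seq_len(50L)) {
            tri <- trigamma(z)
            dif <- tri * (1 - tri / y) / psigamma(z, deriv = 2L)
            z <- z + dif
            if (abs(dif / z) < 1e-10) break
        }
        z
    }, numeric(1L))
}
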