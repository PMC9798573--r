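#' Squeeze proportions away from the [0, 1] boundary
#'
#' The beta density is undefined at 0 and 1; observed proportions are
#' shrunk towards 1/2 by the standard transform
#' \code{(y * (n - 1) + 0.5) / n}, where \code{n} is the number of
#' observations.  Vectorised in \code{y}.
#'
#' @param y proportions in [0, 1].
#' @param n number of observations (>= 2).
#' @return values strictly inside (0, 1).
#' @examples
#' squeezeBoundary(0, 100)    # 0.005
#' squeezeBoundary(1, 100)    # 0.995
#' squeezeBoundary(0.5, 10)   # 0.5 (fixed point)
#' @export
squeezeBoundary <- function(y, n) {
    if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]")
    if (n < 2) stop("n must be at least 2")
    (y * (n - 1) + 0.5) / n
}

#' Beta-regression log-likelihood
#'
#' Log-likelihood of proportions under the beta regression model with a
#' logit mean link and constant precision: the mean is
#' \code{mu = plogis(beta0 + beta1 * group)} and the beta shapes are
#' \code{mu * phi} and \code{(1 - mu) * phi}.
#'
#' @param y responses strictly inside (0, 1); squeeze boundary values
#'   first (\code{\link{squeezeBoundary}}).
#' @param group 0/1 covariate vector, same length as \code{y}.
#' @param beta0,beta1 logit-scale intercept and group coefficient.
#' @param phi positive precision parameter.
#' @return the summed log density.
#' @examples
#' betaLogLik(0.5, 0, 0, 0, 2)  # log Beta(1,1) density at 0.5 = 0
#' @export
betaLogLik <- function(y, group, beta0, beta1, phi) {
    if (length(y) != length(group)) stop("y and group lengths differ")
    if (any(y <= 0 | y >= 1))
        stop("y must lie strictly inside (0, 1); squeeze boundary values")
    if (phi <= 0) stop("phi must be positive")
    mu <- stats::plogis(beta0 + beta1 * group)
    sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

#' Fit a two-group beta regression by maximum likelihood
#'
#' Fits the logit-link, constant-precision beta regression of a
#' proportion on a binary group indicator.  Optimisation is quasi-Newton
#' (BFGS) on \code{(beta0, beta1, log(phi))} from a moment-based start
#' (logits of the group means; precision from the pooled variance), with
#' one restart from a perturbed start on failure.  The standard error of
#' the group coefficient comes from the observed information matrix
#' (inverse of the numeric Hessian of the negative log-likelihood at the
#' optimum).
#'
#' @param y responses strictly inside (0, 1).
#' @param group 0/1 vector; at least 3 observations per group.
#' @return a list of class \code{"BetaRegFit"} with elements
#'   \code{beta0}, \code{beta1}, \code{phi}, \code{seBeta1},
#'   \code{loglik}, \code{converged}.
#' @export
fitBetaRegression <- function(y, group) {
    group <- as.numeric(group)
    if (any(y <= 0 | y >= 1))
        stop("y must lie strictly inside (0, 1); squeeze boundary values")
    if (sum(group == 0) < 3L || sum(group == 1) < 3L)
        stop("at least 3 observations per group are required")
    m0 <- mean(y[group == 0]); m1 <- mean(y[group == 1])
    v <- stats::var(y - ifelse(group == 1, m1, m0))
    mubar <- mean(c(m0, m1))
    phi0 <- max(mubar * (1 - mubar) / max(v, 1e-8) - 1, 0.5)
    start <- c(stats::qlogis(m0), stats::qlogis(m1) - stats::qlogis(m0),
               log(phi0))
    negll <- function(p) {
        ll <- tryCatch(betaLogLik(y, group, p[1L], p[2L], exp(p[3L])),
                       error = function(e) -Inf)
        if (!is.finite(ll)) 1e10 else -ll
    }
    fit <- .tryOptim(start, negll)
    if (is.null(fit))
        fit <- .tryOptim(start + c(0.3, -0.3, 0.5), negll)
    if (is.null(fit)) {
        return(structure(list(beta0 = NA_real_, beta1 = NA_real_,
                              phi = NA_real_, seBeta1 = NA_real_,
                              loglik = NA_real_, converged = FALSE),
                         class = "BetaRegFit"))
    }
    est <- fit$par
    # observed information on the (beta0, beta1, phi) scale
    negllNat <- function(p) {
        if (p[3L] <= 0) return(1e10)
        ll <- tryCatch(betaLogLik(y, group, p[1L], p[2L], p[3L]),
                       error = function(e) -Inf)
        if (!is.finite(ll)) 1e10 else -ll
    }
    nat <- c(est[1L], est[2L], exp(est[3L]))
    H <- tryCatch(stats::optimHess(nat, negllNat), error = function(e) NULL)
    se <- NA_real_
    ok <- FALSE
    if (!is.null(H)) {
        V <- tryCatch(solve(H), error = function(e) NULL)
        if (!is.null(V) && V[2L, 2L] > 0) {
            se <- sqrt(V[2L, 2L])
            ok <- TRUE
        }
    }
    structure(list(beta0 = nat[1L], beta1 = nat[2L], phi = nat[3L],
                   seBeta1 = se, loglik = -fit$value,
                   converged = ok && fit$convergence == 0L),
              class = "BetaRegFit")
}

.tryOptim <- function(start, fn) {
    out <- tryCatch(stats::optim(start, fn, method = "BFGS",
                                 control = list(maxit = 500)),
                    error = function(e) NULL)
    if (is.null(out) || !is.finite(out$value) || out$value >= 1e10) NULL
    else out
}

#' @export
print.BetaRegFit <- function(x, ...) {
    cat("Beta regression fit: beta0 =", signif(x$beta0, 4),
        ", beta1 =", signif(x$beta1, 4), ", phi =", signif(x$phi, 4), "\n")
    cat("  se(beta1) =", signif(x$seBeta1, 4), ", loglik =",
        signif(x$loglik, 6), ", converged =", x$converged, "\n")
    invisible(x)
}

#' Wald test on the group coefficient
#'
#' Two-sided normal p value for \code{beta1 / se(beta1)}.  A
#' non-converged fit yields p = 1 with a warning.
#'
#' @param fit a \code{"BetaRegFit"} from \code{\link{fitBetaRegression}}.
#' @return p value in (0, 1].
#' @export
waldTest <- function(fit) {
    if (!isTRUE(fit$converged) || !is.finite(fit$seBeta1)) {
        warning("non-converged beta regression fit; p reported as 1")
        return(1)
    }
    2 * stats::pnorm(-abs(fit$beta1 / fit$seBeta1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values (via \code{stats::p.adjust}), capped at 1
#' and monotone in rank; invariant to input ordering.
#'
#' @param p p values in [0, 1].
#' @return adjusted q values.
#' @examples
#' bhAdjust(c(0.002, 0.01, 0.03, 0.04))  # 0.008 0.020 0.040 0.040
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Call differentially retained introns
#'
#' Fits the two-group beta regression per intron on boundary-squeezed IR
#' ratios, computes Wald p values and BH q values, and calls an intron
#' differentially retained when \code{|delta IR| > deltaThreshold} and
#' \code{q < qThreshold}.  Delta IR is the difference of the raw
#' (unsqueezed) group mean IR ratios, second contrast level minus first
#' (cancer minus normal by default).
#'
#' @param cohort an \code{\linkS4class{IRCohort}} with two groups.
#' @param mask optional filter mask from \code{\link{applyCohortFilters}};
#'   only mask-passing introns are fitted when supplied.
#' @param contrast length-2 character: (numerator/case, denominator/
#'   reference) group labels; defaults to \code{c("cancer", "normal")}
#'   when present, otherwise the last and first group levels.
#' @param deltaThreshold strict lower bound on \code{|delta IR|}.
#' @param qThreshold strict upper bound on the BH q value.
#' @return a \code{DataFrame} with columns \code{intron_id},
#'   \code{mean_ir_normal}, \code{mean_ir_cancer}, \code{delta_ir},
#'   \code{beta1}, \code{se}, \code{p}, \code{q}, \code{significant},
#'   \code{direction} (\code{up}/\code{down}/\code{ns}).
#' @export
callDIR <- function(cohort, mask = NULL, contrast = NULL,
                    deltaThreshold = 0.1, qThreshold = 0.05) {
    stopifnot(is(cohort, "IRCohort"))
    grp <- factor(cohort$group)
    if (is.null(contrast)) {
        lv <- levels(grp)
        contrast <- if (all(c("cancer", "normal") %in% lv))
            c("cancer", "normal") else c(lv[length(lv)], lv[1L])
    }
    if (!all(contrast %in% levels(grp)))
        stop("contrast groups not present in the cohort")
    ir <- assay(cohort, "irRatio")
    keep <- if (is.null(mask)) rep(TRUE, nrow(ir)) else as.logical(mask$pass_all)
    ids <- rownames(ir)[keep]
    isCase <- grp == contrast[1L]
    isRef <- grp == contrast[2L]
    use <- isCase | isRef
    g01 <- as.numeric(isCase[use])
    nUse <- sum(use)
    res <- lapply(which(keep), function(i) {
        yraw <- ir[i, use]
        mRef <- mean(yraw[g01 == 0]); mCase <- mean(yraw[g01 == 1])
        ysq <- squeezeBoundary(yraw, nUse)
        fit <- fitBetaRegression(ysq, g01)
        p <- suppressWarnings(waldTest(fit))
        c(mRef = mRef, mCase = mCase, beta1 = fit$beta1, se = fit$seBeta1,
          p = p)
    })
    res <- do.call(rbind, res)
    q <- bhAdjust(res[, "p"])
    delta <- res[, "mCase"] - res[, "mRef"]
    sig <- abs(delta) > deltaThreshold & q < qThreshold
    DataFrame(intron_id = ids,
              mean_ir_normal = unname(res[, "mRef"]),
              mean_ir_cancer = unname(res[, "mCase"]),
              delta_ir = unname(delta),
              beta1 = unname(res[, "beta1"]), se = unname(res[, "se"]),
              p = unname(res[, "p"]), q = unname(q),
              significant = unname(sig),
              direction = ifelse(!sig, "ns",
                                 ifelse(delta > 0, "up", "down")))
}

#' Audic-Claverie test for two counts from libraries of known size
#'
#' Tests whether a count \code{y} in a library of size \code{N2} is
#' consistent with a count \code{x} in a library of size \code{N1} under
#' a shared Poisson rate.  The conditional distribution of \code{Y} given
#' \code{x} is
#' \deqn{P(Y = y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}}
#' evaluated in log space; the two-sided p value doubles the smaller of
#' the exactly summed tails \code{P(Y <= y)} and \code{P(Y >= y)}, capped
#' at 1.
#'
#' @param x,y observed counts (non-negative integers).
#' @param N1,N2 library sizes (positive).
#' @return two-sided p value.
#' @examples
#' audicClaverieTest(0, 0, 1e6, 1e6)  # 1: P(Y = 0 | 0) is exactly 0.5
#' @export
audicClaverieTest <- function(x, y, N1, N2) {
    if (x < 0 || y < 0 || x != round(x) || y != round(y))
        stop("x and y must be non-negative integers")
    if (N1 <= 0 || N2 <= 0) stop("N1 and N2 must be positive")
    lower <- .acCumLog(x, y, N1, N2)
    # P(Y >= y) = 1 - P(Y <= y - 1), exact complement of the lower tail
    upper <- if (y == 0) 0 else .acCumLog(x, y - 1, N1, N2)
    pLow <- exp(lower)
    pHigh <- -expm1(upper)          # 1 - exp(upper), accurate near 1
    if (y == 0) pHigh <- 1
    min(1, 2 * min(pLow, pHigh))
}

# log P(Y <= k | x) by exact log-space summation
.acCumLog <- function(x, k, N1, N2) {
    r <- log(N2) - log(N1)
    denom <- log1p(exp(r))           # log(1 + N2/N1)
    ks <- 0:k
    terms <- ks * r + lgamma(x + ks + 1) - lgamma(x + 1) - lgamma(ks + 1) -
        (x + ks + 1) * denom
    m <- max(terms)
    m + log(sum(exp(terms - m)))
}

#' Audic-Claverie conditional probability mass
#'
#' \code{P(Y = y | x)} for the model behind
#' \code{\link{audicClaverieTest}}; exposed for tail-mass diagnostics.
#'
#' @inheritParams audicClaverieTest
#' @return the probability mass at \code{y}.
#' @export
audicClaverieProb <- function(x, y, N1, N2) {
    r <- log(N2) - log(N1)
    exp(y * r + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(exp(r)))
}
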