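# Phylogenetic generalized least squares with Pagel's lambda estimated by
# maximum likelihood.
#
# Model: y = X beta + e,  e ~ N(0, sigma2 * C(lambda)), where C(1) is the
# Brownian covariance from shared root-to-tip path lengths and C(lambda)
# multiplies the off-diagonal entries by lambda in [0, 1]. For fixed lambda
# the GLS estimate is beta = (X' C^-1 X)^-1 X' C^-1 y with ML
# sigma2 = r' C^-1 r / n; lambda maximizes the profile log-likelihood over
# [0, 1] (grid at step 0.01, then local refinement). REML is available by
# flag. beta, lambda and the slope p-value are invariant to rescaling all
# branch lengths; sigma2 rescales.

#' Prune a phylogeny to a species subset
#'
#' Drops tips not in `species` (species absent from the tree are reported
#' with a warning and dropped from the subset). The induced subtree keeps
#' all pairwise patristic distances among retained tips; degree-2 internal
#' nodes are suppressed.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param species Character vector of tip labels to keep.
#' @return The pruned `phylo` tree. Fewer than 3 retained tips is an error.
#' @export
prune_tree <- function(tree, species) {
  stopifnot(inherits(tree, "phylo"))
  miss <- setdiff(species, tree$tip.label)
  if (length(miss))
    warning("species not in tree, dropped: ", paste(miss, collapse = ", "))
  keep <- intersect(species, tree$tip.label)
  if (length(keep) < 3L) stop("fewer than 3 species retained after pruning")
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

# Profile quantities at a fixed lambda via Cholesky of C(lambda).
.pgls_profile <- function(lambda, X, y, C, reml = FALSE) {
  n <- length(y); p <- ncol(X)
  V <- C * lambda; diag(V) <- diag(C)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(ll = -Inf))
  Xs <- backsolve(R, X, transpose = TRUE)
  ys <- backsolve(R, y, transpose = TRUE)
  fit <- stats::lm.fit(Xs, ys)
  beta <- fit$coefficients
  r <- ys - Xs %*% beta
  rss <- sum(r * r)
  ldet <- 2 * sum(log(diag(R)))
  if (reml) {
    sig2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi * sig2) + 1) + ldet +
                    determinant(crossprod(Xs), logarithm = TRUE)$modulus)
  } else {
    sig2 <- rss / n
    ll <- -0.5 * (n * (log(2 * pi * sig2) + 1) + ldet)
  }
  list(ll = as.numeric(ll), beta = beta, sig2 = sig2, rss = rss,
       Xs = Xs, ys = ys, R = R)
}

#' Phylogenetic generalized least squares regression
#'
#' Fits `formula` by GLS under a Brownian covariance with Pagel's lambda
#' transform; `lambda = "ML"` (default) profiles lambda over \[0, 1\] by
#' maximum likelihood, or pass a fixed numeric lambda. Rows of `data` are
#' matched to tree tips via a `species` column if present, else rownames.
#' The slope p-value uses a t statistic on n - p degrees of freedom; R
#' squared is the GLS-weighted proportion of variance about the GLS mean at
#' the fitted lambda.
#'
#' @param formula Model formula, e.g. `cluster_gc ~ log_paralog`.
#' @param data data.frame of tip-level observations.
#' @param tree A `phylo` tree whose tip set matches the data (the tree is
#'   pruned to the data's species first).
#' @param lambda `"ML"` or a fixed value in \[0, 1\].
#' @param method `"ML"` (default) or `"REML"` for the lambda profile.
#' @param grid_step Grid resolution of the lambda profile (default 0.01).
#' @return Object of class `pgls` with coefficients, standard errors,
#'   `lambda`, ML `sigma2`, `logLik`, `r.squared`, p-values, fitted values
#'   and residuals; supported by print, summary, coef, vcov, predict,
#'   residuals, fitted, simulate, plot, logLik and nobs methods.
#' @examples
#' tr <- ape::rcoal(16)
#' pan <- simulate_species_panel(tr, b = -0.03, seed = 7)
#' fit <- pgls(cluster_gc ~ log_paralog, pan$table, tr)
#' summary(fit)
#' @export
pgls <- function(formula, data, tree, lambda = "ML",
                 method = c("ML", "REML"), grid_step = 0.01) {
  method <- match.arg(method)
  stopifnot(inherits(tree, "phylo"), is.data.frame(data))
  sp <- if ("species" %in% names(data)) as.character(data$species)
        else rownames(data)
  if (anyDuplicated(sp)) stop("duplicated species in data")
  if (!all(sp %in% tree$tip.label))
    stop("species missing from tree: ",
         paste(setdiff(sp, tree$tip.label), collapse = ", "))
  tree <- prune_tree(tree, sp)
  data <- data[match(tree$tip.label, sp), , drop = FALSE]

  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y); p <- ncol(X)
  if (n < 3L) stop("need at least 3 species")
  C <- ape::vcv(tree)

  # duplicate zero-distance tips make C(1) singular
  D <- outer(diag(C), diag(C), "+") - 2 * C
  dup <- which(D < 1e-12 & upper.tri(D), arr.ind = TRUE)
  if (nrow(dup))
    stop("zero patristic distance between tips: ",
         paste(apply(dup, 1, function(i)
           paste(rownames(C)[i], collapse = "/")), collapse = ", "))

  reml <- method == "REML"
  if (identical(lambda, "ML")) {
    grid <- seq(0, 1, by = grid_step)
    lls <- vapply(grid, function(l) .pgls_profile(l, X, y, C, reml)$ll, 0)
    j <- which.max(lls)
    lo <- max(0, grid[j] - grid_step); hi <- min(1, grid[j] + grid_step)
    opt <- stats::optimize(function(l) .pgls_profile(l, X, y, C, reml)$ll,
                           interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
    lambda_hat <- if (opt$objective > lls[j]) opt$maximum else grid[j]
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
    lambda_hat <- lambda
  }

  pr <- .pgls_profile(lambda_hat, X, y, C, reml = FALSE)
  if (!is.finite(pr$ll)) stop("singular covariance at lambda = ", lambda_hat)
  beta <- pr$beta
  s2_t <- pr$rss / (n - p)                       # for SEs and t tests
  XtXi <- chol2inv(chol(crossprod(pr$Xs)))
  se <- sqrt(diag(XtXi) * s2_t)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  # GLS total SS about the GLS mean (intercept-only fit at the same lambda)
  pr0 <- .pgls_profile(lambda_hat, matrix(1, n, 1), y, C, reml = FALSE)
  r2 <- 1 - pr$rss / pr0$rss
  fitted <- drop(X %*% beta)

  out <- list(coefficients = stats::setNames(drop(beta), colnames(X)),
              se = stats::setNames(se, colnames(X)),
              tstat = stats::setNames(tval, colnames(X)),
              p.value = stats::setNames(pval, colnames(X)),
              lambda = lambda_hat, sigma2 = pr$sig2,
              logLik = pr$ll, r.squared = r2,
              n = n, df.residual = n - p,
              vcov = XtXi * s2_t,
              fitted.values = stats::setNames(fitted, tree$tip.label),
              residuals = stats::setNames(y - fitted, tree$tip.label),
              normalized.residuals = drop(pr$ys - pr$Xs %*% beta),
              method = method, formula = formula, call = match.call(),
              tree = tree, C = C, model = mf)
  class(out) <- "pgls"
  out
}

#' @export
#' @method print pgls
print.pgls <- function(x, digits = 4, ...) {
  cat("Phylogenetic GLS (Pagel's lambda, ", x$method, ")\n", sep = "")
  cat("  ", deparse(x$formula), ",  n = ", x$n, " species\n", sep = "")
  print(round(x$coefficients, digits))
  cat(sprintf("lambda = %.3f, sigma2 = %.4g, logLik = %.3f, R2 = %.3f\n",
              x$lambda, x$sigma2, x$logLik, x$r.squared))
  invisible(x)
}

#' @export
#' @method summary pgls
summary.pgls <- function(object, ...) {
  ct <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
              `t value` = object$tstat, `Pr(>|t|)` = object$p.value)
  structure(list(coefficients = ct, lambda = object$lambda,
                 sigma2 = object$sigma2, r.squared = object$r.squared,
                 logLik = object$logLik, n = object$n,
                 df.residual = object$df.residual,
                 formula = object$formula, method = object$method),
            class = "summary.pgls")
}

#' @export
#' @method print summary.pgls
print.summary.pgls <- function(x, ...) {
  cat("Phylogenetic GLS (Pagel's lambda, ", x$method, ")\n", sep = "")
  cat("  ", deparse(x$formula), ",  n = ", x$n, " species\n\n", sep = "")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nlambda = %.3f, sigma2 = %.4g, logLik = %.3f, R2 = %.3f\n",
              x$lambda, x$sigma2, x$logLik, x$r.squared))
  invisible(x)
}

#' @export
#' @method coef pgls
coef.pgls <- function(object, ...) object$coefficients

#' @export
#' @method vcov pgls
vcov.pgls <- function(object, ...) object$vcov

#' @export
#' @method logLik pgls
logLik.pgls <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) + 2L,
            nobs = object$n, class = "logLik")
}

#' @export
#' @method nobs pgls
nobs.pgls <- function(object, ...) object$n

#' @export
#' @method fitted pgls
fitted.pgls <- function(object, ...) object$fitted.values

#' @export
#' @method residuals pgls
residuals.pgls <- function(object, type = c("response", "normalized"), ...) {
  type <- match.arg(type)
  if (type == "response") object$residuals else object$normalized.residuals
}

#' @export
#' @method predict pgls
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  tt <- stats::delete.response(stats::terms(object$formula))
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  drop(X %*% object$coefficients)
}

#' @export
#' @method simulate pgls
simulate.pgls <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  V <- object$C * object$lambda; diag(V) <- diag(object$C)
  Lc <- t(chol(object$sigma2 * V))
  n <- object$n
  out <- as.data.frame(
    object$fitted.values + Lc %*% matrix(stats::rnorm(n * nsim), n, nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- names(object$fitted.values)
  out
}

#' @export
#' @method plot pgls
plot.pgls <- function(x, ...) {
  mf <- x$model
  if (ncol(mf) != 2L) {
    graphics::plot(x$fitted.values, residuals(x),
                   xlab = "fitted", ylab = "residuals", ...)
    graphics::abline(h = 0, lty = 2)
  } else {
    graphics::plot(mf[[2L]], mf[[1L]], xlab = names(mf)[2L],
                   ylab = names(mf)[1L], ...)
    graphics::abline(x$coefficients[1L], x$coefficients[2L])
  }
  invisible(x)
}
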