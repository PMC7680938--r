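#' Realized genomic relationship (kinship) matrix
#'
#' VanRaden-type realized relationship matrix from marker dosages: dosages
#' are centred by twice the observed allele frequency, cross-multiplied,
#' and divided by `2 * sum(p * (1 - p))`.  Allele frequencies are computed
#' from the individuals supplied (typically the union of all genotyped
#' clones in the current analysis), so the off-diagonal mean is
#' approximately zero by construction and diagonal entries are near
#' 1 + inbreeding.
#'
#' @param M Dosage matrix, individuals x markers, entries 0/1/2, with
#'   individual ids as row names.
#' @return Symmetric kinship matrix with matching dimnames.
#' @export
compute_kinship <- function(M) {
  stopifnot(is.matrix(M), nrow(M) >= 2, !is.null(rownames(M)))
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic in this genotype set")
  Mp <- M[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(Mp, 2L, 2 * p, "-")
  K <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  (K + t(K)) / 2
}

#' Genomic BLUP with heterogeneous residual variances
#'
#' Fits the single-random-effect mixed model
#' \deqn{y = X\beta + Zu + \epsilon,\quad u \sim N(0, K\sigma^2_u),\quad
#'       \epsilon \sim N(0, R\sigma^2_e)}
#' where the only fixed effect is the overall mean (X is a column of 1s),
#' Z maps phenotype records to genotyped clones (a clone may have records
#' from several trial stages), K is a marker-derived kinship matrix, and R
#' is a known diagonal matrix of *relative* per-record error variances.
#' The system is premultiplied by R^(-1/2), which makes the transformed
#' residuals homoscedastic, and the transformed model is solved in the
#' ordinary way.  Because R only sets relative weights, multiplying all of
#' its entries by a positive constant leaves every prediction unchanged.
#'
#' Variance components are estimated by REML, profiled over the variance
#' ratio \eqn{\lambda = \sigma^2_u / \sigma^2_e} via a spectral
#' decomposition of the transformed genetic covariance, so each fit needs
#' a single eigendecomposition of an n_clones-sized matrix.  The
#' decomposition exploits that Z'R^(-1)Z is diagonal: the non-null
#' spectrum of R^(-1/2) Z K Z' R^(-1/2) equals that of
#' S^(1/2) K S^(1/2) with S = diag(Z'R^(-1)Z).
#'
#' Random effects for every clone in `K` (including unphenotyped
#' selection candidates) are obtained from the kinship covariance with the
#' training clones; phenotyped candidates' own records contribute, giving
#' a weighted average of own phenotype and information from relatives.
#'
#' @param formula Model formula; only `value ~ 1` (an overall mean) is
#'   supported, matching the breeding-programme model.
#' @param data Data frame of phenotype records, one row per record.
#' @param K Kinship matrix covering (at least) every clone with a record;
#'   clones present in `K` but without records are predicted as
#'   candidates.
#' @param id Name of the column holding clone labels (matched to
#'   `rownames(K)`; for mislabeled clones the label's linked genotype is
#'   what `K` was computed from).
#' @param weights Name of the column holding the relative residual
#'   variances (the diagonal of R).
#' @param lambda Optional fixed variance ratio sigma2_u / sigma2_e; when
#'   supplied REML is skipped (used for oracle comparisons and testing).
#' @param interval Log-lambda search interval for REML.
#' @param tol Convergence tolerance of the one-dimensional REML search on
#'   the variance ratio (1e-8).
#' @return An object of class `gblup` with components `mu` (estimated
#'   overall mean), `u` (named vector of BLUPs for every clone in `K`),
#'   `sigma2_u`, `sigma2_e`, `lambda`, `logLik` (restricted), `n`
#'   (records), `train_ids`, and internal solver state used by
#'   [predict.gblup()].
#' @seealso [predict.gblup()], [compute_kinship()]
#' @export
gblup <- function(formula = value ~ 1, data, K, id = "clone_id",
                  weights = "error_variance", lambda = NULL,
                  interval = c(-25, 25), tol = 1e-8) {
  stopifnot(is.data.frame(data), nrow(data) >= 2, is.matrix(K))
  tf <- stats::terms(formula)
  if (length(attr(tf, "term.labels")) > 0L || attr(tf, "intercept") != 1L) {
    stop("only an overall-mean model (value ~ 1) is supported")
  }
  y <- data[[as.character(formula[[2]])]]
  ids <- as.character(data[[id]])
  r <- data[[weights]]
  stopifnot(is.numeric(y), is.numeric(r), all(r > 0), !anyNA(y))
  kid <- rownames(K)
  if (anyNA(match(ids, kid))) stop("record clone(s) missing from K")
  tids <- kid[kid %in% ids]            # training clones, in K order
  ji <- match(ids, tids)               # record -> training clone
  n <- length(y)
  q <- length(tids)

  ## id-level sufficient statistics of the R^(-1/2) transform
  s <- as.vector(rowsum(1 / r, ji))            # Z'R^(-1)Z diagonal
  ty <- as.vector(rowsum(y / r, ji))           # Z'R^(-1)y
  yy <- sum(y^2 / r)
  xx <- sum(1 / r)
  xy <- sum(y / r)

  sq <- sqrt(s)
  B <- (sq %o% sq) * K[tids, tids]
  eg <- eigen(B, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  E <- eg$vectors
  U1y <- as.vector(crossprod(E, ty / sq))
  U1x <- as.vector(crossprod(E, sq))

  quadratics <- function(lam) {
    g <- lam * d / (lam * d + 1)
    Qxx <- xx - sum(g * U1x^2)
    Qxy <- xy - sum(g * U1x * U1y)
    Qyy <- yy - sum(g * U1y^2)
    beta <- Qxy / Qxx
    rss <- max(Qyy - Qxy^2 / Qxx, 1e-300)
    list(g = g, Qxx = Qxx, beta = beta, rss = rss)
  }
  neg2reml <- function(loglam) {
    lam <- exp(loglam)
    qd <- quadratics(lam)
    (n - 1) * log(qd$rss) + sum(log1p(lam * d)) + log(qd$Qxx)
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(neg2reml, interval = interval, tol = tol)
    lambda <- exp(opt$minimum)
    if (abs(opt$minimum - interval[1]) < 1e-6 ||
        abs(opt$minimum - interval[2]) < 1e-6) {
      warning("REML variance-ratio estimate at search boundary")
    }
  }
  qd <- quadratics(lambda)
  sigma2_e <- qd$rss / (n - 1)
  sigma2_u <- lambda * sigma2_e
  ## a = Z' R^(-1/2) V^(-1) (y_t - X_t beta) * sigma2_e  (id-level workvector)
  a <- (ty - qd$beta * s) -
    sq * as.vector(E %*% (qd$g * (U1y - qd$beta * U1x)))
  u <- as.vector(lambda * K[, tids, drop = FALSE] %*% a)
  names(u) <- kid
  ll <- -0.5 * ((n - 1) * (log(2 * pi * sigma2_e) + 1) +
                  sum(log1p(lambda * d)) + log(qd$Qxx / sigma2_e))
  structure(list(mu = qd$beta, u = u, sigma2_u = sigma2_u,
                 sigma2_e = sigma2_e, lambda = lambda, logLik = ll,
                 n = n, n_ids = q, train_ids = tids, alpha = a,
                 record_ids = ids, y = y, r = r,
                 call = match.call()),
            class = "gblup")
}

#' @export
print.gblup <- function(x, ...) {
  cat("Genomic BLUP (heteroscedastic residuals, REML)\n")
  cat(sprintf("  %d records on %d clones (%d clones in K)\n",
              x$n, x$n_ids, length(x$u)))
  cat(sprintf("  sigma2_u = %.4f, sigma2_e = %.4f (lambda = %.4f)\n",
              x$sigma2_u, x$sigma2_e, x$lambda))
  cat(sprintf("  mean = %.4f, restricted logLik = %.2f\n", x$mu, x$logLik))
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  out <- list(n = object$n, n_ids = object$n_ids,
              n_candidates = length(object$u) - object$n_ids,
              mu = object$mu, sigma2_u = object$sigma2_u,
              sigma2_e = object$sigma2_e, lambda = object$lambda,
              logLik = object$logLik,
              u_range = range(object$u))
  class(out) <- "summary.gblup"
  out
}

#' @export
print.summary.gblup <- function(x, ...) {
  cat("Genomic BLUP fit\n")
  cat(sprintf("  records: %d | training clones: %d | extra candidates in K: %d\n",
              x$n, x$n_ids, x$n_candidates))
  cat(sprintf("  variance components: sigma2_u %.4f, sigma2_e %.4f, ratio %.4f\n",
              x$sigma2_u, x$sigma2_e, x$lambda))
  cat(sprintf("  overall mean %.4f; BLUP range [%.3f, %.3f]\n",
              x$mu, x$u_range[1], x$u_range[2]))
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) c(mu = object$mu)

#' Predict genotypic values from a GBLUP fit
#'
#' Returns `mu + u` for the requested clones.  With the fitted kinship
#' (default) this is a lookup of the BLUPs computed at fit time; with a
#' larger kinship matrix covering new candidates it projects the training
#' information through the kinship covariance,
#' `u_new = lambda * K[new, train] %*% a`, which reproduces the one-shot
#' mixed-model solution that includes the candidates with missing
#' phenotypes.
#'
#' @param object A `gblup` fit.
#' @param ids Clone labels to predict (default: everything in `K`).
#' @param K Optional kinship matrix covering the training clones and the
#'   requested ids.
#' @param ... Unused.
#' @return Named numeric vector of predicted genotypic values.
#' @export
predict.gblup <- function(object, ids = NULL, K = NULL, ...) {
  if (is.null(K)) {
    if (is.null(ids)) ids <- names(object$u)
    if (anyNA(match(ids, names(object$u)))) {
      stop("unknown clone(s); supply a kinship matrix covering them")
    }
    return(object$mu + object$u[ids])
  }
  if (is.null(ids)) ids <- rownames(K)
  if (anyNA(match(ids, rownames(K)))) stop("requested clone(s) absent from K")
  if (anyNA(match(object$train_ids, colnames(K)))) {
    stop("K must cover all training clones")
  }
  u <- as.vector(object$lambda *
                   K[ids, object$train_ids, drop = FALSE] %*% object$alpha)
  stats::setNames(object$mu + u, ids)
}

#' @export
fitted.gblup <- function(object, ...) {
  object$mu + object$u[object$record_ids]
}

#' @export
residuals.gblup <- function(object, ...) {
  object$y - fitted(object)
}
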