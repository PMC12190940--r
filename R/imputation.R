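#' Fit a probabilistic PCA model to incomplete data
#'
#' Fits the latent linear model \code{Y = mu + W Z + E} (isotropic Gaussian
#' noise, standard-normal latent scores) by expectation-maximization with
#' the missing entries treated as latent. The E-step computes posterior
#' latent scores and posterior moments of the missing cells per record; the
#' M-step re-estimates \code{mu}, \code{W} and the noise variance from the
#' expected sufficient statistics. With \code{shrinkage = TRUE} an
#' automatic-relevance-determination prior is placed on the columns of
#' \code{W}, so the precision of unneeded components grows and they decay
#' towards zero (Bayesian PCA-style imputation).
#'
#' Convergence is declared when the relative change of the observed-data
#' log-likelihood (the quantity EM increases monotonically) drops below
#' \code{tol}.
#'
#' @param x A \code{cohort} or a numeric records-by-features matrix, with
#'   \code{NA} marking missing entries. Every feature needs at least two
#'   observed values.
#' @param n_components Number of latent components, \code{>= 1} and fewer
#'   than the number of features. Default: features minus one.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param seed Seed for the small Gaussian perturbation used to initialize
#'   \code{W}.
#' @param shrinkage Enable the ARD prior (default \code{TRUE}).
#' @return A \code{latent_linear_model} with elements \code{W} (loadings),
#'   \code{Z} (posterior mean scores), \code{mu}, \code{sigma2},
#'   \code{alpha} (component precisions, if shrinkage), \code{loglik}
#'   (trace) and \code{converged}.
#' @export
fit_latent_model <- function(x, n_components = NULL, max_iter = 500,
                             tol = 1e-8, seed = 1, shrinkage = TRUE) {
  Y <- if (inherits(x, "cohort")) as.matrix(x$data) else as.matrix(x)
  N <- nrow(Y); F_ <- ncol(Y)
  if (is.null(n_components)) n_components <- max(1L, F_ - 1L)
  k <- as.integer(n_components)
  if (k < 1L || k >= F_)
    stop("fit_latent_model: need 1 <= n_components < number of features")
  obs_per_feat <- colSums(!is.na(Y))
  if (any(obs_per_feat == 0L))
    stop("fit_latent_model: feature with all values missing")
  if (any(obs_per_feat < 2L))
    stop("fit_latent_model: every feature needs >= 2 observed values")

  mu <- colMeans(Y, na.rm = TRUE)
  sds <- apply(Y, 2, stats::sd, na.rm = TRUE)
  sds[!is.finite(sds) | sds == 0] <- 1
  set.seed(seed)
  W <- matrix(stats::rnorm(F_ * k, sd = 0.1), F_, k) * sds
  sigma2 <- mean(sds^2)
  alpha <- rep(1 / mean(sds^2), k)

  miss <- is.na(Y)
  pattern <- apply(miss, 1, function(m) paste(as.integer(m), collapse = ""))
  pat_rows <- split(seq_len(N), pattern)

  obs_loglik <- function(W, mu, sigma2) {
    ll <- 0
    for (rows in pat_rows) {
      O <- which(!miss[rows[1], ])
      p <- length(O)
      if (p == 0L) next
      C <- W[O, , drop = FALSE] %*% t(W[O, , drop = FALSE]) +
        diag(sigma2, p)
      ch <- chol(C)
      logdet <- 2 * sum(log(diag(ch)))
      R <- sweep(Y[rows, O, drop = FALSE], 2, mu[O])
      quad <- colSums(backsolve(ch, t(R), transpose = TRUE)^2)  # one per row
      ll <- ll + sum(-0.5 * (p * log(2 * pi) + logdet + quad))
    }
    ll
  }

  ll_trace <- numeric(0)
  converged <- FALSE
  Ez_all <- matrix(0, N, k)
  for (iter in seq_len(max_iter)) {
    # E-step accumulators
    sumEz <- numeric(k)
    sumEzz <- matrix(0, k, k)
    sumY <- numeric(F_)              # sum_i E[y_ij]
    sumYZ <- matrix(0, F_, k)        # sum_i E[y_ij z_i']
    sumY2 <- numeric(F_)             # sum_i E[y_ij^2]
    for (rows in pat_rows) {
      O <- which(!miss[rows[1], ])
      M <- which(miss[rows[1], ])
      WO <- W[O, , drop = FALSE]
      Minv <- solve(crossprod(WO) + diag(sigma2, k))
      Vz <- sigma2 * Minv
      R <- sweep(Y[rows, O, drop = FALSE], 2, mu[O])   # n_p x |O|
      Ez <- R %*% WO %*% Minv                          # n_p x k
      Ez_all[rows, ] <- Ez
      n_p <- length(rows)
      sumEz <- sumEz + colSums(Ez)
      sumEzz <- sumEzz + n_p * Vz + crossprod(Ez)
      # observed features
      Yo <- Y[rows, O, drop = FALSE]
      sumY[O] <- sumY[O] + colSums(Yo)
      sumYZ[O, ] <- sumYZ[O, ] + crossprod(Yo, Ez)
      sumY2[O] <- sumY2[O] + colSums(Yo^2)
      if (length(M)) {
        WM <- W[M, , drop = FALSE]
        Ey <- sweep(Ez %*% t(WM), 2, mu[M], "+")       # n_p x |M|
        sumY[M] <- sumY[M] + colSums(Ey)
        # E[y z'] = mu Ez' + w (Vz + Ez Ez') ; summed over rows
        sumYZ[M, ] <- sumYZ[M, ] + outer(mu[M], colSums(Ez)) +
          WM %*% (n_p * Vz + crossprod(Ez))
        vy <- sigma2 + rowSums((WM %*% Vz) * WM)       # Var(y_j) per j
        sumY2[M] <- sumY2[M] + n_p * vy + colSums(Ey^2)
      }
    }
    # M-step: per-feature regression of E[y] on (1, z)
    A <- rbind(c(N, sumEz), cbind(sumEz, sumEzz))      # (k+1) x (k+1)
    B <- t(cbind(sumY, sumYZ))                         # (k+1) x F
    D <- if (shrinkage) diag(c(0, alpha), k + 1L) else
      diag(0, k + 1L)
    Theta <- solve(A + sigma2 * D, B)
    mu_new <- Theta[1, ]
    W_new <- t(Theta[-1, , drop = FALSE])
    resid <- sumY2 - 2 * colSums(Theta * B) + colSums(Theta * (A %*% Theta))
    sigma2_new <- max(sum(resid) / (N * F_), 1e-10)
    mu <- mu_new; W <- W_new; sigma2 <- sigma2_new
    if (shrinkage) alpha <- F_ / (colSums(W^2) + 1e-10)
    ll <- obs_loglik(W, mu, sigma2)
    ll_trace <- c(ll_trace, ll)
    if (iter > 1L) {
      rel <- abs(ll - ll_trace[iter - 1L]) /
        (abs(ll_trace[iter - 1L]) + 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  if (!converged)
    warning("fit_latent_model: EM did not converge within max_iter")
  structure(list(W = W, Z = Ez_all, mu = mu, sigma2 = sigma2,
                 alpha = if (shrinkage) alpha else NULL,
                 loglik = ll_trace, converged = converged,
                 features = colnames(Y), n_components = k),
            class = "latent_linear_model")
}

#' @export
print.latent_linear_model <- function(x, ...) {
  cat(sprintf("<latent_linear_model> %d features, %d components, sigma2 = %.4g, %s\n",
              nrow(x$W), x$n_components, x$sigma2,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# posterior-mean reconstruction of missing entries of Y under the model
.ppca_complete <- function(model, Y) {
  miss <- is.na(Y)
  out <- Y
  k <- model$n_components
  for (i in which(rowSums(miss) > 0L)) {
    O <- which(!miss[i, ])
    M <- which(miss[i, ])
    WO <- model$W[O, , drop = FALSE]
    Ez <- solve(crossprod(WO) + diag(model$sigma2, k),
                t(WO) %*% (Y[i, O] - model$mu[O]))
    out[i, M] <- model$mu[M] + model$W[M, , drop = FALSE] %*% Ez
  }
  out
}

#' Impute missing cohort values from a fitted latent model
#'
#' Replaces every missing cell by its posterior-mean reconstruction under
#' the probabilistic PCA model; observed cells are untouched. Imputed values
#' are clipped to the feature's declared schema domain when a schema is
#' attached.
#'
#' @param model A \code{latent_linear_model} fitted on the same feature set.
#' @param x A \code{cohort}.
#' @return The completed \code{cohort}; the original missing mask is stored
#'   in the \code{"imputed_mask"} attribute.
#' @export
impute <- function(model, x) {
  stopifnot(inherits(model, "latent_linear_model"), inherits(x, "cohort"))
  if (!identical(model$features, feature_names(x)))
    stop("impute: model/cohort feature mismatch")
  Y <- as.matrix(x$data)
  mask <- is.na(Y)
  Yc <- .ppca_complete(model, Y)
  if (!is.null(x$schema)) {
    for (nm in intersect(names(x$schema), colnames(Yc))) {
      s <- x$schema[[nm]]
      j <- match(nm, colnames(Yc))
      Yc[mask[, j], j] <- pmin(pmax(Yc[mask[, j], j], s$domain_min),
                               s$domain_max)
    }
  }
  x$data <- as.data.frame(Yc)
  attr(x, "imputed_mask") <- mask
  x
}

#' Summarize imputed values
#'
#' Descriptive statistics (mean, sd, min, max) of the imputed cells only,
#' per feature, stratified by outcome class plus a pooled "Total" stratum.
#'
#' @param before Cohort before imputation (with missing values).
#' @param after The same cohort after \code{impute()}.
#' @return Data frame with columns \code{stratum, feature, n_imputed, mean,
#'   sd, min, max}; zero rows when nothing was imputed.
#' @export
imputation_report <- function(before, after) {
  stopifnot(inherits(before, "cohort"), inherits(after, "cohort"))
  if (!identical(dim(before$data), dim(after$data)))
    stop("imputation_report: cohorts differ in shape")
  mask <- is.na(as.matrix(before$data)) & !is.na(as.matrix(after$data))
  strata <- list(Total = rep(TRUE, n_records(before)),
                 `No-PE` = before$outcome == 0L,
                 PE = before$outcome == 1L)
  rows <- list()
  for (st in names(strata)) {
    for (nm in feature_names(before)) {
      j <- match(nm, feature_names(before))
      v <- after$data[[nm]][mask[, j] & strata[[st]]]
      if (length(v) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, feature = nm, n_imputed = length(v),
        mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
        min = min(v), max = max(v))
    }
  }
  if (length(rows) == 0L)
    return(data.frame(stratum = character(), feature = character(),
                      n_imputed = integer(), mean = numeric(),
                      sd = numeric(), min = numeric(), max = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
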