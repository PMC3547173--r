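# Maximum-likelihood path analysis (recursive SEM) on a correlation
# matrix, with AIC model comparison.

#' Directed path model
#'
#' A recursive (acyclic) system of standardised linear equations over
#' named variables.  Variables with no incoming edge are exogenous and
#' get free variances (and, when several, free covariances).
#'
#' @param edges Two-column character matrix or data.frame
#'   (`from`, `to`), or a list of length-2 character vectors.
#' @param variables Ordered variable names; default: every name
#'   appearing in `edges`.
#' @return An object of class `path_model`.
#' @export
path_model <- function(edges, variables = NULL) {
  if (is.list(edges) && !is.data.frame(edges))
    edges <- do.call(rbind, edges)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must be (from, to) pairs")
  colnames(edges) <- c("from", "to")
  if (is.null(variables)) variables <- unique(c(t(edges)))
  unknown <- setdiff(c(edges), variables)
  if (length(unknown)) stop("edge references unknown variable(s): ",
                            paste(unknown, collapse = ", "))
  # acyclicity by Kahn's algorithm
  rem <- edges
  todo <- variables
  repeat {
    sinks <- setdiff(todo, rem[, "from"])
    drop <- todo %in% sinks
    if (!any(drop)) break
    todo <- todo[!drop]
    rem <- rem[!(rem[, "to"] %in% sinks), , drop = FALSE]
    if (length(todo) == 0) break
  }
  if (length(todo) > 0) stop("path model contains a cycle")
  endo <- unique(edges[, "to"])
  exo <- setdiff(variables, endo)
  structure(list(variables = variables, edges = edges,
                 endogenous = endo, exogenous = exo),
            class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat("Path model:", paste(sprintf("%s -> %s", x$edges[, 1], x$edges[, 2]),
                           collapse = ", "), "\n")
  cat("  exogenous:", paste(x$exogenous, collapse = ", "), "\n")
  invisible(x)
}

#' The winning path model of the gamma-frequency analysis
#'
#' V1 size drives columnar width; width drives the interneuron drive
#' a23; a23 drives peak gamma frequency f; and V1 size keeps a direct
#' path to f.
#'
#' @return A [path_model()] object over `v1_size`, `width`, `a23`, `f`.
#' @export
model8 <- function() {
  path_model(rbind(c("v1_size", "width"),
                   c("width", "a23"),
                   c("a23", "f"),
                   c("v1_size", "f")),
             variables = c("v1_size", "width", "a23", "f"))
}

#' Model space over the gamma-frequency path structure
#'
#' All models with the `v1_size -> width` edge fixed and the four edges
#' `width -> a23`, `width -> f`, `a23 -> f`, `v1_size -> f` toggled on
#' or off (models whose a23 equation would be empty keep a23 exogenous).
#'
#' @return Named list of [path_model()] objects (16 models).
#' @export
gamma_path_models <- function() {
  toggles <- expand.grid(width_a23 = c(FALSE, TRUE),
                         width_f = c(FALSE, TRUE),
                         a23_f = c(FALSE, TRUE),
                         v1_f = c(FALSE, TRUE))
  out <- lapply(seq_len(nrow(toggles)), function(i) {
    e <- rbind(c("v1_size", "width"))
    if (toggles$width_a23[i]) e <- rbind(e, c("width", "a23"))
    if (toggles$width_f[i])   e <- rbind(e, c("width", "f"))
    if (toggles$a23_f[i])     e <- rbind(e, c("a23", "f"))
    if (toggles$v1_f[i])      e <- rbind(e, c("v1_size", "f"))
    path_model(e, variables = c("v1_size", "width", "a23", "f"))
  })
  names(out) <- apply(toggles, 1, function(r)
    paste0("m_", paste(as.integer(r), collapse = "")))
  out
}

# free parameters of a path model: path coefficients, exogenous
# (co)variances, endogenous residual variances
sem_parameters <- function(model) {
  exo <- model$exogenous
  exo_cov <- if (length(exo) > 1) t(utils::combn(exo, 2)) else
    matrix(character(0), 0, 2)
  list(n_beta = nrow(model$edges),
       exo = exo, exo_cov = exo_cov,
       endo = model$endogenous,
       n_par = nrow(model$edges) + length(exo) + nrow(exo_cov) +
         length(model$endogenous))
}

# implied covariance from parameter vector theta
sem_implied <- function(model, theta) {
  v <- model$variables
  p <- length(v)
  info <- sem_parameters(model)
  A <- matrix(0, p, p, dimnames = list(v, v))   # A[to, from] = beta
  nb <- info$n_beta
  if (nb > 0)
    A[cbind(match(model$edges[, "to"], v),
            match(model$edges[, "from"], v))] <- theta[seq_len(nb)]
  S <- matrix(0, p, p, dimnames = list(v, v))
  i <- nb
  for (x in info$exo) { i <- i + 1; S[x, x] <- theta[i] }
  if (nrow(info$exo_cov) > 0) {
    for (r in seq_len(nrow(info$exo_cov))) {
      i <- i + 1
      S[info$exo_cov[r, 1], info$exo_cov[r, 2]] <- theta[i]
      S[info$exo_cov[r, 2], info$exo_cov[r, 1]] <- theta[i]
    }
  }
  for (x in info$endo) { i <- i + 1; S[x, x] <- theta[i] }
  IA <- solve(diag(p) - A)
  IA %*% S %*% t(IA)
}

sem_start <- function(model, S) {
  v <- model$variables
  info <- sem_parameters(model)
  beta <- numeric(info$n_beta)
  resid <- stats::setNames(rep(1, length(info$endo)), info$endo)
  for (y in info$endo) {
    parents <- model$edges[model$edges[, "to"] == y, "from"]
    b <- solve(S[parents, parents, drop = FALSE], S[parents, y])
    beta[model$edges[, "to"] == y] <- b
    resid[y] <- max(0.05, S[y, y] - sum(b * S[parents, y]))
  }
  exo_var <- diag(S)[info$exo]
  exo_cov <- if (nrow(info$exo_cov) > 0)
    S[info$exo_cov] else numeric(0)
  c(beta, exo_var, exo_cov, resid)
}

#' Fit a path model to a correlation matrix by maximum likelihood
#'
#' Wishart (normal-theory) maximum likelihood treating the correlation
#' matrix as a covariance matrix with sample size `n` and divisor
#' `n - 1`: the discrepancy `ln|Sigma| + tr(S Sigma^-1)` is minimised
#' over path coefficients and variances; the log-likelihood is
#' `-(n-1)/2 (ln|Sigma| + tr(S Sigma^-1) + p ln 2pi)` and
#' `AIC = -2 logLik + 2k` with `k` free parameters.
#'
#' @param model A [path_model()] object.
#' @param corr A [correlation_matrix()] object over the model's
#'   variables.
#' @return An object of class `path_fit`: standardised path
#'   `coefficients`, `residual_variances`, the `implied`
#'   [correlation_matrix()], `loglik`, `aic`, `df` (sample moments
#'   minus free parameters), `npar`, `converged`.
#' @export
fit_path_model <- function(model, corr) {
  stopifnot(inherits(model, "path_model"),
            inherits(corr, "correlation_matrix"))
  if (!all(model$variables %in% corr$labels))
    stop("correlation matrix lacks variable(s): ",
         paste(setdiff(model$variables, corr$labels), collapse = ", "))
  v <- model$variables
  S <- corr$values[v, v]
  n <- corr$n
  p <- length(v)
  info <- sem_parameters(model)
  ldS <- determinant(S, logarithm = TRUE)$modulus[1]

  discrepancy <- function(theta) {
    Sg <- sem_implied(model, theta)
    ev <- eigen(Sg, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < 1e-10)) return(1e10)   # reject non-PD candidates
    ldet <- sum(log(ev))
    tr <- sum(S * solve(Sg))            # tr(S Sigma^-1), Sigma symmetric
    ldet + tr
  }
  th0 <- sem_start(model, S)
  opt <- stats::optim(th0, discrepancy, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  opt2 <- stats::optim(opt$par, discrepancy, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
  if (opt2$value < opt$value) opt <- opt2
  theta <- opt$par
  Sg <- sem_implied(model, theta)
  implied <- stats::cov2cor(Sg)
  loglik <- -(n - 1) / 2 * (discrepancy(theta) + p * log(2 * pi))
  k <- info$n_par
  aic <- -2 * loglik + 2 * k
  beta <- theta[seq_len(info$n_beta)]
  names(beta) <- sprintf("%s -> %s", model$edges[, "from"],
                         model$edges[, "to"])
  nb <- info$n_beta; ne <- length(info$exo); nc <- nrow(info$exo_cov)
  resid <- theta[(nb + ne + nc + 1):length(theta)]
  names(resid) <- info$endo
  structure(list(model = model,
                 coefficients = beta,
                 exogenous_variances = stats::setNames(
                   theta[nb + seq_len(ne)], info$exo),
                 residual_variances = resid,
                 implied = correlation_matrix(implied, v, n),
                 implied_cov = Sg,
                 loglik = loglik, aic = aic,
                 df = p * (p + 1) / 2 - k, npar = k, n = n,
                 observed = correlation_matrix(S, v, n),
                 converged = opt$convergence == 0),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, digits = 3, ...) {
  cat("Path-model fit (ML on the correlation matrix)\n")
  cat("  coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("  logLik = %.3f, AIC = %.3f, df = %d, npar = %d\n",
              x$loglik, x$aic, x$df, x$npar))
  invisible(x)
}

#' @export
coef.path_fit <- function(object, ...) object$coefficients

#' @export
logLik.path_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, class = "logLik")
}

#' @export
summary.path_fit <- function(object, ...) {
  cat("Implied (upper) vs observed (lower) correlations:\n")
  m <- object$implied$values
  m[lower.tri(m)] <- object$observed$values[lower.tri(m)]
  print(round(m, 3))
  print(object)
  invisible(object)
}

#' Compare path models by AIC
#'
#' Fits every model to the same correlation matrix and returns the
#' AIC-sorted ranking; ties are broken by fewer parameters.
#'
#' @param models Named list of [path_model()] objects over the same
#'   variables.
#' @param corr A [correlation_matrix()] object.
#' @return Data frame with columns `model`, `aic`, `loglik`, `npar`,
#'   `df`, ordered best first; fitted objects in attribute `fits`.
#' @export
compare_path_models <- function(models, corr) {
  if (inherits(models, "path_model")) models <- list(models)
  if (is.null(names(models)))
    names(models) <- paste0("model_", seq_along(models))
  fits <- lapply(models, fit_path_model, corr = corr)
  tab <- data.frame(model = names(models),
                    aic = vapply(fits, `[[`, numeric(1), "aic"),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    npar = vapply(fits, `[[`, numeric(1), "npar"),
                    df = vapply(fits, `[[`, numeric(1), "df"))
  ord <- order(tab$aic, tab$npar)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}
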