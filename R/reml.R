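#' @rdname fit_variance_components
#' @export
vc_models <- function() c("full", "no_covariance", "direct_only", "null")

# component order used everywhere
vc_names <- function() c("sigma_c2", "sigma_m2", "sigma_p2",
                         "sigma_om", "sigma_op", "sigma_mp", "sigma_e2")

# free components per nested model; sigma_mp is estimated only in the full
# model and excluded from the phenotypic-variance total throughout
vc_free <- function(model) {
  switch(model,
    full         = c("sigma_c2", "sigma_m2", "sigma_p2",
                     "sigma_om", "sigma_op", "sigma_mp", "sigma_e2"),
    no_covariance = c("sigma_c2", "sigma_m2", "sigma_p2", "sigma_e2"),
    direct_only  = c("sigma_c2", "sigma_e2"),
    null         = "sigma_e2",
    abort(paste0("unknown model '", model, "'"))
  )
}

#' Construct a variance-component parameter vector
#'
#' @param sigma_c2,sigma_m2,sigma_p2 Direct (child), maternal-indirect and
#'   paternal-indirect genetic variances.
#' @param sigma_om,sigma_op,sigma_mp Covariance parameters between
#'   child/mother, child/father and mother/father genetic effects.
#' @param sigma_e2 Residual variance.
#' @return Named numeric vector of length 7 (class `variance_components`).
#' @export
variance_components <- function(sigma_c2 = 0, sigma_m2 = 0, sigma_p2 = 0,
                                sigma_om = 0, sigma_op = 0, sigma_mp = 0,
                                sigma_e2 = 1) {
  structure(c(sigma_c2 = sigma_c2, sigma_m2 = sigma_m2, sigma_p2 = sigma_p2,
              sigma_om = sigma_om, sigma_op = sigma_op, sigma_mp = sigma_mp,
              sigma_e2 = sigma_e2), class = "variance_components")
}

# symmetrized cross blocks, cached on the trio_grm
vc_block_list <- function(g) {
  list(sigma_c2 = g$A_cc, sigma_m2 = g$A_mm, sigma_p2 = g$A_pp,
       sigma_om = g$A_cm + t(g$A_cm),
       sigma_op = g$A_cp + t(g$A_cp),
       sigma_mp = g$A_mp + t(g$A_mp))
}

#' Phenotypic covariance implied by trio variance components
#'
#' Builds `V = sigma_c2 A_cc + sigma_m2 A_mm + sigma_p2 A_pp +
#' sigma_om (A_cm + A_cm') + sigma_op (A_cp + A_cp') +
#' sigma_mp (A_mp + A_mp') + sigma_e2 I`. Because within-trio child-parent
#' relatedness is ~0.5, the diagonal carries `2 * sigma_om * 0.5 = sigma_om`
#' — each covariance parameter contributes once to the phenotypic variance,
#' matching the decomposition
#' `Var(Y) = sigma_c2 + sigma_m2 + sigma_p2 + sigma_om + sigma_op + sigma_e2`.
#'
#' @param vc Named component vector (see [variance_components()]).
#' @param g A `trio_grm`.
#' @return n x n symmetric covariance matrix.
#' @export
build_covariance <- function(vc, g) {
  stopifnot(inherits(g, "trio_grm"))
  n <- nrow(g$A_cc)
  blocks <- vc_block_list(g)
  v <- diag(vc[["sigma_e2"]], n)
  for (nm in names(blocks)) {
    if (vc[[nm]] != 0) v <- v + vc[[nm]] * blocks[[nm]]
  }
  v
}

#' Restricted log-likelihood (-2 scale) of a trio variance-component model
#'
#' Evaluates `-2 lR = log|V| + log|X'V^-1 X| + y'Py + (n - p) log(2 pi)`
#' with `P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1` and `p = ncol(X)`. The
#' additive constant convention (including the `(n - p) log(2 pi)` term) is
#' fixed; only differences in `-2 lR` are comparable across software.
#'
#' @param vc Named component vector.
#' @param g A `trio_grm`.
#' @param y Outcome vector (one value per trio child).
#' @param X Fixed-effect design matrix, full column rank (default:
#'   intercept).
#' @return Scalar `-2 lR`. Signals a condition of class `triogen_not_pd`
#'   when V is not positive definite (distinct from optimizer failures).
#' @export
reml_neg2ll <- function(vc, g, y, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) abort("`X` must have full column rank.")
  v <- build_covariance(vc, g)
  ch <- tryCatch(chol(v), error = function(e) NULL)
  if (is.null(ch))
    abort("covariance matrix is not positive definite at these parameters.",
          class = "triogen_not_pd")
  logdet_v <- 2 * sum(log(diag(ch)))
  vi_x <- backsolve(ch, forwardsolve(t(ch), X))
  vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  xtvix <- crossprod(X, vi_x)
  ld <- determinant(xtvix, logarithm = TRUE)
  xtviy <- crossprod(X, vi_y)
  ypy <- sum(y * vi_y) - drop(crossprod(xtviy, solve(xtvix, xtviy)))
  as.numeric(logdet_v + ld$modulus + ypy + (n - ncol(X)) * log(2 * pi))
}

# one AI-REML linear-algebra pass at theta; returns likelihood pieces,
# the projection matrix, score and average-information for the free set
reml_pass <- function(theta, free, blocks, n, y, X) {
  vc <- setNames(numeric(7), vc_names())
  vc[names(theta)] <- theta
  v <- diag(vc[["sigma_e2"]], n)
  for (nm in names(blocks)) if (vc[[nm]] != 0) v <- v + vc[[nm]] * blocks[[nm]]
  ch <- tryCatch(chol(v), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  vi <- chol2inv(ch)
  vi_x <- vi %*% X
  xtvix <- crossprod(X, vi_x)
  p_mat <- vi - vi_x %*% solve(xtvix, t(vi_x))
  py <- drop(p_mat %*% y)
  neg2ll <- 2 * sum(log(diag(ch))) +
    as.numeric(determinant(xtvix, logarithm = TRUE)$modulus) +
    sum(y * py) + (n - ncol(X)) * log(2 * pi)
  q <- length(free)
  u <- matrix(0, n, q)        # u_i = (dV/dtheta_i) P y
  tr <- numeric(q)            # tr(P dV/dtheta_i)
  for (i in seq_len(q)) {
    nm <- free[i]
    if (nm == "sigma_e2") {
      u[, i] <- py
      tr[i] <- sum(diag(p_mat))
    } else {
      u[, i] <- blocks[[nm]] %*% py
      tr[i] <- sum(p_mat * blocks[[nm]])
    }
  }
  score <- -0.5 * (tr - drop(crossprod(u, py)))
  ai <- 0.5 * crossprod(u, p_mat %*% u)
  list(neg2ll = drop(neg2ll), score = score, ai = ai)
}

#' Fit a trio variance-component model by AI-REML
#'
#' Restricted maximum likelihood estimation of the nested trio models:
#' `full` (all three genetic variances, all three covariances, residual),
#' `no_covariance` (the three variances and residual), `direct_only`
#' (child variance and residual) and `null` (residual only). Components
#' outside a model are held at zero. Optimization uses average-information
#' (AI) REML updates with step-halving, started from an equal split of the
#' phenotypic variance over the model's free variance components
#' (covariances at zero), with a Nelder-Mead fall-back on the restricted
#' likelihood if AI updates fail to converge. By default estimation is
#' unconstrained — negative variance estimates are permitted and flagged —
#' to avoid boundary bias; set `constrain = TRUE` to clamp variances at
#' zero.
#'
#' @param g A `trio_grm`.
#' @param y Outcome vector, one value per trio child, in trio order.
#' @param X Fixed-effect design matrix (default: intercept only).
#' @param model One of `vc_models()`.
#' @param constrain Clamp variance components at >= 0 during updates.
#' @param max_iter,tol Iteration cap and convergence tolerance on the
#'   change in `-2 lR`.
#' @return A `vc_fit`: `model`, `estimates` (length-7 named vector), `se`
#'   (free components; NA when the information matrix is singular),
#'   `neg2ll`, `k` (fixed-effect columns + free components), `n`, `aic`,
#'   `bic`, `converged`, `iterations`, `negative_variance` flag.
#' @export
fit_variance_components <- function(g, y, X = NULL,
                                    model = c("full", "no_covariance",
                                              "direct_only", "null"),
                                    constrain = FALSE,
                                    max_iter = 100, tol = 1e-8) {
  model <- match.arg(model)
  stopifnot(inherits(g, "trio_grm"))
  n <- length(y)
  if (n < 30) abort("need at least 30 trios for a stable REML fit.")
  if (n != nrow(g$A_cc)) abort("`y` length must match the trio count.")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) abort("`X` must have full column rank.")
  free <- vc_free(model)
  blocks <- vc_block_list(g)[setdiff(vc_names(), "sigma_e2")]
  is_var <- free %in% c("sigma_c2", "sigma_m2", "sigma_p2", "sigma_e2")
  vy <- var(y)
  theta <- setNames(numeric(length(free)), free)
  theta[is_var] <- vy / sum(is_var)

  clamp <- function(th) {
    if (constrain) th[is_var] <- pmax(th[is_var], 1e-10 * vy)
    th
  }
  pass <- reml_pass(theta, free, blocks, n, y, X)
  if (is.null(pass)) abort("initial covariance not positive definite.",
                           class = "triogen_not_pd")
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    delta <- tryCatch(solve(pass$ai, pass$score), error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    new_pass <- NULL
    repeat {
      cand <- clamp(theta + step * delta)
      new_pass <- reml_pass(cand, free, blocks, n, y, X)
      if (!is.null(new_pass) && new_pass$neg2ll <= pass$neg2ll + 1e-10) break
      step <- step / 2
      if (step < 1e-10) { new_pass <- NULL; break }
    }
    if (is.null(new_pass)) break
    done <- abs(pass$neg2ll - new_pass$neg2ll) < tol
    theta <- clamp(theta + step * delta)
    pass <- new_pass
    if (done) { converged <- TRUE; break }
  }
  if (!converged) {
    # generic fall-back: direct minimization of -2 lR
    obj <- function(th) {
      p <- reml_pass(setNames(th, free), free, blocks, n, y, X)
      if (is.null(p)) return(.Machine$double.xmax) else p$neg2ll
    }
    opt <- optim(theta, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    cand <- clamp(setNames(opt$par, free))
    p2 <- reml_pass(cand, free, blocks, n, y, X)
    if (!is.null(p2) && p2$neg2ll <= pass$neg2ll + 1e-8) {
      theta <- cand; pass <- p2
      converged <- opt$convergence == 0
    }
  }
  se <- tryCatch(sqrt(diag(solve(pass$ai))), error = function(e)
    rep(NA_real_, length(free)))
  names(se) <- free
  est <- setNames(numeric(7), vc_names())
  est[free] <- theta
  k <- ncol(X) + length(free)
  structure(list(
    model = model,
    estimates = est, se = se,
    neg2ll = pass$neg2ll, k = k, n = n,
    aic = pass$neg2ll + 2 * k, bic = pass$neg2ll + k * log(n),
    converged = converged, iterations = iter,
    negative_variance = any(theta[is_var] < 0)
  ), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("<vc_fit> model =", x$model, "| n =", x$n,
      "| -2lR =", formatC(x$neg2ll, format = "f", digits = 2),
      "| AIC =", formatC(x$aic, format = "f", digits = 2),
      if (!x$converged) "| NOT CONVERGED" else "", "\n")
  free <- vc_free(x$model)
  est <- x$estimates[free]
  out <- data.frame(component = free, estimate = round(est, 4),
                    se = round(x$se[free], 4))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Fit the full nested model ladder for one outcome
#'
#' @inheritParams fit_variance_components
#' @param models Models to fit (default: all four, from richest to null).
#' @return Named list of `vc_fit` objects (class `vc_ladder`).
#' @export
fit_vc_ladder <- function(g, y, X = NULL, models = vc_models(),
                          constrain = FALSE, ...) {
  fits <- lapply(models, function(m)
    fit_variance_components(g, y, X, model = m, constrain = constrain, ...))
  names(fits) <- models
  structure(fits, class = "vc_ladder")
}
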