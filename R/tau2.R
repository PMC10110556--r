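# Between-study variance estimation for the random-effects model
# y_i = x_i' beta + u_i + e_i,  u_i ~ N(0, tau2),  e_i ~ N(0, v_i).

reml_quantities <- function(y, v, X, tau2) {
  wi <- 1 / (v + tau2)
  A <- crossprod(X, X * wi)            # X' W X
  b <- solve(A, crossprod(X, y * wi))
  r <- y - X %*% b
  Py <- as.vector(wi * r)              # P y
  B <- crossprod(X, X * wi^2)          # X' W^2 X
  D <- crossprod(X, X * wi^3)          # X' W^3 X
  Ainv <- solve(A)
  C <- Ainv %*% B
  tr_P <- sum(wi) - sum(diag(C))
  tr_PP <- sum(wi^2) - 2 * sum(diag(Ainv %*% D)) + sum(diag(C %*% C))
  score <- -0.5 * (tr_P - sum(Py^2))
  info <- 0.5 * tr_PP
  ll <- -0.5 * (sum(log(v + tau2)) + determinant(A)$modulus[1] +
                  sum(wi * r^2))
  list(score = score, info = info, ll = ll)
}

dl_tau2 <- function(y, v, X) {
  w0 <- 1 / v
  A0 <- crossprod(X, X * w0)
  b0 <- solve(A0, crossprod(X, y * w0))
  Q <- sum(w0 * (y - X %*% b0)^2)
  df <- length(y) - ncol(X)
  B0 <- crossprod(X, X * w0^2)
  C <- sum(w0) - sum(diag(solve(A0) %*% B0))
  max(0, (Q - df) / C)
}

#' Estimate the between-study variance tau-squared
#'
#' Restricted maximum likelihood (default) by Fisher scoring, or the
#' closed-form DerSimonian-Laird moment estimator. Both support an optional
#' moderator design matrix, in which case tau2 is the residual heterogeneity
#' of the meta-regression model.
#'
#' REML uses Fisher-scoring iteration (tolerance 1e-8 on successive tau2
#' values, at most 100 iterations) started from the DerSimonian-Laird value;
#' if scoring fails to converge the DerSimonian-Laird estimate is returned
#' with a warning.
#'
#' @param y Effect sizes (log response ratios or sensitivities).
#' @param v Within-study variances, all positive.
#' @param X Optional model matrix of moderators (including the intercept
#'   column); defaults to intercept-only.
#' @param method `"reml"` (default) or `"dl"`.
#' @param tol,max_iter Fisher-scoring convergence tolerance and iteration cap.
#' @return The estimated tau2 (a single non-negative number).
#' @examples
#' set.seed(1)
#' y <- rnorm(50, 0, sqrt(0.01 + 0.05))
#' estimate_tau2(y, rep(0.01, 50))
#' @export
estimate_tau2 <- function(y, v, X = NULL, method = c("reml", "dl"),
                          tol = 1e-8, max_iter = 100) {
  method <- match.arg(method)
  y <- as.numeric(y)
  if (is.null(X)) X <- matrix(1, length(y), 1)
  X <- as.matrix(X)
  if (length(y) < ncol(X) + 1) {
    abort("At least two effects beyond the model dimension are needed to estimate tau2.")
  }
  if (any(v < 0)) abort("Within-study variances must be non-negative.")
  v <- pmax(v, 1e-12)  # guard exact zeros from rounded-to-zero SEs
  tau2_dl <- dl_tau2(y, v, X)
  if (method == "dl") return(tau2_dl)

  tau2 <- tau2_dl
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    q <- reml_quantities(y, v, X, tau2)
    if (!is.finite(q$score) || !is.finite(q$info) || q$info <= 0) break
    step <- q$score / q$info
    tau2_new <- max(0, tau2 + step)
    if (abs(tau2_new - tau2) < tol) {
      tau2 <- tau2_new
      converged <- TRUE
      break
    }
    tau2 <- tau2_new
  }
  if (!converged) {
    # At the boundary the score can stay negative; tau2 = 0 is the REML max.
    if (tau2 == 0 && reml_quantities(y, v, X, 0)$score <= 0) return(0)
    warn("REML scoring did not converge; falling back to DerSimonian-Laird.")
    return(tau2_dl)
  }
  tau2
}
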