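# Statistical emulator of the flood model: partial least squares (PLS)
# regression combined with canonical correlation analysis (CCA).
#
# Inputs and outputs are standardised; NIPALS PLS extracts latent input
# scores that covary maximally with the outputs; a canonical correlation
# transform then aligns the score space with the output space and the
# prediction is the least-squares map from canonical variates to outputs.
# With zero components the emulator reduces to the training output means.

.nipals_pls <- function(X, Y, k, tol = 1e-10, maxit = 500) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, k); P <- matrix(0, p, k); TT <- matrix(0, n, k)
  Xd <- X; Yd <- Y
  for (a in seq_len(k)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var)), drop = TRUE]
    if (all(abs(u) < 1e-12)) u <- Xd[, 1]
    t_old <- rep(Inf, n)
    for (it in seq_len(maxit)) {
      w <- crossprod(Xd, u); wn <- sqrt(sum(w^2))
      if (wn < 1e-12) stop("rank-deficient input: cannot extract component ", a)
      w <- w / wn
      t <- Xd %*% w
      q <- crossprod(Yd, t); qn <- sqrt(sum(q^2))
      u <- if (qn < 1e-12) t else Yd %*% (q / qn)
      if (sum((t - t_old)^2) < tol * sum(t^2)) break
      t_old <- t
    }
    tt <- sum(t^2)
    if (tt < 1e-12) stop("rank-deficient input: component ", a, " degenerate")
    pl <- crossprod(Xd, t) / tt
    Xd <- Xd - t %*% t(pl)
    Yd <- Yd - t %*% t(crossprod(Yd, t) / tt)
    W[, a] <- w; P[, a] <- pl; TT[, a] <- t
  }
  list(W = W, P = P, scores = TT)
}

#' Fit a PLS+CCA emulator
#'
#' @param inputs numeric matrix of forcing summaries (training rows x
#'   input variables)
#' @param outputs numeric matrix of flood summaries (same rows x output
#'   variables)
#' @param n_components number of latent components (0 gives the
#'   mean-prediction null model); must satisfy
#'   `n_components <= min(ncol(inputs), nrow(inputs) - 2)`
#' @param clip01 character vector of output column names to clip into
#'   \[0, 1\] at prediction time (e.g. inundated fractions)
#' @return object of class `delta_emulator`
#' @export
fit_emulator <- function(inputs, outputs, n_components, clip01 = character()) {
  X <- as.matrix(inputs); Y <- as.matrix(outputs)
  if (nrow(X) != nrow(Y)) stop("inputs and outputs need matching rows")
  if (nrow(X) < n_components + 2)
    stop("need at least n_components + 2 training rows")
  if (n_components > min(ncol(X), nrow(X) - 1))
    stop("n_components exceeds input dimensionality")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  mx <- colMeans(X); sx <- apply(X, 2, stats::sd); sx[sx == 0] <- 1
  my <- colMeans(Y); sy <- apply(Y, 2, stats::sd); sy[sy == 0] <- 1
  Xs <- scale(X, mx, sx); Ys <- scale(Y, my, sy)

  model <- list(mx = mx, sx = sx, my = my, sy = sy,
                n_components = n_components, ynames = colnames(Y),
                clip01 = clip01)
  if (n_components == 0) {
    model$null <- TRUE
    return(structure(model, class = "delta_emulator"))
  }
  pls <- .nipals_pls(Xs, Ys, n_components)
  # projection weights: T = Xs %*% R with R = W (P'W)^-1
  R <- pls$W %*% solve(crossprod(pls$P, pls$W))
  TT <- Xs %*% R

  # canonical correlation between latent scores and standardised outputs;
  # the canonical variates lead and the orthogonal complement of the
  # latent space is retained so no predictive direction is lost
  cc <- tryCatch(stats::cancor(TT, Ys),
                 error = function(e) stop("canonical step failed: ",
                                          conditionMessage(e)))
  A <- cc$xcoef
  if (ncol(A) < n_components) {
    qa <- qr(cbind(A, diag(n_components)))
    A <- cbind(A, qr.Q(qa)[, seq(ncol(A) + 1, n_components), drop = FALSE])
  }
  U <- sweep(TT, 2, cc$xcenter) %*% A
  # least-squares map from canonical variates to standardised outputs
  B <- qr.solve(cbind(1, U), Ys)

  model$null <- FALSE
  model$R <- R; model$A <- A; model$xcenter <- cc$xcenter; model$B <- B
  structure(model, class = "delta_emulator")
}

#' Predict from a fitted emulator
#'
#' @param model a `delta_emulator`
#' @param x forcing summaries: numeric vector (one point) or matrix with
#'   the training input dimensionality
#' @return matrix of predicted flood summaries (rows match `x`); columns
#'   listed in the model's `clip01` are clipped to \[0, 1\]
#' @export
predict_emulator <- function(model, x) {
  stopifnot(inherits(model, "delta_emulator"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$mx))
    stop("input has ", ncol(x), " columns; emulator was trained with ",
         length(model$mx))
  if (model$null) {
    out <- matrix(rep(model$my, each = nrow(x)), nrow = nrow(x))
  } else {
    Xs <- scale(x, model$mx, model$sx)
    U <- sweep(Xs %*% model$R, 2, model$xcenter) %*% model$A
    Ys <- cbind(1, U) %*% model$B
    out <- sweep(sweep(Ys, 2, model$sy, "*"), 2, model$my, "+")
  }
  colnames(out) <- model$ynames
  for (cn in intersect(model$clip01, colnames(out)))
    out[, cn] <- pmin(1, pmax(0, out[, cn]))
  out
}

#' @export
print.delta_emulator <- function(x, ...) {
  cat("<delta_emulator>", x$n_components, "components;",
      length(x$mx), "inputs ->", length(x$my), "outputs\n")
  invisible(x)
}

#' Coefficient of determination of emulator predictions
#'
#' Per-output R-squared of predictions against observed values, useful
#' for cross-validation checks of emulator adequacy.
#'
#' @param model a `delta_emulator`
#' @param inputs,outputs evaluation set
#' @return named numeric vector of R-squared values per output column
#' @export
emulator_r2 <- function(model, inputs, outputs) {
  pred <- predict_emulator(model, as.matrix(inputs))
  Y <- as.matrix(outputs)
  sapply(seq_len(ncol(Y)), function(j) {
    ss <- sum((Y[, j] - mean(Y[, j]))^2)
    if (ss == 0) return(NA_real_)
    1 - sum((Y[, j] - pred[, j])^2) / ss
  }) |> stats::setNames(colnames(Y))
}
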