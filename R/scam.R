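#' @include AllClasses.R
NULL

# B-spline basis with interior knots at quantiles of the observed
# temperatures; k columns.
.scam_basis <- function(temperature, k, boundary = range(temperature)) {
  splines::bs(temperature, df = k, degree = 3,
              Boundary.knots = boundary, intercept = TRUE)
}

# Solve min ||y - X theta||^2 + ridge * ||theta_pen||^2 subject to
# theta[j] <= 0 for j in `neg`: box-constrained quadratic solved by L-BFGS-B
# and polished by exact re-solution on the inactive set (clamp-and-resolve
# until the sign constraints hold), so the solution is deterministic and
# accurate to machine precision when the active set is identified.
.constrained_ls <- function(X, y, neg, ridge = 1e-6, pen = neg) {
  p <- ncol(X)
  lam <- rep(0, p)
  lam[pen] <- ridge
  obj <- function(th) sum((y - X %*% th)^2) + sum(lam * th^2)
  grad <- function(th) drop(-2 * crossprod(X, y - X %*% th)) + 2 * lam * th
  upper <- rep(Inf, p)
  upper[neg] <- 0
  th0 <- rep(0, p)
  o <- stats::optim(th0, obj, grad, method = "L-BFGS-B", upper = upper,
                    control = list(maxit = 500, factr = 1e4))
  th <- o$par
  active <- rep(FALSE, p)
  for (it in 1:20) {
    active[neg] <- active[neg] | th[neg] > -1e-8
    free <- which(!active)
    th <- rep(0, p)
    A <- crossprod(X[, free, drop = FALSE]) + diag(lam[free], length(free))
    th[free] <- solve(A, crossprod(X[, free, drop = FALSE], y))
    if (all(th[neg] <= 1e-12)) break
  }
  th[neg] <- pmin(th[neg], 0)
  list(theta = th, active = active)
}

#' Fit a monotone shape-constrained additive model
#'
#' Per-condition monotone-decreasing smooths built from `k` B-spline basis
#' functions whose coefficients are cumulative sums of non-positive
#' increments (a non-increasing coefficient sequence yields a non-increasing
#' B-spline curve), estimated by ridge-stabilized constrained least squares
#' jointly with sum-to-zero biological replicate intercepts. Biological
#' (between-replicate) and technological (within-replicate) variance
#' components are estimated from the replicate-level and residual-level
#' decomposition, and the difference in means (DIM) — treated minus vehicle,
#' averaged over the observed temperatures — carries a standard error
#' incorporating both components.
#'
#' @param data data.frame with columns `temperature`, `value`, `condition`
#'   (two levels, `vehicle`/`treated` ordering by sort), `replicate`.
#' @param k number of basis functions per condition (default 5).
#' @param ridge ridge penalty on the increments, for identifiability.
#' @return a [ScamFit-class].
#' @export
fitScam <- function(data, k = 5, ridge = 1e-6) {
  stopifnot(all(c("temperature", "value", "condition", "replicate") %in%
                  names(data)))
  k <- as.integer(k)
  conds <- sort(unique(data$condition))
  if (length(conds) != 2) stop("fitScam expects exactly two conditions")
  if (length(unique(data$temperature)) < k)
    stop("need at least k distinct temperatures")
  for (cc in conds)
    if (length(unique(data$replicate[data$condition == cc])) < 2)
      stop("need >= 2 replicates per condition")
  n <- nrow(data)
  bnd <- range(data$temperature)
  B <- .scam_basis(data$temperature, k, bnd)
  M <- lower.tri(matrix(1, k, k), diag = TRUE) * 1   # cumulative increments
  BM <- B %*% M    # col 1: level; cols 2..k: non-positive increments
  # per-condition smooth blocks
  X_parts <- list()
  neg <- integer()
  col_cond <- character()
  for (cc in conds) {
    block <- BM * (data$condition == cc)
    colnames(block) <- paste0(cc, "_", seq_len(k))
    X_parts[[cc]] <- block
    neg <- c(neg, length(col_cond) + 2:k)
    col_cond <- c(col_cond, colnames(block))
  }
  X <- do.call(cbind, X_parts)
  # sum-to-zero replicate intercepts within condition
  Zs <- list()
  for (cc in conds) {
    reps <- sort(unique(data$replicate[data$condition == cc]))
    R <- length(reps)
    for (j in seq_len(R - 1)) {
      z <- numeric(n)
      z[data$condition == cc & data$replicate == reps[j]] <- 1
      z[data$condition == cc & data$replicate == reps[R]] <- -1
      Zs[[paste0(cc, "_u", j)]] <- z
    }
  }
  U <- do.call(cbind, Zs)
  Xfull <- cbind(X, U)
  sol <- .constrained_ls(Xfull, data$value, neg = neg, ridge = ridge)
  theta <- sol$theta
  p_smooth <- ncol(X)
  # smooth evaluators
  smooths <- lapply(conds, function(cc) {
    co <- theta[seq_len(k) + (match(cc, conds) - 1) * k]
    force(co)
    function(temp) drop(.scam_basis(temp, k, bnd) %*% M %*% co)
  })
  names(smooths) <- conds
  # variance components: replicate-mean decomposition of smooth residuals
  r_smooth <- data$value - drop(X %*% theta[seq_len(p_smooth)])
  grp <- paste(data$condition, data$replicate, sep = "\r")
  m_g <- tapply(r_smooth, grp, mean)
  n_g <- tapply(r_smooth, grp, length)
  cond_of_g <- sub("\r.*", "", names(m_g))
  dev <- m_g - tapply(m_g, cond_of_g, mean)[cond_of_g]
  df_rep <- sum(tapply(m_g, cond_of_g, length) - 1)
  resid_fine <- r_smooth - m_g[grp]
  df_err <- n - p_smooth - length(m_g)
  sigma_err <- sum(resid_fine^2) / max(df_err, 1)
  sigma_bio <- max(0, sum(dev^2) / max(df_rep, 1) - sigma_err / mean(n_g))
  # DIM and its SE via the linear functional of the (inactive-set) estimator
  grid <- sort(unique(data$temperature))
  Bg <- .scam_basis(grid, k, bnd) %*% M
  a <- numeric(ncol(Xfull))
  i_treated <- match(conds[conds != "vehicle"][1], conds)
  i_vehicle <- if ("vehicle" %in% conds) match("vehicle", conds) else 1L
  if (!"vehicle" %in% conds) { i_vehicle <- 1L; i_treated <- 2L }
  a[seq_len(k) + (i_treated - 1) * k] <- colMeans(Bg)
  a[seq_len(k) + (i_vehicle - 1) * k] <- -colMeans(Bg)
  dim_est <- sum(a * theta)
  free <- which(!sol$active)
  lam <- rep(0, ncol(Xfull)); lam[neg] <- ridge
  A <- crossprod(Xfull[, free, drop = FALSE]) +
    diag(lam[free], length(free))
  cvec <- numeric(n)
  if (any(a[free] != 0)) {
    w <- solve(A, a[free])
    cvec <- drop(Xfull[, free, drop = FALSE] %*% w)
  }
  group_sums <- tapply(cvec, grp, sum)
  dim_var <- sigma_err * sum(cvec^2) + sigma_bio * sum(group_sums^2)
  new("ScamFit", k = k, dim = dim_est, dim_se = sqrt(max(dim_var, 0)),
      sigma_bio_sq = sigma_bio, sigma_error_sq = sigma_err,
      smooths = smooths, converged = TRUE, n_obs = as.integer(n))
}
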