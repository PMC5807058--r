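#' Parse a path-model specification
#'
#' Parses a small lavaan-like model syntax: `latent =~ ind1 + ind2 + ...`
#' defines a latent variable (the first loading is fixed to 1 for
#' identification), `y ~ x1 + x2` a structural regression, and `a ~~ b` a
#' (residual) covariance. Every variable receives a free (residual)
#' variance; covariances among exogenous observed variables are free.
#'
#' @param text Model syntax, one formula per line (or separated by `;`).
#' @return An object of class `path_model_spec` with the parsed edges,
#'   variable lists and free-parameter table.
#' @export
#' @examples
#' path_model("f =~ a + b + c\n f ~ x")
path_model <- function(text) {
  lines <- unlist(strsplit(text, "[\n;]"))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  latent <- list(); reg <- list(); cov <- list()
  for (ln in lines) {
    if (grepl("=~", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "=~", fixed = TRUE)[[1]]
      latent[[trimws(parts[1])]] <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
    } else if (grepl("~~", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "~~", fixed = TRUE)[[1]])
      cov[[length(cov) + 1L]] <- parts
    } else if (grepl("~", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "~", fixed = TRUE)[[1]]
      reg[[trimws(parts[1])]] <- c(reg[[trimws(parts[1])]],
                                   trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]]))
    } else {
      abort(sprintf("Cannot parse model line: '%s'", ln))
    }
  }
  lat_names <- names(latent)
  indicators <- unique(unlist(latent))
  vars_in_reg <- unique(c(names(reg), unlist(reg)))
  observed <- setdiff(unique(c(indicators, vars_in_reg, unlist(cov))), lat_names)
  all_vars <- c(observed, lat_names)
  # incoming edges decide exogeneity
  has_in <- unique(c(indicators, names(reg)))
  exo_obs <- setdiff(observed, has_in)
  structure(
    list(latent = latent, regressions = reg, covariances = cov,
         observed = observed, latent_names = lat_names,
         all_vars = all_vars, exogenous = exo_obs),
    class = "path_model_spec"
  )
}

#' The study's structural model
#'
#' A latent behavioral mind-wandering factor measured by the four SART
#' indicators; structural paths control ~ metacog, detection ~ metacog,
#' MW ~ metacog + control; and a residual covariance between the latent MW
#' factor and the detection index.
#'
#' @return A `path_model_spec`.
#' @export
mw_path_model <- function() {
  path_model("
    mw_behav =~ nogo_fail_pct + go_fail_pct + rt_variability + anticipation_pct
    control ~ metacog
    detection ~ metacog
    mw_behav ~ metacog + control
    mw_behav ~~ detection
  ")
}

# Build RAM matrices (A directed, S symmetric) and the free-parameter table.
ram_skeleton <- function(spec) {
  v <- spec$all_vars
  nv <- length(v)
  idx <- setNames(seq_len(nv), v)
  par <- list()
  addpar <- function(label, kind, i, j, start) {
    par[[length(par) + 1L]] <<- list(label = label, kind = kind, i = i, j = j, start = start)
  }
  A_fixed <- matrix(0, nv, nv, dimnames = list(v, v))
  for (lat in names(spec$latent)) {
    inds <- spec$latent[[lat]]
    A_fixed[idx[inds[1]], idx[lat]] <- 1   # identification
    for (ind in inds[-1]) {
      addpar(paste(lat, "=~", ind), "A", idx[ind], idx[lat], 1)
    }
  }
  for (y in names(spec$regressions)) {
    for (x in spec$regressions[[y]]) {
      addpar(paste(y, "~", x), "A", idx[y], idx[x], 0)
    }
  }
  for (vv in v) {
    addpar(paste(vv, "~~", vv), "S", idx[vv], idx[vv], NA) # start set from data
  }
  for (cv in spec$covariances) {
    addpar(paste(cv[1], "~~", cv[2]), "S", idx[cv[1]], idx[cv[2]], 0)
  }
  if (length(spec$exogenous) > 1) {
    eo <- spec$exogenous
    for (i in seq_along(eo)[-1]) for (j in seq_len(i - 1)) {
      addpar(paste(eo[j], "~~", eo[i]), "S", idx[eo[i]], idx[eo[j]], 0)
    }
  }
  labels <- vapply(par, `[[`, character(1), "label")
  list(vars = v, idx = idx, A_fixed = A_fixed, par = par, labels = labels)
}

ram_sigma <- function(theta, skel, n_obs) {
  nv <- length(skel$vars)
  A <- skel$A_fixed
  S <- matrix(0, nv, nv)
  for (k in seq_along(skel$par)) {
    p <- skel$par[[k]]
    if (p$kind == "A") {
      A[p$i, p$j] <- theta[k]
    } else {
      S[p$i, p$j] <- theta[k]
      S[p$j, p$i] <- theta[k]
    }
  }
  IA <- diag(nv) - A
  B <- solve(IA)
  Sigma_all <- B %*% S %*% t(B)
  list(Sigma = Sigma_all[seq_len(n_obs), seq_len(n_obs), drop = FALSE],
       Sigma_all = Sigma_all, A = A, S = S)
}

ml_discrepancy <- function(Sigma, S_samp, logdetS) {
  ev <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ev)) return(1e10)
  logdetSig <- 2 * sum(log(diag(ev)))
  inv <- chol2inv(ev)
  logdetSig + sum(inv * S_samp) - logdetS - ncol(S_samp)
}

#' Fit a path model by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy
#' `F = log|Sigma(theta)| + tr(S Sigma^-1) - log|S| - p` over the free
#' parameters; `chi_sq = (n - 1) F(theta_hat)`. Standard errors are sandwich
#' (robust) estimates combining the numerical Hessian of the casewise
#' log-likelihood with the outer product of casewise scores; naive
#' inverse-Hessian SEs are returned alongside. The baseline (independence)
#' model for CFI is fit by the same estimator (its MLE is the diagonal of
#' `S`). Negative fitted variances are flagged as Heywood cases but the
#' estimates are still returned.
#'
#' @param spec A `path_model_spec` (or model syntax string).
#' @param data A data frame containing every observed variable; incomplete
#'   rows are dropped (listwise).
#' @return An object of class `sem_fit`; see [tidy.sem_fit()] and
#'   [glance.sem_fit()].
#' @export
fit_ml_sem <- function(spec, data) {
  if (is.character(spec)) spec <- path_model(spec)
  stopifnot(inherits(spec, "path_model_spec"))
  miss <- setdiff(spec$observed, names(data))
  if (length(miss)) {
    abort(paste0("Variables missing from data: ", paste(miss, collapse = ", ")))
  }
  X <- as.matrix(as.data.frame(data)[, spec$observed])
  X <- X[complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  skel <- ram_skeleton(spec)
  q <- length(skel$par)
  p <- length(spec$observed)
  df <- p * (p + 1) / 2 - q
  if (df < 0) abort(sprintf("Model not identified: df = %d < 0.", df))
  if (n <= q) abort(sprintf("Need n > %d free parameters; got n = %d.", q, n))
  S_samp <- cov(X)
  logdetS <- determinant(S_samp, logarithm = TRUE)$modulus[1]

  # starts: variances at half the sample variance (observed) or half the
  # first indicator's variance (latent)
  theta0 <- vapply(skel$par, function(pp) {
    if (!is.na(pp$start)) return(pp$start)
    vn <- skel$vars[pp$i]
    if (vn %in% spec$observed) 0.5 * S_samp[vn, vn]
    else 0.5 * S_samp[spec$latent[[vn]][1], spec$latent[[vn]][1]]
  }, numeric(1))

  obj <- function(th) {
    ml_discrepancy(ram_sigma(th, skel, p)$Sigma, S_samp, logdetS)
  }
  dSigma <- function(th) {
    # derivative of Sigma wrt each free parameter (central differences on
    # the 7x7 implied covariance; Sigma is smooth in theta)
    lapply(seq_along(th), function(k) {
      h <- max(1e-6, 1e-6 * abs(th[k]))
      tp <- th; tp[k] <- tp[k] + h
      tm <- th; tm[k] <- tm[k] - h
      (ram_sigma(tp, skel, p)$Sigma - ram_sigma(tm, skel, p)$Sigma) / (2 * h)
    })
  }
  grad <- function(th) {
    Sig <- ram_sigma(th, skel, p)$Sigma
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(rep(0, length(th)))
    inv <- chol2inv(ch)
    W <- inv - inv %*% S_samp %*% inv   # dF = tr(W dSigma)
    vapply(dSigma(th), function(D) sum(W * D), numeric(1))
  }
  fit <- nlminb(theta0, obj, gradient = grad,
                control = list(rel.tol = 1e-10, abs.tol = 1e-14, iter.max = 1000))
  theta <- fit$par
  names(theta) <- skel$labels
  Fmin <- fit$objective
  grad_norm <- max(abs(grad(theta)))
  chi_sq <- (n - 1) * Fmin
  base_chi <- -(n - 1) * determinant(stats::cov2cor(S_samp), logarithm = TRUE)$modulus[1]
  base_df <- p * (p - 1) / 2
  fi <- fit_indices(chi_sq, df, n, base_chi, base_df)

  mats <- ram_sigma(theta, skel, p)
  sds <- sqrt(pmax(diag(mats$Sigma_all), 1e-12))
  std <- vapply(seq_along(skel$par), function(k) {
    pp <- skel$par[[k]]
    if (pp$kind == "A") theta[k] * sds[pp$j] / sds[pp$i]
    else theta[k] / (sds[pp$i] * sds[pp$j])
  }, numeric(1))

  heywood <- any(vapply(seq_along(skel$par), function(k) {
    pp <- skel$par[[k]]
    pp$kind == "S" && pp$i == pp$j && theta[k] < 0
  }, logical(1)))

  se <- se_naive <- rep(NA_real_, q)
  scores <- NULL
  sw <- tryCatch({
    Dl <- dSigma(theta)
    ch <- chol(mats$Sigma)
    inv <- chol2inv(ch)
    Z <- sweep(X, 2, colMeans(X))
    ZI <- Z %*% inv
    scores <- vapply(Dl, function(D) {
      0.5 * (rowSums((ZI %*% D) * ZI) - sum(inv * D))
    }, numeric(n))             # n x q casewise score contributions
    B <- crossprod(scores)
    # Hessian of the total negative log-likelihood (mean held at x-bar)
    S_ml <- S_samp * (n - 1) / n
    nll <- function(th) {
      Sg <- ram_sigma(th, skel, p)$Sigma
      chh <- tryCatch(chol(Sg), error = function(e) NULL)
      if (is.null(chh)) return(1e10)
      (n / 2) * (2 * sum(log(diag(chh))) + sum(chol2inv(chh) * S_ml))
    }
    H <- optimHess(theta, nll)
    Hinv <- solve(H)
    list(se = sqrt(pmax(diag(Hinv %*% B %*% Hinv), 0)),
         se_naive = sqrt(pmax(diag(Hinv), 0)))
  }, error = function(e) NULL)
  if (!is.null(sw)) { se <- sw$se; se_naive <- sw$se_naive }

  structure(
    list(
      spec = spec, skeleton = skel,
      theta = theta, se = se, se_naive = se_naive,
      standardized = setNames(std, skel$labels),
      chi_sq = chi_sq, df = df,
      p_value = if (df > 0) pchisq(chi_sq, df, lower.tail = FALSE) else NA_real_,
      cfi = fi$cfi, rmsea = fi$rmsea,
      baseline_chi_sq = base_chi, baseline_df = base_df,
      n = n, n_free = q, F_min = Fmin, grad_norm = grad_norm,
      converged = fit$convergence == 0 || grad_norm < 1e-5, heywood = heywood,
      S = S_samp, Sigma = mats$Sigma, scores = scores
    ),
    class = "sem_fit"
  )
}

#' Chi-square based fit indices
#'
#' `CFI = 1 - max(chi_sq - df, 0) / max(baseline_chi_sq - baseline_df,
#' chi_sq - df, 0)` and `RMSEA = sqrt(max(chi_sq - df, 0) / (df * n))`.
#' A model fitting no worse than its degrees of freedom gets RMSEA 0 and
#' CFI 1. With `df = 0` (saturated) RMSEA is defined as 0.
#'
#' @param chi_sq,df Model test statistic and degrees of freedom.
#' @param n Sample size.
#' @param baseline_chi_sq,baseline_df Independence-model statistic fit by
#'   the same estimator.
#' @return A list with `cfi` and `rmsea`.
#' @export
#' @examples
#' fit_indices(12.98, 12, 61, 200, 21)$rmsea  # 0.037
fit_indices <- function(chi_sq, df, n, baseline_chi_sq, baseline_df) {
  stopifnot(df >= 0, n > 1)
  num <- max(chi_sq - df, 0)
  denom <- max(baseline_chi_sq - baseline_df, chi_sq - df, 0)
  cfi <- if (denom <= 0) 1 else 1 - num / denom
  rmsea <- if (df == 0) 0 else sqrt(num / (df * n))
  list(cfi = cfi, rmsea = rmsea)
}

#' Sandwich standard errors of a fitted path model
#'
#' @param fit A `sem_fit`.
#' @return Named numeric vector of robust standard errors.
#' @export
sandwich_se <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  setNames(fit$se, names(fit$theta))
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf(
    "ML path model fit: chi-square(%d) = %.3f, p = %.3f, CFI = %.3f, RMSEA = %.3f, n = %d\n",
    x$df, x$chi_sq, x$p_value, x$cfi, x$rmsea, x$n))
  if (x$heywood) cat("Warning: Heywood case (negative variance estimate).\n")
  invisible(x)
}
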