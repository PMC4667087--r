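#' @name reml
#' @title REML linear mixed models with unstructured within-subject covariance
#'
#' @description Longitudinal cognition is modelled with visit year as a
#' categorical within-subject variable and an unstructured residual
#' covariance over visits: for subject i with observed visit vector
#' `y_i`, `y_i ~ N(X_i beta, Sigma[o_i, o_i])` where `Sigma` is a free
#' symmetric positive-definite visits x visits matrix, subsetted to each
#' subject's observed visits (missing visits are handled by likelihood,
#' not imputation). `Sigma` is estimated by REML over its log-Cholesky
#' factor (unconstrained, always positive definite) with the fixed
#' effects profiled out by GLS; time uses sum-to-zero contrasts so a
#' predictor's main effect is its average effect across visits.
NULL

#' Log-transform a lesion volume
#'
#' Natural log of `v + epsilon_log`. Lesion volume distributions are
#' strongly right-skewed, so volumes enter all models on the log scale;
#' the epsilon floor (default: one voxel volume in cm^3) keeps zero
#' volumes finite.
#'
#' @param v volume(s) in cm^3, >= 0.
#' @param epsilon_log floor in cm^3 (default 0.024, one 2 x 2 x 6 mm
#'   voxel).
#' @return log(v + epsilon_log).
#' @export
log_transform_volume <- function(v, epsilon_log = 0.024) {
  if (any(v < 0, na.rm = TRUE)) stopf("volumes must be non-negative")
  log(v + epsilon_log)
}

theta_to_sigma <- function(theta, m) {
  L <- matrix(0, m, m)
  diag(L) <- exp(pmin(pmax(theta[seq_len(m)], -20), 20))
  if (m > 1) L[lower.tri(L)] <- theta[-seq_len(m)]
  L %*% t(L)
}

sigma_to_theta <- function(Sigma) {
  L <- t(chol(Sigma))
  c(log(diag(L)), L[lower.tri(L)])
}

#' Fit the longitudinal model by REML
#'
#' @param formula model formula for the fixed effects, e.g.
#'   `compound_executive ~ logV * visit_year + age_baseline + sex +
#'   education`. The visit variable is converted to a factor with
#'   sum-to-zero contrasts.
#' @param data data.frame, one row per subject-visit; rows with missing
#'   outcome or covariates are dropped (subjects keep their remaining
#'   visits).
#' @param subject name of the subject id column.
#' @param visit name of the visit column (its sorted unique values define
#'   the visit levels).
#' @param covariance `"unstructured"` (default) or `"scaled_identity"`
#'   (`Sigma = sigma^2 I`, the homoscedastic limit).
#' @param start optional starting covariance matrix.
#' @param control list: `maxit` (default 500), `reltol` (1e-12).
#' @return object of class `wml_lmm` with components `coefficients`,
#'   `sigma` (estimated residual covariance, visit labels on
#'   dimnames), `vcov_beta`, `reml_loglik`, `deviance`, `theta`,
#'   `converged`, `grad_norm`, `n_subjects`, `n_obs` and internal
#'   closures used by [test_effects()].
#' @export
wml_lmm <- function(formula, data, subject = "subject_id",
                    visit = "visit_year",
                    covariance = c("unstructured", "scaled_identity"),
                    start = NULL, control = list()) {
  covariance <- match.arg(covariance)
  maxit <- control$maxit %||% 500
  reltol <- control$reltol %||% 1e-12
  stopifnot(is.data.frame(data), subject %in% names(data),
            visit %in% names(data))

  wd <- data
  vf <- factor(wd[[visit]])
  m <- nlevels(vf)
  contrasts(vf) <- stats::contr.sum(m)
  wd[[visit]] <- vf

  mf <- stats::model.frame(formula, wd, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  keep <- is.finite(y) & stats::complete.cases(X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  subj <- as.character(wd[[subject]])[keep]
  pos <- as.integer(vf)[keep]
  p <- ncol(X); N <- length(y)

  if (length(unique(subj)) < 10)
    stopf("need >= 10 subjects with observed outcomes, got %d",
          length(unique(subj)))
  if (anyDuplicated(paste(subj, pos)))
    stopf("duplicate subject-visit rows")
  if (qr(X)$rank < p)
    stopf("singular fixed-effects design (collinear columns: check predictors)")

  pre <- reml_precompute(y, X, subj, pos, m)
  npar <- if (covariance == "unstructured") m * (m + 1) / 2 else 1L

  parts_fun <- function(theta) reml_parts(theta, pre, covariance)
  dev_fun <- function(theta) {
    pr <- parts_fun(theta)
    if (is.null(pr)) 1e10 else pr$dev
  }

  Sigma0 <- start %||% start_sigma(y, X, subj, pos, m)
  theta0 <- if (covariance == "unstructured") sigma_to_theta(Sigma0)
            else log(sqrt(max(mean(diag(Sigma0)), 1e-8)))

  opt <- stats::optim(theta0, dev_fun, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  theta <- opt$par
  pr <- parts_fun(theta)
  if (is.null(pr)) stopf("REML fit failed: covariance became singular")
  gnorm <- sqrt(sum(pracma::grad(dev_fun, theta)^2))
  converged <- opt$convergence == 0 && is.finite(gnorm) &&
    gnorm < 1e-3 * (1 + abs(pr$dev))

  Sigma <- if (covariance == "unstructured") theta_to_sigma(theta, m)
           else diag(exp(2 * theta), m)
  dimnames(Sigma) <- list(levels(vf), levels(vf))

  env <- new.env(parent = emptyenv())  # lazy cache for vcov(theta)
  fit <- structure(list(
    coefficients = setNames(drop(pr$beta), colnames(X)),
    sigma = Sigma, vcov_beta = pr$C,
    reml_loglik = -pr$dev / 2, deviance = pr$dev,
    theta = theta, covariance = covariance,
    converged = converged, grad_norm = gnorm, optim = opt[c("convergence", "counts")],
    n_subjects = length(unique(subj)), n_obs = N, n_visits = m,
    visit_levels = levels(vf), formula = formula,
    subject = subject, visit = visit,
    dev_fun = dev_fun, parts_fun = parts_fun, cache = env),
    class = "wml_lmm")
  if (!converged)
    warnf("REML did not converge (optim code %d, |grad| = %.2g); results flagged",
          opt$convergence, gnorm)
  fit
}

# Group subjects by missingness pattern and precompute the visit-pair
# cross-products so each REML evaluation is O(m^2 p^2) independent of n.
reml_precompute <- function(y, X, subj, pos, m) {
  p <- ncol(X)
  sid <- factor(subj)
  pat_of <- vapply(split(pos, sid), function(o) paste(sort(o), collapse = ","),
                   character(1))
  patterns <- lapply(unique(pat_of), function(key) {
    obs <- as.integer(strsplit(key, ",")[[1]])
    mp <- length(obs)
    subs <- names(pat_of)[pat_of == key]
    ns <- length(subs)
    Xarr <- array(0, c(ns, mp, p)); Yarr <- matrix(0, ns, mp)
    rows <- which(subj %in% subs)
    si <- match(subj[rows], subs); vi <- match(pos[rows], obs)
    for (r in seq_along(rows)) {
      Xarr[si[r], vi[r], ] <- X[rows[r], ]
      Yarr[si[r], vi[r]] <- y[rows[r]]
    }
    # flattened visit-pair cross-products: one matrix product per pattern
    # turns the REML evaluation into O(m^2 p^2) independent of n
    Cflat <- matrix(0, p * p, mp * mp); Eflat <- matrix(0, p, mp * mp)
    gvec <- numeric(mp * mp)
    for (a in seq_len(mp)) for (b in seq_len(mp)) {
      k <- (b - 1L) * mp + a
      Xa <- matrix(Xarr[, a, ], ns, p); Xb <- matrix(Xarr[, b, ], ns, p)
      Cflat[, k] <- crossprod(Xa, Xb)
      Eflat[, k] <- crossprod(Xa, Yarr[, b])
      gvec[k] <- sum(Yarr[, a] * Yarr[, b])
    }
    list(obs = obs, n = ns, Cflat = Cflat, Eflat = Eflat, gvec = gvec)
  })
  list(patterns = patterns, p = p, N = length(y), m = m)
}

reml_parts <- function(theta, pre, covariance) {
  m <- pre$m; p <- pre$p
  if (any(!is.finite(theta))) return(NULL)
  Sigma <- if (covariance == "unstructured") theta_to_sigma(theta, m)
           else diag(exp(2 * pmin(pmax(theta, -20), 20)), m)
  A <- matrix(0, p, p); bb <- numeric(p); q <- 0; ld <- 0
  for (pat in pre$patterns) {
    V <- Sigma[pat$obs, pat$obs, drop = FALSE]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    # refuse near-singular covariances: past this point cancellation in the
    # profiled RSS can make the deviance spuriously unbounded below
    if ((min(diag(ch)) / max(diag(ch)))^2 < 1e-10) return(NULL)
    W <- chol2inv(ch)
    ld <- ld + pat$n * 2 * sum(log(diag(ch)))
    wv <- as.vector(W)
    A <- A + matrix(pat$Cflat %*% wv, p, p)
    bb <- bb + drop(pat$Eflat %*% wv)
    q <- q + sum(pat$gvec * wv)
  }
  chA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(chA)) return(NULL)
  Ci <- chol2inv(chA)
  beta <- Ci %*% bb
  rss <- q - sum(bb * beta)
  if (rss < -1e-6 * abs(q)) return(NULL)   # catastrophic cancellation
  rss <- max(rss, 0)
  dev <- ld + 2 * sum(log(diag(chA))) + rss + (pre$N - p) * log(2 * pi)
  list(dev = dev, A = A, C = Ci, beta = beta)
}

# starting covariance from OLS residuals (pairwise-complete), clamped PD
start_sigma <- function(y, X, subj, pos, m) {
  beta0 <- qr.coef(qr(X), y)
  res <- y - drop(X %*% beta0)
  sid <- factor(subj)
  R <- matrix(NA_real_, nlevels(sid), m)
  R[cbind(as.integer(sid), pos)] <- res
  S <- suppressWarnings(cov(R, use = "pairwise.complete.obs"))
  S[!is.finite(S)] <- 0
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  floorv <- max(1e-8, 1e-4 * max(eg$values, 0))
  eg$vectors %*% diag(pmax(eg$values, floorv), m) %*% t(eg$vectors)
}

#' @export
print.wml_lmm <- function(x, ...) {
  cat(sprintf("Longitudinal REML fit (%s covariance): %d subjects, %d observations, %d visits\n",
              x$covariance, x$n_subjects, x$n_obs, x$n_visits))
  cat(sprintf("REML log-likelihood: %.3f%s\n", x$reml_loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.wml_lmm <- function(object, ...) object$coefficients

#' @export
vcov.wml_lmm <- function(object, ...) object$vcov_beta

#' @export
logLik.wml_lmm <- function(object, ...) {
  structure(object$reml_loglik, df = length(object$coefficients) +
              length(object$theta), class = "logLik")
}

#' @export
summary.wml_lmm <- function(object, ...) {
  se <- sqrt(diag(object$vcov_beta))
  tv <- object$coefficients / se
  df <- object$n_obs - length(object$coefficients)
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `t value` = tv, `Pr(>|t|)` = 2 * pt(-abs(tv), df))
  structure(list(coefficients = tab, sigma = object$sigma,
                 reml_loglik = object$reml_loglik,
                 converged = object$converged,
                 n_subjects = object$n_subjects, n_obs = object$n_obs),
            class = "summary.wml_lmm")
}

#' @export
print.summary.wml_lmm <- function(x, ...) {
  cat(sprintf("REML longitudinal model (%d subjects, %d observations)\n",
              x$n_subjects, x$n_obs))
  stats::printCoefmat(x$coefficients, digits = 4)
  cat("\nEstimated residual covariance (visits x visits):\n")
  print(round(x$sigma, 4))
  invisible(x)
}

# covariance of the REML covariance parameters, 2 * inverse Hessian of
# the deviance; cached on the fit
vcov_theta <- function(fit) {
  if (!is.null(fit$cache$vcov_theta)) return(fit$cache$vcov_theta)
  H <- pracma::hessian(fit$dev_fun, fit$theta)
  H <- (H + t(H)) / 2
  eg <- eigen(H, symmetric = TRUE)
  vals <- pmax(eg$values, 1e-10 * max(abs(eg$values), 1e-10))
  V <- 2 * eg$vectors %*% diag(1 / vals, length(vals)) %*% t(eg$vectors)
  fit$cache$vcov_theta <- V
  V
}

# Satterthwaite denominator df for the scalar contrast l'beta
satt_df_contrast <- function(fit, l) {
  f <- function(th) {
    pr <- fit$parts_fun(th)
    if (is.null(pr)) return(NA_real_)
    drop(t(l) %*% pr$C %*% l)
  }
  fhat <- drop(t(l) %*% fit$vcov_beta %*% l)
  g <- pracma::grad(f, fit$theta)
  varf <- drop(t(g) %*% vcov_theta(fit) %*% g)
  if (!is.finite(varf) || varf <= 0) return(fit$n_obs - length(fit$coefficients))
  min(max(2 * fhat^2 / varf, 1), 1e7)
}

#' Hypothesis tests for the volume effect in a longitudinal fit
#'
#' Computes (a) the main effect of the predictor — under sum-to-zero time
#' coding, its average effect over the visit years, tested with the
#' interaction present; (b) the predictor x time interaction, a
#' numerator-df = (visits - 1) Wald F test; and (c) the per-year effect
#' of the predictor at each visit (main + that year's interaction
#' deviation) with Wald SEs. Denominator degrees of freedom use the
#' Satterthwaite approximation from the REML covariance-parameter
#' uncertainty.
#'
#' @param fit a [wml_lmm()] object whose formula contains
#'   `predictor * visit`.
#' @param predictor name of the predictor column in the design (default
#'   `"logV"`).
#' @return `wml_effect_tests`: list with `main` (estimate, se, F, df1,
#'   df2, p), `interaction` (F, df1, df2, p) and `per_year` data.frame.
#' @export
test_effects <- function(fit, predictor = "logV") {
  stopifnot(inherits(fit, "wml_lmm"))
  cn <- names(fit$coefficients)
  main_ix <- match(predictor, cn)
  if (is.na(main_ix)) stopf("predictor '%s' not found among coefficients", predictor)
  is_int <- vapply(strsplit(cn, ":", fixed = TRUE), function(parts)
    length(parts) == 2 && predictor %in% parts &&
      any(startsWith(setdiff(parts, predictor), fit$visit)), logical(1))
  int_ix <- which(is_int)
  if (length(int_ix) != fit$n_visits - 1)
    stopf("expected %d interaction coefficients for '%s:%s', found %d",
          fit$n_visits - 1, predictor, fit$visit, length(int_ix))

  beta <- fit$coefficients; C <- fit$vcov_beta; p <- length(beta)
  unit <- function(ix, w = 1) { l <- numeric(p); l[ix] <- w; l }

  # main effect (average over visit years under sum-to-zero coding)
  l_main <- unit(main_ix)
  se_main <- sqrt(drop(t(l_main) %*% C %*% l_main))
  df_main <- satt_df_contrast(fit, l_main)
  t_main <- beta[main_ix] / se_main
  main <- list(estimate = unname(beta[main_ix]), se = se_main,
               F = unname(t_main^2), df1 = 1, df2 = df_main,
               p = unname(2 * pt(-abs(t_main), df_main)))

  # interaction: multi-df Wald F with eigen-decomposed Satterthwaite df
  q <- length(int_ix)
  Cint <- C[int_ix, int_ix, drop = FALSE]
  bI <- beta[int_ix]
  Fint <- drop(t(bI) %*% solve(Cint) %*% bI) / q
  eg <- eigen(Cint, symmetric = TRUE)
  nus <- vapply(seq_len(q), function(j)
    satt_df_contrast(fit, unit(int_ix, eg$vectors[, j])), numeric(1))
  E <- sum(ifelse(nus > 2, nus / (nus - 2), 0))
  df2_int <- if (E > q) 2 * E / (E - q) else fit$n_obs - p
  interaction <- list(F = Fint, df1 = q, df2 = df2_int,
                      p = pf(Fint, q, df2_int, lower.tail = FALSE))

  # per-year effects: main + sum-to-zero interaction deviation
  Cs <- stats::contr.sum(fit$n_visits)
  per_year <- do.call(rbind, lapply(seq_len(fit$n_visits), function(j) {
    l <- numeric(p); l[main_ix] <- 1; l[int_ix] <- Cs[j, ]
    est <- sum(l * beta)
    se <- sqrt(drop(t(l) %*% C %*% l))
    df <- satt_df_contrast(fit, l)
    tv <- est / se
    data.frame(year = fit$visit_levels[j], estimate = est, se = se,
               df = df, t = tv, p = 2 * pt(-abs(tv), df))
  }))
  rownames(per_year) <- NULL
  structure(list(main = main, interaction = interaction, per_year = per_year,
                 predictor = predictor),
            class = "wml_effect_tests")
}

#' @export
print.wml_effect_tests <- function(x, ...) {
  cat(sprintf("Effects of %s:\n", x$predictor))
  cat(sprintf("  Main effect:  est %.4f (se %.4f), F(1, %.1f) = %.2f, p = %.4g\n",
              x$main$estimate, x$main$se, x$main$df2, x$main$F, x$main$p))
  cat(sprintf("  %s x time:    F(%d, %.1f) = %.2f, p = %.4g\n",
              x$predictor, x$interaction$df1, x$interaction$df2,
              x$interaction$F, x$interaction$p))
  cat("  Per year:\n")
  print(cbind(x$per_year[1], round(x$per_year[-1], 4)), row.names = FALSE)
  invisible(x)
}

#' Fit the full predictor-by-outcome model grid
#'
#' Fits every combination of partial lesion volume predictor, cognitive
#' outcome and conventional-volume adjustment: each model is
#' `outcome ~ log(volume) * visit + age + sex + education
#' (+ log V_FLAIR)`, and the output table reports the main effect, the
#' volume x time interaction and per-year contrasts with their
#' significance at alpha = 0.05 (two-sided, unadjusted). Failed fits are
#' recorded and the grid continues.
#'
#' @param data merged cohort data.frame (volumes in cm^3 + cognition +
#'   demographics), one row per subject-visit.
#' @param predictors volume columns tested one by one.
#' @param outcomes outcome columns.
#' @param adjust_vflair logical vector: fit without and/or with
#'   `V_FLAIR` as an extra covariate (needs a `V_FLAIR` column).
#' @param covariates adjustment covariates.
#' @param subject,visit id and time column names.
#' @param epsilon_log floor for the log transform (cm^3).
#' @param alpha significance level for the significance flags.
#' @return data.frame with one row per fitted model.
#' @export
run_model_grid <- function(data,
                           predictors = c("V_DC33", "V_DC66", "V_DC100"),
                           outcomes = c("mmse_total", "vadas_total",
                                        "compound_speed", "compound_executive",
                                        "compound_memory"),
                           adjust_vflair = c(FALSE, TRUE),
                           covariates = c("age_baseline", "sex", "education"),
                           subject = "subject_id", visit = "visit_year",
                           epsilon_log = 0.024, alpha = 0.05) {
  rows <- list()
  for (pred in predictors) for (outc in outcomes) for (adj in adjust_vflair) {
    d <- data
    d$logV <- log_transform_volume(d[[pred]], epsilon_log)
    rhs <- sprintf("logV * %s + %s", visit, paste(covariates, collapse = " + "))
    if (adj) {
      if (!"V_FLAIR" %in% names(d)) stopf("adjust_vflair = TRUE needs a V_FLAIR column")
      d$logV_FLAIR <- log_transform_volume(d$V_FLAIR, epsilon_log)
      rhs <- paste(rhs, "+ logV_FLAIR")
    }
    fml <- stats::as.formula(paste(outc, "~", rhs))
    res <- tryCatch({
      fit <- wml_lmm(fml, d, subject = subject, visit = visit)
      te <- test_effects(fit, "logV")
      py <- te$per_year
      out <- data.frame(predictor = pred, outcome = outc, vflair_adjusted = adj,
                        converged = fit$converged,
                        main_estimate = te$main$estimate, main_se = te$main$se,
                        main_F = te$main$F, main_df2 = te$main$df2,
                        main_p = te$main$p, main_sig = te$main$p < alpha,
                        int_F = te$interaction$F, int_df1 = te$interaction$df1,
                        int_df2 = te$interaction$df2, int_p = te$interaction$p,
                        int_sig = te$interaction$p < alpha,
                        error = NA_character_, stringsAsFactors = FALSE)
      for (j in seq_len(nrow(py))) {
        out[[sprintf("year%s_estimate", py$year[j])]] <- py$estimate[j]
        out[[sprintf("year%s_p", py$year[j])]] <- py$p[j]
        out[[sprintf("year%s_sig", py$year[j])]] <- py$p[j] < alpha
      }
      out
    }, error = function(e)
      data.frame(predictor = pred, outcome = outc, vflair_adjusted = adj,
                 converged = FALSE, main_estimate = NA, main_se = NA,
                 main_F = NA, main_df2 = NA, main_p = NA, main_sig = NA,
                 int_F = NA, int_df1 = NA, int_df2 = NA, int_p = NA,
                 int_sig = NA, error = conditionMessage(e),
                 stringsAsFactors = FALSE))
    rows[[length(rows) + 1]] <- res
  }
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(all_names, names(r))] <- NA; r[all_names] })
  do.call(rbind, rows)
}
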