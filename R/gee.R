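# Generalized estimating equations for clustered binary outcomes,
# logit link, exchangeable or independence working correlation
# (Liang-Zeger Fisher scoring with moment estimation of the correlation
# parameter and robust sandwich covariance).

gee_logistic <- function(y, X, id, corstr = c("exchangeable", "independence"),
                         maxit = 100, tol = 1e-10) {
  corstr <- match.arg(corstr)
  n <- length(y)
  p <- ncol(X)
  id <- as.character(id)
  cluster_rows <- split(seq_len(n), id)

  # initial values + separation screen from the ordinary logistic fit
  glm0 <- withCallingHandlers(
    glm.fit(X, y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop_degenerate(paste0(
          "Complete or quasi-complete separation detected: some criteria ",
          "perfectly predict the clinical judgement; coefficients are not ",
          "identified."))
      }
      invokeRestart("muffleWarning")
    }
  )
  beta <- glm0$coefficients
  if (any(!is.finite(beta)) || max(abs(beta)) > 30) {
    stop_degenerate("Logistic fit diverged (separation or collinear criteria).")
  }

  alpha <- 0
  phi <- 1
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    v <- mu * (1 - mu)
    r <- (y - mu) / sqrt(v)
    phi <- sum(r^2) / (n - p)
    if (corstr == "exchangeable") {
      num <- 0; npairs <- 0
      for (rows in cluster_rows) {
        ni <- length(rows)
        if (ni < 2) next
        ri <- r[rows]
        num <- num + (sum(ri)^2 - sum(ri^2)) / 2
        npairs <- npairs + ni * (ni - 1) / 2
      }
      alpha <- if (npairs > p) num / ((npairs - p) * phi) else 0
      alpha <- min(max(alpha, 0), 0.95)
    }
    H <- matrix(0, p, p)
    U <- numeric(p)
    for (rows in cluster_rows) {
      ni <- length(rows)
      Xi <- X[rows, , drop = FALSE]
      vi <- v[rows]
      Di <- Xi * vi                               # dmu/dbeta for logit
      Ri <- diag(ni) * (1 - alpha) + alpha
      Vi <- phi * (sqrt(vi) %o% sqrt(vi)) * Ri
      VinvD <- solve(Vi, Di)
      H <- H + crossprod(Di, VinvD)
      U <- U + drop(crossprod(VinvD, y[rows] - mu[rows]))
    }
    delta <- solve(H, U)
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }

  # robust sandwich covariance at the solution, with the Mancl-DeRouen
  # bias correction (the plain Liang-Zeger sandwich is anti-conservative
  # when the number of clusters is small, as with a handful of centres)
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  v <- mu * (1 - mu)
  H <- matrix(0, p, p)
  cluster_parts <- lapply(cluster_rows, function(rows) {
    ni <- length(rows)
    Xi <- X[rows, , drop = FALSE]
    vi <- v[rows]
    Di <- Xi * vi
    Ri <- diag(ni) * (1 - alpha) + alpha
    Vi <- phi * (sqrt(vi) %o% sqrt(vi)) * Ri
    VinvD <- solve(Vi, Di)
    H <<- H + crossprod(Di, VinvD)
    list(rows = rows, Di = Di, VinvD = VinvD)
  })
  Hinv <- solve(H)
  M <- matrix(0, p, p)
  for (part in cluster_parts) {
    ni <- length(part$rows)
    ei <- y[part$rows] - mu[part$rows]
    adj_e <- if (length(cluster_parts) > 1) {
      # leverage adjustment (I - H_ii)^{-1} e_i
      Hii <- part$Di %*% Hinv %*% t(part$VinvD)
      solve(diag(ni) - Hii, ei)
    } else {
      ei           # single cluster: I - H_ii is singular, use the plain sandwich
    }
    ui <- drop(crossprod(part$VinvD, adj_e))
    M <- M + ui %o% ui
  }
  robust_cov <- Hinv %*% M %*% Hinv

  list(beta = beta, robust_cov = robust_cov, naive_cov = Hinv,
       alpha = alpha, phi = phi, eta = eta, fitted = mu,
       iterations = it, converged = converged, corstr = corstr,
       n = n, n_clusters = length(cluster_rows))
}

#' Marginal logistic regression of clinical judgement on the seven criteria
#'
#' Fits the population-averaged ("multilevel") model used in the validation
#' study: clinical judgement (referral to highly specialized care, yes/no)
#' regressed on the seven criterion answers coded 0/1, with patients
#' clustered within treatment centres. Estimation is by generalized
#' estimating equations with a binomial family, logit link and an
#' exchangeable working correlation - any two patients of the same centre
#' are assumed equally correlated. Standard errors are robust (sandwich).
#' NA answers enter the design matrix as 0, mirroring the scoring rule's
#' NA-counts-as-no policy so that the model and the tool see the same data.
#'
#' With a single centre the working correlation is unidentified and the fit
#' falls back to ordinary logistic regression with a warning. Complete
#' separation raises a diagnostic error rather than diverging silently.
#'
#' @param records Patient record tibble (columns `centre_id`, `c1`..`c7`,
#'   `clinical_judgement`).
#' @param cluster_by Column defining the clusters (default `"centre_id"`).
#' @param working Working correlation: `"exchangeable"` (default) or
#'   `"independence"` (then the coefficients equal the ordinary logistic
#'   fit).
#' @param config A [tool_config()] supplying the criterion labels.
#' @return Object of class `dtpd_gee` with coefficient table, working
#'   correlation estimate `alpha`, scale `phi`, and per-record
#'   `linear_predictors` (the ROC scores). Supports [tidy()] and [glance()].
#' @export
fit_marginal_logistic <- function(records, cluster_by = "centre_id",
                                  working = c("exchangeable", "independence"),
                                  config = tool_config()) {
  working <- match.arg(working)
  records <- tibble::as_tibble(records)
  if (!cluster_by %in% names(records)) {
    stop_input(sprintf("Records lack the cluster column '%s'.", cluster_by))
  }
  norm <- normalize_answers(records, config)
  X <- cbind(`(Intercept)` = 1, (norm$ans == "yes") * 1)
  colnames(X) <- c("(Intercept)", paste0("c", 1:7))
  y <- as.numeric(parse_judgement(records))
  id <- records[[cluster_by]]
  if (length(unique(id)) < 2) {
    if (working == "exchangeable") {
      warn("Only one cluster present; falling back to ordinary logistic regression (working independence).",
           class = "dtpd_single_cluster_warning")
      working <- "independence"
    }
  }
  fit <- gee_logistic(y, X, id, corstr = working)
  se <- sqrt(diag(fit$robust_cov))
  z <- fit$beta / se
  coef_tbl <- tibble::tibble(
    term = colnames(X),
    label = c("(Intercept)", config$criterion_names),
    estimate = unname(fit$beta),
    std_error = unname(se),
    statistic = unname(z),
    p_value = 2 * pnorm(-abs(z))
  )
  structure(
    list(coefficients = coef_tbl, alpha = fit$alpha, phi = fit$phi,
         linear_predictors = fit$eta, fitted = fit$fitted,
         converged = fit$converged, iterations = fit$iterations,
         working = fit$corstr, n = fit$n, n_clusters = fit$n_clusters,
         robust_cov = fit$robust_cov),
    class = "dtpd_gee"
  )
}

#' @export
print.dtpd_gee <- function(x, digits = 4, ...) {
  cat(sprintf("<dtpd_gee> marginal logistic fit, %d records in %d cluster(s)\n",
              x$n, x$n_clusters))
  cat(sprintf("working correlation: %s (alpha = %.3f), scale phi = %.3f\n",
              x$working, x$alpha, x$phi))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dtpd_gee <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
glance.dtpd_gee <- function(x, ...) {
  tibble::tibble(n = x$n, n_clusters = x$n_clusters, working = x$working,
                 alpha = x$alpha, phi = x$phi, converged = x$converged,
                 iterations = x$iterations)
}
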