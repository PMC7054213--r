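#' Indices kept after three-standard-deviation outlier removal
#'
#' Single pass: mean and standard deviation are computed once on the full
#' input; values with `|x - mean| <= 3 sd` are kept (boundary values are
#' kept). A zero standard deviation keeps everything.
#'
#' @param values numeric vector, length >= 3.
#' @return integer vector of kept indices.
#' @export
remove_outliers <- function(values) {
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  m <- mean(values); s <- stats::sd(values)
  if (is.na(s) || s == 0) return(seq_along(values))
  which(abs(values - m) <= 3 * s)
}

#' Robust linear regression of exposure on age
#'
#' Iteratively reweighted least squares with Tukey bisquare weights
#' (tuning constant 4.685) and MAD residual scale (`1.4826 * median
#' absolute residual`), the defaults of the classic `robustfit`
#' formulation. Slope significance is an F test of the weighted fit
#' against the weighted intercept-only model.
#'
#' @param age,exposure numeric vectors (already outlier-filtered),
#'   length >= 4.
#' @return tibble with `slope` (mutations per year), `intercept`,
#'   `p_value`, `n`, `sigma` (robust residual scale).
#' @export
robust_fit <- function(age, exposure) {
  n <- length(age)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(age) == 0)
    stop("degenerate age variance", call. = FALSE)
  X <- cbind(1, age)
  beta <- stats::lm.fit(X, exposure)$coefficients
  cc <- 4.685
  w <- rep(1, n)
  for (iter in seq_len(50L)) {
    r <- exposure - X %*% beta
    s <- 1.4826 * stats::median(abs(r))
    if (s < 1e-12 * max(1, stats::median(abs(exposure)))) { w <- rep(1, n); break }
    u <- as.numeric(r) / (cc * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 3L) { w <- rep(1, n); break }
    beta_new <- stats::lm.wfit(X, exposure, w)$coefficients
    if (max(abs(beta_new - beta)) <= 1e-8 * max(1, max(abs(beta)))) {
      beta <- beta_new; break
    }
    beta <- beta_new
  }
  # slope test: F statistic on the robust fit, with the M-estimation
  # variance (psi-based sandwich and small-sample correction, as in the
  # classic robustfit implementation) replacing the naive weighted RSS
  r <- as.numeric(exposure - X %*% beta)
  s <- 1.4826 * stats::median(abs(r))
  if (s < 1e-12 * max(1, stats::median(abs(exposure)))) {
    # (near-)perfect fit: slope significance limited by machine precision
    p <- if (abs(beta[2]) > 1e-12) 0 else 1
    sigma <- 0
  } else {
    u <- r / (cc * s)
    psi <- ifelse(abs(u) < 1, r * (1 - u^2)^2, 0)
    dpsi <- ifelse(abs(u) < 1, (1 - u^2) * (1 - 5 * u^2), 0)
    m1 <- mean(dpsi)
    K <- 1 + (2 / n) * stats::var(dpsi) / m1^2
    sigma2 <- (n / (n - 2)) * mean(psi^2) / m1^2 * K^2
    XtXinv <- solve(crossprod(X))
    se_slope <- sqrt(sigma2 * XtXinv[2, 2])
    fstat <- (beta[2] / se_slope)^2
    p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
    sigma <- sqrt(sigma2)
  }
  tibble::tibble(slope = unname(beta[2]), intercept = unname(beta[1]),
                 p_value = p, n = n, sigma = sigma)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up procedure with monotonicity enforcement; results are
#' returned in input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Scan signature activities for association with age, per cancer type
#'
#' For every (signature, cancer type) stratum: remove outliers in age and
#' in exposure (union of removals, one pass each), fit the robust
#' regression of exposure on age, and collect the slope F-test p-values.
#' All p-values are corrected jointly (one Benjamini-Hochberg family
#' across signatures and cancer types). Strata with fewer than 4 samples
#' after removal are skipped and logged.
#'
#' @param exposures matrix signatures x samples (or a
#'   `signature_attribution`).
#' @param metadata tibble with `sample_id`, `age`, `cancer_type`; every
#'   exposure sample must appear.
#' @return object of class `age_scan`: `results` tibble (`signature`,
#'   `cancer_type`, `slope`, `intercept`, `p_value`, `q_value`, `n`) and
#'   `skipped` tibble with reasons.
#' @export
age_scan <- function(exposures, metadata) {
  H <- if (inherits(exposures, "signature_attribution")) exposures$exposures
       else as.matrix(exposures)
  missing <- setdiff(colnames(H), metadata$sample_id)
  if (length(missing))
    stop("metadata lacks sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  meta <- metadata[match(colnames(H), metadata$sample_id), ]
  res <- list(); skip <- list()
  for (type in sort(unique(meta$cancer_type))) {
    in_type <- which(meta$cancer_type == type)
    for (sig in rownames(H)) {
      expo <- H[sig, in_type]
      ages <- meta$age[in_type]
      if (length(in_type) < 3L) {
        skip[[length(skip) + 1L]] <- tibble::tibble(
          signature = sig, cancer_type = type, n = length(in_type),
          reason = "fewer than 3 samples in stratum")
        next
      }
      keep <- intersect(remove_outliers(ages), remove_outliers(expo))
      if (length(keep) < 4L) {
        skip[[length(skip) + 1L]] <- tibble::tibble(
          signature = sig, cancer_type = type, n = length(keep),
          reason = "fewer than 4 samples after outlier removal")
        next
      }
      if (stats::sd(ages[keep]) == 0) {
        skip[[length(skip) + 1L]] <- tibble::tibble(
          signature = sig, cancer_type = type, n = length(keep),
          reason = "degenerate age variance")
        next
      }
      fit <- robust_fit(ages[keep], expo[keep])
      res[[length(res) + 1L]] <- dplyr::mutate(
        fit, signature = sig, cancer_type = type, .before = 1)
    }
  }
  results <- if (length(res)) dplyr::bind_rows(res) else
    tibble::tibble(signature = character(), cancer_type = character(),
                   slope = numeric(), intercept = numeric(),
                   p_value = numeric(), n = integer(), sigma = numeric())
  if (nrow(results)) results$q_value <- bh_adjust(results$p_value)
  structure(list(results = results,
                 skipped = if (length(skip)) dplyr::bind_rows(skip) else
                   tibble::tibble(signature = character(),
                                  cancer_type = character(), n = integer(),
                                  reason = character())),
            class = "age_scan")
}

#' @export
print.age_scan <- function(x, ...) {
  cat("<age_scan>", nrow(x$results), "strata tested,",
      sum(x$results$q_value < 0.05), "with q < 0.05;",
      nrow(x$skipped), "skipped\n")
  invisible(x)
}
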